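test_that("TF enrichment matches the hypergeometric tail", {
  sites <- intervals("chr1", seq(0, by = 2000, length.out = 1000),
                     seq(600, by = 2000, length.out = 1000),
                     id = sprintf("s%04d", 1:1000))
  cas <- sites[1:100, ]
  # TF bound at 50% of CAS and 5% of background
  set.seed(101)
  hit <- c(sample(1:100, 50), sample(101:1000, 45))
  tfs <- list(strong = sites[hit, ], everywhere = cas)
  r <- tf_enrichment(cas, sites, tfs)
  s <- r[r$tf == "strong", ]
  expect_equal(s$prop_cas, 0.5)
  expect_lt(s$p, 1e-10)
  # one-sided enrichment p equals the upper hypergeometric tail
  expect_equal(s$p, phyper(50 - 1, 95, 905, 100, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(r$prop_cas[r$tf == "everywhere"], 1.0)
  # a TF covering equal fractions is unenriched
  set.seed(102)
  tfs2 <- list(flat = sites[c(sample(1:100, 10), sample(101:1000, 90)), ])
  expect_gt(tf_enrichment(cas, sites, tfs2)$p, 0.3)
  expect_warning(tf_enrichment(cas, sites, list(e = sites[0, ],
                                                f = cas)), "empty")
})

test_that("chromatin states use majority-bp labels and compare actives", {
  seg <- function(states)
    data.frame(chrom = "chr1", start = seq(0, by = 200,
                                           length.out = length(states)),
               end = seq(200, by = 200, length.out = length(states)),
               state = states, stringsAsFactors = FALSE)
  sn <- seg(rep(c("1", "15"), each = 25))
  sites <- intervals("chr1", c(100, 5100), c(400, 5400))
  same <- chromatin_state_compare(sites, sn, sn, active_states = "1")
  expect_equal(same$proportions[, "normal"], same$proportions[, "cancer"])
  expect_equal(same$fisher_p, 1)
  expect_equal(sum(same$proportions[, "normal"]), 1)
  # majority rule: a site covering 150 bp of state 1 and 100 bp of state 15
  sites2 <- intervals("chr1", 4850, 5100)
  sc <- seg(rep(c("1", "15"), each = 25))
  r2 <- chromatin_state_compare(sites2, sc, sc, active_states = "1")
  expect_equal(unname(r2$proportions["1", "normal"]), 1)
  # planted active-state gain in cancer is significant
  many <- intervals("chr1", seq(0, by = 200, length.out = 40),
                    seq(150, by = 200, length.out = 40))
  r3 <- chromatin_state_compare(many, seg(rep("15", 50)),
                                seg(rep(c("1", "15"), c(30, 20))),
                                active_states = "1")
  expect_lt(r3$fisher_p, 0.001)
  # uncovered sites are reported missing
  off <- intervals("chr1", 1e6, 1e6 + 100)
  r4 <- chromatin_state_compare(off, sn, sn)
  expect_equal(unname(r4$n_missing), c(1, 1))
})

test_that("depletion response ratios and Fisher comparisons behave", {
  dep <- data.frame(gene_id = sprintf("g%03d", 1:600),
                    log2fc = rep(c(-1, 1), 300),
                    significant = TRUE, stringsAsFactors = FALSE)
  same <- depletion_response_test(list(a = dep$gene_id[1:200],
                                       b = dep$gene_id[1:200]), dep)
  expect_equal(unname(same$ratios["a"]), unname(same$ratios["b"]))
  expect_equal(same$pairwise_p["a", "b"], 1)
  # planted excess of decreased genes
  dep2 <- dep
  dep2$log2fc[1:200] <- -abs(rnorm(200, 1, 0.2))
  r <- depletion_response_test(list(planted = dep$gene_id[1:200],
                                    rest = dep$gene_id[201:600]), dep2)
  expect_gt(r$ratios["planted"], r$ratios["rest"])
  expect_lt(r$pairwise_p["planted", "rest"], 0.05)
  expect_error(depletion_response_test(list(a = "nope"), dep),
               "no genes")
})

test_that("methylation differential detects the planted asymmetry", {
  ch <- small_cohort()
  aux <- generate_clinical_aux(ch, n_meth_samples = 20)
  cls <- ch$truth$class_tissue1
  lost <- ch$sites[cls == "lost", ]
  gained <- ch$sites[cls == "gained", ]
  hyper <- methylation_differential(aux$methylation, lost, ch$sites,
                                    n_draws = 100, seed = 3,
                                    direction = "hyper")
  expect_true(hyper$enriched)
  expect_gt(hyper$query_ratio, hyper$background_quantiles[[3]])
  hypo <- methylation_differential(aux$methylation, gained, ch$sites,
                                   n_draws = 100, seed = 3,
                                   direction = "hypo")
  expect_false(hypo$enriched)
  # identical populations: no loci pass the cutoff, ratios match background
  null_meth <- list(loci = ch$sites, beta_cancer = aux$methylation$beta_normal,
                    beta_normal = aux$methylation$beta_normal)
  r0 <- methylation_differential(null_meth, lost, ch$sites, n_draws = 50,
                                 seed = 3)
  expect_equal(r0$query_ratio, 0)
  bad <- aux$methylation
  bad$beta_cancer[1, 1] <- 1.2
  expect_error(methylation_differential(bad, lost, ch$sites), "\\[0, 1\\]")
})

test_that("conserved sites require high occupancy in both conditions", {
  occ <- rbind(a = rep(TRUE, 20),
               b = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               c = c(rep(TRUE, 9), FALSE, rep(TRUE, 10)))
  colnames(occ) <- sprintf("s%02d", 1:20)
  man <- data.frame(sample_id = colnames(occ),
                    condition = rep(c("cancer", "normal"), each = 10))
  cons <- conserved_sites(occ, man, min_frac = 0.9)
  expect_equal(unname(cons), c(TRUE, FALSE, TRUE))
})

test_that("mutation rates are flat under uniform mutations, enriched when planted", {
  ch <- small_cohort()
  cls <- ch$truth$class_tissue1
  classes <- list(CAS = ch$sites[cls != "stable", ],
                  other = ch$sites[cls == "stable", ])
  aux0 <- generate_clinical_aux(ch, n_mutations = 200000)
  r0 <- mutation_conserved_comparison(aux0$mutations, classes, ch$layout)
  expect_lt(abs(r0$rates["CAS"] / r0$rates["other"] - 1), 0.35)
  expect_gt(r0$pairwise_p["CAS", "other"], 0.01)
  # planted 3x enrichment at gained sites detected within 20%
  aux3 <- generate_clinical_aux(ch, n_mutations = 200000,
                                mutation_enrich_class = "gained",
                                mutation_enrich_fold = 3)
  cls3 <- list(gained = ch$sites[cls == "gained", ],
               other = ch$sites[cls == "stable", ])
  r3 <- mutation_conserved_comparison(aux3$mutations, cls3, ch$layout)
  ratio <- unname(r3$rates["gained"] / r3$rates["other"])
  expect_lt(abs(ratio - 3) / 3, 0.2)
  expect_lt(r3$pairwise_p["gained", "other"], 0.001)
  expect_error(mutation_conserved_comparison(
    aux0$mutations, list(z = ch$sites[0, ]), ch$layout), "zero total bp")
})
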