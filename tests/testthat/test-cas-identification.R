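test_that("consensus building merges peaks and filters by occupancy", {
  ps <- list(s1 = intervals("chr1", 100, 200),
             s2 = intervals("chr1", 150, 250),
             s3 = intervals("chr2", 5000, 5400))
  cons <- build_consensus_sites(ps, min_occupancy = 2)
  expect_equal(nrow(cons$sites), 1)           # single-sample peak removed
  expect_equal(cons$sites$start, 100)
  expect_equal(cons$sites$end, 250)
  expect_equal(cons$sites$occupancy, 2)
  cons1 <- build_consensus_sites(ps, min_occupancy = 1)
  expect_equal(nrow(cons1$sites), 2)
  # chromosomes Y and M excluded by default
  psy <- c(ps, list(s4 = intervals("chrY", 10, 500),
                    s5 = intervals("chrY", 20, 400)))
  expect_equal(nrow(build_consensus_sites(psy)$sites), 1)
  expect_error(build_consensus_sites(list(s1 = ps$s1)), ">= 2")
})

test_that("occupancy matrix equals the brute-force per-sample overlap", {
  set.seed(51)
  ps <- lapply(1:20, function(k) random_intervals(30, seed = 100 + k,
                                                  max_pos = 5e4))
  names(ps) <- sprintf("s%02d", 1:20)
  cons <- build_consensus_sites(ps, min_occupancy = 2)
  for (s in names(ps)) {
    want <- vapply(seq_len(nrow(cons$sites)), function(i) {
      any(ps[[s]]$chrom == cons$sites$chrom[i] &
            ps[[s]]$start < cons$sites$end[i] &
            ps[[s]]$end > cons$sites$start[i])
    }, TRUE)
    expect_equal(unname(cons$occupancy[, s]), want)
  }
  expect_true(all(rowSums(cons$occupancy) >= 2))
})

test_that("occupancy differential matches the hypergeometric enumeration", {
  occ <- rbind(site_a = c(rep(TRUE, 8), rep(FALSE, 2),
                          TRUE, rep(FALSE, 9)),
               site_b = rep(c(TRUE, FALSE), 10))
  colnames(occ) <- sprintf("x%02d", 1:20)
  man <- data.frame(sample_id = colnames(occ),
                    condition = rep(c("cancer", "normal"), each = 10))
  d <- occupancy_differential(occ, man)
  expect_equal(d$po_cancer[1], 0.8)
  expect_equal(d$po_normal[1], 0.1)
  expect_equal(d$poc[1], 0.7)
  expect_equal(d$p_occ[1], oracle_fisher2x2(8, 10, 1, 10), tolerance = 1e-10)
  # identical presence in both conditions
  expect_equal(d$poc[2], 0)
  expect_equal(d$p_occ[2], 1)
  expect_error(occupancy_differential(occ[, 1:10], man[1:10, ]), ">= 2")
})

test_that("intensity differential equals the Welch t-test per site", {
  set.seed(61)
  x <- matrix(rnorm(50 * 14, mean = 5), 50, 14,
              dimnames = list(sprintf("s%02d", 1:50),
                              sprintf("x%02d", 1:14)))
  x[1:10, 1:7] <- x[1:10, 1:7] + 2
  man <- data.frame(sample_id = colnames(x),
                    condition = rep(c("cancer", "normal"), each = 7))
  d <- intensity_differential(x, man)
  for (i in c(1, 5, 20, 50)) {
    tt <- t.test(x[i, 1:7], x[i, 8:14])
    expect_equal(d$p_int[i], tt$p.value, tolerance = 1e-12)
    expect_equal(d$logfc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  # identical groups give logFC 0 and p 1 under the zero-variance rule
  y <- matrix(3, 2, 8, dimnames = list(c("a", "b"), sprintf("y%d", 1:8)))
  man2 <- data.frame(sample_id = colnames(y),
                     condition = rep(c("cancer", "normal"), each = 4))
  d2 <- intensity_differential(y, man2)
  expect_equal(d2$logfc, c(0, 0))
  expect_equal(d2$p_int, c(1, 1))
})

test_that("planted intensity shifts are recovered within tolerance", {
  hit <- vapply(1:1000, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(40, 5, 0.3), 1, 40)
    x[1, 1:20] <- x[1, 1:20] + 1
    abs(mean(x[1, 1:20]) - mean(x[1, 21:40]) - 1) <= 0.2
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("call_cas applies the dual-filter and sign-concordance rule", {
  d <- data.frame(
    site_id = c("a", "b", "c", "d"),
    po_cancer = c(0.85, 0.8, 0.75, 0.1), po_normal = c(0.15, 0.2, 0.15, 0.8),
    poc = c(0.7, 0.6, 0.6, -0.7),
    p_occ = c(1e-5, 1e-4, 1e-4, 1e-5), q_occ = c(1e-4, 1e-3, 1e-3, 1e-4),
    logfc = c(1.6, 0.4, -1.2, -1.5),
    t = 0, p_int = c(1e-4, 0.5, 1e-3, 1e-4),
    q_int = c(1e-3, 0.6, 1e-2 / 2, 1e-3))
  cas <- call_cas(d)
  expect_equal(cas$site_id, c("a", "d"))
  expect_equal(cas$direction, c("gained", "lost"))
  # b passes occupancy only; c is discordant (POC +, logFC -): excluded
  d2 <- d; d2$poc[2] <- 0.4
  expect_false("b" %in% call_cas(d2)$site_id)  # |POC| <= 0.5 fails
})

test_that("CAS recovery on a reduced default-effect cohort is accurate", {
  ch <- small_cohort()
  d <- cas_differential(ch$occupancy$tissue1, ch$intensity$tissue1,
                        ch$manifest, sites = ch$sites)
  cas <- call_cas(d)
  truth <- ch$truth$class_tissue1
  called <- ch$truth$site_id %in% cas$site_id
  expect_gte(sum(called & truth != "stable") / sum(truth != "stable"), 0.85)
  expect_lte(sum(called & truth == "stable") / max(1, nrow(cas)), 0.05)
  dir_truth <- truth[match(cas$site_id, ch$truth$site_id)]
  tp <- dir_truth != "stable"
  expect_identical(cas$direction[tp], dir_truth[tp])
})

test_that("simpson index follows its set-overlap definition", {
  x <- intervals("chr1", seq(0, 900, 100), seq(50, 950, 100),
                 id = sprintf("x%d", 1:10))
  expect_equal(simpson_index(x, x), 1)
  y <- intervals("chr2", 0, 50, id = "y1")
  expect_equal(simpson_index(x, y), 0)
  # |X n Y| = 5, |X| = 10, |Y| = 40 -> 0.5
  y2 <- intervals("chr1", c(seq(0, 400, 100), seq(5000, 8400, 100)),
                  c(seq(20, 420, 100), seq(5020, 8420, 100)))
  expect_equal(simpson_index(x, y2), 0.5)
  expect_equal(simpson_index(y2, x), 0.5)
  expect_error(simpson_index(x, x[0, ]), "empty")
  m <- simpson_matrix(list(a = x, b = y2))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(diag(m), c(a = 1, b = 1))
})

test_that("per-tissue planted CAS sets are tissue-specific", {
  ch <- small_cohort()
  sets <- lapply(ch$tissues, function(tt)
    ch$sites[ch$truth[[paste0("class_", tt)]] != "stable", ])
  names(sets) <- ch$tissues
  m <- simpson_matrix(sets)
  expect_true(all(m[upper.tri(m)] < 0.1))
})

test_that("CTCF change classification covers the 2x2 of overlaps", {
  sites <- intervals("chr1", c(0, 1000, 2000, 3000),
                     c(100, 1100, 2100, 3100))
  cn <- intervals("chr1", c(1050, 2050), c(1090, 2090))
  cc <- intervals("chr1", c(2010, 3010), c(2060, 3060))
  r <- ctcf_change_classify(sites, cn, cc)
  expect_equal(as.character(r$labels),
               c("non-CTCF", "lost-CTCF", "stable-CTCF", "gained-CTCF"))
  expect_equal(sum(r$proportions), 1)
})

test_that("cas_result methods print and plot", {
  ch <- small_cohort()
  d <- cas_differential(ch$occupancy$tissue1, ch$intensity$tissue1,
                        ch$manifest, sites = ch$sites)
  expect_output(print(d), "CAS differential result")
  s <- summary(d)
  expect_output(print(s), "gained")
  expect_equal(s$n_cas, s$n_gained + s$n_lost)
  pdf(NULL)
  expect_silent(plot(d))
  dev.off()
})
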