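test_that("compartment switch classification follows the stated rule", {
  mk <- function(en, ec) {
    sites <- intervals("chr1", seq(0, by = 50000,
                                   length.out = length(en)) + 10000,
                       seq(0, by = 50000, length.out = length(en)) + 10600,
                       id = sprintf("s%d", seq_along(en)))
    list(sites = sites,
         pc1_cancer = list(chr1 = list(signal_track("chr1", 50000, ec))),
         pc1_normal = list(chr1 = list(signal_track("chr1", 50000, en))))
  }
  x <- mk(en = c(-0.1, 0.02, 0.3, 0.4, -0.5, NA),
          ec = c(0.1, -0.02, 0.5, -0.4, -0.2, 0.1))
  sw <- compartment_switch_classify(x$sites, x$pc1_cancer, x$pc1_normal)
  expect_equal(as.character(sw$calls$class),
               c("B-to-A",      # signs flip, |diff| = 0.2 > 0.05
                 "stable-B",    # |diff| = 0.04 fails the threshold
                 "stable-A", "A-to-B", "stable-B", "undefined"))
  expect_equal(sum(sw$proportions), 1)
  # replicate averaging: E is the mean over replicate tracks
  y <- list(chr1 = list(signal_track("chr1", 50000, c(0.3, 0, 0, 0, 0, 0)),
                        signal_track("chr1", 50000, c(-0.5, 0, 0, 0, 0, 0))))
  sw2 <- compartment_switch_classify(x$sites[1, ], y, x$pc1_normal)
  expect_equal(sw2$calls$e_cancer[1], -0.1)
})

test_that("insulation score matches the brute-force diamond oracle", {
  # uniform matrix: IS constant 0
  u <- contact_matrix("chr1", 0, 50000, matrix(4, 40, 40))
  isu <- insulation_score(u, window_bins = 5)
  expect_true(all(abs(isu$values[6:35]) < 1e-12))
  expect_true(all(is.na(isu$values[c(1:5, 36:40)])))
  # two-block matrix: minimum at the junction
  tt <- two_tad_matrix(n = 60, junction = 30)
  ist <- insulation_score(tt, window_bins = 8)
  expect_equal(which.min(ist$values), 30, tolerance = 1)
  # random matrices vs the double-loop oracle at 1e-9
  for (s in 1:3) {
    set.seed(90 + s)
    n <- sample(60:120, 1)
    m <- matrix(rexp(n * n), n, n); m <- m + t(m)
    cm <- contact_matrix("chr1", 0, 50000, m)
    w <- sample(3:10, 1)
    got <- insulation_score(cm, window_bins = w)
    dm <- oracle_diamond_means(m, w)
    want <- log2(dm / mean(dm, na.rm = TRUE))
    expect_equal(got$values, want, tolerance = 1e-9)
  }
  expect_error(insulation_score(
    contact_matrix("chr1", 0, 5e4, matrix(0, 30, 30))), "all-zero")
})

test_that("boundary calling keeps deep, separated insulation minima", {
  tt <- two_tad_matrix(n = 60, junction = 30)
  ist <- insulation_score(tt, window_bins = 8)
  b <- boundary_call(ist, depth_sd = 1, min_sep_bins = 3)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin, 30)
  # uniform insulation: nothing called
  flat <- signal_track("chr1", 50000, rep(0, 50))
  expect_equal(nrow(boundary_call(flat)), 0)
  # two minima one bin apart: only the deeper survives
  v <- rep(0, 30); v[10] <- -3; v[11] <- -2.5
  b2 <- boundary_call(signal_track("chr1", 50000, v), depth_sd = 1,
                      min_sep_bins = 3)
  expect_equal(b2$bin, 10)
})

test_that("ISC is the per-site track difference with exact stratification", {
  v <- c(0.2, -1.5, 0.4, 0.1, 0.3, -0.2, 0.15, 0.5)
  isn <- list(chr1 = signal_track("chr1", 50000, v))
  isc_same <- isc_site_stats(isn, isn,
                             intervals("chr1", c(10000, 160000),
                                       c(10600, 160600)))
  expect_equal(isc_same$isc, c(0, 0))
  isc2 <- list(chr1 = signal_track("chr1", 50000, v + c(0.5, 0, 0.3, 0,
                                                        0, 0, 0, 0)))
  sites <- intervals("chr1", seq(0, 350000, 50000) + 10000,
                     seq(0, 350000, 50000) + 11000,
                     id = sprintf("s%d", 1:8))
  bnd <- data.frame(chrom = "chr1", start = 50000, end = 100000, bin = 2)
  r <- isc_site_stats(isc2, isn, sites, bnd)
  expect_equal(r$isc, c(0.5, 0, 0.3, 0, 0, 0, 0, 0))
  # sites within one bin of the boundary bin (bins 1-3) are 'boundary'
  expect_equal(r$stratum, c(rep("boundary", 3), rep("within-TAD", 5)))
  expect_equal(sort(unique(r$summary$stratum)),
               c("boundary", "within-TAD"))
})

test_that("APA scores uniform matrices at 1 and recovers planted folds", {
  u <- contact_matrix("chr1", 0, 50000, matrix(3, 80, 80))
  loops <- data.frame(chrom1 = "chr1", start1 = 20 * 50000,
                      end1 = 21 * 50000, chrom2 = "chr1",
                      start2 = 45 * 50000, end2 = 46 * 50000)
  expect_equal(apa_score(u, loops)$apa_score, 1)
  expect_equal(apa_score(u, loops, expected_normalize = FALSE)$apa_score, 1)
  # planted 5x loops recovered within 15%
  cm <- generate_contacts_and_loops(seed = 6, loop_fold = 5)
  sc <- vapply(cm$normal, function(m)
    apa_score(m, cm$loops)$apa_score, 0)
  expect_lt(abs(mean(sc) - 5) / 5, 0.15)
  # loops too close to the edge are skipped and counted
  edge <- rbind(loops, data.frame(chrom1 = "chr1", start1 = 0, end1 = 50000,
                                  chrom2 = "chr1", start2 = 2 * 50000,
                                  end2 = 3 * 50000))
  r <- apa_score(u, edge)
  expect_equal(r$n_used, 1)
  expect_equal(r$n_skipped, 1)
  expect_error(apa_score(u, edge[2, , drop = FALSE]), "usable")
})

test_that("condition APA comparison normalizes normal to 1", {
  cm <- generate_contacts_and_loops(seed = 7, strength_ratio = 2)
  cas_loops <- cm$loops[cm$loops$cas_linked, ]
  r <- apa_compare(cm$cancer, cm$normal, cas_loops)
  expect_gt(r$normalized_ratio, 1)
  expect_lt(r$p_value, 0.05)
  rn <- apa_compare(cm$normal, cm$normal, cas_loops)
  expect_equal(rn$normalized_ratio, 1)  # normal vs itself is 1 by definition
  # planted direction recovered across independent replicates
  dir_ok <- vapply(1:15, function(s) {
    g <- generate_contacts_and_loops(seed = 100 + s, strength_ratio = 2,
                                     n_rep = 2)
    apa_compare(g$cancer, g$normal,
                g$loops[g$loops$cas_linked, ])$normalized_ratio > 1
  }, TRUE)
  expect_gte(mean(dir_ok), 0.95)
})

test_that("loop overlap ratios normalize by the same-tissue overlap", {
  cas_a <- intervals("chr1", c(1e5, 2e5, 3e5), c(1e5 + 600, 2e5 + 600,
                                                 3e5 + 600))
  loops_a <- data.frame(chrom1 = "chr1", start1 = c(1e5, 2e5),
                        end1 = c(1e5 + 600, 2e5 + 600), chrom2 = "chr1",
                        start2 = c(2e6, 3e6), end2 = c(2e6 + 600, 3e6 + 600))
  loops_b <- data.frame(chrom1 = "chr1", start1 = 9e6, end1 = 9e6 + 600,
                        chrom2 = "chr1", start2 = 9.5e6, end2 = 9.5e6 + 600)
  r <- loop_overlap_ratio(list(a = cas_a, b = cas_a),
                          list(a = loops_a, b = loops_a), pad_bp = 0)
  expect_equal(unname(r), matrix(1, 2, 2), ignore_attr = TRUE)
  r2 <- loop_overlap_ratio(list(a = cas_a, b = cas_a),
                           list(a = loops_a, b = loops_b), pad_bp = 0)
  expect_equal(r2["a", "b"], 0)   # anchors disjoint from CAS
  # brute-force check of a random instance
  set.seed(95)
  cas_r <- random_intervals(40, seed = 96, chroms = "chr1", max_pos = 9e4)
  lp <- data.frame(chrom1 = "chr1", start1 = s1 <- sample.int(9e4, 15),
                   end1 = s1 + 300, chrom2 = "chr1",
                   start2 = s2 <- sample.int(9e4, 15), end2 = s2 + 300)
  rr <- loop_overlap_ratio(list(a = cas_r, x = cas_r),
                           list(a = lp, x = lp), pad_bp = 100)
  anch <- data.frame(chrom = "chr1", start = pmax(0, c(s1, s2) - 100),
                     end = c(s1 + 300, s2 + 300) + 100)
  hits <- vapply(seq_len(nrow(cas_r)), function(i)
    any(anch$start < cas_r$end[i] & anch$end > cas_r$start[i]), TRUE)
  expect_equal(rr["a", "x"], sum(hits) / sum(hits))
  # zero same-tissue overlap is flagged undefined
  r3 <- loop_overlap_ratio(list(a = cas_a, b = cas_a),
                           list(a = loops_b, b = loops_a), pad_bp = 0)
  expect_true(all(is.na(r3["a", ])))
  expect_equal(attr(r3, "undefined_rows"), "a")
})

test_that("VC-sqrt normalization preserves symmetry and positivity", {
  set.seed(97)
  m <- matrix(rpois(400, 6), 20, 20); m <- m + t(m)
  v <- vc_sqrt_normalize(contact_matrix("chr1", 0, 5e4, m))
  expect_lt(max(abs(v$mat - t(v$mat))), 1e-9)
  expect_true(all(v$mat >= 0))
})
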