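test_that("BED round trip is lossless and ordered", {
  x <- intervals(c("chr2", "chr1", "chr1"), c(500, 100, 300),
                 c(900, 200, 450), id = c("a", "b", "c"),
                 strand = c("+", "-", "."))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(y$start, c(100, 300, 500))
  expect_equal(y$id, c("b", "c", "a"))
  expect_equal(y$strand, c("-", ".", "+"))
  # write-then-read of the re-read set is identical
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(y, path2)
  expect_equal(read_bed(path2), y)
})

test_that("malformed BED lines fail with the line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ts1", "chr1\t200\t100\ts2"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t100\t200", "chr1\tabc\t300"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "line 1")
})

test_that("interval validation enforces half-open invariants", {
  expect_error(intervals("chr1", 200, 100), "start >= end")
  expect_error(intervals("chr1", -5, 100), "negative")
  layout <- genome_layout(c(chr1 = 1000))
  expect_error(intervals("chr2", 0, 10, layout = layout), "absent")
  expect_error(intervals("chr1", 900, 1100, layout = layout), "beyond")
  expect_silent(intervals("chr1", 0, 1000, layout = layout))
})

test_that("overlap_query matches the all-pairs oracle and half-open rules", {
  a <- intervals("chr1", 100, 200, id = "x")
  b <- intervals("chr1", c(150, 200), c(250, 300), id = c("y", "z"))
  hits <- overlap_query(a, b)
  expect_equal(nrow(hits), 1)            # [100,200) vs [200,300) no pair
  expect_equal(hits$overlap_bp, 50)
  ra <- random_intervals(100, seed = 11)
  rb <- random_intervals(100, seed = 12)
  got <- overlap_query(ra, rb)
  want <- oracle_overlap(ra, rb)
  key <- function(d) sort(paste(d$a_id, d$b_id, d$overlap_bp))
  expect_equal(key(got), key(want))
  # min_overlap_bp honored
  got5 <- overlap_query(ra, rb, min_overlap_bp = 50)
  expect_equal(key(got5), key(want[want$overlap_bp >= 50, ]))
})

test_that("nearest_tss_distance matches the exhaustive scan", {
  g <- gene_models(c("g1", "g2"), c("chr1", "chr1"), c(1500, 980),
                   c(3000, 1600), strand = c("+", "+"))
  s <- intervals("chr1", 900, 1100, id = "s1")
  d <- nearest_tss_distance(s, g, cap_bp = 10000)
  expect_equal(d$distance[d$gene_id == "g1"], 500)   # mid 1000 vs TSS 1500
  expect_equal(d$distance[d$gene_id == "g2"], 0)     # TSS inside site
  sites <- random_intervals(50, seed = 21)
  set.seed(22)
  genes <- gene_models(sprintf("g%02d", 1:50),
                       sample(c("chr1", "chr2"), 50, TRUE),
                       st <- sample.int(9e4, 50), st + 5000)
  got <- nearest_tss_distance(sites, genes, cap_bp = 20000)
  want <- oracle_tss_distance(sites, genes, cap = 20000)
  key <- function(d) sort(paste(d$site_id, d$gene_id, d$distance))
  expect_equal(key(got), key(want))
  expect_error(nearest_tss_distance(sites, genes[0, ], 1000), "empty gene")
})

test_that("annotate_context applies the promoter > exon > intron rule", {
  exons <- intervals("chr1", c(10000, 14000), c(10800, 15000),
                     id = c("g1", "g1"))
  g <- gene_models("g1", "chr1", 10000, 15000, strand = "+", exons = exons)
  lab <- annotate_context(
    intervals("chr1", c(9000, 14200, 12000, 500000),
              c(9100, 14300, 12100, 500100)), g)
  expect_equal(as.character(lab),
               c("promoter", "exonic", "intronic", "intergenic"))
  # a site in both the promoter window and an exon is promoter
  lab2 <- annotate_context(intervals("chr1", 10050, 10150), g)
  expect_equal(as.character(lab2), "promoter")
})

test_that("bh_adjust equals the step-up oracle and is well-behaved", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(31)
  for (k in 1:5) {
    p <- runif(50)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p-rank
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("aggregate_signal_profile matches per-site extraction", {
  tr <- signal_track("chr1", 100, rep(2.5, 1000))
  sites <- intervals("chr1", c(20000, 50000), c(20200, 50200),
                     id = c("s1", "s2"))
  pm <- aggregate_signal_profile(sites, tr, flank_bp = 2000, bin_bp = 100)
  expect_true(all(abs(pm$mean_profile - 2.5) < 1e-12))
  # spike at one site midpoint peaks at offset 0
  v <- rep(0, 1000); v[202] <- 10       # bin of position 20100 (mid of s1)
  tr2 <- signal_track("chr1", 100, v)
  pm2 <- aggregate_signal_profile(sites[1, ], tr2, 2000, 100)
  expect_equal(pm2$offsets[which.max(pm2$mean_profile)], 50)
  # random track vs direct bin lookup
  set.seed(41)
  tr3 <- signal_track("chr1", 100, rnorm(1000))
  pm3 <- aggregate_signal_profile(sites, tr3, 1000, 100)
  for (s in 1:2) {
    mid <- floor((sites$start[s] + sites$end[s]) / 2)
    want <- tr3$values[(mid - 1000 + seq(0, 1900, 100)) %/% 100 + 1]
    expect_equal(unname(pm3$values[s, ]), want)
  }
  # off-track sites are flagged missing, not dropped
  far <- intervals("chr2", 1000, 1200, id = "far")
  pm4 <- aggregate_signal_profile(rbind(sites, far), tr, 1000, 100)
  expect_equal(pm4$n_missing_sites, 1)
  expect_equal(nrow(pm4$values), 3)
})

test_that("bedGraph, BEDPE, contact-matrix and layout IO round trip", {
  tr <- signal_track("chr3", 50, c(1.5, NA, -2, 0.25), start_offset = 100)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  tr2 <- read_bedgraph(path)
  expect_equal(tr2$values, tr$values)
  expect_equal(tr2$start_offset, 100)
  expect_equal(tr2$bin_size, 50)

  lp <- data.frame(chrom1 = "chr1", start1 = c(1000, 5000),
                   end1 = c(2000, 6000), chrom2 = "chr1",
                   start2 = c(50000, 90000), end2 = c(51000, 91000),
                   id = c("l1", "l2"), stringsAsFactors = FALSE)
  pb <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(lp, pb)
  expect_equal(read_bedpe(pb)[names(lp)], lp)

  set.seed(7)
  m <- matrix(rpois(100, 4), 10, 10)
  m <- m + t(m)
  cm <- contact_matrix("chr2", 1e6, 5e4, m)
  pc <- withr::local_tempfile(fileext = ".txt")
  write_contact_matrix(cm, pc)
  cm2 <- read_contact_matrix(pc)
  expect_equal(cm2$mat, cm$mat)
  expect_equal(cm2$start_bp, 1e6)

  gl <- genome_layout(c(chr1 = 12345, chr2 = 999))
  pg <- withr::local_tempfile(fileext = ".tsv")
  write_genome_layout(gl, pg)
  expect_equal(read_genome_layout(pg), gl)
})
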