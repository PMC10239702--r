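# Independent brute-force oracles used to check the package's interval and
# statistical kernels. These deliberately share no code with the package
# internals.

# all-pairs overlap scan under half-open semantics
oracle_overlap <- function(a, b, min_bp = 1) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_bp)
      out <- rbind(out, data.frame(a_id = a$id[i], b_id = b$id[j],
                                   overlap_bp = ov))
  }
  out
}

# exhaustive site x gene TSS distance scan
oracle_tss_distance <- function(sites, genes, cap) {
  out <- NULL
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(genes))) {
    if (sites$chrom[i] != genes$chrom[j]) next
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    d <- abs(mid - genes$tss[j])
    if (genes$tss[j] >= sites$start[i] && genes$tss[j] < sites$end[i]) d <- 0
    if (d <= cap)
      out <- rbind(out, data.frame(site_id = sites$id[i],
                                   gene_id = genes$gene_id[j], distance = d))
  }
  out
}

# step-up BH rule applied literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables as or less probable than the observed one
oracle_fisher2x2 <- function(a, n1, b, n2) {
  k <- a + b
  xs <- max(0, k - n2):min(n1, k)
  pr <- dhyper(xs, n1, n2, k)
  sum(pr[pr <= dhyper(a, n1, n2, k) * (1 + 1e-7)])
}

# ARI by direct pair counting (agreement of sample pairs), independent of
# the contingency-sum formula
oracle_ari <- function(x, y) {
  n <- length(x)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tx <- x[i] == x[j]; ty <- y[i] == y[j]
    if (tx && ty) s11 <- s11 + 1
    else if (!tx && !ty) s00 <- s00 + 1
    else if (tx) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- 0.5 * ((s11 + s10) + (s11 + s01))
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# per-bin diamond means of a contact matrix by explicit double loop
oracle_diamond_means <- function(mat, w) {
  n <- nrow(mat)
  dm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    acc <- 0
    for (r in (i - w):(i - 1)) for (cc in (i + 1):(i + w))
      acc <- acc + mat[r, cc]
    dm[i] <- acc / (w * w)
  }
  dm
}

# random interval set on a small genome
random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, width = c(50, 500)) {
  set.seed(seed)
  w <- sample(width[1]:width[2], n, TRUE)
  start <- sample.int(max_pos - max(w), n, TRUE)
  intervals(sample(chroms, n, TRUE), start, start + w,
            id = sprintf("iv%03d", seq_len(n)))
}
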