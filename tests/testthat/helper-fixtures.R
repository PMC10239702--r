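# Small reusable fixtures built in code. The reduced cohort keeps the
# default effect sizes and per-group sample counts but fewer sites on a
# smaller genome, so module tests stay fast while exercising the same
# statistical regime as the full defaults.

small_cohort_config <- function(seed = 1, n_sites = 800, n_tissues = 2,
                                ...) {
  cohort_config(seed = seed, n_sites = n_sites, n_tissues = n_tissues,
                genome = genome_layout(c(chr1 = 8e6, chr2 = 8e6)), ...)
}

# memoized small cohort + expression shared across test files
.fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort_chip(small_cohort_config())
  .fixture_env$cohort
}
small_genedata <- function() {
  if (is.null(.fixture_env$genedata))
    .fixture_env$genedata <- generate_expression(small_cohort(),
                                                 n_genes = 3000)
  .fixture_env$genedata
}

# deterministic two-TAD contact matrix: two dense blocks joined at a bin
two_tad_matrix <- function(n = 60, junction = 30, inside = 10, outside = 1) {
  blk <- c(rep(1, junction), rep(2, n - junction))
  m <- matrix(outside, n, n)
  m[outer(blk, blk, "==")] <- inside
  contact_matrix("chr1", 0, 50000, m)
}
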