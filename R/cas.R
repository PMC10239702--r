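# Cancer-aberrant cohesin site (CAS) calling: consensus-site construction,
# dual differential testing (Fisher on peak occupancy, Welch t on log2 read
# intensity, both BH-adjusted) and threshold-based gained/lost calls.

#' Build consensus cohesin sites from per-sample peak sets
#'
#' Peaks are merged across samples whenever they overlap by >= 1 bp; each
#' merged site's occupancy is the number of samples contributing at least one
#' overlapping peak, and sites below `min_occupancy` are removed.
#' Chromosomes Y and M are excluded by default.
#'
#' @param peak_sets Named list of interval data frames, one per sample.
#' @param min_occupancy Minimum number of supporting samples (inclusive).
#' @param exclude_chroms Chromosomes dropped before merging.
#' @return List: `sites` (consensus interval data frame with `id` and
#'   `occupancy`), `occupancy` (sites x samples logical matrix).
#' @export
build_consensus_sites <- function(peak_sets, min_occupancy = 2,
                                  exclude_chroms = c("chrY", "chrM")) {
  if (!length(peak_sets) || sum(vapply(peak_sets, nrow, 0L)) == 0)
    stop("no peaks supplied")
  if (length(peak_sets) < 2) stop("need peak sets from >= 2 samples")
  if (is.null(names(peak_sets)))
    names(peak_sets) <- sprintf("sample_%03d", seq_along(peak_sets))
  peak_sets <- lapply(peak_sets, function(p)
    p[!p$chrom %in% exclude_chroms, , drop = FALSE])
  pooled <- do.call(rbind, lapply(names(peak_sets), function(s) {
    p <- peak_sets[[s]]
    if (!nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end, sample = s,
               stringsAsFactors = FALSE)
  }))
  merged <- GenomicRanges::reduce(.as_gr(pooled), ignore.strand = TRUE)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged), stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  sites$id <- sprintf("site_%05d", seq_len(nrow(sites)))

  occ <- matrix(FALSE, nrow(sites), length(peak_sets),
                dimnames = list(sites$id, names(peak_sets)))
  for (s in names(peak_sets))
    occ[, s] <- .overlaps_any(sites, peak_sets[[s]])
  keep <- rowSums(occ) >= min_occupancy
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  occ <- occ[keep, , drop = FALSE]
  sites$occupancy <- rowSums(occ)
  list(sites = sites, occupancy = occ)
}

# two-sided Fisher exact p for many 2x2 tables (a, n1 - a; b, n2 - b),
# cached over distinct (a, b) pairs since n1, n2 are fixed cohort sizes
.fisher_vec <- function(a, n1, b, n2) {
  key <- a * (n2 + 1) + b
  uk <- !duplicated(key)
  pu <- mapply(function(x, y)
    stats::fisher.test(matrix(c(x, n1 - x, y, n2 - y), 2))$p.value,
    a[uk], b[uk])
  unname(pu[match(key, key[uk])])
}

.split_conditions <- function(mat, manifest) {
  m <- manifest[match(colnames(mat), manifest$sample_id), ]
  if (anyNA(m$condition)) stop("samples missing from manifest")
  list(cancer = which(m$condition == "cancer"),
       normal = which(m$condition == "normal"))
}

#' Differential peak occupancy
#'
#' Per site, the binomial peak occupancy `PO = N_observed / N_all` per
#' condition, its change `POC = PO_cancer - PO_normal`, a two-sided Fisher
#' exact test on the 2x2 presence table and BH adjustment across sites.
#'
#' @param occ Sites x samples logical matrix.
#' @param manifest Data frame `sample_id`, `condition` (`cancer`/`normal`).
#' @return Data frame `site_id, po_cancer, po_normal, poc, p_occ, q_occ`.
#' @export
occupancy_differential <- function(occ, manifest) {
  idx <- .split_conditions(occ, manifest)
  if (length(idx$cancer) < 2 || length(idx$normal) < 2)
    stop("each condition needs >= 2 samples")
  xc <- rowSums(occ[, idx$cancer, drop = FALSE])
  xn <- rowSums(occ[, idx$normal, drop = FALSE])
  nc <- length(idx$cancer); nn <- length(idx$normal)
  p <- .fisher_vec(xc, nc, xn, nn)
  data.frame(site_id = rownames(occ), po_cancer = xc / nc,
             po_normal = xn / nn, poc = xc / nc - xn / nn,
             p_occ = p, q_occ = bh_adjust(p),
             stringsAsFactors = FALSE)
}

# vectorized Welch (unequal-variance) t-test over matrix rows
.welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # zero variance, equal means: no evidence, p = 1
  list(logfc = mx - my, t = t, df = df, p = p)
}

#' Differential read intensity
#'
#' Per site, `logFC = mean(log2 cancer) - mean(log2 normal)` and a two-sided
#' Welch t-test, BH-adjusted across sites.
#'
#' @param intens Sites x samples matrix of log2 read intensity.
#' @param manifest Data frame `sample_id`, `condition`.
#' @return Data frame `site_id, logfc, t, p_int, q_int`.
#' @export
intensity_differential <- function(intens, manifest) {
  idx <- .split_conditions(intens, manifest)
  if (length(idx$cancer) < 2 || length(idx$normal) < 2)
    stop("each condition needs >= 2 samples")
  if (any(!is.finite(intens))) stop("non-finite intensities")
  w <- .welch_rows(intens[, idx$cancer, drop = FALSE],
                   intens[, idx$normal, drop = FALSE])
  data.frame(site_id = rownames(intens), logfc = w$logfc, t = w$t,
             p_int = w$p, q_int = bh_adjust(w$p), stringsAsFactors = FALSE)
}

#' Joint differential analysis of a cohort tissue
#'
#' Runs [occupancy_differential()] and [intensity_differential()] on paired
#' matrices and returns the merged per-site table as a classed result.
#'
#' @param occ Sites x samples logical occupancy matrix.
#' @param intens Sites x samples log2 intensity matrix (same site order).
#' @param manifest Data frame `sample_id`, `condition`.
#' @param sites Optional interval data frame carrying the site coordinates.
#' @return Data frame of class `cas_result` with both tests' columns.
#' @export
cas_differential <- function(occ, intens, manifest, sites = NULL) {
  if (!identical(rownames(occ), rownames(intens)))
    stop("occupancy and intensity matrices must share site order")
  d <- cbind(occupancy_differential(occ, manifest),
             intensity_differential(intens, manifest)[, -1])
  attr(d, "sites") <- sites
  class(d) <- c("cas_result", class(d))
  d
}

#' Call gained and lost CASs from a differential table
#'
#' A site is a CAS iff both tests pass their thresholds and the occupancy and
#' intensity changes agree in sign; the sign gives the direction.
#'
#' @param diff A [cas_differential()] result (or equivalent data frame).
#' @param thresholds Named list `poc`, `q_occ`, `logfc`, `q_int`.
#' @return `diff` restricted to CASs, with a `direction` column
#'   (`gained`/`lost`).
#' @export
call_cas <- function(diff, thresholds = list(poc = 0.5, q_occ = 0.01,
                                             logfc = 1, q_int = 0.01)) {
  pass <- abs(diff$poc) > thresholds$poc & diff$q_occ < thresholds$q_occ &
    abs(diff$logfc) > thresholds$logfc & diff$q_int < thresholds$q_int &
    sign(diff$poc) == sign(diff$logfc)
  out <- diff[pass, , drop = FALSE]
  out$direction <- ifelse(out$poc > 0, "gained", "lost")
  class(out) <- "data.frame"
  attr(out, "thresholds") <- thresholds
  sites <- attr(diff, "sites")
  if (!is.null(sites))
    attr(out, "sites") <- sites[match(out$site_id, sites$id), , drop = FALSE]
  out
}

#' @export
print.cas_result <- function(x, ...) {
  cat("CAS differential result: ", nrow(x), " sites\n", sep = "")
  cat("  |POC| > 0.5 & q < 0.01: ",
      sum(abs(x$poc) > 0.5 & x$q_occ < 0.01), " sites\n", sep = "")
  cat("  |logFC| > 1 & q < 0.01: ",
      sum(abs(x$logfc) > 1 & x$q_int < 0.01), " sites\n", sep = "")
  invisible(x)
}

#' @export
summary.cas_result <- function(object, thresholds = list(poc = 0.5,
                                                         q_occ = 0.01,
                                                         logfc = 1,
                                                         q_int = 0.01),
                               ...) {
  cas <- call_cas(object, thresholds)
  out <- list(n_sites = nrow(object), n_cas = nrow(cas),
              n_gained = sum(cas$direction == "gained"),
              n_lost = sum(cas$direction == "lost"),
              thresholds = thresholds)
  class(out) <- "summary.cas_result"
  out
}

#' @export
print.summary.cas_result <- function(x, ...) {
  cat("CAS calls: ", x$n_cas, " of ", x$n_sites, " sites (",
      x$n_gained, " gained, ", x$n_lost, " lost)\n", sep = "")
  cat("thresholds: |POC| > ", x$thresholds$poc, ", q_occ < ",
      x$thresholds$q_occ, ", |logFC| > ", x$thresholds$logfc,
      ", q_int < ", x$thresholds$q_int, "\n", sep = "")
  invisible(x)
}

#' @export
plot.cas_result <- function(x, thresholds = list(poc = 0.5, q_occ = 0.01,
                                                 logfc = 1, q_int = 0.01),
                            ...) {
  cas <- call_cas(x, thresholds)
  col <- rep("grey60", nrow(x))
  col[x$site_id %in% cas$site_id[cas$direction == "gained"]] <- "firebrick"
  col[x$site_id %in% cas$site_id[cas$direction == "lost"]] <- "steelblue"
  graphics::plot(x$logfc, -log10(pmax(x$q_int, 1e-300)), col = col,
                 pch = 16, cex = 0.4, xlab = "log2 fold change (intensity)",
                 ylab = "-log10 q (intensity)", ...)
  graphics::abline(v = c(-thresholds$logfc, thresholds$logfc), lty = 2)
  invisible(x)
}

#' Simpson overlap index between two site sets
#'
#' `|X intersect Y| / min(|X|, |Y|)`, intersection by >= 1 bp overlap.
#'
#' @param x,y Interval data frames.
#' @return Numeric in \[0, 1\].
#' @export
simpson_index <- function(x, y) {
  if (!nrow(x) || !nrow(y)) stop("empty site set")
  small <- if (nrow(x) <= nrow(y)) x else y
  large <- if (nrow(x) <= nrow(y)) y else x
  sum(.overlaps_any(small, large)) / nrow(small)
}

#' Pairwise Simpson matrix over tissue CAS sets
#'
#' @param sets Named list of interval data frames.
#' @return Symmetric matrix with unit diagonal.
#' @export
simpson_matrix <- function(sets) {
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    m[i, j] <- m[j, i] <- simpson_index(sets[[i]], sets[[j]])
  m
}

#' Classify CTCF colocalization change at sites
#'
#' Labels each site from the 2x2 of overlap with normal and cancer CTCF peak
#' sets: `non-CTCF` (neither), `stable-CTCF` (both), `gained-CTCF` (cancer
#' only), `lost-CTCF` (normal only).
#'
#' @param sites Interval data frame.
#' @param ctcf_normal,ctcf_cancer CTCF peak interval data frames.
#' @return List: `labels` (factor per site), `proportions` (sums to 1).
#' @export
ctcf_change_classify <- function(sites, ctcf_normal, ctcf_cancer) {
  on <- .overlaps_any(sites, ctcf_normal)
  oc <- .overlaps_any(sites, ctcf_cancer)
  lab <- ifelse(on & oc, "stable-CTCF",
                ifelse(!on & oc, "gained-CTCF",
                       ifelse(on & !oc, "lost-CTCF", "non-CTCF")))
  lab <- factor(lab, levels = c("non-CTCF", "stable-CTCF", "gained-CTCF",
                                "lost-CTCF"))
  list(labels = lab, proportions = prop.table(table(lab)))
}
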