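# 3D-genome statistics at sites: A/B compartment switches, insulation
# scores and their cancer-normal changes, TAD boundaries, aggregate peak
# analysis and loop-anchor overlap ratios.

# condition-mean PC1 value at each site's midpoint bin from replicate tracks
.mean_track_at_sites <- function(sites, tracks_by_chrom) {
  mid <- floor((sites$start + sites$end) / 2)
  e <- rep(NA_real_, nrow(sites))
  for (ch in names(tracks_by_chrom)) {
    on <- which(sites$chrom == ch)
    if (!length(on)) next
    reps <- tracks_by_chrom[[ch]]
    if (inherits(reps, "signal_track")) reps <- list(reps)
    v <- rowMeans(do.call(cbind, lapply(reps, function(tr)
      track_value_at(tr, sites$chrom[on], mid[on]))))
    e[on] <- v
  }
  e
}

#' Classify compartment switches at sites
#'
#' Per site, the compartment eigenvector `E` per condition is the mean of
#' the replicate PC1 tracks at the site's midpoint bin. A site switches iff
#' `E_cancer * E_normal < 0` and `|E_cancer - E_normal| > delta`; direction
#' follows the signs (`B-to-A` when cancer is positive). Non-switching
#' sites are `stable-A`/`stable-B` by the cancer-side sign; sites with a
#' missing `E` are `undefined`.
#'
#' @param sites Interval data frame.
#' @param pc1_cancer,pc1_normal Per-chromosome lists of replicate
#'   [signal_track()]s (or single tracks).
#' @param delta Minimum |E_cancer - E_normal| for a switch.
#' @return List of class `switch_call`: `calls` (per-site data frame with
#'   `class`, `e_cancer`, `e_normal`) and `proportions` (over classifiable
#'   sites, sums to 1).
#' @export
compartment_switch_classify <- function(sites, pc1_cancer, pc1_normal,
                                        delta = 0.05) {
  ec <- .mean_track_at_sites(sites, pc1_cancer)
  en <- .mean_track_at_sites(sites, pc1_normal)
  cls <- rep("undefined", nrow(sites))
  ok <- !is.na(ec) & !is.na(en)
  sw <- ok & ec * en < 0 & abs(ec - en) > delta
  cls[ok & !sw & ec >= 0] <- "stable-A"
  cls[ok & !sw & ec < 0] <- "stable-B"
  cls[sw & ec > 0] <- "B-to-A"
  cls[sw & ec < 0] <- "A-to-B"
  cls <- factor(cls, levels = c("A-to-B", "B-to-A", "stable-A", "stable-B",
                                "undefined"))
  calls <- data.frame(
    site_id = if (!is.null(sites$id)) sites$id
              else as.character(seq_len(nrow(sites))),
    class = cls, e_cancer = ec, e_normal = en, stringsAsFactors = FALSE)
  prop <- prop.table(table(calls$class[calls$class != "undefined"],
                           exclude = "undefined"))
  structure(list(calls = calls, proportions = prop), class = "switch_call")
}

#' Insulation score from a contact matrix
#'
#' Per bin `i`, `IS = log2(diamond_mean(i) / global_diamond_mean)`, where
#' the diamond is the `window_bins x window_bins` submatrix of contacts
#' crossing `i` (rows `i-w..i-1`, columns `i+1..i+w`) and the global mean
#' averages the same geometry over all interior bins. Edge bins are
#' missing.
#'
#' @param m A [contact_matrix()].
#' @param window_bins Diamond half-width in bins, >= 1.
#' @return A [signal_track()] of IS values on the matrix grid.
#' @export
insulation_score <- function(m, window_bins = 10) {
  stopifnot(inherits(m, "contact_matrix"), window_bins >= 1)
  mat <- m$mat
  n <- nrow(mat)
  if (n < 2 * window_bins + 1)
    stop("matrix span must be >= 2 * window_bins + 1")
  if (all(mat == 0)) stop("all-zero contact matrix")
  w <- window_bins
  dm <- rep(NA_real_, n)
  for (i in (w + 1):(n - w))
    dm[i] <- mean(mat[(i - w):(i - 1), (i + 1):(i + w)])
  gm <- mean(dm, na.rm = TRUE)
  signal_track(m$chrom, m$resolution, log2(dm / gm),
               start_offset = m$start_bp)
}

#' Call TAD boundaries from insulation minima
#'
#' Boundaries are local insulation minima deeper than
#' `mean(IS) - depth_sd * sd(IS)`; of any two candidates within
#' `min_sep_bins`, only the deeper is kept (greedy, deepest first).
#'
#' @param is_track An insulation [signal_track()].
#' @param depth_sd Depth threshold in track-sd units.
#' @param min_sep_bins Minimum boundary separation in bins.
#' @return Interval data frame of boundary bins (possibly empty).
#' @export
boundary_call <- function(is_track, depth_sd = 1.0, min_sep_bins = 3) {
  v <- is_track$values
  if (length(v) < 2 * min_sep_bins) stop("track too short")
  mu <- mean(v, na.rm = TRUE); sdv <- stats::sd(v, na.rm = TRUE)
  thr <- mu - depth_sd * sdv
  n <- length(v)
  cand <- which(!is.na(v) & v < thr)
  is_min <- vapply(cand, function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    all(v[i] <= v[lo:hi], na.rm = TRUE)
  }, TRUE)
  cand <- cand[is_min]
  cand <- cand[order(v[cand])]           # deepest first
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) > min_sep_bins))
      kept <- c(kept, i)
  kept <- sort(kept)
  data.frame(
    chrom = rep(is_track$chrom, length(kept)),
    start = is_track$start_offset + (kept - 1) * is_track$bin_size,
    end = is_track$start_offset + kept * is_track$bin_size,
    bin = kept, stringsAsFactors = FALSE)
}

#' Insulation-score change at sites, stratified by boundary proximity
#'
#' `ISC(site) = IS_cancer - IS_normal` at the site's midpoint bin. Sites
#' within one bin of a called boundary are the `boundary` stratum, the rest
#' `within-TAD`; each stratum's ISC is tested against zero by a two-sided
#' Wilcoxon signed-rank test.
#'
#' @param is_cancer,is_normal Per-chromosome lists of insulation
#'   [signal_track()]s (or single tracks).
#' @param sites Interval data frame.
#' @param boundaries Boundary interval data frame (from [boundary_call()]),
#'   or `NULL` to skip stratification.
#' @return List: `isc` (per-site values, NA when missing), `stratum`,
#'   `summary` (per-stratum n, mean, median, p vs 0), `n_missing`.
#' @export
isc_site_stats <- function(is_cancer, is_normal, sites, boundaries = NULL) {
  if (inherits(is_cancer, "signal_track"))
    is_cancer <- stats::setNames(list(is_cancer), is_cancer$chrom)
  if (inherits(is_normal, "signal_track"))
    is_normal <- stats::setNames(list(is_normal), is_normal$chrom)
  ic <- .mean_track_at_sites(sites, is_cancer)
  ino <- .mean_track_at_sites(sites, is_normal)
  isc <- ic - ino
  stratum <- rep("within-TAD", nrow(sites))
  if (!is.null(boundaries) && nrow(boundaries)) {
    bin_size <- is_cancer[[1]]$bin_size
    mid <- floor((sites$start + sites$end) / 2)
    near <- rep(FALSE, nrow(sites))
    for (ch in unique(boundaries$chrom)) {
      b <- boundaries[boundaries$chrom == ch, ]
      on <- which(sites$chrom == ch)
      if (!length(on)) next
      sbin <- floor(mid[on] / bin_size)
      near[on] <- vapply(sbin, function(x)
        any(abs(x - floor(b$start / bin_size)) <= 1), TRUE)
    }
    stratum[near] <- "boundary"
  }
  ok <- !is.na(isc)
  summ <- do.call(rbind, lapply(unique(stratum), function(st) {
    v <- isc[ok & stratum == st]
    p <- if (length(v) >= 2 && any(v != 0))
      suppressWarnings(stats::wilcox.test(v)$p.value) else NA_real_
    data.frame(stratum = st, n = length(v), mean_isc = mean(v),
               median_isc = stats::median(v), p_vs_zero = p)
  }))
  list(isc = isc, stratum = stratum, summary = summ, n_missing = sum(!ok))
}

# per-diagonal expected value of a contact matrix (distance decay)
.expected_by_distance <- function(mat) {
  n <- nrow(mat)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ev <- vapply(0:(n - 1), function(k) mean(mat[d == k]), 0)
  matrix(ev[d + 1], n, n)
}

#' Aggregate peak analysis (APA) over loop pixels
#'
#' Averages `(2 * flank_bins + 1)^2` submatrices centered on loop pixels
#' and scores the aggregate as center value over the mean of the 3x3
#' lower-left corner. By default the matrix is distance-normalized
#' (observed / per-diagonal expected) first, so a uniform matrix scores
#' exactly 1 and the score estimates the loop-pixel fold enrichment.
#'
#' @param m A [contact_matrix()].
#' @param loops BEDPE-style loop data frame on the same chromosome/grid.
#' @param flank_bins Submatrix half-width in bins.
#' @param expected_normalize Divide by the distance-decay expected first.
#' @return List of class `apa_result`: `aggregate` (submatrix), `apa_score`,
#'   `n_used`, `n_skipped`.
#' @export
apa_score <- function(m, loops, flank_bins = 10, expected_normalize = TRUE) {
  stopifnot(inherits(m, "contact_matrix"))
  mat <- m$mat
  if (expected_normalize) {
    ev <- .expected_by_distance(mat)
    mat <- ifelse(ev > 0, mat / ev, 0)
  }
  n <- nrow(mat); f <- flank_bins
  px <- data.frame(
    i = floor(((loops$start1 + loops$end1) / 2 - m$start_bp) /
                m$resolution) + 1,
    j = floor(((loops$start2 + loops$end2) / 2 - m$start_bp) /
                m$resolution) + 1)
  px[px$i > px$j, c("i", "j")] <- px[px$i > px$j, c("j", "i")]
  usable <- px$i - f >= 1 & px$j + f <= n & px$i + f <= n & px$j - f >= 1 &
    loops$chrom1 == m$chrom & loops$chrom2 == m$chrom
  if (!any(usable)) stop("no loop pixels usable at this flank")
  agg <- matrix(0, 2 * f + 1, 2 * f + 1)
  for (k in which(usable))
    agg <- agg + mat[(px$i[k] - f):(px$i[k] + f),
                     (px$j[k] - f):(px$j[k] + f)]
  agg <- agg / sum(usable)
  center <- agg[f + 1, f + 1]
  corner <- mean(agg[(2 * f - 1):(2 * f + 1), 1:3])  # lower-left 3x3
  structure(list(aggregate = agg, apa_score = center / corner,
                 n_used = sum(usable), n_skipped = sum(!usable)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA score = %.3f over %d loop pixels (%d skipped)\n",
              x$apa_score, x$n_used, x$n_skipped))
  invisible(x)
}

#' Compare APA between conditions
#'
#' Per-sample APA scores, each condition's mean expressed relative to the
#' normal mean (normal = 1), and a one-sided t-test for
#' cancer > normal.
#'
#' @param mats_cancer,mats_normal Lists of [contact_matrix()] per sample.
#' @param loops Loop data frame.
#' @param flank_bins Submatrix half-width.
#' @param ... Passed to [apa_score()].
#' @return List: `scores_cancer`, `scores_normal`, `normalized_ratio`
#'   (cancer mean with normal mean set to 1), `p_value`.
#' @export
apa_compare <- function(mats_cancer, mats_normal, loops, flank_bins = 10,
                        ...) {
  sc <- vapply(mats_cancer, function(m)
    apa_score(m, loops, flank_bins, ...)$apa_score, 0)
  sn <- vapply(mats_normal, function(m)
    apa_score(m, loops, flank_bins, ...)$apa_score, 0)
  p <- stats::t.test(sc, sn, alternative = "greater")$p.value
  list(scores_cancer = sc, scores_normal = sn,
       normalized_ratio = mean(sc) / mean(sn), p_value = p)
}

#' Cross-tissue loop-anchor overlap ratios
#'
#' Entry (i, j) is the number of tissue-i CASs overlapping (padded) anchors
#' of tissue-j loops, normalized by the same count against tissue-i's own
#' loops; the diagonal is 1 by construction.
#'
#' @param cas_sets Named list of CAS interval data frames.
#' @param loop_sets Named list of loop data frames (same names).
#' @param pad_bp Anchor padding.
#' @return Matrix of ratios; rows with zero same-tissue overlap are `NA`
#'   and flagged in the `undefined_rows` attribute.
#' @export
loop_overlap_ratio <- function(cas_sets, loop_sets, pad_bp = 5000) {
  stopifnot(length(cas_sets) >= 1, identical(names(cas_sets),
                                             names(loop_sets)))
  anchors <- lapply(loop_sets, function(lp) data.frame(
    chrom = c(lp$chrom1, lp$chrom2),
    start = pmax(0, c(lp$start1, lp$start2) - pad_bp),
    end = c(lp$end1, lp$end2) + pad_bp))
  n <- length(cas_sets)
  cnt <- matrix(0, n, n, dimnames = list(names(cas_sets), names(cas_sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    cnt[i, j] <- sum(.overlaps_any(cas_sets[[i]], anchors[[j]]))
  ratio <- cnt / diag(cnt)
  undef <- diag(cnt) == 0
  ratio[undef, ] <- NA_real_
  attr(ratio, "undefined_rows") <- names(cas_sets)[undef]
  ratio
}

#' Vanilla-coverage square-root normalization
#'
#' Divides each contact by the square root of its row and column sums, the
#' single-region analogue of the VC_SQRT balancing used for raw matrices.
#'
#' @param m A [contact_matrix()] of raw counts.
#' @return A normalized [contact_matrix()].
#' @export
vc_sqrt_normalize <- function(m) {
  rs <- rowSums(m$mat)
  scale <- sqrt(rs %o% rs)
  out <- ifelse(scale > 0, m$mat / scale, 0)
  out <- out * sum(m$mat) / sum(out)  # keep total mass comparable
  contact_matrix(m$chrom, m$start_bp, m$resolution, out)
}
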