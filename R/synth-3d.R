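#' Generate synthetic compartment PC1 and insulation tracks
#'
#' Emits paired cancer/normal 50-kb tracks per chromosome. The PC1 baseline
#' is a block-alternating A/B process; bins containing a gained (lost) site
#' of the focal tissue are flipped B-to-A (A-to-B) with opposite signs and
#' |difference| well above the switch threshold, while all other bins keep
#' their sign in both conditions (replicate noise is multiplicative and
#' sign-preserving, so non-planted bins can never satisfy the switch rule).
#' Insulation tracks carry periodic TAD-boundary minima; cancer insulation
#' is raised (lowered) at gained (lost) site bins, planting positive
#' (negative) insulation-score change.
#'
#' @param cohort A [generate_cohort_chip()] result.
#' @param tissue Tissue whose planted classes drive the perturbations.
#' @param bin Track resolution in bp.
#' @param n_rep Replicate tracks per condition.
#' @param isc_effect Planted |ISC| at aberrant-site bins.
#' @param boundary_every TAD-boundary spacing in bins.
#' @return List with per-chromosome track lists `pc1_cancer`, `pc1_normal`
#'   (each a list of `n_rep` [signal_track()]s), `is_cancer`, `is_normal`,
#'   and `truth_bins` (planted switch class per site).
#' @export
generate_3d_tracks <- function(cohort, tissue = cohort$tissues[1],
                               bin = 50000, n_rep = 2, isc_effect = 0.5,
                               boundary_every = 30) {
  stopifnot(inherits(cohort, "cas_cohort"))
  set.seed(.substream(cohort$config$seed, paste0("tracks_", tissue)))
  layout <- cohort$layout
  cls <- cohort$truth[[paste0("class_", tissue)]]
  sites <- cohort$sites
  mid <- floor((sites$start + sites$end) / 2)

  pc1_cancer <- pc1_normal <- is_cancer <- is_normal <- list()
  truth_bins <- data.frame(site_id = sites$id, class = cls,
                           switch = ifelse(cls == "gained", "B-to-A",
                                           ifelse(cls == "lost", "A-to-B",
                                                  "none")),
                           stringsAsFactors = FALSE)

  for (ch in names(layout)) {
    n <- floor(unclass(layout)[[ch]] / bin)
    # block-alternating baseline: A/B blocks of 20-60 bins
    bl <- c()
    sign_now <- sample(c(-1, 1), 1)
    while (length(bl) < n) {
      len <- sample(20:60, 1)
      bl <- c(bl, rep(sign_now, len))
      sign_now <- -sign_now
    }
    bl <- bl[seq_len(n)]
    e_norm <- bl * stats::runif(n, 0.2, 1)
    e_canc <- e_norm * stats::runif(n, 0.8, 1.2)  # sign-preserving
    on_ch <- which(sites$chrom == ch)
    sbin <- pmin(pmax(floor(mid[on_ch] / bin) + 1, 1), n)
    g <- unique(sbin[cls[on_ch] == "gained"])
    l <- unique(sbin[cls[on_ch] == "lost"])
    # a bin holding both a gained and a lost site cannot switch both ways;
    # leave it unperturbed and record those sites as non-switching
    conflict <- intersect(g, l)
    g <- setdiff(g, conflict); l <- setdiff(l, conflict)
    truth_bins$switch[on_ch][sbin %in% conflict] <- "none"
    e_norm[g] <- -stats::runif(length(g), 0.1, 0.5)   # B in normal
    e_canc[g] <- stats::runif(length(g), 0.1, 0.5)    # A in cancer
    e_norm[l] <- stats::runif(length(l), 0.1, 0.5)
    e_canc[l] <- -stats::runif(length(l), 0.1, 0.5)
    rep_tracks <- function(e) lapply(seq_len(n_rep), function(r)
      signal_track(ch, bin, e * stats::runif(n, 0.85, 1.15)))
    pc1_cancer[[ch]] <- rep_tracks(e_canc)
    pc1_normal[[ch]] <- rep_tracks(e_norm)

    base_is <- stats::filter(stats::rnorm(n + 8, 0, 0.15), rep(1 / 5, 5),
                             sides = 2)[5:(n + 4)]
    base_is[is.na(base_is)] <- 0
    bd <- seq(boundary_every, n - 2, by = boundary_every)
    base_is[bd] <- base_is[bd] - 1.2
    isc <- rep(0, n)
    isc[g] <- isc_effect; isc[l] <- -isc_effect
    is_normal[[ch]] <- signal_track(ch, bin, base_is)
    is_cancer[[ch]] <- signal_track(ch, bin, base_is + isc)
  }
  list(pc1_cancer = pc1_cancer, pc1_normal = pc1_normal,
       is_cancer = is_cancer, is_normal = is_normal,
       truth_bins = truth_bins, bin = bin)
}

#' Generate synthetic contact matrices with planted loops
#'
#' Builds dense symmetric matrices over one region per condition and sample:
#' a power-law distance-decay background, multiplicative TAD blocks, and
#' loop pixels enriched by a configured fold over their local expected
#' value. Loops flagged as site-anchored differ between conditions by
#' `strength_ratio` (cancer fold = normal fold x ratio).
#'
#' @param seed Seed for this generator.
#' @param region_bp Region span (multiple of `resolution`).
#' @param resolution Bin size in bp.
#' @param n_loops Number of planted loops.
#' @param n_cas_loops How many of them are site-anchored (strength-modulated).
#' @param loop_fold Fold enrichment of loop pixels in normal samples.
#' @param strength_ratio Cancer/normal loop-strength ratio at site-anchored
#'   loops.
#' @param n_rep Samples per condition.
#' @param tad_bins TAD block size in bins.
#' @param tad_factor Within-TAD contact multiplier.
#' @param noise_sd Multiplicative lognormal noise sd.
#' @param chrom Chromosome name of the region.
#' @return List: `cancer`, `normal` (lists of [contact_matrix()]), `loops`
#'   (BEDPE-style data frame with `cas_linked` flag), `truth` (per-loop
#'   planted folds per condition).
#' @export
generate_contacts_and_loops <- function(seed = 1L, region_bp = 5e6,
                                        resolution = 50000, n_loops = 8,
                                        n_cas_loops = 4, loop_fold = 5,
                                        strength_ratio = 2, n_rep = 4,
                                        tad_bins = 20, tad_factor = 1.5,
                                        noise_sd = 0.08, chrom = "chr1") {
  if (region_bp %% resolution != 0)
    stop("region_bp must be a multiple of resolution")
  set.seed(.substream(seed, "contacts"))
  n <- region_bp / resolution
  tad_id <- (seq_len(n) - 1) %/% tad_bins
  same_tad <- outer(tad_id, tad_id, "==")
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- 100 / (1 + dist) * ifelse(same_tad, tad_factor, 1)

  # loop anchors: mid-range separations, away from matrix edges
  flank_margin <- 11
  anchors <- data.frame(
    i = sample(seq(flank_margin, n - flank_margin - 26), n_loops),
    j = NA)
  anchors$j <- anchors$i + sample(15:25, n_loops, TRUE)
  cas_linked <- seq_len(n_loops) <= n_cas_loops
  fold_normal <- rep(loop_fold, n_loops)
  fold_cancer <- ifelse(cas_linked, loop_fold * strength_ratio, loop_fold)

  build <- function(folds) {
    base <- expected
    base[cbind(anchors$i, anchors$j)] <-
      expected[cbind(anchors$i, anchors$j)] * folds
    base[cbind(anchors$j, anchors$i)] <- base[cbind(anchors$i, anchors$j)]
    noise <- matrix(stats::rlnorm(n * n, -noise_sd^2 / 2, noise_sd), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    contact_matrix(chrom, 0, resolution, base * noise)
  }
  cancer <- lapply(seq_len(n_rep), function(r) build(fold_cancer))
  normal <- lapply(seq_len(n_rep), function(r) build(fold_normal))

  loops <- data.frame(
    chrom1 = chrom, start1 = (anchors$i - 1) * resolution,
    end1 = anchors$i * resolution,
    chrom2 = chrom, start2 = (anchors$j - 1) * resolution,
    end2 = anchors$j * resolution,
    id = sprintf("loop_%02d", seq_len(n_loops)),
    cas_linked = cas_linked, stringsAsFactors = FALSE)
  list(cancer = cancer, normal = normal, loops = loops,
       truth = data.frame(id = loops$id, fold_normal = fold_normal,
                          fold_cancer = fold_cancer,
                          cas_linked = cas_linked))
}
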