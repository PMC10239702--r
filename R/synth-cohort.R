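# Seeded synthetic-cohort generator with planted ground truth. One root seed
# streams every data modality through named substreams so that modalities can
# be regenerated independently yet reproducibly.

# stable substream seed from a root seed and a modality name (< 2^31)
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.default_layout <- function() {
  genome_layout(c(chr1 = 6e7, chr2 = 6e7, chr3 = 6e7))
}

#' Configure a synthetic ChIP-seq cohort
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 3 tissues, 10,000 consensus sites, 20 cancer + 20 normal samples
#' per tissue, 2% gained + 2% lost sites per tissue, a peak-occupancy-change
#' target of 0.7 and a log2 intensity shift of 1.5 — effect sizes that clear
#' the calling thresholds (|POC| > 0.5, |logFC| > 1) under realistic
#' binomial/Gaussian noise.
#'
#' Planted aberrant sites are modelled as truly unbound on their depleted
#' side: presence there is a technical spurious-peak rate (`spurious_rate`),
#' not the baseline polymorphic occupancy `p_base` of stable sites, so the
#' enriched-side probability is `occupancy_effect + spurious_rate`.
#'
#' @param seed Root seed (integer).
#' @param n_sites Number of consensus sites.
#' @param n_tissues Number of tissues.
#' @param n_cancer,n_normal Samples per tissue and condition.
#' @param fraction_gained,fraction_lost Planted fractions per tissue
#'   (`fraction_gained + fraction_lost < 1`).
#' @param occupancy_effect Target peak-occupancy change (POC) at planted
#'   sites, > 0.
#' @param intensity_effect Target |log2 fold change| at planted sites, > 0.
#' @param intensity_noise_sd Per-sample sd of log2 intensity.
#' @param p_base Presence probability at stable sites (both conditions).
#' @param spurious_rate False-peak presence probability on the depleted side
#'   of planted sites.
#' @param site_width Site width in bp.
#' @param genome A [genome_layout()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_sites = 10000L, n_tissues = 3L,
                          n_cancer = 20L, n_normal = 20L,
                          fraction_gained = 0.02, fraction_lost = 0.02,
                          occupancy_effect = 0.7, intensity_effect = 1.5,
                          intensity_noise_sd = 0.5, p_base = 0.15,
                          spurious_rate = 0.01, site_width = 600L,
                          genome = .default_layout()) {
  stopifnot(fraction_gained >= 0, fraction_lost >= 0,
            fraction_gained + fraction_lost < 1,
            occupancy_effect > 0, intensity_effect > 0,
            n_cancer >= 2, n_normal >= 2, n_tissues >= 1)
  if (p_base + occupancy_effect > 1 || spurious_rate + occupancy_effect > 1)
    stop("infeasible presence probabilities: baseline + effect exceeds 1")
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohesin ChIP-seq cohort
#'
#' Plants, per tissue, `fraction_gained`/`fraction_lost` aberrant sites among
#' `n_sites` consensus sites. Stable sites are present with probability
#' `p_base` in both conditions; gained (lost) sites are present with
#' probability `occupancy_effect + spurious_rate` in cancer (normal) samples
#' and `spurious_rate` in the other condition, and their log2 intensity is
#' shifted by `+intensity_effect` (`-intensity_effect`) in cancer. Intensity
#' is Gaussian on the log2 scale around a site-level lognormal baseline.
#'
#' @param config A [cohort_config()].
#' @return List of class `cas_cohort`: `config`, `sites` (interval data
#'   frame), `manifest` (sample_id, tissue, condition), `occupancy` and
#'   `intensity` (lists of sites x samples matrices, one per tissue), and
#'   `truth` (data frame of per-tissue planted classes
#'   `{gained, lost, stable}`).
#' @export
generate_cohort_chip <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(.substream(config$seed, "sites"))
  layout <- config$genome
  # non-adjacent grid placement keeps sites merge-safe for peak emission
  gap <- max(3L * config$site_width, 3000L)
  slots <- do.call(rbind, lapply(names(layout), function(ch) {
    pos <- seq(gap, unclass(layout)[[ch]] - gap, by = gap)
    data.frame(chrom = ch, start = pos)
  }))
  if (nrow(slots) < config$n_sites)
    stop("genome too small for requested n_sites")
  pick <- sort(sample.int(nrow(slots), config$n_sites))
  sites <- intervals(slots$chrom[pick], slots$start[pick],
                     slots$start[pick] + config$site_width,
                     id = sprintf("site_%05d", seq_len(config$n_sites)),
                     layout = layout)
  tissues <- paste0("tissue", seq_len(config$n_tissues))

  truth <- data.frame(site_id = sites$id, stringsAsFactors = FALSE)
  occupancy <- intensity <- list()
  manifest <- NULL
  n_g <- round(config$fraction_gained * config$n_sites)
  n_l <- round(config$fraction_lost * config$n_sites)

  for (ti in seq_along(tissues)) {
    tt <- tissues[ti]
    set.seed(.substream(config$seed, paste0("chip_", tt)))
    cls <- rep("stable", config$n_sites)
    ab <- sample.int(config$n_sites, n_g + n_l)
    cls[ab[seq_len(n_g)]] <- "gained"
    if (n_l > 0) cls[ab[n_g + seq_len(n_l)]] <- "lost"
    truth[[paste0("class_", tt)]] <- cls

    nc <- config$n_cancer; nn <- config$n_normal
    sam <- data.frame(
      sample_id = c(sprintf("%s_cancer_%02d", tt, seq_len(nc)),
                    sprintf("%s_normal_%02d", tt, seq_len(nn))),
      tissue = tt,
      condition = rep(c("cancer", "normal"), c(nc, nn)),
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest, sam)

    hi <- config$occupancy_effect + config$spurious_rate
    lo <- config$spurious_rate
    p_cancer <- ifelse(cls == "gained", hi,
                       ifelse(cls == "lost", lo, config$p_base))
    p_normal <- ifelse(cls == "gained", lo,
                       ifelse(cls == "lost", hi, config$p_base))
    pres <- cbind(
      matrix(stats::rbinom(config$n_sites * nc, 1, p_cancer),
             config$n_sites, nc) > 0,
      matrix(stats::rbinom(config$n_sites * nn, 1, p_normal),
             config$n_sites, nn) > 0)
    dimnames(pres) <- list(sites$id, sam$sample_id)

    mu <- stats::rnorm(config$n_sites, mean = 3, sd = 1)  # log2 lognormal
    shift <- ifelse(cls == "gained", config$intensity_effect,
                    ifelse(cls == "lost", -config$intensity_effect, 0))
    inten <- matrix(stats::rnorm(config$n_sites * (nc + nn),
                                 mean = mu, sd = config$intensity_noise_sd),
                    config$n_sites, nc + nn)
    inten[, seq_len(nc)] <- inten[, seq_len(nc)] + shift
    dimnames(inten) <- dimnames(pres)

    occupancy[[tt]] <- pres
    intensity[[tt]] <- inten
  }

  structure(list(config = config, layout = layout, sites = sites,
                 manifest = manifest, occupancy = occupancy,
                 intensity = intensity, truth = truth,
                 tissues = tissues),
            class = "cas_cohort")
}

#' @export
print.cas_cohort <- function(x, ...) {
  cat("<cas_cohort> ", nrow(x$sites), " sites, ", length(x$tissues),
      " tissues, ", nrow(x$manifest), " samples (seed ", x$config$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Emit per-sample peak interval sets from an occupancy matrix
#'
#' Reconstructs the raw inputs of consensus building: each sample's peaks are
#' the sites it occupies, with small random edge jitter so peaks from
#' different samples overlap but do not coincide.
#'
#' @param cohort A [generate_cohort_chip()] result.
#' @param tissue Tissue name.
#' @param jitter_bp Maximum edge jitter (bp).
#' @return Named list of interval data frames, one per sample.
#' @export
cohort_peak_sets <- function(cohort, tissue, jitter_bp = 150) {
  occ <- cohort$occupancy[[tissue]]
  if (is.null(occ)) stop("unknown tissue: ", tissue)
  set.seed(.substream(cohort$config$seed, paste0("peaks_", tissue)))
  sites <- cohort$sites
  out <- lapply(colnames(occ), function(s) {
    i <- which(occ[, s])
    if (!length(i))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    j1 <- sample.int(2 * jitter_bp + 1, length(i), TRUE) - jitter_bp - 1
    j2 <- sample.int(2 * jitter_bp + 1, length(i), TRUE) - jitter_bp - 1
    data.frame(chrom = sites$chrom[i],
               start = pmax(0, sites$start[i] + j1),
               end = pmax(sites$start[i] + j1 + 50, sites$end[i] + j2),
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(occ)
  out
}
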