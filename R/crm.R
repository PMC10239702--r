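# Cis-regulatory and orthogonal-evidence statistics: TF colocalization
# enrichment, chromatin-state proportions, cohesin-depletion response,
# methylation differential, and mutation density at site classes.

#' Transcription-factor binding enrichment at CASs
#'
#' Per TF, the 2x2 of (CAS overlapping TF, CAS not) vs (non-CAS
#' overlapping, non-CAS not), tested one-sided for enrichment by Fisher's
#' exact test, with BH adjustment across TFs.
#'
#' @param cas_sites CAS interval data frame (subset of the site universe).
#' @param all_sites Full site universe interval data frame.
#' @param tfs Named list of TF peak interval data frames.
#' @return Data frame `tf, prop_cas, prop_background, odds_ratio, p, q,
#'   neg_log10_p`, one row per non-empty TF.
#' @export
tf_enrichment <- function(cas_sites, all_sites, tfs) {
  is_cas <- if (!is.null(all_sites$id) && !is.null(cas_sites$id))
    all_sites$id %in% cas_sites$id
  else .overlaps_any(all_sites, cas_sites)
  rows <- lapply(names(tfs), function(tf) {
    pk <- tfs[[tf]]
    if (is.null(pk) || !nrow(pk)) {
      warning("empty TF peak set skipped: ", tf)
      return(NULL)
    }
    hit <- .overlaps_any(all_sites, pk)
    tab <- matrix(c(sum(hit & is_cas), sum(!hit & is_cas),
                    sum(hit & !is_cas), sum(!hit & !is_cas)), 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(tf = tf, prop_cas = mean(hit[is_cas]),
               prop_background = mean(hit[!is_cas]),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no non-empty TF peak sets")
  out$q <- bh_adjust(out$p)
  out$neg_log10_p <- -log10(pmax(out$p, .Machine$double.xmin))
  out[order(out$p), , drop = FALSE]
}

# majority-bp chromatin state of each site under a segmentation
.site_state <- function(sites, seg) {
  ov <- overlap_query(
    within(sites, id <- as.character(seq_len(nrow(sites)))), seg)
  state <- rep(NA_character_, nrow(sites))
  if (nrow(ov)) {
    ov$state <- seg$state[as.integer(ov$b_id)]
    agg <- stats::aggregate(overlap_bp ~ a_id + state, ov, sum)
    agg <- agg[order(agg$a_id, -agg$overlap_bp), ]
    agg <- agg[!duplicated(agg$a_id), ]
    state[as.integer(agg$a_id)] <- as.character(agg$state)
  }
  state
}

#' Chromatin-state proportions at sites, compared across conditions
#'
#' Each site's state is the majority-bp label over the site; per-condition
#' proportions over classifiable sites sum to 1. Active-vs-inactive counts
#' between the conditions are compared by a two-sided Fisher exact test.
#'
#' @param sites Interval data frame.
#' @param seg_normal,seg_cancer Segmentations: interval data frames with a
#'   `state` column (labels 1..15 or names).
#' @param active_states States counted as active (default: the active
#'   promoter/enhancer subset of the 15-state vocabulary).
#' @return List: `proportions` (state x condition), `fisher_p`,
#'   `active_counts`, `n_missing` per condition.
#' @export
chromatin_state_compare <- function(sites, seg_normal, seg_cancer,
                                    active_states = c("1", "2", "6", "7")) {
  sn <- .site_state(sites, seg_normal)
  sc <- .site_state(sites, seg_cancer)
  states <- sort(unique(c(seg_normal$state, seg_cancer$state)))
  prop <- cbind(
    normal = prop.table(table(factor(sn, levels = states))),
    cancer = prop.table(table(factor(sc, levels = states))))
  act <- function(s) c(active = sum(s %in% active_states, na.rm = TRUE),
                       inactive = sum(!is.na(s) & !s %in% active_states))
  counts <- rbind(normal = act(sn), cancer = act(sc))
  p <- stats::fisher.test(counts)$p.value
  list(proportions = prop, fisher_p = p, active_counts = counts,
       n_missing = c(normal = sum(is.na(sn)), cancer = sum(is.na(sc))))
}

#' Decreased-gene ratio after cohesin depletion, per gene group
#'
#' Per group, the fraction of its genes (present in the depletion table)
#' that are decreased — negative log2FC and flagged significant — with
#' pairwise two-sided Fisher tests between groups.
#'
#' @param groups Named list of gene-id vectors.
#' @param dep Depletion DE table (`gene_id, log2fc, significant`).
#' @return List: `ratios` (per group), `counts` (decreased / total),
#'   `pairwise_p` (matrix).
#' @export
depletion_response_test <- function(groups, dep) {
  counts <- lapply(names(groups), function(g) {
    i <- match(groups[[g]], dep$gene_id)
    i <- i[!is.na(i)]
    if (!length(i)) stop("group has no genes in the depletion table: ", g)
    c(dec = sum(dep$log2fc[i] < 0 & dep$significant[i]), tot = length(i))
  })
  names(counts) <- names(groups)
  ratios <- vapply(counts, function(x) x["dec"] / x["tot"], 0)
  names(ratios) <- names(groups)
  n <- length(groups)
  pw <- matrix(NA_real_, n, n, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    a <- counts[[i]]; b <- counts[[j]]
    pw[i, j] <- pw[j, i] <- stats::fisher.test(
      matrix(c(a["dec"], a["tot"] - a["dec"],
               b["dec"], b["tot"] - b["dec"]), 2))$p.value
  }
  list(ratios = ratios, counts = counts, pairwise_p = pw)
}

#' Per-locus methylation differential and site-overlap enrichment
#'
#' Tests each locus's cancer vs normal beta values by a two-sided
#' Mann-Whitney test, then compares the fraction of query sites overlapping
#' significantly altered loci (p < `p_cut`) with the fractions from
#' size-matched random draws of background sites. `direction` restricts
#' significant loci to hyper- (cancer > normal) or hypomethylated ones.
#'
#' @param meth List with `loci` (interval data frame), `beta_cancer`,
#'   `beta_normal` (loci x samples matrices in \[0, 1\]).
#' @param query_sites Query (e.g. lost-CAS) interval data frame.
#' @param background_sites Background site universe.
#' @param n_draws Random draws.
#' @param seed Seed.
#' @param p_cut Significance cutoff for an altered locus.
#' @param direction `NULL`, `"hyper"` or `"hypo"`.
#' @return List of class `methylation_enrichment`: `p_locus`, `query_ratio`,
#'   `background_ratios`, `background_quantiles`, `enriched` (query above
#'   the 97.5% envelope).
#' @export
methylation_differential <- function(meth, query_sites, background_sites,
                                     n_draws = 500, seed = 1, p_cut = 1e-7,
                                     direction = NULL) {
  bc <- meth$beta_cancer; bn <- meth$beta_normal
  if (any(bc < 0 | bc > 1) || any(bn < 0 | bn > 1))
    stop("beta values must lie in [0, 1]")
  if (ncol(bc) < 2 || ncol(bn) < 2)
    stop("need >= 2 samples per population")
  p <- vapply(seq_len(nrow(bc)), function(i)
    suppressWarnings(stats::wilcox.test(bc[i, ], bn[i, ])$p.value), 0)
  delta <- rowMeans(bc) - rowMeans(bn)
  sig <- p < p_cut
  if (!is.null(direction))
    sig <- sig & if (direction == "hyper") delta > 0 else delta < 0
  sig_loci <- meth$loci[sig, , drop = FALSE]
  ratio_of <- function(s) if (nrow(s)) mean(.overlaps_any(s, sig_loci)) else 0
  qr <- ratio_of(query_sites)
  nb <- nrow(background_sites)
  set.seed(seed)
  br <- vapply(seq_len(n_draws), function(k)
    ratio_of(background_sites[sample.int(nb, nrow(query_sites)), ,
                              drop = FALSE]), 0)
  qs <- stats::quantile(br, c(0.025, 0.5, 0.975))
  structure(list(p_locus = p, delta_beta = delta, query_ratio = qr,
                 background_ratios = br, background_quantiles = qs,
                 enriched = qr > qs[[3]]),
            class = "methylation_enrichment")
}

#' Classify conserved cohesin sites
#'
#' Conserved sites are observed in at least `min_frac` of both the cancer
#' and the normal ChIP-seq datasets.
#'
#' @param occ Sites x samples logical occupancy matrix.
#' @param manifest Data frame `sample_id`, `condition`.
#' @param min_frac Minimum occupancy fraction per condition.
#' @return Logical vector over sites.
#' @export
conserved_sites <- function(occ, manifest, min_frac = 0.9) {
  idx <- .split_conditions(occ, manifest)
  rowMeans(occ[, idx$cancer, drop = FALSE]) >= min_frac &
    rowMeans(occ[, idx$normal, drop = FALSE]) >= min_frac
}

#' Mutation density at site classes
#'
#' Builds a per-bp mutation rate for each site class (mutations falling
#' inside class sites over total class bp), compares classes pairwise by
#' two-proportion tests, and profiles mutation density around site
#' midpoints.
#'
#' @param mutations Data frame `chrom`, `pos` (0-based positions).
#' @param site_classes Named list of interval data frames partitioning the
#'   site universe (e.g. `CAS`, `other`, `conserved`).
#' @param layout A [genome_layout()].
#' @param flank_bp,bin_bp Profile window around site midpoints.
#' @return List: `rates` (per class, mutations per bp), `counts`,
#'   `pairwise_p`, `profiles` (mean mutation-count profile per class).
#' @export
mutation_conserved_comparison <- function(mutations, site_classes, layout,
                                          flank_bp = 10000, bin_bp = 1000) {
  mut_iv <- data.frame(chrom = mutations$chrom, start = mutations$pos,
                       end = mutations$pos + 1)
  counts <- vapply(site_classes, function(s) {
    if (!sum(s$end - s$start)) stop("site class with zero total bp")
    ov <- GenomicRanges::countOverlaps(.as_gr(mut_iv), .as_gr(s),
                                       ignore.strand = TRUE)
    sum(ov > 0)
  }, 0)
  bp <- vapply(site_classes, function(s) sum(s$end - s$start), 0)
  rates <- counts / bp
  n <- length(site_classes)
  pw <- matrix(NA_real_, n, n,
               dimnames = list(names(site_classes), names(site_classes)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    pw[i, j] <- pw[j, i] <- suppressWarnings(stats::prop.test(
      c(counts[i], counts[j]), c(bp[i], bp[j]))$p.value)
  # mutation-count tracks per chromosome for the density profile
  tracks <- lapply(names(layout), function(ch) {
    nb <- ceiling(unclass(layout)[[ch]] / bin_bp)
    v <- tabulate(mutations$pos[mutations$chrom == ch] %/% bin_bp + 1, nb)
    signal_track(ch, bin_bp, as.numeric(v))
  })
  profiles <- lapply(site_classes, function(s)
    aggregate_signal_profile(s, tracks, flank_bp, bin_bp)$mean_profile)
  list(rates = rates, counts = counts, bp = bp, pairwise_p = pw,
       profiles = profiles)
}
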