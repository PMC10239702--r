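# DEG enrichment around CASs: distance-decay DEG-ratio profiles, the DEG
# ratio score (DRS) against a resampled all-cohesin background, the
# chromatin-loop connectivity model, and the CAS-DEG / other-DEG partition.

# ensure a DE table carries is_deg and direction labels
.label_de <- function(de, lfc_cut = 1, fdr_cut = 0.01) {
  if (is.null(de$is_deg))
    de$is_deg <- abs(de$log2fc) > lfc_cut & de$fdr < fdr_cut
  if (is.null(de$direction))
    de$direction <- ifelse(!de$is_deg, "none",
                           ifelse(de$log2fc > 0, "up", "down"))
  de
}

# DEG indicator per gene, optionally restricted to one direction
.deg_flag <- function(genes, de, direction_filter = NULL) {
  de <- .label_de(de)
  i <- match(genes$gene_id, de$gene_id)
  flag <- de$is_deg[i]
  if (!is.null(direction_filter))
    flag <- flag & de$direction[i] == direction_filter
  flag[is.na(flag)] <- FALSE
  flag
}

# (gene, site, distance) pairs within max_bp, distance-sorted; the engine
# behind profiles and fast background resampling
.site_gene_pairs <- function(sites, genes, max_bp) {
  pr <- nearest_tss_distance(sites, genes, cap_bp = max_bp)
  pr$site_idx <- match(pr$site_id, sites$id)
  pr$gene_idx <- match(pr$gene_id, genes$gene_id)
  pr[order(pr$distance), , drop = FALSE]
}

# per-bin DEG ratio for a site subset, from a precomputed pair table
.profile_from_pairs <- function(pairs, site_keep, deg, n_bins, bin_bp) {
  sel <- site_keep[pairs$site_idx]
  g <- pairs$gene_idx[sel]
  first <- !duplicated(g)                 # nearest selected site per gene
  d <- pairs$distance[sel][first]
  b <- pmin(d %/% bin_bp + 1, n_bins)
  n_genes <- tabulate(b, n_bins)
  n_deg <- tabulate(b[deg[g[first]]], n_bins)
  list(ratio = ifelse(n_genes > 0, n_deg / n_genes, NA_real_),
       n_genes = n_genes)
}

#' DEG ratio as a function of distance from sites
#'
#' Assigns each gene to its nearest queried site (TSS to site midpoint) and
#' reports, per distance bin in `[0, max_bp]`, the fraction of genes that
#' are DEGs. `direction_filter` restricts the DEG numerator to up- or
#' down-regulated genes for the gained/lost analyses.
#'
#' @param sites Interval data frame with `id`.
#' @param genes A [gene_models()] table.
#' @param de DE table (`gene_id, log2fc, fdr` and/or `is_deg, direction`).
#' @param max_bp Maximum distance considered.
#' @param bin_bp Bin width (`bin_bp` divides `max_bp`).
#' @param direction_filter `NULL`, `"up"` or `"down"`.
#' @param cumulative If `TRUE`, report cumulative ratios over `[0, x]`
#'   instead of per-bin ratios.
#' @return List of class `distance_profile`: `bin_edges`, `ratio`,
#'   `n_genes`.
#' @export
deg_ratio_profile <- function(sites, genes, de, max_bp = 200000,
                              bin_bp = 10000, direction_filter = NULL,
                              cumulative = FALSE) {
  if (max_bp %% bin_bp != 0) stop("bin_bp must divide max_bp")
  if (is.null(sites$id)) sites$id <- as.character(seq_len(nrow(sites)))
  pairs <- .site_gene_pairs(sites, genes, max_bp)
  if (!nrow(pairs)) stop("no genes within max_bp of any site")
  deg <- .deg_flag(genes, de, direction_filter)
  n_bins <- max_bp / bin_bp
  pf <- .profile_from_pairs(pairs, rep(TRUE, nrow(sites)), deg, n_bins,
                            bin_bp)
  ratio <- pf$ratio; n_genes <- pf$n_genes
  if (cumulative) {
    nd <- cumsum(ifelse(n_genes > 0, ratio * n_genes, 0))
    ng <- cumsum(n_genes)
    ratio <- ifelse(ng > 0, nd / ng, NA_real_)
  }
  structure(list(bin_edges = seq(0, max_bp, by = bin_bp), ratio = ratio,
                 n_genes = n_genes, bin_bp = bin_bp,
                 direction_filter = direction_filter),
            class = "distance_profile")
}

# discrete integral S = sum_bins f(x) * bin_width; empty bins contribute 0
.profile_integral <- function(ratio, bin_bp) {
  sum(ratio[!is.na(ratio)]) * bin_bp
}

#' DEG ratio score (DRS) against a resampled background
#'
#' `DRS = (S_CAS - S_B) / max(S_CAS, S_B)`, where `S` is the discrete
#' integral of the DEG-ratio-vs-distance curve over `[0, max_bp]` and `S_B`
#' is the mean integral over `n_draws` random site sets of size `|CAS|`
#' drawn without replacement from the background (all-cohesin) sites. The
#' full background draw vector and its quantile envelope are retained.
#' DRS is defined as 0 when both integrals vanish; it always lies in
#' \[-1, 1\].
#'
#' @param cas_sites Query (CAS) interval data frame.
#' @param background_sites Background interval data frame
#'   (`nrow >= nrow(cas_sites)`).
#' @param genes A [gene_models()] table.
#' @param de DE table.
#' @param n_draws Number of background draws, >= 2.
#' @param seed Seed for the draws.
#' @param max_bp,bin_bp Profile window and bin width.
#' @param direction_filter `NULL`, `"up"` or `"down"`.
#' @param background_pairs Optional precomputed site-gene pair table over
#'   `background_sites` (from repeated scoring against one background), as
#'   built internally; leave `NULL` to compute it.
#' @return List of class `drs_result`: `drs`, `s_cas`, `s_background`
#'   (vector), `background_quantiles` (2.5/50/97.5%), `n_draws`.
#' @export
drs_score <- function(cas_sites, background_sites, genes, de, n_draws = 500,
                      seed = 1, max_bp = 200000, bin_bp = 10000,
                      direction_filter = NULL, background_pairs = NULL) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  if (nrow(background_sites) < nrow(cas_sites))
    stop("background must contain at least as many sites as the query")
  if (is.null(background_sites$id))
    background_sites$id <- as.character(seq_len(nrow(background_sites)))
  n_bins <- max_bp / bin_bp
  deg <- .deg_flag(genes, de, direction_filter)

  prof <- deg_ratio_profile(cas_sites, genes, de, max_bp, bin_bp,
                            direction_filter)
  s_cas <- .profile_integral(prof$ratio, bin_bp)

  pairs <- if (is.null(background_pairs))
    .site_gene_pairs(background_sites, genes, max_bp)
  else background_pairs
  nb <- nrow(background_sites)
  set.seed(seed)
  s_bg <- vapply(seq_len(n_draws), function(k) {
    keep <- rep(FALSE, nb)
    keep[sample.int(nb, nrow(cas_sites))] <- TRUE
    pf <- .profile_from_pairs(pairs, keep, deg, n_bins, bin_bp)
    .profile_integral(pf$ratio, bin_bp)
  }, 0)
  s_b <- mean(s_bg)
  drs <- if (max(s_cas, s_b) == 0) 0 else (s_cas - s_b) / max(s_cas, s_b)
  structure(list(drs = drs, s_cas = s_cas, s_background = s_bg,
                 background_quantiles = stats::quantile(
                   s_bg, c(0.025, 0.5, 0.975)),
                 n_draws = n_draws, profile = prof),
            class = "drs_result")
}

#' @export
print.drs_result <- function(x, ...) {
  cat(sprintf("DRS = %.3f  (S_CAS = %.1f, mean S_B = %.1f over %d draws)\n",
              x$drs, x$s_cas, mean(x$s_background), x$n_draws))
  invisible(x)
}

#' Map sites to genes connected through chromatin loops
#'
#' A gene is connected to a site when the site overlaps one (padded) loop
#' anchor and the gene TSS overlaps the other, with the anchor separation
#' inside `span`.
#'
#' @param sites Interval data frame with `id`.
#' @param loops BEDPE-style loop data frame.
#' @param genes A [gene_models()] table.
#' @param span `c(min, max)` anchor separation (bp).
#' @param pad_bp Anchor padding.
#' @return List mapping site index to integer gene indices.
#' @export
loop_connection_map <- function(sites, loops, genes, span = c(2e5, 5e6),
                                pad_bp = 5000) {
  sep <- abs((loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2)
  loops <- loops[loops$chrom1 == loops$chrom2 & sep >= span[1] &
                   sep <= span[2], , drop = FALSE]
  con <- vector("list", nrow(sites))
  if (!nrow(loops)) return(con)
  pad <- function(chrom, start, end)
    data.frame(chrom = chrom, start = pmax(0, start - pad_bp),
               end = end + pad_bp)
  a1 <- pad(loops$chrom1, loops$start1, loops$end1)
  a2 <- pad(loops$chrom2, loops$start2, loops$end2)
  tss <- data.frame(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1)
  ov <- function(a, b) {
    h <- GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                     ignore.strand = TRUE)
    cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
  }
  link <- rbind(
    merge(data.frame(loop = ov(a1, sites)[, 1], site = ov(a1, sites)[, 2]),
          data.frame(loop = ov(a2, tss)[, 1], gene = ov(a2, tss)[, 2])),
    merge(data.frame(loop = ov(a2, sites)[, 1], site = ov(a2, sites)[, 2]),
          data.frame(loop = ov(a1, tss)[, 1], gene = ov(a1, tss)[, 2])))
  if (nrow(link)) {
    sp <- split(link$gene, link$site)
    for (s in names(sp)) con[[as.integer(s)]] <- unique(sp[[s]])
  }
  con
}

# DEG fraction among genes connected to a site subset
.loop_ratio <- function(con, site_keep, deg) {
  g <- unique(unlist(con[site_keep], use.names = FALSE))
  if (!length(g)) return(NA_real_)
  mean(deg[g])
}

#' Loop-model DEG enrichment
#'
#' Compares the DEG fraction among genes loop-connected to the query sites
#' (`R_CAS`) with the fractions from `n_draws` size-matched random site sets
#' from the background, by a two-sided Wilcoxon rank test with a
#' rank-biserial effect size.
#'
#' @param cas_sites Query interval data frame (subset of the background site
#'   universe by `id`).
#' @param loops BEDPE-style loop data frame.
#' @param genes A [gene_models()] table.
#' @param de DE table.
#' @param background_sites Background site universe with `id`.
#' @param span,pad_bp See [loop_connection_map()].
#' @param n_draws Background draws.
#' @param seed Seed.
#' @param direction_filter `NULL`, `"up"` or `"down"`.
#' @param connection_map Optional precomputed [loop_connection_map()] over
#'   `background_sites`.
#' @return List of class `loop_enrichment`: `r_cas`, `r_background`,
#'   `wilcoxon_p`, `effect_size`, `n_connected_genes`, `undefined`.
#' @export
loop_model_enrichment <- function(cas_sites, loops, genes, de,
                                  background_sites, span = c(2e5, 5e6),
                                  pad_bp = 5000, n_draws = 500, seed = 1,
                                  direction_filter = NULL,
                                  connection_map = NULL) {
  if (is.null(background_sites$id))
    background_sites$id <- as.character(seq_len(nrow(background_sites)))
  con <- if (is.null(connection_map))
    loop_connection_map(background_sites, loops, genes, span, pad_bp)
  else connection_map
  deg <- .deg_flag(genes, de, direction_filter)
  nb <- nrow(background_sites)
  keep_cas <- background_sites$id %in% cas_sites$id
  r_cas <- .loop_ratio(con, keep_cas, deg)
  if (is.na(r_cas))
    return(structure(list(r_cas = NA_real_, r_background = numeric(),
                          wilcoxon_p = NA_real_, effect_size = NA_real_,
                          n_connected_genes = 0L, undefined = TRUE),
                     class = "loop_enrichment"))
  set.seed(seed)
  r_bg <- vapply(seq_len(n_draws), function(k) {
    keep <- rep(FALSE, nb)
    keep[sample.int(nb, sum(keep_cas))] <- TRUE
    .loop_ratio(con, keep, deg)
  }, 0)
  r_bg <- r_bg[!is.na(r_bg)]
  # exact two-sided Mann-Whitney p for one ratio against the draws
  # (ties mid-ranked); the normal approximation has no power at n1 = 1
  u <- sum(r_cas > r_bg) + 0.5 * sum(r_cas == r_bg)
  nbg <- length(r_bg)
  p <- min(1, 2 * min(floor(u) + 1, nbg - floor(u) + 1) / (nbg + 1))
  eff <- (sum(r_cas > r_bg) - sum(r_cas < r_bg)) / length(r_bg)
  structure(list(
    r_cas = r_cas, r_background = r_bg, wilcoxon_p = p, effect_size = eff,
    n_connected_genes = length(unique(unlist(con[keep_cas],
                                             use.names = FALSE))),
    undefined = FALSE), class = "loop_enrichment")
}

#' Partition DEGs into CAS-DEGs and other-DEGs
#'
#' CAS-DEGs are DEGs whose TSS lies within `near_bp` of a CAS midpoint; the
#' two partitions' |log2FC| are compared by a two-sided Mann-Whitney U test.
#'
#' @param cas_sites CAS interval data frame.
#' @param de DE table.
#' @param genes A [gene_models()] table.
#' @param near_bp Distance threshold (bp).
#' @return List: `cas_degs`, `other_degs` (gene-id vectors), `p_value`,
#'   `median_abs_lfc` per group, `undefined` flag when a partition is empty.
#' @export
casdeg_partition <- function(cas_sites, de, genes, near_bp = 5000) {
  de <- .label_de(de)
  degs <- de$gene_id[de$is_deg]
  if (is.null(cas_sites$id))
    cas_sites$id <- as.character(seq_len(nrow(cas_sites)))
  near <- character(0)
  if (nrow(cas_sites)) {
    pr <- nearest_tss_distance(cas_sites, genes, cap_bp = near_bp)
    near <- unique(pr$gene_id)
  }
  cas_degs <- intersect(degs, near)
  other_degs <- setdiff(degs, near)
  if (!length(cas_degs) || !length(other_degs))
    return(list(cas_degs = cas_degs, other_degs = other_degs,
                p_value = NA_real_, median_abs_lfc = c(cas = NA, other = NA),
                undefined = TRUE))
  a <- abs(de$log2fc[match(cas_degs, de$gene_id)])
  b <- abs(de$log2fc[match(other_degs, de$gene_id)])
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(cas_degs = cas_degs, other_degs = other_degs, p_value = p,
       median_abs_lfc = c(cas = stats::median(a), other = stats::median(b)),
       undefined = FALSE)
}
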