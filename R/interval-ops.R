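# Interval algebra shared by every stage: overlap joins, TSS distances,
# genomic-context annotation and signal aggregation around sites.

#' Construct a gene model table
#'
#' @param gene_id Gene identifiers (unique).
#' @param chrom,start,end Gene body coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`; the TSS is `start` on `+` and `end - 1` on
#'   `-`.
#' @param exons Optional interval data frame of exons with `id` = gene_id.
#' @param layout Optional [genome_layout()].
#' @return Data frame of class `gene_models` with a computed `tss` column and
#'   an `exons` attribute.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+",
                        exons = NULL, layout = NULL) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  g <- intervals(chrom, start, end, id = as.character(gene_id),
                 strand = strand, layout = layout)
  names(g)[names(g) == "id"] <- "gene_id"
  g$tss <- ifelse(g$strand == "-", g$end - 1, g$start)
  if (!is.null(exons)) {
    validate_intervals(exons)
    if (!all(exons$id %in% g$gene_id))
      stop("exon id not found among gene ids")
  }
  attr(g, "exons") <- exons
  class(g) <- c("gene_models", class(g))
  g
}

#' Overlap join between two interval sets
#'
#' Exact pairs with at least `min_overlap_bp` shared bases under half-open
#' semantics, computed with `GenomicRanges::findOverlaps`.
#'
#' @param a,b Interval data frames (rows identified by `id` when present,
#'   else by row index).
#' @param min_overlap_bp Minimum shared bases, >= 1.
#' @return Data frame `a_id`, `b_id`, `overlap_bp`.
#' @export
overlap_query <- function(a, b, min_overlap_bp = 1) {
  validate_intervals(a); validate_intervals(b)
  stopifnot(min_overlap_bp >= 1)
  hits <- GenomicRanges::findOverlaps(.as_gr(a), .as_gr(b),
                                      minoverlap = min_overlap_bp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(
    a_id = if (!is.null(a$id)) a$id[qi] else as.character(qi),
    b_id = if (!is.null(b$id)) b$id[si] else as.character(si),
    overlap_bp = ov, stringsAsFactors = FALSE)
}

# logical: which rows of a overlap any row of b by >= min_overlap_bp
.overlaps_any <- function(a, b, min_overlap_bp = 1) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b) || !any(a$chrom %in% b$chrom)) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(.as_gr(a), .as_gr(b),
                               minoverlap = min_overlap_bp,
                               ignore.strand = TRUE) > 0
}

#' Site-TSS distances within a cap
#'
#' Distance is `|site midpoint - TSS|`, set to 0 when the TSS lies inside the
#' site. All (site, gene) pairs within `cap_bp` on the same chromosome are
#' returned.
#'
#' @param sites Interval data frame with `id`.
#' @param genes A [gene_models()] table.
#' @param cap_bp Maximum distance reported (bp), >= 0.
#' @return Data frame `site_id`, `gene_id`, `distance`.
#' @export
nearest_tss_distance <- function(sites, genes, cap_bp = 200000) {
  validate_intervals(sites)
  stopifnot(cap_bp >= 0)
  if (is.null(genes) || !nrow(genes)) stop("empty gene set")
  mid <- floor((sites$start + sites$end) / 2)
  probe <- data.frame(chrom = sites$chrom,
                      start = pmax(0, mid - cap_bp),
                      end = mid + cap_bp + 1)
  tss <- data.frame(chrom = genes$chrom, start = genes$tss,
                    end = genes$tss + 1)
  hits <- GenomicRanges::findOverlaps(.as_gr(probe), .as_gr(tss),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  d <- abs(mid[qi] - genes$tss[gi])
  inside <- genes$tss[gi] >= sites$start[qi] & genes$tss[gi] < sites$end[qi]
  d[inside] <- 0
  keep <- d <= cap_bp
  data.frame(
    site_id = if (!is.null(sites$id)) sites$id[qi[keep]]
              else as.character(qi[keep]),
    gene_id = genes$gene_id[gi[keep]],
    distance = d[keep], stringsAsFactors = FALSE)
}

#' Annotate sites with their genomic context
#'
#' Single label per site with precedence promoter > exonic > intronic >
#' intergenic. The promoter window is strand-aware:
#' `[TSS - upstream, TSS + downstream)` on `+` genes and mirrored on `-`.
#'
#' @param sites Interval data frame.
#' @param genes A [gene_models()] table; exon annotation is taken from its
#'   `exons` attribute when present (otherwise gene bodies outside promoters
#'   count as intronic).
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @return Factor of labels, one per site, levels
#'   `promoter, exonic, intronic, intergenic`.
#' @export
annotate_context <- function(sites, genes, promoter_window = c(2000, 500)) {
  validate_intervals(sites)
  up <- promoter_window[1]; dn <- promoter_window[2]
  prom <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(genes$strand == "-", genes$tss - dn + 1,
                           genes$tss - up)),
    end = ifelse(genes$strand == "-", genes$tss + up + 1, genes$tss + dn))
  lab <- rep("intergenic", nrow(sites))
  body <- genes; class(body) <- "data.frame"
  lab[.overlaps_any(sites, body)] <- "intronic"
  exons <- attr(genes, "exons")
  if (!is.null(exons)) {
    within_exon <- rep(FALSE, nrow(sites))
    hits <- GenomicRanges::findOverlaps(.as_gr(sites), .as_gr(exons),
                                        type = "within",
                                        ignore.strand = TRUE)
    within_exon[unique(S4Vectors::queryHits(hits))] <- TRUE
    lab[within_exon] <- "exonic"
  }
  lab[.overlaps_any(sites, prom)] <- "promoter"
  factor(lab, levels = c("promoter", "exonic", "intronic", "intergenic"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' `stats::p.adjust(method = "BH")` with domain validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Aggregate a signal track around site midpoints
#'
#' For each site, track values are averaged within bins of `bin_bp` at signed
#' offsets `-flank_bp ... +flank_bp` from the site midpoint. Sites falling
#' outside the track (or on another chromosome) yield all-`NA` rows; they are
#' kept and counted, never dropped.
#'
#' @param sites Interval data frame.
#' @param track A [signal_track()], or a list of tracks (one per chromosome).
#' @param flank_bp Half-width of the window (multiple of `bin_bp`).
#' @param bin_bp Aggregation bin width in bp.
#' @return List of class `profile_matrix`: `site_ids`, `offsets` (bin center
#'   offsets, bp), `values` (sites x offsets), `mean_profile` (NA-aware
#'   column means), `n_missing_sites`.
#' @export
aggregate_signal_profile <- function(sites, track, flank_bp, bin_bp) {
  validate_intervals(sites)
  if (flank_bp %% bin_bp != 0) stop("flank_bp must be a multiple of bin_bp")
  tracks <- if (inherits(track, "signal_track")) list(track) else track
  names(tracks) <- vapply(tracks, `[[`, "", "chrom")
  nb <- flank_bp / bin_bp
  offsets <- seq(-nb, nb - 1) * bin_bp + bin_bp / 2
  mid <- floor((sites$start + sites$end) / 2)
  vals <- matrix(NA_real_, nrow(sites), length(offsets))
  for (s in seq_len(nrow(sites))) {
    tr <- tracks[[sites$chrom[s]]]
    if (is.null(tr)) next
    lo <- mid[s] - flank_bp + (seq_along(offsets) - 1) * bin_bp
    for (k in seq_along(offsets)) {
      b <- .track_bin(tr, seq(lo[k], lo[k] + bin_bp - 1,
                              by = min(bin_bp, tr$bin_size)))
      b <- b[!is.na(b)]
      if (length(b)) vals[s, k] <- mean(tr$values[unique(b)], na.rm = TRUE)
    }
  }
  vals[is.nan(vals)] <- NA_real_
  structure(list(
    site_ids = if (!is.null(sites$id)) sites$id
               else as.character(seq_len(nrow(sites))),
    offsets = offsets, values = vals,
    mean_profile = colMeans(vals, na.rm = TRUE),
    n_missing_sites = sum(rowSums(!is.na(vals)) == 0)),
    class = "profile_matrix")
}
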