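#' Generate synthetic gene models and differential expression
#'
#' Plants distance-linked differential expression around the cohort's
#' aberrant sites: a gene's probability of being a DEG decays linearly with
#' the distance from its TSS to the nearest planted site, from `prob_near`
#' at distance 0 to `prob_far` at `decay_bp` and beyond. DEG direction
#' follows the site class (gained -> up, lost -> down) with probability
#' `concordance`. An expression matrix over all tissues' samples is emitted
#' consistent with the planted log2 fold changes (gene baselines, per-tissue
#' baseline offsets shared by both conditions, Gaussian sample noise).
#'
#' @param cohort A [generate_cohort_chip()] result.
#' @param n_genes Number of genes tiled over the genome.
#' @param decay_bp Distance at which the DEG probability reaches `prob_far`.
#' @param prob_near,prob_far DEG probability at distance 0 / beyond
#'   `decay_bp` (`prob_near > prob_far`).
#' @param concordance Probability that a planted DEG's direction matches its
#'   nearest site's class.
#' @param lfc_boost Extra |log2FC| amplitude given to DEGs in proportion to
#'   their proximity weight (plants the stronger dysregulation of
#'   site-proximal DEGs).
#' @param tissue_sd Sd of per-gene tissue baseline offsets.
#' @param noise_sd Sd of per-sample expression noise.
#' @return List: `genes` ([gene_models()]), `de` (per-tissue DE tables with
#'   `gene_id, log2fc, fdr, is_deg, direction`), `expr` (genes x samples
#'   matrix), `sample_info`, and `truth_genes` (planted DE status per
#'   tissue).
#' @export
generate_expression <- function(cohort, n_genes = 20000L, decay_bp = 200000,
                                prob_near = 0.6, prob_far = 0.2,
                                concordance = 0.9, lfc_boost = 0.5,
                                tissue_sd = 0.4, noise_sd = 0.5) {
  stopifnot(inherits(cohort, "cas_cohort"), prob_near > prob_far,
            prob_far >= 0, prob_near <= 1)
  layout <- cohort$layout
  set.seed(.substream(cohort$config$seed, "genes"))
  step <- floor(sum(layout) / n_genes)
  pos <- do.call(rbind, lapply(names(layout), function(ch) {
    p <- seq(5000, unclass(layout)[[ch]] - 20000, by = step)
    data.frame(chrom = ch, tss = p)
  }))
  pos <- pos[seq_len(min(n_genes, nrow(pos))), ]
  strand <- sample(c("+", "-"), nrow(pos), TRUE)
  glen <- pmin(round(stats::rlnorm(nrow(pos), log(8000), 0.6)) + 1000, 5e4)
  genes <- gene_models(
    gene_id = sprintf("gene_%05d", seq_len(nrow(pos))),
    chrom = pos$chrom,
    start = ifelse(strand == "+", pos$tss, pmax(0, pos$tss - glen + 1)),
    end = ifelse(strand == "+", pos$tss + glen, pos$tss + 1),
    strand = strand, layout = layout)

  de <- list(); truth_genes <- data.frame(gene_id = genes$gene_id)
  lfc_all <- list()
  for (tt in cohort$tissues) {
    set.seed(.substream(cohort$config$seed, paste0("expr_", tt)))
    cls <- cohort$truth[[paste0("class_", tt)]]
    planted <- cohort$sites[cls != "stable", , drop = FALSE]
    pcls <- cls[cls != "stable"]
    # distance from each TSS to nearest planted site, capped at decay_bp
    d <- rep(Inf, nrow(genes)); ncls <- rep(NA_character_, nrow(genes))
    if (nrow(planted)) {
      pr <- nearest_tss_distance(planted, genes, cap_bp = decay_bp)
      if (nrow(pr)) {
        ord <- order(pr$gene_id, pr$distance)
        pr <- pr[ord, ][!duplicated(pr$gene_id[ord]), ]
        gi <- match(pr$gene_id, genes$gene_id)
        d[gi] <- pr$distance
        ncls[gi] <- pcls[match(pr$site_id, planted$id)]
      }
    }
    w <- pmax(0, 1 - d / decay_bp)  # proximity weight in [0, 1]
    p_de <- prob_far + (prob_near - prob_far) * w
    is_deg <- stats::runif(nrow(genes)) < p_de
    conc <- stats::runif(nrow(genes)) < concordance
    dir_near <- ifelse(ncls == "gained", "up", "down")
    dir_rand <- sample(c("up", "down"), nrow(genes), TRUE)
    direction <- ifelse(is_deg,
                        ifelse(!is.na(ncls) & conc, dir_near, dir_rand),
                        "none")
    amp <- 1 + abs(stats::rnorm(nrow(genes), 0, 0.6)) + lfc_boost * w
    lfc <- ifelse(direction == "up", amp,
                  ifelse(direction == "down", -amp, 0))
    small <- stats::rnorm(nrow(genes), 0, 0.3)
    small[abs(small) >= 1] <- 0.9 * sign(small[abs(small) >= 1])
    lfc[direction == "none"] <- small[direction == "none"]
    fdr <- ifelse(is_deg, stats::runif(nrow(genes), 0, 0.009),
                  stats::runif(nrow(genes), 0.011, 1))
    de[[tt]] <- data.frame(gene_id = genes$gene_id, log2fc = lfc, fdr = fdr,
                           is_deg = is_deg, direction = direction,
                           stringsAsFactors = FALSE)
    truth_genes[[paste0("deg_", tt)]] <- is_deg
    truth_genes[[paste0("dist_", tt)]] <- d
    # non-DEG fold changes are estimation noise around a true null, so
    # only planted DEGs shift the expression matrix
    lfc_all[[tt]] <- ifelse(is_deg, lfc, 0)
  }

  set.seed(.substream(cohort$config$seed, "expr_matrix"))
  man <- cohort$manifest
  base <- stats::rnorm(nrow(genes), 6, 1)
  toff <- matrix(stats::rnorm(nrow(genes) * length(cohort$tissues), 0,
                              tissue_sd),
                 nrow(genes), length(cohort$tissues),
                 dimnames = list(NULL, cohort$tissues))
  expr <- matrix(0, nrow(genes), nrow(man),
                 dimnames = list(genes$gene_id, man$sample_id))
  for (k in seq_len(nrow(man))) {
    mu <- base + toff[, man$tissue[k]]
    if (man$condition[k] == "cancer") mu <- mu + lfc_all[[man$tissue[k]]]
    expr[, k] <- stats::rnorm(nrow(genes), mu, noise_sd)
  }

  list(genes = genes, de = de, expr = expr, sample_info = man,
       truth_genes = truth_genes)
}
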