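#' Generate chromatin loops linking sites to gene promoters
#'
#' Emits BEDPE-style loops whose first anchor is a cohesin site and whose
#' second anchor covers a gene TSS, with spans inside `span`. Loops anchored
#' at planted aberrant sites preferentially target DEGs of the focal tissue
#' with probability `deg_bias` (set `deg_bias = NULL` for unbiased, null
#' loops); all other loops target genes at random.
#'
#' @param cohort A [generate_cohort_chip()] result.
#' @param genedata A [generate_expression()] result.
#' @param tissue Focal tissue.
#' @param n_loops Number of loops.
#' @param span `c(min, max)` anchor separation in bp.
#' @param deg_bias Probability that an aberrant-site loop targets a DEG, or
#'   `NULL` for no bias.
#' @param anchor_halfwidth Half-width of the TSS anchor (bp).
#' @return Loop data frame (`chrom1..end2`, `id`, `site_id`, `gene_id`).
#' @export
generate_gene_loops <- function(cohort, genedata, tissue = cohort$tissues[1],
                                n_loops = 2000, span = c(2e5, 5e6),
                                deg_bias = 0.6, anchor_halfwidth = 2500) {
  set.seed(.substream(cohort$config$seed, paste0("loops_", tissue)))
  sites <- cohort$sites
  genes <- genedata$genes
  de <- genedata$de[[tissue]]
  cls <- cohort$truth[[paste0("class_", tissue)]]
  smid <- floor((sites$start + sites$end) / 2)

  si <- sample.int(nrow(sites), n_loops, replace = TRUE)
  rows <- lapply(seq_len(n_loops), function(k) {
    s <- si[k]
    d <- abs(genes$tss - smid[s])
    ok <- genes$chrom == sites$chrom[s] & d >= span[1] & d <= span[2]
    if (!any(ok)) return(NULL)
    pool <- which(ok)
    if (!is.null(deg_bias) && cls[s] != "stable" &&
        stats::runif(1) < deg_bias) {
      degp <- pool[de$is_deg[pool]]
      if (length(degp)) pool <- degp
    }
    g <- pool[sample.int(length(pool), 1)]
    data.frame(chrom1 = sites$chrom[s], start1 = sites$start[s],
               end1 = sites$end[s], chrom2 = genes$chrom[g],
               start2 = max(0, genes$tss[g] - anchor_halfwidth),
               end2 = genes$tss[g] + anchor_halfwidth,
               site_id = sites$id[s], gene_id = genes$gene_id[g],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("loop_%05d", seq_len(nrow(out)))
  out
}

#' Generate clinical and orthogonal-evidence data
#'
#' Emits, from independent substreams of the cohort seed:
#' * a survival table with exponential times, group-dependent hazards and
#'   uniform censoring, plus a per-patient score that separates the groups;
#' * a methylation beta table over site loci with planted hypermethylation
#'   at lost sites of the focal tissue (gained sites are deliberately left
#'   unperturbed, planting the lost/gained asymmetry);
#' * transcription-factor peak collections with a configurable preference
#'   for aberrant sites;
#' * mutation positions, uniform with optional fold-enrichment inside a
#'   chosen site class;
#' * cohesin-depletion differential-expression tables (cancer and normal
#'   contexts) with a planted excess of decreased genes in a chosen group.
#'
#' @param cohort A [generate_cohort_chip()] result.
#' @param genedata Optional [generate_expression()] result (needed for the
#'   depletion tables).
#' @param tissue Focal tissue.
#' @param n_patients Patients in the survival table.
#' @param hazard_ratio High-risk over low-risk hazard ratio, > 0.
#' @param n_meth_samples Samples per methylation population.
#' @param meth_base,meth_hyper Beta-distribution means (in (0,1)) for
#'   baseline and hypermethylated loci.
#' @param tf_pref_frac,tf_bg_frac Fraction of aberrant / stable sites bound
#'   by the site-preferring TF.
#' @param n_mutations Baseline mutation count.
#' @param mutation_enrich_class Site class to enrich (`"conserved"`,
#'   `"gained"`, `"lost"`) or `NULL`.
#' @param mutation_enrich_fold Fold enrichment inside that class.
#' @param depletion_group Gene-id vector with planted depletion response, or
#'   `NULL`.
#' @param depletion_effect Mean log2FC shift (downward) for that group in the
#'   cancer-context table.
#' @return Named list `survival`, `methylation`, `tf_peaks`, `mutations`,
#'   `depletion`.
#' @export
generate_clinical_aux <- function(cohort, genedata = NULL,
                                  tissue = cohort$tissues[1],
                                  n_patients = 200, hazard_ratio = 3,
                                  n_meth_samples = 20, meth_base = 0.25,
                                  meth_hyper = 0.75, tf_pref_frac = 0.5,
                                  tf_bg_frac = 0.05, n_mutations = 20000,
                                  mutation_enrich_class = NULL,
                                  mutation_enrich_fold = 3,
                                  depletion_group = NULL,
                                  depletion_effect = 0.8) {
  stopifnot(hazard_ratio > 0)
  if (meth_base <= 0 || meth_base >= 1 || meth_hyper <= 0 || meth_hyper >= 1)
    stop("methylation beta means must lie strictly inside (0, 1)")
  cls <- cohort$truth[[paste0("class_", tissue)]]
  sites <- cohort$sites

  # survival: exponential hazards, uniform censoring
  set.seed(.substream(cohort$config$seed, "survival"))
  group <- rep(c("high", "low"), length.out = n_patients)
  h0 <- 1 / 1500
  rate <- ifelse(group == "high", h0 * hazard_ratio, h0)
  t_event <- stats::rexp(n_patients, rate)
  t_cens <- stats::runif(n_patients, 100, 2500)
  surv <- data.frame(
    sample_id = sprintf("patient_%03d", seq_len(n_patients)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = group,
    score = stats::rnorm(n_patients, ifelse(group == "high", 0.5, -0.5), 0.3),
    stringsAsFactors = FALSE)

  # methylation: concentration 20 beta distributions around the target means
  set.seed(.substream(cohort$config$seed, "methylation"))
  conc <- 20
  nloci <- nrow(sites)
  draw <- function(mu, n) matrix(stats::rbeta(nloci * n, mu * conc,
                                              (1 - mu) * conc), nloci, n)
  mu_normal <- rep(meth_base, nloci)
  mu_cancer <- ifelse(cls == "lost", meth_hyper, meth_base)
  meth <- list(loci = sites,
               beta_cancer = draw(mu_cancer, n_meth_samples),
               beta_normal = draw(mu_normal, n_meth_samples))

  # TF peaks: one aberrant-site-preferring TF, one indifferent TF
  set.seed(.substream(cohort$config$seed, "tf"))
  ab <- which(cls != "stable"); st <- which(cls == "stable")
  pick <- function(idx, frac) idx[stats::runif(length(idx)) < frac]
  tf_pref <- sites[sort(c(pick(ab, tf_pref_frac), pick(st, tf_bg_frac))), ]
  tf_unif <- sites[pick(seq_len(nloci), 0.1), ]
  tf_peaks <- list(TF_caspref = tf_pref, TF_uniform = tf_unif)

  # mutations: uniform baseline + optional class enrichment
  set.seed(.substream(cohort$config$seed, "mutations"))
  layout <- cohort$layout
  chrom <- sample(names(layout), n_mutations, TRUE,
                  prob = unclass(layout) / sum(layout))
  pos <- floor(stats::runif(n_mutations) * unclass(layout)[chrom])
  mut <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  if (!is.null(mutation_enrich_class)) {
    tgt <- if (mutation_enrich_class == "conserved")
      which(cls == "stable") else which(cls == mutation_enrich_class)
    tgt_sites <- sites[tgt, , drop = FALSE]
    rate <- n_mutations / sum(layout)
    n_extra <- stats::rpois(1, (mutation_enrich_fold - 1) * rate *
                              sum(tgt_sites$end - tgt_sites$start))
    if (n_extra > 0) {
      si <- sample.int(nrow(tgt_sites), n_extra, TRUE)
      w <- tgt_sites$end[si] - tgt_sites$start[si]
      mut <- rbind(mut, data.frame(
        chrom = tgt_sites$chrom[si],
        pos = tgt_sites$start[si] + floor(stats::runif(n_extra) * w),
        stringsAsFactors = FALSE))
    }
  }

  # cohesin-depletion response tables
  depletion <- NULL
  if (!is.null(genedata)) {
    set.seed(.substream(cohort$config$seed, "depletion"))
    gid <- genedata$genes$gene_id
    mk <- function(context) {
      lfc <- stats::rnorm(length(gid), 0, 0.7)
      if (context == "cancer" && !is.null(depletion_group))
        lfc[gid %in% depletion_group] <-
          lfc[gid %in% depletion_group] - depletion_effect
      data.frame(gene_id = gid, log2fc = lfc,
                 significant = abs(lfc) > 0.5 &
                   stats::runif(length(gid)) < 0.9,
                 context = context, stringsAsFactors = FALSE)
    }
    depletion <- list(cancer = mk("cancer"), normal = mk("normal"))
  }

  list(survival = surv, methylation = meth, tf_peaks = tf_peaks,
       mutations = mut, depletion = depletion)
}
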