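# Patient-level statistics: clustering of expression samples by gene lists
# with adjusted-Rand-index evaluation, gene-set sample scoring with
# Kaplan-Meier / log-rank stratification, and hypergeometric
# over-representation tests.

#' Cluster patient samples by a gene list
#'
#' Samples are represented by the per-gene standardized submatrix of the
#' listed genes. Hierarchical clustering uses correlation distance
#' (1 - Pearson) with average linkage; k-means runs on the standardized
#' values with 50 restarts under a fixed seed.
#'
#' @param expr Genes x samples expression matrix.
#' @param gene_list Gene ids to cluster on (intersection with `expr` rows
#'   must be non-empty).
#' @param k Number of clusters, >= 2.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed Seed for the k-means restarts.
#' @return Integer cluster labels named by sample.
#' @export
cluster_patients <- function(expr, gene_list, k, method = c("kmeans",
                                                            "hierarchical"),
                             seed = 1) {
  method <- match.arg(method)
  stopifnot(k >= 2)
  if (k > ncol(expr)) stop("k exceeds the number of samples")
  g <- intersect(gene_list, rownames(expr))
  if (!length(g)) stop("gene_list has no genes in the expression matrix")
  x <- expr[g, , drop = FALSE]
  sdv <- apply(x, 1, stats::sd)
  x <- (x - rowMeans(x)) / ifelse(sdv > 0, sdv, 1)
  if (method == "kmeans") {
    set.seed(seed)
    cl <- stats::kmeans(t(x), centers = k, nstart = 50,
                        iter.max = 100)$cluster
  } else {
    d <- stats::as.dist(1 - stats::cor(x))
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  }
  stats::setNames(as.integer(cl), colnames(expr))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement from the pair-counting contingency
#' form: with `n_ij` the shared counts, `a_i`, `b_j` the margins and `n`
#' the total,
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' where `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return ARI, <= 1; 1 iff the partitions are identical, ~0 at chance.
#' @export
adjusted_rand_index <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors must have equal length")
  tab <- table(truth, predicted)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  den <- 0.5 * (sa + sb) - e
  if (den == 0) return(1)  # both partitions trivial and identical in form
  (sij - e) / den
}

#' Gene-set sample score
#'
#' Mean, over the set genes, of each sample's per-gene z-score — a
#' deterministic, linear sample-level summary of set expression used to
#' stratify patients (the package's documented stand-in for GSVA-style
#' scoring; the stratification contract, two groups from a set-level score,
#' is preserved).
#'
#' @param expr Genes x samples expression matrix.
#' @param gene_set Gene ids (intersection with `expr` must be non-empty).
#' @return Named numeric score per sample.
#' @export
gene_set_sample_score <- function(expr, gene_set) {
  g <- intersect(gene_set, rownames(expr))
  if (!length(g)) stop("gene_set has no genes in the expression matrix")
  x <- expr[g, , drop = FALSE]
  sdv <- apply(x, 1, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sdv > 0, sdv, 1)
  colMeans(z)
}

#' Kaplan-Meier stratification with a log-rank test
#'
#' Splits samples into high/low groups at the median score (ties to the low
#' group), fits Kaplan-Meier curves per group and tests the difference by
#' the two-group log-rank test (1 df).
#'
#' @param surv Data frame `sample_id, time, event` (1 died, 0 censored).
#' @param scores Named numeric vector over the same samples.
#' @param split Stratification rule; only `"median"` is implemented.
#' @return List of class `km_logrank`: `fit` (a `survfit`), `groups`,
#'   `chisq`, `p_value`, `undefined` (no events).
#' @export
km_logrank <- function(surv, scores, split = "median") {
  split <- match.arg(split, "median")
  s <- scores[surv$sample_id]
  if (anyNA(s)) stop("scores missing for some samples")
  grp <- factor(ifelse(s > stats::median(s), "high", "low"),
                levels = c("low", "high"))
  if (length(unique(grp)) < 2)
    stop("median split produced a single group")
  if (sum(surv$event) == 0)
    return(structure(list(fit = NULL, groups = grp, chisq = NA_real_,
                          p_value = NA_real_, undefined = TRUE),
                     class = "km_logrank"))
  df <- data.frame(time = surv$time, event = surv$event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, groups = grp, chisq = sd$chisq, p_value = p,
                 undefined = FALSE),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  if (x$undefined) cat("log-rank undefined: no events\n")
  else cat(sprintf("log-rank chi-square = %.3f (1 df), p = %.3g\n",
                   x$chisq, x$p_value))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, ...) {
  if (x$undefined) stop("nothing to plot: no events")
  graphics::plot(x$fit, col = c("steelblue", "darkorange"), lwd = 2,
                 xlab = "time", ylab = "survival", ...)
  graphics::legend("topright", legend = levels(x$groups), lwd = 2,
                   col = c("steelblue", "darkorange"), bty = "n")
  invisible(x)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric test of each set's overlap with the query,
#' against a fixed gene universe, with BH adjustment across sets.
#'
#' @param query Query gene ids (must be a subset of `universe`).
#' @param gene_sets Named list of gene-id vectors.
#' @param universe Universe gene ids.
#' @return Data frame `set, n_set, n_overlap, expected, p, q`, ordered by p.
#' @export
ora_enrichment <- function(query, gene_sets, universe) {
  if (!length(query)) stop("empty query")
  if (!all(query %in% universe)) stop("query genes outside the universe")
  n <- length(universe); k <- length(unique(query))
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    m <- length(set)
    x <- length(intersect(query, set))
    p <- stats::phyper(x - 1, m, n - m, k, lower.tail = FALSE)
    data.frame(set = s, n_set = m, n_overlap = x, expected = k * m / n,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Two-list ratio comparison
#'
#' Fisher 2x2 test comparing the fraction of each of two gene lists that
#' falls in a reference set (e.g. oncogene ratio of gained-CAS-DEGs vs
#' lost-CAS-DEGs).
#'
#' @param list_a,list_b Gene-id vectors.
#' @param reference Reference gene-id set.
#' @return List: `ratio_a`, `ratio_b`, `p_value`.
#' @export
ratio_comparison <- function(list_a, list_b, reference) {
  a <- sum(list_a %in% reference); b <- sum(list_b %in% reference)
  p <- stats::fisher.test(matrix(c(a, length(list_a) - a,
                                   b, length(list_b) - b), 2))$p.value
  list(ratio_a = a / length(list_a), ratio_b = b / length(list_b),
       p_value = p)
}
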