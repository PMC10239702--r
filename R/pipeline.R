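# End-to-end orchestration: simulate a cohort, call CASs per tissue, run the
# DEG, 3D-genome, regulatory and clinical stages, and write a reproducible
# report bundle with a provenance manifest.

#' Configure a pipeline run
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (the
#'   simulation route; externally supplied matrices can be analyzed with the
#'   stage functions directly).
#' @param out_dir Output directory (created if absent).
#' @param thresholds CAS-calling thresholds (`poc, q_occ, logfc, q_int`).
#' @param deg_thresholds DEG definition (`lfc`, `fdr`).
#' @param switch_delta Compartment-switch |E| difference threshold.
#' @param n_draws Background draws for DRS and loop/methylation envelopes.
#' @param near_bp CAS-DEG distance threshold (bp).
#' @param stages Character vector of stages to run, a subset of
#'   `c("cas", "deg", "structure", "crm", "clinical")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            out_dir = tempfile("cas_run_"),
                            thresholds = list(poc = 0.5, q_occ = 0.01,
                                              logfc = 1, q_int = 0.01),
                            deg_thresholds = list(lfc = 1, fdr = 0.01),
                            switch_delta = 0.05, n_draws = 500,
                            near_bp = 5000,
                            stages = c("cas", "deg", "structure", "crm",
                                       "clinical")) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(vapply(thresholds, function(x) x > 0, TRUE)))
  bad <- setdiff(stages, c("cas", "deg", "structure", "crm", "clinical"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, out_dir = out_dir,
                 thresholds = thresholds, deg_thresholds = deg_thresholds,
                 switch_delta = switch_delta, n_draws = n_draws,
                 near_bp = near_bp, stages = stages),
            class = "pipeline_config")
}

.stage_guard <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-to-report pipeline
#'
#' Simulates the configured cohort, then runs the requested stages in
#' dependency order: CAS calling per tissue, DEG enrichment (DRS per
#' direction, loop model, CAS-DEG partition), 3D statistics (compartment
#' switches, ISC, APA), regulatory statistics (TF enrichment, methylation
#' envelope), and clinical statistics (clustering ARI, survival). All stage
#' outputs are written as TSV/JSON under `out_dir` together with a
#' `manifest.json` recording the seed, thresholds and package version;
#' a rerun with the same config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list (also serialized under `out_dir`).
#' @export
run_cas_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  seed <- config$cohort$seed

  cohort <- .stage_guard("simulate", generate_cohort_chip(config$cohort))
  genedata <- .stage_guard("simulate", generate_expression(cohort))
  write_bed(cohort$sites, file.path(config$out_dir, "consensus_sites.bed"))

  cas_by_tissue <- list()
  if ("cas" %in% config$stages) {
    for (tt in cohort$tissues) {
      d <- .stage_guard("cas", cas_differential(
        cohort$occupancy[[tt]], cohort$intensity[[tt]], cohort$manifest,
        sites = cohort$sites))
      cas <- call_cas(d, config$thresholds)
      cas_by_tissue[[tt]] <- cas
      write_tsv(d, file.path(config$out_dir,
                             paste0("differential_", tt, ".tsv")))
      bed <- attr(cas, "sites")
      bed$id <- cas$direction
      bed$score <- round(-log10(pmax(pmin(cas$q_occ, cas$q_int),
                                     1e-300)), 3)
      write_bed(bed, file.path(config$out_dir, paste0("cas_", tt, ".bed")))
      truth <- cohort$truth[[paste0("class_", tt)]]
      called <- cohort$truth$site_id %in% cas$site_id
      report$cas[[tt]] <- list(
        n_cas = nrow(cas), n_gained = sum(cas$direction == "gained"),
        n_lost = sum(cas$direction == "lost"),
        sensitivity = sum(called & truth != "stable") /
          max(1, sum(truth != "stable")),
        fdr = if (nrow(cas)) sum(called & truth == "stable") / nrow(cas)
              else 0)
    }
    sets <- lapply(cas_by_tissue, function(cas) attr(cas, "sites"))
    report$simpson <- simpson_matrix(sets)
  }

  tt1 <- cohort$tissues[1]
  cas1 <- if (length(cas_by_tissue)) attr(cas_by_tissue[[tt1]], "sites")
          else NULL
  dir1 <- if (length(cas_by_tissue)) cas_by_tissue[[tt1]]$direction

  if ("deg" %in% config$stages && !is.null(cas1) && nrow(cas1)) {
    de <- genedata$de[[tt1]]
    gained <- cas1[dir1 == "gained", , drop = FALSE]
    lost <- cas1[dir1 == "lost", , drop = FALSE]
    report$drs <- list(
      all = drs_score(cas1, cohort$sites, genedata$genes, de,
                      n_draws = config$n_draws, seed = seed)$drs,
      gained_up = drs_score(gained, cohort$sites, genedata$genes, de,
                            n_draws = config$n_draws, seed = seed,
                            direction_filter = "up")$drs,
      lost_down = drs_score(lost, cohort$sites, genedata$genes, de,
                            n_draws = config$n_draws, seed = seed,
                            direction_filter = "down")$drs)
    part <- casdeg_partition(cas1, de, genedata$genes, config$near_bp)
    report$casdeg <- list(n_cas_degs = length(part$cas_degs),
                          n_other_degs = length(part$other_degs),
                          p_value = part$p_value)
    loops <- generate_gene_loops(cohort, genedata, tt1)
    write_bedpe(loops, file.path(config$out_dir, "loops.bedpe"))
    lm <- loop_model_enrichment(cas1, loops, genedata$genes, de,
                                cohort$sites, n_draws = config$n_draws,
                                seed = seed)
    report$loop_model <- list(r_cas = lm$r_cas,
                              r_background_mean = mean(lm$r_background),
                              p = lm$wilcoxon_p, effect = lm$effect_size)
  }

  if ("structure" %in% config$stages) {
    tr <- .stage_guard("structure", generate_3d_tracks(cohort, tt1))
    sw <- compartment_switch_classify(cohort$sites, tr$pc1_cancer,
                                      tr$pc1_normal, config$switch_delta)
    cls <- cohort$truth[[paste0("class_", tt1)]]
    by_class <- function(keep) {
      x <- sw$calls$class[keep & sw$calls$class != "undefined"]
      prop.table(table(x))
    }
    report$switches <- list(
      all = by_class(rep(TRUE, nrow(cohort$sites))),
      gained = by_class(cls == "gained"),
      lost = by_class(cls == "lost"))
    for (ch in names(tr$is_cancer)) {
      write_bedgraph(tr$is_cancer[[ch]],
                     file.path(config$out_dir, paste0("is_cancer_", ch,
                                                      ".bedgraph")))
    }
    bnd <- do.call(rbind, lapply(tr$is_normal, boundary_call))
    isc <- isc_site_stats(tr$is_cancer, tr$is_normal, cohort$sites, bnd)
    report$isc <- list(
      mean_gained = mean(isc$isc[cls == "gained"], na.rm = TRUE),
      mean_lost = mean(isc$isc[cls == "lost"], na.rm = TRUE),
      mean_all = mean(isc$isc, na.rm = TRUE))
    cm <- generate_contacts_and_loops(seed = seed)
    ap <- apa_compare(cm$cancer, cm$normal, cm$loops[cm$loops$cas_linked, ])
    report$apa <- list(normalized_ratio = ap$normalized_ratio,
                       p = ap$p_value)
  }

  if ("crm" %in% config$stages) {
    cls <- cohort$truth[[paste0("class_", tt1)]]
    aux <- .stage_guard("crm", generate_clinical_aux(
      cohort, genedata, tt1))
    if (!is.null(cas1) && nrow(cas1)) {
      tfe <- tf_enrichment(cas1, cohort$sites, aux$tf_peaks)
      report$tf <- tfe[, c("tf", "prop_cas", "prop_background", "p", "q")]
    }
    lost_sites <- cohort$sites[cls == "lost", , drop = FALSE]
    me <- methylation_differential(aux$methylation, lost_sites,
                                   cohort$sites, n_draws = config$n_draws,
                                   seed = seed, direction = "hyper")
    report$methylation <- list(lost_ratio = me$query_ratio,
                               envelope_hi = me$background_quantiles[[3]],
                               enriched = me$enriched)
  }

  if ("clinical" %in% config$stages && !is.null(cas1) && nrow(cas1)) {
    de <- genedata$de[[tt1]]
    part <- casdeg_partition(cas1, de, genedata$genes, config$near_bp)
    truth_lab <- paste(genedata$sample_info$tissue,
                       genedata$sample_info$condition)
    if (length(part$cas_degs) >= 2) {
      pred <- cluster_patients(genedata$expr, part$cas_degs,
                               k = length(unique(truth_lab)), seed = seed)
      report$clustering <- list(
        ari_cas_degs = adjusted_rand_index(truth_lab, pred))
    }
    aux <- generate_clinical_aux(cohort, genedata, tt1)
    km <- km_logrank(aux$survival,
                     stats::setNames(aux$survival$score,
                                     aux$survival$sample_id))
    report$survival <- list(chisq = km$chisq, p = km$p_value)
  }

  manifest <- list(
    package = "cascall",
    version = as.character(utils::packageVersion("cascall")),
    seed = seed,
    thresholds = config$thresholds,
    deg_thresholds = config$deg_thresholds,
    switch_delta = config$switch_delta,
    n_draws = config$n_draws,
    near_bp = config$near_bp,
    stages = config$stages,
    cohort = config$cohort[setdiff(names(config$cohort), "genome")],
    genome = as.list(unclass(config$cohort$genome)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
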