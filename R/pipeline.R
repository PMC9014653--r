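# Pipeline orchestration --------------------------------------------------
#
# Chains simulate -> qc -> reduce -> modules -> associate -> report over
# delimited-text artifacts in an output directory, with a manifest
# recording the per-stage dimension trajectory and parameter echo.

#' Pipeline configuration
#'
#' Collects all stage parameters with defaults matching the protocol the
#' package implements (missingness 20%/40%, CV 20%, ICC 65%, winsorizing
#' at 3, soft power 10, minimum module size 5, merge threshold r = 0.9,
#' overall filter alpha 1e-5, variance target 0.95). The configuration
#' round-trips through JSON.
#'
#' @param sim a [sim_config()] for the simulate stage (or `NULL` when
#'   reading pre-existing fixtures from `input_dir`).
#' @param input_dir directory of fixture files (defaults to `output_dir`).
#' @param output_dir directory for stage artifacts.
#' @param metabolite_missing_max,participant_missing_max,cv_max,icc_min,
#'   winsor_limit,mahalanobis_alpha,manual_exclusions QC parameters
#'   (see [run_qc()]).
#' @param n_components,variance_target PLS-DA parameters.
#' @param beta,min_cluster_size,merge_r network/module parameters.
#' @param overall_alpha,nominal_alpha association parameters.
#' @param seed global seed (overrides `sim$seed` when `sim` is given).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            output_dir = tempfile("sexmetab_run_"),
                            metabolite_missing_max = 0.20,
                            participant_missing_max = 0.40,
                            cv_max = 0.20, icc_min = 0.65,
                            winsor_limit = NULL, mahalanobis_alpha = 0.001,
                            manual_exclusions = character(0),
                            n_components = 5, variance_target = 0.95,
                            beta = 10, min_cluster_size = 5, merge_r = 0.9,
                            overall_alpha = 1e-5, nominal_alpha = 0.05,
                            seed = NULL) {
  check_scalar_number(metabolite_missing_max, "metabolite_missing_max", 0, 1, TRUE, FALSE)
  check_scalar_number(participant_missing_max, "participant_missing_max", 0, 1, TRUE, FALSE)
  check_scalar_number(cv_max, "cv_max", lower = 0)
  check_scalar_number(icc_min, "icc_min", 0, 1)
  check_scalar_number(beta, "beta", lower = 1)
  check_scalar_number(min_cluster_size, "min_cluster_size", lower = 1)
  check_scalar_number(merge_r, "merge_r", 0, 1)
  check_scalar_number(overall_alpha, "overall_alpha", 0, 1, TRUE, TRUE)
  check_scalar_number(nominal_alpha, "nominal_alpha", 0, 1, TRUE, TRUE)
  check_scalar_number(variance_target, "variance_target", 0, 1)
  if (!is.null(seed) && !is.null(sim)) {
    sim$seed <- as.integer(seed)
  }
  structure(list(sim = sim, input_dir = input_dir, output_dir = output_dir,
                 metabolite_missing_max = metabolite_missing_max,
                 participant_missing_max = participant_missing_max,
                 cv_max = cv_max, icc_min = icc_min,
                 winsor_limit = winsor_limit,
                 mahalanobis_alpha = mahalanobis_alpha,
                 manual_exclusions = manual_exclusions,
                 n_components = n_components,
                 variance_target = variance_target,
                 beta = beta, min_cluster_size = min_cluster_size,
                 merge_r = merge_r, overall_alpha = overall_alpha,
                 nominal_alpha = nominal_alpha),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional), qc, reduce (PLS-DA), modules
#' (network + dynamic cut + merge), associate, report. Each stage writes
#' tab-delimited artifacts into the output directory; a `manifest.json`
#' records per-stage dimensions and parameters. Identical configurations
#' (including the seed) produce byte-identical association tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage outputs
#'   (`cohort`, `qc`, `model`, `scores`, `partition`, `eigens`,
#'   `associations`, `plan`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  manifest <- list(stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## simulate / load -----------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- generate_cohort(config$sim)
    write_fixtures(cohort, out)
    inputs <- list(raw = cohort$raw, covariates = cohort$covariates,
                   brain = cohort$brain, medications = cohort$medications,
                   truth = cohort$truth)
    note("simulate", n_participants = nrow(cohort$covariates),
         n_metabolites = ncol(cohort$raw$values), seed = config$sim$seed)
  } else {
    indir <- if (is.null(config$input_dir)) out else config$input_dir
    inputs <- read_fixtures(indir)
    cohort <- NULL
    note("simulate", skipped = TRUE, input_dir = indir)
  }

  ## qc ------------------------------------------------------------------
  qc <- run_qc(inputs$raw, medications = inputs$medications,
               metabolite_missing_max = config$metabolite_missing_max,
               participant_missing_max = config$participant_missing_max,
               cv_max = config$cv_max, icc_min = config$icc_min,
               winsor_limit = config$winsor_limit,
               mahalanobis_alpha = config$mahalanobis_alpha,
               manual_exclusions = config$manual_exclusions)
  clean <- qc$clean
  write_tsv(data.frame(participant_id = rownames(clean$matrix),
                       clean$matrix, check.names = FALSE),
            file.path(out, "clean_matrix.tsv"))
  jsonlite::write_json(
    list(report = qc$report, imputation_log = qc$imputation_log,
         dimensions = qc$dimensions),
    file.path(out, "qc_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  note("qc", dimensions = qc$dimensions,
       n_removed = if (is.null(qc$report)) 0L else nrow(qc$report))

  ## reduce (PLS-DA) -----------------------------------------------------
  cov <- inputs$covariates
  keep_ids <- rownames(clean$matrix)
  cov <- cov[match(keep_ids, cov$participant_id), , drop = FALSE]
  brain <- inputs$brain[match(keep_ids, inputs$brain$participant_id), , drop = FALSE]
  Xb <- normalize_volumes(brain)
  diag3 <- consolidate_diagnosis(cov$diagnosis6)
  model <- fit_plsda(Xb, diag3, n_components = config$n_components)
  comps <- select_components(model, config$variance_target)
  scores <- model$T[, comps, drop = FALSE]
  scr <- score_outlier_screen(model, comps, alpha = config$mahalanobis_alpha)
  if (length(scr$flagged)) {
    keep_ids <- setdiff(keep_ids, scr$flagged)
    clean$matrix <- clean$matrix[keep_ids, , drop = FALSE]
    clean$participant_id <- keep_ids
    scores <- scores[keep_ids, , drop = FALSE]
    cov <- cov[match(keep_ids, cov$participant_id), , drop = FALSE]
  }
  write_tsv(data.frame(participant_id = rownames(scores), scores,
                       check.names = FALSE),
            file.path(out, "scores.tsv"))
  jsonlite::write_json(
    list(weights = model$W, loadings = model$P,
         x_variance = model$x_variance, y_variance = model$y_variance,
         vip = as.list(model$vip), selected_components = comps),
    file.path(out, "model.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  note("reduce", n_components = length(comps),
       x_variance = model$x_variance, score_outliers = length(scr$flagged))

  ## modules -------------------------------------------------------------
  network <- build_network(clean, beta = config$beta)
  partition <- cluster_modules(network, config$min_cluster_size)
  eigens <- compute_eigen(clean, partition)
  if (ncol(eigens$eigens) >= 2) {
    mg <- merge_close_modules(clean, partition, eigens, config$merge_r)
    partition <- mg$partition; eigens <- mg$eigens
  }
  mm <- rep(NA_real_, length(partition$labels))
  names(mm) <- names(partition$labels)
  mm[names(eigens$membership)] <- eigens$membership
  write_tsv(data.frame(metabolite_id = names(partition$labels),
                       module_label = unname(partition$labels),
                       mm = unname(mm)),
            file.path(out, "modules.tsv"))
  write_tsv(data.frame(participant_id = rownames(eigens$eigens),
                       eigens$eigens, check.names = FALSE),
            file.path(out, "eigens.tsv"))
  note("modules", n_modules = ncol(eigens$eigens),
       n_grey = sum(partition$labels == "grey"))

  ## associate -----------------------------------------------------------
  study <- run_association_study(clean, eigens, scores, cov,
                                 overall_alpha = config$overall_alpha,
                                 nominal_alpha = config$nominal_alpha)
  write_tsv(study$results, file.path(out, "associations.tsv"))
  jsonlite::write_json(unclass(study$plan), file.path(out, "plan.json"),
                       auto_unbox = TRUE, digits = NA)
  note("associate", n_rows = nrow(study$results),
       alpha_module = study$plan$alpha_module,
       alpha_single = study$plan$alpha_single)

  ## report --------------------------------------------------------------
  summ <- summarize_associations(study$results)
  jsonlite::write_json(summ, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_summary(summ), file.path(out, "report.txt"))
  note("report", categories = summ$category_totals)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, qc = qc, model = model, scores = scores,
                 partition = partition, eigens = eigens,
                 associations = study$results, plan = study$plan,
                 summary = summ, manifest = manifest))
}

#' Summarize an association results table
#'
#' Tallies classification categories per unit type and component and
#' lists the screening-significant associations.
#'
#' @param results the `results` data.frame from
#'   [run_association_study()] (possibly empty).
#' @return list with `category_totals`, `by_component` (data.frame) and
#'   `winkler_significant` (data.frame of flagged rows).
#' @export
summarize_associations <- function(results) {
  cats <- c("homogeneous", "heterogeneous", "sex-specific", "none")
  if (is.null(results) || !nrow(results)) {
    return(list(category_totals = stats::setNames(as.list(rep(0L, 4)), cats),
                by_component = data.frame(),
                winkler_significant = data.frame()))
  }
  totals <- lapply(cats, function(cc) sum(results$arnold_category == cc))
  names(totals) <- cats
  by_comp <- as.data.frame(table(unit_type = results$unit_type,
                                 component = results$component,
                                 category = results$arnold_category))
  by_comp <- by_comp[by_comp$Freq > 0, , drop = FALSE]
  rownames(by_comp) <- NULL
  list(category_totals = totals, by_component = by_comp,
       winkler_significant = results[isTRUE_vec(results$winkler_any),
                                     c("unit", "unit_type", "component",
                                       "p_diff", "p_overall")])
}

isTRUE_vec <- function(x) !is.na(x) & x

format_summary <- function(summ) {
  c(sprintf("associations by category: %s",
            paste(sprintf("%s=%d", names(summ$category_totals),
                          unlist(summ$category_totals)), collapse = ", ")),
    sprintf("screening-significant associations: %d",
            nrow(summ$winkler_significant)))
}
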