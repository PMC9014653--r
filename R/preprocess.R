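# Metabolomics quality control -------------------------------------------
#
# Record-level QC for two platform styles: a targeted panel with plates,
# assay replicates and per-plate limits of detection, and an NMR-style
# panel with QC tags and half-minimum imputation. Each operation returns
# the filtered data plus report entries; run_qc() chains them in the
# protocol order and accumulates a provenance log.

qc_entry <- function(step, kind, ids, detail = NA_character_) {
  if (!length(ids)) return(NULL)
  data.frame(step = step, kind = kind, id = ids, detail = detail,
             stringsAsFactors = FALSE)
}

#' Filter metabolites and participants by missingness
#'
#' Metabolites with a missing fraction at or above `metabolite_thresh`
#' are removed first; then records with a missing fraction strictly above
#' `participant_thresh` are removed. The asymmetry (inclusive vs strict)
#' follows the usual wording of metabolomics QC protocols ("20% or more"
#' for analytes, "greater than 40%" for participants).
#'
#' @param data a [raw_metabolite_data()] object.
#' @param metabolite_thresh,participant_thresh fractions in (0, 1].
#' @return list with elements `data` (filtered) and `report` (data.frame
#'   of removed ids with reasons).
#' @export
filter_by_missingness <- function(data, metabolite_thresh = 0.20,
                                  participant_thresh = 0.40) {
  stopifnot(inherits(data, "raw_metab"))
  check_scalar_number(metabolite_thresh, "metabolite_thresh", 0, 1, TRUE, FALSE)
  check_scalar_number(participant_thresh, "participant_thresh", 0, 1, TRUE, FALSE)
  miss_met <- colMeans(is.na(data$values))
  drop_met <- names(miss_met)[miss_met >= metabolite_thresh]
  keep <- setdiff(colnames(data$values), drop_met)
  if (!length(keep)) stop("no metabolites left after missingness filter")
  data$values <- data$values[, keep, drop = FALSE]
  miss_rec <- rowMeans(is.na(data$values))
  drop_rec <- rownames(data$values)[miss_rec > participant_thresh]
  data <- drop_records(data, drop_rec)
  if (!nrow(data$values)) stop("no participants left after missingness filter")
  report <- rbind(
    qc_entry("missingness", "metabolite", drop_met,
             sprintf("missing fraction >= %g", metabolite_thresh)),
    qc_entry("missingness", "participant",
             unique(data_participants_of(drop_rec)),
             sprintf("missing fraction > %g", participant_thresh)))
  list(data = data, report = report)
}

data_participants_of <- function(record_ids) sub("_r[0-9]+$", "", record_ids)

drop_records <- function(data, record_ids) {
  if (!length(record_ids)) return(data)
  keep <- !(rownames(data$values) %in% record_ids)
  data$values <- data$values[keep, , drop = FALSE]
  data$records <- data$records[keep, , drop = FALSE]
  data
}

#' Cross-plate mean normalization
#'
#' For each metabolite, every plate's values are multiplied by the ratio
#' of the metabolite's grand mean to its plate mean, so that after the
#' step each plate's mean equals the grand mean. The multiplicative form
#' preserves positivity for the later log transform and is idempotent.
#' A plate with no observed values for a metabolite is left unscaled with
#' a warning.
#'
#' @param data a [raw_metabolite_data()] object.
#' @return the normalized object.
#' @export
crossplate_normalize <- function(data) {
  stopifnot(inherits(data, "raw_metab"))
  plates <- unique(data$records$plate_id)
  if (length(plates) < 2) return(data)
  for (j in colnames(data$values)) {
    v <- data$values[, j]
    grand <- mean(v, na.rm = TRUE)
    for (pl in plates) {
      rows <- data$records$plate_id == pl
      pm <- mean(v[rows], na.rm = TRUE)
      if (!is.finite(pm)) {
        warning(sprintf("plate %s has no observed values for %s; left unscaled", pl, j))
        next
      }
      if (pm <= 0) stop(sprintf("non-positive plate mean for %s on %s", j, pl))
      data$values[rows, j] <- v[rows] * (grand / pm)
    }
  }
  data
}

#' Replicate-based analyte quality metrics (CV and ICC)
#'
#' The coefficient of variation per metabolite is the arithmetic mean over
#' replicate groups (participants with at least two records) of the group
#' SD divided by the group mean. The intraclass correlation is the one-way
#' random-effects estimate from the replicate-group ANOVA,
#' `(MSB - MSW) / (MSB + (k0 - 1) * MSW)`, with `k0` the unbalanced-design
#' effective group size. Metabolites with `CV > cv_max` (strict) or
#' `ICC < icc_min` (strict) are removed.
#'
#' @param data a [raw_metabolite_data()] object with replicate records.
#' @param cv_max,icc_min quality thresholds (fractions).
#' @return list with `data` (filtered), `metrics` (per-metabolite CV/ICC),
#'   and `report`.
#' @export
replicate_quality <- function(data, cv_max = 0.20, icc_min = 0.65) {
  stopifnot(inherits(data, "raw_metab"))
  grp <- split(seq_len(nrow(data$values)), data$records$participant_id)
  grp <- grp[lengths(grp) >= 2]
  if (!length(grp)) {
    warning("no replicate groups; CV/ICC filtering skipped")
    return(list(data = data, metrics = NULL, report = NULL))
  }
  mets <- colnames(data$values)
  cv <- icc <- stats::setNames(rep(NA_real_, length(mets)), mets)
  for (j in mets) {
    v <- data$values[, j]
    gm <- lapply(grp, function(r) v[r][!is.na(v[r])])
    gm <- gm[lengths(gm) >= 2]
    if (!length(gm)) next
    cv[j] <- mean(vapply(gm, function(x) stats::sd(x) / mean(x), numeric(1)))
    icc[j] <- icc_oneway(gm)
  }
  drop <- mets[(!is.na(cv) & cv > cv_max) | (!is.na(icc) & icc < icc_min)]
  report <- rbind(
    qc_entry("replicate_quality", "metabolite",
             mets[!is.na(cv) & cv > cv_max], sprintf("CV > %g", cv_max)),
    qc_entry("replicate_quality", "metabolite",
             mets[!is.na(icc) & icc < icc_min], sprintf("ICC < %g", icc_min)))
  data$values <- data$values[, setdiff(mets, drop), drop = FALSE]
  list(data = data,
       metrics = data.frame(metabolite_id = mets, cv = cv, icc = icc,
                            row.names = NULL),
       report = report)
}

# One-way random-effects ICC from a list of replicate-group vectors.
icc_oneway <- function(groups) {
  a <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  if (a < 2) return(NA_real_)
  gmeans <- vapply(groups, mean, numeric(1))
  grand <- sum(ni * gmeans) / N
  ssb <- sum(ni * (gmeans - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)    # effective group size, unbalanced
  if (msw == 0) return(1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

#' Average replicate records into one record per participant
#'
#' Each metabolite value becomes the arithmetic mean of the participant's
#' non-missing replicate values; the result is missing only if every
#' replicate was missing. The collapsed record keeps the participant's
#' first plate assignment.
#'
#' @param data a [raw_metabolite_data()] object.
#' @return the collapsed object (one record per participant,
#'   `replicate_no == 1`).
#' @export
collapse_replicates <- function(data) {
  stopifnot(inherits(data, "raw_metab"))
  pid <- unique(data$records$participant_id)
  out <- matrix(NA_real_, length(pid), ncol(data$values),
                dimnames = list(sprintf("%s_r1", pid), colnames(data$values)))
  plate <- character(length(pid))
  for (i in seq_along(pid)) {
    rows <- which(data$records$participant_id == pid[i])
    m <- data$values[rows, , drop = FALSE]
    out[i, ] <- colMeans(m, na.rm = TRUE)
    plate[i] <- data$records$plate_id[rows[1]]
  }
  out[is.nan(out)] <- NA_real_
  data$values <- out
  data$records <- data.frame(record_id = rownames(out), participant_id = pid,
                             plate_id = plate, replicate_no = 1L,
                             stringsAsFactors = FALSE)
  # QC tags follow the participant after collapsing
  if (nrow(data$qc_tags)) {
    data$qc_tags$record_id <- sprintf(
      "%s_r1", data_participants_of(data$qc_tags$record_id))
    data$qc_tags <- unique(data$qc_tags)
  }
  data
}

#' Remove participants by fasting status and QC tags
#'
#' Non-fasting participants are always removed. On the NMR platform,
#' records whose missing cells carry any QC tag other than the
#' below-quantification tag (e.g. "low ethanol", indicating disinfectant
#' contamination) are also removed; below-quantification misses are kept
#' for later imputation.
#'
#' @param data a [raw_metabolite_data()] object.
#' @param blq_tag the tag marking below-limit-of-quantification misses.
#' @return list with `data` and `report`.
#' @export
filter_participants_by_flags <- function(data,
                                         blq_tag = "below limit of quantification") {
  stopifnot(inherits(data, "raw_metab"))
  nonfast <- names(data$fasting)[!data$fasting]
  drop_rec <- rownames(data$values)[data$records$participant_id %in% nonfast]
  report <- qc_entry("flags", "participant",
                     intersect(nonfast, data$records$participant_id),
                     "non-fasting")
  data <- drop_records(data, drop_rec)
  if (data$platform == "nmr" && nrow(data$qc_tags)) {
    bad <- data$qc_tags[data$qc_tags$tag != blq_tag, , drop = FALSE]
    bad_rec <- intersect(unique(bad$record_id), rownames(data$values))
    if (length(bad_rec)) {
      report <- rbind(report, qc_entry(
        "flags", "participant", unique(data_participants_of(bad_rec)),
        "missing value with non-BLQ QC tag"))
      data <- drop_records(data, bad_rec)
    }
  }
  list(data = data, report = report)
}

#' Impute left-censored missing values
#'
#' Targeted platform: each missing cell is replaced by half the limit of
#' detection for that metabolite on the record's plate. NMR platform: half
#' the minimum observed value of the metabolite. Every imputed cell is
#' logged.
#'
#' @param data a [raw_metabolite_data()] object whose remaining missing
#'   values are attributable to left-censoring.
#' @return list with `data` (complete matrix) and `log` (data.frame with
#'   one row per imputed cell).
#' @export
impute_left_censored <- function(data) {
  stopifnot(inherits(data, "raw_metab"))
  idx <- which(is.na(data$values), arr.ind = TRUE)
  if (!nrow(idx))
    return(list(data = data, log = data.frame(record_id = character(),
                                              metabolite_id = character(),
                                              imputed = numeric(),
                                              rule = character())))
  met <- colnames(data$values)[idx[, 2]]
  if (data$platform == "targeted") {
    plate <- data$records$plate_id[idx[, 1]]
    bad <- is.na(data$lod[cbind(met, plate)])
    if (any(bad))
      stop(sprintf("missing LOD entry for (%s, %s)", met[bad][1], plate[bad][1]))
    imputed <- data$lod[cbind(met, plate)] / 2
    rule <- "half-LOD"
  } else {
    mins <- apply(data$values, 2, min, na.rm = TRUE)
    imputed <- mins[met] / 2
    rule <- "half-minimum"
  }
  data$values[idx] <- imputed
  list(data = data,
       log = data.frame(record_id = rownames(data$values)[idx[, 1]],
                        metabolite_id = met, imputed = unname(imputed),
                        rule = rule, stringsAsFactors = FALSE))
}

#' Transform concentrations to winsorized z-scores
#'
#' Applies, in this fixed order: add 1 to every concentration (so zero
#' LODs remain loggable), log2-transform, per-column z-score (population
#' SD), then clamp to `[-winsor_limit, winsor_limit]`. Set
#' `winsor_limit = Inf` to skip winsorizing (NMR-style processing).
#'
#' @param data a [raw_metabolite_data()] object with no missing values.
#' @param winsor_limit clamp bound in z-units (default 3).
#' @return object of class `clean_metab`: list with `matrix`
#'   (participants x metabolites, rownames are participant ids),
#'   `participant_id`, and a `provenance` character vector.
#' @export
transform_concentrations <- function(data, winsor_limit = 3) {
  stopifnot(inherits(data, "raw_metab"))
  if (any(is.na(data$values)))
    stop("transform requires a complete matrix; impute first")
  if (any(data$values < 0)) stop("concentration values must be non-negative")
  m <- log2(data$values + 1)
  for (j in seq_len(ncol(m))) {
    s <- sqrt(mean((m[, j] - mean(m[, j]))^2))
    if (s == 0)
      stop(sprintf("zero-variance column: %s", colnames(m)[j]))
    m[, j] <- (m[, j] - mean(m[, j])) / s
  }
  m <- pmin(pmax(m, -winsor_limit), winsor_limit)
  rownames(m) <- data$records$participant_id
  structure(list(matrix = m, participant_id = data$records$participant_id,
                 provenance = sprintf("add1/log2/zscore/winsor(%g)", winsor_limit)),
            class = "clean_metab")
}

#' @export
print.clean_metab <- function(x, ...) {
  cat(sprintf("clean_metab: %d participants x %d metabolites\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Multivariate outlier screen via the Mahalanobis distance
#'
#' Computes squared Mahalanobis distances from the sample mean under the
#' sample covariance and flags rows whose upper-tail chi-square
#' probability (df = number of variables) falls below `alpha`.
#'
#' @param matrix numeric matrix, observations x variables, with more
#'   observations than variables.
#' @param alpha tail probability threshold (default 0.001).
#' @return list with `flagged` (rownames or indices of flagged rows),
#'   `d2` (squared distances) and `p` (tail probabilities).
#' @export
mahalanobis_screen <- function(matrix, alpha = 0.001) {
  m <- as.matrix(matrix)
  n <- nrow(m); p <- ncol(m)
  if (n <= p)
    stop("Mahalanobis screen requires more observations than variables; reduce dimension first")
  S <- stats::cov(m)
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok || rcond(S) < 1e-12)
    stop("singular sample covariance; reduce dimension (e.g. PCA/PLS scores) first")
  d2 <- stats::mahalanobis(m, colMeans(m), S)
  pv <- stats::pchisq(d2, df = p, lower.tail = FALSE)
  flagged <- if (!is.null(rownames(m))) rownames(m)[pv < alpha] else which(pv < alpha)
  list(flagged = flagged, d2 = d2, p = pv)
}

#' Residualize metabolites on medication intake
#'
#' For each metabolite column, fits a linear regression on the binary
#' medication indicators, removes the least significant predictor until
#' all remaining predictors have `P < alpha_keep` (backward selection),
#' and replaces the column by the residuals of the final model. Columns
#' for which no predictor survives pass through unchanged. Duplicate
#' (collinear) medication columns are dropped with a warning.
#'
#' @param clean a `clean_metab` object.
#' @param medications data.frame or matrix of binary indicators with
#'   either a `participant_id` column or rownames aligned to the clean
#'   matrix.
#' @param alpha_keep significance threshold for keeping a predictor.
#' @return the residualized `clean_metab` object, with an attribute
#'   `kept_medications` (list per metabolite).
#' @export
residualize_medications <- function(clean, medications, alpha_keep = 0.05) {
  stopifnot(inherits(clean, "clean_metab"))
  meds <- medications
  if (is.data.frame(meds) && "participant_id" %in% names(meds)) {
    rn <- meds$participant_id
    meds <- as.matrix(meds[, setdiff(names(meds), "participant_id"), drop = FALSE])
    rownames(meds) <- rn
  } else meds <- as.matrix(meds)
  if (ncol(meds) == 0) return(clean)
  if (!is.null(rownames(meds))) {
    missing_ids <- setdiff(clean$participant_id, rownames(meds))
    if (length(missing_ids))
      stop("medication matrix missing participants: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    meds <- meds[clean$participant_id, , drop = FALSE]
  } else if (nrow(meds) != nrow(clean$matrix))
    stop("medication matrix not aligned to participants")
  dup <- duplicated(t(meds))
  if (any(dup)) {
    warning("dropping duplicated medication columns: ",
            paste(colnames(meds)[dup], collapse = ", "))
    meds <- meds[, !dup, drop = FALSE]
  }
  kept <- vector("list", ncol(clean$matrix))
  names(kept) <- colnames(clean$matrix)
  for (j in seq_len(ncol(clean$matrix))) {
    y <- clean$matrix[, j]
    active <- colnames(meds)
    repeat {
      if (!length(active)) break
      fit <- stats::lm(y ~ ., data = as.data.frame(meds[, active, drop = FALSE]))
      pv <- summary(fit)$coefficients[-1, 4]
      if (!length(pv) || max(pv) < alpha_keep) break
      active <- setdiff(active, active[which.max(pv)])
    }
    kept[[j]] <- active
    if (length(active)) {
      fit <- stats::lm(y ~ ., data = as.data.frame(meds[, active, drop = FALSE]))
      clean$matrix[, j] <- stats::residuals(fit)
    }
  }
  attr(clean, "kept_medications") <- kept
  clean
}

#' Run the full metabolomics QC protocol
#'
#' Chains the QC operations in the protocol order for the data's platform.
#' Targeted: missingness filter, cross-plate normalization, replicate
#' CV/ICC filter, fasting filter, replicate averaging, manual exclusions,
#' half-LOD imputation, add-1/log2/z-score/winsorize, medication
#' residualization, Mahalanobis outlier removal. NMR: missingness filter,
#' fasting + QC-tag filter, replicate averaging, manual exclusions,
#' half-minimum imputation, add-1/log2/z-score (no winsorizing by
#' default), medication residualization, Mahalanobis removal.
#'
#' @param data a [raw_metabolite_data()] object.
#' @param medications optional medication indicator table (see
#'   [residualize_medications()]).
#' @param metabolite_missing_max,participant_missing_max missingness
#'   thresholds.
#' @param cv_max,icc_min replicate quality thresholds.
#' @param winsor_limit clamp bound; `NULL` selects the platform default
#'   (3 for targeted, `Inf` for NMR).
#' @param mahalanobis_alpha outlier screen tail probability; `NA` skips
#'   the screen (e.g. when p >= n).
#' @param manual_exclusions character vector of metabolite ids excluded
#'   for bespoke assay reasons (calibration issues etc.).
#' @return list with `clean` (a `clean_metab` object), `report`
#'   (removals with reasons), `imputation_log`, `metrics` (CV/ICC), and
#'   `dimensions` (the per-step dimension trajectory).
#' @export
run_qc <- function(data, medications = NULL,
                   metabolite_missing_max = 0.20,
                   participant_missing_max = 0.40,
                   cv_max = 0.20, icc_min = 0.65,
                   winsor_limit = NULL, mahalanobis_alpha = 0.001,
                   manual_exclusions = character(0)) {
  stopifnot(inherits(data, "raw_metab"))
  if (is.null(winsor_limit))
    winsor_limit <- if (data$platform == "targeted") 3 else Inf
  dims <- list(input = dim(data$values))
  report <- NULL

  st <- filter_by_missingness(data, metabolite_missing_max, participant_missing_max)
  data <- st$data; report <- rbind(report, st$report)
  dims$missingness <- dim(data$values)

  metrics <- NULL
  if (data$platform == "targeted") {
    data <- crossplate_normalize(data)
    rq <- replicate_quality(data, cv_max, icc_min)
    data <- rq$data; metrics <- rq$metrics
    report <- rbind(report, rq$report)
    dims$replicate_quality <- dim(data$values)
  }

  fl <- filter_participants_by_flags(data)
  data <- fl$data; report <- rbind(report, fl$report)
  dims$flags <- dim(data$values)

  data <- collapse_replicates(data)
  dims$collapsed <- dim(data$values)

  manual <- intersect(manual_exclusions, colnames(data$values))
  if (length(manual)) {
    data$values <- data$values[, setdiff(colnames(data$values), manual),
                               drop = FALSE]
    report <- rbind(report, qc_entry("manual", "metabolite", manual,
                                     "manual exclusion list"))
  }

  imp <- impute_left_censored(data)
  data <- imp$data
  clean <- transform_concentrations(data, winsor_limit)

  if (!is.null(medications))
    clean <- residualize_medications(clean, medications)

  if (!is.na(mahalanobis_alpha)) {
    scr <- mahalanobis_screen(clean$matrix, mahalanobis_alpha)
    if (length(scr$flagged)) {
      keep <- setdiff(rownames(clean$matrix), scr$flagged)
      clean$matrix <- clean$matrix[keep, , drop = FALSE]
      clean$participant_id <- keep
      report <- rbind(report, qc_entry("mahalanobis", "participant",
                                       scr$flagged,
                                       sprintf("chi-square P < %g", mahalanobis_alpha)))
    }
  }
  dims$final <- dim(clean$matrix)
  list(clean = clean, report = report, imputation_log = imp$log,
       metrics = metrics, dimensions = dims)
}
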