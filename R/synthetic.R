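# Synthetic cohort generation -------------------------------------------
#
# Generates ADNI-like cohorts with a known ground truth so every stage of
# the pipeline (QC, PLS-DA, network modules, sex-stratified association)
# has a recoverable answer. The generative model is a latent-factor model:
# a continuous disease-severity factor drives diagnosis-linked brain
# atrophy (with ventricular enlargement), and metabolite modules load on
# the latent brain factors with per-sex coefficients.

BRAIN_SEGMENTS <- c("ventricles", "hippocampus", "entorhinal",
                    "fusiform", "midtemporal", "wholebrain")
N_BRAIN_FACTORS <- 5L

DEFAULT_ATROPHY <- c(ventricles = 0.25, hippocampus = -0.10,
                     entorhinal = -0.12, fusiform = -0.05,
                     midtemporal = -0.07, wholebrain = -0.035)

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' defaults describe a cohort of the size and structure typical of a
#' multi-site neuroimaging/metabolomics study: roughly 45% female, three
#' consolidated diagnosis groups, block-correlated metabolite panels with
#' multiplicative plate effects, left-censoring at the limit of detection,
#' and a small fraction of duplicated/triplicated assay records.
#'
#' @param n_participants number of biological participants.
#' @param sex_ratio fraction of participants that are female.
#' @param n_metabolites total number of metabolites on the panel.
#' @param module_spec list of module descriptions, each a list with
#'   elements `size` (member count), `rho` (target within-module pairwise
#'   correlation, in `[0, 1)`), and `effects`, itself a list with numeric
#'   vectors `female` and `male` giving the module latent factor's loading
#'   on each latent brain factor (recycled/padded to 5 factors; factor 1
#'   is the disease-severity axis). Module sizes must sum to at most
#'   `n_metabolites`; the remainder are uncorrelated "noise" metabolites.
#' @param n_plates number of assay plates.
#' @param plate_effect_sd SD of the per-metabolite, per-plate multiplicative
#'   batch effect on the log scale.
#' @param lod_quantile fraction of each plate's values censored below the
#'   limit of detection (0 disables censoring).
#' @param replicate_fraction fraction of participants assayed more than once.
#' @param replicate_noise_sd SD of replicate technical noise in latent
#'   z-units.
#' @param diagnosis_probs length-3 probability vector for CN/MCI/AD.
#' @param atrophy_effects named length-6 vector of fractional volume change
#'   per diagnosis step for each brain segment (positive = enlargement).
#' @param nonfasting_fraction fraction of participants flagged non-fasting.
#' @param n_medications number of binary medication indicators.
#' @param med_effects optional `n_medications x n_metabolites` matrix of
#'   additive medication effects in latent z-units (default none).
#' @param platform `"targeted"` (plate/LOD metadata) or `"nmr"` (QC tags,
#'   half-minimum imputation downstream).
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1000,
                       sex_ratio = 0.45,
                       n_metabolites = 60,
                       module_spec = default_module_spec(),
                       n_plates = 4,
                       plate_effect_sd = 0.1,
                       lod_quantile = 0.02,
                       replicate_fraction = 0.1,
                       replicate_noise_sd = 0.1,
                       diagnosis_probs = c(0.45, 0.40, 0.15),
                       atrophy_effects = DEFAULT_ATROPHY,
                       nonfasting_fraction = 0.05,
                       n_medications = 5,
                       med_effects = NULL,
                       platform = c("targeted", "nmr"),
                       seed = 1L) {
  platform <- match.arg(platform)
  check_scalar_number(n_participants, "n_participants", lower = 10)
  check_scalar_number(sex_ratio, "sex_ratio", 0, 1, TRUE, TRUE)
  check_scalar_number(n_metabolites, "n_metabolites", lower = 1)
  check_scalar_number(n_plates, "n_plates", lower = 1)
  check_scalar_number(plate_effect_sd, "plate_effect_sd", lower = 0)
  check_scalar_number(lod_quantile, "lod_quantile", 0, 0.5)
  check_scalar_number(replicate_fraction, "replicate_fraction", 0, 1)
  check_scalar_number(replicate_noise_sd, "replicate_noise_sd", lower = 0)
  check_scalar_number(nonfasting_fraction, "nonfasting_fraction", 0, 1)
  check_scalar_number(n_medications, "n_medications", lower = 0)
  if (!is.numeric(diagnosis_probs) || length(diagnosis_probs) != 3L ||
      any(diagnosis_probs < 0) || abs(sum(diagnosis_probs) - 1) > 1e-8)
    stop_config("diagnosis_probs", "must be a 3-vector of probabilities summing to 1")
  if (!is.numeric(atrophy_effects) || length(atrophy_effects) != 6L)
    stop_config("atrophy_effects", "must be a length-6 numeric vector")
  atrophy_effects <- stats::setNames(as.numeric(atrophy_effects), BRAIN_SEGMENTS)
  if (!is.list(module_spec))
    stop_config("module_spec", "must be a list of module descriptions")
  module_spec <- lapply(module_spec, normalize_module_entry)
  sizes <- vapply(module_spec, function(m) m$size, numeric(1))
  if (sum(sizes) > n_metabolites)
    stop_config("module_spec", "module sizes exceed n_metabolites")
  if (!is.null(med_effects)) {
    med_effects <- as.matrix(med_effects)
    if (nrow(med_effects) != n_medications || ncol(med_effects) != n_metabolites)
      stop_config("med_effects", "must be n_medications x n_metabolites")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("seed", "must be a single integer")
  structure(list(
    n_participants = as.integer(n_participants), sex_ratio = sex_ratio,
    n_metabolites = as.integer(n_metabolites), module_spec = module_spec,
    n_plates = as.integer(n_plates), plate_effect_sd = plate_effect_sd,
    lod_quantile = lod_quantile, replicate_fraction = replicate_fraction,
    replicate_noise_sd = replicate_noise_sd,
    diagnosis_probs = diagnosis_probs, atrophy_effects = atrophy_effects,
    nonfasting_fraction = nonfasting_fraction,
    n_medications = as.integer(n_medications), med_effects = med_effects,
    platform = platform, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default module specification
#'
#' Three correlated metabolite modules. The first has a sex-differential
#' loading on the disease-severity brain factor (female 0.6, male 0.2, a
#' between-sex gap of 0.4 with both sexes carrying a detectable signal);
#' the second loads equally in both sexes; the third is a pure correlation
#' block with no brain association.
#'
#' @return list suitable for the `module_spec` argument of [sim_config()].
#' @export
default_module_spec <- function() {
  list(
    list(size = 15, rho = 0.6,
         effects = list(female = c(0.6, 0, 0, 0, 0),
                        male   = c(0.2, 0, 0, 0, 0))),
    list(size = 15, rho = 0.6,
         effects = list(female = c(0.3, 0, 0, 0, 0),
                        male   = c(0.3, 0, 0, 0, 0))),
    list(size = 10, rho = 0.6,
         effects = list(female = numeric(5), male = numeric(5)))
  )
}

normalize_module_entry <- function(m) {
  if (is.null(m$size) || m$size < 1)
    stop_config("module_spec$size", "module size must be a positive count")
  if (is.null(m$rho) || m$rho < 0 || m$rho >= 1)
    stop_config("module_spec$rho", "rho must lie in [0, 1)")
  eff <- m$effects
  if (is.null(eff)) eff <- list(female = numeric(5), male = numeric(5))
  pad <- function(v) { v <- as.numeric(v); length(v) <- N_BRAIN_FACTORS; v[is.na(v)] <- 0; v }
  list(size = as.integer(m$size), rho = as.numeric(m$rho),
       effects = list(female = pad(eff$female), male = pad(eff$male)))
}

#' Container for raw metabolomics assay data
#'
#' Record-level concentration values with plate, replicate, LOD, QC-tag
#' and fasting metadata. Rows of `values` are assay records (a participant
#' may contribute several replicate records); columns are metabolites.
#'
#' @param values numeric matrix, records x metabolites, with dimnames;
#'   missing values allowed, all recorded values must be non-negative.
#' @param records data.frame with columns `record_id`, `participant_id`,
#'   `plate_id`, `replicate_no`, one row per row of `values`.
#' @param lod metabolite x plate matrix of limits of detection (required
#'   for the targeted platform; may be `NULL` for NMR).
#' @param qc_tags data.frame with columns `record_id`, `metabolite_id`,
#'   `tag` describing flagged (missing) cells.
#' @param fasting named logical vector per participant.
#' @param platform `"targeted"` or `"nmr"`.
#' @return object of class `raw_metab`.
#' @export
raw_metabolite_data <- function(values, records, lod = NULL,
                                qc_tags = empty_qc_tags(),
                                fasting = NULL,
                                platform = c("targeted", "nmr")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values matrix must have record and metabolite dimnames")
  if (any(values < 0, na.rm = TRUE))
    stop("recorded concentration values must be non-negative")
  if (nrow(records) != nrow(values) ||
      !all(records$record_id == rownames(values)))
    stop("records metadata must align with the rows of 'values'")
  if (platform == "targeted") {
    if (is.null(lod)) stop("targeted platform requires an LOD matrix")
    lod <- as.matrix(lod)
    missing_met <- setdiff(colnames(values), rownames(lod))
    missing_pl <- setdiff(unique(records$plate_id), colnames(lod))
    if (length(missing_met) || length(missing_pl))
      stop("LOD must be defined for every (metabolite, plate)")
  }
  if (is.null(fasting)) {
    fasting <- rep(TRUE, length(unique(records$participant_id)))
    names(fasting) <- unique(records$participant_id)
  }
  structure(list(values = values, records = records, lod = lod,
                 qc_tags = qc_tags, fasting = fasting, platform = platform),
            class = "raw_metab")
}

empty_qc_tags <- function() {
  data.frame(record_id = character(), metabolite_id = character(),
             tag = character(), stringsAsFactors = FALSE)
}

#' @export
print.raw_metab <- function(x, ...) {
  cat(sprintf("raw_metab [%s]: %d records x %d metabolites, %d plates, %d missing\n",
              x$platform, nrow(x$values), ncol(x$values),
              length(unique(x$records$plate_id)), sum(is.na(x$values))))
  invisible(x)
}

DIAG6 <- c("CN", "SMC", "EMCI", "MCI", "LMCI", "AD")

#' Generate a synthetic cohort
#'
#' Draws a full cohort from the latent-factor model described in the
#' package vignette: covariates, diagnosis-linked brain segment volumes
#' (ventricular enlargement, atrophy elsewhere), and block-correlated
#' metabolite concentrations with multiplicative plate effects, replicate
#' records, and left-censoring at the limit of detection. Module members
#' are `sqrt(rho) * latent + sqrt(1 - rho) * noise`, so the expected
#' pairwise within-module correlation is exactly `rho`. All randomness is
#' governed by `config$seed`; the same configuration always yields the
#' identical cohort.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_cohort`: a list with elements
#'   `covariates`, `brain`, `medications` (data.frames), `raw`
#'   (a [raw_metabolite_data()] object), `truth` (module labels, per-sex
#'   effects, injected outliers), and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_config("config", "must be created by sim_config()")
  n <- config$n_participants
  p <- config$n_metabolites
  pid <- sprintf("P%04d", seq_len(n))

  ## -- covariates -------------------------------------------------------
  set.seed(substream_seed(config$seed, 1L))
  n_f <- round(n * config$sex_ratio)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  diag3 <- sample(c("CN", "MCI", "AD"), n, TRUE, config$diagnosis_probs)
  diag6 <- vapply(diag3, function(d) switch(d,
    CN  = sample(c("CN", "SMC"), 1),
    MCI = sample(c("EMCI", "MCI", "LMCI"), 1),
    AD  = "AD"), character(1), USE.NAMES = FALSE)
  age <- pmin(pmax(round(stats::rnorm(n, 73, 7), 1), 55), 92)
  education <- pmin(pmax(round(stats::rnorm(n, 16, 2.8)), 6), 20)
  apoe4 <- sample(0:2, n, TRUE, c(0.55, 0.34, 0.11))
  fasting <- stats::runif(n) >= config$nonfasting_fraction
  covariates <- data.frame(participant_id = pid, sex = sex, age = age,
                           education = education, apoe4 = apoe4,
                           diagnosis6 = diag6, diagnosis3 = diag3,
                           fasting = fasting, stringsAsFactors = FALSE)

  ## -- brain volumes ----------------------------------------------------
  set.seed(substream_seed(config$seed, 2L))
  severity <- match(diag3, c("CN", "MCI", "AD")) - 1
  b1 <- as.numeric(scale(severity + stats::rnorm(n, 0, 0.4)))
  B <- cbind(b1, matrix(stats::rnorm(n * (N_BRAIN_FACTORS - 1)), n))
  icv <- stats::rnorm(n, 1.45e6, 1.3e5) + ifelse(sex == "M", 1.3e5, 0)
  icv <- pmax(icv, 9e5)
  base <- c(ventricles = 30000, hippocampus = 7200, entorhinal = 3800,
            fusiform = 17500, midtemporal = 20000, wholebrain = 1050000)
  # fixed secondary loadings give components 2+ some reproducible structure
  L2 <- matrix(c( 0.04, -0.02,  0.01,  0.00,
                 -0.02,  0.03,  0.00,  0.01,
                  0.01,  0.00, -0.03,  0.02,
                  0.00,  0.02,  0.02, -0.02,
                  0.02, -0.01,  0.00,  0.03,
                 -0.01,  0.01,  0.02,  0.00), 6, 4, byrow = TRUE)
  noise_sd <- c(0.12, 0.05, 0.07, 0.05, 0.05, 0.03)
  brain <- matrix(NA_real_, n, 6, dimnames = list(pid, BRAIN_SEGMENTS))
  sec <- B[, 2:5, drop = FALSE] %*% t(L2)
  for (j in seq_len(6)) {
    rel <- 1 + config$atrophy_effects[j] * severity + sec[, j] +
      stats::rnorm(n, 0, noise_sd[j])
    brain[, j] <- pmax(base[j] * (icv / 1.5e6) * rel, 1)
  }
  brain_df <- data.frame(participant_id = pid, brain, icv = icv,
                         stringsAsFactors = FALSE, row.names = NULL)

  ## -- metabolite latent values ----------------------------------------
  set.seed(substream_seed(config$seed, 3L))
  met_id <- sprintf("M%03d", seq_len(p))
  sizes <- vapply(config$module_spec, function(m) m$size, integer(1))
  labels <- rep("grey", p)
  idx <- 1L
  for (m in seq_along(sizes)) {
    labels[idx:(idx + sizes[m] - 1L)] <- sprintf("mod%02d", m)
    idx <- idx + sizes[m]
  }
  Z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(pid, met_id))
  is_f <- sex == "F"
  for (m in seq_along(config$module_spec)) {
    sp <- config$module_spec[[m]]
    gam_f <- sp$effects$female; gam_m <- sp$effects$male
    f_struct <- numeric(n)
    f_struct[is_f] <- B[is_f, , drop = FALSE] %*% gam_f
    f_struct[!is_f] <- B[!is_f, , drop = FALSE] %*% gam_m
    var_f <- ifelse(is_f, sum(gam_f^2), sum(gam_m^2))
    f <- f_struct + sqrt(pmax(0, 1 - var_f)) * stats::rnorm(n)
    members <- which(labels == sprintf("mod%02d", m))
    for (k in members)
      Z[, k] <- sqrt(sp$rho) * f + sqrt(1 - sp$rho) * stats::rnorm(n)
  }

  ## -- medications ------------------------------------------------------
  set.seed(substream_seed(config$seed, 6L))
  n_med <- config$n_medications
  meds <- matrix(0L, n, max(n_med, 0),
                 dimnames = list(pid, if (n_med > 0) sprintf("med%02d", seq_len(n_med))))
  if (n_med > 0) {
    prev <- stats::runif(n_med, 0.1, 0.4)
    for (j in seq_len(n_med)) meds[, j] <- stats::rbinom(n, 1, prev[j])
    if (!is.null(config$med_effects))
      Z <- Z + meds %*% config$med_effects
  }
  med_df <- data.frame(participant_id = pid, meds,
                       stringsAsFactors = FALSE, row.names = NULL)

  ## -- plates, replicates, concentrations ------------------------------
  set.seed(substream_seed(config$seed, 4L))
  plate_id <- sprintf("PL%02d", seq_len(config$n_plates))
  plate_of <- sample(rep_len(plate_id, n))
  names(plate_of) <- pid
  scale_k <- 10^stats::runif(p, 0, 2)
  plate_eff <- matrix(exp(stats::rnorm(p * config$n_plates, 0, config$plate_effect_sd)),
                      p, config$n_plates, dimnames = list(met_id, plate_id))

  set.seed(substream_seed(config$seed, 5L))
  n_rep <- floor(config$replicate_fraction * n)
  rep_pid <- if (n_rep > 0) sort(sample(pid, n_rep)) else character(0)
  rec_participant <- pid
  rec_no <- rep(1L, n)
  for (i in seq_along(rep_pid)) {
    extra <- if (i %% 5L == 0L) 2L else 1L   # every 5th replicated participant is a triplicate
    rec_participant <- c(rec_participant, rep(rep_pid[i], extra))
    rec_no <- c(rec_no, seq_len(extra) + 1L)
  }
  rec_id <- sprintf("%s_r%d", rec_participant, rec_no)
  n_rec <- length(rec_id)
  Zrec <- Z[rec_participant, , drop = FALSE]
  extra_rows <- which(rec_no > 1L)
  if (length(extra_rows))
    Zrec[extra_rows, ] <- Zrec[extra_rows, ] +
      matrix(stats::rnorm(length(extra_rows) * p, 0, config$replicate_noise_sd),
             length(extra_rows), p)
  rec_plate <- plate_of[rec_participant]
  values <- exp(Zrec) * matrix(scale_k, n_rec, p, byrow = TRUE) *
    t(plate_eff[, rec_plate, drop = FALSE])
  dimnames(values) <- list(rec_id, met_id)
  records <- data.frame(record_id = rec_id, participant_id = rec_participant,
                        plate_id = unname(rec_plate), replicate_no = rec_no,
                        stringsAsFactors = FALSE)

  ## -- left-censoring at the LOD ---------------------------------------
  lod <- matrix(0, p, config$n_plates, dimnames = list(met_id, plate_id))
  qc_tags <- empty_qc_tags()
  if (config$lod_quantile > 0) {
    for (pl in plate_id) {
      rows <- which(records$plate_id == pl)
      if (!length(rows)) next
      q <- apply(values[rows, , drop = FALSE], 2, stats::quantile,
                 probs = config$lod_quantile, names = FALSE)
      lod[, pl] <- q
      for (j in seq_len(p)) {
        cens <- rows[values[rows, j] < q[j]]
        if (length(cens)) values[cens, j] <- NA_real_
      }
    }
    if (config$platform == "nmr") {
      cens_idx <- which(is.na(values), arr.ind = TRUE)
      if (nrow(cens_idx))
        qc_tags <- data.frame(
          record_id = rec_id[cens_idx[, 1]],
          metabolite_id = met_id[cens_idx[, 2]],
          tag = "below limit of quantification", stringsAsFactors = FALSE)
    }
  }

  fasting_named <- stats::setNames(covariates$fasting, pid)
  raw <- raw_metabolite_data(values, records,
                             lod = if (config$platform == "targeted") lod else NULL,
                             qc_tags = qc_tags, fasting = fasting_named,
                             platform = config$platform)

  truth <- list(
    module_labels = stats::setNames(labels, met_id),
    effects = lapply(config$module_spec, `[[`, "effects"),
    outliers = character(0),
    latent_brain = B)
  structure(list(covariates = covariates, brain = brain_df,
                 medications = med_df, raw = raw, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants, %d metabolites (%s), %d modules\n",
              nrow(x$covariates), ncol(x$raw$values), x$config$platform,
              length(x$config$module_spec)))
  invisible(x)
}

#' Inject multivariate outlier participants
#'
#' Shifts randomly chosen participants by `magnitude` (in latent z-units)
#' along a random unit direction of metabolite space — drawn independently
#' per outlier so the outliers do not form a cluster that masks itself in
#' the sample covariance — recording the chosen participant ids in the
#' cohort's truth record. Because concentrations are `exp(z) * scale`, the
#' shift multiplies each affected concentration by `exp(magnitude * u_k)`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_outliers number of participants to shift (must be fewer than
#'   the number of participants).
#' @param magnitude total shift length in z-units; must be positive.
#' @return the modified cohort.
#' @export
inject_outliers <- function(cohort, n_outliers, magnitude = 10) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (n_outliers == 0) return(cohort)
  if (magnitude <= 0) stop("outlier magnitude must be positive")
  n <- nrow(cohort$covariates)
  if (n_outliers >= n)
    stop("n_outliers must be smaller than the number of participants")
  set.seed(substream_seed(cohort$config$seed, 7L))
  chosen <- sort(sample(cohort$covariates$participant_id, n_outliers))
  p <- ncol(cohort$raw$values)
  for (id in chosen) {
    u <- stats::rnorm(p)
    u <- u / sqrt(sum(u^2))
    mult <- exp(magnitude * u)
    rows <- which(cohort$raw$records$participant_id == id)
    cohort$raw$values[rows, ] <- sweep(cohort$raw$values[rows, , drop = FALSE],
                                       2, mult, `*`)
  }
  cohort$truth$outliers <- chosen
  cohort
}

# Fixture I/O ------------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a synthetic cohort as delimited-text fixtures
#'
#' Writes `metabolites.tsv` (long format: participant, metabolite, plate,
#' replicate, value), `lod.tsv`, `covariates.tsv`, `brain.tsv`,
#' `medications.tsv`, `qc_tags.tsv` and `truth.json` into `directory`.
#' All tables are tab-delimited with a header; missing values are empty
#' fields. The files round-trip losslessly through [read_fixtures()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_fixtures <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  raw <- cohort$raw
  long <- data.frame(
    record_id = rep(rownames(raw$values), ncol(raw$values)),
    participant_id = rep(raw$records$participant_id, ncol(raw$values)),
    metabolite_id = rep(colnames(raw$values), each = nrow(raw$values)),
    plate_id = rep(raw$records$plate_id, ncol(raw$values)),
    replicate_no = rep(raw$records$replicate_no, ncol(raw$values)),
    value = as.vector(raw$values), stringsAsFactors = FALSE)
  files <- c(metabolites = "metabolites.tsv", lod = "lod.tsv",
             covariates = "covariates.tsv", brain = "brain.tsv",
             medications = "medications.tsv", qc_tags = "qc_tags.tsv",
             truth = "truth.json")
  paths <- file.path(directory, files)
  names(paths) <- names(files)
  write_tsv(long, paths[["metabolites"]])
  if (!is.null(raw$lod)) {
    lod_long <- data.frame(
      metabolite_id = rep(rownames(raw$lod), ncol(raw$lod)),
      plate_id = rep(colnames(raw$lod), each = nrow(raw$lod)),
      lod = as.vector(raw$lod), stringsAsFactors = FALSE)
    write_tsv(lod_long, paths[["lod"]])
  }
  write_tsv(cohort$covariates, paths[["covariates"]])
  write_tsv(cohort$brain, paths[["brain"]])
  write_tsv(cohort$medications, paths[["medications"]])
  write_tsv(raw$qc_tags, paths[["qc_tags"]])
  truth <- cohort$truth
  truth$latent_brain <- NULL                # large, derivable, not needed on disk
  jsonlite::write_json(
    list(module_labels = as.list(truth$module_labels),
         effects = truth$effects, outliers = truth$outliers,
         platform = cohort$config$platform, seed = cohort$config$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths[file.exists(paths)])
}

#' Read cohort fixtures written by [write_fixtures()]
#'
#' @param directory directory containing the fixture files.
#' @return list with elements `raw` (a [raw_metabolite_data()] object),
#'   `covariates`, `brain`, `medications`, and `truth`.
#' @export
read_fixtures <- function(directory) {
  long <- read_tsv(file.path(directory, "metabolites.tsv"))
  met_id <- unique(long$metabolite_id)
  rec <- unique(long[, c("record_id", "participant_id", "plate_id", "replicate_no")])
  rownames(rec) <- NULL
  values <- matrix(NA_real_, nrow(rec), length(met_id),
                   dimnames = list(rec$record_id, met_id))
  values[cbind(match(long$record_id, rec$record_id),
               match(long$metabolite_id, met_id))] <- long$value
  lod <- NULL
  lod_path <- file.path(directory, "lod.tsv")
  if (file.exists(lod_path)) {
    lod_long <- read_tsv(lod_path)
    plates <- unique(lod_long$plate_id)
    mets <- unique(lod_long$metabolite_id)
    lod <- matrix(NA_real_, length(mets), length(plates),
                  dimnames = list(mets, plates))
    lod[cbind(match(lod_long$metabolite_id, mets),
              match(lod_long$plate_id, plates))] <- lod_long$lod
  }
  covariates <- read_tsv(file.path(directory, "covariates.tsv"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  qc_path <- file.path(directory, "qc_tags.tsv")
  qc_tags <- if (file.exists(qc_path)) read_tsv(qc_path) else empty_qc_tags()
  if (nrow(qc_tags) == 0) qc_tags <- empty_qc_tags()
  fasting <- stats::setNames(as.logical(covariates$fasting),
                             covariates$participant_id)
  raw <- raw_metabolite_data(values, rec, lod = lod, qc_tags = qc_tags,
                             fasting = fasting,
                             platform = if (is.null(truth$platform)) "targeted" else truth$platform)
  list(raw = raw, covariates = covariates,
       brain = read_tsv(file.path(directory, "brain.tsv")),
       medications = read_tsv(file.path(directory, "medications.tsv")),
       truth = truth)
}
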