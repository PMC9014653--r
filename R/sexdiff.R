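# Sex-stratified association and sex-difference detection -----------------
#
# Per-sex OLS of each metabolite (or module eigen-metabolite) on the
# brain components plus covariates, the heterogeneity Z-test, the
# inverse-variance overall Z, a two-fold screening procedure, a
# criterion-based classification of associations, and the eigenvalue
# estimator of the effective number of independent tests.

#' Sex-stratified linear regression of an outcome on brain components
#'
#' Within each sex, fits ordinary least squares of the outcome on all
#' supplied brain components jointly plus age, education and APOE e4
#' allele count (entered linearly); a pooled model over both sexes adds
#' sex as an additional covariate. Returns per-component estimates: with
#' orthogonal component scores the joint-model coefficients coincide with
#' single-component fits.
#'
#' @param outcome numeric vector (metabolite or eigen-metabolite values).
#' @param components numeric matrix of brain component scores
#'   (participants x components).
#' @param covariates data.frame with columns `age`, `education`, `apoe4`.
#' @param sex character/factor vector with levels `"F"` and `"M"`.
#' @return data.frame with one row per component: `component`, `beta_f`,
#'   `se_f`, `p_f`, `n_f`, `beta_m`, `se_m`, `p_m`, `n_m`, `beta_all`,
#'   `se_all`, `p_all`.
#' @export
stratified_regression <- function(outcome, components, covariates, sex) {
  components <- as.matrix(components)
  if (is.null(colnames(components)))
    colnames(components) <- paste0("C", seq_len(ncol(components)))
  n <- length(outcome)
  stopifnot(nrow(components) == n, nrow(covariates) == n, length(sex) == n)
  sex <- as.character(sex)
  cc <- stats::complete.cases(outcome, components, covariates, sex)
  outcome <- outcome[cc]; components <- components[cc, , drop = FALSE]
  covariates <- covariates[cc, , drop = FALSE]; sex <- sex[cc]
  if (!all(c("F", "M") %in% sex)) stop("both sex strata must be non-empty")
  Xcov <- cbind(age = covariates$age, education = covariates$education,
                apoe4 = covariates$apoe4)
  fit_stratum <- function(rows, extra = NULL) {
    X <- cbind(`(Intercept)` = 1, components[rows, , drop = FALSE],
               Xcov[rows, , drop = FALSE], extra)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    y <- outcome[rows]
    beta <- qr.coef(qrX, y)
    res <- y - X %*% beta
    df <- length(rows) - ncol(X)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
    se <- sqrt(sigma2 * diag(XtXinv))
    pv <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
    comp_idx <- seq_len(ncol(components)) + 1L
    list(beta = beta[comp_idx], se = se[comp_idx], p = pv[comp_idx],
         n = length(rows))
  }
  f <- fit_stratum(which(sex == "F"))
  m <- fit_stratum(which(sex == "M"))
  all_fit <- fit_stratum(seq_along(outcome),
                         extra = cbind(sexM = as.numeric(sex == "M")))
  data.frame(component = colnames(components),
             beta_f = unname(f$beta), se_f = unname(f$se), p_f = unname(f$p),
             n_f = f$n,
             beta_m = unname(m$beta), se_m = unname(m$se), p_m = unname(m$p),
             n_m = m$n,
             beta_all = unname(all_fit$beta), se_all = unname(all_fit$se),
             p_all = unname(all_fit$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sex-difference (heterogeneity) Z-test
#'
#' `Z_diff = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)`, compared against
#' the standard normal (two-sided).
#'
#' @param beta_f,se_f,beta_m,se_m stratified estimates and standard
#'   errors (vectorized; SEs must be positive).
#' @return list with `z` and `p`.
#' @export
z_diff_test <- function(beta_f, se_f, beta_m, se_m) {
  if (any(se_f <= 0) || any(se_m <= 0)) stop("standard errors must be positive")
  z <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Inverse-variance overall association Z-test
#'
#' `Z_overall = (beta_f/se_f^2 + beta_m/se_m^2) / sqrt(1/se_f^2 + 1/se_m^2)`,
#' the fixed-effects meta-analytic combination of the two strata,
#' compared against the standard normal (two-sided).
#'
#' @inheritParams z_diff_test
#' @return list with `z` and `p`.
#' @export
z_overall_test <- function(beta_f, se_f, beta_m, se_m) {
  if (any(se_f <= 0) || any(se_m <= 0)) stop("standard errors must be positive")
  z <- (beta_f / se_f^2 + beta_m / se_m^2) / sqrt(1 / se_f^2 + 1 / se_m^2)
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Multiple-testing plan
#'
#' Holds the Bonferroni levels used by the classification and screening
#' procedures: the module-level level `0.05/(M*C)`, the single-metabolite
#' level `0.05/(I*C)` with `I` the effective number of independent tests,
#' and the overall-association filter level.
#'
#' @param n_modules M, number of modules tested.
#' @param n_components C, number of brain components.
#' @param effective_tests I, effective number of independent metabolite
#'   tests (see [effective_tests()]).
#' @param base_alpha family-wise level (default 0.05).
#' @param overall_alpha filter level for significant overall associations
#'   (default 1e-5).
#' @param nominal_alpha nominal per-test level (default 0.05).
#' @return object of class `testing_plan`.
#' @export
testing_plan <- function(n_modules, n_components, effective_tests = NULL,
                         base_alpha = 0.05, overall_alpha = 1e-5,
                         nominal_alpha = 0.05) {
  structure(list(
    n_modules = n_modules, n_components = n_components,
    effective_tests = effective_tests,
    alpha_module = base_alpha / (n_modules * n_components),
    alpha_single = if (is.null(effective_tests)) NA_real_
                   else base_alpha / (effective_tests * n_components),
    base_alpha = base_alpha, overall_alpha = overall_alpha,
    nominal_alpha = nominal_alpha), class = "testing_plan")
}

#' Two-fold sex-difference screening
#'
#' Screen 1 applies the sex-difference test Bonferroni-corrected over all
#' `N` associations (`P_diff < base_alpha / N`). Screen 2 first restricts
#' to associations with a significant overall effect
#' (`P_overall < overall_alpha`), then applies the sex-difference test
#' Bonferroni-corrected over that subset. An association is flagged if it
#' passes either screen.
#'
#' @param p_diff,p_overall numeric vectors over associations.
#' @param plan a [testing_plan()].
#' @return data.frame with logical columns `screen_all`, `passes_filter`,
#'   `screen_filtered`, `significant`.
#' @export
winkler_screen <- function(p_diff, p_overall, plan) {
  n_all <- length(p_diff)
  if (n_all == 0)
    return(data.frame(screen_all = logical(), passes_filter = logical(),
                      screen_filtered = logical(), significant = logical()))
  screen_all <- p_diff < plan$base_alpha / n_all
  passes <- p_overall < plan$overall_alpha
  n_filt <- sum(passes)
  screen_filtered <- passes & (n_filt > 0) & (p_diff < plan$base_alpha / max(n_filt, 1))
  data.frame(screen_all = screen_all, passes_filter = passes,
             screen_filtered = screen_filtered,
             significant = screen_all | screen_filtered)
}

#' Criterion-based classification of sex differences
#'
#' An association is selected when any of these holds: (a) it is
#' Bonferroni significant in the pooled cohort (`p_all < alpha_bonf`);
#' (b) it is Bonferroni significant in at least one sex; or (c) it is
#' nominally significant in at least one sex (`P < nominal_alpha`) with a
#' significant sex-difference test (`p_diff < nominal_alpha`).
#' Unselected associations are `"none"`. Selected associations that are
#' Bonferroni significant in exactly one sex with `p_diff < nominal_alpha`
#' are `"sex-specific"`; otherwise `p_diff < nominal_alpha` gives
#' `"heterogeneous"` and `p_diff >= nominal_alpha` gives
#' `"homogeneous"`.
#'
#' @param p_all,p_f,p_m,p_diff P-values (vectorized).
#' @param alpha_bonf Bonferroni level for the association family.
#' @param nominal_alpha nominal level (default 0.05).
#' @return character vector of categories.
#' @export
arnold_classify <- function(p_all, p_f, p_m, p_diff, alpha_bonf,
                            nominal_alpha = 0.05) {
  bon_f <- p_f < alpha_bonf
  bon_m <- p_m < alpha_bonf
  sel <- (p_all < alpha_bonf) | bon_f | bon_m |
    (pmin(p_f, p_m) < nominal_alpha & p_diff < nominal_alpha)
  diff_sig <- p_diff < nominal_alpha
  out <- rep("none", length(p_all))
  one_sex <- xor(bon_f, bon_m)
  out[sel & one_sex & diff_sig] <- "sex-specific"
  out[sel & !(one_sex & diff_sig) & diff_sig] <- "heterogeneous"
  out[sel & !diff_sig] <- "homogeneous"
  out
}

#' Effective number of independent tests
#'
#' Eigenvalue-based estimator: with eigenvalues `lambda_i` of the
#' correlation matrix, `I = sum( 1(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)) )`. Equals the number of variables for an identity
#' correlation and decreases with increasing correlation.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @return numeric scalar `I` with `1 <= I <= ncol(corr)`.
#' @export
effective_tests <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  sum((lambda >= 1) + (lambda - floor(lambda)))
}

#' Run the full association study
#'
#' Iterates module eigen-metabolites and single metabolites over all
#' brain components: sex-stratified regressions, the heterogeneity and
#' overall Z-tests, the two-fold screen (within each unit type), and the
#' criterion-based classification (module-level Bonferroni for modules,
#' effective-tests Bonferroni for single metabolites). Component scores
#' are standardized to unit variance so that effect sizes are per SD of
#' brain component.
#'
#' @param clean a `clean_metab` object (single-metabolite outcomes).
#' @param eigens a [compute_eigen()] result, or `NULL` to skip modules.
#' @param scores matrix of brain component scores (participants x
#'   components, rownames = participant ids).
#' @param covariates data.frame with `participant_id`, `age`,
#'   `education`, `apoe4`, `sex`.
#' @param overall_alpha,nominal_alpha,base_alpha plan parameters.
#' @return list with `results` (tidy data.frame, one row per
#'   (unit, component)) and `plan`.
#' @export
run_association_study <- function(clean, eigens, scores, covariates,
                                  overall_alpha = 1e-5, nominal_alpha = 0.05,
                                  base_alpha = 0.05) {
  stopifnot(inherits(clean, "clean_metab"))
  scores <- as.matrix(scores)
  ids <- rownames(clean$matrix)
  if (is.null(rownames(scores)))
    stop("score matrix must carry participant ids as rownames")
  common <- Reduce(intersect, list(ids, rownames(scores),
                                   covariates$participant_id))
  mismatched <- setdiff(ids, common)
  if (!length(common))
    stop("participant misalignment between inputs; no common ids")
  if (length(mismatched) > 0.5 * length(ids))
    stop("participant misalignment; e.g. ", paste(utils::head(mismatched, 5), collapse = ", "))
  mat <- clean$matrix[common, , drop = FALSE]
  sc <- scale(scores[common, , drop = FALSE], center = TRUE, scale = TRUE)
  cov_df <- covariates[match(common, covariates$participant_id), , drop = FALSE]
  sexv <- cov_df$sex
  cov3 <- cov_df[, c("age", "education", "apoe4")]

  assoc_block <- function(units, unit_type) {
    rows <- lapply(colnames(units), function(u) {
      res <- stratified_regression(units[, u], sc, cov3, sexv)
      res$unit <- u; res$unit_type <- unit_type
      res
    })
    do.call(rbind, rows)
  }
  res <- NULL
  if (!is.null(eigens) && ncol(eigens$eigens) > 0)
    res <- assoc_block(eigens$eigens[common, , drop = FALSE], "module")
  res <- rbind(res, assoc_block(mat, "metabolite"))

  zd <- z_diff_test(res$beta_f, res$se_f, res$beta_m, res$se_m)
  zo <- z_overall_test(res$beta_f, res$se_f, res$beta_m, res$se_m)
  res$z_diff <- zd$z; res$p_diff <- zd$p
  res$z_overall <- zo$z; res$p_overall <- zo$p

  n_modules <- if (is.null(eigens)) 0 else ncol(eigens$eigens)
  I_eff <- effective_tests(stats::cor(mat))
  plan <- testing_plan(n_modules = max(n_modules, 1),
                       n_components = ncol(sc),
                       effective_tests = I_eff,
                       base_alpha = base_alpha,
                       overall_alpha = overall_alpha,
                       nominal_alpha = nominal_alpha)

  res$winkler_any <- NA
  res$arnold_category <- NA_character_
  for (ut in unique(res$unit_type)) {
    sel <- res$unit_type == ut
    wk <- winkler_screen(res$p_diff[sel], res$p_overall[sel], plan)
    res$winkler_any[sel] <- wk$significant
    alpha_bonf <- if (ut == "module") plan$alpha_module else plan$alpha_single
    res$arnold_category[sel] <- arnold_classify(
      res$p_all[sel], res$p_f[sel], res$p_m[sel], res$p_diff[sel],
      alpha_bonf, nominal_alpha)
  }
  cols <- c("unit", "unit_type", "component", "beta_f", "se_f", "p_f", "n_f",
            "beta_m", "se_m", "p_m", "n_m", "beta_all", "se_all", "p_all",
            "z_diff", "p_diff", "z_overall", "p_overall", "winkler_any",
            "arnold_category")
  list(results = res[, cols], plan = plan)
}
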