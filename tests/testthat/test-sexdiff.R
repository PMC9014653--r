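make_strat_fixture <- function(seed = 40, n = 400, beta_f = 0, beta_m = 0,
                               n_comp = 3) {
  set.seed(seed)
  sex <- rep(c("F", "M"), each = n / 2)
  comp <- matrix(rnorm(n * n_comp), n, n_comp,
                 dimnames = list(NULL, paste0("C", seq_len(n_comp))))
  cov <- data.frame(age = rnorm(n, 73, 7), education = rnorm(n, 16, 3),
                    apoe4 = sample(0:2, n, TRUE))
  y <- rnorm(n) + ifelse(sex == "F", beta_f, beta_m) * comp[, 1]
  list(y = y, comp = comp, cov = cov, sex = sex)
}

test_that("stratified regression matches per-sex OLS and handles edge cases", {
  fx <- make_strat_fixture(seed = 41, beta_f = 0.3, beta_m = 0.3)
  res <- stratified_regression(fx$y, fx$comp, fx$cov, fx$sex)
  expect_equal(nrow(res), 3)
  # oracle: lm() per stratum
  d <- data.frame(y = fx$y, fx$comp, fx$cov)
  for (s in c("F", "M")) {
    fit <- lm(y ~ C1 + C2 + C3 + age + education + apoe4, d[fx$sex == s, ])
    sm <- summary(fit)$coefficients
    col <- if (s == "F") c("beta_f", "se_f", "p_f") else c("beta_m", "se_m", "p_m")
    expect_equal(res[[col[1]]], unname(sm[paste0("C", 1:3), 1]), tolerance = 1e-10)
    expect_equal(res[[col[2]]], unname(sm[paste0("C", 1:3), 2]), tolerance = 1e-10)
    expect_equal(res[[col[3]]], unname(sm[paste0("C", 1:3), 4]), tolerance = 1e-10)
  }
  # pooled model with sex covariate
  d$sexM <- as.numeric(fx$sex == "M")
  fitp <- lm(y ~ C1 + C2 + C3 + age + education + apoe4 + sexM, d)
  expect_equal(res$beta_all, unname(summary(fitp)$coefficients[paste0("C", 1:3), 1]),
               tolerance = 1e-10)

  # identical outcome and design in both strata -> identical estimates
  fx2 <- make_strat_fixture(seed = 42, n = 100)
  half <- 1:50
  y2 <- c(fx2$y[half], fx2$y[half])
  comp2 <- rbind(fx2$comp[half, ], fx2$comp[half, ])
  cov2 <- rbind(fx2$cov[half, ], fx2$cov[half, ])
  res2 <- stratified_regression(y2, comp2, cov2, rep(c("F", "M"), each = 50))
  expect_equal(res2$beta_f, res2$beta_m, tolerance = 1e-12)

  # rank-deficient design names the collinear column
  comp_bad <- cbind(fx$comp, C4 = fx$comp[, 1])
  expect_error(stratified_regression(fx$y, comp_bad, fx$cov, fx$sex), "C4")
  expect_error(stratified_regression(fx$y, fx$comp, fx$cov, rep("F", 400)),
               "strata")
})

test_that("orthogonal components give joint betas equal to marginal betas", {
  # exact only when components are orthogonal to each other AND to the
  # covariates within each stratum; construct such a design blockwise
  set.seed(43)
  n <- 200
  fx <- make_strat_fixture(seed = 44, n = n)
  comp <- matrix(0, n, 3, dimnames = list(NULL, paste0("C", 1:3)))
  for (s in c("F", "M")) {
    rows <- which(fx$sex == s)
    base <- cbind(1, fx$cov$age[rows], fx$cov$education[rows],
                  fx$cov$apoe4[rows])
    Q <- qr.Q(qr(cbind(base, matrix(rnorm(length(rows) * 3), ncol = 3))))
    comp[rows, ] <- Q[, 5:7] * sqrt(length(rows))
  }
  y <- rnorm(n) + 0.4 * comp[, 2]
  joint <- stratified_regression(y, comp, fx$cov, fx$sex)
  for (j in 1:3) {
    single <- stratified_regression(y, comp[, j, drop = FALSE], fx$cov, fx$sex)
    expect_equal(joint$beta_f[j], single$beta_f[1], tolerance = 1e-6)
    expect_equal(joint$beta_m[j], single$beta_m[1], tolerance = 1e-6)
  }
})

test_that("effect recovery: injected female-only effect is estimated without bias", {
  hits_f <- 0; betas_m <- numeric(0)
  for (r in 1:50) {
    fx <- make_strat_fixture(seed = 4000 + r, n = 300, beta_f = 0.3, beta_m = 0)
    res <- stratified_regression(fx$y, fx$comp, fx$cov, fx$sex)
    if (abs(res$beta_f[1] - 0.3) <= 3 * res$se_f[1]) hits_f <- hits_f + 1
    betas_m <- c(betas_m, res$beta_m[1])
  }
  expect_gte(hits_f, 48)                       # >= 95% coverage at 3 SE
  expect_lt(abs(mean(betas_m)), 0.03)          # male stratum centered at zero
})

test_that("Z_diff follows its closed form, the normal law, and antisymmetry", {
  expect_equal(z_diff_test(1, 1, 1, 2)$z, 0)
  expect_equal(z_diff_test(1, 1, 1, 2)$p, 1)
  zd <- z_diff_test(1, 1, 0, 1)
  expect_equal(zd$z, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(zd$p, 2 * pnorm(1 / sqrt(2), lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(zd$p, 0.4795, tolerance = 1e-4)
  expect_error(z_diff_test(1, 0, 1, 1), "positive")
  # antisymmetry under stratum swap
  set.seed(45)
  for (i in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.1, 2)
    expect_equal(z_diff_test(b[1], s[1], b[2], s[2])$z,
                 -z_diff_test(b[2], s[2], b[1], s[1])$z, tolerance = 1e-12)
  }
})

test_that("Z_overall equals the inverse-variance meta-analysis oracle", {
  expect_equal(z_overall_test(0, 1, 0, 2)$z, 0)
  expect_equal(z_overall_test(1, 1, 1, 1)$z, sqrt(2), tolerance = 1e-12)
  # uninformative stratum limit
  zo <- z_overall_test(5, 1e6, 0.7, 0.1)
  expect_equal(zo$z, 0.7 / 0.1, tolerance = 1e-6)
  expect_error(z_overall_test(1, 1, 1, -1), "positive")
  set.seed(46)
  b_f <- rnorm(1000); b_m <- rnorm(1000)
  s_f <- runif(1000, 0.05, 2); s_m <- runif(1000, 0.05, 2)
  expect_equal(z_overall_test(b_f, s_f, b_m, s_m)$z,
               meta_oracle_z(b_f, s_f, b_m, s_m), tolerance = 1e-12)
})

test_that("the two-fold screen applies both Bonferroni families", {
  plan <- testing_plan(5, 4)
  # empty input
  expect_equal(nrow(winkler_screen(numeric(0), numeric(0), plan)), 0)
  # screen 1: corrected over all associations
  p_diff <- c(1e-6, 0.02, 0.5, 0.02)
  p_over <- c(0.5, 1e-8, 1e-9, 0.5)
  res <- winkler_screen(p_diff, p_over, plan)
  expect_equal(res$screen_all, c(TRUE, FALSE, FALSE, FALSE))   # 0.05/4 = 0.0125
  expect_equal(res$passes_filter, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$screen_filtered, c(FALSE, TRUE, FALSE, FALSE)) # 0.05/2 = 0.025
  expect_equal(res$significant, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("screen 1 controls family-wise error near its nominal level", {
  set.seed(47)
  plan <- testing_plan(5, 4)
  fwer <- mean(replicate(200, {
    p_diff <- 2 * pnorm(abs(rnorm(1000)), lower.tail = FALSE)   # exact null
    any(winkler_screen(p_diff, rep(1, 1000), plan)$screen_all)
  }))
  expect_lte(fwer, 0.07)
})

test_that("screen 2 detects a sex gap among filtered associations", {
  set.seed(48)
  # 500 null associations plus one with a shared effect and a true gap
  n <- 501
  b_f <- c(rnorm(n - 1, 0, 0.05), 1.25)
  b_m <- c(rnorm(n - 1, 0, 0.05), 0.75)
  se <- rep(0.05, n)
  zo <- z_overall_test(b_f, se, b_m, se)
  zd <- z_diff_test(b_f, se, b_m, se)
  res <- winkler_screen(zd$p, zo$p, testing_plan(5, 4))
  expect_true(res$screen_filtered[n])
})

test_that("classification reproduces the full boundary truth table", {
  ab <- 1e-3            # Bonferroni level for the family
  lo <- 1e-6            # clearly below ab
  mid <- 0.01           # between ab and 0.05
  hi <- 0.5             # above 0.05
  cases <- list(
    # p_all, p_f, p_m, p_diff -> expected
    list(lo,  hi,  hi,  hi,  "homogeneous"),   # (a) only, no diff
    list(lo,  hi,  hi,  mid, "heterogeneous"), # (a) with diff, no single-sex bonf
    list(hi,  lo,  hi,  mid, "sex-specific"),  # (b) one sex + diff
    list(hi,  lo,  hi,  hi,  "homogeneous"),   # (b) one sex, no diff
    list(hi,  hi,  lo,  mid, "sex-specific"),  # (b) other sex + diff
    list(hi,  lo,  lo,  hi,  "homogeneous"),   # both sexes bonf, no diff
    list(hi,  lo,  lo,  mid, "heterogeneous"), # both sexes bonf + diff
    list(hi,  mid, hi,  mid, "heterogeneous"), # (c) nominal + diff
    list(hi,  mid, hi,  hi,  "none"),          # nominal but no diff
    list(hi,  hi,  hi,  mid, "none"),          # diff alone does not select
    list(hi,  hi,  hi,  hi,  "none"),
    list(lo,  lo,  hi,  mid, "sex-specific"),  # (a)+(b) one sex + diff
    list(lo,  lo,  lo,  mid, "heterogeneous"), # all significant + diff
    list(lo,  lo,  lo,  hi,  "homogeneous"),
    list(lo,  mid, hi,  mid, "heterogeneous"), # (a) + nominal + diff
    list(mid, lo,  hi,  hi,  "homogeneous"),   # (b) selected, no diff
    list(hi,  mid, mid, mid, "heterogeneous"), # (c) both nominal
    list(lo,  hi,  hi,  lo,  "heterogeneous")  # (a) + strong diff, no sex bonf
  )
  for (cs in cases) {
    got <- arnold_classify(cs[[1]], cs[[2]], cs[[3]], cs[[4]], alpha_bonf = ab)
    expect_equal(got, cs[[5]],
                 label = sprintf("case (%g,%g,%g,%g)", cs[[1]], cs[[2]],
                                 cs[[3]], cs[[4]]))
  }
  # vectorized call agrees with scalar calls
  pa <- sapply(cases, `[[`, 1); pf <- sapply(cases, `[[`, 2)
  pm <- sapply(cases, `[[`, 3); pd <- sapply(cases, `[[`, 4)
  expect_equal(arnold_classify(pa, pf, pm, pd, ab),
               vapply(cases, `[[`, character(1), 5))
})

test_that("effective number of tests follows the eigenvalue rule", {
  expect_equal(effective_tests(diag(10)), 10)
  dup <- matrix(1, 2, 2)                         # lambda = {2, 0}
  expect_equal(effective_tests(dup), 1)
  half <- matrix(c(1, 0.5, 0.5, 1), 2)           # lambda = {1.5, 0.5}
  expect_equal(effective_tests(half), 2.0)
  expect_error(effective_tests(matrix(c(1, 0.2, 0.4, 1), 2)), "symmetric")
  expect_error(effective_tests(matrix(c(2, 0, 0, 2), 2)), "unit diagonal")
  # bounds and permutation invariance on random correlation matrices
  set.seed(49)
  for (i in 1:10) {
    C <- cor(matrix(rnorm(60 * 8), 60, 8))
    I <- effective_tests(C)
    expect_gte(I, 1); expect_lte(I, 8 + 1e-9)
    perm <- sample(8)
    expect_equal(effective_tests(C[perm, perm]), I, tolerance = 1e-10)
  }
})

test_that("run_association_study builds the full cartesian table with aligned ids", {
  set.seed(50)
  n <- 200
  ids <- sprintf("P%03d", 1:n)
  mat <- matrix(rnorm(n * 6), n, 6, dimnames = list(ids, sprintf("M%03d", 1:6)))
  eig <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, c("turquoise", "blue")))
  eigens <- structure(list(eigens = eig,
                           membership = setNames(rep(0.9, 6), colnames(mat)),
                           labels = setNames(rep("turquoise", 6), colnames(mat))),
                      class = "eigen_metab")
  scores <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, paste0("C", 1:3)))
  cov <- data.frame(participant_id = ids, age = rnorm(n, 73, 7),
                    education = rnorm(n, 16, 3), apoe4 = sample(0:2, n, TRUE),
                    sex = rep(c("F", "M"), n / 2))
  st <- run_association_study(make_clean(mat), eigens, scores, cov)
  expect_equal(sum(st$results$unit_type == "module"), 2 * 3)
  expect_equal(sum(st$results$unit_type == "metabolite"), 6 * 3)
  expect_true(all(st$results$arnold_category %in%
                  c("none", "homogeneous", "heterogeneous", "sex-specific")))
  expect_equal(st$plan$alpha_module, 0.05 / (2 * 3))
  expect_lte(st$plan$effective_tests, 6)
  # misalignment errors
  bad_scores <- scores; rownames(bad_scores) <- sprintf("Q%03d", 1:n)
  expect_error(run_association_study(make_clean(mat), eigens, bad_scores, cov),
               "misalignment")
})
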