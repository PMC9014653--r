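test_that("missingness filter uses inclusive analyte and strict participant bounds", {
  set.seed(1)
  v <- matrix(runif(10 * 6, 1, 10), 10, 6)
  v[1:2, 1] <- NA          # 2/10 = 20% -> removed (inclusive)
  v[1, 2] <- NA            # 1/10 -> retained
  raw <- make_raw(v)
  res <- filter_by_missingness(raw, 0.20, 0.40)
  expect_false("M001" %in% colnames(res$data$values))
  expect_true("M002" %in% colnames(res$data$values))

  # planted fixture: 3 over-missing metabolites, 1 over-missing participant
  set.seed(2)
  v <- matrix(runif(20 * 10, 1, 10), 20, 10)
  v[1:5, 1:3] <- NA                   # 25% missing in metabolites 1-3
  v[20, 4:8] <- NA                    # 5/7 remaining -> 71% > 40%
  raw <- make_raw(v)
  res <- filter_by_missingness(raw, 0.20, 0.40)
  rep_met <- res$report$id[res$report$kind == "metabolite"]
  rep_par <- res$report$id[res$report$kind == "participant"]
  expect_setequal(rep_met, c("M001", "M002", "M003"))
  expect_equal(rep_par, "P020")
  expect_equal(dim(res$data$values), c(19, 7))
})

test_that("cross-plate normalization scales every plate to the grand mean and is idempotent", {
  v <- matrix(c(rep(10, 4), rep(20, 4)), ncol = 1)
  colnames(v) <- "M001"
  raw <- make_raw(v, plate = rep(c("A", "B"), each = 4),
                  lod = matrix(0, 1, 2, dimnames = list("M001", c("A", "B"))))
  out <- crossplate_normalize(raw)
  expect_equal(unname(out$values[1:4, 1]), rep(15, 4))   # scale 1.5
  expect_equal(unname(out$values[5:8, 1]), rep(15, 4))   # scale 0.75
  expect_equal(crossplate_normalize(out)$values, out$values)

  single <- make_raw(v)
  expect_equal(crossplate_normalize(single)$values, single$values)
})

test_that("replicate CV/ICC match closed forms and filter as specified", {
  # 30 participants in duplicate; M001 well-behaved, M002 pure noise (ICC ~ 0)
  set.seed(3)
  n <- 200
  base <- exp(rnorm(n, log(100), 0.8))
  v1 <- c(base * exp(rnorm(n, 0, 0.03)), base * exp(rnorm(n, 0, 0.03)))
  v2 <- runif(2 * n, 90, 110)          # no participant component at all
  v <- cbind(M001 = v1, M002 = v2)
  raw <- make_raw(v, participant = rep(sprintf("P%03d", 1:n), 2),
                  replicate_no = rep(1:2, each = n))
  res <- replicate_quality(raw, cv_max = 0.20, icc_min = 0.65)
  expect_true("M001" %in% colnames(res$data$values))
  expect_false("M002" %in% colnames(res$data$values))
  expect_lt(res$metrics$icc[res$metrics$metabolite_id == "M002"], 0.1)

  # hand-computed pair CV: sd(90,110)/mean = 14.142/100
  vv <- matrix(c(90, 110), 2, 1, dimnames = list(NULL, "M001"))
  raw2 <- make_raw(vv, participant = c("P1", "P1"), replicate_no = 1:2)
  res2 <- replicate_quality(raw2)
  expect_equal(res2$metrics$cv[1], sd(c(90, 110)) / 100, tolerance = 1e-12)
  expect_true("M001" %in% colnames(res2$data$values))

  # identical replicate pairs: CV = 0, ICC = 1
  vv3 <- matrix(rep(c(5, 7, 9), each = 2), 6, 1, dimnames = list(NULL, "M001"))
  raw3 <- make_raw(vv3, participant = rep(c("A", "B", "C"), each = 2),
                   replicate_no = rep(1:2, 3))
  res3 <- replicate_quality(raw3)
  expect_equal(res3$metrics$cv[1], 0)
  expect_equal(res3$metrics$icc[1], 1)

  expect_warning(replicate_quality(make_raw(vv3[c(1, 3, 5), , drop = FALSE])),
                 "no replicate groups")
})

test_that("replicate collapsing averages available values", {
  v <- matrix(c(4, 6,  4, NA,  1, 2, 9), ncol = 1,
              dimnames = list(NULL, "M001"))
  raw <- make_raw(v, participant = c("A", "A", "B", "B", "C", "C", "C"),
                  replicate_no = c(1, 2, 1, 2, 1, 2, 3))
  out <- collapse_replicates(raw)
  expect_equal(unname(out$values[, 1]), c(5, 4, 4))
  expect_equal(out$records$participant_id, c("A", "B", "C"))
})

test_that("fasting and QC-tag filters remove the right participants", {
  v <- matrix(runif(4 * 2, 1, 5), 4, 2)
  v[2, 1] <- NA; v[3, 2] <- NA
  fasting <- c(P001 = TRUE, P002 = TRUE, P003 = TRUE, P004 = FALSE)
  tags <- data.frame(record_id = c("P002_r1", "P003_r1"),
                     metabolite_id = c("M001", "M002"),
                     tag = c("low ethanol", "below limit of quantification"),
                     stringsAsFactors = FALSE)
  raw <- make_raw(v, fasting = fasting, qc_tags = tags, platform = "nmr",
                  lod = NULL)
  res <- filter_participants_by_flags(raw)
  kept <- res$data$records$participant_id
  expect_false("P004" %in% kept)          # non-fasting
  expect_false("P002" %in% kept)          # contamination tag
  expect_true("P003" %in% kept)           # below-LOQ miss kept for imputation
  expect_setequal(res$report$id, c("P004", "P002"))
})

test_that("left-censored imputation applies half-LOD and half-minimum rules", {
  v <- matrix(c(NA, 1, 2, 3), 4, 1, dimnames = list(NULL, "M001"))
  lod <- matrix(0.4, 1, 1, dimnames = list("M001", "PL01"))
  raw <- make_raw(v, lod = lod)
  out <- impute_left_censored(raw)
  expect_equal(unname(out$data$values[1, 1]), 0.2)
  expect_equal(nrow(out$log), 1)
  expect_equal(out$log$rule, "half-LOD")

  nm <- make_raw(matrix(c(NA, 0.06, 0.1, 0.5), 4, 1,
                        dimnames = list(NULL, "M001")),
                 platform = "nmr", lod = NULL)
  out2 <- impute_left_censored(nm)
  expect_equal(unname(out2$data$values[1, 1]), 0.03)

  lod_na <- matrix(NA_real_, 1, 1, dimnames = list("M001", "PL01"))
  expect_error(impute_left_censored(make_raw(v, lod = lod_na)), "LOD")
})

test_that("transformation follows add-1/log2/z-score/winsorize with population SD", {
  raw <- make_raw(matrix(c(0, 1, 3), 3, 1, dimnames = list(NULL, "M001")))
  cl <- transform_concentrations(raw)
  expect_equal(unname(cl$matrix[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)

  # heavy outlier clamps to the winsor limit
  raw2 <- make_raw(matrix(c(rep(1, 30), 4000), 31, 1,
                          dimnames = list(NULL, "M001")))
  cl2 <- transform_concentrations(raw2, winsor_limit = 3)
  expect_equal(max(cl2$matrix), 3)
  expect_true(all(abs(cl2$matrix) <= 3))

  expect_error(transform_concentrations(
    make_raw(matrix(rep(2, 5), 5, 1, dimnames = list(NULL, "M777")))), "M777")
  expect_error(transform_concentrations(
    make_raw(matrix(c(NA, 1), 2, 1, dimnames = list(NULL, "M001")))), "impute")
})

test_that("transformed columns are exactly standardized before winsorizing", {
  set.seed(4)
  raw <- make_raw(matrix(exp(rnorm(200 * 8)) * 5, 200, 8))
  cl <- transform_concentrations(raw, winsor_limit = Inf)
  expect_lt(max(abs(colMeans(cl$matrix))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(cl$matrix^2)) - 1)), 1e-8)
})

test_that("Mahalanobis screen matches the chi-square oracle and brute force", {
  set.seed(5)
  m <- rbind(matrix(rnorm(400), 200, 2), c(5, 5))
  rownames(m) <- sprintf("P%03d", 1:201)
  res <- mahalanobis_screen(m, alpha = 0.001)
  expect_true("P201" %in% res$flagged)
  # brute-force quadratic form on a small instance
  m2 <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(unname(mahalanobis_screen(m2, alpha = 1)$d2),
               unname(mahalanobis_brute(m2)), tolerance = 1e-10)
  # singular covariance
  sing <- cbind(1:20, (1:20) * 2)
  expect_error(mahalanobis_screen(sing, 0.001), "singular|reduce")
  expect_error(mahalanobis_screen(matrix(rnorm(12), 3, 4)), "more observations")
})

test_that("Mahalanobis null flag rate is near nominal across replicate cohorts", {
  set.seed(6)
  rates <- replicate(10, {
    m <- matrix(rnorm(2000 * 5), 2000, 5)
    length(mahalanobis_screen(m, alpha = 0.001)$flagged) / 2000
  })
  # doubled binomial tolerance around 0.001
  expect_lt(mean(rates), 0.001 + 2 * 2 * sqrt(0.001 * 0.999 / 20000))
})

test_that("medication residualization keeps true predictors and passes through nulls", {
  set.seed(7)
  n <- 500
  meds <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
                 dimnames = list(sprintf("P%03d", 1:n), c("a", "b", "c")))
  y_null <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(sprintf("P%03d", 1:n), sprintf("M%03d", 1:4)))
  cl <- make_clean(y_null)
  out <- residualize_medications(cl, meds)
  kept <- attr(out, "kept_medications")
  # under the null most columns pass through unchanged
  untouched <- vapply(seq_len(4), function(j)
    length(kept[[j]]) == 0, logical(1))
  expect_gte(sum(untouched), 2)
  expect_equal(out$matrix[, untouched], y_null[, untouched])

  # injected 1.0 z-unit effect of medication "a" is recovered and removed
  y_eff <- y_null
  y_eff[, 1] <- y_eff[, 1] + 1.0 * meds[, "a"]
  out2 <- residualize_medications(make_clean(y_eff), meds)
  expect_true("a" %in% attr(out2, "kept_medications")[[1]])
  expect_lt(abs(cor(out2$matrix[, 1], meds[, "a"])), 0.05)

  # zero medications: identity
  out3 <- residualize_medications(cl, meds[, 0])
  expect_identical(out3$matrix, cl$matrix)

  # duplicated medication columns are dropped with a warning
  dup <- cbind(meds, a2 = meds[, "a"])
  expect_warning(residualize_medications(cl, dup), "duplicat")
})

test_that("run_qc reproduces the protocol's dimension trajectory", {
  cfg <- sim_config(n_participants = 250, n_metabolites = 25,
                    module_spec = list(list(size = 10, rho = 0.6)),
                    lod_quantile = 0.03, replicate_fraction = 0.15,
                    nonfasting_fraction = 0.06, seed = 71)
  co <- generate_cohort(cfg)
  qc <- run_qc(co$raw)     # winsor bound holds pre-residualization
  expect_s3_class(qc$clean, "clean_metab")
  expect_false(any(is.na(qc$clean$matrix)))
  expect_true(all(abs(qc$clean$matrix) <= 3))
  # non-fasting participants are gone
  nonfast <- co$covariates$participant_id[!co$covariates$fasting]
  expect_false(any(nonfast %in% rownames(qc$clean$matrix)))
  # imputation handled every censored cell that survived filtering
  expect_gt(nrow(qc$imputation_log), 0)
  # dimension bookkeeping: rows only shrink
  dims <- qc$dimensions
  expect_true(dims$final[1] <= dims$collapsed[1])
  expect_true(dims$collapsed[1] <= dims$flags[1])
})
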