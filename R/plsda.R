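# Brain phenotype processing and PLS-DA ----------------------------------
#
# Reduces six ICV-normalized brain segment volumes against consolidated
# diagnosis labels with a NIPALS PLS2 fit on a dummy-coded class matrix.
# Scores from the selected components serve as the "brain component"
# phenotypes for the downstream association stage.

DIAG6_LEVELS <- c("CN", "SMC", "EMCI", "MCI", "LMCI", "AD")

#' Consolidate six diagnosis labels into three groups
#'
#' Controls and subjective memory complaints map to `CN`; early, late and
#' plain mild cognitive impairment map to `MCI`; `AD` stays `AD`.
#'
#' @param labels6 character vector with values in
#'   `c("CN","SMC","EMCI","MCI","LMCI","AD")`.
#' @return character vector with values in `c("CN","MCI","AD")`.
#' @export
consolidate_diagnosis <- function(labels6) {
  unknown <- setdiff(unique(labels6), DIAG6_LEVELS)
  if (length(unknown))
    stop("unknown diagnosis label(s): ", paste(unknown, collapse = ", "))
  map <- c(CN = "CN", SMC = "CN", EMCI = "MCI", MCI = "MCI", LMCI = "MCI",
           AD = "AD")
  unname(map[labels6])
}

#' Normalize brain segment volumes by intracranial volume
#'
#' Divides each of the six segment volumes by ICV; the ventricle ratio,
#' whose distribution is strongly right-skewed, is replaced by its
#' natural logarithm. Column order is fixed: ventricles (log ratio),
#' hippocampus, entorhinal, fusiform, midtemporal, wholebrain.
#'
#' @param volumes data.frame with columns for the six segments
#'   (`ventricles`, `hippocampus`, `entorhinal`, `fusiform`,
#'   `midtemporal`, `wholebrain`) and `icv`; an optional
#'   `participant_id` column becomes rownames.
#' @return numeric matrix, participants x 6.
#' @export
normalize_volumes <- function(volumes) {
  need <- c(BRAIN_SEGMENTS, "icv")
  if (!all(need %in% names(volumes)))
    stop("volumes table must contain columns: ", paste(need, collapse = ", "))
  if (any(volumes$icv <= 0)) stop("ICV must be positive")
  m <- as.matrix(volumes[, BRAIN_SEGMENTS]) / volumes$icv
  if (any(m[, "ventricles"] <= 0))
    stop("non-positive ventricle/ICV ratio cannot be log-transformed")
  m[, "ventricles"] <- log(m[, "ventricles"])
  if ("participant_id" %in% names(volumes))
    rownames(m) <- volumes$participant_id
  m
}

#' Fit a PLS-DA model of brain volumes against diagnosis
#'
#' NIPALS PLS2: predictors are centered and unit-scaled, the outcome is a
#' centered one-hot dummy matrix of the class labels. Components are
#' extracted iteratively with deflation of X only, which makes the score
#' vectors mutually orthogonal. Per-component variance explained is
#' reported for X (share of the centered/scaled predictor sum of squares)
#' and for Y (share of the dummy-matrix sum of squares, used in VIP).
#'
#' @param X numeric matrix of predictors (e.g. [normalize_volumes()]).
#' @param y class labels (2 or more classes present).
#' @param n_components number of components to extract (at most the rank
#'   of centered X).
#' @return object of class `plsda`: list with weights `W` (normalized,
#'   p x A), loadings `P`, Y-loadings `Q`, scores `T` (n x A),
#'   `x_variance` and `y_variance` (per-component fractions), `vip`,
#'   `center`, `scale`, `classes`.
#' @export
fit_plsda <- function(X, y, n_components = 5) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X and y must align")
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("PLS-DA requires at least 2 classes")
  if (n_components >= nrow(X)) stop("fewer participants than components")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant predictor column")
  Xs <- scale(X, center = ctr, scale = scl)
  Y <- outer(y, classes, `==`) * 1
  colnames(Y) <- classes
  Y <- scale(Y, center = TRUE, scale = FALSE)
  A <- min(n_components, qr(Xs)$rank)
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, A)
  Q <- matrix(0, ncol(Y), A)
  Tm <- matrix(0, n, A)
  ssx0 <- sum(Xs^2); ssy0 <- sum(Y^2)
  Xd <- Xs
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(1000)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < 1e-24 * sum(tt^2)) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pp)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
  }
  tss <- colSums(Tm^2)
  x_var <- tss * colSums(P^2) / ssx0
  y_var <- tss * colSums(Q^2) / ssy0
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("C", seq_len(A)))
  dimnames(Q) <- list(classes, paste0("C", seq_len(A)))
  dimnames(Tm) <- list(rownames(X), paste0("C", seq_len(A)))
  model <- structure(list(W = W, P = P, Q = Q, T = Tm,
                          x_variance = unname(x_var),
                          y_variance = unname(y_var),
                          center = ctr, scale = scl, classes = classes,
                          n_components = A),
                     class = "plsda")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d components, X-variance explained %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$x_variance), collapse = " ")))
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a)`
#' where `SSY_a` is the Y-variance explained by component `a`. The mean
#' of the squared VIPs is 1, so `sum(VIP^2) = p`.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return named numeric vector of VIP scores per predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$y_variance
  if (sum(ssy) <= 0) stop("zero total Y-variance explained; VIP undefined")
  p <- nrow(model$W)
  W2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), `/`)^2
  vip <- sqrt(p * as.numeric(W2 %*% ssy) / sum(ssy))
  stats::setNames(vip, rownames(model$W))
}

#' Select leading components reaching a variance target
#'
#' Returns the indices of the smallest leading prefix of components whose
#' cumulative X-variance explained reaches `variance_target`; if the
#' target is unreachable with the fitted components, all components are
#' returned with a warning.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param variance_target cumulative X-variance fraction (default 0.95).
#' @return integer vector of component indices.
#' @export
select_components <- function(model, variance_target = 0.95) {
  stopifnot(inherits(model, "plsda"))
  cum <- cumsum(model$x_variance)
  if (variance_target <= 0) return(1L)
  k <- which(cum >= variance_target)
  if (!length(k)) {
    warning(sprintf("variance target %g unreachable (cumulative %.3f); returning all %d components",
                    variance_target, max(cum), model$n_components))
    return(seq_len(model$n_components))
  }
  seq_len(min(k))
}

#' Outlier screen on PLS-DA scores
#'
#' Applies [mahalanobis_screen()] to the selected score columns.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param components component indices (default: all fitted).
#' @param alpha chi-square tail probability.
#' @return as [mahalanobis_screen()].
#' @export
score_outlier_screen <- function(model, components = NULL, alpha = 0.001) {
  stopifnot(inherits(model, "plsda"))
  if (is.null(components)) components <- seq_len(model$n_components)
  mahalanobis_screen(model$T[, components, drop = FALSE], alpha)
}
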