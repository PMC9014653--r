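# Independent oracles and fixture builders used across the suite.

# Block-structured latent-factor matrix: n_blocks modules of `size`
# members at within-correlation rho, plus `extra` independent noise
# columns. Returns a plain z-scale matrix (participants x metabolites).
gen_block_matrix <- function(seed, n = 500, size = 20, rho = 0.8,
                             n_blocks = 3, extra = 0) {
  set.seed(seed)
  p <- n_blocks * size + extra
  Z <- matrix(rnorm(n * p), n, p)
  for (b in seq_len(n_blocks)) {
    f <- rnorm(n)
    idx <- ((b - 1) * size + 1):(b * size)
    for (k in idx) Z[, k] <- sqrt(rho) * f + sqrt(1 - rho) * rnorm(n)
  }
  dimnames(Z) <- list(sprintf("P%04d", seq_len(n)), sprintf("M%03d", seq_len(p)))
  Z
}

block_truth <- function(size = 20, n_blocks = 3, extra = 0)
  c(rep(seq_len(n_blocks), each = size), rep(0, extra))

# Brute-force TOM by triple loop (independent of the vectorized path).
tom_brute <- function(A) {
  p <- nrow(A)
  k <- rowSums(A) - 1
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(p)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    tom[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# Brute-force per-point Mahalanobis quadratic form.
mahalanobis_brute <- function(m) {
  mu <- colMeans(m)
  Sinv <- solve(cov(m))
  apply(m, 1, function(x) as.numeric(t(x - mu) %*% Sinv %*% (x - mu)))
}

# Fixed-effects inverse-variance meta-analysis oracle: weighted mean
# effect over its pooled standard error.
meta_oracle_z <- function(beta_f, se_f, beta_m, se_m) {
  w_f <- 1 / se_f^2; w_m <- 1 / se_m^2
  est <- (w_f * beta_f + w_m * beta_m) / (w_f + w_m)
  est / sqrt(1 / (w_f + w_m))
}

# Brute-force PLS2 oracle: per deflation step the weight vector is the
# leading eigenvector of X' Y Y' X.
pls_oracle <- function(X, y, A) {
  classes <- sort(unique(y))
  Y <- scale(outer(y, classes, `==`) * 1, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  Tm <- matrix(0, nrow(Xs), A)
  for (a in seq_len(A)) {
    M <- crossprod(Xs, Y) %*% crossprod(Y, Xs)
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    tt <- Xs %*% w
    pp <- crossprod(Xs, tt) / sum(tt^2)
    Xs <- Xs - tt %*% t(pp)
    Tm[, a] <- tt
  }
  Tm
}

# Hand-built raw_metab object for unit tests. `values` is a
# records x metabolites matrix; plates/replicates via arguments.
make_raw <- function(values, plate = NULL, participant = NULL,
                     replicate_no = NULL, lod = NULL, fasting = NULL,
                     qc_tags = NULL, platform = "targeted") {
  n <- nrow(values)
  if (is.null(participant)) participant <- sprintf("P%03d", seq_len(n))
  if (is.null(replicate_no)) {
    replicate_no <- stats::ave(seq_len(n), participant, FUN = seq_along)
  }
  if (is.null(plate)) plate <- rep("PL01", n)
  rec_id <- sprintf("%s_r%d", participant, replicate_no)
  rownames(values) <- rec_id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  records <- data.frame(record_id = rec_id, participant_id = participant,
                        plate_id = plate, replicate_no = replicate_no,
                        stringsAsFactors = FALSE)
  if (is.null(lod) && platform == "targeted") {
    lod <- matrix(0, ncol(values), length(unique(plate)),
                  dimnames = list(colnames(values), unique(plate)))
  }
  if (is.null(fasting)) {
    fasting <- rep(TRUE, length(unique(participant)))
    names(fasting) <- unique(participant)
  }
  args <- list(values = values, records = records, lod = lod,
               fasting = fasting, platform = platform)
  if (!is.null(qc_tags)) args$qc_tags <- qc_tags
  do.call(raw_metabolite_data, args)
}

# Clean matrix wrapper for functions expecting clean_metab.
make_clean <- function(m) {
  structure(list(matrix = m, participant_id = rownames(m),
                 provenance = "test"), class = "clean_metab")
}
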