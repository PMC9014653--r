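# Weighted correlation network modules ------------------------------------
#
# Unsigned WGCNA-style workflow: similarity = |Pearson correlation|,
# adjacency = similarity^beta, topological overlap matrix (TOM),
# average-linkage clustering of 1-TOM, a deterministic top-down dynamic
# branch cut, eigen-metabolite summaries and module merging.

MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Build an unsigned weighted correlation network
#'
#' Similarity is the absolute Pearson correlation between metabolite
#' profiles; the adjacency raises it elementwise to the soft-thresholding
#' power `beta`; the topological overlap matrix is
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' the sum over `u != i, j` and `k_i` the connectivity of node `i`.
#'
#' @param clean a `clean_metab` object or a numeric matrix
#'   (participants x metabolites).
#' @param beta soft-thresholding power (>= 1).
#' @return object of class `metab_network`: list with `similarity`,
#'   `adjacency`, `tom`, `beta`, `metabolite_id`.
#' @export
build_network <- function(clean, beta = 10) {
  m <- if (inherits(clean, "clean_metab")) clean$matrix else as.matrix(clean)
  if (ncol(m) < 3) stop("network construction needs at least 3 metabolites")
  if (beta < 1) stop("soft power beta must be >= 1")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant metabolite column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  S <- abs(stats::cor(m))
  A <- S^beta
  diag(A) <- 1
  structure(list(similarity = S, adjacency = A, tom = tom_from_adjacency(A),
                 beta = beta, metabolite_id = colnames(m)),
            class = "metab_network")
}

# TOM from an adjacency matrix with unit diagonal (vectorized).
tom_from_adjacency <- function(A) {
  k <- rowSums(A) - 1
  AA <- A %*% A
  num <- AA - 2 * A + A            # sum over u != i,j plus A_ij itself
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each candidate power, computes the connectivity distribution of
#' the resulting adjacency, bins `log10(k)` and regresses the log
#' frequency on the log mean connectivity per bin. The returned R-squared
#' is signed (negated when the slope is positive, as in the usual
#' scale-free fit diagnostic); `NA` marks degenerate distributions.
#'
#' @param clean a `clean_metab` object or numeric matrix.
#' @param candidate_powers numeric vector of powers to evaluate.
#' @param n_bins number of connectivity bins.
#' @return data.frame with columns `power`, `r_squared`, `mean_k`.
#' @export
pick_soft_threshold <- function(clean, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                n_bins = 10) {
  m <- if (inherits(clean, "clean_metab")) clean$matrix else as.matrix(clean)
  if (ncol(m) < 20)
    stop("scale-free fit needs at least 20 metabolites")
  S <- abs(stats::cor(m))
  out <- data.frame(power = candidate_powers, r_squared = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    A <- S^candidate_powers[i]
    diag(A) <- 1
    k <- rowSums(A) - 1
    out$mean_k[i] <- mean(k)
    k <- k[k > 0]
    if (length(unique(k)) < 3) next
    cuts <- cut(k, breaks = n_bins, include.lowest = TRUE)   # equal-width bins
    freq <- tapply(k, cuts, length)
    kmean <- tapply(k, cuts, mean)
    keep <- !is.na(freq) & freq > 0 & !is.na(kmean)
    if (sum(keep) < 3) next
    df <- data.frame(lp = log10(freq[keep] / length(k)), lk = log10(kmean[keep]))
    fit <- stats::lm(lp ~ lk, data = df)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # tolerate near-perfect fits
    if (stats::coef(fit)[2] > 0) r2 <- -r2
    out$r_squared[i] <- r2
  }
  out
}

#' Cluster metabolites into modules by adaptive branch cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM), cut into branches at a height adapted to the tree's own
#' merge-height distribution: `h_max - gap_frac * (h_max - h_min)`.
#' Because module-joining merges concentrate near the top of the tree
#' while within-module merges sit below, this separates the branch
#' structure across a wide range of soft powers without a hand-set
#' height. Branches smaller than `min_cluster_size` are unassigned
#' ("grey"). A fixed dissimilarity can be supplied via `cut_height`
#' (static fallback mode).
#'
#' @param network a [build_network()] result.
#' @param min_cluster_size smallest assignable module size.
#' @param gap_frac fraction of the merge-height range that the cut sits
#'   below the tree top (default 0.15).
#' @param cut_height if non-`NULL`, cut at this fixed dissimilarity
#'   height instead of the adaptive one.
#' @return object of class `module_partition`: list with `labels`
#'   (named character vector; "grey" = unassigned), `min_cluster_size`,
#'   `cut_height` used, `dendrogram` (the hclust object),
#'   `merge_history`.
#' @export
cluster_modules <- function(network, min_cluster_size = 5, gap_frac = 0.15,
                            cut_height = NULL) {
  stopifnot(inherits(network, "metab_network"))
  p <- length(network$metabolite_id)
  if (min_cluster_size > p)
    stop("min_cluster_size exceeds the number of metabolites")
  d <- stats::as.dist(1 - network$tom)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    rng <- diff(range(hc$height))
    # degenerate tree (all merges at one height) collapses to one cluster
    cut_height <- if (rng < 1e-8) max(hc$height) else
      max(hc$height) - gap_frac * rng
  }
  raw <- stats::cutree(hc, h = cut_height)
  raw_labels <- split(seq_len(p), raw)
  sizes <- lengths(raw_labels)
  keep <- names(sizes)[sizes >= min_cluster_size & names(sizes) != "0"]
  # order modules by decreasing size for stable color naming
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- rep("grey", p)
  for (i in seq_along(keep)) {
    col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else sprintf("module%03d", i)
    labels[raw_labels[[keep[i]]]] <- col
  }
  names(labels) <- network$metabolite_id
  structure(list(labels = labels, min_cluster_size = min_cluster_size,
                 cut_height = cut_height, dendrogram = hc,
                 merge_history = list()),
            class = "module_partition")
}

#' Module eigen-metabolites and module membership
#'
#' Each assigned module is summarized by the first principal component of
#' its member profiles (members centered and unit-scaled), rescaled to
#' unit variance, with the sign chosen so the eigen-metabolite correlates
#' positively with the module's mean member profile. Module membership
#' (MM, also called kME) is the Pearson correlation of each member
#' metabolite with its own module's eigen-metabolite; grey metabolites
#' have no MM.
#'
#' @param clean a `clean_metab` object or numeric matrix.
#' @param partition a [cluster_modules()] result.
#' @return object of class `eigen_metab`: list with `eigens`
#'   (participants x modules matrix), `membership` (named numeric vector
#'   per assigned metabolite), `labels`.
#' @export
compute_eigen <- function(clean, partition) {
  m <- if (inherits(clean, "clean_metab")) clean$matrix else as.matrix(clean)
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels[colnames(m)]
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, MODULE_COLORS))]
  eig <- matrix(NA_real_, nrow(m), length(mods),
                dimnames = list(rownames(m), mods))
  mm <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (mod in mods) {
    cols <- names(labels)[labels == mod]
    sub <- scale(m[, cols, drop = FALSE])
    if (length(cols) == 1) {
      warning(sprintf("module %s has a single member; eigen set to that column", mod))
      e <- as.numeric(sub)
    } else {
      sv <- svd(sub, nu = 1, nv = 0)
      e <- sv$u[, 1]
    }
    e <- e / stats::sd(e)
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    eig[, mod] <- e
    mm[cols] <- as.numeric(stats::cor(m[, cols, drop = FALSE], e))
  }
  structure(list(eigens = eig, membership = mm[!is.na(mm)], labels = labels),
            class = "eigen_metab")
}

#' Merge highly correlated modules
#'
#' Iteratively merges the pair of modules whose eigen-metabolite Pearson
#' correlation is highest, while that correlation strictly exceeds
#' `merge_r`; eigen-metabolites are recomputed after every merge. Ties
#' are broken by the alphabetically smallest module-label pair. The
#' merged module keeps the label of the larger member.
#'
#' @param clean a `clean_metab` object or numeric matrix.
#' @param partition a [cluster_modules()] result.
#' @param eigens a [compute_eigen()] result for `partition`.
#' @param merge_r correlation threshold (strict; default 0.9).
#' @return list with updated `partition` and `eigens`; the partition's
#'   `merge_history` records each merge.
#' @export
merge_close_modules <- function(clean, partition, eigens, merge_r = 0.9) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(eigens, "eigen_metab"))
  history <- list()
  repeat {
    mods <- colnames(eigens$eigens)
    if (length(mods) < 2) break
    C <- stats::cor(eigens$eigens)
    diag(C) <- -Inf
    best <- max(C)
    if (!(best > merge_r)) break
    cand <- which(C == best, arr.ind = TRUE)
    pairs <- t(apply(cand, 1, function(r) sort(mods[r])))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    a <- pairs[1, 1]; b <- pairs[1, 2]
    sizes <- table(partition$labels)
    into <- if (sizes[[a]] >= sizes[[b]]) a else b
    from <- if (into == a) b else a
    partition$labels[partition$labels == from] <- into
    history[[length(history) + 1]] <- list(from = from, into = into, r = best)
    eigens <- compute_eigen(clean, partition)
  }
  partition$merge_history <- c(partition$merge_history, history)
  list(partition = partition, eigens = eigens)
}
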