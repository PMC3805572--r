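#' Correlation neighborhood of a target feature
#'
#' Pearson correlation of every other feature against a target (on the
#' log10 replicate-averaged scale by default, pairwise-complete), split
#' into positively and negatively correlated sets at `|r| >= r_threshold`.
#' The reported per-feature p-value is the usual two-sided t-based
#' correlation test at the realized sample size.
#'
#' @param table a `feature_table`.
#' @param target feature id of the anchor feature.
#' @param r_threshold absolute correlation threshold (default 0.3).
#' @param on_log correlate log10 intensities (default `TRUE`).
#' @return list with `r` (named vector over the other features), `p`,
#'   `positive` (ids with `r >= threshold`), `negative` (ids with
#'   `r <= -threshold`).
#' @export
target_correlates <- function(table, target, r_threshold = 0.3,
                              on_log = TRUE) {
  X <- sample_matrix(table, log10 = on_log)
  if (!target %in% colnames(X)) stop("unknown target feature: ", target)
  x0 <- X[, target]
  if (stats::sd(x0, na.rm = TRUE) == 0 || all(is.na(x0)))
    stop("target feature is constant")
  others <- setdiff(colnames(X), target)
  r <- suppressWarnings(
    as.numeric(stats::cor(X[, others, drop = FALSE], x0,
                          use = "pairwise.complete.obs")))
  names(r) <- others
  n_eff <- colSums(!is.na(X[, others, drop = FALSE]) & !is.na(x0))
  tv <- r * sqrt(pmax(n_eff - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tv), pmax(n_eff - 2, 1))
  list(r = r, p = stats::setNames(p, others),
       positive = names(r)[!is.na(r) & r >= r_threshold],
       negative = names(r)[!is.na(r) & r <= -r_threshold])
}

#' Soft-threshold correlation adjacency
#'
#' Weighted-network adjacency between features: unsigned
#' `|cor|^beta` (default) or signed `((1 + cor)/2)^beta`. The diagonal is
#' set to 0 so connectivity sums exclude self-adjacency. Constant features
#' produce undefined correlations and are rejected with an error naming
#' them; drop them upstream.
#'
#' @param X samples-by-features matrix.
#' @param beta soft-threshold power, >= 1 (default 6, the customary
#'   unsigned default).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return symmetric adjacency matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
adjacency <- function(X, beta = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (beta < 1) stop("beta must be >= 1")
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  bad <- colSums(is.na(C)) == nrow(C) - 1 | is.na(diag(C))
  if (any(bad))
    stop("constant feature(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  C[is.na(C)] <- 0
  A <- if (mode == "unsigned") abs(C)^beta else ((1 + C) / 2)^beta
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' Network similarity combining direct adjacency with shared neighbors:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_u a_iu`; the diagonal is 1 and `1 - TOM` is the
#' clustering dissimilarity.
#'
#' @param A symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @return the TOM matrix (unit diagonal).
#' @export
topological_overlap <- function(A) {
  A <- as.matrix(A)
  if (any(abs(diag(A)) > 0)) stop("adjacency must have zero diagonal")
  k <- colSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a static tree
#' cut at `cut_height`; clusters smaller than `min_size` are relabeled 0
#' (unassigned), and surviving modules are labeled 1, 2, ... by decreasing
#' size.
#'
#' @param TOM a topological overlap matrix.
#' @param min_size smallest retained module (default 10).
#' @param cut_height static cut height on the dissimilarity dendrogram
#'   (default 0.99).
#' @return object of class `module_partition`: list with `labels` (named
#'   integer vector, 0 = unassigned), `n_modules`, `parameters`.
#' @export
detect_modules <- function(TOM, min_size = 10, cut_height = 0.99) {
  d <- stats::as.dist(1 - TOM)
  h <- stats::hclust(d, method = "average")
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  } else {
    warning("no module reaches min_size; all features unassigned")
  }
  names(labels) <- colnames(TOM)
  structure(list(labels = labels, n_modules = length(keep),
                 parameters = list(min_size = min_size,
                                   cut_height = cut_height)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules; %d of %d features assigned\n",
              x$n_modules, sum(x$labels > 0), length(x$labels)))
  invisible(x)
}

#' Module eigengene
#'
#' The first principal component of a module's standardized member matrix,
#' returned as a unit-norm per-sample score that summarizes the module's
#' intensity pattern. The sign is oriented so the average correlation with
#' the members is nonnegative, which makes the eigengene invariant to
#' flipping all member intensities.
#'
#' @param X_module samples-by-members matrix (>= 2 members, none constant).
#' @return numeric per-sample vector with attribute `var_explained`.
#' @export
module_eigengene <- function(X_module) {
  X_module <- as.matrix(X_module)
  if (ncol(X_module) < 2) stop("module needs at least 2 members")
  Z <- scale(X_module)
  if (anyNA(Z)) stop("degenerate module: constant or missing member")
  s <- svd(Z, nu = 1, nv = 0)
  e <- s$u[, 1]
  if (mean(stats::cor(e, Z)) < 0) e <- -e
  attr(e, "var_explained") <- s$d[1]^2 / sum(s$d^2)
  e
}

#' Eigengenes for every module of a partition
#'
#' @param X samples-by-features matrix covering the partition's features.
#' @param partition a `module_partition` (or named label vector).
#' @return samples-by-modules matrix (columns `ME1`, `ME2`, ...).
#' @export
module_eigengenes <- function(X, partition) {
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("partition has no modules")
  E <- vapply(mods, function(k) {
    members <- names(labels)[labels == k]
    missing <- setdiff(members, colnames(X))
    if (length(missing))
      stop("module ", k, " members missing from matrix: ",
           paste(missing, collapse = ", "))
    as.numeric(module_eigengene(X[, members, drop = FALSE]))
  }, numeric(nrow(X)))
  dimnames(E) <- list(rownames(X), paste0("ME", mods))
  E
}

#' Eigengene network
#'
#' Module-level adjacency `A_IJ = (1 + cor(E_I, E_J)) / 2`: 1 for
#' perfectly correlated eigengenes, 0 for perfectly anticorrelated, 0.5
#' for unrelated ones.
#'
#' @param E samples-by-modules eigengene matrix.
#' @return object of class `eigengene_network`: list with `adjacency` and
#'   `eigengenes`.
#' @export
eigengene_network <- function(E) {
  if (ncol(E) < 2) stop("need at least 2 modules")
  A <- (1 + stats::cor(E)) / 2
  A <- pmin(pmax(A, 0), 1)
  diag(A) <- 1
  structure(list(adjacency = A, eigengenes = E),
            class = "eigengene_network")
}

#' Module preservation between a reference and a test cohort
#'
#' The reference partition's modules are summarized by their eigengenes in
#' both datasets; the preservation matrix is one minus the absolute
#' difference of the two eigengene networks, `P = 1 - |A_ref - A_test|`,
#' and the per-module preservation statistic is the column mean of `P`
#' (excluding the identically-1 diagonal by default).
#'
#' @param ref_X,test_X samples-by-features matrices for the two cohorts;
#'   `test_X` must contain every module member.
#' @param partition a `module_partition` defined on the reference cohort.
#' @param include_diagonal include the diagonal in column means (default
#'   `FALSE`).
#' @return list with `P` (preservation matrix), `preservation` (per-module
#'   column means), `ref_network`, `test_network`.
#' @export
module_preservation <- function(ref_X, test_X, partition,
                                include_diagonal = FALSE) {
  E_ref <- module_eigengenes(ref_X, partition)
  E_test <- module_eigengenes(test_X, partition)
  A_ref <- eigengene_network(E_ref)$adjacency
  A_test <- eigengene_network(E_test)$adjacency
  P <- 1 - abs(A_ref - A_test)
  means <- vapply(seq_len(ncol(P)), function(j) {
    v <- P[, j]
    if (!include_diagonal) v <- v[-j]
    mean(v)
  }, numeric(1))
  names(means) <- colnames(P)
  list(P = P, preservation = means,
       ref_network = A_ref, test_network = A_test)
}

#' Build a weighted correlation network from a feature table
#'
#' Convenience wrapper: log10 replicate-averaged matrix, soft-threshold
#' adjacency, TOM, and module detection in one call.
#'
#' @param table a `feature_table`.
#' @param beta,mode see [adjacency()].
#' @param min_size,cut_height see [detect_modules()].
#' @param on_log see [sample_matrix()].
#' @return list with `X` (the matrix used), `adjacency`, `TOM`,
#'   `partition`.
#' @export
build_network <- function(table, beta = 6, mode = "unsigned",
                          min_size = 10, cut_height = 0.99,
                          on_log = TRUE) {
  X <- sample_matrix(table, log10 = on_log)
  A <- adjacency(X, beta = beta, mode = mode)
  tom <- topological_overlap(A)
  list(X = X, adjacency = A, TOM = tom,
       partition = detect_modules(tom, min_size, cut_height))
}
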