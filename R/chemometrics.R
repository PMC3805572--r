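#' Autoscale a sample-by-feature matrix
#'
#' Column-wise centering and unit-variance (n-1) scaling, the standard
#' pretreatment before PCA and PLS-DA so every feature contributes equally
#' regardless of its mean intensity. Constant columns are centered only and
#' flagged rather than divided by zero.
#'
#' @param X numeric matrix, samples in rows. No missing values (filter
#'   first; the detection filter at 1.0 guarantees completeness).
#' @return object of class `scaled_matrix`: list with `values`, `center`,
#'   `scale`, `constant` (logical flags).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X))
    stop("autoscale requires a complete matrix; apply detection_filter first")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  constant <- sds < 1e-12
  scl <- ifelse(constant, 1, sds)
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  structure(list(values = Z, center = ctr, scale = scl,
                 constant = constant),
            class = "scaled_matrix")
}

as_values <- function(Z) {
  if (inherits(Z, "scaled_matrix")) Z$values else as.matrix(Z)
}

ssq <- function(m) sum(m^2)

#' Principal component analysis by singular value decomposition
#'
#' @param Z a `scaled_matrix` or plain (already centered) matrix.
#' @param k number of components, at most `min(n - 1, n_features)`.
#' @return list with `scores` (`n x k`), `loadings` (`features x k`,
#'   orthonormal), `variance_fraction` (per component).
#' @export
pca <- function(Z, k = 2) {
  V <- as_values(Z)
  if (k > min(nrow(V) - 1, ncol(V)))
    stop("k exceeds min(n - 1, n_features)")
  s <- svd(V, nu = k, nv = k)
  scores <- s$u %*% diag(s$d[seq_len(k)], k, k)
  list(scores = scores, loadings = s$v,
       variance_fraction = (s$d^2 / sum(s$d^2))[seq_len(k)])
}

#' Centered one-hot group dummy matrix
#'
#' One column per group, one-hot coded then column-centered -- the standard
#' PLS-DA response.
#'
#' @param group character/factor vector of group labels.
#' @return centered numeric matrix, `n x n_groups`.
#' @export
group_dummy <- function(group) {
  f <- factor(group)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  scale(Y, center = TRUE, scale = FALSE)
}

project_out <- function(t, qrY) t - qr.fitted(qrY, t)

#' Orthogonal signal correction
#'
#' Removes from the autoscaled data matrix the dominant variation that is
#' orthogonal to the class response. Per component: seed the score `t`
#' with the dominant PC score of the current matrix; orthogonalize `t`
#' against the response columns; find the minimum-norm weight vector `w`
#' solving `Zw ~ t` (least squares via the SVD), normalize it, recompute
#' `t = Zw`, re-orthogonalize, and iterate to convergence; then deflate
#' with the loading `p = Z't / (t't)`. Every removed score is therefore
#' orthogonal to every response column by construction.
#'
#' @param Z a `scaled_matrix` or centered matrix.
#' @param y_dummy centered response matrix (see [group_dummy()]).
#' @param n_osc number of components to remove (default 1).
#' @param tol relative convergence tolerance on the score direction.
#' @param max_iter iteration cap; non-convergence warns and keeps the best
#'   iterate.
#' @return list with `corrected` (deflated matrix), `scores`, `loadings`,
#'   `weights` (one column per removed component), `r2x_removed` (fraction
#'   of the input sum of squares removed per component).
#' @export
osc_filter <- function(Z, y_dummy, n_osc = 1, tol = 1e-10,
                       max_iter = 100) {
  Zc <- as_values(Z)
  stopifnot(n_osc >= 1)
  qrY <- qr(y_dummy)
  ss0 <- ssq(Zc)
  n <- nrow(Zc)
  scores <- matrix(0, n, n_osc)
  loadings <- matrix(0, ncol(Zc), n_osc)
  weights <- matrix(0, ncol(Zc), n_osc)
  r2x <- numeric(n_osc)
  for (comp in seq_len(n_osc)) {
    sv <- svd(Zc)
    keep <- sv$d > sv$d[1] * 1e-10
    t_vec <- project_out(sv$u[, 1] * sv$d[1], qrY)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # minimum-norm least squares: w = V D^-1 U' t
      w <- sv$v[, keep, drop = FALSE] %*%
        (crossprod(sv$u[, keep, drop = FALSE], t_vec) / sv$d[keep])
      w <- w / sqrt(ssq(w))
      t_new <- project_out(Zc %*% w, qrY)
      delta <- sqrt(ssq(t_new / sqrt(ssq(t_new)) -
                        t_vec / sqrt(ssq(t_vec))))
      t_vec <- t_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("OSC component ", comp, " did not converge in ", max_iter,
              " iterations; using best iterate")
    p <- crossprod(Zc, t_vec) / ssq(t_vec)
    Zc <- Zc - tcrossprod(t_vec, p)
    scores[, comp] <- t_vec
    loadings[, comp] <- p
    weights[, comp] <- w
    r2x[comp] <- ssq(tcrossprod(t_vec, p)) / ss0
  }
  list(corrected = Zc, scores = scores, loadings = loadings,
       weights = weights, r2x_removed = r2x)
}

#' Partial least squares discriminant analysis (NIPALS PLS2)
#'
#' Iterates, per component, `w = Z'u` (normalized), `t = Zw`,
#' `q = Y't` (normalized), `u = Yq` until the score stabilizes; then
#' deflates `Z` by `t p'` with `p = Z't/(t't)`. `Y` deflation is optional
#' and off by default. Each component's sign is oriented so its
#' largest-magnitude loading is positive, making score plots reproducible.
#'
#' @param Z a `scaled_matrix` or centered matrix.
#' @param y_dummy centered response matrix.
#' @param n_comp number of predictive components.
#' @param tol,max_iter NIPALS convergence controls.
#' @param deflate_y also deflate the response (default `FALSE`).
#' @return an `opls_model` (here with no OSC part): list with `scores`,
#'   `loadings`, `weights`, `y_loadings`, `r2x`, `r2y`, `y_dummy`.
#' @export
plsda <- function(Z, y_dummy, n_comp = 2, tol = 1e-12, max_iter = 500,
                  deflate_y = FALSE) {
  Zc <- as_values(Z)
  if (n_comp > min(nrow(Zc) - 1, ncol(Zc)))
    stop("n_comp exceeds min(n - 1, n_features)")
  Yc <- y_dummy
  ssz <- ssq(Zc)
  ssy <- ssq(Yc)
  n <- nrow(Zc)
  p_feat <- ncol(Zc)
  T_mat <- matrix(0, n, n_comp)
  P <- matrix(0, p_feat, n_comp)
  W <- matrix(0, p_feat, n_comp)
  C <- matrix(0, ncol(Yc), n_comp)
  r2x <- r2y <- numeric(n_comp)
  for (a in seq_len(n_comp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    t_old <- rep(0, n)
    for (iter in seq_len(max_iter)) {
      w <- crossprod(Zc, u)
      w <- w / sqrt(ssq(w))
      t_vec <- Zc %*% w
      qv <- crossprod(Yc, t_vec)
      qv <- qv / sqrt(ssq(qv))
      u <- Yc %*% qv
      if (sqrt(ssq(t_vec - t_old)) / sqrt(ssq(t_vec)) < tol) break
      t_old <- t_vec
    }
    if (iter == max_iter)
      warning("PLS component ", a, " did not converge; using best iterate")
    p <- crossprod(Zc, t_vec) / ssq(t_vec)
    cvec <- crossprod(Yc, t_vec) / ssq(t_vec)
    j <- which.max(abs(p))
    if (p[j] < 0) { t_vec <- -t_vec; w <- -w; p <- -p; cvec <- -cvec }
    Zc <- Zc - tcrossprod(t_vec, p)
    if (deflate_y) Yc <- Yc - tcrossprod(t_vec, cvec)
    T_mat[, a] <- t_vec
    P[, a] <- p
    W[, a] <- w
    C[, a] <- cvec
    r2x[a] <- ssq(tcrossprod(t_vec, p)) / ssz
    r2y[a] <- ssq(tcrossprod(t_vec, cvec)) / ssy
  }
  structure(list(scores = T_mat, loadings = P, weights = W,
                 y_loadings = C, r2x = r2x, r2y = r2y,
                 y_dummy = y_dummy, osc = NULL),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("opls_model: %d predictive component(s), %d OSC component(s)\n",
              ncol(x$scores),
              if (is.null(x$osc)) 0L else ncol(x$osc$scores)))
  cat("r2x:", paste(sprintf("%.3f", x$r2x), collapse = " "),
      " r2y:", paste(sprintf("%.3f", x$r2y), collapse = " "), "\n")
  invisible(x)
}

#' OSC-corrected PLS-DA on a feature table
#'
#' The full supervised chemometric stage: autoscale the log10
#' replicate-averaged intensities of the requested groups, remove `n_osc`
#' orthogonal-signal components, then fit a NIPALS PLS-DA with `n_pred`
#' predictive components. With `n_osc = 0` this is plain PLS-DA.
#'
#' @param table a `feature_table`.
#' @param meta sample metadata.
#' @param groups character vector (pair or triple) of groups to model.
#' @param n_pred predictive components (default 2, matching two-component
#'   score plots).
#' @param n_osc orthogonal components to remove (default 1).
#' @param on_log model log10 intensities (default `TRUE`).
#' @return an `opls_model` with additional elements `osc` (removed
#'   components), `Z` (the corrected autoscaled matrix used for fitting),
#'   `feature_id`, `sample_id`, `group`, and `score_plot` (data.frame of
#'   per-sample scores with group labels).
#' @export
oplsda <- function(table, meta, groups, n_pred = 2, n_osc = 1,
                   on_log = TRUE) {
  X <- sample_matrix(table, log10 = on_log)
  grp <- meta$group[match(rownames(X), meta$sample_id)]
  keep <- grp %in% groups
  if (!any(keep)) stop("no samples in the requested groups")
  X <- X[keep, , drop = FALSE]
  grp <- grp[keep]
  if (anyNA(X))
    stop("missing intensities in the modeling matrix; apply detection_filter")
  sc <- autoscale(X)
  Y <- group_dummy(grp)
  Zc <- sc$values
  osc <- NULL
  if (n_osc > 0) {
    osc <- osc_filter(sc, Y, n_osc = n_osc)
    Zc <- osc$corrected
  }
  model <- plsda(Zc, Y, n_comp = n_pred)
  model$osc <- osc[c("scores", "loadings", "weights", "r2x_removed")]
  if (n_osc == 0) model$osc <- NULL
  model$Z <- Zc
  model$feature_id <- colnames(X)
  model$sample_id <- rownames(X)
  model$group <- grp
  model$score_plot <- data.frame(sample_id = rownames(X), group = grp,
                                 t1 = model$scores[, 1],
                                 t2 = if (n_pred >= 2) model$scores[, 2]
                                      else NA_real_,
                                 stringsAsFactors = FALSE)
  model
}

#' PCLS feature selection from PLS-DA scores
#'
#' The loading-correlation selector: each feature's combined correlation
#' `R` is its multiple correlation on the first two predictive score
#' vectors (scores are mutually orthogonal, so `R^2 = r1^2 + r2^2`).
#' Features with `R` at or above `corr_threshold` are candidates; the
#' selected set is the top `round(top_fraction * m)` candidates ranked by
#' `R` (or by the magnitude of the first-component loading), where `m` is
#' the full feature count (`fraction_of = "all"`, default) or the
#' candidate count (`"candidates"`).
#'
#' @param model an `opls_model` from [oplsda()] (needs >= 2 predictive
#'   components).
#' @param Z optional feature matrix; defaults to the model's corrected
#'   autoscaled matrix.
#' @param corr_threshold candidate gate on `R` (default 0.95).
#' @param top_fraction selected fraction (default 0.01).
#' @param rank_by `"combined_R"` (default) or `"loading_magnitude"`.
#' @param fraction_of `"all"` (default) or `"candidates"`.
#' @return data.frame (`pcls_result`): `feature_id`, `r1`, `r2`,
#'   `combined_R`, `rank_key`, `candidate`, `selected`.
#' @export
pcls_select <- function(model, Z = NULL, corr_threshold = 0.95,
                        top_fraction = 0.01,
                        rank_by = c("combined_R", "loading_magnitude"),
                        fraction_of = c("all", "candidates")) {
  rank_by <- match.arg(rank_by)
  fraction_of <- match.arg(fraction_of)
  if (ncol(model$scores) < 2)
    stop("PCLS needs at least 2 predictive components")
  if (is.null(Z)) Z <- model$Z
  Z <- as_values(Z)
  r1 <- suppressWarnings(as.numeric(stats::cor(Z, model$scores[, 1])))
  r2 <- suppressWarnings(as.numeric(stats::cor(Z, model$scores[, 2])))
  r1[is.na(r1)] <- 0
  r2[is.na(r2)] <- 0
  R <- sqrt(pmin(r1^2 + r2^2, 1))
  key <- if (rank_by == "combined_R") R else abs(model$loadings[, 1])
  candidate <- R >= corr_threshold
  m <- if (fraction_of == "all") length(R) else sum(candidate)
  n_sel <- round(top_fraction * m)
  selected <- rep(FALSE, length(R))
  cand_idx <- which(candidate)
  if (n_sel > 0 && length(cand_idx)) {
    take <- cand_idx[order(key[cand_idx], decreasing = TRUE)]
    selected[utils::head(take, n_sel)] <- TRUE
  }
  ids <- if (!is.null(model$feature_id) &&
             length(model$feature_id) == length(R)) model$feature_id
         else if (!is.null(colnames(Z))) colnames(Z)
         else sprintf("col%d", seq_along(R))
  out <- data.frame(feature_id = ids,
                    r1 = r1, r2 = r2, combined_R = R, rank_key = key,
                    candidate = candidate, selected = selected,
                    stringsAsFactors = FALSE)
  attr(out, "parameters") <- list(corr_threshold = corr_threshold,
                                  top_fraction = top_fraction,
                                  rank_by = rank_by,
                                  fraction_of = fraction_of)
  class(out) <- c("pcls_result", "data.frame")
  out
}

#' Intersect two feature selections
#'
#' The overlap of (for example) the FDR-significant and PCLS-selected
#' feature sets, with Venn counts.
#'
#' @param set_a,set_b character vectors of feature ids over the same
#'   universe.
#' @return list with `both`, `a_only`, `b_only` and integer `counts`.
#' @export
intersect_selections <- function(set_a, set_b) {
  both <- intersect(set_a, set_b)
  list(both = both,
       a_only = setdiff(set_a, set_b),
       b_only = setdiff(set_b, set_a),
       counts = c(a_only = length(setdiff(set_a, set_b)),
                  both = length(both),
                  b_only = length(setdiff(set_b, set_a))))
}
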