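scaled_random <- function(n, p, seed = 1) {
  set.seed(seed)
  autoscale(matrix(rnorm(n * p), n, p))
}

test_that("autoscaling centers, scales and flags constant columns", {
  Z <- autoscale(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(unname(Z$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(Z$values[, 2]), c(0, 0, 0))
  expect_true(Z$constant[2] && !Z$constant[1])
  # idempotence on an already-scaled matrix
  Z2 <- autoscale(Z$values[, 1, drop = FALSE])
  expect_equal(Z2$values, Z$values[, 1, drop = FALSE], tolerance = 1e-12)
  expect_error(autoscale(matrix(c(1, NA), 2, 1)), "complete")
})

test_that("PCA agrees with the covariance eigendecomposition", {
  set.seed(2)
  X <- matrix(rnorm(20), 5, 4)
  Z <- autoscale(X)
  res <- pca(Z, k = 3)
  eig <- eigen(cov(Z$values))
  for (k in 1:3) {
    expect_equal(abs(res$loadings[, k]), abs(eig$vectors[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(res$variance_fraction,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
  expect_equal(crossprod(res$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-1 input loads everything on PC1
  r1 <- pca(tcrossprod(1:4, c(2, -1, 3)), k = 1)
  expect_equal(r1$variance_fraction[1], 1, tolerance = 1e-12)
  expect_error(pca(Z, k = 5), "exceeds")
})

test_that("OSC scores are orthogonal to the class response", {
  set.seed(4)
  n <- 30
  grp <- rep(c("slow", "rapid"), each = n / 2)
  Y <- group_dummy(grp)
  Z <- scaled_random(n, 40, seed = 4)
  osc <- osc_filter(Z, Y, n_osc = 2)
  for (comp in 1:2) {
    cors <- crossprod(Y, osc$scores[, comp])
    expect_lt(max(abs(cors)) / sqrt(sum(osc$scores[, comp]^2)), 1e-8)
  }
  # deflation removes the reported share of variance
  expect_equal(sum(osc$corrected^2) / sum(Z$values^2),
               1 - sum(osc$r2x_removed), tolerance = 1e-10)
})

test_that("OSC removes a class-orthogonal nuisance factor", {
  # nuisance: a strong factor shared by all samples independent of class
  sep <- function(t, grp) {
    d <- abs(mean(t[grp == "rapid"]) - mean(t[grp == "slow"]))
    d / sd(t)
  }
  wins <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 40
    grp <- rep(c("slow", "rapid"), each = n / 2)
    cls <- ifelse(grp == "rapid", 0.5, -0.5)
    nuis <- rnorm(n, sd = 2)
    X <- sapply(1:60, function(j) {
      w_c <- if (j <= 10) 1 else 0
      w_c * cls + nuis * runif(1, 0.5, 1.5) + rnorm(n)
    })
    Z <- autoscale(X)
    Y <- group_dummy(grp)
    plain <- plsda(Z, Y, n_comp = 1)
    corrected <- plsda(osc_filter(Z, Y, n_osc = 1)$corrected, Y, n_comp = 1)
    if (sep(corrected$scores[, 1], grp) >= sep(plain$scores[, 1], grp))
      wins <- wins + 1
  }
  expect_gte(wins / n_seeds, 0.8)
})

test_that("one-component PLS weight equals the normalized Z'y", {
  set.seed(6)
  n <- 25
  y <- scale(rep(c(1, 0), c(12, 13)), scale = FALSE)
  Z <- scaled_random(n, 15, seed = 6)
  model <- plsda(Z, y, n_comp = 1)
  w_ref <- crossprod(Z$values, y)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(min(sum((model$weights[, 1] - w_ref)^2),
                sum((model$weights[, 1] + w_ref)^2)), 1e-16)
})

test_that("PLS scores are mutually orthogonal and r2 fractions behave", {
  set.seed(7)
  grp <- sample(rep(c("control", "slow", "rapid"), times = c(6, 7, 7)))
  Z <- scaled_random(20, 30, seed = 7)
  model <- plsda(Z, group_dummy(grp), n_comp = 3)
  G <- crossprod(model$scores)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[1] * diag(G)[2])
  expect_true(all(offdiag < 1e-8))
  expect_true(all(model$r2x >= 0))
  expect_lte(sum(model$r2x), 1 + 1e-10)
  expect_true(all(model$r2y >= 0 & model$r2y <= 1))
})

test_that("oplsda separates planted groups and reduces to plsda at n_osc 0", {
  cfg <- synth_config(n_features = 200,
                      n_per_group = c(control = 0, slow = 25, rapid = 25),
                      n_replicates = 1, n_effect_features = 15,
                      effect_size = 1.5, n_modules = 0, missing_rate = 0,
                      seed = 8)
  sim <- simulate_cohort(cfg)
  model <- oplsda(sim$table, sim$meta, c("slow", "rapid"))
  t1 <- model$scores[, 1]
  grp <- model$group
  smd <- abs(mean(t1[grp == "rapid"]) - mean(t1[grp == "slow"])) / sd(t1)
  expect_gt(smd, 1.5)
  # midpoint threshold on t1 misclassifies few samples
  mid <- (mean(t1[grp == "rapid"]) + mean(t1[grp == "slow"])) / 2
  pred <- ifelse(t1 > mid, "rapid", "slow")
  if (mean(pred == grp) < 0.5) pred <- ifelse(t1 > mid, "slow", "rapid")
  expect_lte(mean(pred != grp), 0.10)

  m0 <- oplsda(sim$table, sim$meta, c("slow", "rapid"), n_osc = 0)
  Z <- autoscale(sample_matrix(sim$table))
  ref <- plsda(Z, group_dummy(grp), n_comp = 2)
  expect_equal(m0$scores, ref$scores, tolerance = 1e-10)
  expect_null(m0$osc)
})

test_that("PCLS correlation gate and ranking behave on known structure", {
  set.seed(9)
  n <- 100
  grp <- rep(c("slow", "rapid"), each = n / 2)
  cls <- ifelse(grp == "rapid", 1, -1)
  X <- cbind(sapply(1:5, function(j) cls + rnorm(n, sd = 0.3)),
             matrix(rnorm(n * 95), n, 95))
  colnames(X) <- sprintf("F%03d", 1:100)
  tab <- feature_table(t(10^X), mz = 1:100, rt = 1:100,
                       sample_id = rownames(X) <- sprintf("S%03d", 1:n),
                       replicate = rep(1, n), feature_id = colnames(X),
                       group = grp)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:n), group = grp)
  model <- oplsda(tab, meta, c("slow", "rapid"), n_osc = 0)

  # a feature equal to t1 itself is always a candidate
  Z <- model$Z
  Zx <- cbind(Z, t1copy = model$scores[, 1])
  res <- pcls_select(model, Z = Zx, corr_threshold = 0.95)
  expect_true(res$candidate[ncol(Zx)])
  expect_equal(res$combined_R[ncol(Zx)], 1, tolerance = 1e-10)

  # pure-noise features stay far below the 0.95 gate
  res2 <- pcls_select(model, corr_threshold = 0.95, top_fraction = 0.05)
  expect_true(all(res2$combined_R[6:100] < 0.95))

  # strong class features are found with an attainable gate
  res3 <- pcls_select(model, corr_threshold = 0.5, top_fraction = 0.05)
  expect_setequal(res3$feature_id[res3$selected], sprintf("F%03d", 1:5))
  expect_true(all(res3$selected <= res3$candidate))
})

test_that("PCLS precision on an effect-only synthetic cohort", {
  hits <- 0
  total <- 0
  for (s in 1:5) {
    cfg <- synth_config(n_features = 300,
                        n_per_group = c(control = 0, slow = 40, rapid = 40),
                        n_replicates = 1, n_effect_features = 10,
                        effect_size = 1.5, n_modules = 0, missing_rate = 0,
                        seed = 700 + s)
    sim <- simulate_cohort(cfg)
    model <- oplsda(sim$table, sim$meta, c("slow", "rapid"))
    res <- pcls_select(model, corr_threshold = 0.5, top_fraction = 0.05)
    sel <- res$feature_id[res$selected]
    hits <- hits + sum(sel %in% sim$truth$effect_feature_ids)
    total <- total + length(sel)
  }
  expect_gte(hits / total, 0.8)
})

test_that("selection intersection reports exact Venn partitions", {
  v <- intersect_selections(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(v$both, c("b", "c"))
  expect_equal(v$counts, c(a_only = 1, both = 2, b_only = 1))
  expect_length(intersect_selections(c("a"), c("b"))$both, 0)
  same <- intersect_selections(c("a", "b"), c("a", "b"))
  expect_setequal(same$both, c("a", "b"))
})
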