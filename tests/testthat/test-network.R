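two_block_matrix <- function(n = 60, block = 25, noise = 10, r = 0.95,
                             seed = 1) {
  set.seed(seed)
  make_block <- function(k) {
    f <- rnorm(n)
    sapply(seq_len(block), function(j) sqrt(r) * f + sqrt(1 - r) * rnorm(n))
  }
  X <- cbind(make_block(1), make_block(2),
             matrix(rnorm(n * noise), n, noise))
  colnames(X) <- sprintf("F%03d", seq_len(ncol(X)))
  rownames(X) <- sprintf("S%03d", seq_len(n))
  X
}

test_that("target correlation neighborhood partitions by sign", {
  n <- 30
  set.seed(1)
  base <- rnorm(n, 5, 0.5)
  X <- cbind(t = base,
             same = base,
             anti = 10 - base,
             noise = rnorm(n, 5, 0.5))
  tab <- feature_table(t(10^X), mz = 1:4, rt = 1:4,
                       sample_id = sprintf("S%02d", 1:n),
                       replicate = rep(1, n),
                       feature_id = colnames(X))
  res <- target_correlates(tab, "t", r_threshold = 0.3)
  expect_equal(unname(res$r["same"]), 1, tolerance = 1e-12)
  expect_equal(unname(res$r["anti"]), -1, tolerance = 1e-12)
  expect_true("same" %in% res$positive)
  expect_true("anti" %in% res$negative)

  const <- feature_table(matrix(1, 2, 3), mz = 1:2, rt = 1:2,
                         sample_id = c("a", "b", "c"), replicate = c(1, 1, 1))
  expect_error(target_correlates(const, "F00001"), "constant")
})

test_that("pearson r matches the hand-computed three-point example", {
  x <- c(1, 2, 4)
  y <- c(1, 3, 3)
  n <- 3
  tab <- feature_table(t(10^cbind(t = x, other = y)), mz = 1:2, rt = 1:2,
                       sample_id = c("a", "b", "c"), replicate = rep(1, 3),
                       feature_id = c("t", "other"))
  res <- target_correlates(tab, "t")
  expect_equal(unname(res$r["other"]), 24 / sqrt(42 * 24), tolerance = 1e-12)
  expect_equal(unname(res$r["other"]), 0.756, tolerance = 1e-3)
})

test_that("adjacency applies the soft-threshold power", {
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  colnames(X) <- letters[1:4]
  A1 <- adjacency(X, beta = 1)
  expect_equal(A1[1, 2], abs(cor(X[, 1], X[, 2])), tolerance = 1e-12)
  expect_equal(diag(A1), rep(0, 4), ignore_attr = TRUE)
  A6 <- adjacency(X, beta = 6)
  expect_equal(A6[1, 2], abs(cor(X[, 1], X[, 2]))^6, tolerance = 1e-12)
  expect_equal(0.5^6, 0.015625)
  # signed mode maps r = -1 to 0
  Xs <- cbind(u = X[, 1], v = -X[, 1])
  expect_equal(adjacency(Xs, beta = 2, mode = "signed")[1, 2], 0,
               tolerance = 1e-12)
  expect_error(adjacency(cbind(X, k = rep(1, 20))), "constant")
  expect_error(adjacency(X, beta = 0.5), "beta")
})

test_that("TOM matches hand values and the triple-loop oracle", {
  ones <- matrix(1, 3, 3) - diag(3)
  tom <- topological_overlap(ones)
  expect_equal(tom[1, 2], 1)
  empty <- matrix(0, 4, 4)
  expect_equal(topological_overlap(empty) - diag(4), matrix(0, 4, 4))
  expect_error(topological_overlap(diag(3)), "zero diagonal")

  set.seed(3)
  for (trial in 1:5) {
    A <- matrix(runif(400), 20, 20)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    expect_equal(topological_overlap(A), tom_oracle(A), tolerance = 1e-12)
  }
})

test_that("module detection recovers separable blocks and ignores noise", {
  # two pure blocks, zero between-block correlation: exact recovery
  Xp <- two_block_matrix(seed = 4, r = 0.995, noise = 0)
  part_pure <- detect_modules(topological_overlap(adjacency(Xp)),
                              min_size = 10, cut_height = 0.99)
  expect_equal(part_pure$n_modules, 2)
  expect_equal(unname(ari(part_pure$labels, rep(c(1, 2), each = 25))), 1)

  # with background noise features the blocks still dominate
  X <- two_block_matrix(seed = 4, r = 0.995)
  net <- topological_overlap(adjacency(X))
  part <- detect_modules(net, min_size = 10, cut_height = 0.99)
  expect_equal(part$n_modules, 2)
  truth <- rep(c(1, 2, 0), c(25, 25, 10))
  expect_gte(unname(ari(part$labels, truth)), 0.9)

  # labels ordered by decreasing size
  X2 <- two_block_matrix(n = 60, block = 25, seed = 5,
                         r = 0.995)[, -(1:10)]
  part2 <- detect_modules(topological_overlap(adjacency(X2)), min_size = 5)
  sizes <- table(part2$labels[part2$labels > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))

  # pure noise yields no (or only unassigned) modules
  set.seed(6)
  noise <- matrix(rnorm(50 * 40), 50, 40)
  colnames(noise) <- sprintf("N%02d", 1:40)
  part3 <- suppressWarnings(
    detect_modules(topological_overlap(adjacency(noise)), min_size = 10))
  expect_equal(part3$n_modules, 0)

  # permutation invariance up to label renaming
  perm <- sample(ncol(X))
  part_p <- detect_modules(topological_overlap(adjacency(X[, perm])),
                           min_size = 10, cut_height = 0.99)
  expect_equal(unname(ari(part_p$labels[colnames(X)],
                          part$labels[colnames(X)])), 1)
})

test_that("module eigengene matches the SVD oracle and orientation rule", {
  set.seed(7)
  X <- matrix(rnorm(60), 10, 6)
  e <- module_eigengene(X)
  s <- svd(scale(X))
  expect_lt(min(sum((as.numeric(e) - s$u[, 1])^2),
                sum((as.numeric(e) + s$u[, 1])^2)), 1e-16)
  expect_equal(attr(e, "var_explained"), s$d[1]^2 / sum(s$d^2),
               tolerance = 1e-12)
  # the orientation rule is anchored to the members: flipping every member
  # flips the eigengene with them, preserving all member correlations
  e_flip <- module_eigengene(-X)
  expect_equal(as.numeric(e_flip), -as.numeric(e), tolerance = 1e-10)
  expect_equal(cor(as.numeric(e_flip), -X), cor(as.numeric(e), X),
               tolerance = 1e-10)
  # identical members: variance explained is 1
  same <- matrix(rnorm(10), 10, 3)
  e_same <- module_eigengene(same + matrix(rnorm(30, sd = 1e-8), 10, 3))
  expect_gt(attr(e_same, "var_explained"), 0.999)
  expect_error(module_eigengene(X[, 1, drop = FALSE]), "2 members")
  expect_error(module_eigengene(cbind(rep(1, 5), rnorm(5))), "degenerate")
})

test_that("eigengene network maps correlation to [0, 1] adjacency", {
  set.seed(8)
  e1 <- rnorm(20)
  e2 <- rnorm(20)
  E <- cbind(a = e1, b = e1, c = -e1, d = e2)
  net <- eigengene_network(E)
  A <- net$adjacency
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], 0)
  expect_lt(abs(A["a", "d"] - 0.5), 0.35)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(diag(A), rep(1, 4), ignore_attr = TRUE)
})

test_that("module preservation is exact on identical data and detects loss", {
  X <- two_block_matrix(n = 50, seed = 9)
  part <- detect_modules(topological_overlap(adjacency(X)), min_size = 10)
  pres_self <- module_preservation(X, X, part)
  expect_equal(pres_self$P, matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(pres_self$preservation), c(1, 1))
  expect_true(isSymmetric(pres_self$P))

  # missing members in the test set are an error naming features
  expect_error(module_preservation(X, X[, -1], part), "F001")
})

test_that("destroyed structure scores below intact preservation", {
  cfg <- synth_config(n_features = 150,
                      n_per_group = c(control = 0, slow = 41, rapid = 39),
                      n_replicates = 1, n_effect_features = 0,
                      n_modules = 4, module_size = 25,
                      between_module_r = 0.6, missing_rate = 0, seed = 10)
  sim <- simulate_cohort(cfg)
  X <- sample_matrix(sim$table)
  grp <- sim$meta$group[match(rownames(X), sim$meta$sample_id)]
  Xs <- X[grp == "slow", ]
  Xr <- X[grp == "rapid", ]
  truth <- sim$truth$module_labels[colnames(X)]
  intact <- module_preservation(Xs, Xr, truth)
  set.seed(11)
  Xd <- apply(Xr, 2, sample)
  rownames(Xd) <- rownames(Xr)
  destroyed <- module_preservation(Xs, Xd, truth)
  expect_gt(mean(intact$preservation), 0.9)
  expect_gt(mean(intact$preservation) - mean(destroyed$preservation), 0.1)
  expect_true(all(intact$P >= 0 & intact$P <= 1))
})
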