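test_that("objective matches direct summation", {
  pr <- random_problem(1, n = 20, p = 10, G = 3)
  # w = 0: N log 2 plus no penalty
  expect_equal(sgl_objective(rep(0, 10), pr$M, pr$A, 1, 1), 20 * log(2))
  # lambda = 0: plain logistic loss equals the independent summation
  set.seed(2)
  w <- rnorm(10)
  expect_equal(sgl_objective(w, pr$M, pr$A, 0, 0),
               oracle_logloss(pr$X, pr$y, w))
  # single-group penalty: l_g * ||w_g||_2
  pr1 <- random_problem(2, n = 10, p = 2, G = 1)
  yfit <- c(3, 4)
  expect_equal(
    sgl_objective(yfit, pr1$M, pr1$A, 1, 0) -
      sgl_objective(yfit, pr1$M, pr1$A, 0, 0),
    2 * 5)
  expect_error(sgl_objective(c(w[-1], NaN), pr$M, pr$A, 1, 1),
               "non-finite")
})

test_that("prox fixes the origin and zeroes below-threshold groups", {
  pr <- random_problem(3, p = 12, G = 3)
  expect_equal(prox_sgl(rep(0, 12), pr$A, 1, 1), rep(0, 12))
  # a group whose soft-thresholded norm is below t*lambda1*l_g vanishes
  v <- c(rep(0.1, 4), rep(5, 8))
  out <- prox_sgl(v, pr$A, t_lambda1 = 0.2, t_lambda2 = 0.05)
  expect_equal(out[1:4], rep(0, 4))   # ||(0.05,..)|| = 0.1 < 0.2*4
  expect_true(all(out[5:12] > 0))
})

test_that("prox matches the numeric argmin of its defining problem", {
  # 25 random (v, t, lambda1, lambda2) cases against scipy SLSQP on the
  # exact reformulation min 0.5||w-v||^2 + t*penalty
  set.seed(91)
  problems <- list()
  keys <- list()
  for (case in 1:25) {
    p <- sample(4:10, 1)
    G <- sample(1:3, 1)
    grp <- sort(rep_len(seq_len(G), p))
    v <- rnorm(p, sd = 2)
    step <- runif(1, 0.1, 2)
    l1 <- runif(1, 0, 0.8)
    l2 <- runif(1, 0, 0.8)
    sizes <- tabulate(grp, G)
    problems[[case]] <- list(mode = "prox", v = v, step = step,
                             groups = grp, lambda1 = l1, lambda2 = l2,
                             q = sizes)
    keys[[case]] <- list(v = v, step = step, grp = grp, l1 = l1, l2 = l2)
  }
  sols <- slsqp_oracle(problems)
  for (case in seq_along(problems)) {
    ky <- keys[[case]]
    A <- peakgl:::.as_group_assignment(ky$grp)
    mine <- prox_sgl(ky$v, A, ky$step * ky$l1, ky$step * ky$l2)
    expect_equal(mine, unlist(sols[[case]]$w), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("large penalties give the exact all-zero solution", {
  pr <- random_problem(5)
  lmax <- sgl_lambda_max(pr$M, pr$A)
  fit <- sgl_fit(pr$M, pr$A, 1.01 * lmax$lambda1_max,
                 1.01 * lmax$lambda2_max)
  expect_identical(unname(fit$w), rep(0, 30))
  expect_equal(utils::tail(fit$objective_trace, 1), 60 * log(2))
})

test_that("unregularized fit matches IRLS logistic regression", {
  pr <- random_problem(6, n = 80, p = 6, G = 2)
  fit <- sgl_fit(pr$M, pr$A, 0, 0, tol = 1e-10, max_iter = 20000)
  glm_fit <- stats::glm.fit(pr$X, (pr$y + 1) / 2,
                            family = stats::binomial(),
                            intercept = FALSE)
  obj_mine <- sgl_objective(unname(fit$w), pr$M, pr$A, 0, 0)
  obj_glm <- sgl_objective(unname(glm_fit$coefficients), pr$M, pr$A, 0, 0)
  expect_equal(obj_mine, obj_glm, tolerance = 1e-5)
})

test_that("objective trace decreases and zero groups are exact", {
  pr <- random_problem(7)
  fit <- sgl_fit(pr$M, pr$A, 0.1, 0.1)
  expect_true(fit$converged)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  gn <- sqrt(rowsum(fit$w^2, pr$A$group_of)[, 1])
  # every group entirely zero or with a nonzero member (no epsilons)
  for (g in seq_len(pr$A$G)) {
    wg <- fit$w[pr$A$group_of == g]
    expect_true(all(wg == 0) || any(wg != 0))
    if (gn[g] == 0) expect_identical(unname(wg), rep(0, length(wg)))
  }
})

test_that("solution is invariant to feature permutation", {
  pr <- random_problem(8, n = 40, p = 12, G = 4)
  fit <- sgl_fit(pr$M, pr$A, 0.2, 0.2)
  set.seed(1)
  perm <- sample(12)
  Mp <- pr$M
  Mp$counts <- pr$M$counts[, perm]
  Mp$space$patterns <- pr$M$space$patterns[perm]
  Ap <- peakgl:::.as_group_assignment(
    stats::setNames(pr$A$group_of[perm], Mp$space$patterns))
  fitp <- sgl_fit(Mp, Ap, 0.2, 0.2)
  expect_equal(unname(fitp$w), unname(fit$w[perm]), tolerance = 1e-6)
})

test_that("cross-validation selects a signal-recovering penalty", {
  sp <- kmer_feature_space(6, 1)
  sim <- simulate_two_motif_set(seed = 5, n_pos = 80, n_neg = 80,
                                width = 60, motif_a = "TGACTG",
                                motif_b = "CACGTG")
  M <- select_features(count_features(sim$seqs, sp), 150)
  A <- cluster_features(M, 5)
  lmax <- sgl_lambda_max(M, A)
  cv <- sgl_cv(M, A,
               lambda1_grid = lmax$lambda1_max * c(0.01, 0.1, 1),
               lambda2_grid = lmax$lambda2_max * c(0.01, 1),
               folds = 4, seed = 9)
  expect_equal(nrow(cv$cv_table), 6)
  expect_true(all(is.finite(cv$cv_table$mean_auroc)))
  expect_true(any(cv$fit$w != 0))

  # single grid point returns trivially
  cv1 <- sgl_cv(M, A, lambda1_grid = 0.01 * lmax$lambda1_max,
                lambda2_grid = 0.01 * lmax$lambda2_max, folds = 4,
                seed = 2)
  expect_equal(nrow(cv1$cv_table), 1)

  # too many folds for the class sizes errors with advice
  expect_error(sgl_cv(M, A, 0.1, 0.1, folds = 500, seed = 1), "folds")
})

test_that("held-out auROC on pure noise stays near chance", {
  # no feature pre-selection here: selecting discriminative features on
  # the pooled data before cross-validating would leak the fold labels
  sp <- kmer_feature_space(5, 0)
  hits <- 0
  for (seed in 1:6) {
    sim <- simulate_peak_sequences(60, 60, 50, plants = list(),
                                   seed = seed)
    M <- count_features(sim$seqs, sp)
    A <- suppressWarnings(cluster_features(M, 5))
    lmax <- sgl_lambda_max(M, A)
    cv <- sgl_cv(M, A, lambda1_grid = lmax$lambda1_max * c(0.05, 1),
                 lambda2_grid = lmax$lambda2_max * c(0.05, 1),
                 folds = 3, seed = seed)
    best <- max(cv$cv_table$mean_auroc)
    if (best >= 0.35 && best <= 0.65) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("KKT conditions hold at the solution", {
  for (seed in c(21, 22)) {
    pr <- random_problem(seed)
    fit <- sgl_fit(pr$M, pr$A, 0.1, 0.1, tol = 1e-12, max_iter = 50000)
    expect_lt(peakgl:::sgl_kkt_residual(fit, pr$M), 1e-4)
  }
})
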