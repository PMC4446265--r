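# Sparse group lasso logistic regression, fit by accelerated proximal
# gradient (FISTA with adaptive restart and backtracking line search).

# numerically stable log(1 + exp(-m))
.log1pexp_neg <- function(m) {
  out <- numeric(length(m))
  pos <- m > 0
  out[pos] <- log1p(exp(-m[pos]))
  out[!pos] <- -m[!pos] + log1p(exp(m[!pos]))
  out
}

# logistic loss and gradient for margins m = y * (X w)
.logistic_loss <- function(X, y, w) sum(.log1pexp_neg(y * as.numeric(X %*% w)))

.logistic_grad <- function(X, y, w) {
  m <- y * as.numeric(X %*% w)
  # d/dw sum log(1+exp(-m)) = -X' (y * sigma(-m))
  s <- 1 / (1 + exp(m))
  -as.numeric(Matrix::crossprod(X, y * s))
}

# penalty: lambda1 * sum_g mult_g * l_g^expo * ||w_g|| + lambda2 * sum |w| * l1w
.sgl_penalty <- function(w, group_of, lambda1, lambda2, l_pow,
                         group_mult = NULL, l1_mult = NULL) {
  gn <- sqrt(rowsum(w^2, group_of)[, 1])
  gm <- if (is.null(group_mult)) 1 else group_mult
  lw <- if (is.null(l1_mult)) 1 else l1_mult
  lambda1 * sum(gm * l_pow * gn) + lambda2 * sum(lw * abs(w))
}

#' Sparse group lasso logistic objective
#'
#' `sum_i log(1 + exp(-y_i w.x_i)) + lambda1 sum_g l_g ||w_g||_2 +
#' lambda2 sum_m |w_m|`: logistic loss over all examples plus a group
#' lasso penalty weighted by the group sizes `l_g` and an elementwise
#' lasso penalty.  The group-size weight exponent is configurable
#' (`group_weight_exponent = 0.5` gives the conventional `sqrt(l_g)`
#' weighting; the default 1 uses `l_g` itself).
#'
#' @param w weight vector, one entry per feature.
#' @param M a `feature_matrix`.
#' @param A a `group_assignment` over the same features.
#' @param lambda1 group-level regularization weight.
#' @param lambda2 feature-level (lasso) regularization weight.
#' @param group_weight_exponent exponent applied to `l_g` (default 1).
#' @return The scalar objective value.
#' @export
sgl_objective <- function(w, M, A, lambda1, lambda2,
                          group_weight_exponent = 1) {
  stopifnot(length(w) == ncol(M$counts),
            length(A$group_of) == length(w))
  if (any(!is.finite(w))) stop("non-finite weights")
  gn <- sqrt(rowsum(w^2, A$group_of)[, 1])
  .logistic_loss(M$counts, M$labels, w) +
    lambda1 * sum(A$sizes^group_weight_exponent * gn) +
    lambda2 * sum(abs(w))
}

#' Proximal operator of the sparse group lasso penalty
#'
#' Evaluates `argmin_w 0.5 ||w - v||^2 + t_lambda2 ||w||_1 +
#' t_lambda1 sum_g l_g ||w_g||_2` in closed form: elementwise soft
#' thresholding at `t_lambda2`, then groupwise shrinkage
#' `w_g = max(0, 1 - t_lambda1 l_g / ||u_g||) u_g`.  Groups whose
#' soft-thresholded norm falls below the group threshold are exactly
#' zero, which is what makes whole-group selection possible.
#'
#' @param v input vector (typically a gradient step).
#' @param A a `group_assignment`.
#' @param t_lambda1 step size times group penalty weight.
#' @param t_lambda2 step size times lasso penalty weight.
#' @param group_weight_exponent exponent on `l_g` (default 1).
#' @param group_mult,l1_mult optional per-group / per-coordinate penalty
#'   multipliers (used by the multitask model).
#' @return The proximal point, same length as `v`.
#' @export
prox_sgl <- function(v, A, t_lambda1, t_lambda2,
                     group_weight_exponent = 1,
                     group_mult = NULL, l1_mult = NULL) {
  stopifnot(length(v) == length(A$group_of))
  lw <- if (is.null(l1_mult)) rep(1, length(v)) else l1_mult
  u <- sign(v) * pmax(abs(v) - t_lambda2 * lw, 0)
  gn <- unname(sqrt(rowsum(u^2, A$group_of)[, 1]))
  gm <- if (is.null(group_mult)) rep(1, A$G) else group_mult
  thresh <- t_lambda1 * gm * A$sizes^group_weight_exponent
  scale <- ifelse(gn > 0, pmax(0, 1 - thresh / gn), 0)
  u * scale[A$group_of]
}

# spectral-norm-based Lipschitz estimate for the logistic loss:
# L = ||X||_2^2 / 4, via power iteration on X'X
.lipschitz <- function(X, iters = 30) {
  p <- ncol(X)
  v <- rep(1 / sqrt(p), p)
  for (i in seq_len(iters)) {
    u <- as.numeric(crossprod(X, X %*% v))
    nv <- sqrt(sum(u^2))
    if (nv == 0) return(1)
    v <- u / nv
  }
  nv / 4
}

#' Data-derived upper bounds for the regularization path
#'
#' Computes, from the gradient of the logistic loss at `w = 0`, the
#' smallest penalty weights that keep every weight at zero: `lambda2_max`
#' when used alone, and `lambda1_max` (per the `l_g` group weighting)
#' when used alone.  Any pair at or above both bounds yields the exact
#' all-zero solution.
#'
#' @inheritParams sgl_objective
#' @return list with `lambda1_max` and `lambda2_max`.
#' @export
sgl_lambda_max <- function(M, A, group_weight_exponent = 1) {
  g0 <- abs(.logistic_grad(M$counts, M$labels, rep(0, ncol(M$counts))))
  gn <- sqrt(rowsum(g0^2, A$group_of)[, 1])
  list(lambda1_max = max(gn / A$sizes^group_weight_exponent),
       lambda2_max = max(g0))
}

#' Fit the sparse group lasso logistic regression
#'
#' Accelerated proximal gradient descent (FISTA) from a cold start at
#' `w = 0`, with backtracking line search from a spectral step-size
#' estimate and adaptive restart whenever the objective increases, run
#' until the relative objective change drops below `tol` or `max_iter`
#' iterations.  The returned solution has exactly-zero groups (no
#' epsilon thresholding is needed downstream) and a non-increasing
#' objective trace after the final restart.
#'
#' @inheritParams sgl_objective
#' @param tol relative objective-change tolerance (default 1e-7).
#' @param max_iter iteration cap (default 5000).
#' @return An object of class `sgl_fit`: list with `w` (named by
#'   pattern), `lambda1`, `lambda2`, `objective_trace`, `converged`,
#'   `iterations`, the `assignment` and `group_weight_exponent`.
#' @export
sgl_fit <- function(M, A, lambda1, lambda2, tol = 1e-7, max_iter = 5000,
                    group_weight_exponent = 1) {
  stopifnot(inherits(M, "feature_matrix") || is.list(M))
  y <- M$labels
  if (!any(y > 0) || !any(y < 0)) stop("both classes must be present")
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative")
  X <- as.matrix(M$counts)

  res <- .fista(
    grad = function(w) .logistic_grad(X, y, w),
    loss = function(w) .logistic_loss(X, y, w),
    prox = function(v, t) prox_sgl(v, A, t * lambda1, t * lambda2,
                                   group_weight_exponent),
    penalty = function(w) .sgl_penalty(w, A$group_of, lambda1, lambda2,
                                       A$sizes^group_weight_exponent),
    p = ncol(X), L0 = .lipschitz(X), tol = tol, max_iter = max_iter)

  structure(
    list(w = stats::setNames(res$w, M$space$patterns),
         lambda1 = lambda1, lambda2 = lambda2,
         objective_trace = res$trace, converged = res$converged,
         iterations = res$iterations, assignment = A,
         group_weight_exponent = group_weight_exponent),
    class = "sgl_fit")
}

# generic FISTA engine shared by single-task and multitask fits
.fista <- function(grad, loss, prox, penalty, p, L0, tol, max_iter) {
  w <- rep(0, p)
  z <- w
  t_mom <- 1
  step <- 1 / max(L0, .Machine$double.eps)
  f_w <- loss(w)
  obj <- f_w + penalty(w)
  trace <- obj

  for (it in seq_len(max_iter)) {
    g <- grad(z)
    f_z <- loss(z)
    # backtracking: shrink step until majorization holds at the prox point
    repeat {
      w_new <- prox(z - step * g, step)
      dz <- w_new - z
      f_new <- loss(w_new)
      if (f_new <= f_z + sum(g * dz) + sum(dz^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-18) break
    }
    obj_new <- f_new + penalty(w_new)

    if (obj_new > obj) {
      # adaptive restart: drop momentum, retry plain proximal step from w
      z <- w
      t_mom <- 1
      g <- grad(z)
      f_z <- loss(z)
      repeat {
        w_new <- prox(z - step * g, step)
        dz <- w_new - z
        f_new <- loss(w_new)
        if (f_new <= f_z + sum(g * dz) + sum(dz^2) / (2 * step) + 1e-12) break
        step <- step / 2
        if (step < 1e-18) break
      }
      obj_new <- f_new + penalty(w_new)
    }

    t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    z <- w_new + ((t_mom - 1) / t_next) * (w_new - w)
    w_prev_obj <- obj
    w <- w_new
    obj <- obj_new
    t_mom <- t_next
    trace <- c(trace, obj)

    if (abs(w_prev_obj - obj) <= tol * max(1, abs(w_prev_obj))) {
      return(list(w = w, trace = trace, converged = TRUE, iterations = it))
    }
  }
  list(w = w, trace = trace, converged = FALSE, iterations = max_iter)
}

#' @export
print.sgl_fit <- function(x, ...) {
  nz_groups <- unique(x$assignment$group_of[x$w != 0])
  cat("sparse group lasso fit: lambda1 =", x$lambda1,
      ", lambda2 =", x$lambda2, "\n")
  cat("  ", sum(x$w != 0), "/", length(x$w), " nonzero weights in ",
      length(nz_groups), "/", x$assignment$G, " groups; ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Decision values of a fitted model
#'
#' @param object an `sgl_fit`.
#' @param M a `feature_matrix` over the same feature space.
#' @param ... unused.
#' @return Numeric vector `X w`, one decision value per example.
#' @export
predict.sgl_fit <- function(object, M, ...) {
  stats::setNames(as.numeric(M$counts %*% object$w), M$ids)
}

# KKT residual of an sgl_fit: max violation of subgradient optimality.
# On nonzero coordinates the full stationarity equation must hold; on
# zero coordinates/groups the gradient must lie inside the subdifferential.
sgl_kkt_residual <- function(fit, M) {
  w <- fit$w
  A <- fit$assignment
  g <- .logistic_grad(as.matrix(M$counts), M$labels, w)
  l_pow <- A$sizes^fit$group_weight_exponent
  gn <- sqrt(rowsum(w^2, A$group_of)[, 1])
  res <- 0
  for (gg in seq_len(A$G)) {
    idx <- which(A$group_of == gg)
    if (gn[gg] > 0) {
      grp_dir <- fit$lambda1 * l_pow[gg] * w[idx] / gn[gg]
      r <- g[idx] + grp_dir
      nzc <- w[idx] != 0
      res <- max(res, if (any(nzc))
        max(abs(r[nzc] + fit$lambda2 * sign(w[idx][nzc]))) else 0)
      if (any(!nzc)) {
        res <- max(res, max(pmax(abs(r[!nzc]) - fit$lambda2, 0)))
      }
    }
  }
  res
}

#' Cross-validate the regularization weights
#'
#' Stratified k-fold cross-validation over a grid of `(lambda1, lambda2)`
#' pairs.  The selection criterion is the mean held-out auROC of the
#' decision values `X w`; ties are broken toward the larger (more
#' regularized) pair.
#'
#' @inheritParams sgl_fit
#' @param lambda1_grid,lambda2_grid candidate penalty weights.  When
#'   `NULL`, an 8-point log-spaced grid from the data-derived maximum
#'   down three decades is used for each.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment (the only source of
#'   randomness in training).
#' @return list with `lambda1`, `lambda2`, `cv_table` (one row per grid
#'   point with the mean held-out auROC) and `fit`, the model refit on
#'   all examples at the chosen pair.
#' @export
sgl_cv <- function(M, A, lambda1_grid = NULL, lambda2_grid = NULL,
                   folds = 10, seed = 1, tol = 1e-6, max_iter = 2000,
                   group_weight_exponent = 1) {
  if (folds < 2) stop("folds must be >= 2")
  if (is.null(lambda1_grid) || is.null(lambda2_grid)) {
    lmax <- sgl_lambda_max(M, A, group_weight_exponent)
    if (is.null(lambda1_grid)) {
      lambda1_grid <- 10^seq(log10(lmax$lambda1_max), log10(lmax$lambda1_max) - 3,
                             length.out = 8)
    }
    if (is.null(lambda2_grid)) {
      lambda2_grid <- 10^seq(log10(lmax$lambda2_max), log10(lmax$lambda2_max) - 3,
                             length.out = 8)
    }
  }
  y <- M$labels
  fold_of <- integer(length(y))
  rng <- .with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(y == cls)
      if (length(idx) < folds) {
        stop("a fold would miss a class; use fewer folds")
      }
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold_of
  })
  fold_of <- rng

  grid <- expand.grid(lambda1 = sort(lambda1_grid),
                      lambda2 = sort(lambda2_grid))
  X <- as.matrix(M$counts)
  auc <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (!any(y[tr] > 0) || !any(y[tr] < 0) ||
        !any(y[!tr] > 0) || !any(y[!tr] < 0)) {
      stop("a fold is missing a class; use fewer folds")
    }
    Mtr <- M
    Mtr$counts <- M$counts[tr, , drop = FALSE]
    Mtr$labels <- y[tr]
    Mtr$ids <- M$ids[tr]
    for (gi in seq_len(nrow(grid))) {
      fit <- sgl_fit(Mtr, A, grid$lambda1[gi], grid$lambda2[gi],
                     tol = tol, max_iter = max_iter,
                     group_weight_exponent = group_weight_exponent)
      scores <- as.numeric(X[!tr, , drop = FALSE] %*% fit$w)
      auc[gi, f] <- auroc(scores, y[!tr])
    }
  }
  grid$mean_auroc <- rowMeans(auc)
  # ties toward larger (lambda1, lambda2): grid is sorted ascending, so
  # scanning in order and keeping >= prefers the most regularized winner
  best <- 1
  for (gi in seq_len(nrow(grid))) {
    if (grid$mean_auroc[gi] >= grid$mean_auroc[best]) best <- gi
  }
  fit <- sgl_fit(M, A, grid$lambda1[best], grid$lambda2[best],
                 tol = tol, max_iter = max_iter,
                 group_weight_exponent = group_weight_exponent)
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       cv_table = grid, fit = fit)
}

# evaluate expr with a local RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit the multitask sparse group lasso model
#'
#' Joint model over two (or more) tasks: each example of task `t` is
#' scored by `(w_c + w_t) . x`, where `w_c` is a common weight vector
#' capturing signals shared by all tasks and `w_t` captures what is
#' specific to task `t`.  The objective is the summed logistic loss plus
#' sparse group lasso penalties on each block, with the task-specific
#' penalties multiplied by `alpha` and the common penalty by `beta`; the
#' ratio `alpha / beta` trades off how much signal is pushed into the
#' common block (larger `alpha` penalizes the task blocks more, so shared
#' signals concentrate in `w_c`).
#'
#' @param M a `feature_matrix` whose `tasks` field names each example's
#'   task; all tasks share the (union) feature space.
#' @param A_common `group_assignment` for the common block.
#' @param A_tasks named list of per-task `group_assignment`s, in task
#'   order.
#' @param lambda1,lambda2 penalty weights as in [sgl_fit()].
#' @param alpha task-specific penalty multiplier (default 1.5).
#' @param beta common penalty multiplier (default 1).
#' @inheritParams sgl_fit
#' @return An object of class `multitask_fit`: `w_common`, `w_task`
#'   (named list), penalties, trace and convergence metadata.
#' @export
sgl_fit_multitask <- function(M, A_common, A_tasks, lambda1, lambda2,
                              alpha = 1.5, beta = 1, tol = 1e-7,
                              max_iter = 5000, group_weight_exponent = 1) {
  task_ids <- names(A_tasks)
  if (is.null(task_ids) || length(task_ids) < 2) {
    stop("need >= 2 named per-task group assignments")
  }
  if (!all(M$tasks %in% task_ids)) stop("example task not in A_tasks")
  y <- M$labels
  for (t in task_ids) {
    yt <- y[M$tasks == t]
    if (!any(yt > 0) || !any(yt < 0)) {
      stop("task ", t, " is missing a class")
    }
  }
  X <- as.matrix(M$counts)
  p <- ncol(X)
  Tn <- length(task_ids)
  rows_of <- lapply(task_ids, function(t) which(M$tasks == t))

  # stacked coefficient vector: (w_c, w_t1, ..., w_tT)
  blk <- function(b) (b - 1) * p + seq_len(p)
  pred <- function(W) {
    eta <- as.numeric(X %*% W[blk(1)])
    for (t in seq_len(Tn)) {
      r <- rows_of[[t]]
      eta[r] <- eta[r] + as.numeric(X[r, , drop = FALSE] %*% W[blk(t + 1)])
    }
    eta
  }
  loss <- function(W) sum(.log1pexp_neg(y * pred(W)))
  grad <- function(W) {
    m <- y * pred(W)
    s <- y / (1 + exp(m))
    g <- numeric((Tn + 1) * p)
    g[blk(1)] <- -as.numeric(crossprod(X, s))
    for (t in seq_len(Tn)) {
      r <- rows_of[[t]]
      g[blk(t + 1)] <- -as.numeric(crossprod(X[r, , drop = FALSE], s[r]))
    }
    g
  }

  # stacked group structure with disjoint group ids and per-block
  # penalty multipliers
  group_of <- integer((Tn + 1) * p)
  group_of[blk(1)] <- A_common$group_of
  off <- A_common$G
  sizes <- A_common$sizes
  gmult <- rep(beta, A_common$G)
  for (t in seq_len(Tn)) {
    At <- A_tasks[[t]]
    group_of[blk(t + 1)] <- At$group_of + off
    sizes <- c(sizes, At$sizes)
    gmult <- c(gmult, rep(alpha, At$G))
    off <- off + At$G
  }
  A_stack <- structure(list(group_of = group_of, sizes = sizes, G = off),
                       class = "group_assignment")
  l1w <- c(rep(beta, p), rep(alpha, Tn * p))

  # Lipschitz bound for the stacked operator: each example row appears in
  # at most two blocks, so ||A||^2 <= 2 ||X||^2
  L0 <- 2 * .lipschitz(X)

  res <- .fista(
    grad = grad, loss = loss,
    prox = function(v, t) prox_sgl(v, A_stack, t * lambda1, t * lambda2,
                                   group_weight_exponent,
                                   group_mult = gmult, l1_mult = l1w),
    penalty = function(W) .sgl_penalty(W, A_stack$group_of, lambda1,
                                       lambda2,
                                       A_stack$sizes^group_weight_exponent,
                                       group_mult = gmult, l1_mult = l1w),
    p = (Tn + 1) * p, L0 = L0, tol = tol, max_iter = max_iter)

  W <- res$w
  w_task <- lapply(seq_len(Tn), function(t)
    stats::setNames(W[blk(t + 1)], M$space$patterns))
  names(w_task) <- task_ids
  structure(
    list(w_common = stats::setNames(W[blk(1)], M$space$patterns),
         w_task = w_task, lambda1 = lambda1, lambda2 = lambda2,
         alpha = alpha, beta = beta,
         objective_trace = res$trace, converged = res$converged,
         iterations = res$iterations,
         assignment_common = A_common, assignment_tasks = A_tasks,
         group_weight_exponent = group_weight_exponent),
    class = "multitask_fit")
}

#' @export
print.multitask_fit <- function(x, ...) {
  cat("multitask sparse group lasso fit (alpha =", x$alpha,
      ", beta =", x$beta, ")\n")
  cat("  common block:", sum(x$w_common != 0), "nonzero weights\n")
  for (t in names(x$w_task)) {
    cat("  task ", t, ": ", sum(x$w_task[[t]] != 0),
        " nonzero weights\n", sep = "")
  }
  invisible(x)
}

#' Build the multitask feature space and group assignments
#'
#' Implements the multitask featurization protocol: the most
#' discriminative features are selected within each task separately,
#' the union of the selections defines the shared feature space, the
#' common group assignment is clustered on all examples pooled, and
#' each task's assignment is clustered on that task's examples only.
#'
#' @param M a `feature_matrix` over the full feature space whose
#'   `tasks` field names each example's task.
#' @param n_top features selected per task before the union.
#' @param G number of groups for every clustering.
#' @param linkage linkage method passed to [cluster_features()].
#' @return list with `M` (reduced to the union space), `A_common`, and
#'   `A_tasks` (named list in task order).
#' @export
multitask_feature_union <- function(M, n_top = 5000, G = 20,
                                    linkage = "ward.D2") {
  task_ids <- unique(M$tasks[!is.na(M$tasks)])
  if (length(task_ids) < 2) stop("need >= 2 tasks")
  subset_rows <- function(M, keep) {
    M$counts <- M$counts[keep, , drop = FALSE]
    M$labels <- M$labels[keep]
    M$ids <- M$ids[keep]
    M$tasks <- M$tasks[keep]
    M
  }
  sel_cols <- lapply(task_ids, function(t) {
    sel <- select_features(subset_rows(M, M$tasks == t), n_top)
    match(sel$space$patterns, M$space$patterns)
  })
  keep_cols <- sort(unique(unlist(sel_cols)))
  M$counts <- M$counts[, keep_cols, drop = FALSE]
  M$space <- .subset_space(M$space, keep_cols)

  A_common <- cluster_features(M, G, linkage = linkage)
  A_tasks <- lapply(task_ids, function(t)
    cluster_features(subset_rows(M, M$tasks == t), G, linkage = linkage))
  names(A_tasks) <- task_ids
  list(M = M, A_common = A_common, A_tasks = A_tasks)
}

#' @export
#' @rdname predict.sgl_fit
predict.multitask_fit <- function(object, M, ...) {
  eta <- as.numeric(M$counts %*% object$w_common)
  for (t in names(object$w_task)) {
    r <- which(M$tasks == t)
    eta[r] <- eta[r] +
      as.numeric(M$counts[r, , drop = FALSE] %*% object$w_task[[t]])
  }
  stats::setNames(eta, M$ids)
}
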