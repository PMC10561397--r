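## Finite-N oracle for the batch theory: exact convex minimisation of the
## L2-regularised logistic loss per phase, with elastic anchoring to the
## previous phase's minimiser.

## objective / gradient / Hessian-vector product of
##   sum_mu log(1 + exp(-y f)) + gamma/2 ||W||^2 + gl/2 ||W - A||^2,
## f = X W / sqrt(N)
.batch_obj <- function(W, X, y, N, gamma, gl, A) {
  f <- drop(X %*% W) / sqrt(N)
  sum(log1p(exp(-y * f))) + gamma / 2 * sum(W^2) + gl / 2 * sum((W - A)^2)
}
.batch_grad <- function(W, X, y, N, gamma, gl, A) {
  f <- drop(X %*% W) / sqrt(N)
  p <- -y / (1 + exp(y * f))
  drop(crossprod(X, p)) / sqrt(N) + gamma * W + gl * (W - A)
}
.batch_hessvec <- function(v, W, X, y, N, gamma, gl) {
  f <- drop(X %*% W) / sqrt(N)
  s <- 1 / (1 + exp(-y * f))
  d <- s * (1 - s)
  drop(crossprod(X, d * drop(X %*% v))) / N + (gamma + gl) * v
}

## conjugate-gradient solve of H d = -g (H strictly positive definite)
.cg_solve <- function(g, W, X, y, N, gamma, gl, tol = 1e-12, maxit = 200) {
  d <- numeric(length(g))
  r <- -g
  p <- r
  rs <- sum(r^2)
  for (i in seq_len(maxit)) {
    Hp <- .batch_hessvec(p, W, X, y, N, gamma, gl)
    al <- rs / sum(p * Hp)
    d <- d + al * p
    r <- r - al * Hp
    rs2 <- sum(r^2)
    if (sqrt(rs2) < tol * max(1, sqrt(sum(g^2)))) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  d
}

#' Fit one batch phase by convex optimisation
#'
#' Minimises
#' \deqn{\sum_\mu \log(1 + e^{-y^\mu W\cdot x^\mu/\sqrt N})
#'   + \frac\gamma2 \|W\|^2
#'   + \frac{\gamma_{link}}2 \|W - W_{anchor}\|^2}
#' with an L-BFGS pass followed by Newton conjugate-gradient polishing until
#' the gradient norm drops below `tol`. The objective is strongly convex
#' whenever `gamma + gamma_link > 0`, so the minimiser is unique.
#'
#' @param slices a [sample_slice()] or list of slices (rows are pooled).
#' @param gamma ridge intensity.
#' @param gamma_link elastic anchoring intensity (0 for none).
#' @param anchor_weights anchor weight vector (required iff
#'   `gamma_link > 0`).
#' @param tol gradient infinity-norm tolerance (default 1e-10).
#' @param W0 optional starting point (defaults to the anchor, else zero).
#' @return Weight vector of the minimiser, with attributes `objective` and
#'   `grad_norm`.
#' @export
fit_phase <- function(slices, gamma, gamma_link = 0, anchor_weights = NULL,
                      tol = 1e-10, W0 = NULL) {
  if (inherits(slices, "dataset_slice")) slices <- list(slices)
  if (gamma + gamma_link <= 0) stop("gamma + gamma_link must be positive")
  if (gamma_link > 0 && is.null(anchor_weights))
    stop("anchored fit requires anchor_weights")
  X <- do.call(rbind, lapply(slices, `[[`, "X"))
  y <- unlist(lapply(slices, `[[`, "y"))
  N <- slices[[1]]$N
  A <- if (is.null(anchor_weights)) numeric(N) else anchor_weights
  W <- if (!is.null(W0)) W0 else A
  o <- stats::optim(W, .batch_obj, .batch_grad, X = X, y = y, N = N,
                    gamma = gamma, gl = gamma_link, A = A,
                    method = "L-BFGS-B",
                    control = list(maxit = 500, factr = 10))
  W <- o$par
  for (it in seq_len(50)) {
    g <- .batch_grad(W, X, y, N, gamma, gamma_link, A)
    if (max(abs(g)) < tol) break
    W <- W + .cg_solve(g, W, X, y, N, gamma, gamma_link)
  }
  g <- .batch_grad(W, X, y, N, gamma, gamma_link, A)
  if (max(abs(g)) >= tol)
    stop(sprintf("convex fit did not reach tolerance (|grad| = %.3g)",
                 max(abs(g))))
  structure(W, objective = .batch_obj(W, X, y, N, gamma, gamma_link, A),
            grad_norm = max(abs(g)))
}

#' Configuration of a finite-N batch experiment
#'
#' @param N input dimension.
#' @param seeds replicate seeds; each replicate draws a fresh teacher
#'   (seed offset) and fresh slices with per-phase seeds, so curriculum and
#'   anti-curriculum see the same underlying slices in different order.
#' @param alphas,deltas slice sizes and difficulties.
#' @param gamma ridge intensity (per phase, recycled).
#' @param gamma12 elastic coupling between consecutive phases.
#' @param tol optimiser gradient tolerance.
#' @export
batch_config <- function(N, seeds = 0:9, alphas, deltas, gamma,
                         gamma12 = 0, tol = 1e-8) {
  stopifnot(N >= 20, length(alphas) == length(deltas))
  structure(list(N = as.integer(N), seeds = as.integer(seeds),
                 alphas = alphas, deltas = deltas, gamma = gamma,
                 gamma12 = gamma12, tol = tol), class = "batch_config")
}

#' Run a batch curriculum strategy at finite N
#'
#' For each seed: draws difficulty slices, orders them per the strategy
#' (pooling them into a single fit for `"none"`), chains [fit_phase()] with
#' the previous phase's minimiser as elastic anchor, and evaluates metrics
#' analytically at the empirical order parameters of the final weights.
#'
#' @param teacher a [make_teacher()] object (`teacher$N == cfg$N`).
#' @param cfg a [batch_config()].
#' @param strategy `"curriculum"`, `"anti-curriculum"` or `"none"`.
#' @param eval_delta difficulty for the headline accuracy (default: hardest
#'   slice).
#' @return List of class `batch_result`: per-seed final [order_params()] and
#'   metrics, their seed means, and the per-seed per-phase objective values.
#' @export
run_batch_strategy <- function(teacher, cfg, strategy = c("curriculum",
                                                          "anti-curriculum",
                                                          "none"),
                               eval_delta = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(teacher, "teacher_model"), inherits(cfg, "batch_config"))
  if (teacher$N != cfg$N) stop("teacher dimension must equal cfg$N")
  if (is.null(eval_delta)) eval_delta <- max(cfg$deltas)
  ord <- switch(strategy, "curriculum" = order(cfg$deltas),
                "anti-curriculum" = order(-cfg$deltas),
                "none" = seq_along(cfg$deltas))
  gam <- rep_len(cfg$gamma, length(cfg$deltas))
  per_seed <- lapply(cfg$seeds, function(s) {
    ## per-phase data seeds depend on the slice identity, not the order,
    ## so all strategies see the same underlying slices
    slices <- lapply(seq_along(cfg$deltas), function(k)
      sample_slice(teacher, cfg$alphas[k], cfg$deltas[k],
                   seed = 131071L * s + k))
    if (strategy == "none") {
      W <- fit_phase(slices, gam[1], tol = cfg$tol)
      objs <- attr(W, "objective")
    } else {
      W <- NULL
      objs <- numeric(0)
      for (k in ord) {
        W <- fit_phase(slices[[k]], gam[k],
                       gamma_link = if (is.null(W)) 0 else cfg$gamma12,
                       anchor_weights = W, tol = cfg$tol)
        objs <- c(objs, attr(W, "objective"))
      }
    }
    op <- empirical_order_params(as.numeric(W), teacher)
    list(op = op, objective = objs,
         accuracy = suppressMessages(accuracy(op, eval_delta)),
         loss = test_loss(op, eval_delta))
  })
  accs <- vapply(per_seed, `[[`, numeric(1), "accuracy")
  ops <- vapply(per_seed, function(p) unlist(p$op), numeric(4))
  structure(list(per_seed = per_seed, strategy = strategy,
                 eval_delta = eval_delta,
                 accuracy_hard = mean(accs), accuracy_se = stats::sd(accs) /
                   sqrt(length(accs)),
                 mean_op = setNames(rowMeans(ops), rownames(ops))),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "<batch_result> %s, %d seeds; accuracy at delta = %.3g: %.5f (se %.2g)\n",
    x$strategy, length(x$per_seed), x$eval_delta, x$accuracy_hard,
    x$accuracy_se))
  invisible(x)
}
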