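## Exact high-dimensional order-parameter dynamics of online SGD.
##
## Each SGD step on a fresh sample changes (Qr, Qi, R) by O(1/N); in the
## limit N -> infinity the order parameters concentrate and evolve by the
## deterministic map obtained by averaging the one-step increment over the
## joint Gaussian law of the student and teacher fields. The four Gaussian
## integrals involved (drift of R, relevant/irrelevant drift of the norms,
## and the squared error signal driving the norm diffusion) have elementary
## closed forms, implemented in C++ and validated against Monte-Carlo
## averages of the literal SGD increment.

#' Configuration for the online theory iteration
#'
#' @param eta learning rate (> 0 for learning; `eta = 0` freezes the state).
#' @param gamma per-step weight-decay intensity (>= 0). The decay is applied
#'   per SGD step, so its cumulative effect over one unit of `alpha` is
#'   `(1 - gamma)^N_theory`; `N_theory` makes this convention explicit.
#' @param sigma0_sq initial weight variance; the self-averaging initial state
#'   is `Qr = rho * sigma0_sq`, `Qi = (1 - rho) * sigma0_sq`, `R = 0`.
#'   Default `1e-4` (small, optimised-initialisation regime); use values of
#'   order 1 for the large-initialisation regime.
#' @param N_theory step resolution: the expected map is iterated
#'   `alpha * N_theory` times (>= 100; default `1e4`).
#' @return A list of class `online_config`.
#' @export
online_config <- function(eta, gamma = 0, sigma0_sq = 1e-4, N_theory = 1e4) {
  stopifnot(eta >= 0, gamma >= 0, sigma0_sq >= 0, N_theory >= 100)
  structure(list(eta = eta, gamma = gamma, sigma0_sq = sigma0_sq,
                 N_theory = as.integer(N_theory)),
            class = "online_config")
}

#' Expected one-step update of the online order parameters
#'
#' Applies one step of the averaged SGD map at difficulty `delta`: the O(eta)
#' drift of (Qr, Qi, R), the O(eta^2) diffusion-of-norm contribution to Qr
#' and Qi (which is O(1) per unit alpha and therefore retained), and the
#' per-step `-gamma W` decay. `T` is unchanged. The per-step scale is
#' `1 / cfg$N_theory`.
#'
#' @param op an [order_params()] state.
#' @param delta difficulty of the presented sample.
#' @param cfg an [online_config()].
#' @param rho teacher sparsity (sets the fraction of coordinates receiving
#'   the relevant-block diffusion term).
#' @return The updated [order_params()] state.
#' @examples
#' op <- order_params(0.3, 0.2, 0.1, 0.5)
#' expected_update(op, delta = 1, online_config(eta = 1), rho = 0.5)
#' @export
expected_update <- function(op, delta, cfg, rho = 0.5) {
  op <- .as_op(op)
  stopifnot(inherits(cfg, "online_config"), delta >= 0)
  I <- .cpp_online_integrals(op$Qr, op$Qi, op$R, op$T, delta)
  invN <- 1 / cfg$N_theory
  d <- 1 - cfg$gamma
  order_params(
    Qr = d^2 * op$Qr + 2 * d * cfg$eta * invN * I[["Glr"]] +
      cfg$eta^2 * invN * rho * I[["G2"]],
    Qi = d^2 * op$Qi + 2 * d * cfg$eta * invN * I[["Gli"]] +
      cfg$eta^2 * invN * (1 - rho) * delta * I[["G2"]],
    R = d * op$R + cfg$eta * invN * I[["Gnu"]],
    T = op$T)
}

#' Gaussian-integral building blocks of the expected update
#'
#' Returns the four closed-form expectations over the joint Gaussian fields
#' `(lambda, nu)` that drive the map: `Gnu = E[G nu]`,
#' `Glr = E[G lambda_r]`, `Gli = E[G lambda_i]` and `G2 = E[G^2]`, where
#' `G = sigma'(lambda) (sign(nu) - sigma(lambda))` is the per-sample error
#' signal of the erf student.
#'
#' @inheritParams expected_update
#' @return Named numeric vector `(Gnu, Glr, Gli, G2)`.
#' @export
online_integrals <- function(op, delta) {
  op <- .as_op(op)
  .cpp_online_integrals(op$Qr, op$Qi, op$R, op$T, delta)
}

#' Integrate the online theory through a curriculum schedule
#'
#' Iterates [expected_update()] for `alpha * N_theory` steps, switching the
#' difficulty at slice boundaries for ordered strategies. For the shuffled
#' baseline (`strategy = "none"`) the per-step increment is, in expectation,
#' the slice-probability mixture of the per-difficulty increments
#' (a deterministic map). Records the state and per-difficulty metrics on a
#' uniform alpha grid.
#'
#' @param schedule a [make_schedule()] object (data slices or
#'   [theory_slice()] descriptors).
#' @param cfg an [online_config()].
#' @param n_record number of recorded grid points (default 200).
#' @param baseline how the shuffled strategy is iterated: `"mixture"`
#'   (deterministic slice-probability mixture of the per-difficulty
#'   increments, the default) or `"stochastic"` (per-step difficulty drawn
#'   without replacement from the pooled counts, for validating the mixture
#'   map; uses the schedule seed).
#' @return A `trajectory` object: list with `ops` (data.frame of
#'   `alpha, Qr, Qi, R, T`), `metrics` (long data.frame of
#'   `alpha, delta, loss, accuracy` for each slice difficulty plus the
#'   alpha-weighted mixture, tagged `delta = NA`), `strategy` and `cfg`.
#' @export
run_theory <- function(schedule, cfg, n_record = 200,
                       baseline = c("mixture", "stochastic")) {
  stopifnot(inherits(schedule, "curriculum_schedule"),
            inherits(cfg, "online_config"))
  baseline <- match.arg(baseline)
  rho <- schedule$rho
  total_steps <- round(schedule$alphas * cfg$N_theory)
  n_record <- min(n_record, sum(total_steps))
  if (schedule$strategy == "none" && baseline == "stochastic") {
    set.seed(schedule$seed)
    deltaseq <- sample(rep(schedule$deltas, total_steps))
    rec <- .cpp_run_theory(deltaseq, as.integer(rep(1, length(deltaseq))),
                           numeric(0), cfg$eta, cfg$gamma, cfg$sigma0_sq,
                           cfg$N_theory, rho, as.integer(n_record))
  } else if (schedule$strategy == "none") {
    rec <- .cpp_run_theory(schedule$deltas, as.integer(sum(total_steps)),
                           schedule$alphas / sum(schedule$alphas),
                           cfg$eta, cfg$gamma, cfg$sigma0_sq, cfg$N_theory,
                           rho, as.integer(n_record))
  } else {
    rec <- .cpp_run_theory(schedule$deltas, as.integer(total_steps),
                           numeric(0), cfg$eta, cfg$gamma, cfg$sigma0_sq,
                           cfg$N_theory, rho, as.integer(n_record))
  }
  .trajectory_from_rec(rec, schedule, cfg)
}

## Build the tidy trajectory object from a (alpha, Qr, Qi, R, T) record matrix
.trajectory_from_rec <- function(rec, schedule, cfg, seed = NULL) {
  ops <- as.data.frame(rec)
  colnames(ops) <- c("alpha", "Qr", "Qi", "R", "T")
  deltas <- sort(unique(schedule$deltas))
  w <- schedule$alphas[order(schedule$deltas)] / sum(schedule$alphas)
  metr <- do.call(rbind, lapply(seq_len(nrow(ops)), function(i) {
    op <- order_params(max(ops$Qr[i], 0), max(ops$Qi[i], 0), ops$R[i],
                       ops$T[i])
    per <- t(vapply(deltas, function(d)
      c(test_loss(op, d), suppressMessages(accuracy(op, d))), numeric(2)))
    mix <- c(sum(w * per[, 1]), sum(w * per[, 2]))
    data.frame(alpha = ops$alpha[i], delta = c(deltas, NA),
               loss = c(per[, 1], mix[1]), accuracy = c(per[, 2], mix[2]))
  }))
  structure(list(ops = ops, metrics = metr, strategy = schedule$strategy,
                 cfg = cfg, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  fin <- x$metrics[x$metrics$alpha == max(x$metrics$alpha), ]
  cat(sprintf("<trajectory> strategy = %s, final alpha = %.3g\n", x$strategy,
              max(x$ops$alpha)))
  print(fin, row.names = FALSE)
  invisible(x)
}

#' Accuracy of a trajectory at a given alpha and difficulty
#'
#' Convenience accessor: accuracy at the recorded grid point closest to
#' `alpha`, on test difficulty `delta` (`NA` for the mixture).
#'
#' @param traj a `trajectory` from [run_theory()] or [run_simulation()].
#' @param alpha training time (sample ratio) to query.
#' @param delta test difficulty present in the trajectory metrics.
#' @export
trajectory_accuracy <- function(traj, alpha, delta) {
  m <- traj$metrics
  sel <- if (is.na(delta)) is.na(m$delta) else !is.na(m$delta) & m$delta == delta
  m <- m[sel, ]
  m$accuracy[which.min(abs(m$alpha - alpha))]
}
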