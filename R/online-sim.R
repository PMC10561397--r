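## Finite-N stochastic simulator of the literal per-sample SGD update,
## used as the empirical oracle for the asymptotic theory.

#' One literal SGD step of the erf student
#'
#' \deqn{W' = W - \frac{\eta}{\sqrt N}\,\sigma'(W\cdot x/\sqrt N)
#'   \left(\sigma(W\cdot x/\sqrt N) - y\right) x - \gamma W,
#'   \qquad \sigma(u) = \mathrm{erf}(u/\sqrt 2).}
#'
#' @param W student weight vector.
#' @param x input vector (same length).
#' @param y label in -1/+1.
#' @param eta learning rate.
#' @param gamma per-step weight-decay intensity.
#' @param N field-normalisation dimension (defaults to `length(W)`).
#' @return Updated weight vector.
#' @export
sgd_step <- function(W, x, y, eta, gamma = 0, N = length(W)) {
  if (length(x) != length(W)) stop("dimension mismatch")
  lam <- sum(W * x) / sqrt(N)
  sig <- 2 * stats::pnorm(lam) - 1             # erf(lam / sqrt(2))
  sigp <- sqrt(2 / pi) * exp(-lam^2 / 2)
  W - (eta / sqrt(N)) * sigp * (sig - y) * x - gamma * W
}

#' Configuration of a finite-N online simulation run
#'
#' @param N input dimension (>= 100).
#' @param seeds integer vector of replicate seeds (at least one).
#' @param eta,gamma,sigma0_sq as in [online_config()]; initial weights are
#'   i.i.d. normal with variance `sigma0_sq`.
#' @param n_record number of evaluation points on the alpha grid.
#' @export
sim_config <- function(N, seeds = 0:9, eta, gamma = 0, sigma0_sq = 1e-4,
                       n_record = 200) {
  stopifnot(N >= 100, length(seeds) >= 1, eta >= 0, gamma >= 0)
  structure(list(N = as.integer(N), seeds = as.integer(seeds), eta = eta,
                 gamma = gamma, sigma0_sq = sigma0_sq,
                 n_record = as.integer(n_record)),
            class = "sim_config")
}

#' Run the finite-N online SGD simulation
#'
#' One pass through the scheduled sample stream (each sample generated on the
#' fly and used once). Order parameters are logged on a uniform alpha grid
#' and metrics are evaluated analytically at the empirical order parameters
#' (exact as N -> infinity, low-variance at finite N). For the shuffled
#' baseline each step draws its difficulty with probability proportional to
#' the remaining sample count of each slice.
#'
#' @param teacher a [make_teacher()] object with `teacher$N == cfg$N`.
#' @param schedule a [make_schedule()] object; slice sizes are
#'   `round(alpha * N)` samples each.
#' @param cfg a [sim_config()].
#' @return List of class `sim_result`: `runs` (one `trajectory` per seed) and
#'   `mean` (a `trajectory` whose order parameters and metrics are averaged
#'   across seeds).
#' @export
run_simulation <- function(teacher, schedule, cfg) {
  stopifnot(inherits(teacher, "teacher_model"), inherits(cfg, "sim_config"),
            inherits(schedule, "curriculum_schedule"))
  if (teacher$N != cfg$N) stop("teacher dimension must equal cfg$N")
  counts <- as.integer(round(schedule$alphas * cfg$N))
  n_record <- min(cfg$n_record, sum(counts))
  runs <- lapply(cfg$seeds, function(s) {
    set.seed(s)
    rec <- .cpp_run_sim(teacher$weights, teacher$n_rel, schedule$deltas,
                        counts, schedule$strategy == "none", cfg$eta,
                        cfg$gamma, cfg$sigma0_sq, as.integer(n_record))
    .trajectory_from_rec(rec, schedule, cfg, seed = s)
  })
  ## seed-mean of both the order parameters and the per-seed metrics
  ## (metrics are nonlinear in the state, so they are averaged directly)
  mean_ops <- Reduce(`+`, lapply(runs, function(r) as.matrix(r$ops))) /
    length(runs)
  mean_metr <- runs[[1]]$metrics
  mm <- Reduce(`+`, lapply(runs, function(r)
    as.matrix(r$metrics[, c("loss", "accuracy")]))) / length(runs)
  mean_metr$loss <- mm[, "loss"]
  mean_metr$accuracy <- mm[, "accuracy"]
  mean_traj <- structure(list(ops = as.data.frame(mean_ops),
                              metrics = mean_metr,
                              strategy = schedule$strategy, cfg = cfg,
                              seed = NULL),
                         class = "trajectory")
  structure(list(runs = runs, mean = mean_traj), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d seeds; seed-mean final state:\n",
              length(x$runs)))
  print(x$mean)
  invisible(x)
}
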