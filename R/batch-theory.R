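## Replica-symmetric (RS) saddle-point solver for batch learning.
##
## Each batch phase minimises an L2-regularised logistic loss on its data
## slices, optionally tied to the previous phase's minimiser by an elastic
## (Gaussian-prior) coupling of intensity gamma_link. In the high-dimensional
## limit the minimiser's macroscopic state solves a fixed point coupling two
## scalar channels:
##
##  * the energetic channel g_E(Delta): a Gaussian expectation (over the
##    teacher field nu and the orthogonal part of the student cavity field h)
##    of the Moreau envelope of the logistic loss, whose curvature is set by
##    the response parameters chi_r, chi_i (the zero-temperature limit of the
##    delta-Q variance parameters);
##  * the entropic channel g_S: the exact Gaussian integral over the
##    quadratic single-coordinate measure induced by ridge + elastic
##    anchoring + the sparse-teacher alignment field (the alignment conjugate
##    acts on the relevant block only).
##
## The convexity of each phase makes the RS ansatz exact; the beta -> inf
## limit is taken analytically. The data slices of the two phases are
## independent, so the anchor enters the second phase's entropic channel only
## through its converged order parameters.

#' Gauss-Hermite nodes and weights for a standard normal expectation
#'
#' Golub-Welsch eigen-decomposition of the Hermite Jacobi matrix, rescaled so
#' that `sum(w * f(x))` approximates `E[f(Z)]`, `Z ~ N(0,1)`.
#'
#' @param n number of nodes.
#' @return List with nodes `x` and weights `w` (weights sum to 1).
#' @export
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord] * sqrt(2), w = (e$vectors[1, ]^2)[ord])
}

#' Proximal operator of the logistic loss
#'
#' Solves `u* = argmin_u [ log(1 + exp(-y u)) + (u - h)^2 / (2 chi) ]` by a
#' safeguarded vectorised Newton iteration (the problem is scalar, smooth and
#' strongly convex).
#'
#' @param h numeric vector of field values.
#' @param y labels in -1/+1 (recycled against `h`).
#' @param chi positive curvature parameter.
#' @param tol Newton tolerance on the step (default 1e-12).
#' @return Vector of minimisers `u*`.
#' @export
prox_logistic <- function(h, y, chi, tol = 1e-12) {
  stopifnot(chi > 0)
  ## in the margin variable v = y u the optimality condition is
  ## f(v) = v - y h - chi * s(-v) = 0 with s the logistic sigmoid;
  ## f is strictly increasing with f(yh) <= 0 <= f(yh + chi), so Newton
  ## steps are safeguarded by this bracket
  b <- y * h
  lo <- b
  hi <- b + chi
  v <- b + chi / 2
  tolv <- tol * pmax(1, abs(b) + chi)   # ulp-aware per-element tolerance
  for (it in seq_len(500)) {
    s <- 1 / (1 + exp(v))
    f <- v - b - chi * s
    lo[f < 0] <- v[f < 0]
    hi[f >= 0] <- v[f >= 0]
    fp <- 1 + chi * s * (1 - s)
    step <- f / fp
    v <- v - step
    ## fall back to bisection when Newton leaves the bracket or fails to
    ## beat it (prevents two-cycles far from the root)
    out <- v <= lo | v >= hi | abs(step) > 0.5 * (hi - lo)
    v[out] <- (lo[out] + hi[out]) / 2
    done <- abs(step) < tolv | (hi - lo) < tolv
    if (all(done)) break
  }
  if (!all(done)) stop("logistic prox solve did not converge")
  y * v
}

#' Phase specification for batch learning
#'
#' @param alphas,deltas sample-size ratios and difficulties of the slices
#'   optimised jointly in this phase.
#' @param gamma ridge intensity of the phase.
#' @param gamma_link elastic-coupling intensity to the previous phase's
#'   minimiser (0 for an unanchored phase). `gamma + gamma_link` must be
#'   positive so the measure is normalisable.
#' @export
phase_spec <- function(alphas, deltas, gamma, gamma_link = 0) {
  stopifnot(length(alphas) == length(deltas), all(alphas > 0),
            all(deltas >= 0), gamma >= 0, gamma_link >= 0)
  if (gamma + gamma_link <= 0) stop("gamma + gamma_link must be positive")
  structure(list(alphas = alphas, deltas = deltas, gamma = gamma,
                 gamma_link = gamma_link), class = "phase_spec")
}

#' Solver configuration for the saddle-point iteration
#'
#' @param damping damping factor in (0, 1] for the fixed-point update.
#' @param tol convergence tolerance on the maximum absolute order-parameter
#'   change (default 1e-9).
#' @param max_iter iteration cap.
#' @param quad_nodes Gauss-Hermite nodes per dimension (default 121).
#' @param init optional initial state: named list with
#'   `Qr, Qi, R, chi_r, chi_i`.
#' @export
solver_config <- function(damping = 0.5, tol = 1e-9, max_iter = 1e4,
                          quad_nodes = 121, init = NULL) {
  stopifnot(damping > 0, damping <= 1, tol > 0, max_iter >= 1,
            quad_nodes >= 11)
  structure(list(damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 quad_nodes = as.integer(quad_nodes), init = init),
            class = "solver_config")
}

## Gauss-Legendre nodes/weights on (0, 1) (Golub-Welsch on the Legendre
## Jacobi matrix)
.gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = (e$values[ord] + 1) / 2, w = (e$vectors[1, ]^2)[ord])
}

## Quadrature grid for the energetic expectations. The sign label makes the
## integrand non-smooth at nu = 0, so the teacher field is folded onto the
## positive half-line via the (h, y) -> (-h, -y) symmetry and the resulting
## analytic integrand is integrated against the explicit Gaussian density
## with Gauss-Legendre on [0, 10] (spectral accuracy; the truncated tail
## carries < 1e-22 of the mass). The orthogonal field keeps Gauss-Hermite.
.quad_grid <- function(n, L = 10) {
  gl <- .gauss_legendre01(n)
  gh <- gauss_hermite(n)
  xi <- L * gl$x
  wxi <- 2 * L * gl$w * stats::dnorm(xi)
  list(xi = rep(xi, each = n), z = rep(gh$x, n),
       w = rep(wxi, each = n) * rep(gh$w, n))
}

#' Energetic channel of the RS free energy
#'
#' Evaluates, for one difficulty level, the zero-temperature energetic term
#' `g_E(Delta) = -E[ min_u ( l(y u) + (u - h)^2 / (2 chi) ) ]` where
#' `l` is the logistic loss, `y = sign(nu)` the teacher label,
#' `h` the student cavity field (variance `Qr + Delta*Qi`, teacher overlap
#' `R`) and `chi = chi_r + Delta*chi_i` the response. Returns the value, its
#' partial derivatives with respect to the order parameters, and the raw
#' expectations used by the fixed-point update.
#'
#' @param state named list (or `saddle_state`) with `Qr, Qi, R, chi_r,
#'   chi_i, T`.
#' @param delta slice difficulty.
#' @param quad_nodes Gauss-Hermite nodes per dimension.
#' @return List with `value`, `partials` (named vector over
#'   `Qr, Qi, R, chi_r, chi_i`) and `expectations`
#'   (`Eg2 = E[g^2]`, `Ew = E[l''/(1+chi l'')]`, `Egnu = E[g nu]`,
#'   `Eloss = E[l(y u*)]`, with `g = (u* - h)/chi`).
#' @export
energetic_channel <- function(state, delta, quad_nodes = 121) {
  Tt <- state$T
  q <- state$Qr + delta * state$Qi
  chi <- state$chi_r + delta * state$chi_i
  stopifnot(chi > 0, Tt > 0)
  gq <- .quad_grid(quad_nodes)
  nu <- sqrt(Tt) * gq$xi       # folded onto nu > 0, so y = +1 throughout
  y <- 1
  s2 <- max(q - state$R^2 / Tt, 0)
  h <- (state$R / Tt) * nu + sqrt(s2) * gq$z
  u <- prox_logistic(h, y, chi)
  g <- (u - h) / chi
  sig <- 1 / (1 + exp(-y * u))
  lpp <- sig * (1 - sig)
  wv <- lpp / (1 + chi * lpp)
  Eg2 <- sum(gq$w * g^2)
  Ew <- sum(gq$w * wv)
  Egnu <- sum(gq$w * g * nu)
  Eloss <- sum(gq$w * log1p(exp(-y * u)))
  Emor <- Eloss + chi * Eg2 / 2
  partials <- c(Qr = -Ew / 2, Qi = -delta * Ew / 2,
                R = (Egnu + state$R * Ew) / Tt,
                chi_r = Eg2 / 2, chi_i = delta * Eg2 / 2)
  list(value = -Emor, partials = partials,
       expectations = c(Eg2 = Eg2, Ew = Ew, Egnu = Egnu, Eloss = Eloss))
}

#' Entropic channel of the RS free energy
#'
#' The prior side of the saddle point. Each coordinate of block `b` (relevant
#' or irrelevant, fractions `rho` and `1 - rho`) sees the quadratic
#' single-site problem `max_w [ B w - Lambda_b w^2 / 2 ]` with curvature
#' `Lambda_b = gamma + gamma_link + qhat_chi_b` and Gaussian local field
#' `B = mhat W_T 1(b = r) + sqrt(qhat_b) z + gamma_link w_anchor`. The value
#' is the exact Gaussian expectation `sum_b c_b E[B^2] / (2 Lambda_b)`; the
#' same moments give the order-parameter updates, including the
#' cross-overlaps with the anchor phase.
#'
#' @param hats named list/vector with the conjugate parameters
#'   `qhat_r, qhat_i, chihat_r, chihat_i, mhat`.
#' @param phase a [phase_spec()] (supplies `gamma` and `gamma_link`).
#' @param anchor converged `saddle_state` of the previous phase, or `NULL`
#'   (required iff `gamma_link > 0`).
#' @param rho teacher sparsity; the teacher coordinates are standard normal
#'   on the relevant block, so `T = rho`.
#' @return List with `value` and `updates` (named vector
#'   `Qr, Qi, R, chi_r, chi_i, cross_r, cross_i`; the cross entries are the
#'   per-dimension overlaps with the anchor, zero when unanchored).
#' @export
entropic_channel <- function(hats, phase, anchor = NULL, rho) {
  gl <- phase$gamma_link
  if (gl > 0 && is.null(anchor)) stop("anchored phase requires an anchor state")
  if (gl == 0) anchor <- list(Qr = 0, Qi = 0, R = 0)
  Lr <- phase$gamma + gl + hats[["chihat_r"]]
  Li <- phase$gamma + gl + hats[["chihat_i"]]
  mh <- hats[["mhat"]]
  ## second moments of the local fields, aggregated per block (x fraction)
  EB2_r <- rho * (hats[["qhat_r"]] + mh^2) + gl^2 * anchor$Qr +
    2 * mh * gl * anchor$R
  EB2_i <- (1 - rho) * hats[["qhat_i"]] + gl^2 * anchor$Qi
  value <- EB2_r / (2 * Lr) + EB2_i / (2 * Li)
  cross_r <- if (gl > 0) (mh * anchor$R + gl * anchor$Qr) / Lr else 0
  cross_i <- if (gl > 0) gl * anchor$Qi / Li else 0
  updates <- c(Qr = EB2_r / Lr^2, Qi = EB2_i / Li^2,
               R = (rho * mh + gl * anchor$R) / Lr,
               chi_r = rho / Lr, chi_i = (1 - rho) / Li,
               cross_r = cross_r, cross_i = cross_i)
  list(value = value, updates = updates)
}

#' Solve the RS saddle point of one batch learning phase
#'
#' Damped fixed-point iteration alternating the energetic conjugate updates
#' (two-dimensional quadrature with an inner safeguarded-Newton solve of the
#' logistic proximal problem) and the closed-form entropic updates. The
#' damping is reduced automatically when the residual stagnates.
#'
#' @param phase a [phase_spec()].
#' @param anchor converged `saddle_state` of the previous phase (or `NULL`).
#' @param cfg a [solver_config()].
#' @param rho teacher sparsity; the theory uses the self-averaging teacher
#'   norm `T = rho`.
#' @return A `saddle_state`: list with order parameters
#'   `Qr, Qi, R, chi_r, chi_i`, conjugates `hats`, cross-overlaps to the
#'   anchor (`cross_r`, `cross_i`), `T = rho`, the typical per-dimension
#'   training objective `objective`, convergence diagnostics (`residual`,
#'   `iters`, `converged`) and the residual trace.
#' @export
solve_phase <- function(phase, anchor = NULL, cfg = solver_config(),
                        rho = 0.5) {
  stopifnot(inherits(phase, "phase_spec"), inherits(cfg, "solver_config"))
  if (phase$gamma_link > 0 && is.null(anchor))
    stop("anchored phase requires the previous phase's state")
  Tt <- rho
  g0 <- phase$gamma + phase$gamma_link
  st <- cfg$init
  if (is.null(st))
    st <- list(Qr = 0.1 * rho, Qi = 0.1 * (1 - rho), R = 0.01,
               chi_r = rho / (g0 + 1), chi_i = (1 - rho) / (g0 + 1))
  keys <- c("Qr", "Qi", "R", "chi_r", "chi_i")
  trace <- numeric(0)
  hats <- NULL
  upd <- NULL
  damping <- cfg$damping
  best_res <- Inf
  stall <- 0L
  for (it in seq_len(cfg$max_iter)) {
    hq_r <- hq_i <- hx_r <- hx_i <- hm <- 0
    stt <- c(st, list(T = Tt))
    for (k in seq_along(phase$alphas)) {
      en <- energetic_channel(stt, phase$deltas[k], cfg$quad_nodes)
      ex <- en$expectations
      a <- phase$alphas[k]
      d <- phase$deltas[k]
      hq_r <- hq_r + a * ex[["Eg2"]]
      hq_i <- hq_i + a * d * ex[["Eg2"]]
      hx_r <- hx_r + a * ex[["Ew"]]
      hx_i <- hx_i + a * d * ex[["Ew"]]
      hm <- hm + a * (ex[["Egnu"]] + st$R * ex[["Ew"]]) / Tt
    }
    hats <- c(qhat_r = hq_r, qhat_i = hq_i, chihat_r = hx_r,
              chihat_i = hx_i, mhat = hm)
    ent <- entropic_channel(hats, phase, anchor, rho)
    upd <- ent$updates
    res <- max(abs(upd[keys] - unlist(st)[keys]))
    trace <- c(trace, res)
    ## reduce damping when the residual stagnates (the map can be locally
    ## expansive near degenerate fixed points, e.g. Q -> 0)
    if (res < best_res * 0.999) { best_res <- res; stall <- 0L }
    else if ((stall <- stall + 1L) >= 50L && damping > 0.02) {
      damping <- damping / 2
      stall <- 0L
    }
    for (k in keys) st[[k]] <- (1 - damping) * st[[k]] + damping * upd[[k]]
    if (res < cfg$tol) break
  }
  if (trace[length(trace)] >= cfg$tol) {
    cond <- structure(class = c("curricula_nonconvergence", "error",
                                "condition"),
                      list(message = sprintf(
                        "saddle-point iteration did not converge (residual %.3g after %d iterations)",
                        trace[length(trace)], it), call = sys.call(),
                        residual_trace = trace))
    stop(cond)
  }
  ## converged state: evaluate channels once more at the fixed point
  stt <- c(st, list(T = Tt))
  Eloss <- 0
  for (k in seq_along(phase$alphas)) {
    en <- energetic_channel(stt, phase$deltas[k], cfg$quad_nodes)
    Eloss <- Eloss + phase$alphas[k] * en$expectations[["Eloss"]]
  }
  dist2 <- if (phase$gamma_link > 0)
    (st$Qr + anchor$Qr - 2 * upd[["cross_r"]]) +
      (st$Qi + anchor$Qi - 2 * upd[["cross_i"]]) else 0
  objective <- Eloss + phase$gamma / 2 * (st$Qr + st$Qi) +
    phase$gamma_link / 2 * dist2
  structure(list(Qr = st$Qr, Qi = st$Qi, R = st$R, chi_r = st$chi_r,
                 chi_i = st$chi_i, T = Tt, rho = rho, hats = hats,
                 cross_r = unname(upd[["cross_r"]]),
                 cross_i = unname(upd[["cross_i"]]),
                 anchor_dist2 = dist2, objective = unname(objective),
                 phase = phase, residual = trace[length(trace)], iters = it,
                 converged = TRUE, residual_trace = trace),
            class = "saddle_state")
}

#' @export
print.saddle_state <- function(x, ...) {
  cat(sprintf(
    "<saddle_state> Qr = %.5g, Qi = %.5g, R = %.5g (T = %.3g)\n  objective = %.6g, %d iterations, residual %.2e\n",
    x$Qr, x$Qi, x$R, x$T, x$objective, x$iters, x$residual))
  invisible(x)
}

#' Order parameters of a converged saddle state
#' @param state a `saddle_state`.
#' @export
saddle_order_params <- function(state) {
  order_params(state$Qr, state$Qi, state$R, state$T)
}

#' Run a full batch curriculum strategy through the RS theory
#'
#' Sequentially solves one saddle point per phase in schedule order,
#' chaining each converged state as the elastic anchor of the next phase.
#' `"curriculum"` presents slices by increasing difficulty,
#' `"anti-curriculum"` by decreasing difficulty; `"none"` performs a single
#' phase on the pooled slices (batch learning is order-free within a phase).
#'
#' @param slices list of [theory_slice()] (or [sample_slice()]) descriptors.
#' @param strategy `"curriculum"`, `"anti-curriculum"` or `"none"`.
#' @param gammas ridge intensity per phase (recycled if scalar).
#' @param gamma12 elastic coupling between consecutive phases (ignored for
#'   `"none"`).
#' @param cfg a [solver_config()].
#' @param eval_delta difficulty at which final metrics are reported
#'   (default: the hardest slice).
#' @param warm_start chain each phase's solution as the next solve's
#'   initialisation (default TRUE).
#' @return List of class `strategy_result`: `states` (one `saddle_state` per
#'   phase), `final_op`, and `metrics` (data.frame of loss/accuracy at each
#'   slice difficulty plus `eval_delta`).
#' @export
run_strategy <- function(slices, strategy = c("curriculum", "anti-curriculum",
                                              "none"),
                         gammas, gamma12 = 0, cfg = solver_config(),
                         eval_delta = NULL, warm_start = TRUE) {
  strategy <- match.arg(strategy)
  sched <- make_schedule(slices, strategy)
  rho <- sched$rho
  if (is.null(eval_delta)) eval_delta <- max(sched$deltas)
  if (strategy == "none") {
    phases <- list(phase_spec(sched$alphas, sched$deltas, gammas[1], 0))
  } else {
    gam <- rep_len(gammas, length(sched$deltas))
    phases <- lapply(seq_along(sched$deltas), function(k)
      phase_spec(sched$alphas[k], sched$deltas[k], gam[k],
                 if (k == 1) 0 else gamma12))
  }
  states <- vector("list", length(phases))
  anchor <- NULL
  for (k in seq_along(phases)) {
    cfg_k <- cfg
    if (warm_start && !is.null(anchor))
      cfg_k$init <- anchor[c("Qr", "Qi", "R", "chi_r", "chi_i")]
    states[[k]] <- solve_phase(phases[[k]], anchor, cfg_k, rho)
    anchor <- states[[k]]
  }
  fin <- states[[length(states)]]
  op <- saddle_order_params(fin)
  dl <- sort(unique(c(sched$deltas, eval_delta)))
  metrics <- data.frame(
    delta = dl,
    loss = vapply(dl, function(d) test_loss(op, d), numeric(1)),
    accuracy = vapply(dl, function(d) suppressMessages(accuracy(op, d)),
                      numeric(1)))
  structure(list(states = states, final_op = op, metrics = metrics,
                 strategy = strategy, eval_delta = eval_delta,
                 accuracy_hard = metrics$accuracy[metrics$delta == eval_delta]),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s, %d phase(s); accuracy at delta = %.3g: %.5f\n",
              x$strategy, length(x$states), x$eval_delta, x$accuracy_hard))
  invisible(x)
}
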