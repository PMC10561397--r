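#' Create a sparse teacher perceptron
#'
#' The teacher is a length-`N` weight vector whose first `round(rho * N)`
#' (relevant) components are drawn i.i.d. standard normal and whose remaining
#' (irrelevant) components are exactly zero. Labels produced by the teacher
#' depend only on the relevant block, so the irrelevant coordinates of an
#' input carry pure noise.
#'
#' Two teacher-norm conventions coexist: the sampled (empirical)
#' `T = sum(weights^2) / N`, used by the finite-N simulators, and the
#' self-averaging value `T = rho` used by the theory modules, which removes
#' the O(1/sqrt(N)) sampling bias from asymptotic predictions.
#'
#' @param N input dimension (positive integer).
#' @param rho fraction of relevant (non-zero) components, in (0, 1];
#'   `round(rho * N)` must be at least 1.
#' @param seed integer seed; the teacher is deterministic given the seed.
#' @return An object of class `teacher_model`: a list with `weights`, `N`,
#'   `rho`, `n_rel` (number of relevant components), `T_emp` (empirical
#'   squared norm / N) and `T_theory = rho`.
#' @examples
#' tch <- make_teacher(1000, 0.5, seed = 1)
#' sum(tch$weights != 0) == tch$n_rel
#' @export
make_teacher <- function(N, rho, seed = 0L) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("N must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1)
    stop("rho must be in (0, 1]")
  n_rel <- as.integer(round(rho * N))
  if (n_rel < 1) stop("round(rho * N) must be at least 1")
  set.seed(seed)
  w <- c(rnorm(n_rel), rep(0, N - n_rel))
  structure(
    list(weights = w, N = as.integer(N), rho = rho, n_rel = n_rel,
         T_emp = sum(w^2) / N, T_theory = rho, seed = as.integer(seed)),
    class = "teacher_model")
}

#' @export
print.teacher_model <- function(x, ...) {
  cat(sprintf("<teacher_model> N = %d, rho = %.3f (%d relevant), T_emp = %.4f\n",
              x$N, x$rho, x$n_rel, x$T_emp))
  invisible(x)
}

#' Sample a difficulty-stratified slice of labelled Gaussian inputs
#'
#' Draws `M = round(alpha * N)` inputs whose relevant coordinates are
#' standard normal and whose irrelevant coordinates have variance `delta`
#' (the slice difficulty). Labels are the sign of the teacher field computed
#' on the relevant block only; `sign(0)` is resolved to `+1`.
#'
#' @param teacher a [make_teacher()] object.
#' @param alpha sample-size ratio M/N (positive; `round(alpha * N) >= 1`).
#' @param delta non-negative variance of the irrelevant coordinates.
#' @param seed integer seed.
#' @return An object of class `dataset_slice`: list with `X` (M x N matrix),
#'   `y` (labels in -1/+1), `delta`, `alpha` (realised M/N), `M`, `N`,
#'   `rho`, `seed`.
#' @examples
#' tch <- make_teacher(200, 0.5, seed = 1)
#' sl <- sample_slice(tch, alpha = 0.5, delta = 1, seed = 2)
#' table(sl$y)
#' @export
sample_slice <- function(teacher, alpha, delta, seed = 0L) {
  stopifnot(inherits(teacher, "teacher_model"))
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("delta must be a non-negative scalar")
  N <- teacher$N
  M <- as.integer(round(alpha * N))
  if (M < 1) stop("alpha * N must be at least 1")
  set.seed(seed)
  nr <- teacher$n_rel
  X <- matrix(rnorm(M * N), M, N)
  if (nr < N) X[, (nr + 1):N] <- X[, (nr + 1):N] * sqrt(delta)
  field <- X[, seq_len(nr), drop = FALSE] %*% teacher$weights[seq_len(nr)]
  y <- ifelse(drop(field) >= 0, 1, -1)
  structure(
    list(X = X, y = y, delta = delta, alpha = M / N, M = M, N = N,
         rho = teacher$rho, seed = as.integer(seed)),
    class = "dataset_slice")
}

#' @export
print.dataset_slice <- function(x, ...) {
  cat(sprintf("<dataset_slice> M = %d, N = %d, delta = %.3g, alpha = %.3g\n",
              x$M, x$N, x$delta, x$alpha))
  invisible(x)
}

#' Empirical order parameters of a student weight vector
#'
#' Computes the macroscopic state of a student relative to a sparse teacher:
#' `Qr` and `Qi`, the squared norms per dimension of the relevant and
#' irrelevant weight blocks; `R`, the relevant-block overlap with the teacher;
#' and `T`, the teacher's empirical squared norm per dimension.
#'
#' @param student_weights numeric vector of length `teacher$N`.
#' @param teacher a [make_teacher()] object.
#' @return An [order_params()] object (with the empirical `T`).
#' @export
empirical_order_params <- function(student_weights, teacher) {
  stopifnot(inherits(teacher, "teacher_model"))
  if (length(student_weights) != teacher$N)
    stop("student/teacher dimension mismatch")
  N <- teacher$N
  nr <- teacher$n_rel
  wr <- student_weights[seq_len(nr)]
  wi <- if (nr < N) student_weights[(nr + 1):N] else numeric(0)
  order_params(Qr = sum(wr^2) / N, Qi = sum(wi^2) / N,
               R = sum(wr * teacher$weights[seq_len(nr)]) / N,
               T = teacher$T_emp)
}

#' Order-parameter state
#'
#' Container for the macroscopic state (Qr, Qi, R, T) of a student. Validates
#' non-negativity of the norms and the Cauchy-Schwarz bound
#' `R^2 <= Qr * T` (up to rounding tolerance).
#'
#' @param Qr,Qi squared norm per dimension of the relevant / irrelevant
#'   student block (non-negative).
#' @param R relevant-block teacher-student overlap.
#' @param T teacher squared norm per dimension (positive).
#' @return A named list of class `order_params`.
#' @export
order_params <- function(Qr, Qi, R, T) {
  if (Qr < 0 || Qi < 0) stop("Qr and Qi must be non-negative")
  if (T <= 0) stop("T must be positive")
  if (R^2 > Qr * T * (1 + 1e-9) + 1e-12)
    stop("Cauchy-Schwarz violation: R^2 > Qr * T")
  structure(list(Qr = Qr, Qi = Qi, R = R, T = T), class = "order_params")
}

#' @export
print.order_params <- function(x, ...) {
  cat(sprintf("<order_params> Qr = %.5g, Qi = %.5g, R = %.5g, T = %.5g\n",
              x$Qr, x$Qi, x$R, x$T))
  invisible(x)
}

#' Order dataset slices into a curriculum schedule
#'
#' A schedule fixes the presentation order of difficulty slices:
#' `"curriculum"` sorts by increasing difficulty `delta`, `"anti-curriculum"`
#' by decreasing `delta`, and `"none"` pools all samples and presents them in
#' a uniformly shuffled order (consumers realise the shuffle; the schedule
#' records the pooled slices and a shuffle seed). Ties in `delta` are broken
#' by input order, so equal-difficulty schedules coincide across strategies.
#'
#' @param slices list of [sample_slice()] objects, or a list of lightweight
#'   slice descriptors from [theory_slice()].
#' @param strategy one of `"curriculum"`, `"anti-curriculum"`, `"none"`.
#' @param seed shuffle seed used by simulators when `strategy = "none"`.
#' @return An object of class `curriculum_schedule` with the ordered
#'   `slices`, `strategy`, `deltas`, `alphas`, `rho` and `seed`.
#' @examples
#' s <- make_schedule(list(theory_slice(1, 1, 0.5), theory_slice(1, 0, 0.5)),
#'                    "curriculum")
#' s$deltas  # 0 then 1
#' @export
make_schedule <- function(slices, strategy = c("curriculum", "anti-curriculum",
                                               "none"), seed = 0L) {
  strategy <- match.arg(strategy)
  if (!is.list(slices) || length(slices) < 1) stop("need at least one slice")
  if (inherits(slices, "dataset_slice") || inherits(slices, "theory_slice"))
    slices <- list(slices)
  deltas <- vapply(slices, function(s) s$delta, numeric(1))
  alphas <- vapply(slices, function(s) s$alpha, numeric(1))
  rhos <- vapply(slices, function(s) s$rho, numeric(1))
  if (length(unique(rhos)) != 1) stop("slices must share one rho")
  ## ties in delta are allowed and broken by input order (order() is
  ## stable), so equal-difficulty slices behave identically under every
  ## strategy -- the symmetry-null configuration
  ord <- switch(strategy,
                "curriculum" = order(deltas),
                "anti-curriculum" = order(-deltas),
                "none" = seq_along(deltas))
  structure(
    list(slices = slices[ord], strategy = strategy, deltas = deltas[ord],
         alphas = alphas[ord], rho = rhos[1], seed = as.integer(seed)),
    class = "curriculum_schedule")
}

#' Lightweight slice descriptor for theory-only schedules
#'
#' The asymptotic solvers need only `(alpha, delta, rho)`; this constructs a
#' data-free stand-in for [sample_slice()] output usable in
#' [make_schedule()], [run_theory()] and [run_strategy()].
#'
#' @param alpha sample-size ratio of the slice.
#' @param delta irrelevant-coordinate variance (difficulty).
#' @param rho teacher sparsity.
#' @export
theory_slice <- function(alpha, delta, rho) {
  stopifnot(alpha > 0, delta >= 0, rho > 0, rho <= 1)
  structure(list(alpha = alpha, delta = delta, rho = rho),
            class = "theory_slice")
}

#' @export
print.curriculum_schedule <- function(x, ...) {
  cat(sprintf("<curriculum_schedule> %s: deltas (%s), alphas (%s)\n",
              x$strategy, paste(signif(x$deltas, 3), collapse = ", "),
              paste(signif(x$alphas, 3), collapse = ", ")))
  invisible(x)
}

#' Write / read a dataset slice
#'
#' Serialises a slice as a flat columnar CSV (inputs `x1..xN` plus the label
#' column `y`) with a JSON sidecar `<path>.json` recording
#' `(N, rho, delta, alpha, seed)`.
#'
#' @param slice a [sample_slice()] object.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_slice` returns `path` invisibly; `read_slice` returns a
#'   `dataset_slice`.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "dataset_slice"))
  df <- data.table::as.data.table(slice$X)
  data.table::setnames(df, paste0("x", seq_len(ncol(df))))
  df$y <- slice$y
  data.table::fwrite(df, path)
  meta <- slice[c("N", "M", "rho", "delta", "alpha", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- data.table::fread(path)
  y <- as.numeric(df$y)
  X <- as.matrix(df[, setdiff(names(df), "y"), with = FALSE])
  dimnames(X) <- NULL
  structure(
    list(X = X, y = y, delta = meta$delta, alpha = meta$alpha, M = meta$M,
         N = meta$N, rho = meta$rho, seed = meta$seed),
    class = "dataset_slice")
}
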