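## Closed-form generalisation metrics at a macroscopic state.
## Both follow from the joint Gaussianity of the student field
## lambda = W.x/sqrt(N) (variance Q = Qr + delta*Qi) and the teacher field
## nu (variance T, covariance R) in the high-dimensional limit.

.clip_asin <- function(x, tol = 1e-12) {
  if (any(abs(x) > 1 + tol)) stop("asin argument outside [-1, 1] beyond tolerance")
  lim <- 1 - 1e-15
  pmin(lim, pmax(-lim, x))
}

.as_op <- function(op) {
  if (inherits(op, "order_params")) return(op)
  if (is.numeric(op) && length(op) == 4 &&
      all(c("Qr", "Qi", "R", "T") %in% names(op)))
    return(order_params(op[["Qr"]], op[["Qi"]], op[["R"]], op[["T"]]))
  stop("expected an order_params object")
}

#' Test loss at a macroscopic state
#'
#' Mean-squared-error test loss `E[(sigma(lambda) - y)^2] / 2` of an
#' erf-activation student against sign-teacher labels, on fresh examples with
#' irrelevant-coordinate variance `delta`:
#' \deqn{L = \frac12 + \frac1\pi \arcsin\frac{Q}{1+Q}
#'        - \frac2\pi \arcsin\frac{R/\sqrt{T}}{\sqrt{Q+1}},
#'       \quad Q = Q_r + \Delta Q_i.}
#'
#' @param op an [order_params()] state.
#' @param delta difficulty (irrelevant-coordinate variance) of the test set.
#' @return Scalar loss in \[0, 1\].
#' @examples
#' test_loss(order_params(1, 0, 0, 1), delta = 2)  # 2/3
#' @export
test_loss <- function(op, delta) {
  op <- .as_op(op)
  Q <- op$Qr + delta * op$Qi
  0.5 + asin(.clip_asin(Q / (1 + Q))) / pi -
    2 * asin(.clip_asin((op$R / sqrt(op$T)) / sqrt(Q + 1))) / pi
}

#' Classification accuracy at a macroscopic state
#'
#' Probability that the sign of the student field matches the teacher label
#' on a fresh example of difficulty `delta`:
#' \deqn{A = \frac12 + \frac1\pi
#'        \arcsin\frac{R}{\sqrt{T (Q_r + \Delta Q_i)}}.}
#' A zero-norm student (`Qr + delta * Qi = 0`) guesses at random and the
#' accuracy is defined as 1/2 (a message is emitted).
#'
#' @inheritParams test_loss
#' @return Scalar accuracy in \[0, 1\].
#' @examples
#' accuracy(order_params(1, 1, 0.5, 0.5), delta = 1)  # 2/3
#' @export
accuracy <- function(op, delta) {
  op <- .as_op(op)
  Q <- op$Qr + delta * op$Qi
  if (Q <= 0) {
    message("zero student norm: accuracy defined as 1/2 (random guessing)")
    return(0.5)
  }
  0.5 + asin(.clip_asin(op$R / sqrt(op$T * Q))) / pi
}

#' Metrics on a mixture of difficulty levels
#'
#' Loss and accuracy on a test set that mixes difficulty levels `deltas`
#' with the given probability weights (the weighted average over partitions).
#'
#' @inheritParams test_loss
#' @param deltas numeric vector of difficulty levels.
#' @param weights non-negative weights summing to 1, one per delta.
#' @return Named list with `loss` and `accuracy`.
#' @export
mixture_metrics <- function(op, deltas, weights) {
  if (length(deltas) != length(weights)) stop("deltas/weights length mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  op <- .as_op(op)
  list(loss = sum(weights * vapply(deltas, function(d) test_loss(op, d),
                                   numeric(1))),
       accuracy = sum(weights * vapply(deltas, function(d) accuracy(op, d),
                                       numeric(1))))
}
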