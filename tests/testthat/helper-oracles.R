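## Monte-Carlo oracles over the joint Gaussian fields, independent of the
## closed-form implementation.

erf1 <- function(u) 2 * pnorm(u * sqrt(2)) - 1

## sample (lambda_r, lambda_i, nu): (lambda_r, nu) correlated via R,
## lambda_i independent with variance delta * Qi
mc_fields <- function(n, Qr, Qi, R, T, delta) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  if (Qr > 0) {
    lr <- sqrt(Qr) * z1
    nu <- (R / sqrt(Qr)) * z1 + sqrt(max(T - R^2 / Qr, 0)) * z2
  } else {
    lr <- numeric(n)
    nu <- sqrt(T) * z2
  }
  li <- sqrt(delta * Qi) * rnorm(n)
  list(lr = lr, li = li, nu = nu)
}

## MC estimate of test loss and accuracy at a state
mc_metrics <- function(op, delta, n = 2e5) {
  f <- mc_fields(n, op$Qr, op$Qi, op$R, op$T, delta)
  lam <- f$lr + f$li
  y <- ifelse(f$nu >= 0, 1, -1)
  L <- (erf1(lam / sqrt(2)) - y)^2 / 2
  A <- (sign(lam) == y)
  list(loss = mean(L), loss_se = sd(L) / sqrt(n),
       acc = mean(A), acc_se = sd(A) / sqrt(n))
}

## MC estimate of the expected one-step update of (Qr, Qi, R) from the
## literal SGD increment expressed through the fields (the independent
## oracle for the closed-form map)
mc_update <- function(op, delta, eta, gamma, N_theory, rho, n = 1e6,
                      chunk = 1e6) {
  sums <- c(Glr = 0, Gli = 0, Gnu = 0, G2 = 0)
  sq <- c(Glr = 0, Gli = 0, Gnu = 0, G2 = 0)
  left <- n
  while (left > 0) {
    m <- min(chunk, left)
    f <- mc_fields(m, op$Qr, op$Qi, op$R, op$T, delta)
    lam <- f$lr + f$li
    y <- ifelse(f$nu >= 0, 1, -1)
    G <- sqrt(2 / pi) * exp(-lam^2 / 2) * (y - erf1(lam / sqrt(2)))
    v <- cbind(Glr = G * f$lr, Gli = G * f$li, Gnu = G * f$nu, G2 = G^2)
    sums <- sums + colSums(v)
    sq <- sq + colSums(v^2)
    left <- left - m
  }
  mu <- sums / n
  se <- sqrt(pmax(sq / n - mu^2, 0) / n)
  d <- 1 - gamma
  invN <- 1 / N_theory
  list(
    Qr = d^2 * op$Qr + 2 * d * eta * invN * mu[["Glr"]] +
      eta^2 * invN * rho * mu[["G2"]],
    Qi = d^2 * op$Qi + 2 * d * eta * invN * mu[["Gli"]] +
      eta^2 * invN * (1 - rho) * delta * mu[["G2"]],
    R = d * op$R + eta * invN * mu[["Gnu"]],
    se_Qr = invN * sqrt((2 * d * eta * se[["Glr"]])^2 +
                          (eta^2 * rho * se[["G2"]])^2),
    se_Qi = invN * sqrt((2 * d * eta * se[["Gli"]])^2 +
                          (eta^2 * (1 - rho) * delta * se[["G2"]])^2),
    se_R = eta * invN * se[["Gnu"]])
}

## two-slice schedule helper
two_slice <- function(strategy, a1 = 1, a2 = 1, d1 = 0, d2 = 1, rho = 0.5,
                      seed = 0L) {
  make_schedule(list(theory_slice(a1, d1, rho), theory_slice(a2, d2, rho)),
                strategy, seed = seed)
}
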