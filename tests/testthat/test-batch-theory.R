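test_that("logistic prox solves the scalar optimality condition", {
  set.seed(1)
  h <- rnorm(50, sd = 3)
  y <- sample(c(-1, 1), 50, replace = TRUE)
  for (chi in c(1e-3, 0.5, 50)) {
    u <- prox_logistic(h, y, chi)
    resid <- u - h - chi * y / (1 + exp(y * u))
    expect_lt(max(abs(resid)), 1e-10)
    # a generic scalar optimiser never finds a lower objective
    obj <- function(v, i) log1p(exp(-y[i] * v)) + (v - h[i])^2 / (2 * chi)
    for (i in c(1, 17, 42)) {
      o <- optimize(obj, interval = h[i] + c(-1, 1) * (chi + 5), i = i,
                    tol = 1e-10)
      expect_lt(obj(u[i], i), o$objective + 1e-9)
    }
  }
})

test_that("energetic channel: value, partials and limits", {
  st <- list(Qr = 0.6, Qi = 0.4, R = 0.3, chi_r = 0.8, chi_i = 0.5, T = 0.5)
  en <- energetic_channel(st, delta = 0.7, quad_nodes = 81)

  # partial derivatives agree with central finite differences
  num_partial <- function(name, eps = 1e-6) {
    up <- st; up[[name]] <- up[[name]] + eps
    dn <- st; dn[[name]] <- dn[[name]] - eps
    (energetic_channel(up, 0.7, 81)$value -
       energetic_channel(dn, 0.7, 81)$value) / (2 * eps)
  }
  for (nm in c("Qr", "Qi", "R", "chi_r", "chi_i"))
    expect_equal(en$partials[[nm]], num_partial(nm), tolerance = 1e-5)

  # value matches a dense double-integration oracle over the unfolded
  # (nu, z) plane -- composite Simpson in the teacher direction with the
  # sign label taken literally, dense Gauss-Hermite in the orthogonal one
  q <- st$Qr + 0.7 * st$Qi; chi <- st$chi_r + 0.7 * st$chi_i
  s <- sqrt(q - st$R^2 / st$T)
  gh <- gauss_hermite(121)
  inner <- function(xi) {
    nu <- sqrt(st$T) * xi
    ysign <- if (xi >= 0) 1 else -1
    h <- (st$R / st$T) * nu + s * gh$x
    u <- prox_logistic(h, ysign, chi, tol = 1e-14)
    sum(gh$w * (log1p(exp(-ysign * u)) + (u - h)^2 / (2 * chi))) * dnorm(xi)
  }
  np <- 12001
  xg <- seq(-12, 12, length.out = np)
  fg <- vapply(xg, inner, numeric(1))
  sw <- c(1, rep(c(4, 2), (np - 3) / 2), 4, 1)
  oracle <- -sum(sw * fg) * (xg[2] - xg[1]) / 3
  expect_equal(energetic_channel(st, 0.7, 61)$value, oracle,
               tolerance = 1e-8)

  # node-count convergence
  expect_equal(energetic_channel(st, 0.7, 61)$value,
               energetic_channel(st, 0.7, 121)$value, tolerance = 1e-9)

  # almost-surely correct with huge margin: vanishing loss contribution
  big <- list(Qr = 1e6, Qi = 0, R = sqrt(1e6 * 0.5) * (1 - 1e-12),
              chi_r = 1, chi_i = 0.1, T = 0.5)
  expect_lt(abs(energetic_channel(big, 0, 61)$value), 1e-3)
})

test_that("entropic channel: closed form equals an explicit Gaussian integral", {
  hats <- c(qhat_r = 0.8, qhat_i = 0.3, chihat_r = 1.2, chihat_i = 0.7,
            mhat = 0.9)
  rho <- 0.5
  ph <- phase_spec(1, 1, gamma = 0.3, gamma_link = 0.6)
  # explicit coordinate model for the anchor with matching moments:
  # w1 = m1 W_T + sqrt(v1r) z1 on the relevant block, sqrt(v1i) z1 elsewhere
  m1 <- 0.5; v1r <- 0.2; v1i <- 0.35
  anchor <- list(Qr = rho * (m1^2 + v1r), Qi = (1 - rho) * v1i,
                 R = rho * m1)
  ent <- entropic_channel(hats, ph, anchor, rho)

  g <- gauss_hermite(61)
  Lr <- ph$gamma + ph$gamma_link + hats[["chihat_r"]]
  Li <- ph$gamma + ph$gamma_link + hats[["chihat_i"]]
  # relevant block: 3D expectation over (W_T, z1, z2)
  val_r <- 0
  for (i in seq_along(g$x)) for (j in seq_along(g$x)) for (k in seq_along(g$x)) {
    w1 <- m1 * g$x[i] + sqrt(v1r) * g$x[j]
    B <- hats[["mhat"]] * g$x[i] + sqrt(hats[["qhat_r"]]) * g$x[k] +
      ph$gamma_link * w1
    val_r <- val_r + g$w[i] * g$w[j] * g$w[k] * B^2 / (2 * Lr)
  }
  # irrelevant block: 2D expectation over (z1, z2)
  val_i <- 0
  for (j in seq_along(g$x)) for (k in seq_along(g$x)) {
    w1 <- sqrt(v1i) * g$x[j]
    B <- sqrt(hats[["qhat_i"]]) * g$x[k] + ph$gamma_link * w1
    val_i <- val_i + g$w[j] * g$w[k] * B^2 / (2 * Li)
  }
  oracle <- rho * val_r + (1 - rho) * val_i
  expect_equal(ent$value, oracle, tolerance = 1e-10)

  # decoupling: gamma_link = 0 reduces to the single-phase term
  ph0 <- phase_spec(1, 1, gamma = 0.3, gamma_link = 0)
  e0 <- entropic_channel(hats, ph0, NULL, rho)
  expect_equal(e0$updates[["cross_r"]], 0)
  # pinning: enormous coupling forces the anchor state
  php <- phase_spec(1, 1, gamma = 0.3, gamma_link = 1e8)
  ep <- entropic_channel(hats, php, anchor, rho)
  expect_equal(ep$updates[["Qr"]], anchor$Qr, tolerance = 1e-6)
  expect_equal(ep$updates[["Qi"]], anchor$Qi, tolerance = 1e-6)
  expect_equal(ep$updates[["R"]], anchor$R, tolerance = 1e-6)
})

test_that("saddle-point solver: limits, decoupling and initialisation independence", {
  cfg <- solver_config(tol = 1e-10, quad_nodes = 61)
  # vanishing data: ridge prior pins the student at zero, chance accuracy
  # (the Q -> 0 fixed point is stiff; lighter settings suffice for the limit)
  st0 <- solve_phase(phase_spec(1e-6, 1, gamma = 0.1), NULL,
                     solver_config(tol = 1e-7, quad_nodes = 41), rho = 0.5)
  expect_lt(st0$Qr + st0$Qi, 1e-4)
  expect_equal(suppressMessages(accuracy(saddle_order_params(st0), 1)), 0.5,
               tolerance = 1e-3)

  # memorylessness: zero coupling equals a standalone phase-2 solve
  st1 <- solve_phase(phase_spec(1, 0, gamma = 0.05), NULL, cfg, 0.5)
  chained <- solve_phase(phase_spec(1, 1, gamma = 0.05, gamma_link = 0),
                         NULL, cfg, 0.5)
  alone <- solve_phase(phase_spec(1, 1, gamma = 0.05), NULL, cfg, 0.5)
  for (k in c("Qr", "Qi", "R"))
    expect_equal(chained[[k]], alone[[k]], tolerance = 1e-8)

  # convexity: endpoint independent of the initial state
  inits <- list(
    list(Qr = 1e-3, Qi = 1e-3, R = 0, chi_r = 0.1, chi_i = 0.1),
    list(Qr = 2, Qi = 2, R = 0.5, chi_r = 2, chi_i = 2),
    list(Qr = 0.5, Qi = 0.01, R = -0.1, chi_r = 0.5, chi_i = 1))
  sols <- lapply(inits, function(ini) {
    c2 <- cfg; c2$init <- ini
    solve_phase(phase_spec(1, 1, gamma = 0.05), NULL, c2, 0.5)
  })
  for (k in c("Qr", "Qi", "R")) {
    vals <- vapply(sols, `[[`, numeric(1), k)
    expect_lt(diff(range(vals)), 1e-7)
  }
  # stationarity: converged residual below tolerance and CS bound holds
  expect_lt(sols[[1]]$residual, 1e-10)
  expect_true(sols[[1]]$R^2 <= sols[[1]]$Qr * sols[[1]]$T + 1e-9)
})

test_that("pinning is monotone in the elastic coupling", {
  cfg <- solver_config(tol = 1e-10, quad_nodes = 61)
  st1 <- solve_phase(phase_spec(1, 0, gamma = 0.05), NULL, cfg, 0.5)
  g12s <- c(0.01, 0.1, 1, 10, 100, 1e4, 1e6)
  ov <- vapply(g12s, function(g12) {
    st2 <- solve_phase(phase_spec(1, 1, gamma = 0.05, gamma_link = g12),
                       st1, cfg, 0.5)
    (st2$cross_r + st2$cross_i) /
      sqrt((st2$Qr + st2$Qi) * (st1$Qr + st1$Qi))
  }, numeric(1))
  expect_true(all(diff(ov) > -1e-8))
  # strongest coupling reproduces the anchor
  stp <- solve_phase(phase_spec(1, 1, gamma = 0.05, gamma_link = 1e6),
                     st1, cfg, 0.5)
  expect_equal(stp$Qr, st1$Qr, tolerance = 1e-4)
  expect_equal(stp$R, st1$R, tolerance = 1e-4)
})

test_that("run_strategy composes phases with the right symmetries", {
  cfg <- solver_config(tol = 1e-9, quad_nodes = 61)
  one <- list(theory_slice(1, 0.8, 0.5))
  res <- lapply(c("curriculum", "anti-curriculum", "none"), function(s)
    run_strategy(one, s, gammas = 0.05, gamma12 = 0.3, cfg = cfg))
  expect_equal(res[[1]]$accuracy_hard, res[[2]]$accuracy_hard)
  expect_equal(res[[1]]$accuracy_hard, res[[3]]$accuracy_hard)

  # equal difficulties and sizes: curriculum and anti-curriculum coincide
  two <- list(theory_slice(0.5, 1, 0.5), theory_slice(0.5, 1 + 1e-9, 0.5))
  rc <- run_strategy(two, "curriculum", 0.05, 0.3, cfg)
  ra <- run_strategy(two, "anti-curriculum", 0.05, 0.3, cfg)
  expect_equal(rc$accuracy_hard, ra$accuracy_hard, tolerance = 1e-6)

  # errors propagate: non-normalisable phase
  expect_error(phase_spec(1, 1, gamma = 0), "positive")
})
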