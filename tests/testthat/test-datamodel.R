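test_that("teacher construction respects sparsity, norm and determinism", {
  tch <- make_teacher(1000, 0.5, seed = 3)
  expect_equal(tch$n_rel, 500)
  expect_true(all(tch$weights[501:1000] == 0))
  expect_true(all(tch$weights[1:500] != 0))
  expect_identical(tch$weights, make_teacher(1000, 0.5, seed = 3)$weights)

  # no zero block at the sparsity boundary
  full <- make_teacher(50, 1, seed = 1)
  expect_true(all(full$weights != 0))

  # empirical norm concentrates on rho (3 standard errors; var of w^2 is 2)
  big <- make_teacher(10000, 0.5, seed = 5)
  se <- sqrt(2 * 0.5 / 10000)
  expect_lt(abs(big$T_emp - 0.5), 3 * se)

  expect_error(make_teacher(100, 0), "rho")
  expect_error(make_teacher(100, 1.2), "rho")
  expect_error(make_teacher(10, 0.01), "at least 1")
  expect_error(make_teacher(-5, 0.5), "positive integer")
})

test_that("slices have the stratified covariance and teacher-blind labels", {
  tch <- make_teacher(1000, 0.5, seed = 1)

  sl0 <- sample_slice(tch, alpha = 0.2, delta = 0, seed = 2)
  expect_true(all(sl0$X[, 501:1000] == 0))
  expect_true(all(sl0$y %in% c(-1, 1)))

  sl <- sample_slice(tch, alpha = 1, delta = 1, seed = 2)
  # irrelevant sample variance within 3 standard errors of delta = 1
  v <- sl$X[, 501:1000]
  expect_lt(abs(mean(v^2) - 1), 3 * sqrt(2 / length(v)))
  # relevant variance is 1
  vr <- sl$X[, 1:500]
  expect_lt(abs(mean(vr^2) - 1), 3 * sqrt(2 / length(vr)))

  # labels depend only on relevant coordinates
  f <- sl$X[, 1:500] %*% tch$weights[1:500]
  expect_identical(sl$y, ifelse(drop(f) >= 0, 1, -1))
  X2 <- sl$X
  X2[, 501:1000] <- X2[, 501:1000] + matrix(rnorm(500 * 1000, sd = 5),
                                            1000, 500)
  f2 <- X2[, 1:500] %*% tch$weights[1:500]
  expect_identical(ifelse(drop(f2) >= 0, 1, -1), sl$y)

  # rho = 1: no irrelevant block, label is sign of the full dot product
  t1 <- make_teacher(200, 1, seed = 4)
  s1 <- sample_slice(t1, alpha = 0.5, delta = 3, seed = 5)
  expect_identical(s1$y, ifelse(drop(s1$X %*% t1$weights) >= 0, 1, -1))

  # bit-identical reproducibility
  expect_identical(sample_slice(tch, 0.1, 0.5, seed = 9)$X,
                   sample_slice(tch, 0.1, 0.5, seed = 9)$X)
  expect_error(sample_slice(tch, 0.1, -1, seed = 1), "non-negative")
})

test_that("empirical order parameters split at the relevant boundary", {
  tch <- make_teacher(10000, 0.5, seed = 2)
  # self-overlap
  op <- empirical_order_params(tch$weights, tch)
  expect_equal(op$Qr, tch$T_emp)
  expect_equal(op$Qi, 0)
  expect_equal(op$R, tch$T_emp)
  # zero student
  op0 <- empirical_order_params(rep(0, 10000), tch)
  expect_equal(unlist(op0[c("Qr", "Qi", "R")]), c(Qr = 0, Qi = 0, R = 0))
  # random unit-variance student concentrates
  set.seed(7)
  w <- rnorm(10000)
  opr <- empirical_order_params(w, tch)
  expect_lt(abs(opr$Qr - 0.5), 3 / sqrt(10000) * sqrt(2))
  expect_lt(abs(opr$Qi - 0.5), 3 / sqrt(10000) * sqrt(2))
  expect_lt(abs(opr$R), 3 / sqrt(10000))
  expect_error(empirical_order_params(rnorm(10), tch), "mismatch")
})

test_that("schedules order slices by difficulty as requested", {
  sl <- list(theory_slice(1, 1, 0.5), theory_slice(0.5, 0, 0.5))
  expect_equal(make_schedule(sl, "curriculum")$deltas, c(0, 1))
  expect_equal(make_schedule(sl, "anti-curriculum")$deltas, c(1, 0))
  expect_equal(sort(make_schedule(sl, "none")$deltas), c(0, 1))
  # single slice: all strategies coincide
  one <- list(theory_slice(1, 0.5, 0.5))
  for (s in c("curriculum", "anti-curriculum", "none"))
    expect_equal(make_schedule(one, s)$deltas, 0.5)
  expect_error(make_schedule(sl, "nonsense"))
  # ties are allowed and stable: both orderings coincide (symmetry null)
  dup <- list(theory_slice(1, 1, 0.5), theory_slice(0.5, 1, 0.5))
  expect_equal(make_schedule(dup, "curriculum")$alphas,
               make_schedule(dup, "anti-curriculum")$alphas)
})

test_that("order_params validates its invariants", {
  expect_error(order_params(-1, 0, 0, 1), "non-negative")
  expect_error(order_params(1, 0, 0, 0), "positive")
  expect_error(order_params(0.1, 0, 1, 0.5), "Cauchy-Schwarz")
  expect_silent(order_params(1, 1, sqrt(0.5), 0.5))
})

test_that("slice serialisation round-trips through CSV + JSON sidecar", {
  tch <- make_teacher(40, 0.5, seed = 1)
  sl <- sample_slice(tch, alpha = 0.5, delta = 0.7, seed = 2)
  path <- file.path(tempdir(), "slice_test.csv")
  write_slice(sl, path)
  back <- read_slice(path)
  expect_equal(back$X, sl$X, tolerance = 1e-12)
  expect_identical(back$y, sl$y)
  expect_equal(back[c("N", "M", "rho", "delta", "alpha", "seed")],
               sl[c("N", "M", "rho", "delta", "alpha", "seed")])
  unlink(c(path, paste0(path, ".json")))
})
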