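small_online_search <- list(eta = c(1, 3), gamma = c(0, 1e-4),
                            sigma0_sq = 1e-4)
small_batch_search <- list(gamma = c(0.01, 0.1), gamma12 = c(0, 1))

test_that("optimise_cell returns the singleton point and skips dominated ones", {
  single <- list(eta = 3, gamma = 1e-5, sigma0_sq = 1e-4)
  res <- optimise_cell(1, 1, 0, 1, 0.5, "curriculum", single,
                       "online_theory", N_theory = 2000)
  direct <- run_theory(two_slice("curriculum"),
                       online_config(3, 1e-5, 1e-4, 2000), n_record = 2)
  expect_equal(res$accuracy, trajectory_accuracy(direct, 2, 1))
  expect_equal(res$best$eta, 3)
  expect_true(res$valid)

  # eta = 0 (chance accuracy) is never selected over a learning rate > 0
  dom <- optimise_cell(1, 1, 0, 1, 0.5, "curriculum",
                       list(eta = c(0, 2), gamma = 0, sigma0_sq = 1e-4),
                       "online_theory", N_theory = 2000)
  expect_gt(dom$best$eta, 0)
})

test_that("equal difficulties give unit accuracy ratios everywhere", {
  gs <- grid_spec(alpha_total = 1, alpha1 = 0.5, delta1 = 0.6, delta2 = 0.6,
                  search = small_online_search, backend = "online_theory")
  pd <- phase_diagram(gs, N_theory = 1000)
  expect_equal(pd$ratios$ratio_curr_none, 1, tolerance = 1e-9)
  expect_equal(pd$ratios$ratio_curr_anti, 1, tolerance = 1e-9)
})

test_that("a 1x1 diagram equals direct optimise_cell calls", {
  gs <- grid_spec(alpha_total = 1.5, alpha1 = 0.5,
                  search = small_online_search, backend = "online_theory")
  pd <- phase_diagram(gs, N_theory = 1000)
  for (s in c("curriculum", "none")) {
    direct <- optimise_cell(0.5, 1, 0, 1, 0.5, s, small_online_search,
                            "online_theory", N_theory = 1000)
    expect_equal(pd$cells$accuracy[pd$cells$strategy == s], direct$accuracy)
  }
})

test_that("cached cells reproduce fresh computation exactly", {
  gs <- grid_spec(alpha_total = 1, alpha1 = 0.5,
                  search = small_online_search, backend = "online_theory")
  cache <- file.path(tempdir(), "pd_cache_test")
  unlink(cache, recursive = TRUE)
  fresh <- phase_diagram(gs, cache_dir = cache, N_theory = 1000)
  cached <- phase_diagram(gs, cache_dir = cache, N_theory = 1000)
  expect_identical(fresh$cells, cached$cells)
  expect_identical(fresh$ratios, cached$ratios)
  unlink(cache, recursive = TRUE)
})

test_that("difficulty_scan evaluates ratio curves at fixed end states", {
  ops <- list(curriculum = order_params(1, 0.2, 0.6, 0.5),
              none = order_params(1, 0.4, 0.55, 0.5))
  tab <- difficulty_scan(ops, delta_grid = c(0, 0.5, 1))
  # at delta = 0 only (Qr, R) matter
  a0 <- tab$accuracy[tab$strategy == "curriculum" & tab$delta == 0]
  expect_equal(a0, accuracy(order_params(1, 0, 0.6, 0.5), 0))
  # identical end states give unit ratio at every difficulty
  same <- difficulty_scan(list(curriculum = ops$none, none = ops$none),
                          delta_grid = c(0, 1, 2))
  expect_equal(same$ratio_to_none, rep(1, 6))
})

test_that("sparsity_scan handles the empty-easy-slice edge", {
  tab <- sparsity_scan(0.5, c(0, 0.5), backend = "online_theory",
                       search = small_online_search, N_theory = 1000)
  # alpha1 = 0: all strategies train on the hard slice only -> ratio 1
  r0 <- tab[tab$alpha1 == 0, ]
  expect_equal(r0$ratio_curr_none, 1, tolerance = 1e-9)
  expect_equal(r0$ratio_curr_anti, 1, tolerance = 1e-9)
})

test_that("batch backend optimisation works on a minimal grid", {
  res <- optimise_cell(0.5, 0.5, 0, 1, 0.5, "curriculum",
                       small_batch_search, "batch_theory",
                       solver = solver_config(tol = 1e-7, quad_nodes = 41))
  expect_true(res$valid)
  expect_true(res$accuracy > 0.5 && res$accuracy <= 1)
  expect_true(all(c("gamma", "gamma12") %in% names(res$best)))
})
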