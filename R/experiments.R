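## Experiment drivers: per-cell hyperparameter optimisation and the
## accuracy-ratio maps over dataset composition, difficulty and sparsity.

#' Default hyperparameter search spaces
#'
#' Desk-scale log-spaced grids: for the online backend, learning rate
#' `eta` (13 points in \[1e-2, 10\]), weight decay `gamma` (11 points in
#' \[1e-6, 1e-1\] plus 0) and initial variance `sigma0_sq` in
#' `{1e-4, 1e-2, 1}`; for the batch backend, ridge `gamma` (15 points in
#' \[1e-4, 10\]) and elastic coupling `gamma12` (16 points in
#' \[1e-3, 100\] plus 0).
#'
#' @name default_search
#' @return Named list of grids.
NULL

#' @rdname default_search
#' @export
default_search_online <- function() {
  list(eta = 10^seq(-2, 1, length.out = 13),
       gamma = c(0, 10^seq(-6, -1, length.out = 11)),
       sigma0_sq = c(1e-4, 1e-2, 1))
}

#' @rdname default_search
#' @export
default_search_batch <- function() {
  list(gamma = 10^seq(-4, 1, length.out = 15),
       gamma12 = c(0, 10^seq(-3, 2, length.out = 16)))
}

#' Optimise hyperparameters for one strategy in one cell
#'
#' Grid search maximising the final accuracy on the hard partition
#' (`delta2`). The online backend integrates [run_theory()] over
#' `(eta, gamma, sigma0_sq)`; the batch backend solves the RS saddle points
#' over `(gamma, gamma12)`, warm-starting along the coupling grid.
#' Non-convergent grid points are skipped and counted; a cell where every
#' point fails is marked invalid.
#'
#' @param alpha1,alpha2 easy / hard sample-size ratios.
#' @param delta1,delta2 easy / hard difficulties (`delta1 < delta2`).
#' @param rho teacher sparsity.
#' @param strategy `"curriculum"`, `"anti-curriculum"` or `"none"`.
#' @param search named list of grids ([default_search_online()] or
#'   [default_search_batch()]).
#' @param backend `"online_theory"` or `"batch_theory"`.
#' @param N_theory step resolution for the online backend.
#' @param solver a [solver_config()] for the batch backend.
#' @return List with `accuracy` (best final hard-instance accuracy), `best`
#'   (argmax hyperparameters), `n_ok`, `n_failed`, and `valid`.
#' @export
optimise_cell <- function(alpha1, alpha2, delta1, delta2, rho,
                          strategy = c("curriculum", "anti-curriculum",
                                       "none"),
                          search, backend = c("online_theory",
                                              "batch_theory"),
                          N_theory = 1e4,
                          solver = solver_config(tol = 1e-8,
                                                 quad_nodes = 61)) {
  strategy <- match.arg(strategy)
  backend <- match.arg(backend)
  best <- list(accuracy = -Inf, best = NULL)
  n_ok <- 0L
  n_failed <- 0L
  single <- alpha1 <= 0  # empty easy slice: every strategy reduces to the
                         # hard-slice-only problem
  if (backend == "online_theory") {
    slices <- if (single) list(theory_slice(alpha2, delta2, rho))
              else list(theory_slice(alpha1, delta1, rho),
                        theory_slice(alpha2, delta2, rho))
    ## equal difficulties: presentation order is immaterial online, so the
    ## pooled mixture stands in for every strategy
    strat <- if (single || delta1 == delta2) "none" else strategy
    sched <- make_schedule(slices, strat)
    for (s02 in search$sigma0_sq) for (gm in search$gamma)
      for (et in search$eta) {
        acc <- tryCatch({
          traj <- run_theory(sched, online_config(et, gm, s02, N_theory),
                             n_record = 2)
          trajectory_accuracy(traj, alpha1 + alpha2, delta2)
        }, error = function(e) NA_real_)
        if (is.na(acc)) { n_failed <- n_failed + 1L; next }
        n_ok <- n_ok + 1L
        if (acc > best$accuracy)
          best <- list(accuracy = acc,
                       best = list(eta = et, gamma = gm, sigma0_sq = s02))
      }
  } else {
    deltas <- c(delta1, delta2)
    alphas <- c(alpha1, alpha2)
    if (single) { deltas <- delta2; alphas <- alpha2 }
    ord <- switch(strategy, "curriculum" = order(deltas),
                  "anti-curriculum" = order(-deltas), "none" = NULL)
    for (gm in search$gamma) {
      if (strategy == "none" || single) {
        acc <- tryCatch({
          st <- solve_phase(phase_spec(alphas, deltas, gm), NULL, solver,
                            rho)
          suppressMessages(accuracy(saddle_order_params(st), delta2))
        }, error = function(e) NA_real_)
        if (is.na(acc)) { n_failed <- n_failed + 1L; next }
        n_ok <- n_ok + 1L
        if (acc > best$accuracy)
          best <- list(accuracy = acc, best = list(gamma = gm))
        next
      }
      st1 <- tryCatch(
        solve_phase(phase_spec(alphas[ord[1]], deltas[ord[1]], gm), NULL,
                    solver, rho),
        error = function(e) NULL)
      if (is.null(st1)) { n_failed <- n_failed + length(search$gamma12); next }
      cfg2 <- solver
      for (g12 in sort(search$gamma12)) {
        acc <- tryCatch({
          st2 <- solve_phase(
            phase_spec(alphas[ord[2]], deltas[ord[2]], gm, g12), st1, cfg2,
            rho)
          cfg2$init <- st2[c("Qr", "Qi", "R", "chi_r", "chi_i")]
          suppressMessages(accuracy(saddle_order_params(st2), delta2))
        }, error = function(e) NA_real_)
        if (is.na(acc)) { n_failed <- n_failed + 1L; next }
        n_ok <- n_ok + 1L
        if (acc > best$accuracy)
          best <- list(accuracy = acc, best = list(gamma = gm, gamma12 = g12))
      }
    }
  }
  list(accuracy = if (n_ok > 0) best$accuracy else NA_real_,
       best = best$best, n_ok = n_ok, n_failed = n_failed, valid = n_ok > 0)
}

#' Grid specification for a phase diagram
#'
#' @param alpha_total,alpha1 axes: total dataset size and easy-slice size
#'   (cells with `alpha1 >= alpha_total` are skipped).
#' @param delta1,delta2,rho task parameters.
#' @param strategies strategies to compare.
#' @param search hyperparameter search space.
#' @param backend `"online_theory"` or `"batch_theory"`.
#' @export
grid_spec <- function(alpha_total, alpha1, delta1 = 0, delta2 = 1, rho = 0.5,
                      strategies = c("curriculum", "anti-curriculum", "none"),
                      search = NULL, backend = c("online_theory",
                                                 "batch_theory")) {
  backend <- match.arg(backend)
  if (is.null(search))
    search <- if (backend == "online_theory") default_search_online()
              else default_search_batch()
  stopifnot(length(alpha_total) >= 1, length(alpha1) >= 1)
  structure(list(alpha_total = alpha_total, alpha1 = alpha1, delta1 = delta1,
                 delta2 = delta2, rho = rho, strategies = strategies,
                 search = search, backend = backend), class = "grid_spec")
}

#' Accuracy-ratio phase diagram over dataset composition
#'
#' For every `(alpha_total, alpha1)` cell and every strategy, optimises
#' hyperparameters via [optimise_cell()] and tabulates the best
#' hard-instance accuracy; pairwise accuracy ratios
#' (curriculum/none, anti/none, curriculum/anti) are derived columns.
#' Per-cell results can be cached on disk (`cache_dir`) and are saved
#' incrementally, so an interrupted scan resumes where it stopped.
#'
#' @param grid a [grid_spec()].
#' @param cache_dir optional directory for per-cell cache files.
#' @param ... passed to [optimise_cell()] (e.g. `N_theory`, `solver`).
#' @return A `phase_diagram` object: `cells` (long data.frame of
#'   `alpha_total, alpha1, strategy, accuracy, ...best parameters`) and
#'   `ratios` (wide data.frame with the pairwise ratio columns).
#' @export
phase_diagram <- function(grid, cache_dir = NULL, ...) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  rows <- list()
  for (at in grid$alpha_total) for (a1 in grid$alpha1) {
    if (a1 >= at) next
    for (strat in grid$strategies) {
      key <- sprintf("cell_%g_%g_%s.rds", at, a1, strat)
      cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, key)
      if (!is.null(cache_file) && file.exists(cache_file)) {
        res <- readRDS(cache_file)
      } else {
        res <- optimise_cell(a1, at - a1, grid$delta1, grid$delta2,
                             grid$rho, strat, grid$search, grid$backend,
                             ...)
        if (!is.null(cache_file)) saveRDS(res, cache_file)
      }
      rows[[length(rows) + 1]] <- data.frame(
        alpha_total = at, alpha1 = a1, strategy = strat,
        accuracy = res$accuracy, valid = res$valid,
        n_failed = res$n_failed)
    }
  }
  cells <- do.call(rbind, rows)
  ratios <- NULL
  wide <- split(cells, list(cells$alpha_total, cells$alpha1), drop = TRUE)
  ratios <- do.call(rbind, lapply(wide, function(d) {
    g <- function(s) if (s %in% d$strategy) d$accuracy[d$strategy == s]
                     else NA_real_
    data.frame(alpha_total = d$alpha_total[1], alpha1 = d$alpha1[1],
               curriculum = g("curriculum"), anti = g("anti-curriculum"),
               none = g("none"),
               ratio_curr_none = g("curriculum") / g("none"),
               ratio_anti_none = g("anti-curriculum") / g("none"),
               ratio_curr_anti = g("curriculum") / g("anti-curriculum"))
  }))
  rownames(ratios) <- NULL
  structure(list(cells = cells, ratios = ratios, grid = grid),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> backend = %s, %d cells\n", x$grid$backend,
              nrow(x$ratios)))
  print(utils::head(x$ratios, 10), row.names = FALSE)
  invisible(x)
}

#' Accuracy versus test difficulty for trained end states
#'
#' Evaluates the closed-form accuracy across a grid of test difficulties at
#' each strategy's final order parameters, and the accuracy ratio of every
#' strategy to the shuffled baseline (when present).
#'
#' @param end_states named list of final [order_params()] (one per
#'   strategy; names are the strategy labels).
#' @param delta_grid difficulties to evaluate.
#' @return Data.frame `strategy, delta, accuracy, ratio_to_none`.
#' @export
difficulty_scan <- function(end_states, delta_grid) {
  stopifnot(is.list(end_states), length(names(end_states)) > 0)
  tab <- do.call(rbind, lapply(names(end_states), function(nm) {
    op <- .as_op(end_states[[nm]])
    data.frame(strategy = nm, delta = delta_grid,
               accuracy = vapply(delta_grid, function(d)
                 suppressMessages(accuracy(op, d)), numeric(1)))
  }))
  if ("none" %in% names(end_states)) {
    none <- tab$accuracy[tab$strategy == "none"]
    tab$ratio_to_none <- tab$accuracy / none[match(tab$delta, delta_grid)]
  } else {
    tab$ratio_to_none <- NA_real_
  }
  tab
}

#' Curriculum benefit across teacher sparsity and easy-slice size
#'
#' At fixed total dataset size, optimises each strategy per
#' `(rho, alpha1)` and reports the accuracy ratios of curriculum over the
#' shuffled baseline and over anti-curriculum.
#'
#' @param rho_grid sparsity values.
#' @param alpha1_grid easy-slice sizes (must stay below `alpha_total`).
#' @param backend `"online_theory"` or `"batch_theory"`.
#' @param alpha_total total dataset size (default 1).
#' @param delta1,delta2 easy / hard difficulties.
#' @param search hyperparameter grids (backend default if `NULL`).
#' @param ... passed to [optimise_cell()].
#' @return Data.frame
#'   `rho, alpha1, curriculum, anti, none, ratio_curr_none, ratio_curr_anti`.
#' @export
sparsity_scan <- function(rho_grid, alpha1_grid, backend = c("online_theory",
                                                             "batch_theory"),
                          alpha_total = 1, delta1 = 0, delta2 = 1,
                          search = NULL, ...) {
  backend <- match.arg(backend)
  if (is.null(search))
    search <- if (backend == "online_theory") default_search_online()
              else default_search_batch()
  rows <- list()
  for (rho in rho_grid) for (a1 in alpha1_grid) {
    if (a1 >= alpha_total) next
    accs <- vapply(c("curriculum", "anti-curriculum", "none"), function(s)
      optimise_cell(a1, alpha_total - a1, delta1, delta2, rho, s, search,
                    backend, ...)$accuracy, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      rho = rho, alpha1 = a1, curriculum = accs[1], anti = accs[2],
      none = accs[3], ratio_curr_none = accs[1] / accs[3],
      ratio_curr_anti = accs[1] / accs[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
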