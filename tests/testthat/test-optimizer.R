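fit_three <- function(des, responses, lambda = 0) {
  list(size_nm = fit_tps(des, responses$size_nm, lambda = lambda,
                         transform = "log10", response = "size_nm"),
       pdi = fit_tps(des, responses$pdi, lambda = lambda, response = "pdi"),
       le_pct = fit_tps(des, responses$le_pct, lambda = lambda,
                        response = "le_pct"))
}

test_that("a single bowl-shaped objective is minimized at its analytic optimum", {
  # centered bowl on the standard design: by symmetry the interpolant's
  # minimum coincides with the bowl's
  des <- standard_design()
  X <- coded_matrix(des)
  fit_c <- fit_tps(des, X[, 1]^2 + X[, 2]^2, response = "pdi")
  opt_c <- find_optimum(list(pdi = fit_c),
                        objective_spec(c(pdi = "minimize")))
  expect_lt(max(abs(opt_c$par_coded)), 1e-3)

  # off-center bowl sampled densely enough that the interpolant tracks it
  gx <- seq(-1, 1, length.out = 9)
  Xd <- as.matrix(expand.grid(gx, gx))
  a <- 0.3
  b <- -0.2
  fit <- fit_tps(design_from_coded(Xd),
                 (Xd[, 1] - a)^2 + (Xd[, 2] - b)^2, response = "pdi")
  opt <- find_optimum(list(pdi = fit),
                      objective_spec(c(pdi = "minimize")))
  expect_lt(max(abs(opt$par_coded - c(a, b))), 1e-3)
  expect_equal(unname(opt$predicted["pdi"]),
               predict(fit, matrix(opt$par_coded, 1, 2)),
               tolerance = 1e-10)
})

test_that("mirror-symmetric competing objectives settle on the symmetry line", {
  des <- standard_design()
  X <- coded_matrix(des)
  y1 <- (X[, 1] - 0.5)^2 + X[, 2]^2
  y2 <- (X[, 1] + 0.5)^2 + X[, 2]^2
  surfaces <- list(r1 = fit_tps(des, y1, response = "r1"),
                   r2 = fit_tps(des, y2, response = "r2"))
  opt <- find_optimum(surfaces,
                      objective_spec(c(r1 = "minimize", r2 = "minimize")))
  expect_lt(abs(opt$par_coded[["pressure_A"]]), 1e-3)
})

test_that("the optimum stays inside the box and beats every grid node", {
  des <- standard_design()
  set.seed(3)
  responses <- data.frame(size_nm = 10^stats::rnorm(10, 2.4, 0.1),
                          pdi = stats::runif(10, 0.2, 0.5),
                          le_pct = stats::runif(10, 5, 20))
  surfaces <- fit_three(des, responses)
  spec <- objective_spec(standard_goals())
  opt <- find_optimum(surfaces, spec, resolution = 61)
  expect_true(all(opt$par >= c(400, 350) - 1e-9))
  expect_true(all(opt$par <= c(800, 750) + 1e-9))
  expect_equal(unname(opt$predicted),
               unname(vapply(surfaces, predict, numeric(1),
                             newdata = matrix(opt$par_coded, 1, 2))),
               tolerance = 1e-10)
})

test_that("grid search plus polish agrees with a fine-grid oracle", {
  des <- standard_design()
  set.seed(17)
  for (trial in 1:5) {
    responses <- data.frame(size_nm = 10^stats::rnorm(10, 2.4, 0.08),
                            pdi = stats::runif(10, 0.2, 0.6),
                            le_pct = stats::runif(10, 5, 25))
    surfaces <- fit_three(des, responses)
    spec <- objective_spec(standard_goals())
    opt <- find_optimum(surfaces, spec, resolution = 41)

    # oracle: naive prediction over a much finer grid, same scalarization
    axes <- seq(-1, 1, length.out = 161)
    grid <- as.matrix(expand.grid(axes, axes))
    preds <- lapply(surfaces, function(s) {
      oracle_tps_predict(s$nodes, s$weights, s$poly_coeffs, grid)
    })
    u <- mapply(function(p, goal) {
      v <- (p - min(p)) / (max(p) - min(p))
      if (goal == "maximize") v <- 1 - v
      v
    }, preds, standard_goals())
    best <- grid[which.min(sqrt(rowSums(u^2))), ]
    cell <- 2 / 40  # coarse-grid cell width in coded units
    expect_true(all(abs(opt$par_coded - best) <= cell + 1e-9))
  }
})

test_that("relabelling pressure units rescales the optimum consistently", {
  des_hpa <- standard_design()
  f_kpa <- list(factor_spec("pressure_A", 40, 80, unit = "kPa"),
                factor_spec("pressure_B", 35, 75, unit = "kPa"))
  des_kpa <- make_ccd(f_kpa)
  set.seed(23)
  responses <- data.frame(size_nm = 10^stats::rnorm(10, 2.4, 0.1),
                          pdi = stats::runif(10, 0.2, 0.5),
                          le_pct = stats::runif(10, 5, 20))
  spec <- objective_spec(standard_goals())
  opt1 <- find_optimum(fit_three(des_hpa, responses), spec)
  opt2 <- find_optimum(fit_three(des_kpa, responses), spec)
  expect_equal(opt1$par_coded, opt2$par_coded, tolerance = 1e-10)
  expect_equal(unname(opt1$par), unname(10 * opt2$par), tolerance = 1e-8)
})

test_that("desirability scalarization agrees with distance where they must", {
  des <- standard_design()
  X <- coded_matrix(des)
  # single response: both scalarizations are monotone in the same
  # prediction, so the optimum coincides
  fit <- fit_tps(des, X[, 1]^2 + X[, 2]^2, response = "pdi")
  o_dist <- find_optimum(list(pdi = fit),
                         objective_spec(c(pdi = "minimize")))
  o_des <- find_optimum(list(pdi = fit),
                        objective_spec(c(pdi = "minimize"),
                                       method = "desirability"))
  expect_lt(max(abs(o_dist$par_coded - o_des$par_coded)), 1e-3)
  expect_lt(o_des$objective, 0)  # negated overall desirability

  # mirror-symmetric pair stays on the symmetry line under both
  surfaces <- list(
    r1 = fit_tps(des, (X[, 1] - 0.5)^2 + X[, 2]^2, response = "r1"),
    r2 = fit_tps(des, (X[, 1] + 0.5)^2 + X[, 2]^2, response = "r2"))
  o2 <- find_optimum(surfaces,
                     objective_spec(c(r1 = "minimize", r2 = "minimize"),
                                    method = "desirability"))
  expect_lt(abs(o2$par_coded[["pressure_A"]]), 1e-3)
})

test_that("flat surfaces are dropped from the objective with a warning", {
  des <- standard_design()
  X <- coded_matrix(des)
  surfaces <- list(flat = fit_tps(des, rep(2, 10), response = "flat"),
                   bowl = fit_tps(des, rowSums(X^2), response = "bowl"))
  spec <- objective_spec(c(flat = "minimize", bowl = "minimize"))
  expect_warning(opt <- find_optimum(surfaces, spec, resolution = 41),
                 "flat")
  expect_lt(max(abs(opt$par_coded)), 1e-3)
})

test_that("bootstrap summaries are reproducible and account for every resample", {
  des <- standard_design()
  sim <- generate_experiment(synthetic_config(seed = 30), des)
  spec <- objective_spec(standard_goals())
  b1 <- bootstrap_optimum(des, sim$responses, spec, B = 40, seed = 99,
                          transforms = standard_transforms())
  b2 <- bootstrap_optimum(des, sim$responses, spec, B = 40, seed = 99,
                          transforms = standard_transforms())
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$mean, b2$mean)
  expect_equal(nrow(b1$draws), 40L)
  expect_true(all(b1$sd >= 0))

  # a different master seed gives a different resample sequence
  b3 <- bootstrap_optimum(des, sim$responses, spec, B = 40, seed = 100,
                          transforms = standard_transforms())
  expect_false(identical(b1$draws, b3$draws))

  expect_error(bootstrap_optimum(des, sim$responses, spec, B = 0,
                                 seed = 1), "positive integer")
  small <- des[1:3, , drop = FALSE]
  attr(small, "factors") <- attr(des, "factors")
  expect_error(bootstrap_optimum(small, sim$responses[1:3, ], spec,
                                 B = 5, seed = 1), "at least 4")
})

test_that("shorter bootstrap runs are prefixes of longer ones under one master seed", {
  des <- standard_design()
  sim <- generate_experiment(synthetic_config(seed = 12), des)
  spec <- objective_spec(standard_goals())
  b_long <- bootstrap_optimum(des, sim$responses, spec, B = 120, seed = 5,
                              transforms = standard_transforms())
  b_short <- bootstrap_optimum(des, sim$responses, spec, B = 40, seed = 5,
                               transforms = standard_transforms())
  expect_identical(b_short$draws, b_long$draws[1:40, ])
})

test_that("bootstrap spread of the optimum grows with measurement noise", {
  des <- standard_design()
  spec <- objective_spec(standard_goals())
  sd_at <- function(scale, seed) {
    cfg <- synthetic_config(sigma_size = 0.01 * scale,
                            sigma_pdi = 0.03 * scale,
                            sigma_le = 0.4 * scale, seed = seed)
    sim <- generate_experiment(cfg, des)
    b <- bootstrap_optimum(des, sim$responses, spec, B = 60, seed = seed,
                           transforms = standard_transforms())
    mean(b$sd[c("pressure_A", "pressure_B")])
  }
  lo <- vapply(1:5, function(s) sd_at(0.2, s), numeric(1))
  hi <- vapply(1:5, function(s) sd_at(6, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("stability tables flag converged and diverged solution sets", {
  mk <- function(B, means) {
    structure(list(B = as.integer(B), seed = 1,
                   mean = means, sd = means * 0,
                   draws = NULL, n_redrawn = 0L),
              class = "bootstrap_summary")
  }
  m <- c(pressure_A = 600, pressure_B = 550)
  st <- bootstrap_stability(list(mk(100, m), mk(200, m)))
  expect_true(attr(st, "stable"))
  expect_equal(st$spread, c(0, 0))

  st2 <- bootstrap_stability(list(mk(100, m), mk(200, m * 1.2)))
  expect_false(attr(st2, "stable"))

  expect_error(bootstrap_stability(list(mk(100, m))), ">= 2")
  expect_error(bootstrap_stability(list(mk(100, m), mk(100, m))),
               "distinct B")
  expect_error(
    bootstrap_stability(list(mk(100, m), mk(200, c(x = 1, y = 2)))),
    "components")
})

test_that("bootstrap-mean spread across B shrinks as B grows", {
  des <- standard_design()
  spec <- objective_spec(standard_goals())
  spread_for <- function(Bs, seed) {
    cfg <- synthetic_config(sigma_size = 0.01, sigma_pdi = 0.03,
                            sigma_le = 0.4, seed = seed)
    sim <- generate_experiment(cfg, des)
    sums <- lapply(Bs, function(B) {
      bootstrap_optimum(des, sim$responses, spec, B = B, seed = seed,
                        transforms = standard_transforms())
    })
    st <- bootstrap_stability(sums)
    mean(st$spread[st$component %in% c("pressure_A", "pressure_B")])
  }
  small_B <- vapply(1:3, function(s) spread_for(c(25, 50), s), numeric(1))
  large_B <- vapply(1:3, function(s) spread_for(c(400, 800), s), numeric(1))
  expect_lt(mean(large_B), mean(small_B))
})
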