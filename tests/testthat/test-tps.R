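test_that("lambda = 0 surfaces interpolate distinct nodes exactly", {
  des <- standard_design()
  X <- coded_matrix(des)
  y <- X[, 1]^2 + X[, 2]^2
  fit <- fit_tps(des, y)
  nodes <- unique(X)
  expect_lt(max(abs(predict(fit, nodes) - (nodes[, 1]^2 + nodes[, 2]^2))),
            1e-8)
  # side conditions: radial weights orthogonal to affine functions
  expect_lt(abs(sum(fit$weights)), 1e-8)
  expect_lt(max(abs(colSums(fit$weights * fit$nodes))), 1e-8)
})

test_that("replicated coordinates are averaged into one node before solving", {
  des <- standard_design()
  y <- rep(0, 10)
  y[des$role == "center"] <- c(1, 3)
  fit <- fit_tps(des, y)
  expect_equal(nrow(fit$nodes), 9L)
  expect_equal(predict(fit, matrix(c(0, 0), 1, 2)), 2, tolerance = 1e-8)
})

test_that("fit and prediction match an independently coded dense solve", {
  set.seed(41)
  for (trial in 1:20) {
    n <- sample(6:12, 1)
    lambda <- sample(c(0, 0.01, 0.5), 1)
    X <- random_nodes(n)
    y <- stats::rnorm(n)
    fit <- fit_tps(design_from_coded(X), y, lambda = lambda)
    ora <- oracle_tps_solve(X, y, lambda = lambda)
    expect_equal(unname(fit$weights), unname(ora$w), tolerance = 1e-7)
    expect_equal(unname(fit$poly_coeffs), unname(ora$c), tolerance = 1e-7)
    pts <- random_nodes(25)
    expect_lt(max(abs(predict(fit, pts) -
                        oracle_tps_predict(X, ora$w, ora$c, pts))), 1e-10)
  }
})

test_that("node residuals grow monotonically with the smoothing parameter", {
  set.seed(7)
  X <- random_nodes(9)
  y <- stats::rnorm(9)
  des <- design_from_coded(X)
  rss <- vapply(c(0, 1e-4, 1e-2, 0.1, 1, 10), function(lam) {
    fit <- fit_tps(des, y, lambda = lam)
    sum((predict(fit, X) - y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-10))
})

test_that("fitting is invariant to run order", {
  des <- standard_design()
  set.seed(11)
  y <- stats::rnorm(10)
  perm <- sample(10)
  des2 <- des[perm, , drop = FALSE]
  attr(des2, "factors") <- attr(des, "factors")
  f1 <- fit_tps(des, y)
  f2 <- fit_tps(des2, y[perm])
  pts <- random_nodes(30)
  expect_equal(predict(f1, pts), predict(f2, pts), tolerance = 1e-10)
})

test_that("a constant response yields the constant surface", {
  des <- standard_design()
  fit <- fit_tps(des, rep(4.2, 10))
  expect_lt(max(abs(fit$weights)), 1e-8)
  expect_equal(predict(fit, random_nodes(10)), rep(4.2, 10),
               tolerance = 1e-8)
})

test_that("log10-transformed surfaces back-transform on request", {
  des <- standard_design()
  X <- coded_matrix(des)
  size <- 10^(2.3 + 0.1 * rowSums(X^2))
  fit <- fit_tps(des, size, transform = "log10", response = "size_nm")
  at <- matrix(c(1, 1), 1, 2)
  expect_equal(predict(fit, at, type = "response"),
               10^predict(fit, at), tolerance = 1e-12)
  expect_equal(predict(fit, at, type = "response"), 10^2.5,
               tolerance = 1e-6)
})

test_that("degenerate fits are rejected with a diagnosis", {
  des <- standard_design()
  expect_error(fit_tps(des, c(rep(1, 9), NA)), "finite")
  expect_error(fit_tps(des, rep(-1, 10), transform = "log10"), "positive")
  collinear <- design_from_coded(cbind(seq(-1, 1, length.out = 6), 0))
  expect_error(fit_tps(collinear, stats::rnorm(6)), "collinear")
  few <- design_from_coded(matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2,
                                  byrow = TRUE))
  expect_error(fit_tps(few, stats::rnorm(4)), "at least 5 distinct")
  fit <- fit_tps(des, stats::rnorm(10))
  expect_error(predict(fit, matrix(0, 1, 3)), "dimensionality")
  expect_error(predict(fit, matrix(c(0, NA), 1, 2)), "finite")
})

test_that("surface grids cover the requested box and warn on extrapolation", {
  des <- standard_design()
  X <- coded_matrix(des)
  fit <- fit_tps(des, 19 - 4 * rowSums(X^2), response = "le_pct")
  g2 <- surface_grid(fit, resolution = 2)
  expect_equal(nrow(g2), 4L)
  expect_setequal(g2$pressure_A, c(400, 800))
  expect_setequal(g2$pressure_B, c(350, 750))
  g <- surface_grid(fit, resolution = 21)
  expect_lte(min(g$value), max(g$value))
  expect_equal(g$response, rep("le_pct", 441))
  expect_warning(
    surface_grid(fit, resolution = 3,
                 bounds = list(c(0, 1500), c(350, 750))),
    "extrapolate")
})
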