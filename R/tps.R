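#' Fit a thin-plate-spline response surface
#'
#' Fits the exact thin-plate spline f(x) = c0 + c'x + sum_i w_i phi(||x -
#' node_i||), phi(r) = r^2 log r, to one response over the coded factor
#' space by solving the augmented linear system
#' \deqn{[K + \lambda I, P; P', 0] [w; c] = [y; 0]}
#' where K is the kernel matrix over the (deduplicated) design points and
#' P = \[1, X\] the affine basis. The side conditions P'w = 0 make the
#' radial part orthogonal to affine trends and minimize bending energy.
#' With `lambda = 0` the surface interpolates the node values exactly;
#' `lambda > 0` trades exactness for smoothness (ridge on the kernel
#' block). Replicated coordinates — the center replicates of a central
#' composite design — are averaged into a single node before solving,
#' since an interpolant cannot take two values at one point.
#'
#' Fitting is carried out in coded (-1..+1) units: the thin-plate kernel is
#' not scale-invariant, and coding makes factors with different natural
#' ranges commensurate. Responses spanning decades (particle size) are
#' usually modelled on the log10 scale via `transform`.
#'
#' @param design a [make_ccd()] design (coded coordinates are taken from it).
#' @param y numeric response, one value per design run, finite.
#' @param lambda non-negative smoothing parameter (default 0, interpolation).
#' @param transform modelling scale: `"identity"` or `"log10"` (requires
#'   positive `y`).
#' @param response label used in printing and exports.
#' @return A `tps_surface` with elements `nodes` (coded, deduplicated),
#'   `weights`, `poly_coeffs` (intercept then one slope per factor),
#'   `lambda`, `transform`, `response`, `factors`, and `node_values`
#'   (replicate-averaged transformed responses).
#' @seealso [predict.tps_surface()], [loocv_r()], [surface_grid()]
#' @examples
#' des <- make_ccd(list(factor_spec("pressure_A", 400, 800),
#'                      factor_spec("pressure_B", 350, 750)))
#' X <- coded_matrix(des)
#' fit <- fit_tps(des, 0.3 + 0.05 * rowSums(X^2), response = "pdi")
#' predict(fit, data.frame(pressure_A = 600, pressure_B = 550),
#'         units = "natural")
#' @export
fit_tps <- function(design, y, lambda = 0,
                    transform = c("identity", "log10"),
                    response = "response") {
  transform <- match.arg(transform)
  X <- coded_matrix(design)
  k <- ncol(X)
  if (!is.numeric(y) || length(y) != nrow(X)) {
    stop("'y' must supply one value per design run", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("'y' contains non-finite values", call. = FALSE)
  .assert_scalar_number(lambda, "lambda")
  if (lambda < 0) stop("'lambda' must be non-negative", call. = FALSE)
  if (transform == "log10") {
    if (any(y <= 0)) stop("log10 transform requires positive responses",
                          call. = FALSE)
    y <- log10(y)
  }

  dd <- .dedupe_nodes(X, y)
  q <- nrow(dd$nodes)
  if (q < k + 3L) {
    stop(sprintf(
      "thin-plate fit needs at least %d distinct design points (got %d)",
      k + 3L, q), call. = FALSE)
  }
  P <- cbind(1, dd$nodes)
  if (qr(P)$rank < k + 1L) {
    stop("singular thin-plate system: design points are collinear",
         call. = FALSE)
  }
  K <- .tps_phi(.pairdist2(dd$nodes, dd$nodes)) + lambda * diag(q)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, k + 1L, k + 1L)))
  z <- tryCatch(solve(M, c(dd$values, rep(0, k + 1L))),
                error = function(e) {
                  stop("singular thin-plate system: ", conditionMessage(e),
                       call. = FALSE)
                })

  fnames <- vapply(attr(design, "factors"), `[[`, character(1), "name")
  structure(list(
    nodes = dd$nodes,
    weights = z[seq_len(q)],
    poly_coeffs = stats::setNames(z[q + seq_len(k + 1L)],
                                  c("(Intercept)", fnames)),
    lambda = lambda,
    transform = transform,
    response = response,
    factors = attr(design, "factors"),
    node_values = dd$values
  ), class = "tps_surface")
}

# average responses observed at coincident coordinates (to 1e-9)
.dedupe_nodes <- function(X, y) {
  key <- apply(round(X, 9), 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  nodes <- X[first, , drop = FALSE]
  values <- vapply(key[first],
                   function(kk) mean(y[key == kk]), numeric(1))
  list(nodes = nodes, values = unname(values))
}

#' @export
print.tps_surface <- function(x, ...) {
  cat(sprintf("Thin-plate spline surface for '%s' (%s scale)\n",
              x$response, x$transform))
  cat(sprintf("  %d nodes, lambda = %g\n", nrow(x$nodes), x$lambda))
  invisible(x)
}

#' Predict from a thin-plate-spline surface
#'
#' Evaluates f(x) = poly(x) + sum_i w_i phi(||x - node_i||) at arbitrary
#' points, with phi(0) = 0 by continuity.
#'
#' @param object a `tps_surface`.
#' @param newdata matrix or data frame of evaluation points; columns in
#'   factor order (or named by factor).
#' @param units `"coded"` (default) or `"natural"`; natural coordinates are
#'   encoded through the surface's factor bounds first.
#' @param type `"transformed"` returns values on the modelling scale (e.g.
#'   log10 size); `"response"` back-transforms to the original scale.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.tps_surface <- function(object, newdata,
                                units = c("coded", "natural"),
                                type = c("transformed", "response"), ...) {
  units <- match.arg(units)
  type <- match.arg(type)
  X <- .as_points(newdata, object$factors)
  if (ncol(X) != ncol(object$nodes)) {
    stop("prediction points have wrong dimensionality", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("prediction points must be finite", call. = FALSE)
  if (units == "natural") X <- encode_levels(X, object$factors)
  pred <- drop(cbind(1, X) %*% object$poly_coeffs +
                 .tps_phi(.pairdist2(X, object$nodes)) %*% object$weights)
  if (type == "response" && object$transform == "log10") pred <- 10^pred
  unname(pred)
}

.as_points <- function(newdata, factors) {
  nms <- vapply(factors, `[[`, character(1), "name")
  if (is.data.frame(newdata)) {
    if (all(nms %in% names(newdata))) newdata <- newdata[, nms, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = length(nms))
  storage.mode(newdata) <- "double"
  newdata
}

#' Evaluate a fitted surface on a regular grid
#'
#' Produces the long-format table behind a response-surface plot: a
#' `resolution` x `resolution` grid in natural units with the predicted
#' response per cell.
#'
#' @param surface a `tps_surface`.
#' @param resolution grid points per axis (>= 2).
#' @param bounds optional list of `c(low, high)` per factor (natural
#'   units); defaults to the factor bounds. Bounds reaching beyond the
#'   coded design box by more than `margin` (fraction of the factor range)
#'   trigger an extrapolation warning.
#' @param type passed to [predict.tps_surface()]; `"response"` (default)
#'   back-transforms, so a log10-modelled size grid is in nm.
#' @param margin allowed extrapolation fraction (default 0.25).
#' @return data frame: one natural-unit column per factor, `response`,
#'   `value`.
#' @export
surface_grid <- function(surface, resolution = 50L, bounds = NULL,
                         type = c("response", "transformed"),
                         margin = 0.25) {
  type <- match.arg(type)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution < 2) {
    stop("'resolution' must be an integer >= 2", call. = FALSE)
  }
  f <- surface$factors
  nms <- vapply(f, `[[`, character(1), "name")
  if (is.null(bounds)) {
    bounds <- lapply(f, function(fi) c(fi$low, fi$high))
  }
  if (length(bounds) != length(f)) {
    stop("'bounds' must give c(low, high) per factor", call. = FALSE)
  }
  for (j in seq_along(f)) {
    r <- f[[j]]$high - f[[j]]$low
    if (bounds[[j]][1] < f[[j]]$low - margin * r ||
        bounds[[j]][2] > f[[j]]$high + margin * r) {
      warning(sprintf("grid bounds for '%s' extrapolate beyond the design box",
                      nms[j]), call. = FALSE)
    }
  }
  axes <- lapply(seq_along(f), function(j) {
    seq(bounds[[j]][1], bounds[[j]][2], length.out = resolution)
  })
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nms
  grid$response <- surface$response
  grid$value <- predict(surface, grid[, nms, drop = FALSE],
                        units = "natural", type = type)
  grid
}
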