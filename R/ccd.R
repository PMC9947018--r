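#' Describe one experimental factor
#'
#' A factor specification holds the label, unit and natural-unit bounds of a
#' single controllable factor (for the microfluidic application, a pump
#' pressure in hPa). The bounds map to the coded levels -1 and +1 of the
#' design; axial runs of a rotatable design fall outside them.
#'
#' @param name factor label, e.g. `"pressure_A"`. Must be non-empty.
#' @param low natural value at coded level -1.
#' @param high natural value at coded level +1. Must exceed `low`.
#' @param unit measurement unit label (default `"hPa"`).
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("pressure_A", 400, 800)
#' @export
factor_spec <- function(name, low, high, unit = "hPa") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("factor 'name' must be a non-empty string", call. = FALSE)
  }
  .assert_scalar_number(low, "low")
  .assert_scalar_number(high, "high")
  if (low >= high) stop("factor bounds require low < high", call. = FALSE)
  structure(list(name = name, unit = unit, low = low, high = high),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s': [%g, %g] %s (coded -1..+1)\n",
              x$name, x$low, x$high, x$unit))
  invisible(x)
}

.check_factors <- function(factors) {
  if (!is.list(factors) || length(factors) < 2L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a list of at least two factor_spec objects",
         call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("factor names must be unique", call. = FALSE)
  factors
}

#' Generate a central composite design
#'
#' Builds a two-level full factorial (all coded combinations of -1/+1),
#' adds 2k axial runs at coded distance `alpha` along each axis, and
#' `n_center` replicated center runs, in that order (center runs last).
#' This is the classic layout for fitting curved response surfaces; with
#' two factors, a rotatable alpha of sqrt(2) and two center replicates it
#' yields the 10-run design used to map pump-pressure effects on particle
#' size, PdI and loading efficiency.
#'
#' @param factors list of [factor_spec()] objects (k >= 2).
#' @param alpha axial coded distance: a positive number, `"rotatable"`
#'   (2^(k/4), which makes prediction variance a function of distance from
#'   the center only), or `"face"` (1, axial runs on the factorial faces).
#' @param n_center number of replicated center runs (>= 0).
#' @return A `ccd_design`: a data frame with columns `run_id`, `role`
#'   (factorial/axial/center), one coded column `<name>_coded` and one
#'   natural-unit column `<name>` per factor. The factor specifications are
#'   kept in the `"factors"` attribute.
#' @examples
#' des <- make_ccd(list(factor_spec("pressure_A", 400, 800),
#'                      factor_spec("pressure_B", 350, 750)),
#'                 alpha = "rotatable", n_center = 2)
#' nrow(des)  # 4 factorial + 4 axial + 2 center = 10
#' @export
make_ccd <- function(factors, alpha = "rotatable", n_center = 2L) {
  factors <- .check_factors(factors)
  k <- length(factors)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 0 ||
      n_center != round(n_center)) {
    stop("'n_center' must be a non-negative integer", call. = FALSE)
  }
  if (is.character(alpha)) {
    alpha <- match.arg(alpha, c("rotatable", "face"))
    alpha <- if (alpha == "rotatable") 2^(k / 4) else 1
  } else {
    .assert_scalar_number(alpha, "alpha")
    if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  }

  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, n_center, k)
  coded <- rbind(corners, axial, center)
  dimnames(coded) <- NULL
  role <- c(rep("factorial", nrow(corners)),
            rep("axial", nrow(axial)),
            rep("center", n_center))

  nms <- vapply(factors, `[[`, character(1), "name")
  des <- data.frame(run_id = seq_len(nrow(coded)), role = role,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    f <- factors[[j]]
    des[[paste0(nms[j], "_coded")]] <- coded[, j]
    des[[nms[j]]] <- f$low + (coded[, j] + 1) / 2 * (f$high - f$low)
  }
  structure(des, factors = factors, alpha = alpha,
            class = c("ccd_design", "data.frame"))
}

#' @export
print.ccd_design <- function(x, ...) {
  f <- attr(x, "factors")
  cat(sprintf("Central composite design: %d runs, %d factors (alpha = %.4f)\n",
              nrow(x), length(f), attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Extract the coded design matrix
#'
#' @param design a `ccd_design` (or any data frame carrying a `factors`
#'   attribute and `<name>_coded` columns).
#' @return numeric matrix, one row per run, one column per factor.
#' @export
coded_matrix <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor specifications", call. = FALSE)
  nms <- vapply(f, `[[`, character(1), "name")
  as.matrix(design[, paste0(nms, "_coded"), drop = FALSE])
}

#' Convert coded design coordinates to natural units
#'
#' Applies natural = low + (coded + 1)/2 * (high - low) per factor.
#'
#' @param design a `ccd_design`.
#' @return data frame of natural coordinates (one column per factor).
#' @export
decode_levels <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("design carries no factor specifications", call. = FALSE)
  coded <- coded_matrix(design)
  out <- as.data.frame(encode_or_decode(coded, f, decode = TRUE))
  names(out) <- vapply(f, `[[`, character(1), "name")
  out
}

#' Convert natural coordinates to coded units
#'
#' Inverse of [decode_levels()]: coded = 2 (natural - low)/(high - low) - 1.
#'
#' @param x matrix or data frame of natural coordinates, columns ordered (or
#'   named) as in `factors`.
#' @param factors list of [factor_spec()] objects.
#' @return numeric matrix of coded coordinates.
#' @export
encode_levels <- function(x, factors) {
  factors <- .check_factors(factors)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (is.data.frame(x)) {
    if (all(nms %in% names(x))) x <- x[, nms, drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = length(factors))
  if (ncol(x) != length(factors)) {
    stop("'x' must have one column per factor", call. = FALSE)
  }
  encode_or_decode(x, factors, decode = FALSE)
}

encode_or_decode <- function(x, factors, decode) {
  out <- x
  for (j in seq_along(factors)) {
    f <- factors[[j]]
    if (f$high == f$low) stop("degenerate factor bounds (low == high)",
                              call. = FALSE)
    out[, j] <- if (decode) {
      f$low + (x[, j] + 1) / 2 * (f$high - f$low)
    } else {
      2 * (x[, j] - f$low) / (f$high - f$low) - 1
    }
  }
  colnames(out) <- vapply(factors, `[[`, character(1), "name")
  out
}
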