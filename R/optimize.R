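#' Declare optimization goals for a set of responses
#'
#' @param goals named character vector mapping each response to
#'   `"minimize"` or `"maximize"`, e.g.
#'   `c(size_nm = "minimize", pdi = "minimize", le_pct = "maximize")`.
#' @param weights positive weights, recycled to the number of responses
#'   (default: equal).
#' @param method how [find_optimum()] combines the responses:
#'   `"distance"` (weighted Euclidean distance from the ideal point,
#'   default) or `"desirability"` (weighted geometric mean of per-response
#'   desirabilities, maximized).
#' @return an `objective_spec`.
#' @export
objective_spec <- function(goals, weights = 1,
                           method = c("distance", "desirability")) {
  method <- match.arg(method)
  if (is.null(names(goals)) || any(!nzchar(names(goals)))) {
    stop("'goals' must be a named vector (one entry per response)",
         call. = FALSE)
  }
  goals <- vapply(goals, match.arg, character(1),
                  choices = c("minimize", "maximize"))
  weights <- rep_len(weights, length(goals))
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("'weights' must be positive and finite", call. = FALSE)
  }
  structure(list(goals = goals,
                 weights = stats::setNames(weights, names(goals)),
                 method = method),
            class = "objective_spec")
}

#' Find the multi-objective optimum over fitted surfaces
#'
#' Scalarizes several fitted response surfaces into a single
#' distance-from-ideal score and minimizes it over a rectangular search
#' box. Each surface's predictions over the search grid are min-max
#' normalized to \[0, 1\]; responses to be maximized are reflected so that
#' 0 is always ideal; the score is the weighted Euclidean distance to the
#' ideal point (all zeros). An [objective_spec()] with
#' `method = "desirability"` swaps the score for the negated weighted
#' geometric mean of per-response desirabilities d = 1 - u (Derringer-type
#' overall desirability). The minimizer is located by dense grid search
#' (first-found lowest cell in row-major order breaks exact ties, making
#' the search deterministic) and then polished by box-constrained
#' quasi-Newton refinement with the normalization anchors frozen.
#'
#' For the siRNA-vesicle application the three surfaces are particle size
#' (log10 scale), PdI and loading efficiency, with size and PdI minimized
#' and loading efficiency maximized.
#'
#' @param surfaces named list of [fit_tps()] surfaces sharing one factor
#'   space; names must match `spec`.
#' @param spec an [objective_spec()].
#' @param box optional list of `c(low, high)` per factor in natural units;
#'   defaults to the factor bounds (no extrapolation beyond the coded
#'   design box).
#' @param resolution grid points per axis for the dense search (default 201).
#' @param polish logical: refine the best cell with `optim(L-BFGS-B)`.
#' @return An `optimum`: list with `par` (natural units), `par_coded`,
#'   `predicted` (per response, transformed scale), `predicted_response`
#'   (back-transformed), `objective`, `spec`, and `diagnostics`.
#' @export
find_optimum <- function(surfaces, spec, box = NULL, resolution = 201L,
                         polish = TRUE) {
  stopifnot(inherits(spec, "objective_spec"))
  if (!is.list(surfaces) || is.null(names(surfaces)) ||
      !all(vapply(surfaces, inherits, logical(1), "tps_surface"))) {
    stop("'surfaces' must be a named list of tps_surface objects",
         call. = FALSE)
  }
  if (!setequal(names(surfaces), names(spec$goals))) {
    stop("surface names and objective goals must match", call. = FALSE)
  }
  surfaces <- surfaces[names(spec$goals)]
  factors <- surfaces[[1]]$factors
  fnames <- vapply(factors, `[[`, character(1), "name")
  for (s in surfaces) {
    if (!identical(vapply(s$factors, `[[`, character(1), "name"), fnames)) {
      stop("all surfaces must share one factor space", call. = FALSE)
    }
  }
  k <- length(factors)
  if (is.null(box)) box <- lapply(factors, function(f) c(f$low, f$high))
  if (length(box) != k ||
      any(vapply(box, function(b) length(b) != 2L || b[1] >= b[2],
                 logical(1)))) {
    stop("'box' must give c(low, high) with low < high per factor",
         call. = FALSE)
  }
  if (!is.numeric(resolution) || resolution < 2) {
    stop("'resolution' must be >= 2", call. = FALSE)
  }

  box_nat <- do.call(rbind, box)
  box_coded <- encode_levels(t(box_nat), factors)  # 2 x k: rows lo/hi
  axes <- lapply(seq_len(k), function(j) {
    seq(box_coded[1, j], box_coded[2, j], length.out = resolution)
  })
  # row-major order: first axis varies fastest is expand.grid's column-major;
  # which.min over this layout is the documented deterministic tie-break
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))

  # all resample fits share one node set; compute the kernel matrix once
  same_nodes <- all(vapply(surfaces[-1], function(s) {
    identical(s$nodes, surfaces[[1]]$nodes)
  }, logical(1)))
  preds <- if (same_nodes) {
    Phi <- .tps_phi(.pairdist2(grid, surfaces[[1]]$nodes))
    Pg <- cbind(1, grid)
    lapply(surfaces, function(s) {
      drop(Pg %*% s$poly_coeffs + Phi %*% s$weights)
    })
  } else {
    lapply(surfaces, predict, newdata = grid)
  }
  anchors <- lapply(preds, range)
  keep <- vapply(anchors, function(a) diff(a) > 1e-12 * max(1, abs(a[2])),
                 logical(1))
  if (!any(keep)) stop("all surfaces are flat over the search box",
                       call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("flat surface(s) dropped from the objective: %s",
                    paste(names(surfaces)[!keep], collapse = ", ")),
            call. = FALSE)
  }

  normalize <- function(p, nm) {
    a <- anchors[[nm]]
    u <- (p - a[1]) / (a[2] - a[1])
    if (spec$goals[[nm]] == "maximize") u <- 1 - u
    u
  }
  kept <- names(surfaces)[keep]
  wsum <- sum(spec$weights[kept])
  combine <- function(u_list) {
    if (spec$method == "distance") {
      sqrt(Reduce(`+`, lapply(kept, function(nm) {
        spec$weights[[nm]] * u_list[[nm]]^2
      })))
    } else {
      # overall desirability (weighted geometric mean), negated so that
      # the search can minimize; u outside [0,1] counts as undesirable
      d <- Reduce(`*`, lapply(kept, function(nm) {
        pmax(1 - u_list[[nm]], 0)^spec$weights[[nm]]
      }))
      -d^(1 / wsum)
    }
  }
  score_at <- function(x) {
    # x: matrix of coded points
    combine(stats::setNames(lapply(kept, function(nm) {
      normalize(predict(surfaces[[nm]], x), nm)
    }), kept))
  }

  scores <- combine(stats::setNames(lapply(kept, function(nm) {
    normalize(preds[[nm]], nm)
  }), kept))
  best <- which.min(scores)
  x0 <- grid[best, ]
  iters <- 0L
  if (polish) {
    opt <- stats::optim(x0, function(p) score_at(matrix(p, nrow = 1L)),
                        method = "L-BFGS-B",
                        lower = box_coded[1, ], upper = box_coded[2, ])
    if (opt$value <= scores[best]) {
      x0 <- opt$par
      iters <- opt$counts[["function"]]
    }
  }

  par_coded <- stats::setNames(as.numeric(x0), fnames)
  par_nat <- drop(encode_or_decode(matrix(x0, nrow = 1L), factors,
                                   decode = TRUE))
  predicted <- vapply(surfaces, predict,
                      numeric(1), newdata = matrix(x0, nrow = 1L))
  predicted_resp <- vapply(names(surfaces), function(nm) {
    predict(surfaces[[nm]], matrix(x0, nrow = 1L), type = "response")
  }, numeric(1))

  structure(list(
    par = par_nat,
    par_coded = par_coded,
    predicted = predicted,
    predicted_response = predicted_resp,
    objective = score_at(matrix(x0, nrow = 1L)),
    spec = spec,
    diagnostics = list(resolution = as.integer(resolution),
                       polish_evals = iters,
                       dropped = names(surfaces)[!keep],
                       box = box_nat)
  ), class = "optimum")
}

#' @export
print.optimum <- function(x, ...) {
  cat("Multi-objective optimum\n")
  for (nm in names(x$par)) cat(sprintf("  %s = %.4f\n", nm, x$par[[nm]]))
  cat("Predicted responses (transformed scale):\n")
  for (nm in names(x$predicted)) {
    cat(sprintf("  %s = %.4f\n", nm, x$predicted[[nm]]))
  }
  lab <- if (x$spec$method == "desirability") {
    "negated overall desirability"
  } else "distance from ideal"
  cat(sprintf("Objective (%s): %.6f\n", lab, x$objective))
  invisible(x)
}
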