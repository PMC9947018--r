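#' Leave-one-out cross-validated accuracy of a surface
#'
#' Scores how well a thin-plate-spline surface generalizes across the
#' design: each physical run is held out in turn (a center replicate's
#' twin stays in), the surface is refitted on the remaining runs, and the
#' held-out response is predicted. Accuracy is summarized by the Pearson
#' correlation r between held-out predictions and observations on the
#' modelling (transformed) scale — the conventional surrogate-model
#' accuracy score for small designed experiments, where r near 1 marks a
#' response the design resolves well and r near 0 one dominated by noise.
#'
#' @inheritParams fit_tps
#' @return A `loocv_report`: list with `response`, `r`, and a
#'   `predictions` data frame (`run_id`, `observed`, `predicted`, `valid`)
#'   on the transformed scale.
#' @details Folds whose reduced design cannot be fitted (too few distinct
#'   points or a singular system) are flagged invalid and dropped from r
#'   with a warning.
#' @export
loocv_r <- function(design, y, lambda = 0,
                    transform = c("identity", "log10"),
                    response = "response") {
  transform <- match.arg(transform)
  n <- nrow(design)
  if (n < 4L) stop("leave-one-out needs at least 4 runs", call. = FALSE)
  if (!is.numeric(y) || length(y) != n) {
    stop("'y' must supply one value per design run", call. = FALSE)
  }
  yt <- if (transform == "log10") log10(y) else y
  if (stats::sd(yt) == 0) {
    stop("constant response: leave-one-out correlation is undefined",
         call. = FALSE)
  }

  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- design[-i, , drop = FALSE]
    attr(sub, "factors") <- attr(design, "factors")
    fit_i <- tryCatch(
      fit_tps(sub, y[-i], lambda = lambda, transform = transform,
              response = response),
      error = function(e) NULL)
    if (!is.null(fit_i)) {
      pred[i] <- predict(fit_i, coded_matrix(design)[i, , drop = FALSE])
    }
  }
  valid <- !is.na(pred)
  if (any(!valid)) {
    warning(sprintf("%d of %d leave-one-out folds could not be fitted; r %s",
                    sum(!valid), n, "computed over the remaining folds"),
            call. = FALSE)
  }
  r <- stats::cor(pred[valid], yt[valid])
  structure(list(
    response = response,
    r = r,
    predictions = data.frame(run_id = design$run_id, observed = yt,
                             predicted = pred, valid = valid)
  ), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out accuracy for '%s': r = %.4f (%d/%d folds)\n",
              x$response, x$r, sum(x$predictions$valid),
              nrow(x$predictions)))
  invisible(x)
}

#' Choose the smoothing parameter by generalized cross-validation
#'
#' Evaluates GCV(lambda) = q * RSS(lambda) / (q - tr S(lambda))^2 over a
#' grid of candidate lambdas, where S is the smoother matrix mapping the
#' (replicate-averaged) node values to fitted values and q the number of
#' distinct nodes, and returns the minimizer. At lambda = 0 (pure
#' interpolation) the criterion is a degenerate 0/0 and is scored as
#' infinite, so the minimizer is always a strictly positive lambda; pass
#' `lambda = 0` to [fit_tps()] directly when exact interpolation is wanted.
#'
#' @inheritParams fit_tps
#' @param lambdas candidate smoothing values (non-negative).
#' @return list with `lambda` (the GCV minimizer) and the `gcv` table.
#' @export
gcv_lambda <- function(design, y, lambdas = c(0, 10^seq(-6, 1, by = 0.5)),
                       transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  X <- coded_matrix(design)
  k <- ncol(X)
  yt <- if (transform == "log10") log10(y) else y
  dd <- .dedupe_nodes(X, yt)
  q <- nrow(dd$nodes)
  P <- cbind(1, dd$nodes)
  K0 <- .tps_phi(.pairdist2(dd$nodes, dd$nodes))
  scores <- vapply(lambdas, function(lam) {
    M <- rbind(cbind(K0 + lam * diag(q), P),
               cbind(t(P), matrix(0, k + 1L, k + 1L)))
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) return(Inf)
    S <- cbind(K0, P) %*% Minv[, seq_len(q), drop = FALSE]
    fitted <- drop(S %*% dd$values)
    edf <- sum(diag(S))
    denom <- q - edf
    if (denom <= .Machine$double.eps^0.5) return(Inf)
    q * sum((dd$values - fitted)^2) / denom^2
  }, numeric(1))
  best <- which.min(scores)
  list(lambda = lambdas[best],
       gcv = data.frame(lambda = lambdas, gcv = scores))
}
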