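#' Bootstrap the optimal solution
#'
#' Quantifies how stable the multi-objective optimum is under resampling
#' of the experiment: draws `B` resamples of the physical runs with
#' replacement, refits every response surface on each resample, re-runs
#' [find_optimum()], and summarizes the `B` optima component-wise by mean
#' and standard deviation. A tight spread means the optimum is determined
#' by the data rather than by individual runs.
#'
#' Center replicates are resampled as individual physical runs;
#' replicate-averaging of coincident coordinates happens afterwards,
#' inside each fit. Resamples with too few distinct coordinates to
#' support a thin-plate fit are rejected and redrawn (the count is
#' reported in the summary). Each resample derives its own RNG substream
#' deterministically from `seed` and the resample index, so results are
#' fully reproducible and the first 1000 resamples of a `B = 5000` run
#' coincide with a `B = 1000` run under the same master seed.
#'
#' @param design a [make_ccd()] design (n >= 4 runs).
#' @param responses data frame aligned with `design`, one column per
#'   response named as in `spec` (plus an ignored `run_id` column if
#'   present).
#' @param spec an [objective_spec()].
#' @param B number of bootstrap resamples (>= 1).
#' @param seed master seed (integer).
#' @param transforms named character vector of modelling scales per
#'   response (`"identity"`/`"log10"`); defaults to identity for all.
#' @param lambda smoothing parameter passed to every fit.
#' @param resolution grid resolution for each resample's optimization
#'   (default 61; coarser than a one-shot [find_optimum()] because
#'   averaging over resamples smooths out grid quantization).
#' @param polish passed to [find_optimum()]; off by default here — the
#'   polish moves each resample's optimum by far less than the bootstrap
#'   spread at several times the cost.
#' @param box passed to [find_optimum()].
#' @param max_redraw cap on redraws per resample slot.
#' @return A `bootstrap_summary`: list with `B`, `seed`, `mean`, `sd`
#'   (named vectors over factor coordinates, transformed predicted
#'   responses, and the objective), `draws` (one row per accepted
#'   resample), and `n_redrawn`.
#' @export
bootstrap_optimum <- function(design, responses, spec, B, seed,
                              transforms = NULL, lambda = 0,
                              resolution = 61L, polish = FALSE, box = NULL,
                              max_redraw = 100L) {
  stopifnot(inherits(spec, "objective_spec"))
  n <- nrow(design)
  if (n < 4L) stop("bootstrap needs at least 4 runs", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B)) {
    stop("'B' must be a positive integer", call. = FALSE)
  }
  .assert_scalar_number(seed, "seed")
  rnames <- names(spec$goals)
  if (!all(rnames %in% names(responses))) {
    stop("'responses' must contain a column per objective response",
         call. = FALSE)
  }
  if (nrow(responses) != n) {
    stop("'responses' rows must align with design runs", call. = FALSE)
  }
  if (is.null(transforms)) {
    transforms <- stats::setNames(rep("identity", length(rnames)), rnames)
  }

  fit_resample <- function(idx) {
    sub <- design[idx, , drop = FALSE]
    attr(sub, "factors") <- attr(design, "factors")
    surfaces <- lapply(rnames, function(nm) {
      fit_tps(sub, responses[[nm]][idx], lambda = lambda,
              transform = transforms[[nm]], response = nm)
    })
    names(surfaces) <- rnames
    find_optimum(surfaces, spec, box = box, resolution = resolution,
                 polish = polish)
  }

  draws <- vector("list", B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    res <- NULL
    for (attempt in seq_len(max_redraw)) {
      set.seed(.substream_seed(seed, b, attempt))
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(fit_resample(idx), error = function(e) NULL)
      if (!is.null(res)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(res)) {
      stop(sprintf("resample %d failed %d times; data too degenerate",
                   b, max_redraw), call. = FALSE)
    }
    draws[[b]] <- c(res$par, res$predicted, objective = res$objective)
  }
  draws <- as.data.frame(do.call(rbind, draws))

  structure(list(
    B = as.integer(B),
    seed = seed,
    mean = vapply(draws, mean, numeric(1)),
    sd = vapply(draws, stats::sd, numeric(1)),
    draws = draws,
    n_redrawn = n_redrawn
  ), class = "bootstrap_summary")
}

# deterministic 31-bit substream seed per (master, resample, attempt)
.substream_seed <- function(master, b, attempt) {
  h <- (abs(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((h + b * 69621 + attempt * 7919) %% 2147483647)
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("Bootstrap of the optimal solution: B = %d (seed %s, %d redrawn)\n",
              x$B, format(x$seed), x$n_redrawn))
  tab <- data.frame(mean = x$mean, sd = x$sd)
  print(tab, ...)
  invisible(x)
}

#' Compare bootstrap summaries across resample counts
#'
#' Checks whether the bootstrap-mean optimal solution has converged in the
#' number of resamples B: for every summarized component, computes the
#' maximum spread of the means across the supplied summaries relative to
#' the component's mean magnitude, and flags the solution stable when all
#' spreads fall below `threshold`.
#'
#' @param summaries list of [bootstrap_optimum()] results with distinct B.
#' @param threshold relative-spread threshold (default 0.01, i.e. 1%).
#' @return A `stability_table` data frame: `component`, `spread` (relative),
#'   `spread_pct`, `stable`, with attribute `stable` — the overall flag,
#'   which covers the solution components (factor settings and predicted
#'   responses) but not the derived scalar objective score.
#' @export
bootstrap_stability <- function(summaries, threshold = 0.01) {
  if (!is.list(summaries) || length(summaries) < 2L ||
      !all(vapply(summaries, inherits, logical(1), "bootstrap_summary"))) {
    stop("'summaries' must be a list of >= 2 bootstrap_summary objects",
         call. = FALSE)
  }
  Bs <- vapply(summaries, `[[`, integer(1), "B")
  if (anyDuplicated(Bs)) stop("summaries must have distinct B", call. = FALSE)
  comp <- names(summaries[[1]]$mean)
  for (s in summaries) {
    if (!identical(names(s$mean), comp)) {
      stop("summaries report different components", call. = FALSE)
    }
  }
  means <- do.call(rbind, lapply(summaries, `[[`, "mean"))
  spread <- apply(means, 2L, function(v) {
    scale <- mean(abs(v))
    if (scale == 0) return(0)
    (max(v) - min(v)) / scale
  })
  out <- data.frame(component = comp, spread = spread,
                    spread_pct = 100 * spread,
                    stable = spread < threshold, row.names = NULL)
  attr(out, "B") <- sort(Bs)
  # the solution is the factor settings and predicted responses; the
  # scalar objective score is derived and excluded from the overall flag
  attr(out, "stable") <- all(out$stable[out$component != "objective"])
  class(out) <- c("stability_table", "data.frame")
  out
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("Optimal-solution stability across B = {%s}: %s\n",
              paste(attr(x, "B"), collapse = ", "),
              if (attr(x, "stable")) "stable" else "NOT stable"))
  print.data.frame(x, ...)
  invisible(x)
}
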