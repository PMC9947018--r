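#' Configure a synthetic formulation experiment
#'
#' Defines ground-truth response surfaces over a two-pressure factor box,
#' mimicking the structure seen when siRNA-vesicle formulations are mapped
#' over microfluidic pump pressures: particle size (log10 scale) and PdI
#' are bowls with a minimum near the center of the box, loading efficiency
#' is a dome peaking there. Each truth function is quadratic in the
#' normalized offset from its own optimum,
#' `f(x) = level +/- curvature * sum_j ((x_j - opt_j)/halfrange_j)^2`,
#' so fitted thin-plate splines face genuine model mismatch. Gaussian
#' noise is added per response (on the log10 scale for size).
#'
#' Defaults describe a 400-800 / 350-750 hPa pressure box with a joint
#' optimum at its center (600, 550), a size floor of 195 nm, a PdI floor
#' of 0.29 and a loading-efficiency peak of 19.3%; noise levels
#' (sigma_size = 0.02 log10 units, sigma_pdi = 0.06, sigma_le = 0.8%)
#' are calibrated so that leave-one-out accuracy is high for size and
#' loading efficiency but low for PdI, the pattern typical of these
#' assays where PdI is by far the noisiest readout.
#'
#' @param factors list of two [factor_spec()]s (the pressure box).
#' @param size_opt,pdi_opt,le_opt natural-unit coordinates of each
#'   response's own optimum.
#' @param size_floor_nm minimum true particle size (nm) at `size_opt`.
#' @param size_curv curvature of log10(size) per squared normalized offset.
#' @param pdi_floor,pdi_curv minimum true PdI and its curvature.
#' @param le_peak,le_curv maximum true loading efficiency (%) and its
#'   (downward) curvature.
#' @param sigma_size,sigma_pdi,sigma_le noise SDs (log10 units, PdI units,
#'   LE percentage points).
#' @param assay_le_pct,assay_suppression_pct,assay_suppression_ref_pct,assay_colocal
#'   ground truth for the auxiliary assay tables: true loading efficiency,
#'   true gene suppression for the vesicle formulation and for the
#'   reference transfection reagent, and the fractions where siRNA and
#'   particles co-localize.
#' @param seed integer seed used by [generate_experiment()].
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(
    factors = list(factor_spec("pressure_A", 400, 800),
                   factor_spec("pressure_B", 350, 750)),
    size_opt = c(600, 550), size_floor_nm = 195, size_curv = 0.13,
    pdi_opt = c(600, 550), pdi_floor = 0.29, pdi_curv = 0.07,
    le_opt = c(600, 550), le_peak = 19.3, le_curv = 4.5,
    sigma_size = 0.02, sigma_pdi = 0.06, sigma_le = 0.8,
    assay_le_pct = 11, assay_suppression_pct = 52.7,
    assay_suppression_ref_pct = 85.2, assay_colocal = c(8L, 9L),
    seed = 1L) {
  factors <- .check_factors(factors)
  for (v in list(size_curv, pdi_curv, le_curv)) {
    if (!is.finite(v) || v <= 0) stop("curvatures must be positive",
                                      call. = FALSE)
  }
  if (size_floor_nm <= 0) stop("size floor must be positive (nm)",
                               call. = FALSE)
  if (pdi_floor < 0 || pdi_floor > 1) stop("PdI floor must lie in [0, 1]",
                                           call. = FALSE)
  if (le_peak < 0 || le_peak > 100) stop("LE peak must lie in [0, 100]",
                                         call. = FALSE)
  for (s in list(sigma_size, sigma_pdi, sigma_le)) {
    if (!is.finite(s) || s < 0) stop("noise SDs must be non-negative",
                                     call. = FALSE)
  }
  for (opt in list(size_opt, pdi_opt, le_opt)) {
    if (length(opt) != length(factors)) {
      stop("optimum coordinates must match the number of factors",
           call. = FALSE)
    }
  }
  structure(list(
    factors = factors,
    size_opt = size_opt, size_floor_nm = size_floor_nm,
    size_curv = size_curv,
    pdi_opt = pdi_opt, pdi_floor = pdi_floor, pdi_curv = pdi_curv,
    le_opt = le_opt, le_peak = le_peak, le_curv = le_curv,
    sigma_size = sigma_size, sigma_pdi = sigma_pdi, sigma_le = sigma_le,
    assay_le_pct = assay_le_pct,
    assay_suppression_pct = assay_suppression_pct,
    assay_suppression_ref_pct = assay_suppression_ref_pct,
    assay_colocal = as.integer(assay_colocal),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# squared normalized radius from an optimum, per row of natural coords
.rho2 <- function(x_nat, opt, factors) {
  half <- vapply(factors, function(f) (f$high - f$low) / 2, numeric(1))
  rowSums(sweep(sweep(x_nat, 2L, opt), 2L, half, "/")^2)
}

# ground-truth response functions on natural coordinates
.true_responses <- function(cfg, x_nat) {
  list(
    size_log10 = log10(cfg$size_floor_nm) +
      cfg$size_curv * .rho2(x_nat, cfg$size_opt, cfg$factors),
    pdi = pmin(1, pmax(0, cfg$pdi_floor +
                         cfg$pdi_curv * .rho2(x_nat, cfg$pdi_opt,
                                              cfg$factors))),
    le_pct = pmin(100, pmax(0, cfg$le_peak -
                              cfg$le_curv * .rho2(x_nat, cfg$le_opt,
                                                  cfg$factors)))
  )
}

#' Simulate responses for a designed experiment
#'
#' Evaluates the configured ground-truth surfaces at every design run,
#' adds independent Gaussian noise per response, and clamps results to
#' their physical ranges (PdI to \[0, 1\], LE% to \[0, 100\]; size stays
#' positive because noise acts on the log10 scale). The returned ground
#' truth contains everything needed to score downstream recovery: the
#' noiseless responses, each response's own optimum, and the joint
#' optimum of the equal-weight distance-from-ideal scalarization computed
#' on the *true* surfaces by dense grid search — independent of any
#' fitted spline.
#'
#' @param cfg a [synthetic_config()].
#' @param design a [make_ccd()] design over the same factors.
#' @param truth_resolution grid resolution for locating the true joint
#'   optimum.
#' @return list with `responses` (data frame: `run_id`, `size_nm`, `pdi`,
#'   `le_pct`), `truth` (noiseless values, per-response optima, joint
#'   optimum and the true responses there), and `n_clamped`.
#' @export
generate_experiment <- function(cfg, design, truth_resolution = 201L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg_names <- vapply(cfg$factors, `[[`, character(1), "name")
  des_names <- vapply(attr(design, "factors"), `[[`, character(1), "name")
  if (!identical(cfg_names, des_names)) {
    stop("design factors do not match the synthetic configuration",
         call. = FALSE)
  }
  x_nat <- as.matrix(decode_levels(design))
  truth <- .true_responses(cfg, x_nat)

  set.seed(cfg$seed)
  n <- nrow(x_nat)
  size_nm <- 10^(truth$size_log10 + stats::rnorm(n, 0, cfg$sigma_size))
  pdi_raw <- truth$pdi + stats::rnorm(n, 0, cfg$sigma_pdi)
  le_raw <- truth$le_pct + stats::rnorm(n, 0, cfg$sigma_le)
  pdi <- pmin(1, pmax(0, pdi_raw))
  le <- pmin(100, pmax(0, le_raw))
  n_clamped <- sum(pdi != pdi_raw) + sum(le != le_raw)
  if (n_clamped > 0) {
    message(sprintf("%d simulated value(s) clamped to physical range",
                    n_clamped))
  }

  joint <- .true_joint_optimum(cfg, truth_resolution)
  list(
    responses = data.frame(run_id = design$run_id, size_nm = size_nm,
                           pdi = pdi, le_pct = le),
    truth = list(
      noiseless = data.frame(run_id = design$run_id,
                             size_log10 = truth$size_log10,
                             pdi = truth$pdi, le_pct = truth$le_pct),
      size_opt = cfg$size_opt, pdi_opt = cfg$pdi_opt, le_opt = cfg$le_opt,
      joint_optimum = joint$par,
      joint_responses = joint$responses
    ),
    n_clamped = n_clamped
  )
}

# equal-weight distance-from-ideal optimum of the TRUE surfaces by grid
.true_joint_optimum <- function(cfg, resolution) {
  axes <- lapply(cfg$factors, function(f) {
    seq(f$low, f$high, length.out = resolution)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  tr <- .true_responses(cfg, grid)
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  score <- sqrt(norm01(tr$size_log10)^2 + norm01(tr$pdi)^2 +
                  (1 - norm01(tr$le_pct))^2)
  i <- which.min(score)
  par <- stats::setNames(as.numeric(grid[i, ]),
                         vapply(cfg$factors, `[[`, character(1), "name"))
  list(par = par,
       responses = c(size_log10 = tr$size_log10[i], pdi = tr$pdi[i],
                     le_pct = tr$le_pct[i]))
}

#' Emit synthetic assay fixtures with known ground truth
#'
#' Builds the small tables consumed by the scalar assay metrics, all
#' self-consistent with the configured truths: an 11-fraction density
#' gradient profile with free siRNA in early fractions (1-3) and joint
#' siRNA/particle peaks in the configured co-localized fractions; a
#' fluorescence pair whose [loading_efficiency()] equals
#' `cfg$assay_le_pct`; and three-well luciferase tables (control, vesicle
#' formulation, reference reagent) whose [suppression_ratio()] equals the
#' configured suppressions. Deterministic: well-to-well variation is a
#' fixed zero-mean pattern, so group means are exact.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `fractions`, `fluorescence` (encapsulated, total,
#'   blank), and `expression` (data frame with group, luminescence,
#'   protein).
#' @export
generate_assay_tables <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_frac <- 11L
  sirna <- numeric(n_frac)
  particles <- numeric(n_frac)
  sirna[1:3] <- c(80, 100, 60)          # free siRNA band near the top
  sirna[cfg$assay_colocal] <- c(70, 55)[seq_along(cfg$assay_colocal)]
  particles[cfg$assay_colocal] <- c(9e9, 7e9)[seq_along(cfg$assay_colocal)]
  fractions <- data.frame(fraction = seq_len(n_frac), sirna = sirna,
                          particles = particles)

  blank <- 5
  total <- 400
  fluorescence <- list(
    encapsulated = blank + cfg$assay_le_pct / 100 * (total - blank),
    total = total, blank = blank)

  wells <- c(-0.04, 0, 0.04)  # fixed zero-mean well pattern
  protein <- c(0.95, 1.00, 1.05)
  make_group <- function(label, level) {
    data.frame(group = label,
               luminescence = level * (1 + wells) * protein,
               protein = protein)
  }
  expression <- rbind(
    make_group("siCont", 1000),
    make_group("siLuc_vesicle", 1000 * (1 - cfg$assay_suppression_pct / 100)),
    make_group("siLuc_reference",
               1000 * (1 - cfg$assay_suppression_ref_pct / 100)))

  list(fractions = fractions, fluorescence = fluorescence,
       expression = expression)
}
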