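# Scalar characterization metrics for siRNA-vesicle formulations.
# All inputs are plain numbers or small data frames; no instrument-file
# parsing happens here.

#' siRNA loading efficiency (LE%)
#'
#' Percent of the supplied siRNA found encapsulated in vesicles, from
#' fluorescence readings taken after separating free from
#' vesicle-associated siRNA (e.g. ultrafiltration): 100 *
#' (encapsulated - blank) / (total - blank). The blank is subtracted from
#' numerator and denominator alike. Negative results (encapsulated signal
#' below blank) are clamped to 0 with a warning.
#'
#' @param encapsulated fluorescence of the vesicle-associated fraction.
#' @param total fluorescence of all supplied siRNA.
#' @param blank blank/background fluorescence (default 0).
#' @return loading efficiency in percent (vectorized).
#' @export
loading_efficiency <- function(encapsulated, total, blank = 0) {
  if (any(!is.finite(encapsulated)) || any(!is.finite(total)) ||
      any(!is.finite(blank))) {
    stop("fluorescence readings must be finite", call. = FALSE)
  }
  if (any(encapsulated < 0) || any(total < 0) || any(blank < 0)) {
    stop("fluorescence readings must be non-negative", call. = FALSE)
  }
  if (any(total - blank <= 0)) {
    stop("total signal must exceed the blank", call. = FALSE)
  }
  le <- 100 * (encapsulated - blank) / (total - blank)
  if (any(le < 0)) {
    warning("negative loading efficiency clamped to 0", call. = FALSE)
    le <- pmax(le, 0)
  }
  le
}

#' Mean fluorescence intensity ratio (MFIR)
#'
#' Flow-cytometry uptake metric: sample MFI divided by untreated-cell MFI.
#' Vectorized, so a table of concentrations x time points maps to a table
#' of ratios.
#'
#' @param sample_mfi mean fluorescence intensity of treated cells.
#' @param untreated_mfi mean fluorescence intensity of untreated cells
#'   (> 0).
#' @return ratio(s).
#' @export
mfir <- function(sample_mfi, untreated_mfi) {
  if (any(!is.finite(sample_mfi)) || any(!is.finite(untreated_mfi))) {
    stop("MFI values must be finite", call. = FALSE)
  }
  if (any(untreated_mfi <= 0)) {
    stop("untreated MFI must be positive", call. = FALSE)
  }
  sample_mfi / untreated_mfi
}

#' Gene-suppression ratio from a luciferase readout
#'
#' Each well's luminescence is first normalized by its protein
#' concentration (compensating for well-to-well cell mass); suppression is
#' 100 * (1 - mean(treated) / mean(control)) on the normalized scale. An
#' approximate standard deviation by the delta method is attached for
#' reporting.
#'
#' @param treated,control data frames with columns `luminescence` and
#'   `protein` (one row per well, protein > 0).
#' @return list with `suppression_pct`, `sd_pct`, and the group means.
#' @export
suppression_ratio <- function(treated, control) {
  norm_group <- function(g, label) {
    if (!is.data.frame(g) || nrow(g) < 1L ||
        !all(c("luminescence", "protein") %in% names(g))) {
      stop(sprintf(
        "'%s' must be a non-empty data frame with luminescence and protein",
        label), call. = FALSE)
    }
    if (any(g$protein <= 0)) {
      stop("protein concentrations must be positive", call. = FALSE)
    }
    g$luminescence / g$protein
  }
  t_norm <- norm_group(treated, "treated")
  c_norm <- norm_group(control, "control")
  m_c <- mean(c_norm)
  if (m_c <= 0) {
    stop("control mean normalized luminescence must be positive",
         call. = FALSE)
  }
  m_t <- mean(t_norm)
  ratio <- m_t / m_c
  # delta-method variance of the ratio of two independent means
  v_t <- if (length(t_norm) > 1L) stats::var(t_norm) / length(t_norm) else 0
  v_c <- if (length(c_norm) > 1L) stats::var(c_norm) / length(c_norm) else 0
  sd_ratio <- abs(ratio) * sqrt(v_t / m_t^2 + v_c / m_c^2)
  list(suppression_pct = 100 * (1 - ratio),
       sd_pct = 100 * sd_ratio,
       mean_treated = m_t, mean_control = m_c)
}

#' Fractions where siRNA and particles co-localize
#'
#' Given a density-gradient fraction profile (per-fraction siRNA
#' fluorescence and particle counts), returns the fraction ids where both
#' channels exceed their thresholds — the signature of intact
#' siRNA-loaded vesicles, as opposed to early fractions containing free
#' siRNA only. Thresholds default to 10% of each channel's maximum, which
#' makes the qualitative read-off of a fraction plot explicit.
#'
#' @param profile data frame with columns `fraction`, `sirna`,
#'   `particles` (values >= 0).
#' @param sirna_threshold,particle_threshold absolute thresholds; `NULL`
#'   means 10% of the channel maximum.
#' @return integer vector of fraction ids (possibly empty).
#' @export
colocalized_fractions <- function(profile, sirna_threshold = NULL,
                                  particle_threshold = NULL) {
  req <- c("fraction", "sirna", "particles")
  if (!is.data.frame(profile) || !all(req %in% names(profile))) {
    stop("'profile' needs columns fraction, sirna, particles", call. = FALSE)
  }
  if (any(profile$sirna < 0) || any(profile$particles < 0)) {
    stop("profile values must be non-negative", call. = FALSE)
  }
  if (is.null(sirna_threshold)) sirna_threshold <- 0.1 * max(profile$sirna)
  if (is.null(particle_threshold)) {
    particle_threshold <- 0.1 * max(profile$particles)
  }
  if (sirna_threshold < 0 || particle_threshold < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  hit <- profile$sirna > sirna_threshold &
    profile$particles > particle_threshold
  as.integer(profile$fraction[hit])
}

#' Chromatographic peak-area ratio to an internal standard
#'
#' Analyte peak area divided by the internal-standard peak area, the
#' normalization used to compare lipid classes across LC-MS/MS runs. The
#' internal-standard specification used in the vesicle lipid assays
#' (17:0-20:4 phosphatidylinositol at 0.38 umol/L) is available as
#' [default_internal_standard()].
#'
#' @param analyte_area analyte peak area(s).
#' @param is_area internal-standard peak area (> 0).
#' @return ratio(s).
#' @export
peak_area_ratio <- function(analyte_area, is_area) {
  if (any(!is.finite(analyte_area)) || any(!is.finite(is_area))) {
    stop("peak areas must be finite", call. = FALSE)
  }
  if (any(is_area <= 0)) {
    stop("internal-standard area must be positive", call. = FALSE)
  }
  analyte_area / is_area
}

#' Internal-standard metadata for lipid peak-area ratios
#'
#' @return list describing the reference internal standard: a 17:0-20:4
#'   phosphatidylinositol spiked at 0.38 umol/L.
#' @export
default_internal_standard <- function() {
  list(lipid = "PI 17:0-20:4", class = "phosphatidylinositol",
       concentration = 0.38, unit = "umol/L")
}
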