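# CSV schemas: comma-separated, UTF-8, '.' decimal, full float precision.
# A leading '#'-comment line may carry provenance (config hash); readers
# skip it.

.write_table_full <- function(df, path, comment = NULL) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.require_numeric <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s column '%s' is not numeric (first bad row: %s)",
                   what, cl, ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop(sprintf("%s column '%s' has non-finite value(s) (row %d)",
                   what, cl, which(!is.finite(v))[1]), call. = FALSE)
    }
  }
  df
}

#' Write a design to CSV
#'
#' Columns: `run_id`, one natural-unit column per factor, `role`.
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip is lossless.
#'
#' @param design a [make_ccd()] design.
#' @param path output file.
#' @param comment optional provenance comment written as a leading `#` line.
#' @return the path, invisibly.
#' @export
write_design <- function(design, path, comment = NULL) {
  f <- attr(design, "factors")
  nms <- vapply(f, `[[`, character(1), "name")
  .write_table_full(design[, c("run_id", nms, "role")], path,
                    comment = comment)
}

#' Read a design from CSV
#'
#' Reads the schema written by [write_design()] and reconstructs coded
#' coordinates. When `factors` is omitted, bounds are inferred under the
#' assumption of a rotatable central composite design: the extreme
#' natural values on each axis are the axial runs at coded distance
#' sqrt(2), so the -1/+1 bounds sit at center +/- extent/sqrt(2). Supply
#' `factors` explicitly for any other layout.
#'
#' @param path CSV file.
#' @param factors optional list of [factor_spec()]s giving the true bounds.
#' @return a `ccd_design`.
#' @export
read_design <- function(path, factors = NULL) {
  df <- .read_table(path, "design")
  if (!"run_id" %in% names(df)) {
    stop("design is missing column(s): run_id", call. = FALSE)
  }
  if (anyDuplicated(df$run_id)) {
    stop("duplicate run_id in design file", call. = FALSE)
  }
  fac_cols <- setdiff(names(df), c("run_id", "role"))
  if (is.null(factors)) {
    factors <- lapply(fac_cols, function(nm) {
      v <- df[[nm]]
      center <- (max(v) + min(v)) / 2
      half <- (max(v) - min(v)) / 2 / sqrt(2)
      factor_spec(nm, center - half, center + half)
    })
  } else {
    factors <- .check_factors(factors)
    nms <- vapply(factors, `[[`, character(1), "name")
    if (!all(nms %in% names(df))) {
      stop("design file lacks columns for the supplied factors",
           call. = FALSE)
    }
    fac_cols <- nms
  }
  df <- .require_numeric(df, fac_cols, "design")
  coded <- encode_levels(df[, fac_cols, drop = FALSE], factors)
  out <- data.frame(run_id = df$run_id, stringsAsFactors = FALSE)
  out$role <- if ("role" %in% names(df)) df$role else .infer_role(coded)
  for (j in seq_along(fac_cols)) {
    out[[paste0(fac_cols[j], "_coded")]] <- coded[, j]
    out[[fac_cols[j]]] <- df[[fac_cols[j]]]
  }
  structure(out, factors = factors, alpha = max(abs(coded)),
            class = c("ccd_design", "data.frame"))
}

.infer_role <- function(coded, tol = 1e-6) {
  apply(coded, 1L, function(x) {
    nz <- sum(abs(x) > tol)
    if (nz == 0) "center" else if (nz == 1L) "axial" else "factorial"
  })
}

#' Write measured responses to CSV
#'
#' Columns: `run_id`, `size_nm`, `pdi`, `le_pct`, full float precision.
#'
#' @param responses response data frame.
#' @param path output file.
#' @param comment optional provenance comment.
#' @return the path, invisibly.
#' @export
write_responses <- function(responses, path, comment = NULL) {
  .write_table_full(responses[, c("run_id", "size_nm", "pdi", "le_pct")],
                    path, comment = comment)
}

#' Read and validate measured responses
#'
#' Enforces the physical ranges (size > 0 nm, PdI in \[0, 1\], LE% in
#' \[0, 100\]), rejects duplicate run ids, and — when a design is supplied
#' — aligns rows to the design's run order, rejecting any mismatch in the
#' run-id sets.
#'
#' @param path CSV with columns `run_id`, `size_nm`, `pdi`, `le_pct`.
#' @param design optional `ccd_design` to align against.
#' @return validated response data frame (design order when aligned).
#' @export
read_responses <- function(path, design = NULL) {
  df <- .read_table(path, "responses")
  df <- .require_numeric(df, c("size_nm", "pdi", "le_pct"), "responses")
  if (!"run_id" %in% names(df)) {
    stop("responses is missing column(s): run_id", call. = FALSE)
  }
  if (anyDuplicated(df$run_id)) {
    stop("duplicate run_id in responses file", call. = FALSE)
  }
  if (any(df$size_nm <= 0)) {
    stop(sprintf("size_nm must be positive (row %d)",
                 which(df$size_nm <= 0)[1]), call. = FALSE)
  }
  if (any(df$pdi < 0 | df$pdi > 1)) {
    stop(sprintf("pdi out of [0, 1] (row %d)",
                 which(df$pdi < 0 | df$pdi > 1)[1]), call. = FALSE)
  }
  if (any(df$le_pct < 0 | df$le_pct > 100)) {
    stop(sprintf("le_pct out of [0, 100] (row %d)",
                 which(df$le_pct < 0 | df$le_pct > 100)[1]), call. = FALSE)
  }
  if (!is.null(design)) {
    if (!setequal(df$run_id, design$run_id) ||
        nrow(df) != nrow(design)) {
      stop("responses do not align with the design's run ids", call. = FALSE)
    }
    df <- df[match(design$run_id, df$run_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Export a fitted surface as a plain-text model file
#'
#' @param surface a `tps_surface`.
#' @param path output JSON file.
#' @param extra named list merged into the JSON record (e.g. provenance).
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path, extra = NULL) {
  rec <- c(list(
    response = surface$response,
    transform = surface$transform,
    lambda = surface$lambda,
    factors = lapply(surface$factors, unclass),
    nodes = unname(apply(surface$nodes, 1L, as.numeric, simplify = FALSE)),
    weights = as.numeric(surface$weights),
    poly_coeffs = as.list(surface$poly_coeffs),
    node_values = as.numeric(surface$node_values)
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
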