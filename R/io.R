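#' Read a beat series from a text or CSV file
#'
#' Text files carry one beat value per line; `#` comments and blank
#' lines are skipped.  CSV files are read with [utils::read.csv()] and
#' the beat column is located by name (`rr_s`, `rr`, `rr_seconds` for
#' RR input; `hr_bpm`, `hr` for heart rate), or given via `column`.
#' Values must be strictly positive; offending entries are reported with
#' their line (or row) number.
#'
#' @param path file path.
#' @param kind `"rr_seconds"` or `"hr_bpm"`.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @param column CSV column name override.
#' @return An `hr_series` (see [to_log_hr()]).
#' @export
read_beat_series <- function(path, kind = c("rr_seconds", "hr_bpm"),
                             format = c("auto", "txt", "csv"),
                             column = NULL) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "txt") {
    lines <- readLines(path, warn = FALSE)
    stripped <- sub("#.*$", "", lines)
    keep <- which(nzchar(trimws(stripped)))
    vals <- suppressWarnings(as.numeric(trimws(stripped[keep])))
    if (anyNA(vals))
      stop("unparseable value on line ", keep[which(is.na(vals))[1L]],
           " of ", path, call. = FALSE)
    bad <- which(vals <= 0)
    if (length(bad))
      stop("nonpositive beat value on line ", keep[bad[1L]], " of ", path,
           call. = FALSE)
  } else {
    d <- read.csv(path, comment.char = "#")
    cand <- if (!is.null(column)) column
            else if (kind == "rr_seconds") c("rr_s", "rr", "rr_seconds")
            else c("hr_bpm", "hr")
    col <- intersect(cand, names(d))
    if (!length(col))
      stop("no beat column found (looked for: ",
           paste(cand, collapse = ", "), ")", call. = FALSE)
    vals <- d[[col[1L]]]
    if (!is.numeric(vals) || anyNA(vals))
      stop("unparseable entries in column '", col[1L], "'", call. = FALSE)
    bad <- which(vals <= 0)
    if (length(bad))
      stop("nonpositive beat value in row ", bad[1L], " of ", path,
           call. = FALSE)
  }
  to_log_hr(vals, kind)
}

#' Write a beat series as plain text
#'
#' One value per line, full double precision, with a `#` header noting
#' the kind.  A written file read back with [read_beat_series()]
#' reproduces the series exactly.
#'
#' @param values numeric beat values, or an `hr_series` (its raw values
#'   are written).
#' @param path output path.
#' @param kind `"rr_seconds"` or `"hr_bpm"`.
#' @return `path`, invisibly.
#' @export
write_beat_series <- function(values, path, kind = c("rr_seconds", "hr_bpm")) {
  if (inherits(values, "hr_series")) {
    kind <- values$kind
    values <- values$raw
  } else kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# beat series (%s)", kind),
               sprintf("%.17g", values)), con)
  invisible(path)
}

regime_presets <- list(
  stable_fixed_point = list(omega = 1e-4, sigma = 0.0275, alpha = 0.7786,
                            beta = 0.3),
  unit_root          = list(omega = 0,    sigma = 0.0275, alpha = 0.7786,
                            beta = 0),
  stable_two_cycle   = list(omega = 0,    sigma = 0.0275, alpha = 0.7786,
                            beta = 1.2 * (4 - 2 * 0.7786))
)

#' Generate a synthetic beat-series fixture
#'
#' Simulates an NLARI log-HR series, converts it to beats
#' (HR = exp(X) bpm, RR = 60/HR s) and writes the series together with
#' a JSON manifest of the true generating parameters, so estimates on
#' the fixture can be checked against ground truth.  Fixtures emulate
#' the shape of typical analysis windows: 900 beats in the stable
#' fixed-point regime (or at its boundaries), with a linear trend and
#' Gaussian innovations.
#'
#' @param regime `"stable_fixed_point"` (default), `"unit_root"` or
#'   `"stable_two_cycle"`; ignored when `params` is given.
#' @param params optional explicit [nlari_params()].
#' @param n series length (default 900, minimum 100).
#' @param x0 baseline log-HR level (default `log(60)`).
#' @param seed RNG seed (required).
#' @param kind output representation, `"rr_seconds"` or `"hr_bpm"`.
#' @param dir output directory (created if needed).
#' @param name file stem (default derived from regime and seed).
#' @return A list with `series_path`, `manifest_path` and the manifest.
#' @export
make_fixture <- function(regime = names(regime_presets), params = NULL,
                         n = 900L, x0 = log(60), seed,
                         kind = c("rr_seconds", "hr_bpm"),
                         dir = tempdir(), name = NULL) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n < 100L) stop("fixtures must have n >= 100", call. = FALSE)
  if (is.null(params)) {
    regime <- match.arg(regime)
    params <- do.call(nlari_params, regime_presets[[regime]])
  } else {
    stopifnot(inherits(params, "nlari_params"))
    regime <- classify_regime(params)$label
  }
  s <- simulate_nlari(params, n = n, x0 = x0, seed = seed)
  hr <- exp(s$x)
  values <- if (kind == "rr_seconds") 60 / hr else hr
  if (is.null(name)) name <- sprintf("%s_seed%d", regime, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series_path <- file.path(dir, paste0(name, ".txt"))
  manifest_path <- file.path(dir, paste0(name, ".json"))
  write_beat_series(values, series_path, kind)
  manifest <- list(regime = regime, kind = kind, n = n, x0 = x0, seed = seed,
                   params = params[c("omega", "sigma", "alpha", "beta",
                                     "kappa2")],
                   derived = derived_params(params))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  list(series_path = series_path, manifest_path = manifest_path,
       manifest = manifest)
}
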