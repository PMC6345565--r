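# CSV dialects: concentrations are nanomolar (conc_nM) and times minutes
# (time_min) at the file interface; molar and minutes internally.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  stop(sprintf("cannot parse %s file %s: %s", what, path,
                               conditionMessage(e)), call. = FALSE))
  if (!nrow(d))
    stop(sprintf("%s file %s is empty", what, path), call. = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("%s file %s is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  d
}

#' Read a dose-response table (conc_nM, replicate, signal)
#'
#' @param path CSV file with header `conc_nM,replicate,signal` (`replicate`
#'   optional).
#' @return Data frame with columns `conc` (molar), `replicate`, `signal`.
#' @export
read_dose_table <- function(path) {
  d <- .read_csv_checked(path, c("conc_nM", "signal"), "dose-response")
  data.frame(conc = d$conc_nM * 1e-9,
             replicate = if ("replicate" %in% names(d)) d$replicate else 1L,
             signal = d$signal)
}

#' Read a time-course table (time_min, replicate, signal)
#'
#' @param path CSV file with header `time_min,replicate,signal` (`replicate`
#'   optional).
#' @return Data frame with columns `time` (minutes), `replicate`, `signal`.
#' @export
read_timecourse_table <- function(path) {
  d <- .read_csv_checked(path, c("time_min", "signal"), "time-course")
  data.frame(time = d$time_min,
             replicate = if ("replicate" %in% names(d)) d$replicate else 1L,
             signal = d$signal)
}

#' Read a fluorescence-polarization table
#'
#' Accepts either precomputed polarization (`conc_M,fp`) or plane-resolved
#' intensities (`conc_M,iv,ih`, converted with [polarization()] and g-factor
#' `g`).
#'
#' @param path CSV file.
#' @param g Instrument g-factor for the intensity form.
#' @return Data frame with columns `conc` (molar) and `fp`.
#' @export
read_fp_table <- function(path, g = 1) {
  d <- .read_csv_checked(path, "conc_M", "FP")
  if (!("fp" %in% names(d))) {
    miss <- setdiff(c("iv", "ih"), names(d))
    if (length(miss))
      stop(sprintf("FP file %s is missing column(s): %s (need fp, or iv and ih)",
                   path, paste(miss, collapse = ", ")), call. = FALSE)
    d$fp <- polarization(d$iv, d$ih, g)
  }
  data.frame(conc = d$conc_M, fp = d$fp)
}

#' Read a membrane-sheet ROI table
#'
#' @param path CSV file with header
#'   `sheet_id,condition,conc_nM,ch,i_obs,i_back,saturated`.
#' @return Data frame in the [quantify_binding()] dialect.
#' @export
read_roi_table <- function(path) {
  d <- .read_csv_checked(
    path, c("sheet_id", "condition", "conc_nM", "ch", "i_obs", "i_back",
            "saturated"), "ROI")
  d$saturated <- as.logical(d$saturated)
  d
}

#' Write a simulated time course as CSV
#'
#' @param tc An `"avk_timecourse"` object.
#' @param path Output CSV (`time_min,U,G,R,B,signal`).
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "avk_timecourse"))
  utils::write.csv(as.data.frame(tc)[c("time_min", "U", "G", "R", "B",
                                       "signal")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated saturation curve as CSV
#'
#' @param sat An `"avk_saturation"` object.
#' @param path Output CSV (`conc_nM,U,G,R,B,total_signal`).
#' @return `path`, invisibly.
#' @export
write_saturation_csv <- function(sat, path) {
  stopifnot(inherits(sat, "avk_saturation"))
  d <- as.data.frame(sat)
  out <- data.frame(conc_nM = d$conc * 1e9, U = d$U, G = d$G, R = d$R,
                    B = d$B, total_signal = d$total_signal)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fit as a JSON record
#'
#' Writes the parameter table (parameter, estimate, stderr), derived
#' quantities and fit statistics of any package fit object as JSON.
#'
#' @param fit An `"avk_fit"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "avk_fit"))
  derived <- fit$derived
  derived <- derived[vapply(derived, function(x)
    is.numeric(x) && length(x) == 1, logical(1))]
  rec <- list(model = fit$model,
              parameters = .fit_record(fit),
              derived = derived,
              n = fit$n, rss = fit$rss, aicc = fit$aicc)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a flat CSV summary of one or more fits
#'
#' @param fits A single `"avk_fit"` or a named list of them.
#' @param path Output CSV (`fit,parameter,estimate,stderr`).
#' @return `path`, invisibly.
#' @export
write_fit_summary_csv <- function(fits, path) {
  if (inherits(fits, "avk_fit")) fits <- list(fit = fits)
  rows <- lapply(names(fits), function(nm) {
    rec <- .fit_record(fits[[nm]])
    cbind(fit = nm, rec)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a flat rate-parameter configuration file
#'
#' Key-value text (YAML-compatible `key: value` lines) with keys
#' `k1_per_M_min`, `k_off_per_min`, `r_angstrom`, `f` and optionally
#' `k2_per_min` (an explicit composite rate overriding the derived one; a
#' mismatch above 1 percent raises a warning) and `stat_factors` (four numbers).
#'
#' @param path Configuration file path.
#' @return An [rate_parameters()] object.
#' @export
read_rate_config <- function(path) {
  if (!file.exists(path))
    stop("rate-parameter config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  .params_from_config(cfg)
}

.params_from_config <- function(cfg) {
  for (key in c("k1_per_M_min", "k_off_per_min"))
    if (is.null(cfg[[key]]))
      stop(sprintf("rate-parameter config is missing required field `%s`", key),
           call. = FALSE)
  if (is.null(cfg$k2_per_min) && (is.null(cfg$r_angstrom) || is.null(cfg$f)))
    stop("rate-parameter config needs `k2_per_min` or both `r_angstrom` and `f`",
         call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  args <- list(k1 = num(cfg$k1_per_M_min), k_off = num(cfg$k_off_per_min),
               r = num(cfg$r_angstrom), f = num(cfg$f),
               k2 = num(cfg$k2_per_min))
  if (!is.null(cfg$stat_factors))
    args$stat_factors <- as.numeric(cfg$stat_factors)
  do.call(rate_parameters, args)
}
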