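#' Four-parameter log-logistic dose-response model
#'
#' The sigmoidal saturation/competition binding model used throughout the
#' empirical fits:
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} EC_{50} - \log_{10} c)\,h}}}
#' Ascending for Hill slope `hill > 0`; at `conc = ec50` the midpoint
#' `(top + bottom)/2` is returned, and `conc = 0` returns `bottom` (the limit,
#' not an error).
#'
#' @param conc Concentrations (molar, >= 0); vectorised.
#' @param top,bottom Upper and lower asymptotes (signal units).
#' @param ec50 Half-maximal concentration (molar, > 0).
#' @param hill Hill slope (dimensionless, default 1).
#'
#' @return Model signal at `conc`.
#' @examples
#' dose_response_model(470e-9, top = 100, bottom = 0, ec50 = 47e-9)  # 90.9
#' @export
dose_response_model <- function(conc, top, bottom = 0, ec50, hill = 1) {
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  if (any(ec50 <= 0)) stop("`ec50` must be positive", call. = FALSE)
  y <- bottom + (top - bottom) /
    (1 + 10^((log10(ec50) - log10(conc)) * hill))
  # conc = 0: limit is bottom for hill > 0, top for hill < 0
  y[conc == 0] <- if (hill > 0) bottom else top
  y
}

.check_dose_data <- function(data, what = "dose-response") {
  if (!is.data.frame(data) || !all(c("conc", "signal") %in% names(data)))
    stop(sprintf("%s data must be a data frame with columns `conc` and `signal`",
                 what), call. = FALSE)
  data <- data[is.finite(data$conc) & is.finite(data$signal), , drop = FALSE]
  if (any(data$conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  pos <- data[data$conc > 0, , drop = FALSE]
  if (length(unique(pos$conc)) < 5)
    stop(sprintf("%s fit needs at least 5 distinct positive concentrations",
                 what), call. = FALSE)
  if (stats::sd(data$signal) == 0)
    stop(sprintf("%s fit is underdetermined: signal has no variation", what),
         call. = FALSE)
  data
}

# Deterministic start values: asymptotes from the data range, ec50 from the
# concentration whose mean signal is nearest half-range.
.dr_start <- function(conc, signal, descending) {
  m <- tapply(signal, conc, mean)
  cs <- as.numeric(names(m))
  half <- (max(m) + min(m)) / 2
  le0 <- log10(cs[which.min(abs(m - half))])
  list(bottom = min(m), top = max(m), log_e = le0)
}

#' Fit a sigmoidal saturation binding curve
#'
#' Least-squares fit of [dose_response_model()] to pooled replicate
#' measurements.  By default the Hill slope is pinned to 1 (single-site
#' paradigm); `variable_slope = TRUE` frees it ("variable slope sigmoidal
#' dose-response").  Points at `conc = 0` are excluded from the log-logistic
#' fit.  Replicates enter as individual, unweighted points.
#'
#' @param data Data frame with columns `conc` (molar) and `signal`; an
#'   optional `replicate` column is carried along but not used for weighting.
#' @param variable_slope Free the Hill slope? Default `FALSE`.
#' @param reference_top Optional reference amplitude; when given,
#'   `bmax_percent = 100 * (top - bottom) / reference_top` is reported.
#'
#' @return A `"dr_fit"` object (see [coef()], [summary()], [predict()]),
#'   whose coefficients are `top`, `bottom`, `log_ec50`, `hill`, with derived
#'   `ec50` (molar, reported with a delta-method standard error) and `bmax`.
#'
#' @examples
#' d <- gen_saturation(seed = 1)
#' fit <- fit_dose_response(d)
#' summary(fit)
#' @export
fit_dose_response <- function(data, variable_slope = FALSE,
                              reference_top = NULL) {
  data <- .check_dose_data(data, "saturation")
  data <- data[data$conc > 0, , drop = FALSE]
  df <- data.frame(lc = log10(data$conc), y = data$signal)
  st <- .dr_start(data$conc, data$signal, descending = FALSE)

  if (variable_slope) {
    fit <- .fit_nls(y ~ bottom + (top - bottom) / (1 + 10^((log_e - lc) * hill)),
                    df,
                    start = c(st, list(hill = 1)),
                    lower = c(-Inf, -Inf, log10(min(data$conc)) - 3, 0.1),
                    upper = c(Inf, Inf, log10(max(data$conc)) + 3, 10),
                    what = "variable-slope saturation")
  } else {
    fit <- .fit_nls(y ~ bottom + (top - bottom) / (1 + 10^(log_e - lc)),
                    df, start = st, what = "saturation")
  }

  cf <- stats::coef(fit)
  se <- .se_of(fit)
  hill <- if (variable_slope) cf[["hill"]] else 1
  hill_se <- if (variable_slope) se[["hill"]] else 0
  est <- c(top = cf[["top"]], bottom = cf[["bottom"]],
           log_ec50 = cf[["log_e"]], hill = hill)
  ses <- c(top = se[["top"]], bottom = se[["bottom"]],
           log_ec50 = se[["log_e"]], hill = hill_se)
  if (est[["top"]] < est[["bottom"]])
    warning("fitted top is below bottom; curve may be descending", call. = FALSE)
  ec50 <- 10^est[["log_ec50"]]
  derived <- list(ec50 = ec50,
                  ec50_se = log(10) * ec50 * ses[["log_ec50"]],
                  bmax = est[["top"]] - est[["bottom"]])
  if (!is.null(reference_top))
    derived$bmax_percent <- 100 * derived$bmax / reference_top
  .new_avk_fit("dr_fit", fit, data, est, ses,
               extra = list(derived = derived, variable_slope = variable_slope,
                            descending = FALSE),
               model_name = if (variable_slope)
                 "Variable-slope sigmoidal dose-response"
               else "Sigmoidal dose-response (Hill slope = 1)")
}

#' Fit a competition (displacement) binding curve
#'
#' Descending four-parameter log-logistic fit of signal against unlabeled
#' competitor concentration at a fixed tracer concentration; the half-maximal
#' competitor concentration is reported as `ic50` (the apparent Ki* when the
#' tracer is near its Kd*).
#'
#' @param data Data frame with columns `conc` (competitor, molar) and
#'   `signal`.
#' @param variable_slope Free the Hill slope? Default `FALSE`.
#' @param tracer_conc Optional fixed tracer concentration (molar), stored as
#'   metadata.
#'
#' @return A `"dr_fit"` object with derived `ic50`.
#' @examples
#' x <- 10^seq(-9, -5.5, length.out = 8)
#' d <- data.frame(conc = x,
#'                 signal = dose_response_model(x, 100, 0, 29e-9, -1))
#' fit_competition(d)
#' @export
fit_competition <- function(data, variable_slope = FALSE, tracer_conc = NULL) {
  data <- .check_dose_data(data, "competition")
  data <- data[data$conc > 0, , drop = FALSE]
  df <- data.frame(lc = log10(data$conc), y = data$signal)
  st <- .dr_start(data$conc, data$signal, descending = TRUE)

  if (variable_slope) {
    fit <- .fit_nls(y ~ bottom + (top - bottom) / (1 + 10^((lc - log_e) * hill)),
                    df, start = c(st, list(hill = 1)),
                    lower = c(-Inf, -Inf, log10(min(data$conc)) - 3, 0.1),
                    upper = c(Inf, Inf, log10(max(data$conc)) + 3, 10),
                    what = "variable-slope competition")
  } else {
    fit <- .fit_nls(y ~ bottom + (top - bottom) / (1 + 10^(lc - log_e)),
                    df, start = st, what = "competition")
  }
  cf <- stats::coef(fit)
  se <- .se_of(fit)
  hill <- if (variable_slope) cf[["hill"]] else 1
  hill_se <- if (variable_slope) se[["hill"]] else 0
  est <- c(top = cf[["top"]], bottom = cf[["bottom"]],
           log_ic50 = cf[["log_e"]], hill = hill)
  ses <- c(top = se[["top"]], bottom = se[["bottom"]],
           log_ic50 = se[["log_e"]], hill = hill_se)
  ic50 <- 10^est[["log_ic50"]]
  derived <- list(ic50 = ic50,
                  ic50_se = log(10) * ic50 * ses[["log_ic50"]],
                  tracer_conc = tracer_conc)
  .new_avk_fit("dr_fit", fit, data, est, ses,
               extra = list(derived = derived, variable_slope = variable_slope,
                            descending = TRUE),
               model_name = "Competition (descending) dose-response")
}

#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  conc <- if (is.data.frame(newdata)) newdata$conc else newdata
  est <- object$coefficients
  le <- est[[3]]   # log_ec50 or log_ic50
  hill <- if (object$descending) -est[["hill"]] else est[["hill"]]
  dose_response_model(conc, top = est[["top"]], bottom = est[["bottom"]],
                      ec50 = 10^le, hill = hill)
}

#' @export
plot.dr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc * 1e9, d$signal, log = "x", pch = 20,
                 xlab = "concentration (nM)", ylab = x$response, ...)
  grid_c <- 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = 200)
  graphics::lines(grid_c * 1e9, predict(x, grid_c), col = "firebrick")
  invisible(x)
}

#' Normalize independent dose-response experiments to their fitted top
#'
#' Each independent experiment (identified by the `replicate` column) is
#' fitted separately and its signals rescaled to percent of that experiment's
#' fitted top, so curves can be pooled on a common 0-100 scale before a
#' combined fit.
#'
#' @param data Data frame with columns `conc`, `replicate`, `signal`.
#' @param variable_slope Passed to the per-experiment [fit_dose_response()].
#' @return `data` with `signal` rescaled to percent of the per-experiment top.
#' @export
normalize_experiments <- function(data, variable_slope = FALSE) {
  if (!all(c("conc", "replicate", "signal") %in% names(data)))
    stop("data must have columns `conc`, `replicate`, `signal`", call. = FALSE)
  parts <- split(data, data$replicate)
  out <- lapply(parts, function(d) {
    top <- fit_dose_response(d, variable_slope = variable_slope)$coefficients[["top"]]
    d$signal <- 100 * d$signal / top
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
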