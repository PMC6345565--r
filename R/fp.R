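#' Fluorescence polarization from plane-resolved emission intensities
#'
#' \deqn{FP = (I_V - g I_H) / (I_V + g I_H)}
#' where `iv` and `ih` are the emission intensities measured in the vertical
#' and horizontal planes and `g` is the instrument g-factor.  Units of the
#' intensities cancel; the result lies in \[-1, 1\] for `g = 1`.
#'
#' @param iv,ih Non-negative emission intensities (vectorised).
#' @param g Instrument g-factor (default 1).
#' @return Polarization (dimensionless).
#' @examples
#' polarization(3, 1)   # 0.5
#' @export
polarization <- function(iv, ih, g = 1) {
  if (any(iv < 0) || any(ih < 0))
    stop("`iv` and `ih` must be non-negative", call. = FALSE)
  denom <- iv + g * ih
  if (any(denom == 0))
    stop("undefined polarization: iv + g*ih is zero", call. = FALSE)
  (iv - g * ih) / denom
}

#' Single-site FP saturation binding model
#'
#' The observed polarization is the weighted average of free and bound tracer:
#' \deqn{FP = FP_f + (FP_b - FP_f) \frac{[R_t]}{K_d + [R_t]}}
#' `rt` is the total protein concentration, treated as free protein (tracer in
#' trace amounts, no depletion).
#'
#' @param rt Total protein concentration (molar, >= 0; vectorised).
#' @param fp_free,fp_bound Polarization of free and bound tracer (same,
#'   opaque units; `fp_bound >= fp_free`).
#' @param kd Dissociation constant (molar, > 0).
#' @return Model polarization.
#' @examples
#' fp_saturation_model(9e-6, fp_free = 50, fp_bound = 250, kd = 9e-6)  # 150
#' @export
fp_saturation_model <- function(rt, fp_free, fp_bound, kd) {
  if (any(rt < 0)) stop("`rt` must be non-negative", call. = FALSE)
  if (any(kd <= 0)) stop("`kd` must be positive", call. = FALSE)
  fp_free + (fp_bound - fp_free) * rt / (kd + rt)
}

#' FP competition binding model
#'
#' Displacement of the tracer by an unlabeled competitor at concentration `x`
#' with inhibition constant `ki`:
#' \deqn{FP = FP_f + (FP_b - FP_f) \frac{[R_t]}{K_d (1 + x/K_i) + [R_t]}}
#' Reduces to [fp_saturation_model()] at `x = 0` and tends to `fp_free` as
#' `x` grows.
#'
#' @inheritParams fp_saturation_model
#' @param x Competitor concentration (molar, >= 0; vectorised).
#' @param ki Competitor inhibition constant (molar, > 0).
#' @return Model polarization.
#' @export
fp_competition_model <- function(x, fp_free, fp_bound, rt, kd, ki) {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  if (any(ki <= 0)) stop("`ki` must be positive", call. = FALSE)
  if (any(kd <= 0)) stop("`kd` must be positive", call. = FALSE)
  fp_free + (fp_bound - fp_free) * rt / (kd * (1 + x / ki) + rt)
}

#' Fit the FP saturation binding model
#'
#' Least-squares fit of [fp_saturation_model()] to an FP titration, estimating
#' `fp_free`, `fp_bound` and `kd`.
#'
#' @param data Data frame with columns `rt` (protein concentration, molar) and
#'   `fp`, or `rt`, `iv`, `ih` (converted via [polarization()]).
#' @param g Instrument g-factor used when converting `iv`/`ih`.
#' @return An `"fp_fit"` object with derived `kd` (molar).
#' @examples
#' d <- gen_fp("saturation", seed = 1)
#' fit_fp_saturation(d)
#' @export
fit_fp_saturation <- function(data, g = 1) {
  if (!is.data.frame(data) || !("rt" %in% names(data)))
    stop("FP saturation data must have an `rt` column", call. = FALSE)
  if (!("fp" %in% names(data))) {
    if (!all(c("iv", "ih") %in% names(data)))
      stop("FP data must have an `fp` column or both `iv` and `ih`",
           call. = FALSE)
    data$fp <- polarization(data$iv, data$ih, g)
  }
  data <- data[is.finite(data$rt) & is.finite(data$fp), , drop = FALSE]
  if (length(unique(data$rt)) < 5)
    stop("FP saturation fit needs at least 5 distinct protein concentrations",
         call. = FALSE)
  if (stats::sd(data$fp) == 0)
    stop("FP saturation fit is underdetermined: polarization has no variation",
         call. = FALSE)
  m <- tapply(data$fp, data$rt, mean)
  cs <- as.numeric(names(m))
  half <- (max(m) + min(m)) / 2
  st <- list(fp_free = min(m), fp_bound = max(m),
             log_kd = log10(max(cs[which.min(abs(m - half))], min(cs[cs > 0]))))
  fit <- .fit_nls(fp ~ fp_free + (fp_bound - fp_free) * rt / (10^log_kd + rt),
                  data, st, what = "FP saturation")
  cf <- stats::coef(fit); se <- .se_of(fit)
  est <- c(fp_free = cf[["fp_free"]], fp_bound = cf[["fp_bound"]],
           log_kd = cf[["log_kd"]])
  ses <- c(fp_free = se[["fp_free"]], fp_bound = se[["fp_bound"]],
           log_kd = se[["log_kd"]])
  kd <- 10^est[["log_kd"]]
  derived <- list(kd = kd, kd_se = log(10) * kd * ses[["log_kd"]])
  .new_avk_fit("fp_fit", fit, data, est, ses,
               extra = list(derived = derived, assay = "saturation"),
               model_name = "FP saturation binding", response = "fp")
}

#' Fit the FP competition binding model
#'
#' Least-squares fit of [fp_competition_model()] against competitor
#' concentration with the apparent `kd` (from a prior saturation fit) and the
#' protein concentration `rt` held fixed; estimates `fp_free`, `fp_bound` and
#' `ki`.
#'
#' @param data Data frame with columns `x` (competitor concentration, molar)
#'   and `fp` (or `iv`/`ih`).
#' @param rt Fixed protein concentration (molar).
#' @param kd Apparent dissociation constant from the saturation fit (molar).
#' @param g Instrument g-factor used when converting `iv`/`ih`.
#' @return An `"fp_fit"` object with derived `ki` (molar).
#' @examples
#' d <- gen_fp("competition", seed = 1)
#' fit_fp_competition(d, rt = 9e-6, kd = 9e-6)
#' @export
fit_fp_competition <- function(data, rt, kd, g = 1) {
  if (missing(kd) || is.null(kd) || !is.finite(kd) || kd <= 0)
    stop("`kd` (apparent, from a prior saturation fit) must be supplied",
         call. = FALSE)
  if (missing(rt) || is.null(rt) || !is.finite(rt) || rt <= 0)
    stop("`rt` (fixed protein concentration) must be supplied", call. = FALSE)
  if (!is.data.frame(data) || !("x" %in% names(data)))
    stop("FP competition data must have an `x` column", call. = FALSE)
  if (!("fp" %in% names(data))) {
    if (!all(c("iv", "ih") %in% names(data)))
      stop("FP data must have an `fp` column or both `iv` and `ih`",
           call. = FALSE)
    data$fp <- polarization(data$iv, data$ih, g)
  }
  data <- data[is.finite(data$x) & is.finite(data$fp), , drop = FALSE]
  if (length(unique(data$x)) < 5)
    stop("FP competition fit needs at least 5 distinct competitor concentrations",
         call. = FALSE)
  if (stats::sd(data$fp) == 0)
    stop("FP competition fit is underdetermined: polarization has no variation",
         call. = FALSE)
  m <- tapply(data$fp, data$x, mean)
  cs <- as.numeric(names(m))
  half <- (max(m) + min(m)) / 2
  ki0 <- cs[which.min(abs(m - half))]
  if (ki0 <= 0) ki0 <- stats::median(cs[cs > 0])
  df <- data; df$rt_fix <- rt; df$kd_fix <- kd
  st <- list(fp_free = min(m), fp_bound = max(m), log_ki = log10(ki0))
  fit <- .fit_nls(
    fp ~ fp_free + (fp_bound - fp_free) * rt_fix /
      (kd_fix * (1 + x / 10^log_ki) + rt_fix),
    df, st, what = "FP competition")
  cf <- stats::coef(fit); se <- .se_of(fit)
  est <- c(fp_free = cf[["fp_free"]], fp_bound = cf[["fp_bound"]],
           log_ki = cf[["log_ki"]])
  ses <- c(fp_free = se[["fp_free"]], fp_bound = se[["fp_bound"]],
           log_ki = se[["log_ki"]])
  ki <- 10^est[["log_ki"]]
  derived <- list(ki = ki, ki_se = log(10) * ki * ses[["log_ki"]],
                  rt = rt, kd = kd)
  wide <- is.finite(ses[["log_ki"]]) && ses[["log_ki"]] > 1
  if (wide)
    warning("ki is poorly constrained by the competitor range (stderr spans more than a decade)",
            call. = FALSE)
  .new_avk_fit("fp_fit", fit, data, est, ses,
               extra = list(derived = derived, assay = "competition",
                            wide_stderr = wide),
               model_name = "FP competition binding", response = "fp")
}

#' @export
predict.fp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  est <- object$coefficients
  if (object$assay == "saturation") {
    rt <- if (is.data.frame(newdata)) newdata$rt else newdata
    fp_saturation_model(rt, est[["fp_free"]], est[["fp_bound"]],
                        10^est[["log_kd"]])
  } else {
    x <- if (is.data.frame(newdata)) newdata$x else newdata
    fp_competition_model(x, est[["fp_free"]], est[["fp_bound"]],
                         object$derived$rt, object$derived$kd,
                         10^est[["log_ki"]])
  }
}
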