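# Shared nonlinear least-squares plumbing for the empirical fit families.
# All fits go through nlsLM (Levenberg-Marquardt, supports box bounds) with a
# plain nls() port-algorithm fallback; failures surface the optimiser's own
# diagnostics rather than a bare NA.

.fit_nls <- function(formula, data, start, lower = NULL, upper = NULL,
                     what = "model") {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper, control = ctrl),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # nlsLM (and default nls) can abort on essentially zero-residual data;
    # the port algorithm handles that case and also honours bounds
    first_err <- fit
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(formula, data = data, start = start, algorithm = "port",
                   lower = if (is.null(lower)) -Inf else lower,
                   upper = if (is.null(upper)) Inf else upper,
                   control = stats::nls.control(maxiter = 500))),
      error = function(e) e)
    if (inherits(fit, "error"))
      stop(sprintf("%s fit did not converge (start = %s): %s",
                   what,
                   paste(sprintf("%s=%.4g", names(start), unlist(start)),
                         collapse = ", "),
                   conditionMessage(first_err)), call. = FALSE)
  }
  fit
}

# Corrected Akaike information criterion for a least-squares fit; the error
# variance counts as a parameter.
.aicc <- function(rss, n, npar) {
  k <- npar + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.se_of <- function(fit) {
  s <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                error = function(e) NULL)
  if (is.null(s)) {
    s <- rep(NA_real_, length(stats::coef(fit)))
    names(s) <- names(stats::coef(fit))
  }
  s
}

.new_avk_fit <- function(subclass, fit, data, coefficients, se, extra = list(),
                         model_name, response = "signal") {
  rss <- sum(stats::resid(fit)^2)
  n <- length(stats::resid(fit))
  npar <- length(stats::coef(fit))
  structure(
    c(list(model = model_name, fit = fit, data = data,
           coefficients = coefficients, se = se,
           rss = rss, n = n, npar = npar,
           aicc = .aicc(rss, n, npar), response = response),
      extra),
    class = c(subclass, "avk_fit"))
}

#' @export
coef.avk_fit <- function(object, ...) object$coefficients

#' @export
residuals.avk_fit <- function(object, ...) as.numeric(stats::resid(object$fit))

#' @export
fitted.avk_fit <- function(object, ...) as.numeric(stats::fitted(object$fit))

#' @export
print.avk_fit <- function(x, ...) {
  cat(x$model, "fit\n")
  est <- x$coefficients
  se <- x$se[names(est)]
  out <- data.frame(estimate = signif(est, 4),
                    std.error = signif(se, 4), row.names = names(est))
  print(out)
  cat(sprintf("n = %d, RSS = %.4g, AICc = %.2f\n", x$n, x$rss, x$aicc))
  invisible(x)
}

#' @export
summary.avk_fit <- function(object, ...) {
  res <- list(model = object$model,
              coefficients = object$coefficients, se = object$se,
              n = object$n, rss = object$rss, aicc = object$aicc,
              derived = object$derived)
  class(res) <- "summary.avk_fit"
  res
}

#' @export
print.summary.avk_fit <- function(x, ...) {
  cat(x$model, "fit\n\nCoefficients:\n")
  out <- data.frame(estimate = signif(x$coefficients, 4),
                    std.error = signif(x$se[names(x$coefficients)], 4),
                    row.names = names(x$coefficients))
  print(out)
  if (!is.null(x$derived) && length(x$derived)) {
    cat("\nDerived quantities:\n")
    for (nm in names(x$derived))
      cat(sprintf("  %s = %.4g\n", nm, x$derived[[nm]]))
  }
  cat(sprintf("\nn = %d, RSS = %.4g, AICc = %.2f\n", x$n, x$rss, x$aicc))
  invisible(x)
}

# Flat parameter table used by the JSON/CSV fit exports.
.fit_record <- function(object) {
  est <- object$coefficients
  data.frame(parameter = names(est),
             estimate = as.numeric(est),
             stderr = as.numeric(object$se[names(est)]),
             row.names = NULL)
}
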