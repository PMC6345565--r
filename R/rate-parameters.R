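# Avogadro's number (mol^-1)
.N_AVOGADRO <- 6.022e23

#' Local concentration of a tethered binding domain
#'
#' After one domain of a homobivalent ligand has bound, its second, still free
#' domain is confined near the neighbouring target site.  Its effective
#' ("local") concentration is modelled as that of a single molecule inside a
#' half-sphere whose radius is the inter-domain reach \code{r}.
#'
#' @param r_angstrom Inter-domain reach radius in ångström (> 0).
#'
#' @return Local concentration in molar.
#'
#' @details The half-sphere volume is \eqn{(2/3)\pi r^3} with \eqn{r} in
#'   decimetres (1 Å = 1e-9 dm), so the result is
#'   \eqn{1 / (N_A \cdot (2/3)\pi r^3)} mol/L.
#'
#' @examples
#' local_concentration(180)   # ~1.36e-4 M for an 18 nm reach
#' @export
local_concentration <- function(r_angstrom) {
  if (!is.numeric(r_angstrom) || any(!is.finite(r_angstrom)) || any(r_angstrom <= 0))
    stop("`r_angstrom` must be a positive finite number", call. = FALSE)
  r_dm <- r_angstrom * 1e-9
  1 / (.N_AVOGADRO * (2 / 3) * pi * r_dm^3)
}

#' Composite intramolecular rebinding rate constant
#'
#' First-order rate constant for closure of the singly bound complex into the
#' bivalently bound one: the intrinsic bimolecular rate \code{k1} acting on the
#' local concentration of the tethered domain, reduced by a dimensionless
#' penalty factor \code{f} that lumps steric hindrance, restricted rotation and
#' entropic cost.
#'
#' @param k1 Intrinsic association rate constant (M^-1 min^-1, > 0).
#' @param r_angstrom Inter-domain reach radius in ångström (> 0).
#' @param f Penalty factor (dimensionless, > 0; 1 means no penalty).
#'
#' @return Composite first-order rate constant k2 in min^-1.
#'
#' @examples
#' composite_k2(1.85e5, 180, 185)   # ~0.136 min^-1
#' @export
composite_k2 <- function(k1, r_angstrom, f) {
  if (!is.numeric(k1) || any(!is.finite(k1)) || any(k1 <= 0))
    stop("`k1` must be a positive finite number", call. = FALSE)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be a positive finite number", call. = FALSE)
  k1 * local_concentration(r_angstrom) / f
}

#' Intrinsic dissociation constant
#'
#' @param k1 Association rate constant (M^-1 min^-1, > 0).
#' @param k_off Dissociation rate constant (min^-1, >= 0).
#'
#' @return Kd = k_off / k1 in molar.
#' @examples
#' intrinsic_kd(1.85e5, 0.0085)   # 45.9 nM
#' @export
intrinsic_kd <- function(k1, k_off) {
  if (!is.numeric(k1) || any(!is.finite(k1)) || any(k1 <= 0))
    stop("`k1` must be a positive finite number", call. = FALSE)
  if (!is.numeric(k_off) || any(!is.finite(k_off)) || any(k_off < 0))
    stop("`k_off` must be a non-negative finite number", call. = FALSE)
  k_off / k1
}

#' Rate-parameter set for the homobivalent binding scheme
#'
#' Bundles the intrinsic rate constants with the geometry-derived quantities:
#' the local concentration \code{L} of the tethered second domain, the
#' composite first-order rebinding rate \code{k2 = k1 * L / f}, and the
#' intrinsic dissociation constant \code{kd_int = k_off / k1}.
#'
#' @param k1 Intrinsic bimolecular association rate constant (M^-1 min^-1).
#' @param k_off Intrinsic dissociation rate constant (min^-1).
#' @param r Inter-domain reach radius in ångström.  May be omitted when an
#'   explicit `k2` is supplied.
#' @param f Penalty factor (dimensionless, >= 1 in the physical regime).
#' @param k2 Optional explicit composite rebinding rate (min^-1).  When both
#'   an explicit `k2` and (`r`, `f`) are given and they disagree by more than
#'   1 percent, a warning is raised and the explicit value wins.
#' @param stat_factors Integer multiplicities (s1..s4) applied to the four
#'   fluxes of the pooled-species scheme; see [bivalent_derivatives()].  The
#'   default `c(2, 2, 2, 1)` is the convention this package ships for the
#'   pooled singly-bound formulation (see the package vignette).
#'
#' @return An object of class `"avk_params"`: a list with elements `k1`,
#'   `k_off`, `r`, `f`, `L`, `k2`, `kd_int`, `stat_factors`.
#'
#' @examples
#' p <- rate_parameters(k1 = 1.85e5, k_off = 0.0085, r = 180, f = 185)
#' p$k2       # ~0.136 min^-1
#' p$kd_int   # ~4.59e-8 M
#' @export
rate_parameters <- function(k1, k_off, r = NULL, f = NULL, k2 = NULL,
                            stat_factors = c(2, 2, 2, 1)) {
  if (!is.numeric(k1) || length(k1) != 1 || !is.finite(k1) || k1 <= 0)
    stop("`k1` must be a single positive number", call. = FALSE)
  if (!is.numeric(k_off) || length(k_off) != 1 || !is.finite(k_off) || k_off < 0)
    stop("`k_off` must be a single non-negative number", call. = FALSE)
  if (length(stat_factors) != 4 || any(!is.finite(stat_factors)) ||
      any(stat_factors < 0))
    stop("`stat_factors` must be four non-negative numbers", call. = FALSE)

  L <- if (!is.null(r)) local_concentration(r) else NA_real_
  k2_derived <- if (!is.null(r) && !is.null(f)) composite_k2(k1, r, f) else NA_real_

  if (is.null(k2)) {
    if (is.na(k2_derived))
      stop("supply either `k2` or both `r` and `f`", call. = FALSE)
    k2 <- k2_derived
  } else {
    if (!is.numeric(k2) || length(k2) != 1 || !is.finite(k2) || k2 < 0)
      stop("`k2` must be a single non-negative number", call. = FALSE)
    if (!is.na(k2_derived) && k2_derived > 0 &&
        abs(k2 - k2_derived) / k2_derived > 0.01)
      warning(sprintf(
        "explicit k2 = %.4g min^-1 differs from derived k1*L/f = %.4g min^-1 by more than 1%%; using the explicit value",
        k2, k2_derived), call. = FALSE)
  }

  structure(
    list(k1 = k1, k_off = k_off,
         r = if (is.null(r)) NA_real_ else r,
         f = if (is.null(f)) NA_real_ else f,
         L = L, k2 = k2, kd_int = intrinsic_kd(k1, k_off),
         stat_factors = as.numeric(stat_factors)),
    class = "avk_params")
}

#' @export
print.avk_params <- function(x, ...) {
  cat("Homobivalent binding rate parameters\n")
  cat(sprintf("  k1     = %.4g M^-1 min^-1   (intrinsic association)\n", x$k1))
  cat(sprintf("  k_off  = %.4g min^-1        (intrinsic dissociation)\n", x$k_off))
  if (!is.na(x$r))
    cat(sprintf("  r      = %.4g angstrom      (inter-domain reach)\n", x$r))
  if (!is.na(x$f))
    cat(sprintf("  f      = %.4g               (penalty factor)\n", x$f))
  if (!is.na(x$L))
    cat(sprintf("  [L]    = %.4g M             (local concentration)\n", x$L))
  cat(sprintf("  k2     = %.4g min^-1        (composite rebinding)\n", x$k2))
  cat(sprintf("  Kd_int = %.4g M             (k_off / k1)\n", x$kd_int))
  cat(sprintf("  statistical factors (s1..s4): %s\n",
              paste(x$stat_factors, collapse = ", ")))
  invisible(x)
}

#' Published PICK1 rate-parameter set
#'
#' Convenience constructor for the rate constants used in the simulations of
#' dimeric PICK1 binding to membrane-embedded PDZ ligands: k1 = 1.85e5
#' M^-1 min^-1 and k_off = 0.0085 min^-1 from in-solution PDZ binding, an
#' inter-PDZ reach of 180 ångström from the SAXS-derived structure, and a
#' penalty factor f = 185, giving k2 = 0.136 min^-1 and Kd_int = 45.9 nM.
#'
#' @param ... Overrides passed on to [rate_parameters()].
#' @return An `"avk_params"` object.
#' @examples
#' pick1_parameters()
#' @export
pick1_parameters <- function(...) {
  args <- utils::modifyList(
    list(k1 = 1.85e5, k_off = 0.0085, r = 180, f = 185),
    list(...))
  do.call(rate_parameters, args)
}

#' Bulk-ligand incubation/washout schedule
#'
#' The bulk ligand is assumed in large excess over the membrane targets, so its
#' concentration is held exactly constant during incubation; during washout it
#' is exactly zero (released ligand does not rebind from the bulk).
#'
#' @param incubation_conc Bulk ligand concentration during incubation (molar,
#'   >= 0).
#' @param t_incubation Incubation duration in minutes (> 0).
#' @param washout Logical; follow incubation with a washout phase?
#' @param t_washout Washout duration in minutes (required when `washout`).
#'
#' @return An object of class `"avk_schedule"`.
#' @examples
#' ligand_schedule(200e-9, 120, washout = TRUE, t_washout = 600)
#' @export
ligand_schedule <- function(incubation_conc, t_incubation = 120,
                            washout = FALSE, t_washout = NULL) {
  if (!is.numeric(incubation_conc) || length(incubation_conc) != 1 ||
      !is.finite(incubation_conc) || incubation_conc < 0)
    stop("`incubation_conc` must be a single non-negative molar concentration",
         call. = FALSE)
  if (!is.numeric(t_incubation) || t_incubation <= 0)
    stop("`t_incubation` must be positive (minutes)", call. = FALSE)
  if (washout) {
    if (is.null(t_washout) || !is.numeric(t_washout) || t_washout <= 0)
      stop("`t_washout` must be positive when `washout = TRUE`", call. = FALSE)
  } else t_washout <- 0
  structure(list(incubation_conc = incubation_conc,
                 t_incubation = t_incubation,
                 washout = isTRUE(washout),
                 t_washout = t_washout),
            class = "avk_schedule")
}

#' @export
print.avk_schedule <- function(x, ...) {
  cat(sprintf("Incubation: %.4g nM for %g min", x$incubation_conc * 1e9,
              x$t_incubation))
  if (x$washout) cat(sprintf("; washout ([aa] = 0) for %g min", x$t_washout))
  cat("\n")
  invisible(x)
}
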