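# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the global stream is used (non-reproducible).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.add_noise <- function(y, sd, type = c("proportional", "absolute")) {
  type <- match.arg(type)
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0)
    stop("noise `sd` must be a single non-negative number", call. = FALSE)
  if (sd == 0) return(y)
  if (type == "proportional") y * (1 + stats::rnorm(length(y), 0, sd))
  else y + stats::rnorm(length(y), 0, sd)
}

#' Generate a synthetic saturation dose-response table
#'
#' Sigmoidal saturation data from [dose_response_model()] with Gaussian noise,
#' for exercising [fit_dose_response()] against known truth.  Defaults emulate
#' a membrane-sheet saturation experiment: apparent Kd* = 47 nM, Bmax = 100 on
#' a 7-point log grid from 1 nM to 1 µM with 3 replicates and 5 % proportional
#' noise.
#'
#' @param ec50,top,bottom,hill Generating truth, see [dose_response_model()].
#' @param conc Concentration grid (molar).
#' @param replicates Number of replicate measurements per concentration.
#' @param noise_sd Gaussian noise level (default 0.05).
#' @param noise_type `"proportional"` (sd is a fraction of the signal,
#'   default) or `"absolute"` (signal units).
#' @param seed Integer seed fixing the output exactly; `NULL` draws from the
#'   global stream.
#' @return Data frame with columns `conc`, `replicate`, `signal`; the truth
#'   parameters are attached as attribute `truth`.
#' @examples
#' d <- gen_saturation(seed = 1)
#' fit_dose_response(d)
#' @export
gen_saturation <- function(ec50 = 47e-9, top = 100, bottom = 0, hill = 1,
                           conc = 10^seq(-9, -6, length.out = 7),
                           replicates = 3, noise_sd = 0.05,
                           noise_type = c("proportional", "absolute"),
                           seed = NULL) {
  noise_type <- match.arg(noise_type)
  if (any(conc < 0)) stop("`conc` must be non-negative", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  grid <- expand.grid(replicate = seq_len(replicates), conc = conc)
  mu <- dose_response_model(grid$conc, top, bottom, ec50, hill)
  sig <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
  out <- data.frame(conc = grid$conc, replicate = grid$replicate, signal = sig)
  attr(out, "truth") <- list(ec50 = ec50, top = top, bottom = bottom,
                             hill = hill, noise_sd = noise_sd,
                             noise_type = noise_type)
  out
}

#' Generate a synthetic exponential-decay time course
#'
#' One-phase (`half_life` scalar) or two-phase (`half_life` length 2, with
#' `fraction_fast`) dissociation traces.  Defaults mirror the washout
#' experiments: sampling every 30 min out to 600 min and 2 % proportional
#' noise; the stock truths are a slow single phase (431 min) or fast/slow
#' phases of 21 and 373 min.
#'
#' @param half_life Half-life in minutes (length 1) or `c(fast, slow)`
#'   half-lives (length 2).
#' @param fraction_fast Fraction of the amplitude in the fast phase
#'   (two-phase only, default 0.4).
#' @param amplitude Total amplitude at time 0 (default 1).
#' @param times Sampling times in minutes (default `seq(0, 600, by = 30)`).
#' @param noise_sd,noise_type,seed As in [gen_saturation()]; default 2 %
#'   proportional noise.
#' @return Data frame with columns `time`, `signal` and attribute `truth`.
#' @examples
#' d <- gen_decay(half_life = c(21, 373), seed = 1)
#' fit_decay(d, mode = "two")
#' @export
gen_decay <- function(half_life = 431, fraction_fast = 0.4, amplitude = 1,
                      times = seq(0, 600, by = 30), noise_sd = 0.02,
                      noise_type = c("proportional", "absolute"),
                      seed = NULL) {
  noise_type <- match.arg(noise_type)
  if (any(half_life <= 0)) stop("`half_life` must be positive", call. = FALSE)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  k <- log(2) / half_life
  if (length(half_life) == 1) {
    mu <- amplitude * exp(-k * times)
  } else if (length(half_life) == 2) {
    if (fraction_fast < 0 || fraction_fast > 1)
      stop("`fraction_fast` must be in [0, 1]", call. = FALSE)
    kf <- max(k); ks <- min(k)
    mu <- amplitude * (fraction_fast * exp(-kf * times) +
                         (1 - fraction_fast) * exp(-ks * times))
  } else stop("`half_life` must have length 1 or 2", call. = FALSE)
  sig <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
  out <- data.frame(time = times, signal = sig)
  attr(out, "truth") <- list(half_life = half_life,
                             fraction_fast = if (length(half_life) == 2)
                               fraction_fast else NA_real_,
                             amplitude = amplitude, noise_sd = noise_sd,
                             noise_type = noise_type)
  out
}

#' Generate a synthetic fluorescence-polarization titration
#'
#' Saturation mode titrates protein against a fixed tracer
#' ([fp_saturation_model()]); competition mode titrates unlabeled competitor
#' at fixed protein ([fp_competition_model()]).  Default truths: Kd = 9 µM,
#' Ki = 2.1 µM, free/bound polarizations 50 and 250, 3 % proportional noise.
#'
#' @param mode `"saturation"` or `"competition"`.
#' @param kd,ki,fp_free,fp_bound Generating truth (molar; polarization units
#'   are opaque).
#' @param rt Protein grid (saturation mode) or the fixed protein concentration
#'   (competition mode; default 70 percent saturating, `kd * 7/3`).
#' @param x Competitor grid (competition mode, molar).
#' @param noise_sd,noise_type,seed As in [gen_saturation()].
#' @return Data frame with columns `rt`, `fp` (saturation) or `x`, `fp`
#'   (competition) and attribute `truth`.
#' @examples
#' fit_fp_saturation(gen_fp("saturation", seed = 1))
#' @export
gen_fp <- function(mode = c("saturation", "competition"), kd = 9e-6,
                   ki = 2.1e-6, fp_free = 50, fp_bound = 250,
                   rt = NULL, x = 10^seq(-8, -3, length.out = 10),
                   noise_sd = 0.03,
                   noise_type = c("proportional", "absolute"), seed = NULL) {
  mode <- match.arg(mode)
  noise_type <- match.arg(noise_type)
  if (mode == "saturation") {
    if (is.null(rt)) rt <- 10^seq(-7, -3.5, length.out = 10)
    mu <- fp_saturation_model(rt, fp_free, fp_bound, kd)
    fp <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
    out <- data.frame(rt = rt, fp = fp)
  } else {
    if (is.null(rt)) rt <- kd * 7 / 3
    if (length(rt) != 1) stop("competition mode needs a single fixed `rt`",
                              call. = FALSE)
    mu <- fp_competition_model(x, fp_free, fp_bound, rt, kd, ki)
    fp <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
    out <- data.frame(x = x, fp = fp)
  }
  attr(out, "truth") <- list(mode = mode, kd = kd,
                             ki = if (mode == "competition") ki else NA_real_,
                             fp_free = fp_free, fp_bound = fp_bound,
                             rt = rt, noise_sd = noise_sd,
                             noise_type = noise_type)
  out
}

#' Generate a synthetic two-channel ROI table with planted QC outliers
#'
#' Builds a membrane-sheet ROI table in the dialect consumed by
#' [quantify_binding()], with known per-sheet ligand/receptor ratios and
#' planted saturated and dim sheets.  Observed intensities are constructed by
#' inverting [corrected_intensity()] under the supplied calibrations, so at
#' zero noise the quantified ratios equal the planted truth exactly.
#'
#' @param n_pass,n_saturated,n_dim Sheet counts per planted QC class.
#' @param ratios Planted true ratios for the passing sheets (recycled to
#'   `n_pass`; default 1.5).
#' @param receptor_intensity Corrected receptor-channel intensity of passing
#'   sheets (arbitrary units, default 1000).
#' @param background_mean,background_sd Background intensity distribution per
#'   channel (default 100 and 5).
#' @param condition,conc_nM Metadata columns (defaults `"synthetic"`, 100).
#' @param cal_ligand,cal_receptor [channel_calibration()] objects used when
#'   inverting the intensity correction.
#' @param noise_sd,noise_type Noise on the observed intensities (default 0).
#' @param seed Integer seed.
#' @return ROI data frame (two rows per sheet: `ch = "ligand"` and
#'   `"receptor"`) with attribute `truth` holding the planted ratios and the
#'   planted per-sheet QC status.
#' @examples
#' tab <- gen_roi_table(seed = 1)
#' attr(quantify_binding(tab), "qc_counts")
#' @export
gen_roi_table <- function(n_pass = 10, n_saturated = 2, n_dim = 3,
                          ratios = 1.5, receptor_intensity = 1000,
                          background_mean = 100, background_sd = 5,
                          condition = "synthetic", conc_nM = 100,
                          cal_ligand = channel_calibration(),
                          cal_receptor = channel_calibration(),
                          noise_sd = 0, noise_type = "proportional",
                          seed = NULL) {
  stopifnot(n_pass >= 0, n_saturated >= 0, n_dim >= 0)
  n <- n_pass + n_saturated + n_dim
  status <- rep(c("pass", "saturated", "dim"), c(n_pass, n_saturated, n_dim))
  ratios <- rep_len(ratios, n_pass)
  .with_seed(seed, {
    sheet_id <- sprintf("sheet_%02d", seq_len(n))
    # backgrounds drawn per sheet and channel
    back_l <- stats::rnorm(n, background_mean, background_sd)
    back_r <- stats::rnorm(n, background_mean, background_sd)
    # corrected target intensities per planted class
    corr_r <- rep(receptor_intensity, n)
    corr_l <- numeric(n)
    corr_l[status == "pass"] <- ratios * receptor_intensity
    # dim sheets sit within the dim threshold (obs below back + 2 sd);
    # saturated sheets are bright but carry the saturation flag
    corr_l[status == "saturated"] <- 2 * receptor_intensity
    dim_idx <- status == "dim"
    # invert the correction: i_obs = L * (corr / G + i_back)
    obs_from <- function(corr, back, cal)
      cal$labeling_degree * (corr / cal$gain + back)
    i_obs_l <- obs_from(corr_l, back_l, cal_ligand)
    i_obs_r <- obs_from(corr_r, back_r, cal_receptor)
    # plant dim sheets directly in observed units: barely above background
    i_obs_l[dim_idx] <- back_l[dim_idx] + 0.2 * background_sd
    i_obs_r[dim_idx] <- back_r[dim_idx] + 0.2 * background_sd
    if (noise_sd > 0) {
      keep <- !dim_idx
      i_obs_l[keep] <- .add_noise(i_obs_l[keep], noise_sd, noise_type)
      i_obs_r[keep] <- .add_noise(i_obs_r[keep], noise_sd, noise_type)
    }
    out <- rbind(
      data.frame(sheet_id = sheet_id, condition = condition,
                 conc_nM = conc_nM, ch = "ligand", i_obs = i_obs_l,
                 i_back = back_l, saturated = status == "saturated"),
      data.frame(sheet_id = sheet_id, condition = condition,
                 conc_nM = conc_nM, ch = "receptor", i_obs = i_obs_r,
                 i_back = back_r, saturated = status == "saturated"))
    out <- out[order(out$sheet_id, out$ch), ]
    rownames(out) <- NULL
    attr(out, "truth") <- list(
      status = stats::setNames(status, sheet_id),
      ratios = stats::setNames(rep(NA_real_, n), sheet_id))
    attr(out, "truth")$ratios[status == "pass"] <- ratios
    out
  })
}

#' Sample noisy tables from the mechanistic bivalent-binding simulator
#'
#' Runs the kinetic model and emits tables in the dialects consumed by the
#' empirical fits: `mode = "saturation"` gives an endpoint dose-response table
#' (`conc`, `replicate`, `signal`); `mode = "washout"` gives a normalized
#' dissociation time course (`time`, `signal`) after pre-incubation.
#'
#' @param params An [rate_parameters()] object (default [pick1_parameters()]).
#' @param mode `"saturation"` or `"washout"`.
#' @param conc Saturation concentration grid (molar).
#' @param preincubation_conc Washout pre-incubation bulk concentration
#'   (molar, default 200 nM).
#' @param t_incubation Incubation time in minutes (default 120).
#' @param times Washout sampling times (minutes from washout start, default
#'   `seq(0, 600, by = 30)`).
#' @param replicates Replicates per concentration (saturation mode).
#' @param noise_sd,noise_type,seed As in [gen_saturation()]; default 5 %
#'   proportional noise.
#' @param signal Signal definition, see [simulate_time_course()].
#' @return Data frame in the respective dialect with attribute `truth`
#'   (parameters and the noiseless trace).
#' @examples
#' d <- gen_mechanistic(mode = "washout", preincubation_conc = 200e-9,
#'                      seed = 1)
#' compare_decay_models(d)
#' @export
gen_mechanistic <- function(params = pick1_parameters(),
                            mode = c("saturation", "washout"),
                            conc = 10^seq(-9, -6, length.out = 8),
                            preincubation_conc = 200e-9,
                            t_incubation = 120,
                            times = seq(0, 600, by = 30),
                            replicates = 1, noise_sd = 0.05,
                            noise_type = c("proportional", "absolute"),
                            seed = NULL, signal = "ligand") {
  mode <- match.arg(mode)
  noise_type <- match.arg(noise_type)
  if (mode == "saturation") {
    sat <- simulate_saturation_curve(params, conc, t_incubation,
                                     signal = signal)
    grid <- expand.grid(replicate = seq_len(replicates), conc = sat$conc)
    mu <- rep(sat$total_signal, each = replicates)
    sig <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
    out <- data.frame(conc = grid$conc, replicate = grid$replicate,
                      signal = sig)
    attr(out, "truth") <- list(params = params, mode = mode,
                               noiseless = sat, noise_sd = noise_sd)
    return(out)
  }
  sched <- ligand_schedule(preincubation_conc, t_incubation, washout = TRUE,
                           t_washout = max(times))
  tc <- simulate_time_course(params, sched,
                             sample_times = c(0, t_incubation + times),
                             signal = signal)
  wash <- tc[tc$time_min >= t_incubation, ]
  mu <- wash$signal / wash$signal[1]   # normalized to the washout start
  sig <- .with_seed(seed, .add_noise(mu, noise_sd, noise_type))
  out <- data.frame(time = wash$time_min - t_incubation, signal = sig)
  attr(out, "truth") <- list(params = params, mode = mode,
                             preincubation_conc = preincubation_conc,
                             noiseless = data.frame(time = out$time,
                                                    signal = mu),
                             noise_sd = noise_sd)
  out
}
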