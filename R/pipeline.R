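# Pipeline entry points: each takes a run configuration (a named list or a
# YAML-ish key:value file) and writes the module's standard outputs.  A thin
# command-line front-end over these functions ships in inst/cli/pdzavidity.R.

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("`config` must be a named list or the path to a config file",
         call. = FALSE)
  config
}

.log_stage <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

#' Run a saturation or dissociation simulation from a configuration
#'
#' Configuration fields: a `parameters` block (see [read_rate_config()] for
#' the keys), `mode` (`"saturation"` or `"dissociation"`), `output` (CSV
#' path), and either `conc_nM` (grid; default 8 log-spaced points 1-1000) plus
#' `t_incubation_min`, or `preincubation_nM` plus `t_washout_min`.  Optional:
#' `signal` ("ligand"/"complex"), `plot` (PNG path).
#'
#' @param config Named list or path to a config file.
#' @param verbose Log derived constants and record counts (default TRUE).
#' @return The simulation object, invisibly.
#' @export
run_simulate <- function(config, verbose = TRUE) {
  cfg <- .load_config(config)
  if (is.null(cfg$parameters))
    stop("config is missing the `parameters` block", call. = FALSE)
  params <- .params_from_config(cfg$parameters)
  mode <- match.arg(cfg$mode %||% "saturation", c("saturation", "dissociation"))
  out_path <- cfg$output %||% stop("config is missing `output`", call. = FALSE)
  signal <- cfg$signal %||% "ligand"
  t_inc <- cfg$t_incubation_min %||% 120
  .log_stage(verbose,
             "simulate(%s): [L] = %.4g M, k2 = %.4g min^-1, Kd_int = %.4g M",
             mode, params$L, params$k2, params$kd_int)

  if (mode == "saturation") {
    conc <- (cfg$conc_nM %||% 10^seq(0, 3, length.out = 8)) * 1e-9
    sat <- simulate_saturation_curve(params, conc, t_inc, signal = signal)
    write_saturation_csv(sat, out_path)
    .log_stage(verbose, "simulate(saturation): %d concentrations -> %s",
               nrow(sat), out_path)
    res <- sat
  } else {
    pre <- (cfg$preincubation_nM %||%
              stop("dissociation config needs `preincubation_nM`",
                   call. = FALSE)) * 1e-9
    t_wash <- cfg$t_washout_min %||% 600
    sched <- ligand_schedule(pre, t_inc, washout = TRUE, t_washout = t_wash)
    tc <- simulate_time_course(params, sched, signal = signal)
    write_timecourse_csv(tc, out_path)
    .log_stage(verbose, "simulate(dissociation): %d samples -> %s",
               nrow(tc), out_path)
    res <- tc
  }
  if (!is.null(cfg$plot)) {
    grDevices::png(cfg$plot, width = 720, height = 540)
    plot(res)
    grDevices::dev.off()
  }
  invisible(res)
}

#' Run a curve fit from a configuration
#'
#' Configuration fields: `fit` (one of `"saturation"`, `"competition"`,
#' `"association"`, `"dissociation"`, `"fp-saturation"`, `"fp-competition"`),
#' `input` (CSV in the matching dialect), `output_json`, and optionally
#' `output_csv`, `variable_slope`, `mode` ("one"/"two" for dissociation),
#' `rt_M`/`kd_M` (FP competition), `g_factor`.
#'
#' @param config Named list or path to a config file.
#' @param verbose Log a stage summary (default TRUE).
#' @return The fit object, invisibly.
#' @export
run_fit <- function(config, verbose = TRUE) {
  cfg <- .load_config(config)
  kind <- match.arg(cfg$fit %||% stop("config is missing `fit`", call. = FALSE),
                    c("saturation", "competition", "association",
                      "dissociation", "fp-saturation", "fp-competition"))
  input <- cfg$input %||% stop("config is missing `input`", call. = FALSE)
  fit <- switch(kind,
    "saturation" = fit_dose_response(read_dose_table(input),
                                     variable_slope = isTRUE(cfg$variable_slope)),
    "competition" = fit_competition(read_dose_table(input),
                                    variable_slope = isTRUE(cfg$variable_slope)),
    "association" = fit_association(read_timecourse_table(input)),
    "dissociation" = fit_decay(read_timecourse_table(input),
                               mode = cfg$mode %||% "one"),
    "fp-saturation" = {
      d <- read_fp_table(input, g = cfg$g_factor %||% 1)
      fit_fp_saturation(data.frame(rt = d$conc, fp = d$fp))
    },
    "fp-competition" = {
      d <- read_fp_table(input, g = cfg$g_factor %||% 1)
      fit_fp_competition(data.frame(x = d$conc, fp = d$fp),
                         rt = cfg$rt_M %||% stop("fp-competition needs `rt_M`",
                                                 call. = FALSE),
                         kd = cfg$kd_M %||% stop("fp-competition needs `kd_M`",
                                                 call. = FALSE))
    })
  if (!is.null(cfg$output_json)) write_fit_json(fit, cfg$output_json)
  if (!is.null(cfg$output_csv)) write_fit_summary_csv(fit, cfg$output_csv)
  .log_stage(verbose, "fit(%s): n = %d, RSS = %.4g%s", kind, fit$n, fit$rss,
             if (!is.null(cfg$output_json))
               paste0(" -> ", cfg$output_json) else "")
  invisible(fit)
}

#' Quantify a membrane-sheet ROI table from a configuration
#'
#' Configuration fields: `input` (ROI CSV), `output` (quantified CSV),
#' optional `calibration` block with `ligand`/`receptor` sub-blocks (keys
#' `labeling_degree`, `pmt_v1`, `pmt_v2`, `alpha`, `n_dynodes`) and
#' `sigma_mult`.
#'
#' @param config Named list or path to a config file.
#' @param verbose Log QC counts (default TRUE).
#' @return The quantified data frame, invisibly.
#' @export
run_quantify <- function(config, verbose = TRUE) {
  cfg <- .load_config(config)
  input <- cfg$input %||% stop("config is missing `input`", call. = FALSE)
  out_path <- cfg$output %||% stop("config is missing `output`", call. = FALSE)
  cal_of <- function(blk) {
    if (is.null(blk)) return(channel_calibration())
    do.call(channel_calibration, blk)
  }
  rois <- read_roi_table(input)
  res <- quantify_binding(rois,
                          cal_ligand = cal_of(cfg$calibration$ligand),
                          cal_receptor = cal_of(cfg$calibration$receptor),
                          sigma_mult = cfg$sigma_mult %||% 2)
  counts <- attr(res, "qc_counts")
  if (counts[["pass"]] == 0)
    warning("no sheets passed QC", call. = FALSE)
  utils::write.csv(res, out_path, row.names = FALSE, quote = FALSE)
  .log_stage(verbose, "quantify: %d pass / %d saturated / %d dim -> %s",
             counts[["pass"]], counts[["saturated"]], counts[["dim"]],
             out_path)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
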