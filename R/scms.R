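#' Degree of labeling (dye per protein) from absorbance
#'
#' Standard spectrophotometric DOL: moles of dye per mole of protein,
#' \deqn{DOL = \frac{A_{dye}/\varepsilon_{dye}}{(A_{280} - A_{dye}\,cf_{280})/\varepsilon_{280}}}
#' where `cf_280` is the dye's 280-nm correction factor (the fraction of the
#' dye's peak absorbance it contributes at 280 nm; 0 when the dye does not
#' absorb there).
#'
#' @param a_dye Absorbance at the dye excitation maximum (>= 0).
#' @param a_280 Absorbance at 280 nm (>= 0).
#' @param eps_280 Protein molar extinction coefficient at 280 nm (> 0).
#' @param eps_dye Dye molar extinction coefficient (> 0).
#' @param cf_280 Dye 280-nm correction factor (default 0).
#' @return Labeling degree (mol dye / mol protein).
#' @examples
#' degree_of_labeling(a_dye = 0.5, a_280 = 1.0, eps_280 = 5e4, eps_dye = 7e4,
#'                    cf_280 = 0.1)   # ~0.376
#' @export
degree_of_labeling <- function(a_dye, a_280, eps_280, eps_dye, cf_280 = 0) {
  if (any(a_dye < 0) || any(a_280 < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  if (any(eps_280 <= 0) || any(eps_dye <= 0))
    stop("extinction coefficients must be positive", call. = FALSE)
  protein <- (a_280 - a_dye * cf_280) / eps_280
  if (any(protein <= 0))
    stop("corrected protein absorbance is non-positive; check cf_280 and A280",
         call. = FALSE)
  (a_dye / eps_dye) / protein
}

#' PMT gain correction factor between two detector voltages
#'
#' Photomultiplier gain scales as voltage to the power of the dynode
#' conductance exponent times the number of dynodes:
#' \deqn{G(V) = (V_2/V_1)^{\alpha n}}
#'
#' @param v1 Reference PMT voltage (> 0).
#' @param v2 Acquisition PMT voltage (> 0).
#' @param alpha Dynode conductance exponent (dimensionless, >= 0).
#' @param n_dynodes Number of dynodes (>= 0).
#' @return Multiplicative intensity correction factor.
#' @examples
#' gain_correction(500, 550, alpha = 0.7, n_dynodes = 10)   # 1.1^7
#' @export
gain_correction <- function(v1, v2, alpha, n_dynodes) {
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("PMT voltages must be positive", call. = FALSE)
  if (any(alpha < 0) || any(n_dynodes < 0))
    stop("`alpha` and `n_dynodes` must be non-negative", call. = FALSE)
  (v2 / v1)^(alpha * n_dynodes)
}

#' Channel calibration record
#'
#' @param labeling_degree Labeled fraction of the imaged protein, in (0, 1].
#' @param pmt_v1,pmt_v2 Reference and acquisition PMT voltages (volts).
#' @param alpha Dynode conductance exponent.
#' @param n_dynodes Number of PMT dynodes.
#' @return A `"channel_calibration"` list with the precomputed `gain`.
#' @export
channel_calibration <- function(labeling_degree = 1, pmt_v1 = 1, pmt_v2 = 1,
                                alpha = 1, n_dynodes = 0) {
  if (labeling_degree <= 0 || labeling_degree > 1)
    stop("`labeling_degree` must be in (0, 1]", call. = FALSE)
  structure(list(labeling_degree = labeling_degree,
                 pmt_v1 = pmt_v1, pmt_v2 = pmt_v2,
                 alpha = alpha, n_dynodes = n_dynodes,
                 gain = gain_correction(pmt_v1, pmt_v2, alpha, n_dynodes)),
            class = "channel_calibration")
}

#' Background-, labeling- and gain-corrected ROI intensity
#'
#' \deqn{I_{corr} = (I_{obs} / L) G(V) - I_{back} G(V)}
#' The labeling correction divides the observed intensity by the labeled
#' fraction `L` (unlabeled protein is invisible, so raw intensity undercounts
#' it); the background is gain-corrected but not labeling-corrected.  Negative
#' corrected intensities are returned as-is with a `"flagged_dim"` attribute
#' rather than clipped.
#'
#' @param i_obs Observed mean ROI intensity (>= 0; vectorised).
#' @param i_back Mean background intensity (>= 0).
#' @param labeling_degree Labeled fraction in (0, 1].
#' @param gain Gain correction factor from [gain_correction()] (default 1).
#' @return Corrected intensity, with attribute `flagged_dim` marking entries
#'   that fell at or below zero.
#' @examples
#' corrected_intensity(100, 10, labeling_degree = 0.72)   # ~128.9
#' @export
corrected_intensity <- function(i_obs, i_back, labeling_degree = 1, gain = 1) {
  if (any(i_obs < 0) || any(i_back < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(labeling_degree <= 0) || any(labeling_degree > 1))
    stop("`labeling_degree` must be in (0, 1]", call. = FALSE)
  out <- (i_obs / labeling_degree) * gain - i_back * gain
  structure(out, flagged_dim = out <= 0)
}

#' QC-filter membrane-sheet ROI measurements
#'
#' Partitions sheets into `pass`, `saturated` (any channel carries a
#' saturated-pixel flag) and `dim` (any channel's observed intensity lies
#' below its own background plus `sigma_mult` standard deviations of the
#' channel's background distribution).
#'
#' @param rois Data frame with columns `sheet_id`, `ch`, `i_obs`, `i_back`,
#'   `saturated` (logical); other columns are carried along.
#' @param sigma_mult Background-sd multiplier for the dim threshold
#'   (default 2).
#' @return The input with a per-sheet `qc_status` column; the counts per
#'   status are attached as attribute `qc_counts`.
#' @examples
#' tab <- gen_roi_table(seed = 1)
#' table(qc_filter(tab)$qc_status) / 2   # two channel rows per sheet
#' @export
qc_filter <- function(rois, sigma_mult = 2) {
  need <- c("sheet_id", "ch", "i_obs", "i_back", "saturated")
  miss <- setdiff(need, names(rois))
  if (length(miss))
    stop("ROI table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(rois)) {
    warning("empty ROI table", call. = FALSE)
    rois$qc_status <- character(0)
    return(structure(rois, qc_counts = c(pass = 0, saturated = 0, dim = 0)))
  }
  bg_sd <- tapply(rois$i_back, rois$ch, stats::sd)
  bg_sd[is.na(bg_sd)] <- 0
  dim_row <- rois$i_obs < rois$i_back + sigma_mult * bg_sd[as.character(rois$ch)]
  sat_sheet <- tapply(rois$saturated, rois$sheet_id, any)
  dim_sheet <- tapply(dim_row, rois$sheet_id, any)
  status <- ifelse(sat_sheet[as.character(rois$sheet_id)], "saturated",
                   ifelse(dim_sheet[as.character(rois$sheet_id)], "dim", "pass"))
  rois$qc_status <- unname(status)
  counts <- c(pass = sum(sat_sheet == FALSE & dim_sheet == FALSE),
              saturated = sum(sat_sheet),
              dim = sum(!sat_sheet & dim_sheet))
  structure(rois, qc_counts = counts)
}

#' Normalized binding ratio of two corrected channel intensities
#'
#' @param ligand Corrected ligand-channel intensity.
#' @param receptor Corrected receptor-channel intensity (> 0).
#' @return `ligand / receptor`.
#' @export
normalized_binding <- function(ligand, receptor) {
  if (any(receptor <= 0))
    stop("undefined ratio: corrected receptor intensity must be positive",
         call. = FALSE)
  ligand / receptor
}

#' Quantify per-sheet normalized binding from a two-channel ROI table
#'
#' Runs [qc_filter()], applies [corrected_intensity()] per channel with the
#' supplied calibrations, and reports the ligand/receptor ratio for passing
#' sheets.
#'
#' @param rois Data frame in the ROI dialect: columns `sheet_id`, `condition`,
#'   `conc_nM`, `ch` (`"ligand"` or `"receptor"`), `i_obs`, `i_back`,
#'   `saturated`.
#' @param cal_ligand,cal_receptor [channel_calibration()] objects (defaults:
#'   unit calibration).
#' @param sigma_mult Dim-sheet threshold multiplier, see [qc_filter()].
#' @return Data frame with columns `sheet_id`, `condition`, `conc_nM`,
#'   `ratio` (NA unless `qc_status == "pass"`), `qc_status`; QC counts
#'   attached as attribute `qc_counts`.
#' @examples
#' quantify_binding(gen_roi_table(seed = 1))
#' @export
quantify_binding <- function(rois, cal_ligand = channel_calibration(),
                             cal_receptor = channel_calibration(),
                             sigma_mult = 2) {
  stopifnot(inherits(cal_ligand, "channel_calibration"),
            inherits(cal_receptor, "channel_calibration"))
  rois <- qc_filter(rois, sigma_mult = sigma_mult)
  if (!nrow(rois)) {
    return(structure(data.frame(sheet_id = character(0),
                                condition = character(0),
                                conc_nM = numeric(0), ratio = numeric(0),
                                qc_status = character(0)),
                     qc_counts = attr(rois, "qc_counts")))
  }
  if (!all(c("ligand", "receptor") %in% unique(rois$ch)))
    stop("ROI table must contain both a `ligand` and a `receptor` channel",
         call. = FALSE)
  per_sheet <- lapply(split(rois, rois$sheet_id), function(d) {
    lig <- d[d$ch == "ligand", ][1, ]
    rec <- d[d$ch == "receptor", ][1, ]
    ratio <- NA_real_
    status <- d$qc_status[1]
    if (status == "pass") {
      il <- corrected_intensity(lig$i_obs, lig$i_back,
                                cal_ligand$labeling_degree, cal_ligand$gain)
      ir <- corrected_intensity(rec$i_obs, rec$i_back,
                                cal_receptor$labeling_degree,
                                cal_receptor$gain)
      if (ir <= 0 || il <= 0) status <- "dim"
      else ratio <- normalized_binding(as.numeric(il), as.numeric(ir))
    }
    data.frame(sheet_id = d$sheet_id[1], condition = d$condition[1],
               conc_nM = d$conc_nM[1], ratio = ratio, qc_status = status)
  })
  out <- do.call(rbind, per_sheet)
  rownames(out) <- NULL
  counts <- table(factor(out$qc_status, levels = c("pass", "saturated", "dim")))
  structure(out, qc_counts = c(counts))
}
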