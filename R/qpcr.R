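#' Fit a qPCR standard curve
#'
#' Least-squares regression of Ct on log10(concentration) over a dilution
#' series. The amplification efficiency (fold amplification per cycle;
#' 2.0 = perfect doubling) is `10^(-1/slope)`; percent efficiency, when
#' wanted for reports, is `(E - 1) * 100`.
#'
#' @param concentration Standard concentrations (ng/uL, > 0), one per well.
#' @param ct Observed Ct values (cycles), same length.
#' @param target Optional label ("TEL"/"ALB") carried into the result.
#' @return List of class `standard_curve`: `target`, `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
#' @examples
#' conc <- 25 / 2^(0:4)
#' fit_standard_curve(conc, 30 - log2(conc / 1.5625))$efficiency  # 2.0
fit_standard_curve <- function(concentration, ct, target = NA_character_) {
  if (length(concentration) != length(ct))
    stop("concentration and ct lengths differ", call. = FALSE)
  if (any(concentration <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(concentration)) < 3)
    stop("insufficient standards: need >= 3 distinct concentrations",
         call. = FALSE)
  lx <- log10(concentration)
  fit <- stats::lm(ct ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative", call. = FALSE)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((ct - mean(ct))^2)
  structure(list(target = target,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ssr / sst,
                 efficiency = 10^(-1 / slope)),
            class = "standard_curve")
}

#' Collapse replicate Ct wells for one reaction
#'
#' Arithmetic mean of the replicate Cts with QC flags: `HIGH_RANGE` when the
#' replicate spread (max - min) exceeds `qc_range` cycles, `LOW_REPLICATES`
#' when fewer than 3 wells are present. Flagged reactions are retained, not
#' dropped.
#'
#' @param ct Replicate Ct values for one sample x target (>= 1 well).
#' @param qc_range Allowed Ct range across replicates (default 0.5 cycles).
#' @return List with `mean_ct` and `qc_flags` (character vector, possibly
#'   empty).
#' @export
collapse_triplicates <- function(ct, qc_range = 0.5) {
  ct <- ct[is.finite(ct)]
  if (length(ct) == 0)
    stop("missing reaction: no Ct wells to collapse", call. = FALSE)
  flags <- character(0)
  if (length(ct) < 3) flags <- c(flags, "LOW_REPLICATES")
  if (length(ct) > 1 && diff(range(ct)) > qc_range)
    flags <- c(flags, "HIGH_RANGE")
  list(mean_ct = mean(ct), qc_flags = flags)
}

#' Efficiency-corrected relative T/S ratio
#'
#' The relative telomere (T) to single-copy gene (S; albumin) ratio of a
#' sample against the calibrator, with per-target amplification
#' efficiencies:
#' \deqn{TS = E_{tel}^{\,Ct^{cal}_{tel} - Ct^{s}_{tel}} /
#'       E_{alb}^{\,Ct^{cal}_{alb} - Ct^{s}_{alb}}}
#' When both efficiencies are 2 this reduces to the textbook
#' \eqn{2^{-\Delta\Delta Ct}}. The calibrator's own ratio is exactly 1.
#'
#' @param tel_ct,alb_ct Sample mean Cts for the telomere and albumin
#'   reactions.
#' @param cal_tel_ct,cal_alb_ct Calibrator mean Cts.
#' @param e_tel,e_alb Amplification efficiencies in (1, 2.2].
#' @return Positive numeric T/S ratio.
#' @export
#' @examples
#' compute_ts_ratio(20, 18, 22, 18, 2, 2)  # 2^2 / 2^0 = 4
compute_ts_ratio <- function(tel_ct, alb_ct, cal_tel_ct, cal_alb_ct,
                             e_tel, e_alb) {
  cts <- c(tel_ct, alb_ct, cal_tel_ct, cal_alb_ct)
  if (!all(is.finite(cts))) stop("all Cts must be finite", call. = FALSE)
  if (e_tel <= 1 || e_tel > 2.2 || e_alb <= 1 || e_alb > 2.2)
    stop("efficiencies must lie in (1, 2.2]", call. = FALSE)
  e_tel^(cal_tel_ct - tel_ct) / e_alb^(cal_alb_ct - alb_ct)
}

#' Quantify a plate into per-sample T/S ratios
#'
#' Runs the full quantification for one plate: fits per-target standard
#' curves (efficiencies, R^2), collapses replicate wells with QC, and
#' computes efficiency-corrected T/S ratios. Two modes are provided:
#' `"calibrator"` (default) references each sample's delta-Cts to the
#' designated calibrator sample; `"curve"` converts Cts to standard-curve
#' quantities per target and ratios them, normalized so the calibrator's
#' ratio is 1.
#'
#' @param plate `qpcr_plate` object or path readable by [read_plate()].
#' @param fix_efficiency Optional named vector `c(TEL = , ALB = )` to pin
#'   efficiencies (e.g. the published 1.87 / 1.90) instead of the per-plate
#'   fitted ones.
#' @param qc_range Replicate Ct range threshold (cycles), see
#'   [collapse_triplicates()].
#' @param mode `"calibrator"` or `"curve"`.
#' @return List of class `ts_quant`: `ts` (data.frame `sample_id`, `ts`,
#'   `tel_ct_mean`, `alb_ct_mean`, `qc_flags`), `curves` (per-target
#'   `standard_curve`), `duplicate_pairs`.
#' @export
quantify_plate <- function(plate, fix_efficiency = NULL, qc_range = 0.5,
                           mode = c("calibrator", "curve")) {
  mode <- match.arg(mode)
  if (is.character(plate)) plate <- read_plate(plate)
  wells <- plate$wells

  curves <- lapply(c(TEL = "TEL", ALB = "ALB"), function(tg) {
    std <- wells[wells$role == "standard" & wells$target == tg, ]
    if (nrow(std) == 0) return(NULL)
    fit_standard_curve(std$concentration, std$Ct, target = tg)
  })
  eff <- c(TEL = curves$TEL$efficiency %||% NA_real_,
           ALB = curves$ALB$efficiency %||% NA_real_)
  if (!is.null(fix_efficiency)) {
    eff[names(fix_efficiency)] <- fix_efficiency
  }
  if (any(!is.finite(eff)))
    stop("efficiencies unavailable: no standards and no fix_efficiency",
         call. = FALSE)

  cal <- wells[wells$role == "calibrator", ]
  if (nrow(cal) == 0)
    stop("configuration error: plate has no designated calibrator sample",
         call. = FALSE)
  cal_tel <- collapse_triplicates(cal$Ct[cal$target == "TEL"], qc_range)
  cal_alb <- collapse_triplicates(cal$Ct[cal$target == "ALB"], qc_range)

  smp <- wells[wells$role %in% c("sample", "calibrator"), ]
  ids <- unique(smp$sample_id)
  out <- data.frame(sample_id = ids, ts = NA_real_, tel_ct_mean = NA_real_,
                    alb_ct_mean = NA_real_, qc_flags = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    w <- smp[smp$sample_id == ids[i], ]
    tel <- collapse_triplicates(w$Ct[w$target == "TEL"], qc_range)
    alb <- collapse_triplicates(w$Ct[w$target == "ALB"], qc_range)
    ts <- if (mode == "calibrator") {
      compute_ts_ratio(tel$mean_ct, alb$mean_ct,
                       cal_tel$mean_ct, cal_alb$mean_ct,
                       eff["TEL"], eff["ALB"])
    } else {
      q <- function(ct, curve) 10^((ct - curve$intercept) / curve$slope)
      if (is.null(curves$TEL) || is.null(curves$ALB))
        stop("curve mode requires standards for both targets", call. = FALSE)
      (q(tel$mean_ct, curves$TEL) / q(alb$mean_ct, curves$ALB)) /
        (q(cal_tel$mean_ct, curves$TEL) / q(cal_alb$mean_ct, curves$ALB))
    }
    flags <- unique(c(paste0("TEL_", tel$qc_flags), paste0("ALB_", alb$qc_flags)))
    flags <- flags[!flags %in% c("TEL_", "ALB_")]
    out$ts[i] <- ts
    out$tel_ct_mean[i] <- tel$mean_ct
    out$alb_ct_mean[i] <- alb$mean_ct
    out$qc_flags[i] <- paste(flags, collapse = ";")
  }
  structure(list(ts = out, curves = curves,
                 efficiencies = eff,
                 duplicate_pairs = plate$duplicate_pairs %||%
                   data.frame(sample_id = character(0),
                              duplicate_id = character(0))),
            class = "ts_quant")
}

#' Repeatability of duplicate T/S measurements (ICC)
#'
#' One-way random-effects, single-measure intraclass correlation from paired
#' repeat measurements: with between/within mean squares MSB and MSW over n
#' pairs (k = 2), `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`.
#'
#' @param x,y Paired measurement vectors (first and repeat runs), length
#'   >= 5.
#' @return ICC estimate in `[-1, 1]`.
#' @export
compute_icc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("insufficient data: need >= 5 pairs", call. = FALSE)
  k <- 2
  m <- (x + y) / 2
  grand <- mean(c(x, y))
  msb <- k * sum((m - grand)^2) / (n - 1)
  msw <- sum((x - m)^2 + (y - m)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Write quantification outputs
#'
#' Writes `ts_ratios.csv` (per-sample T/S with QC flags) and `curves.json`
#' (per-target slope, intercept, R^2, efficiency).
#'
#' @param quant A `ts_quant` object from [quantify_plate()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_ts_ratios <- function(quant, dir) {
  stopifnot(inherits(quant, "ts_quant"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_plain(quant$ts, file.path(dir, "ts_ratios.csv"))
  jsonlite::write_json(
    lapply(quant$curves, function(cv)
      cv[c("target", "slope", "intercept", "r_squared", "efficiency")]),
    file.path(dir, "curves.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
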