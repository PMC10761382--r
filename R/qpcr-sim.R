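#' Simulate a qPCR plate for telomere and albumin reactions
#'
#' Builds a synthetic plate matching the layout of the telomere length assay:
#' triplicate telomere (TEL) and albumin (ALB) wells per sample, one
#' designated calibrator sample, and a per-target 5-point two-fold standard
#' dilution series from 25 ng/uL (25, 12.5, 6.25, 3.125, 1.5625). Sample Cts
#' are back-computed from the true T/S ratios through the inverse of the
#' efficiency-corrected (Pfaffl) ratio relative to the calibrator, so with
#' `noise_sd = 0` downstream quantification recovers `true_ts` exactly. A
#' per-sample DNA-input offset shifts both targets coherently (it cancels in
#' the ratio); independent Gaussian well noise with SD `noise_sd` cycles is
#' added on top. A configurable fraction of samples is plated twice
#' (`<id>_rep2`) to exercise repeatability (ICC).
#'
#' @param true_ts Named positive vector of true T/S ratios (names = sample
#'   ids), interpreted relative to the calibrator.
#' @param e_tel,e_alb Amplification efficiencies (factor per cycle, in
#'   (1, 2]); defaults 1.87 and 1.90, the published average efficiencies.
#' @param noise_sd Per-well Gaussian Ct noise SD in cycles (>= 0).
#' @param duplicate_fraction Fraction of samples plated in duplicate
#'   (default 95/411, mirroring the published repeatability subset).
#' @param calibrator_ct_tel,calibrator_ct_alb Noise-free calibrator mean Cts.
#' @param input_sd SD (cycles) of the per-sample DNA-input offset.
#' @param seed Integer seed; identical config + seed gives an identical plate.
#' @return List of class `qpcr_plate`: `wells` (data.frame `sample_id`,
#'   `target`, `replicate`, `Ct`, `role`, `concentration`),
#'   `duplicate_pairs` (data.frame `sample_id`, `duplicate_id`), and
#'   `params`.
#' @export
generate_qpcr_plate <- function(true_ts,
                                e_tel = 1.87, e_alb = 1.90,
                                noise_sd = 0.15,
                                duplicate_fraction = 95 / 411,
                                calibrator_ct_tel = 22,
                                calibrator_ct_alb = 18,
                                input_sd = 0.3,
                                seed) {
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  if (e_tel <= 1 || e_tel > 2 || e_alb <= 1 || e_alb > 2)
    stop("efficiencies must lie in (1, 2]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(true_ts)))
    names(true_ts) <- sprintf("S%04d", seq_along(true_ts))
  if (any(true_ts <= 0)) stop("true_ts must be positive", call. = FALSE)

  set.seed(seed)
  n <- length(true_ts)
  conc <- 25 / 2^(0:4)                        # two-fold series from 25 ng/uL
  slope <- function(e) -1 / log10(e)
  # standard curves anchored so the calibrator sits mid-series
  icpt_tel <- calibrator_ct_tel - slope(e_tel) * log10(6.25)
  icpt_alb <- calibrator_ct_alb - slope(e_alb) * log10(6.25)

  dup_n <- floor(duplicate_fraction * n)
  dup_idx <- if (dup_n > 0) sort(sample.int(n, dup_n)) else integer(0)
  dup_ids <- names(true_ts)[dup_idx]
  dup_pairs <- data.frame(sample_id = dup_ids,
                          duplicate_id = paste0(dup_ids, "_rep2",
                                                recycle0 = TRUE),
                          stringsAsFactors = FALSE)

  ids_all <- c(names(true_ts), dup_pairs$duplicate_id)
  ts_all <- c(true_ts, true_ts[dup_idx])
  offs <- stats::rnorm(length(ids_all), 0, input_sd)

  # invert the Pfaffl ratio: fix ALB Ct from the input offset, solve TEL Ct
  ct_alb <- calibrator_ct_alb + offs
  ct_tel <- calibrator_ct_tel + offs * log(e_alb) / log(e_tel) -
    log(ts_all) / log(e_tel)

  reps <- function(ct0) {
    rep(unname(ct0), 3) + if (noise_sd > 0) stats::rnorm(3, 0, noise_sd) else 0
  }
  well_rows <- vector("list", 0)
  add <- function(id, target, ct0, role, conc_val = NA_real_) {
    data.frame(sample_id = id, target = target, replicate = 1:3,
               Ct = reps(ct0), role = role, concentration = conc_val,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(ids_all)) {
    well_rows[[length(well_rows) + 1]] <- add(ids_all[i], "TEL", ct_tel[i], "sample")
    well_rows[[length(well_rows) + 1]] <- add(ids_all[i], "ALB", ct_alb[i], "sample")
  }
  well_rows[[length(well_rows) + 1]] <-
    add("CAL", "TEL", calibrator_ct_tel, "calibrator")
  well_rows[[length(well_rows) + 1]] <-
    add("CAL", "ALB", calibrator_ct_alb, "calibrator")
  for (j in seq_along(conc)) {
    well_rows[[length(well_rows) + 1]] <-
      add(paste0("STD", j), "TEL", icpt_tel + slope(e_tel) * log10(conc[j]),
          "standard", conc[j])
    well_rows[[length(well_rows) + 1]] <-
      add(paste0("STD", j), "ALB", icpt_alb + slope(e_alb) * log10(conc[j]),
          "standard", conc[j])
  }
  wells <- do.call(rbind, well_rows)
  rownames(wells) <- NULL
  structure(list(wells = wells, duplicate_pairs = dup_pairs,
                 params = list(e_tel = e_tel, e_alb = e_alb,
                               noise_sd = noise_sd, seed = seed,
                               standard_concentrations = conc)),
            class = "qpcr_plate")
}

#' Write / read a plate as CSV
#'
#' The CSV carries the well table only (`sample_id`, `target`, `replicate`,
#' `Ct`, `role`, `concentration`); duplicate pairing is recoverable from the
#' `_rep2` id suffix.
#'
#' @param plate A `qpcr_plate` object (or bare well data.frame).
#' @param path Output CSV path.
#' @return `write_plate`: invisibly, the path. `read_plate`: a `qpcr_plate`
#'   list with `wells` and reconstructed `duplicate_pairs`.
#' @export
write_plate <- function(plate, path) {
  wells <- if (inherits(plate, "qpcr_plate")) plate$wells else plate
  write_csv_plain(wells, path)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "replicate", "Ct", "role")
  if (!all(need %in% names(wells)))
    stop("plate file missing columns: ",
         paste(setdiff(need, names(wells)), collapse = ", "), call. = FALSE)
  dups <- grep("_rep2$", unique(wells$sample_id), value = TRUE)
  dup_pairs <- data.frame(sample_id = sub("_rep2$", "", dups),
                          duplicate_id = dups, stringsAsFactors = FALSE)
  structure(list(wells = wells, duplicate_pairs = dup_pairs, params = list()),
            class = "qpcr_plate")
}
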