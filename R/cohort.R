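#' Generate a synthetic adolescent cohort
#'
#' Simulates a cross-sectional cohort with the statistical structure the
#' moderated telomere--internalizing analysis assumes: demographics (age
#' truncated-normal on 11-17, sex Bernoulli, saliva collection date uniform
#' over one year, caregiver education), one latent-factor Likert item table
#' per registry scale calibrated so realized Cronbach's alpha matches the
#' registry target, a right-skewed T/S ratio (log-normal moment-matched to
#' the configured mean/SD), and anxiety/depression outcomes built from a
#' linear model over z-scored scale scores, z-scored T/S, their products and
#' the forced covariates, with seeded true coefficients.
#'
#' The linear predictor plus Gaussian noise is divided by its theoretical SD
#' (assuming independent standardized predictors), so the standardized
#' regression coefficients of the z-scored outcome equal the effect-map
#' entries; the outcome is then affine-mapped to the instrument metric
#' (published mean/SD) and clipped to the instrument range. The clipped
#' fraction is recorded in the returned truth object.
#'
#' Item-level missingness is applied after outcome generation: MCAR at
#' `missing_rate`, or MAR with missingness log-odds linear in z-scored
#' caregiver education (slope `mar_slope`, intercept calibrated so the
#' marginal rate stays near `missing_rate`).
#'
#' @param n Number of participants (>= 10). Default 411, the study's final
#'   analytic sample.
#' @param registry Scale registry data.frame, see [scale_registry()].
#' @param effects Named list with elements `anxiety` and `depression`, each
#'   an effect map from [default_effects()].
#' @param missing_rate Item-wise missingness fraction (default 0.05).
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`.
#' @param mar_slope Log-odds slope on z-scored caregiver education for MAR.
#' @param ts_mean,ts_sd Target marginal mean/SD of the T/S ratio (defaults
#'   0.29 and 0.81, the published descriptives; SD >> mean forces the right
#'   skew the log-normal supplies).
#' @param age_mean,age_sd Age distribution parameters (defaults 14.23, 1.85),
#'   truncated to 11-17.
#' @param female_prob Probability of sex = 1 (female), default 0.54.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return A list of class `cohort` with elements
#'   \describe{
#'     \item{participants}{data.frame: `participant_id`, `age`, `sex`,
#'       `collection_date`, `cg_education`.}
#'     \item{items}{named list of item tables (one per scale):
#'       `participant_id` plus `item1..itemK` columns, possibly with NAs.}
#'     \item{outcomes}{data.frame: `participant_id`, `anxiety`, `depression`
#'       on the instrument metrics.}
#'     \item{truth}{list: the effect maps, `true_ts`, per-outcome latent
#'       z-scale outcomes (`latent_outcomes`), the z-scored true predictor
#'       matrix (`predictors_z`), clipping fractions, seed and config.}
#'   }
#' @export
#' @examples
#' ch <- generate_cohort(n = 50, seed = 1)
#' nrow(ch$participants)
generate_cohort <- function(n = 411,
                            registry = scale_registry(),
                            effects = list(anxiety = default_effects("anxiety"),
                                           depression = default_effects("depression")),
                            missing_rate = 0.05,
                            missing_mechanism = c("MCAR", "MAR"),
                            mar_slope = 0.5,
                            ts_mean = 0.29, ts_sd = 0.81,
                            age_mean = 14.23, age_sd = 1.85,
                            female_prob = 0.54,
                            seed) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  validate_registry(registry)
  for (em in effects) validate_effect_map(em, registry)

  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))

  # demographics -------------------------------------------------------
  age <- stats::rnorm(n, age_mean, age_sd)
  while (any(bad <- age < 11 | age > 17))      # resample the truncated tails
    age[bad] <- stats::rnorm(sum(bad), age_mean, age_sd)
  age <- round(age, 2)
  sex <- stats::rbinom(n, 1, female_prob)
  collection_date <- as.Date("2014-01-01") + sample.int(365, n, replace = TRUE) - 1L
  cg_education <- sample(1:5, n, replace = TRUE,
                         prob = c(0.10, 0.25, 0.30, 0.25, 0.10))
  participants <- data.frame(participant_id = ids, age = age, sex = sex,
                             collection_date = collection_date,
                             cg_education = cg_education,
                             stringsAsFactors = FALSE)

  # T/S ratio: log-normal moment-matched to (ts_mean, ts_sd) ----------
  sig2 <- log(1 + (ts_sd / ts_mean)^2)
  mu <- log(ts_mean) - sig2 / 2
  true_ts <- stats::rlnorm(n, mu, sqrt(sig2))

  # item tables: one latent factor per participant per scale ----------
  items <- vector("list", nrow(registry))
  names(items) <- registry$name
  scores_complete <- matrix(NA_real_, n, nrow(registry),
                            dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(registry))) {
    sp <- registry[i, ]
    tab <- tryCatch(
      simulate_scale_items(n, sp$n_items, sp$likert_min, sp$likert_max,
                           sp$target_alpha),
      error = function(e) stop("scale '", sp$name, "': ", conditionMessage(e),
                               call. = FALSE))
    items[[i]] <- data.frame(participant_id = ids, tab,
                             stringsAsFactors = FALSE)
    scores_complete[, i] <- rowMeans(tab)
  }

  # outcomes from the effect maps --------------------------------------
  season <- ifelse(format(collection_date, "%m") %in%
                     c("09", "10", "11", "12", "01", "02"), 1, 0)
  predictors_z <- build_truth_predictors(scores_complete, true_ts, age, sex,
                                         season)
  outcomes <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  latent <- list(); clip_frac <- list()
  for (oc in names(effects)) {
    em <- effects[[oc]]
    gen <- realize_outcome(em, predictors_z, n, outcome_metric(oc))
    outcomes[[oc]] <- gen$instrument
    latent[[oc]] <- gen$latent_z
    clip_frac[[oc]] <- gen$clip_fraction
  }

  # item-level missingness ---------------------------------------------
  if (missing_rate > 0) {
    if (missing_mechanism == "MCAR") {
      p_miss <- rep(missing_rate, n)
    } else {
      eta <- stats::qlogis(missing_rate) + mar_slope * zscore(cg_education)
      p_miss <- stats::plogis(eta)
    }
    for (s in names(items)) {
      cols <- setdiff(names(items[[s]]), "participant_id")
      for (cl in cols) {
        hit <- stats::runif(n) < p_miss
        items[[s]][[cl]][hit] <- NA_integer_
      }
    }
  }

  truth <- list(effect_map = effects,
                true_ts = stats::setNames(true_ts, ids),
                latent_outcomes = latent,
                predictors_z = predictors_z,
                clip_fraction = clip_frac,
                generator_seed = seed,
                missing_rate = missing_rate,
                missing_mechanism = missing_mechanism,
                n_participants = n)
  structure(list(participants = participants, items = items,
                 outcomes = outcomes, truth = truth),
            class = "cohort")
}

# Likert items from a single latent factor, with the latent loading
# calibrated through the thresholding attenuation so the *discretized*
# items reach the target reliability.
simulate_scale_items <- function(n, k, lmin, lmax, target_alpha) {
  levels <- lmax - lmin + 1L
  target_r <- if (k == 2) target_alpha else alpha_to_interitem_r(target_alpha, k)
  rho <- latent_rho_for_target(target_r, levels)
  lam <- sqrt(rho)
  f <- stats::rnorm(n)
  tau <- likert_thresholds(levels)
  tab <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    x <- lam * f + sqrt(1 - rho) * stats::rnorm(n)
    tab[, j] <- lmin + findInterval(x, tau)
  }
  colnames(tab) <- paste0("item", seq_len(k))
  tab
}

build_truth_predictors <- function(scores, true_ts, age, sex, season) {
  z_scores <- apply(scores, 2, zscore)
  z_ts <- zscore(true_ts)
  inter <- scale(z_scores * z_ts, center = TRUE, scale = FALSE)
  colnames(inter) <- paste0(colnames(scores), ":ts")
  cbind(ts = z_ts, z_scores, inter,
        age = zscore(age), sex = sex - mean(sex), season = season - mean(season))
}

realize_outcome <- function(em, predictors_z, n, metric) {
  b <- numeric(ncol(predictors_z))
  names(b) <- colnames(predictors_z)
  b["ts"] <- em$ts_effect
  b[names(em$direct_effects)] <- em$direct_effects
  if (length(em$interaction_effects))
    b[paste0(names(em$interaction_effects), ":ts")] <- em$interaction_effects
  b[c("age", "sex", "season")] <- em$covariate_effects[c("age", "sex", "season")]
  lp <- drop(predictors_z %*% b)
  # theoretical variance under independent standardized parents; binary
  # covariates contribute p(1-p) ~ 1/4
  v <- sum(b^2) - b["sex"]^2 * 0.75 - b["season"]^2 * 0.75 + em$residual_sd^2
  latent_z <- (lp + stats::rnorm(n, 0, em$residual_sd)) / sqrt(v)
  raw <- metric$mean + metric$sd * latent_z
  inst <- pmin(pmax(raw, metric$min), metric$max)
  list(latent_z = latent_z,
       instrument = round(inst, 4),
       clip_fraction = mean(raw < metric$min | raw > metric$max))
}

#' Write cohort tables to a directory
#'
#' Writes `participants.csv`, `outcomes.csv`, one `items_<scale>.csv` per
#' scale, and `truth.json` (effect maps, true T/S, seed, clipping log).
#'
#' @param cohort A `cohort` object from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_plain(cohort$participants, file.path(dir, "participants.csv"))
  write_csv_plain(cohort$outcomes, file.path(dir, "outcomes.csv"))
  for (s in names(cohort$items))
    write_csv_plain(cohort$items[[s]], file.path(dir, paste0("items_", s, ".csv")))
  truth <- cohort$truth
  truth$predictors_z <- NULL      # bulky; reproducible from the seed
  truth$effect_map <- lapply(truth$effect_map, unclass)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
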