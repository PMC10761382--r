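#' Registry of social-environment scales
#'
#' Returns the default registry of the 38 social-environment instruments
#' used as candidate moderators of the telomere--internalizing association:
#' youth- and caregiver-reported risk and protective factors spanning
#' individual, family, interpersonal and neighborhood domains. Each row is a
#' `ScaleSpec`: the instrument name, reporter, number of Likert items, item
#' response range, and the internal-consistency value the synthetic cohort
#' generator targets (Cronbach's alpha for 3+ item scales, the inter-item
#' correlation for 2-item scales).
#'
#' Item response ranges follow the instrument family conventions (e.g.
#' PROMIS 1-5, CES-D 0-3, Conflict Tactics Scales 0-6); the two violence
#' exposure checklists carry 0/1 items and a synthetic reliability target of
#' 0.75 since no value is published for them.
#'
#' @return A data.frame with columns `name`, `reporter` ("youth" or
#'   "caregiver"), `n_items`, `likert_min`, `likert_max`, `target_alpha`,
#'   `domain_block`.
#' @export
#' @examples
#' reg <- scale_registry()
#' table(reg$domain_block)
scale_registry <- function() {
  spec <- function(name, reporter, n_items, lmin, lmax, alpha, block) {
    data.frame(name = name, reporter = reporter, n_items = n_items,
               likert_min = lmin, likert_max = lmax, target_alpha = alpha,
               domain_block = block, stringsAsFactors = FALSE)
  }
  reg <- rbind(
    # individual block (youth report)
    spec("self_control",                     "youth",      9, 1, 5, 0.70, "individual"),
    spec("youth_attitude_violence",          "youth",      7, 1, 5, 0.78, "individual"),
    spec("loneliness",                       "youth",      9, 1, 5, 0.91, "individual"),
    spec("personal_religiosity",             "youth",      2, 0, 3, 0.50, "individual"),
    spec("religious_activity",               "youth",      2, 0, 3, 0.54, "individual"),
    spec("shame_teachers",                   "youth",      5, 0, 2, 0.85, "individual"),
    spec("shame_parents",                    "youth",      5, 0, 2, 0.88, "individual"),
    spec("shame_friends",                    "youth",      5, 0, 2, 0.91, "individual"),
    # family block
    spec("family_environment",               "caregiver",  9, 0, 1, 0.62, "family"),
    spec("family_support",                   "youth",      6, 1, 3, 0.78, "family"),
    spec("family_care",                      "youth",      3, 1, 5, 0.90, "family"),
    spec("cg_depression",                    "caregiver",  9, 0, 3, 0.70, "family"),
    spec("cg_social_support",                "caregiver", 21, 1, 5, 0.98, "family"),
    spec("cg_perceived_stress",              "caregiver",  9, 0, 4, 0.73, "family"),
    spec("cg_anxiety",                       "caregiver",  8, 0, 4, 0.93, "family"),
    spec("parent_attitude_violence",         "caregiver",  2, 1, 5, 0.35, "family"),
    spec("cg_inflicted_ip_psych_aggression", "caregiver",  4, 0, 6, 0.56, "family"),
    spec("cg_sustained_ip_psych_aggression", "caregiver",  4, 0, 6, 0.65, "family"),
    spec("cg_inflicted_ip_physical_assault", "caregiver",  7, 0, 6, 0.55, "family"),
    spec("cg_expressed_ip_negotiation",      "caregiver",  3, 0, 6, 0.69, "family"),
    spec("cg_sustained_ip_physical_assault", "caregiver",  7, 0, 6, 0.57, "family"),
    spec("cg_received_ip_negotiation",       "caregiver",  3, 0, 6, 0.60, "family"),
    spec("nonviolent_discipline",            "caregiver",  4, 0, 6, 0.77, "family"),
    spec("psych_aggression_child",           "caregiver",  4, 0, 6, 0.74, "family"),
    spec("physical_aggression_child",        "caregiver",  3, 0, 6, 0.62, "family"),
    # interpersonal block
    spec("friend_support",                   "youth",      8, 1, 3, 0.76, "interpersonal"),
    spec("teacher_care",                     "youth",      5, 1, 5, 0.87, "interpersonal"),
    spec("school_parent_trust",              "youth",      5, 1, 5, 0.96, "interpersonal"),
    spec("school_belongingness",             "youth",      6, 1, 5, 0.74, "interpersonal"),
    spec("perceived_discrimination",         "youth",      9, 1, 4, 0.87, "interpersonal"),
    # neighborhood block
    spec("direct_violence_victimization",    "youth",     10, 0, 1, 0.75, "neighborhood"),
    spec("witness_violence_victimization",   "youth",     11, 0, 1, 0.75, "neighborhood"),
    spec("neighborhood_collective_efficacy", "caregiver", 13, 1, 5, 0.87, "neighborhood"),
    spec("neighborhood_care",                "youth",      3, 1, 5, 0.90, "neighborhood"),
    spec("neighborhood_belongingness",       "caregiver",  4, 1, 5, 0.88, "neighborhood"),
    spec("neighborhood_disorder",            "caregiver", 14, 0, 3, 0.95, "neighborhood"),
    spec("trust_police",                     "caregiver",  7, 1, 5, 0.79, "neighborhood"),
    spec("neighborhood_violence",            "caregiver",  5, 0, 3, 0.71, "neighborhood")
  )
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg),
            all(c("name", "reporter", "n_items", "likert_min", "likert_max",
                  "target_alpha", "domain_block") %in% names(reg)))
  if (anyDuplicated(reg$name))
    stop("duplicate scale names in registry", call. = FALSE)
  if (any(reg$n_items < 2))
    stop("every scale needs n_items >= 2", call. = FALSE)
  if (any(reg$likert_min >= reg$likert_max))
    stop("likert_min must be < likert_max", call. = FALSE)
  if (any(reg$target_alpha <= 0 | reg$target_alpha > 1))
    stop("target_alpha must lie in (0, 1]", call. = FALSE)
  if (!all(reg$reporter %in% c("youth", "caregiver")))
    stop("reporter must be 'youth' or 'caregiver'", call. = FALSE)
  invisible(reg)
}

#' Default true effect maps for the synthetic cohort
#'
#' The generator's "truth": standardized coefficients used to build each
#' outcome from z-scored scale scores, z-scored T/S ratio, their products,
#' and the forced covariates. Defaults seed the published credible effects:
#' for anxiety, direct effects of family support (-0.14), loneliness (0.14),
#' perceived stress (0.28) and school belongingness (0.10) plus the two
#' credible T/S interactions (perceived stress -0.15, school belongingness
#' -0.16); for depression, family support (-0.16), perceived stress (0.23),
#' loneliness (0.12) and the T/S x caregiver-sustained inter-partner
#' psychological aggression interaction (-0.14). The direct T/S effect
#' defaults to 0 (it was not a credible direct predictor). Covariate effects
#' are small plausible values (the study controls for them but reports no
#' estimates).
#'
#' @param outcome `"anxiety"` or `"depression"`.
#' @param null_effects If `TRUE`, all coefficients are zeroed (for null
#'   calibration experiments); `residual_sd` is kept.
#' @return A list of class `effect_map` with elements `outcome`,
#'   `direct_effects`, `interaction_effects`, `ts_effect`,
#'   `covariate_effects` (named `age`, `sex`, `season`) and `residual_sd`.
#' @export
default_effects <- function(outcome = c("anxiety", "depression"),
                            null_effects = FALSE) {
  outcome <- match.arg(outcome)
  if (outcome == "anxiety") {
    direct <- c(family_support = -0.14, loneliness = 0.14,
                cg_perceived_stress = 0.28, school_belongingness = 0.10)
    inter  <- c(cg_perceived_stress = -0.15, school_belongingness = -0.16)
  } else {
    direct <- c(family_support = -0.16, cg_perceived_stress = 0.23,
                loneliness = 0.12)
    inter  <- c(cg_sustained_ip_psych_aggression = -0.14)
  }
  em <- list(outcome = outcome,
             direct_effects = direct,
             interaction_effects = inter,
             ts_effect = 0,
             covariate_effects = c(age = 0.05, sex = 0.10, season = 0.05),
             residual_sd = 1)
  if (null_effects) {
    em$direct_effects <- numeric(0)
    em$interaction_effects <- numeric(0)
    em$ts_effect <- 0
    em$covariate_effects <- c(age = 0, sex = 0, season = 0)
  }
  class(em) <- "effect_map"
  em
}

validate_effect_map <- function(em, registry) {
  if (!inherits(em, "effect_map") && !is.list(em))
    stop("effect map must be a list (see default_effects())", call. = FALSE)
  if (!is.numeric(em$residual_sd) || em$residual_sd <= 0)
    stop("residual_sd must be > 0", call. = FALSE)
  named <- c(names(em$direct_effects), names(em$interaction_effects))
  unknown <- setdiff(named, registry$name)
  if (length(unknown))
    stop("effect map names not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(em)
}

#' Instrument metrics for the two outcomes
#'
#' Published descriptives used to map the generator's z-scale outcome onto
#' the instrument metric: anxiety (8 PROMIS items, 1-5, M 1.76, SD 0.71) and
#' depressive symptoms (9 CES-D short-form items, 0-3, M 0.82, SD 0.56).
#'
#' @param outcome `"anxiety"` or `"depression"`.
#' @return list with `mean`, `sd`, `min`, `max`, `n_items`.
#' @export
outcome_metric <- function(outcome = c("anxiety", "depression")) {
  outcome <- match.arg(outcome)
  if (outcome == "anxiety") {
    list(mean = 1.76, sd = 0.71, min = 1, max = 5, n_items = 8)
  } else {
    list(mean = 0.82, sd = 0.56, min = 0, max = 3, n_items = 9)
  }
}
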