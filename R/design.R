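#' Assemble the standardized moderated-regression design matrix
#'
#' Joins scale scores, T/S ratios, forced covariates and the outcome on
#' participant id and builds the model matrix the Bayesian regression
#' consumes: the outcome, the T/S ratio and every moderator score are
#' z-scored; each moderator contributes a direct column and an interaction
#' column formed as the elementwise product of the two z-scored parents
#' (not re-standardized, keeping coefficients on the simple-slopes scale);
#' age is z-scored and the binary covariates (sex, season) are centered.
#' Column roles are recorded (`direct`, `interaction`, `forced`), and the
#' predictor count is `1 + 2k + 3` for `k` moderators.
#'
#' @param scores data.frame: `participant_id` plus one numeric column per
#'   scale score.
#' @param ts data.frame: `participant_id`, `ts`.
#' @param covariates data.frame: `participant_id`, `age`, `sex` (0/1),
#'   `season` (0/1 or the factor from [dichotomize_season()]).
#' @param outcome data.frame: `participant_id` plus a single outcome column.
#' @param moderators Character vector of scale columns to use (default: all
#'   scale columns in `scores`); scales failing the reliability gate should
#'   be excluded by the caller (see [reliability_report()]).
#' @return Object of class `ts_design`: list with `y` (z-scored outcome),
#'   `X` (numeric matrix), `roles` (named character vector over columns of
#'   `X`), `participant_id`, `outcome_name`.
#' @export
build_design_matrix <- function(scores, ts, covariates, outcome,
                                moderators = NULL) {
  ids <- Reduce(intersect, list(scores$participant_id, ts$participant_id,
                                covariates$participant_id,
                                outcome$participant_id))
  if (length(ids) == 0)
    stop("join error: no overlapping participant ids", call. = FALSE)
  scores <- scores[match(ids, scores$participant_id), , drop = FALSE]
  ts <- ts[match(ids, ts$participant_id), , drop = FALSE]
  covariates <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  outcome <- outcome[match(ids, outcome$participant_id), , drop = FALSE]

  if (is.null(moderators))
    moderators <- setdiff(names(scores), "participant_id")
  miss <- setdiff(moderators, names(scores))
  if (length(miss))
    stop("moderators absent from scores: ", paste(miss, collapse = ", "),
         call. = FALSE)
  oc_name <- setdiff(names(outcome), "participant_id")[1]

  blocks <- c(list(outcome[[oc_name]], ts$ts),
              lapply(moderators, function(s) scores[[s]]),
              list(covariates$age))
  if (anyNA(unlist(blocks)) || anyNA(covariates$sex) || anyNA(covariates$season))
    stop("design inputs contain missing values; impute first", call. = FALSE)

  zcol <- function(x, what) {
    if (stats::sd(x) == 0)
      stop("degenerate column: zero variance in ", what, call. = FALSE)
    zscore(x)
  }
  y <- zcol(outcome[[oc_name]], paste("outcome", oc_name))
  z_ts <- zcol(ts$ts, "ts")
  z_sc <- sapply(moderators, function(s) zcol(scores[[s]], s))
  # products of z-scored parents, centered (their raw mean is the sample
  # correlation of the parents) but not re-scaled
  inter <- scale(z_sc * z_ts, center = TRUE, scale = FALSE)
  colnames(inter) <- paste0(moderators, ":ts")
  season_num <- if (is.factor(covariates$season))
    as.integer(covariates$season == "autumn_winter") else covariates$season
  X <- cbind(ts = z_ts, z_sc, inter,
             age = zcol(covariates$age, "age"),
             sex = covariates$sex - mean(covariates$sex),
             season = season_num - mean(season_num))
  roles <- c(ts = "direct",
             stats::setNames(rep("direct", length(moderators)), moderators),
             stats::setNames(rep("interaction", length(moderators)),
                             colnames(inter)),
             age = "forced", sex = "forced", season = "forced")
  ts_design(X, y, roles, participant_id = ids, outcome_name = oc_name)
}

#' Low-level design constructor
#'
#' Wraps a response vector and model matrix (already on the modeling scale)
#' into the `ts_design` container [gibbs_fit()] consumes. Used directly in
#' tests and for reduced problems; [build_design_matrix()] is the standard
#' route.
#'
#' @param X Numeric matrix (may have zero rows for prior-only fits).
#' @param y Numeric response, `length(y) == nrow(X)`.
#' @param roles Named character vector mapping columns to
#'   `direct`/`interaction`/`forced`; defaults to all `direct`.
#' @param participant_id Optional row ids.
#' @param outcome_name Label for reports.
#' @return A `ts_design` list.
#' @export
ts_design <- function(X, y, roles = NULL, participant_id = NULL,
                      outcome_name = "y") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  if (is.null(roles))
    roles <- stats::setNames(rep("direct", ncol(X)), colnames(X))
  roles <- roles[colnames(X)]
  structure(list(y = as.numeric(y), X = X, roles = roles,
                 participant_id = participant_id, outcome_name = outcome_name),
            class = "ts_design")
}

#' @export
print.ts_design <- function(x, ...) {
  cat("ts_design:", length(x$y), "rows,", ncol(x$X), "predictors (",
      sum(x$roles == "direct"), "direct,", sum(x$roles == "interaction"),
      "interaction,", sum(x$roles == "forced"), "forced ) outcome:",
      x$outcome_name, "\n")
  invisible(x)
}
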