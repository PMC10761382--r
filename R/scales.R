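#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`, with
#' sample variances (denominator n - 1).
#'
#' @param x Numeric matrix or data.frame, rows = participants, columns =
#'   items; >= 3 items, >= 3 complete rows required.
#' @return Alpha (<= 1; can be negative for incoherent items).
#' @export
#' @examples
#' cronbach_alpha(cbind(1:4, 2:5, 3:6))  # parallel shifted items: 1
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("cronbach_alpha needs >= 3 items", call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("cronbach_alpha needs >= 3 participants", call. = FALSE)
  k <- ncol(x)
  vt <- stats::var(rowSums(x))
  if (!is.finite(vt) || vt == 0)
    stop("undefined reliability: zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Score one psychometric scale
#'
#' Per-participant aggregation of the item responses (item mean by default,
#' sum optionally), with the reliability statistic and the publication's
#' inclusion gate attached: scales with 3+ items require Cronbach's alpha
#' strictly above `alpha_min` (default 0.6), 2-item scales require the
#' inter-item Pearson correlation strictly above `r_min` (default 0.2).
#'
#' @param items Item table: data.frame with `participant_id` plus item
#'   columns (run after imputation; missing cells only allowed with
#'   `na_waive = TRUE`, in which case a participant with no observed items
#'   gets an NA score).
#' @param name Scale name (for messages and output).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @param alpha_min,r_min Inclusion-gate thresholds (strict inequalities).
#' @param na_waive Allow missing cells (scored from observed items).
#' @return List of class `scale_score`: `name`, `scores` (named numeric),
#'   `reliability`, `reliability_type` ("alpha" or "r"), `included`,
#'   `n_items`.
#' @export
score_scale <- function(items, name = "scale", aggregate = c("mean", "sum"),
                        alpha_min = 0.6, r_min = 0.2, na_waive = FALSE) {
  aggregate <- match.arg(aggregate)
  ids <- items$participant_id
  mat <- as.matrix(items[setdiff(names(items), "participant_id")])
  storage.mode(mat) <- "double"
  if (anyNA(mat) && !na_waive)
    stop("scale '", name, "' has missing cells; impute first or set na_waive",
         call. = FALSE)
  k <- ncol(mat)
  if (k < 2) stop("scale '", name, "' needs >= 2 items", call. = FALSE)
  sc <- if (aggregate == "mean") rowMeans(mat, na.rm = na_waive)
        else rowSums(mat, na.rm = na_waive)
  sc[rowSums(is.finite(mat)) == 0] <- NA_real_
  # reliability degrades to NA (and exclusion) on degenerate inputs rather
  # than blocking the scoring itself
  if (k >= 3) {
    rel <- tryCatch(cronbach_alpha(mat), error = function(e) NA_real_)
    type <- "alpha"; included <- isTRUE(rel > alpha_min)
  } else {
    cc <- stats::complete.cases(mat)
    rel <- if (sum(cc) >= 3) suppressWarnings(stats::cor(mat[cc, 1], mat[cc, 2]))
           else NA_real_
    type <- "r"; included <- isTRUE(is.finite(rel) && rel > r_min)
  }
  structure(list(name = name, scores = stats::setNames(sc, ids),
                 reliability = rel, reliability_type = type,
                 included = included, n_items = k),
            class = "scale_score")
}

#' Dichotomize collection season
#'
#' Maps saliva collection dates to the seasonal indicator used as a forced
#' covariate: September through February is `"autumn_winter"`, March through
#' August is `"spring_summer"`.
#'
#' @param dates `Date` vector or parseable `"YYYY-MM-DD"` strings.
#' @return Factor with levels `autumn_winter`, `spring_summer`.
#' @export
#' @examples
#' dichotomize_season(c("2014-09-01", "2014-03-01"))
dichotomize_season <- function(dates) {
  d <- as.Date(dates)
  if (anyNA(d)) stop("unparseable collection date", call. = FALSE)
  mo <- as.integer(format(d, "%m"))
  factor(ifelse(mo >= 9 | mo <= 2, "autumn_winter", "spring_summer"),
         levels = c("autumn_winter", "spring_summer"))
}

#' Reliability report across scales
#'
#' Convenience wrapper: scores every scale in a cohort-style item list and
#' tabulates the reliability statistic and inclusion decision.
#'
#' @param items Named list of item tables.
#' @param alpha_min,r_min Gate thresholds, see [score_scale()].
#' @return data.frame with `scale`, `n_items`, `reliability`, `type`,
#'   `included`.
#' @export
reliability_report <- function(items, alpha_min = 0.6, r_min = 0.2) {
  rows <- lapply(names(items), function(s) {
    sc <- score_scale(items[[s]], name = s, alpha_min = alpha_min,
                      r_min = r_min, na_waive = TRUE)
    data.frame(scale = s, n_items = sc$n_items,
               reliability = sc$reliability, type = sc$reliability_type,
               included = sc$included, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
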