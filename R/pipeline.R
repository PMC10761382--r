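#' Run configuration for the end-to-end analysis
#'
#' Collects every stage's knobs into one validated list. The default is a
#' fully simulated run: a synthetic cohort of `n` participants, a matching
#' qPCR plate, quantification, imputation + scoring with the reliability
#' gate, and separate Bayesian fits per outcome with offset seeds
#' (`seed` for anxiety, `seed + 1000` for depression).
#'
#' @param outcome `"anxiety"`, `"depression"`, or both (default both).
#' @param n Cohort size for the simulate block.
#' @param seed Base seed driving every stage.
#' @param missing_rate,missing_mechanism Passed to [generate_cohort()].
#' @param effects Effect maps (default [default_effects()] per outcome);
#'   pass `null_effects = TRUE` maps for calibration runs.
#' @param qpcr List: `noise_sd`, `qc_range`, `fix_efficiency` (NULL or named
#'   `c(TEL=, ALB=)`), `mode` ("calibrator"/"curve").
#' @param imputation List: `m`, `sweeps`, `pmm_k`.
#' @param gate List: `alpha_min`, `r_min`.
#' @param mcmc List: `chains`, `iterations`, `warmup`.
#' @param priors A [prior_spec()].
#' @param bf_cap Bayes factor cap for reporting.
#' @return List of class `run_config`.
#' @export
run_config <- function(outcome = c("anxiety", "depression"),
                       n = 411, seed = 1,
                       missing_rate = 0.05, missing_mechanism = "MCAR",
                       effects = NULL,
                       qpcr = list(), imputation = list(), gate = list(),
                       mcmc = list(), priors = prior_spec(), bf_cap = 1e6) {
  outcome <- match.arg(outcome, several.ok = TRUE)
  qpcr <- utils::modifyList(list(noise_sd = 0.15, qc_range = 0.5,
                                 fix_efficiency = NULL, mode = "calibrator"),
                            qpcr)
  imputation <- utils::modifyList(list(m = 5, sweeps = 10, pmm_k = 5),
                                  imputation)
  gate <- utils::modifyList(list(alpha_min = 0.6, r_min = 0.2), gate)
  mcmc <- utils::modifyList(list(chains = 4, iterations = 5000,
                                 warmup = 1000), mcmc)
  if (is.null(effects))
    effects <- list(anxiety = default_effects("anxiety"),
                    depression = default_effects("depression"))
  structure(list(outcome = outcome, n = n, seed = seed,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism, effects = effects,
                 qpcr = qpcr, imputation = imputation, gate = gate,
                 mcmc = mcmc, priors = priors, bf_cap = bf_cap),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Thin loader for CLI use: top-level keys mirror the [run_config()]
#' arguments (`outcome`, `n`, `seed`, `missing_rate`, `qpcr:`,
#' `imputation:`, `gate:`, `mcmc:`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses bare n/y keys as booleans; map them back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  args <- cfg[intersect(names(cfg),
                        c("outcome", "n", "seed", "missing_rate",
                          "missing_mechanism", "qpcr", "imputation", "gate",
                          "mcmc", "bf_cap"))]
  do.call(run_config, args)
}

#' Run the full moderated-regression analysis
#'
#' Executes the pipeline for each requested outcome: synthetic cohort ->
#' qPCR plate -> T/S quantification (duplicates feed the ICC, then are
#' dropped) -> multiple imputation of item tables -> scale scoring (scores
#' averaged across the `m` completed datasets; the reliability gate is
#' evaluated on the first) -> standardized design with T/S interactions and
#' forced covariates -> conjugate Gibbs fit -> convergence, HDIs,
#' Savage-Dickey BFs and credibility flags. Non-convergence is reported and
#' flagged, never silently dropped.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built cohort (then the simulate block of
#'   `config` is ignored except for seeds).
#' @return List of class `ts_results`, one element per outcome, each with
#'   `summary` (a `coefficient_summary`), `convergence`, `posterior`,
#'   `design`, plus shared `reliability`, `icc`, `cohort_truth`, `config`
#'   and `seeds` entries.
#' @export
run_analysis <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("synthetic_cohort",
                    generate_cohort(n = config$n,
                                    effects = config$effects,
                                    missing_rate = config$missing_rate,
                                    missing_mechanism = config$missing_mechanism,
                                    seed = config$seed))

  plate <- stage("qpcr_plate",
                 generate_qpcr_plate(cohort$truth$true_ts,
                                     noise_sd = config$qpcr$noise_sd,
                                     seed = config$seed + 1L))
  quant <- stage("qpcr_quant",
                 quantify_plate(plate,
                                fix_efficiency = config$qpcr$fix_efficiency,
                                qc_range = config$qpcr$qc_range,
                                mode = config$qpcr$mode))
  tsdf <- quant$ts
  icc <- NA_real_
  dp <- quant$duplicate_pairs
  if (nrow(dp) >= 5) {
    first <- tsdf$ts[match(dp$sample_id, tsdf$sample_id)]
    second <- tsdf$ts[match(dp$duplicate_id, tsdf$sample_id)]
    icc <- compute_icc(first, second)
  }
  tsdf <- tsdf[!grepl("_rep2$", tsdf$sample_id) & tsdf$sample_id != "CAL", ]
  names(tsdf)[names(tsdf) == "sample_id"] <- "participant_id"

  completed <- stage("imputation",
                     impute_items(cohort$items, m = config$imputation$m,
                                  seed = config$seed + 2L,
                                  sweeps = config$imputation$sweeps,
                                  pmm_k = config$imputation$pmm_k))
  rel <- stage("reliability",
               reliability_report(completed[[1]],
                                  alpha_min = config$gate$alpha_min,
                                  r_min = config$gate$r_min))
  # scores averaged over the m completed datasets
  score_one <- function(tabs) {
    sc <- lapply(names(tabs), function(s) score_scale(tabs[[s]], s)$scores)
    names(sc) <- names(tabs)
    as.data.frame(sc, optional = TRUE)
  }
  score_mats <- lapply(completed, score_one)
  scores <- Reduce(`+`, score_mats) / length(score_mats)
  scores <- cbind(participant_id = cohort$participants$participant_id, scores,
                  stringsAsFactors = FALSE)
  moderators <- rel$scale[rel$included]

  covariates <- data.frame(
    participant_id = cohort$participants$participant_id,
    age = cohort$participants$age,
    sex = cohort$participants$sex,
    season = dichotomize_season(cohort$participants$collection_date),
    stringsAsFactors = FALSE)

  results <- list()
  seeds <- c(anxiety = config$seed, depression = config$seed + 1000L)
  for (oc in config$outcome) {
    outcome_df <- cohort$outcomes[c("participant_id", oc)]
    design <- stage("design_matrix",
                    build_design_matrix(scores, tsdf, covariates, outcome_df,
                                        moderators = moderators))
    post <- stage("bayes_engine",
                  gibbs_fit(design, priors = config$priors,
                            n_chains = config$mcmc$chains,
                            n_iter = config$mcmc$iterations,
                            warmup = config$mcmc$warmup,
                            seed = seeds[[oc]]))
    conv <- compute_rhat(post)
    if (!conv$converged)
      warning("outcome '", oc, "': chains not converged (max Rhat ",
              format(conv$max_r_hat, digits = 5), "); results flagged",
              call. = FALSE)
    summ <- summarize_coefficients(post, bf_cap = config$bf_cap)
    results[[oc]] <- list(summary = summ, convergence = conv,
                          posterior = post, design = design)
  }
  structure(list(outcomes = results, reliability = rel, icc = icc,
                 scores = scores, ts_ratios = tsdf, curves = quant$curves,
                 cohort = cohort, config = config, seeds = seeds),
            class = "ts_results")
}

#' @export
print.ts_results <- function(x, ...) {
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    cred <- r$summary[which(r$summary$credible %in% TRUE), "name"]
    cat(oc, ": max Rhat ", sprintf("%.4f", r$convergence$max_r_hat),
        "; credible terms: ",
        if (length(cred)) paste(cred, collapse = ", ") else "(none)", "\n",
        sep = "")
  }
  invisible(x)
}

#' Credible-effect decision rule
#'
#' A non-forced coefficient is credible when `Pr(incl) > 0.5` and its 95%
#' HDI excludes zero.
#'
#' @param summary A `coefficient_summary` row set (or any data.frame with
#'   `pr_incl`, `hdi_low`, `hdi_high`, `role`).
#' @return Logical vector.
#' @export
#' @examples
#' classify_credible(data.frame(role = "interaction", pr_incl = 0.57,
#'                              hdi_low = -0.26, hdi_high = -0.03))
classify_credible <- function(summary) {
  if (any(summary$role == "forced"))
    stop("not applicable: forced covariates carry no credibility flag",
         call. = FALSE)
  summary$pr_incl > 0.5 & (summary$hdi_low > 0 | summary$hdi_high < 0)
}

#' Median-split visualization export
#'
#' Dichotomizes a moderator at its sample median (values equal to the
#' median go to the low group) and fits a least-squares line of the outcome
#' on T/S within each group — the data behind the published
#' moderation figures. Visualization only; never feeds inference.
#'
#' @param ts Numeric T/S values.
#' @param moderator Numeric moderator values (same length, non-constant).
#' @param outcome Numeric outcome values.
#' @param name Moderator label.
#' @return List of class `median_split`: `moderator`, `median`,
#'   `assignment` (factor low/high), `points` (data.frame `ts`, `outcome`,
#'   `group`), `lines` (per-group `intercept`, `slope`, `n`).
#' @export
median_split_export <- function(ts, moderator, outcome, name = "moderator") {
  stopifnot(length(ts) == length(moderator), length(ts) == length(outcome))
  if (anyNA(c(ts, moderator, outcome)))
    stop("median split inputs must be complete", call. = FALSE)
  if (stats::sd(moderator) == 0)
    stop("degenerate split: moderator is constant", call. = FALSE)
  med <- stats::median(moderator)
  grp <- factor(ifelse(moderator <= med, "low", "high"),
                levels = c("low", "high"))
  lines <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    co <- stats::coef(stats::lm(outcome[sel] ~ ts[sel]))
    data.frame(group = g, intercept = unname(co[1]),
               slope = unname(co[2]), n = sum(sel), stringsAsFactors = FALSE)
  }))
  structure(list(moderator = name, median = med, assignment = grp,
                 points = data.frame(ts = ts, outcome = outcome, group = grp),
                 lines = lines),
            class = "median_split")
}

#' Write the results tables
#'
#' Exports `coefficient_summary_<outcome>.csv`, `credible_effects.csv`
#' (header-only when nothing is credible), `reliability_report.csv`,
#' `ts_ratios.csv`, one `median_split_<moderator>.csv` per supplied split,
#' `convergence.json` and `run_manifest.json` (seed, config hash, n).
#' Output is deterministic given the inputs.
#'
#' @param results A `ts_results` from [run_analysis()].
#' @param dir Output directory.
#' @param splits Optional list of `median_split` objects.
#' @param write_draws Also write `posterior_draws_<outcome>.csv` in long
#'   format (chain, iteration, parameter, value); off by default as it is
#'   ~20k rows per parameter.
#' @return Invisibly, the directory.
#' @export
write_report <- function(results, dir, splits = list(), write_draws = FALSE) {
  stopifnot(inherits(results, "ts_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cred_rows <- list()
  conv <- list()
  for (oc in names(results$outcomes)) {
    r <- results$outcomes[[oc]]
    write_csv_plain(r$summary,
                    file.path(dir, paste0("coefficient_summary_", oc, ".csv")))
    keep <- which(r$summary$credible %in% TRUE)
    if (length(keep))
      cred_rows[[oc]] <- cbind(outcome = oc, r$summary[keep, , drop = FALSE])
    conv[[oc]] <- list(max_r_hat = r$convergence$max_r_hat,
                       converged = r$convergence$converged,
                       threshold = r$convergence$threshold)
    dm <- data.frame(participant_id = r$design$participant_id,
                     outcome = r$design$y, r$design$X,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_csv_plain(dm, file.path(dir, paste0("design_matrix_", oc, ".csv")))
    if (write_draws) {
      dd <- r$posterior$draws
      long <- expand.grid(iteration = seq_len(dim(dd)[1]),
                          chain = seq_len(dim(dd)[2]),
                          parameter = dimnames(dd)[[3]],
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      long$value <- as.vector(dd)
      write_csv_plain(long[c("chain", "iteration", "parameter", "value")],
                      file.path(dir, paste0("posterior_draws_", oc, ".csv")))
    }
  }
  # predictor correlation matrix (mirrors the supplementary correlation table)
  d1 <- results$outcomes[[1]]$design
  cm <- stats::cor(d1$X)
  write_csv_plain(data.frame(predictor = rownames(cm), cm,
                             check.names = FALSE),
                  file.path(dir, "correlations.csv"))
  cred <- if (length(cred_rows)) do.call(rbind, cred_rows) else
    cbind(outcome = character(0),
          summarize_template())
  write_csv_plain(cred, file.path(dir, "credible_effects.csv"))
  write_csv_plain(results$reliability, file.path(dir, "reliability_report.csv"))
  write_csv_plain(results$scores, file.path(dir, "scores.csv"))
  write_csv_plain(results$ts_ratios, file.path(dir, "ts_ratios.csv"))
  for (sp in splits) {
    out <- merge(sp$points,
                 sp$lines, by = "group", sort = TRUE)
    write_csv_plain(out, file.path(dir, paste0("median_split_",
                                               sp$moderator, ".csv")))
  }
  jsonlite::write_json(conv, file.path(dir, "convergence.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- results$config
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   n_participants = cfg$n,
                   outcomes = names(results$outcomes),
                   icc = results$icc,
                   package_version = as.character(utils::packageVersion("telomod")))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

summarize_template <- function() {
  data.frame(name = character(0), role = character(0), mean = numeric(0),
             hdi_low = numeric(0), hdi_high = numeric(0), bf10 = numeric(0),
             pr_incl = numeric(0), credible = logical(0),
             bf_capped = logical(0), stringsAsFactors = FALSE)
}

# stable hash of the config: serialized, then summed in 32-bit chunks
config_hash <- function(cfg) {
  raw <- serialize(cfg, connection = NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}
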