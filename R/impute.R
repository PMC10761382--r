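#' Multiple imputation of item tables by chained equations
#'
#' Fills missing item-level cells with a chained-equations sweep, variable
#' by variable: ordinal/continuous columns use predictive mean matching
#' (PMM) with a k-nearest-donor draw against a least-squares prediction from
#' the table's other columns; columns declared nominal use a multinomial
#' draw from linear-discriminant posterior class probabilities. Each item
#' table is imputed separately (the sibling items of a scale are its
#' dominant predictors). Observed cells are never altered; `m` independent
#' streams are returned.
#'
#' @param tables Named list of item tables (data.frames with
#'   `participant_id` plus item columns), or a single table.
#' @param m Number of completed datasets (>= 1), default 5.
#' @param seed Integer seed; stream j uses `seed + j`.
#' @param sweeps Chained-equation passes over the incomplete columns per
#'   stream (default 10).
#' @param pmm_k PMM donor-pool size (default 5).
#' @param nominal Character vector of column names to treat as nominal.
#' @return List of length `m`; each element mirrors `tables` with all cells
#'   completed.
#' @export
impute_items <- function(tables, m = 5, seed, sweeps = 10, pmm_k = 5,
                         nominal = character(0)) {
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  single <- is.data.frame(tables)
  if (single) tables <- list(table = tables)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    set.seed(seed + j)
    out[[j]] <- lapply(names(tables), function(nm)
      impute_one_table(tables[[nm]], nm, sweeps, pmm_k, nominal))
    names(out[[j]]) <- names(tables)
    if (single) out[[j]] <- out[[j]]$table
  }
  out
}

impute_one_table <- function(tab, tab_name, sweeps, pmm_k, nominal) {
  id_col <- intersect("participant_id", names(tab))
  cols <- setdiff(names(tab), id_col)
  x <- as.matrix(tab[cols])
  storage.mode(x) <- "double"
  miss <- is.na(x)
  if (!any(miss)) return(tab)
  nobs <- colSums(!miss)
  if (any(nobs == 0)) {
    bad <- cols[which(nobs == 0)[1]]
    stop("unimputable variable '", bad, "' in table '", tab_name,
         "': no observed values", call. = FALSE)
  }
  # initialize by sampling observed values per column
  for (j in seq_along(cols)) {
    mj <- miss[, j]
    if (any(mj))
      x[mj, j] <- sample(x[!mj, j], sum(mj), replace = TRUE)
  }
  incomplete <- which(colSums(miss) > 0)
  for (s in seq_len(sweeps)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      preds <- x[, -j, drop = FALSE]
      if (cols[j] %in% nominal) {
        x[!obs, j] <- draw_nominal(x[obs, j], preds[obs, , drop = FALSE],
                                   preds[!obs, , drop = FALSE])
      } else {
        x[!obs, j] <- draw_pmm(x[obs, j], preds[obs, , drop = FALSE],
                               preds[!obs, , drop = FALSE], pmm_k)
      }
    }
  }
  done <- tab
  done[cols] <- as.data.frame(x)
  done
}

# PMM: least-squares prediction (rank-safe: aliased coefficients are
# dropped), then each missing row takes the observed value of one of the
# pmm_k donors whose predictions are nearest to its own. The donor search
# exploits that the k nearest values in a sorted vector are found by a
# two-pointer merge, vectorized over all missing rows at once.
draw_pmm <- function(y_obs, X_obs, X_mis, pmm_k) {
  if (ncol(X_obs) == 0 || nrow(X_obs) < 3) {
    return(sample(y_obs, nrow(X_mis), replace = TRUE))
  }
  A_obs <- cbind(1, X_obs)
  fit <- .lm.fit(A_obs, y_obs)
  beta <- numeric(ncol(A_obs))
  beta[fit$pivot[seq_len(fit$rank)]] <- fit$coefficients[seq_len(fit$rank)]
  pred_obs <- drop(A_obs %*% beta)
  pred_mis <- drop(cbind(1, X_mis) %*% beta)
  k <- min(pmm_k, length(y_obs))
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo <- y_obs[ord]
  npo <- length(po)
  nm <- length(pred_mis)
  lo <- findInterval(pred_mis, po)          # largest po <= pred
  hi <- lo + 1L
  donor <- matrix(0L, nm, k)
  for (step in seq_len(k)) {
    take_left <- lo >= 1L &
      (hi > npo | (pred_mis - ifelse(lo >= 1L, po[pmax(lo, 1L)], -Inf)) <=
                  (ifelse(hi <= npo, po[pmin(hi, npo)], Inf) - pred_mis))
    donor[, step] <- ifelse(take_left, lo, hi)
    lo <- lo - as.integer(take_left)
    hi <- hi + as.integer(!take_left)
  }
  pick <- donor[cbind(seq_len(nm), sample.int(k, nm, replace = TRUE))]
  yo[pick]
}

# Nominal draw: LDA posterior class probabilities, multinomial sample.
# Falls back to the marginal class frequencies when LDA is degenerate.
draw_nominal <- function(y_obs, X_obs, X_mis) {
  classes <- sort(unique(y_obs))
  if (length(classes) == 1) return(rep(classes, nrow(X_mis)))
  post <- tryCatch({
    keep <- apply(X_obs, 2, stats::var) > 0
    fit <- MASS::lda(x = X_obs[, keep, drop = FALSE], grouping = factor(y_obs))
    stats::predict(fit, X_mis[, keep, drop = FALSE])$posterior
  }, error = function(e) NULL)
  if (is.null(post)) {
    p <- table(factor(y_obs, levels = classes)) / length(y_obs)
    post <- matrix(rep(as.numeric(p), each = nrow(X_mis)), nrow = nrow(X_mis))
    colnames(post) <- as.character(classes)
  }
  lev <- as.numeric(colnames(post))
  vapply(seq_len(nrow(post)), function(i)
    lev[sample.int(length(lev), 1, prob = post[i, ])], numeric(1))
}
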