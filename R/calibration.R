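#' Order-of-magnitude accuracy of a predicted profile
#'
#' Mean absolute difference of log10 levels over the matched metabolites —
#' the average error of the prediction measured in orders of magnitude
#' (dex). By default both vectors are renormalized over the matched subset
#' before comparison, since the predicted metabolome is relative while
#' measured units are instrument-specific.
#'
#' @param predicted,measured named numeric vectors; only metabolites present
#'   in both are compared.
#' @param floor positive lower bound applied before taking logs.
#' @param renormalize renormalize both vectors over the matched subset.
#' @return non-negative scalar (dex).
#' @export
log_accuracy <- function(predicted, measured, floor = 1e-6,
                         renormalize = TRUE) {
  stopifnot(floor > 0)
  ids <- intersect(names(predicted), names(measured))
  if (!length(ids)) stop("no matched metabolites between the two profiles")
  p <- predicted[ids]; m <- measured[ids]
  if (renormalize) {
    if (sum(p) > 0) p <- p / sum(p)
    if (sum(m) > 0) m <- m / sum(m)
  }
  mean(abs(log10(pmax(p, floor)) - log10(pmax(m, floor))))
}

#' Pearson correlation of log10-transformed profiles
#'
#' @inheritParams log_accuracy
#' @return Pearson r of the floored log10 values over the matched subset,
#'   or `NA` with a warning when either side has zero variance; requires at
#'   least 3 matched metabolites.
#' @export
pearson_log <- function(predicted, measured, floor = 1e-6,
                        renormalize = TRUE) {
  ids <- intersect(names(predicted), names(measured))
  if (length(ids) < 3L) stop("need at least 3 matched metabolites, have ",
                             length(ids))
  p <- predicted[ids]; m <- measured[ids]
  if (renormalize) {
    if (sum(p) > 0) p <- p / sum(p)
    if (sum(m) > 0) m <- m / sum(m)
  }
  lp <- log10(pmax(p, floor)); lm_ <- log10(pmax(m, floor))
  if (stats::sd(lp) == 0 || stats::sd(lm_) == 0) {
    warning("zero variance in log profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(lp, lm_)
}

#' P-value of a correlation, adjusted for fitted model parameters
#'
#' The usual one-tailed t-test of a Pearson correlation uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom. With
#' `p_adj` adjustable model parameters behind the prediction, the statistic
#' is shrunk by `sqrt((n - 2 - p_adj) / (n - 2))` and referred to a
#' Student-t with `n - 2 - p_adj` degrees of freedom, which makes the test
#' conservative relative to the unadjusted one.
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @param n number of points used to compute `r`.
#' @param p_adj number of adjustable model parameters (default 2: the
#'   byproduct fraction and the level count).
#' @return list with `t`, `adjusted_t`, `adjusted_p` (upper tail) and
#'   `df = n - 2 - p_adj`.
#' @export
adjusted_pvalue <- function(r, n, p_adj = 2L) {
  stopifnot(length(r) == 1L, length(n) == 1L)
  if (is.na(r)) return(list(t = NA_real_, adjusted_t = NA_real_,
                            adjusted_p = NA_real_, df = n - 2L - p_adj))
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (n <= p_adj + 2L) {
    stop("need n > p_adj + 2 (df = n - 2 - p_adj must be positive); n = ", n)
  }
  if (abs(r) == 1) {     # continuous limit: perfect correlation
    return(list(t = Inf * r, adjusted_t = Inf * r,
                adjusted_p = if (r > 0) 0 else 1, df = n - 2L - p_adj))
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  adj_t <- t_stat * sqrt((n - 2 - p_adj) / (n - 2))
  list(t = t_stat, adjusted_t = adj_t,
       adjusted_p = stats::pt(adj_t, df = n - 2 - p_adj, lower.tail = FALSE),
       df = n - 2L - p_adj)
}

#' Score a predicted metabolome against a measured one
#'
#' @param predicted named predicted metabolome (relative).
#' @param measured named measured metabolome.
#' @param floor log floor.
#' @param renormalize renormalize over the matched subset (default).
#' @param p_adj adjustable-parameter count for [adjusted_pvalue()].
#' @return list of class `metabolome_comparison`: matched ids, `n`,
#'   `pearson_r`, `t`, `adjusted_t`, `adjusted_p`, `log_accuracy`.
#' @export
compare_metabolomes <- function(predicted, measured, floor = 1e-6,
                                renormalize = TRUE, p_adj = 2L) {
  ids <- intersect(names(predicted), names(measured))
  r <- if (length(ids) >= 3L) {
    pearson_log(predicted, measured, floor, renormalize)
  } else NA_real_
  pv <- if (!is.na(r) && length(ids) > p_adj + 2L) {
    adjusted_pvalue(r, length(ids), p_adj)
  } else list(t = NA_real_, adjusted_t = NA_real_, adjusted_p = NA_real_)
  la <- if (length(ids)) {
    log_accuracy(predicted, measured, floor, renormalize)
  } else NA_real_
  structure(
    list(matched = ids, n = length(ids), pearson_r = r, t = pv$t,
         adjusted_t = pv$adjusted_t, adjusted_p = pv$adjusted_p,
         log_accuracy = la),
    class = "metabolome_comparison"
  )
}

#' Calibrate the byproduct fraction and level count on a cohort
#'
#' Grid search over `(f, n_levels)`: in every cell, each sample's intake is
#' fitted to its observed abundances, the metabolome is predicted from the
#' fitted intake, and compared with the sample's measured metabolome. Cells
#' are scored by the mean Pearson correlation of log profiles, the median
#' adjusted P-value, and the mean logarithmic accuracy across samples. The
#' default grid spans f from 0.1 to 0.99 and 2 to 10 levels.
#'
#' @param cht a [cohort()] whose samples all carry measured metabolomes.
#' @param intake_metabolites candidate intake metabolite ids.
#' @param f_values,n_values grid axes.
#' @param n_restarts,seed,floor,tol fitting options (see [fit_intake()]);
#'   each (cell, sample) fit uses a seed derived deterministically from
#'   `seed`, so the result is invariant to sample ordering.
#' @param renormalize score on matched-subset-renormalized profiles.
#' @param params_template `flow_parameters` supplying uptake rates and
#'   secretion mode for every cell.
#' @return object of class `calibration_result`: `grid` (data.frame with
#'   f, n_levels, mean_r, median_adjusted_p, mean_log_accuracy, n_samples),
#'   `best_by_r` and `best_by_log_accuracy` rows, and `per_sample` scores.
#' @export
calibrate_grid <- function(cht, intake_metabolites,
                           f_values = c(seq(0.1, 0.9, by = 0.1), 0.95, 0.99),
                           n_values = 2:10,
                           n_restarts = 5L, seed = 1L, floor = 1e-6,
                           tol = 1e-10, renormalize = TRUE,
                           params_template = flow_parameters()) {
  stopifnot(inherits(cht, "cohort"))
  has_met <- vapply(cht$samples, function(s) !is.null(s$metabolome), TRUE)
  if (!all(has_met)) stop("every sample needs a measured metabolome")
  cells <- expand.grid(f = f_values, n_levels = n_values,
                       KEEP.OUT.ATTRS = FALSE)
  sample_ids <- vapply(cht$samples, `[[`, "", "sample_id")
  per_sample <- vector("list", nrow(cells))
  grid <- cells
  grid$mean_r <- NA_real_
  grid$median_adjusted_p <- NA_real_
  grid$mean_log_accuracy <- NA_real_
  grid$n_samples <- 0L
  for (ci in seq_len(nrow(cells))) {
    params <- flow_parameters(
      f = cells$f[ci], n_levels = cells$n_levels[ci],
      uptake_rates = params_template$uptake_rates,
      secretion_mode = params_template$secretion_mode,
      secretion_weights = params_template$secretion_weights
    )
    rows <- lapply(seq_along(cht$samples), function(si) {
      s <- cht$samples[[si]]
      # per-(cell, sample) seed keyed by sample id, not position
      fit_seed <- as.integer((as.numeric(seed) * 1009 + ci * 131 +
                                strtoi(substr(digest_id(s$sample_id), 1L, 6L),
                                       16L)) %% 2147483629) + 1L
      resp <- intake_response(cht$network, s, params, intake_metabolites)
      fit <- fit_intake_response(resp, s$abundances, n_restarts = n_restarts,
                                 seed = fit_seed, floor = floor, tol = tol)
      pm <- drop(resp$metabolome %*% fit$intake)
      if (sum(pm) > 0) pm <- pm / sum(pm)
      cmp <- compare_metabolomes(pm, s$metabolome, floor = floor,
                                 renormalize = renormalize)
      data.frame(sample_id = s$sample_id, f = params$f,
                 n_levels = params$n_levels, n_matched = cmp$n,
                 pearson_r = cmp$pearson_r, adjusted_p = cmp$adjusted_p,
                 log_accuracy = cmp$log_accuracy,
                 fit_objective = fit$objective, stringsAsFactors = FALSE)
    })
    sc <- do.call(rbind, rows)
    per_sample[[ci]] <- sc
    ok <- !is.na(sc$pearson_r)
    if (any(ok)) {
      grid$mean_r[ci] <- mean(sc$pearson_r[ok])
      grid$median_adjusted_p[ci] <- stats::median(sc$adjusted_p[ok])
      grid$mean_log_accuracy[ci] <- mean(sc$log_accuracy[ok])
      grid$n_samples[ci] <- sum(ok)
    }
  }
  per_sample <- do.call(rbind, per_sample)
  scored <- which(!is.na(grid$mean_r))
  if (!length(scored)) stop("no grid cell matched >= 3 metabolites in any sample")
  best_r <- scored[which.max(grid$mean_r[scored])]
  best_la <- scored[which.min(grid$mean_log_accuracy[scored])]
  structure(
    list(grid = grid,
         best_by_r = grid[best_r, , drop = FALSE],
         best_by_log_accuracy = grid[best_la, , drop = FALSE],
         per_sample = per_sample,
         seed = seed, sample_ids = sample_ids),
    class = "calibration_result"
  )
}

# stable short hex id for a string (order-independent per-sample seeds)
digest_id <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 16777213
  sprintf("%06x", as.integer(h))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration over", nrow(x$grid), "grid cells,",
      length(x$sample_ids), "samples\n")
  cat(sprintf("  best by mean r: f = %.2f, n_levels = %d (r = %.3f)\n",
              x$best_by_r$f, x$best_by_r$n_levels, x$best_by_r$mean_r))
  cat(sprintf("  best by log accuracy: f = %.2f, n_levels = %d (%.3f dex)\n",
              x$best_by_log_accuracy$f, x$best_by_log_accuracy$n_levels,
              x$best_by_log_accuracy$mean_log_accuracy))
  invisible(x)
}
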