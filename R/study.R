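#' Run one simulation repetition of the equating pipeline
#'
#' Generates abilities, item parameters and responses for a setting, runs the
#' concurrent calibration, builds the anchored tables and the concordance
#' table, transforms raw scores in both directions with both the true-score
#' and the identity method, and computes the precision statistics.
#'
#' Replicates in which the concurrent fit does not converge, or in which some
#' item has an unobserved category, are re-drawn with a derived seed (up to
#' \code{max_redraws} attempts, counted in the result). If redraws are
#' exhausted the last replicate is analysed anyway: boundary-capped
#' thresholds leave the test characteristic curve essentially unchanged in
#' the score range that is actually observed, whereas dropping the replicate
#' would bias the setting summaries in poorly targeted settings.
#'
#' @param setting one row of \code{\link{settings_grid}}.
#' @param seed integer seed for the repetition.
#' @param max_redraws bounded redraw attempts for degenerate replicates.
#' @param detail if \code{TRUE}, attach the fit, tables, concordance and raw
#'   scores to the result.
#' @return A list with \code{precision} (4-row data frame: direction x
#'   method), \code{converged}, \code{redraws}, \code{unobserved_items},
#'   \code{seed_used}; plus the fitted objects when \code{detail = TRUE}.
#' @export
run_repetition <- function(setting, seed, max_redraws = 5L, detail = FALSE) {
  s <- as.list(setting)
  attempt <- 0L
  repeat {
    seed_used <- child_seed(seed, setting = 1L, rep = 1L, attempt = attempt)
    dat <- simulate_equating_data(setting, seed = seed_used)
    fit <- withCallingHandlers(
      concurrent_calibrate(dat$responses),
      pcmlink_unobserved = function(w) invokeRestart("muffleWarning"))
    degenerate <- !fit$converged || length(fit$unobserved_items) > 0L
    if (!degenerate || attempt >= max_redraws) break
    attempt <- attempt + 1L
  }
  tables <- build_score_theta_tables(fit)
  concordance <- build_concordance(tables$X, tables$Y)
  rx <- raw_scores(dat$responses, "X")
  ry <- raw_scores(dat$responses, "Y")
  I <- s$n_items_per_scale
  rng <- c(0L, 2L * I)
  precision <- rbind(
    precision_record(true_score_transform(rx, concordance, "XtoY"), ry,
                     rng, "XtoY", "true_score"),
    precision_record(true_score_transform(ry, concordance, "YtoX"), rx,
                     rng, "YtoX", "true_score"),
    precision_record(identity_transform(rx, rng), ry, rng, "XtoY", "identity"),
    precision_record(identity_transform(ry, rng), rx, rng, "YtoX", "identity"))
  out <- list(precision = precision, converged = fit$converged,
              redraws = attempt, unobserved_items = fit$unobserved_items,
              seed_used = seed_used)
  if (detail) {
    out$fit <- fit
    out$tables <- tables
    out$concordance <- concordance
    out$raw_scores <- list(X = rx, Y = ry)
    out$data <- dat
  }
  out
}

#' Run all repetitions of one setting and summarize
#'
#' Child seeds are spawned deterministically from the master seed via
#' \code{\link{child_seed}}, so any single repetition can be reproduced in
#' isolation and the summaries do not depend on execution order. Quantiles
#' use the linear-interpolation rule (\code{stats::quantile} type 7).
#'
#' @param setting one row of \code{\link{settings_grid}}.
#' @param n_reps number of repetitions (>= 2).
#' @param master_seed master integer seed.
#' @param setting_index integer used in the seed derivation (defaults to 1;
#'   \code{\link{run_grid}} passes each setting's row number).
#' @return A list with \code{results} (long data frame: one row per
#'   repetition x direction x method) and \code{summary} (per
#'   direction/method/metric: Q1, median, Q3, min, max).
#' @export
run_setting <- function(setting, n_reps, master_seed, setting_index = 1L) {
  if (n_reps < 2L) stop("'n_reps' must be at least 2")
  s <- as.list(setting)
  reps <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- child_seed(master_seed, setting = setting_index, rep = r)
    res <- run_repetition(setting, seed = rep_seed)
    cbind(setting_id = s$setting_id, rep = r, seed = rep_seed,
          res$precision, converged = res$converged, redraws = res$redraws,
          stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, reps)
  list(results = results, summary = summarize_results(results))
}

#' Quantile summaries of long-format repetition results
#'
#' @param results long data frame as produced by \code{\link{run_setting}} or
#'   \code{\link{run_grid}}.
#' @param metrics which metric columns to summarize.
#' @return Data frame keyed by setting, direction, method and metric with
#'   columns \code{q1}, \code{median}, \code{q3}, \code{min}, \code{max}.
#' @export
summarize_results <- function(results,
                              metrics = c("nrmse", "percent_bias")) {
  groups <- unique(results[, c("setting_id", "direction", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- results$setting_id == groups$setting_id[g] &
      results$direction == groups$direction[g] &
      results$method == groups$method[g]
    do.call(rbind, lapply(metrics, function(m) {
      v <- results[[m]][sel]
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(setting_id = groups$setting_id[g],
                 direction = groups$direction[g],
                 method = groups$method[g], metric = m,
                 q1 = q[1], median = q[2], q3 = q[3],
                 min = min(v), max = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Run a (subset of the) settings grid
#'
#' @param settings data frame of settings (rows of \code{\link{settings_grid}}).
#' @param n_reps repetitions per setting.
#' @param master_seed master integer seed.
#' @param progress print one line per completed setting.
#' @return Long-format results data frame (one row per repetition x
#'   direction x method across all settings).
#' @export
run_grid <- function(settings, n_reps, master_seed, progress = FALSE) {
  out <- lapply(seq_len(nrow(settings)), function(k) {
    res <- run_setting(settings[k, ], n_reps, master_seed, setting_index = k)
    if (progress)
      message(sprintf("[%d/%d] %s done", k, nrow(settings),
                      settings$setting_id[k]))
    res$results
  })
  do.call(rbind, out)
}

#' Score-level transformation error curves
#'
#' Aggregates the transformation error (transformed minus observed score) at
#' each observed raw-score level of the source scale, with a +/- 1 standard
#' deviation band, per method. Error magnitudes typically grow toward the
#' extremes of the score range.
#'
#' @param setting one row of \code{\link{settings_grid}}.
#' @param n_reps repetitions to aggregate.
#' @param master_seed master integer seed.
#' @param direction \code{"XtoY"} or \code{"YtoX"}.
#' @return Data frame per raw-score level and method: \code{mean_error},
#'   \code{sd_error}, \code{n}.
#' @export
score_error_curves <- function(setting, n_reps, master_seed,
                               direction = c("XtoY", "YtoX")) {
  direction <- match.arg(direction)
  I <- as.list(setting)$n_items_per_scale
  rng <- c(0L, 2L * I)
  rows <- list()
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(master_seed, setting = 1L, rep = r)
    res <- run_repetition(setting, seed = rep_seed, detail = TRUE)
    src <- if (direction == "XtoY") res$raw_scores$X else res$raw_scores$Y
    obs <- if (direction == "XtoY") res$raw_scores$Y else res$raw_scores$X
    ts <- true_score_transform(src, res$concordance, direction)
    id <- identity_transform(src, rng)
    rows[[length(rows) + 1L]] <- data.frame(
      source_score = rep(src, 2), error = c(ts - obs, id - obs),
      method = rep(c("true_score", "identity"), each = length(src)))
  }
  d <- do.call(rbind, rows)
  agg <- aggregate(error ~ source_score + method, data = d,
                   FUN = function(e) c(mean = mean(e), sd = sd(e),
                                       n = length(e)))
  out <- data.frame(raw_score = agg$source_score, method = agg$method,
                    mean_error = agg$error[, "mean"],
                    sd_error = agg$error[, "sd"], n = agg$error[, "n"])
  out[order(out$method, out$raw_score), ]
}
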