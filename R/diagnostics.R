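# Rasch model-fit battery: item fit, threshold ordering, local dependency,
# residual-based dimensionality. Residuals are computed at the anchored
# (TCC-inverted) person estimates under the supplied fit's thresholds.

# standardized residual matrix z_ni = (x - E[x]) / sqrt(Var[x]) at theta_hat
standardized_residuals <- function(fit, responses) {
  items <- coef(fit)
  j <- match(items$item, colnames(responses))
  if (anyNA(j)) stop("responses lack items present in the fit")
  X <- responses[, j, drop = FALSE]
  theta <- person_parameters(fit, responses, "XY")$theta
  Z <- matrix(NA_real_, nrow(X), ncol(X), dimnames = list(NULL, items$item))
  E <- Z; V <- Z
  for (k in seq_len(nrow(items))) {
    P <- pcm_category_probs(theta, c(items$d1[k], items$d2[k]))
    x <- seq_len(ncol(P)) - 1
    e <- drop(P %*% x)
    v <- drop(P %*% x^2) - e^2
    E[, k] <- e; V[, k] <- v
    Z[, k] <- (X[, k] - e) / sqrt(pmax(v, 1e-12))
  }
  list(Z = Z, E = E, V = V, X = X, theta = theta)
}

#' Item infit and outfit mean squares
#'
#' Standardized residuals of each response under the fitted model (at the
#' anchored person estimates) aggregated per item: outfit is the unweighted
#' mean square, infit the information-weighted mean square. Values near 1
#' indicate model-consistent items; the battery's default acceptance band is
#' 0.7 to 1.3.
#'
#' @param fit a \code{"pcm"} fit.
#' @param responses the response matrix the fit refers to.
#' @return Data frame with columns \code{item}, \code{infit}, \code{outfit}.
#' @export
item_fit <- function(fit, responses) {
  res <- standardized_residuals(fit, responses)
  if (ncol(res$X) == 0L) stop("no items to assess")
  zero_var <- apply(res$X, 2, function(x) var(x) == 0)
  if (any(zero_var))
    stop("items with zero response variance: ",
         paste(colnames(res$X)[zero_var], collapse = ", "))
  sqres <- (res$X - res$E)^2
  data.frame(item = colnames(res$X),
             infit = colSums(sqres) / colSums(res$V),
             outfit = colMeans(sqres / pmax(res$V, 1e-12)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold ordering check
#'
#' Flags, per item, whether the estimated step thresholds are ordered
#' (\code{d1 < d2}), the expected pattern for well-behaved three-category
#' items.
#'
#' @param fit a \code{"pcm"} fit.
#' @return Data frame \code{item}, \code{ordered} (logical).
#' @export
threshold_order_check <- function(fit) {
  thr <- coef(fit)
  data.frame(item = thr$item, ordered = thr$d1 < thr$d2,
             stringsAsFactors = FALSE)
}

#' Residual correlations and the local-dependency statistic
#'
#' Pearson correlations between items' standardized residuals. The summary
#' statistic is the largest absolute off-diagonal correlation (the LID value
#' reported in applied Rasch equating studies); values well above the mean
#' residual correlation indicate a locally dependent item pair.
#'
#' @inheritParams item_fit
#' @return List with \code{matrix} (item x item correlations), \code{max_lid}
#'   (largest absolute off-diagonal), and \code{max_above_mean} (largest
#'   off-diagonal minus the mean off-diagonal correlation).
#' @export
residual_correlations <- function(fit, responses) {
  res <- standardized_residuals(fit, responses)
  if (ncol(res$Z) < 3L) stop("need at least 3 items for residual correlations")
  R <- cor(res$Z)
  off <- R[lower.tri(R)]
  list(matrix = R, max_lid = max(abs(off)),
       max_above_mean = max(off) - mean(off))
}

#' Residual-based dimensionality check (percent significant t-tests)
#'
#' Splits the items by the sign of their loading on the first principal
#' component of the residual correlation matrix, estimates each person's
#' ability separately from the two item subsets (anchored TCC inversion), and
#' tests the difference per person with a t statistic built from the two
#' estimates' standard errors. In unidimensional data about 5 percent of
#' persons are expected to be flagged at the 0.05 level; clearly larger
#' percentages indicate a second dimension.
#'
#' @inheritParams item_fit
#' @param alpha significance level of the per-person tests.
#' @return List with \code{percent_significant}, \code{loadings}, and the
#'   item id sets \code{subset_positive}, \code{subset_negative}.
#' @export
dimensionality_ttests <- function(fit, responses, alpha = 0.05) {
  items <- coef(fit)
  if (nrow(items) < 6L) stop("need at least 6 items for the dimensionality check")
  res <- standardized_residuals(fit, responses)
  R <- cor(res$Z)
  pc1 <- eigen(R, symmetric = TRUE)$vectors[, 1]
  pos <- items$item[pc1 >= 0]
  neg <- items$item[pc1 < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("degenerate residual-component split: one item subset is empty")
  est <- function(ids) {
    sub <- items[items$item %in% ids, , drop = FALSE]
    r <- as.integer(rowSums(res$X[, sub$item, drop = FALSE]))
    tab <- score_to_theta(0:(2 * nrow(sub)), sub)
    tab[r + 1L, , drop = FALSE]
  }
  a <- est(pos); b <- est(neg)
  tstat <- (a$theta - b$theta) /
    sqrt(a$standard_error^2 + b$standard_error^2)
  sig <- abs(tstat) > qnorm(1 - alpha / 2)
  list(percent_significant = 100 * mean(sig), loadings = pc1,
       subset_positive = pos, subset_negative = neg)
}

#' Assemble the step-by-step diagnostic report
#'
#' Collects the fit battery for the separate and concurrent analyses into the
#' row categories of a standard equating report: item fit, threshold
#' ordering, local dependency, dimensionality, and targeting (mean/SD of item
#' locations and of person estimates), plus the two-dimensional fit's latent
#' correlation when supplied.
#'
#' @param separate list with elements \code{X} and \code{Y}, each a list
#'   \code{(fit, responses)} from the separate calibrations.
#' @param concurrent list \code{(fit, responses)} for the concurrent
#'   calibration.
#' @param twodim optional two-dimensional \code{"pcm"} fit.
#' @param fit_band acceptable infit/outfit interval.
#' @return An object of class \code{"pcm_fit_report"} (nested list).
#' @export
fit_report <- function(separate, concurrent, twodim = NULL,
                       fit_band = c(0.7, 1.3)) {
  battery <- function(fit, responses, scale = "XY") {
    fi <- item_fit(fit, responses)
    ord <- threshold_order_check(fit)
    lid <- residual_correlations(fit, responses)
    dim <- dimensionality_ttests(fit, responses)
    pp <- person_parameters(fit, responses, "XY")
    thr <- coef(fit)
    list(
      item_fit = fi,
      item_fit_ok = all(fi$infit >= fit_band[1] & fi$infit <= fit_band[2] &
                          fi$outfit >= fit_band[1] & fi$outfit <= fit_band[2]),
      thresholds_ordered = all(ord$ordered),
      lid = lid$max_lid,
      percent_significant_ttests = dim$percent_significant,
      targeting = list(mu_delta = mean(thr$location),
                       sigma_delta = sd(thr$location),
                       mu_theta = mean(pp$theta),
                       sigma_theta = sd(pp$theta),
                       mean_theta_se = mean(pp$standard_error))
    )
  }
  # anchored battery: each scale's items under the concurrent thresholds
  anchored_one <- function(scale) {
    memb <- scale_membership(concurrent$responses)
    sub <- concurrent$responses[, memb == scale, drop = FALSE]
    attr(sub, "scale") <- memb[memb == scale]
    fit <- concurrent$fit
    anch <- fit
    anch$thresholds <- fit$thresholds[fit$thresholds$scale == scale, , drop = FALSE]
    anch$n_items <- nrow(anch$thresholds)
    battery(anch, sub)
  }
  out <- list(
    factor_correlation = if (!is.null(twodim)) twodim$latent_correlation,
    separate = list(X = battery(separate$X$fit, separate$X$responses),
                    Y = battery(separate$Y$fit, separate$Y$responses)),
    concurrent = battery(concurrent$fit, concurrent$responses),
    anchored = list(X = anchored_one("X"), Y = anchored_one("Y")),
    fit_band = fit_band
  )
  class(out) <- "pcm_fit_report"
  out
}

#' @export
print.pcm_fit_report <- function(x, ...) {
  fmt <- function(b) sprintf(
    "item fit %s | thresholds %s | LID %.2f | %%sig t-tests %.2f%% | mu_d %.2f (%.2f) mu_t %.2f (%.2f)",
    if (b$item_fit_ok) "good" else "POOR",
    if (b$thresholds_ordered) "ordered" else "DISORDERED",
    b$lid, b$percent_significant_ttests,
    b$targeting$mu_delta, b$targeting$sigma_delta,
    b$targeting$mu_theta, b$targeting$sigma_theta)
  if (!is.null(x$factor_correlation))
    cat(sprintf("Two-dimensional PCM factor correlation: %.2f\n",
                x$factor_correlation))
  cat("A) Separate analyses\n")
  cat("   X:", fmt(x$separate$X), "\n")
  cat("   Y:", fmt(x$separate$Y), "\n")
  cat("B) Concurrent analysis\n")
  cat("  XY:", fmt(x$concurrent), "\n")
  cat("C) Anchored analyses\n")
  cat("   X:", fmt(x$anchored$X), "\n")
  cat("   Y:", fmt(x$anchored$Y), "\n")
  invisible(x)
}

#' Serialize a diagnostic report to JSON
#'
#' @param report a \code{\link{fit_report}} object.
#' @param file optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
fit_report_json <- function(report, file = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
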