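#' Convert a raw score to an ability estimate by TCC inversion
#'
#' For an interior raw score the ability estimate is the unique root of
#' \code{pcm_expected_score(theta) = raw_score}, found by bracketed root
#' finding to tolerance 1e-8. The maximum-likelihood estimate for the extreme
#' scores (0 and the maximum) is infinite, so they receive the conventional
#' 0.3 score-point adjustment (0 is solved at 0.3, the maximum at max - 0.3),
#' which yields the finite equated values seen in published concordance
#' tables. The standard error is the inverse square root of the test
#' information at the solution.
#'
#' @param raw_score integer raw score (vectorized), in \code{0..2 * n_items}.
#' @param items item data frame with \code{d1}, \code{d2} columns, typically
#'   a scale's rows of a concurrent fit's \code{coef.pcm}.
#' @param adjust extreme-score adjustment in score points (default 0.3).
#' @return Data frame with columns \code{raw_score}, \code{theta},
#'   \code{standard_error}.
#' @export
score_to_theta <- function(raw_score, items, adjust = 0.3) {
  max_score <- 2 * nrow(items)
  if (any(raw_score < 0 | raw_score > max_score))
    stop("raw scores must lie in 0..", max_score)
  target <- pmin(pmax(raw_score, adjust), max_score - adjust)
  theta <- tcc_invert(target, items)
  se <- 1 / sqrt(pcm_information(theta, items))
  data.frame(raw_score = as.integer(raw_score), theta = theta,
             standard_error = se)
}

# Monotone root finding on the TCC, vectorized over targets: bracketed
# bisection run to well below the 1e-8 tolerance. The default bracket
# [-10, 10] expands for boundary-threshold items.
tcc_invert <- function(target, items, lo = -10, hi = 10) {
  while (pcm_expected_score(lo, items) > min(target) && lo > -45) lo <- lo - 5
  while (pcm_expected_score(hi, items) < max(target) && hi < 45) hi <- hi + 5
  a <- rep(lo, length(target)); b <- rep(hi, length(target))
  for (k in 1:60) {
    mid <- (a + b) / 2
    below <- pcm_expected_score(mid, items) < target
    a[below] <- mid[below]
    b[!below] <- mid[!below]
  }
  (a + b) / 2
}

#' Anchored raw-score to ability lookup table for one scale
#'
#' Maps every raw score \code{0..2I} of a scale to an ability estimate under
#' item thresholds held fixed at the concurrent-calibration estimates, so the
#' resulting abilities live on the common metric. Because the raw score is
#' sufficient for the person parameter, the table fully describes the
#' anchored person estimates.
#'
#' Two estimators are available. \code{"eap"} (the default, and what the
#' standard marginal-maximum-likelihood IRT software reports for anchored
#' person parameters) is the posterior mean of ability given the raw score,
#' with the fit's estimated latent distribution as prior and the posterior
#' standard deviation as standard error. \code{"tcc"} inverts the test
#' characteristic curve through \code{\link{score_to_theta}} (maximum
#' likelihood with the 0.3-point extreme-score adjustment).
#'
#' @param fit a concurrent \code{"pcm"} fit covering both scales (or any fit
#'   covering the scale's items).
#' @param scale \code{"X"} or \code{"Y"}.
#' @param method \code{"eap"} or \code{"tcc"}.
#' @param n_nodes quadrature nodes for the EAP posterior.
#' @return A \code{score_theta_table}: data frame \code{raw_score},
#'   \code{theta}, \code{standard_error} with attribute \code{"scale"}.
#' @export
score_theta_table <- function(fit, scale = c("X", "Y"),
                              method = c("eap", "tcc"), n_nodes = 201L) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  items <- coef(fit)
  items <- items[items$scale == scale, , drop = FALSE]
  if (nrow(items) == 0L) stop("fit contains no items of scale ", scale)
  tab <- if (method == "tcc") {
    score_to_theta(0:(2 * nrow(items)), items)
  } else {
    eap_score_table(items, sigma = fit$latent_sd[1], n_nodes = n_nodes)
  }
  attr(tab, "scale") <- scale
  class(tab) <- c("score_theta_table", "data.frame")
  tab
}

#' Anchored latent standard deviation of one scale
#'
#' Step C of the equating workflow fits each scale separately with its item
#' thresholds fixed at the concurrent-calibration estimates; only the latent
#' standard deviation is (re-)estimated by marginal maximum likelihood. The
#' resulting scale-specific dispersion is the prior used for that scale's
#' anchored EAP person estimates.
#'
#' @param fit a concurrent \code{"pcm"} fit covering the scale's items.
#' @param responses response matrix containing the scale's items.
#' @param scale \code{"X"} or \code{"Y"}.
#' @param n_nodes,tol,maxit EM controls as in \code{\link{pcm}}.
#' @return The estimated latent standard deviation (numeric scalar) with
#'   attribute \code{"converged"}.
#' @export
anchored_latent_sd <- function(fit, responses, scale = c("X", "Y"),
                               n_nodes = 61L, tol = 1e-6, maxit = 500L) {
  scale <- match.arg(scale)
  items <- coef(fit)
  items <- items[items$scale == scale, , drop = FALSE]
  sub <- responses[, match(items$item, colnames(responses)), drop = FALSE]
  storage.mode(sub) <- "integer"
  z <- seq(-6, 6, length.out = n_nodes)
  wz <- dnorm(z); wz <- wz / sum(wz)
  res <- .pcm_em_1d(sub, as.matrix(items[, c("d1", "d2")]), z, wz,
                    fit$latent_sd[1], TRUE, tol, as.integer(maxit), 12,
                    TRUE)
  structure(res$sigma, converged = res$converged)
}

# EAP ability per raw score. Under the equal-slope PCM the likelihood of a
# response pattern factorizes as exp(r * theta) times a pattern-specific
# constant and the shared denominators, so the posterior of theta given the
# pattern depends on the pattern only through the raw score r.
eap_score_table <- function(items, sigma, n_nodes = 201L) {
  z <- seq(-6, 6, length.out = n_nodes)
  th <- sigma * z
  lw <- log(dnorm(z))
  logD <- numeric(n_nodes)
  for (i in seq_len(nrow(items))) {
    s1 <- th - items$d1[i]
    s2 <- 2 * th - items$d1[i] - items$d2[i]
    m <- pmax(0, s1, s2)
    logD <- logD + m + log(exp(-m) + exp(s1 - m) + exp(s2 - m))
  }
  scores <- 0:(2 * nrow(items))
  est <- vapply(scores, function(r) {
    lp <- lw + r * th - logD
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    mu <- sum(w * th)
    c(mu, sqrt(sum(w * (th - mu)^2)))
  }, numeric(2))
  data.frame(raw_score = scores, theta = est[1, ], standard_error = est[2, ])
}

#' Anchored person ability estimates
#'
#' Because the raw score is sufficient for the person parameter in the PCM,
#' anchored estimation reduces to a per-score lookup: every person receives
#' the TCC-inversion estimate of their raw score on the scale, with item
#' parameters fixed at the supplied fit's thresholds.
#'
#' @param fit a \code{"pcm"} fit providing the anchored thresholds.
#' @param responses response matrix containing the scale's items.
#' @param scale \code{"X"}, \code{"Y"} or \code{"XY"} (all items).
#' @param method \code{"tcc"} (TCC inversion, the default, equivalent to
#'   \code{\link{score_to_theta}} lookups) or \code{"eap"}.
#' @return Data frame with one row per person: \code{raw_score},
#'   \code{theta}, \code{standard_error}.
#' @export
person_parameters <- function(fit, responses, scale = c("X", "Y", "XY"),
                              method = c("tcc", "eap")) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  items <- coef(fit)
  if (scale != "XY") items <- items[items$scale == scale, , drop = FALSE]
  sub <- responses[, match(items$item, colnames(responses)), drop = FALSE]
  if (anyNA(sub)) stop("responses contain missing values")
  r <- as.integer(rowSums(sub))
  tab <- if (method == "tcc") score_to_theta(0:(2 * nrow(items)), items)
         else eap_score_table(items, sigma = fit$latent_sd[1])
  out <- tab[r + 1L, c("raw_score", "theta", "standard_error"), drop = FALSE]
  rownames(out) <- NULL
  out
}
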