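#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("Partial credit model (%d-dimensional, slopes fixed at 1)\n",
              x$dimensions))
  cat(sprintf("  %d persons, %d items, log-likelihood %.2f (%s, %d EM iterations)\n",
              x$n_persons, x$n_items, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  if (x$dimensions == 1) {
    cat(sprintf("  latent SD: %.3f\n", x$latent_sd))
  } else {
    cat(sprintf("  latent SDs: %.3f (X), %.3f (Y); latent correlation: %.3f\n",
                x$latent_sd[1], x$latent_sd[2], x$latent_correlation))
  }
  if (length(x$unobserved_items))
    cat("  items with unobserved categories:",
        paste(x$unobserved_items, collapse = ", "), "\n")
  invisible(x)
}

#' Extract estimated item thresholds
#'
#' @param object a fitted \code{"pcm"} model.
#' @param ... unused.
#' @return Data frame with one row per item: \code{item}, \code{scale},
#'   \code{d1}, \code{d2}, \code{location}.
#' @export
coef.pcm <- function(object, ...) object$thresholds

#' @export
logLik.pcm <- function(object, ...) {
  df <- 2 * object$n_items + object$dimensions +
    if (object$dimensions == 2) 1L else 0L
  structure(object$log_likelihood, df = df, nobs = object$n_persons,
            class = "logLik")
}

#' Summarize a fitted partial credit model
#'
#' Reports per-scale targeting (mean and SD of item locations), the latent
#' distribution estimates and convergence information.
#'
#' @param object a fitted \code{"pcm"} model.
#' @param ... unused.
#' @export
summary.pcm <- function(object, ...) {
  thr <- object$thresholds
  targeting <- do.call(rbind, lapply(split(thr, thr$scale), function(d)
    data.frame(scale = d$scale[1], n_items = nrow(d),
               mu_delta = mean(d$location), sigma_delta = sd(d$location))))
  rownames(targeting) <- NULL
  out <- list(targeting = targeting, latent_sd = object$latent_sd,
              latent_correlation = object$latent_correlation,
              log_likelihood = object$log_likelihood,
              converged = object$converged,
              n_iterations = object$n_iterations,
              dimensions = object$dimensions,
              thresholds = thr)
  class(out) <- "summary.pcm"
  out
}

#' @export
print.summary.pcm <- function(x, ...) {
  cat(sprintf("Partial credit model (%d-dimensional)\n", x$dimensions))
  cat("Targeting (item locations):\n")
  print(x$targeting, digits = 3, row.names = FALSE)
  cat(sprintf("Latent SD: %s\n",
              paste(sprintf("%.3f", x$latent_sd), collapse = " / ")))
  if (!is.null(x$latent_correlation))
    cat(sprintf("Latent correlation: %.3f\n", x$latent_correlation))
  cat(sprintf("Log-likelihood %.2f, %s in %d iterations\n",
              x$log_likelihood,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}

#' Simulate response matrices from a fitted model
#'
#' Draws new persons from the fitted latent distribution and responses from
#' the fitted category probabilities. Useful for parametric-bootstrap checks
#' of the diagnostic battery.
#'
#' @param object a fitted \code{"pcm"} model.
#' @param nsim number of response matrices.
#' @param seed optional integer seed.
#' @param n_persons number of persons per matrix (defaults to the fit's).
#' @param ... unused.
#' @return A list of response matrices (length \code{nsim}).
#' @export
simulate.pcm <- function(object, nsim = 1, seed = NULL, n_persons = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- if (is.null(n_persons)) object$n_persons else n_persons
  thr <- object$thresholds
  items <- data.frame(item = thr$item, scale = thr$scale,
                      d1 = thr$d1, d2 = thr$d2, stringsAsFactors = FALSE)
  lapply(seq_len(nsim), function(k) {
    if (object$dimensions == 1) {
      th <- rnorm(N, 0, object$latent_sd)
      ab <- cbind(theta_x = th, theta_y = th)
    } else {
      s <- object$latent_sd; r <- object$latent_correlation
      Sigma <- matrix(c(s[1]^2, r * s[1] * s[2], r * s[1] * s[2], s[2]^2), 2)
      ab <- MASS::mvrnorm(N, c(0, 0), Sigma)
      colnames(ab) <- c("theta_x", "theta_y")
    }
    simulate_responses(items, ab)
  })
}

#' Collapse the top two categories of selected items
#'
#' Real-data helper for items whose top category is (almost) unobserved:
#' recodes category 2 into category 1, turning the item dichotomous.
#'
#' @param responses response matrix.
#' @param items character vector of item ids (column names) to collapse.
#' @return The recoded response matrix.
#' @export
collapse_categories <- function(responses, items) {
  j <- match(items, colnames(responses))
  if (anyNA(j)) stop("unknown item ids: ",
                     paste(items[is.na(j)], collapse = ", "))
  responses[, j] <- pmin(responses[, j, drop = FALSE], 1L)
  responses
}

#' Serialize a fitted model to JSON
#'
#' Writes thresholds (keyed by item id), latent parameters and convergence
#' metadata, so anchored analyses can re-use item estimates across runs.
#'
#' @param fit a fitted \code{"pcm"} model.
#' @param file optional path; when omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
pcm_to_json <- function(fit, file = NULL) {
  payload <- list(
    dimensions = fit$dimensions,
    thresholds = fit$thresholds[, c("item", "scale", "d1", "d2")],
    latent_sd = as.list(fit$latent_sd),
    latent_correlation = fit$latent_correlation,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    n_persons = fit$n_persons
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' @rdname pcm_to_json
#' @param json a path to, or string of, JSON written by \code{pcm_to_json}.
#' @export
pcm_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  thr <- p$thresholds
  thr$location <- (thr$d1 + thr$d2) / 2
  structure(list(
    thresholds = thr,
    latent_sd = unlist(p$latent_sd),
    latent_correlation = p$latent_correlation,
    log_likelihood = p$log_likelihood,
    loglik_trace = p$log_likelihood,
    converged = p$converged,
    n_iterations = p$n_iterations,
    dimensions = p$dimensions,
    n_persons = p$n_persons,
    n_items = nrow(thr),
    unobserved_items = character(0),
    call = quote(pcm_from_json())
  ), class = "pcm")
}
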