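#' Normalized root-mean-squared error of a score transformation
#'
#' RMSE of transformed versus observed raw scores, divided by the theoretical
#' score range of the target scale, so the value reads as a fraction of the
#' scale range.
#'
#' @param transformed,observed equal-length numeric vectors of transformed
#'   and observed raw scores.
#' @param score_range length-2 vector \code{c(min, max)} of the target scale.
#' @return A single non-negative number.
#' @examples
#' nrmse(rep(2, 5) + 0:4 * 0, 0:4 * 0, c(0, 20))  # constant error of 2 on 0-20
#' @export
nrmse <- function(transformed, observed, score_range) {
  check_score_vectors(transformed, observed)
  rng <- diff(range(score_range))
  if (rng <= 0) stop("score range must be non-degenerate")
  sqrt(mean((transformed - observed)^2)) / rng
}

#' Percent bias of a score transformation
#'
#' Signed mean difference between observed and transformed scores as a
#' percentage of the observed score total:
#' \code{sum(R - Rhat) / sum(R) * 100}. Positive values mean the
#' transformation under-predicts. Conventional reading: below 10\% in
#' absolute value negligible, 10--20\% substantial, above 20\% unacceptable.
#'
#' @inheritParams nrmse
#' @return Signed percentage.
#' @export
percent_bias <- function(transformed, observed) {
  check_score_vectors(transformed, observed)
  if (sum(observed) <= 0) stop("observed scores sum to zero; percent bias undefined")
  sum(observed - transformed) / sum(observed) * 100
}

#' Decompose the mean squared transformation error
#'
#' \code{mse = mean((Rhat - R)^2)}; \code{bias = mean(R - Rhat)};
#' \code{variance = mse - bias^2} (the variance of the transformation error,
#' so that \code{mse = variance + bias^2} holds exactly).
#'
#' @inheritParams nrmse
#' @return Named list \code{mse}, \code{variance}, \code{bias}.
#' @export
mse_decomposition <- function(transformed, observed) {
  check_score_vectors(transformed, observed)
  mse <- mean((transformed - observed)^2)
  bias <- mean(observed - transformed)
  list(mse = mse, variance = mse - bias^2, bias = bias)
}

check_score_vectors <- function(transformed, observed) {
  if (length(transformed) != length(observed))
    stop("'transformed' and 'observed' must have equal length")
  if (length(observed) == 0L) stop("empty score vectors")
  invisible(TRUE)
}

# One long-format row of transformation-precision statistics.
precision_record <- function(transformed, observed, score_range,
                             direction, method) {
  dec <- mse_decomposition(transformed, observed)
  data.frame(direction = direction, method = method,
             nrmse = nrmse(transformed, observed, score_range),
             percent_bias = percent_bias(transformed, observed),
             rmse = sqrt(dec$mse), bias = dec$bias, variance = dec$variance,
             stringsAsFactors = FALSE)
}
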