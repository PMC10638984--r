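#' Partial credit model category probabilities
#'
#' Closed-form category probabilities of the slope-1 PCM. For a person with
#' ability \code{theta} and an item with step thresholds
#' \code{delta = (d_1, ..., d_m)}, the probability of category
#' \code{x in 0..m} is proportional to \code{exp(sum_{h <= x} (theta - d_h))}
#' with the empty sum equal to zero.
#'
#' @param theta numeric vector of abilities (logits).
#' @param delta numeric vector of step thresholds for one item (logits).
#' @return Matrix of probabilities, \code{length(theta)} rows and
#'   \code{length(delta) + 1} columns; rows sum to one.
#' @examples
#' pcm_category_probs(0, c(0, 0))        # (1/3, 1/3, 1/3)
#' pcm_category_probs(0.7, c(-0.7, 0.7))
#' @export
pcm_category_probs <- function(theta, delta) {
  m <- length(delta)
  s <- outer(theta, seq_len(m), "*")  # x * theta for x = 1..m
  s <- sweep(s, 2, cumsum(delta), "-")
  s <- cbind(0, s)
  mx <- apply(s, 1, max)
  e <- exp(s - mx)
  e / rowSums(e)
}

#' Expected raw score (test characteristic curve)
#'
#' Expected raw score over a set of items at ability \code{theta}:
#' \code{sum_i sum_x x P(x | theta, item i)}. As a function of \code{theta}
#' this is the test characteristic curve (TCC), strictly increasing from 0 to
#' the maximum raw score.
#'
#' @param theta numeric vector of abilities.
#' @param items item data frame with threshold columns \code{d1}, \code{d2}
#'   (as from \code{\link{draw_item_parameters}} or a fitted model's
#'   \code{\link{coef.pcm}}).
#' @return Numeric vector of expected scores, one per value of \code{theta}.
#' @export
pcm_expected_score <- function(theta, items) {
  if (nrow(items) == 0L) stop("'items' must contain at least one item")
  .pcm_tcc(as.numeric(theta), items$d1, items$d2)
}

#' Test information of the raw score
#'
#' Sum over items of the conditional variance of the item score at
#' \code{theta}. Its inverse square root is the standard error attached to a
#' TCC-inverted ability estimate.
#'
#' @inheritParams pcm_expected_score
#' @return Numeric vector of information values.
#' @export
pcm_information <- function(theta, items) {
  info <- numeric(length(theta))
  for (j in seq_len(nrow(items))) {
    P <- pcm_category_probs(theta, c(items$d1[j], items$d2[j]))
    x <- seq_len(ncol(P)) - 1
    ex <- drop(P %*% x)
    ex2 <- drop(P %*% x^2)
    info <- info + (ex2 - ex^2)
  }
  info
}
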