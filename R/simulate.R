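#' Draw person abilities for two correlated latent dimensions
#'
#' Samples \code{n_persons} ability pairs from a bivariate normal with mean
#' (0, 0), standard deviation \code{sigma_theta} on each dimension and
#' covariance \code{rho_sim * sigma_theta^2}, i.e. the correlation between the
#' Scale X and Scale Y dimensions equals the construct-similarity parameter
#' \code{rho_sim}. At \code{rho_sim = 1} the two columns are identical and the
#' design collapses to a unidimensional model.
#'
#' @param setting one row of \code{\link{settings_grid}} (data frame or list).
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @return An \code{n_persons} x 2 matrix with columns \code{theta_x},
#'   \code{theta_y} (logits).
#' @export
draw_abilities <- function(setting, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.list(setting)
  v <- s$sigma_theta^2
  Sigma <- matrix(c(v, s$rho_sim * v, s$rho_sim * v, v), 2, 2)
  th <- MASS::mvrnorm(s$n_persons, mu = c(0, 0), Sigma = Sigma)
  colnames(th) <- c("theta_x", "theta_y")
  th
}

#' Draw item locations and thresholds for both scales
#'
#' Item locations are drawn per scale from normal distributions with means
#' \code{-shift/2} (Scale X) and \code{+shift/2} (Scale Y) and standard
#' deviations \code{sigma_delta_x}, \code{sigma_delta_y}. Each item's two
#' step thresholds sit at equal distance \code{d} below and above the
#' location, with \code{d ~ Normal(0.7, 0.15)} truncated below at 0.05 logits
#' so thresholds are always strictly ordered.
#'
#' @inheritParams draw_abilities
#' @return A data frame with columns \code{item} (id, prefixed \code{X_} or
#'   \code{Y_}), \code{scale} (factor X/Y), \code{location}, \code{d1},
#'   \code{d2} (ordered thresholds, logits).
#' @export
draw_item_parameters <- function(setting, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.list(setting)
  I <- s$n_items_per_scale
  loc <- c(rnorm(I, mean = -s$shift / 2, sd = s$sigma_delta_x),
           rnorm(I, mean = +s$shift / 2, sd = s$sigma_delta_y))
  half <- pmax(rnorm(2 * I, mean = 0.7, sd = 0.15), 0.05)
  scale <- rep(c("X", "Y"), each = I)
  data.frame(
    item = paste0(scale, "_", rep(seq_len(I), 2)),
    scale = scale,
    location = loc,
    d1 = loc - half,
    d2 = loc + half,
    stringsAsFactors = FALSE
  )
}

#' Simulate polytomous responses under the partial credit model
#'
#' Draws one response per person-item cell from the three-category PCM
#' (slope 1) at the person's ability on the item's dimension: Scale X items
#' use \code{theta_x}, Scale Y items use \code{theta_y}.
#'
#' @param items item parameter data frame from
#'   \code{\link{draw_item_parameters}}.
#' @param abilities matrix from \code{\link{draw_abilities}}.
#' @param seed optional integer seed.
#' @return Integer response matrix (persons x items, values 0..2) with item
#'   ids as column names and a \code{"scale"} attribute giving each column's
#'   scale membership.
#' @export
simulate_responses <- function(items, abilities, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(items$scale %in% c("X", "Y")), ncol(abilities) == 2L)
  N <- nrow(abilities)
  X <- matrix(0L, N, nrow(items))
  for (j in seq_len(nrow(items))) {
    th <- abilities[, if (items$scale[j] == "X") 1L else 2L]
    P <- pcm_category_probs(th, c(items$d1[j], items$d2[j]))
    u <- runif(N)
    X[, j] <- (u > P[, 1]) + (u > P[, 1] + P[, 2])
  }
  storage.mode(X) <- "integer"
  colnames(X) <- items$item
  attr(X, "scale") <- items$scale
  X
}

#' Generate one full equating data set for a simulation setting
#'
#' Convenience wrapper that draws abilities, item parameters and responses
#' from a single seed (sub-seeds are derived with \code{\link{child_seed}}).
#'
#' @inheritParams draw_abilities
#' @return A list with elements \code{abilities}, \code{items},
#'   \code{responses} and \code{setting}.
#' @export
simulate_equating_data <- function(setting, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    lapply(1:3, function(k) child_seed(seed, setting = 0L, rep = 0L, attempt = k))
  ab <- draw_abilities(setting, seed = seeds[[1]])
  it <- draw_item_parameters(setting, seed = seeds[[2]])
  rs <- simulate_responses(it, ab, seed = seeds[[3]])
  list(abilities = ab, items = it, responses = rs, setting = as.list(setting))
}

#' Raw scores per scale
#'
#' Row sums of a response matrix restricted to one scale's columns.
#'
#' @param responses response matrix with a \code{"scale"} attribute or
#'   \code{X_}/\code{Y_}-prefixed column names.
#' @param scale \code{"X"}, \code{"Y"}, or \code{"XY"} for the combined score.
#' @return Integer vector of raw scores.
#' @export
raw_scores <- function(responses, scale = c("X", "Y", "XY")) {
  scale <- match.arg(scale)
  memb <- scale_membership(responses)
  cols <- if (scale == "XY") rep(TRUE, ncol(responses)) else memb == scale
  as.integer(rowSums(responses[, cols, drop = FALSE]))
}

scale_membership <- function(responses) {
  memb <- attr(responses, "scale")
  if (is.null(memb)) {
    cn <- colnames(responses)
    if (is.null(cn) || !all(grepl("^[XY]_", cn)))
      stop("cannot infer scale membership: no 'scale' attribute and no X_/Y_ column prefixes")
    memb <- substr(cn, 1, 1)
  }
  memb
}

#' Read / write response matrices as CSV
#'
#' The CSV has a header of item ids prefixed \code{X_}/\code{Y_} and one row
#' of integer responses per person; scale membership is recovered from the
#' prefixes on reading.
#'
#' @param responses response matrix.
#' @param file path to a CSV file.
#' @return \code{read_responses} returns an integer matrix with a
#'   \code{"scale"} attribute; \code{write_responses} returns \code{file}
#'   invisibly.
#' @export
write_responses <- function(responses, file) {
  write.csv(as.data.frame(responses), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_responses
#' @export
read_responses <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  X <- as.matrix(df)
  storage.mode(X) <- "integer"
  attr(X, "scale") <- substr(colnames(X), 1, 1)
  X
}
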