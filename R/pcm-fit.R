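#' Fit a partial credit model by marginal maximum likelihood
#'
#' Estimates step thresholds of the slope-1 partial credit model for
#' three-category items, integrating the latent ability out with an EM
#' algorithm over a fixed quadrature grid. Identification follows the usual
#' Rasch convention: latent mean(s) fixed at zero, slopes fixed at one, latent
#' variance(s) (and, for two dimensions, the latent correlation) estimated.
#'
#' With \code{dimensions = 2} each item is assigned to one dimension through
#' \code{membership} (defaulting to the response matrix's scale metadata) and
#' the latent distribution is bivariate normal; the estimated correlation
#' \code{latent_correlation} is the construct-similarity statistic used to
#' judge whether two scales are equatable.
#'
#' Items for which some category is never observed cannot pin down the
#' corresponding threshold; the estimate drifts to the boundary
#' \code{(+/- dmax)}. Such items are reported via a warning of class
#' \code{"pcmlink_unobserved"} (or an error when
#' \code{on_unobserved = "error"}), so callers can collapse categories with
#' \code{\link{collapse_categories}} or accept the boundary fit.
#'
#' @param responses integer matrix (persons x items, categories 0..2).
#' @param dimensions 1 (all items load on one ability) or 2.
#' @param membership character vector of \code{"X"}/\code{"Y"} per item; only
#'   used when \code{dimensions = 2}. Defaults to the matrix's scale
#'   metadata.
#' @param n_nodes quadrature nodes per dimension (default 61 for one
#'   dimension, 31 for two) spanning \code{[-6, 6]} latent standard
#'   deviations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations.
#' @param sigma_start starting latent standard deviation.
#' @param dmax threshold estimates clamped to \code{[-dmax, dmax]} logits.
#' @param on_unobserved \code{"warn"} (default) or \code{"error"} when some
#'   item has an unobserved category.
#' @return An object of class \code{"pcm"}: a list with \code{thresholds}
#'   (data frame \code{item}, \code{scale}, \code{d1}, \code{d2},
#'   \code{location}), \code{latent_sd}, \code{latent_correlation} (2-D only),
#'   \code{log_likelihood}, \code{loglik_trace}, \code{converged},
#'   \code{n_iterations}, \code{dimensions}, \code{n_persons},
#'   \code{unobserved_items}.
#' @seealso \code{\link{score_to_theta}}, \code{\link{equate_scales}},
#'   \code{\link{fit_report}}
#' @examples
#' set.seed(1)
#' g <- settings_grid()
#' dat <- simulate_equating_data(g[g$setting_id == "I10_N0500_r1.00_t1.0_d0_s1-1", ], seed = 7)
#' fit <- pcm(dat$responses)
#' fit
#' @export
pcm <- function(responses, dimensions = 1, membership = NULL,
                n_nodes = if (dimensions == 1) 61L else 31L,
                tol = 1e-6, maxit = 500L, sigma_start = 1,
                dmax = 12, on_unobserved = c("warn", "error")) {
  on_unobserved <- match.arg(on_unobserved)
  X <- as.matrix(responses)
  storage.mode(X) <- "integer"
  if (any(is.na(X))) stop("missing responses are not supported; drop incomplete rows first")
  if (any(X < 0L | X > 2L)) stop("responses must be integers in 0..2")
  N <- nrow(X); I <- ncol(X)
  items <- colnames(X)
  if (is.null(items)) items <- paste0("item_", seq_len(I))
  memb <- membership
  if (is.null(memb)) memb <- tryCatch(scale_membership(responses),
                                      error = function(e) rep("X", I))

  unobs <- vapply(seq_len(I), function(j) length(unique(X[, j])) < 3L, logical(1))
  if (any(unobs)) {
    msg <- paste0("items with unobserved categories (threshold estimates ",
                  "will sit at the boundary): ",
                  paste(items[unobs], collapse = ", "))
    if (on_unobserved == "error")
      stop(structure(class = c("pcmlink_unobserved", "error", "condition"),
                     list(message = msg, call = sys.call(-1),
                          items = items[unobs])))
    warning(structure(class = c("pcmlink_unobserved", "warning", "condition"),
                      list(message = msg, call = sys.call(-1),
                           items = items[unobs])))
  }

  z <- seq(-6, 6, length.out = n_nodes)
  wz <- dnorm(z); wz <- wz / sum(wz)

  if (dimensions == 1) {
    res <- .pcm_em_1d(X, matrix(0, I, 2), z, wz, sigma_start, TRUE,
                      tol, as.integer(maxit), dmax)
    thr <- data.frame(item = items, scale = memb,
                      d1 = res$thresholds[, 1], d2 = res$thresholds[, 2],
                      stringsAsFactors = FALSE)
    latent_sd <- c(theta = res$sigma)
    latent_correlation <- NULL
  } else if (dimensions == 2) {
    if (!all(memb %in% c("X", "Y")) || length(unique(memb)) != 2L)
      stop("two-dimensional fits need a membership vector assigning each item to scale X or Y")
    res <- pcm_em_2d(X, memb, z, wz, tol = tol, maxit = maxit,
                     sigma_start = sigma_start, dmax = dmax)
    thr <- data.frame(item = items, scale = memb,
                      d1 = res$thresholds[, 1], d2 = res$thresholds[, 2],
                      stringsAsFactors = FALSE)
    latent_sd <- res$sigma
    latent_correlation <- res$rho
  } else stop("'dimensions' must be 1 or 2")

  thr$location <- (thr$d1 + thr$d2) / 2
  structure(list(
    thresholds = thr,
    latent_sd = latent_sd,
    latent_correlation = latent_correlation,
    log_likelihood = res$loglik_trace[length(res$loglik_trace)],
    loglik_trace = res$loglik_trace,
    converged = res$converged,
    n_iterations = res$n_iterations,
    dimensions = dimensions,
    n_persons = N,
    n_items = I,
    unobserved_items = items[unobs],
    call = match.call()
  ), class = "pcm")
}

# Two-dimensional MML-EM on a 2-D rectangle-rule grid. Items of scale X load
# on dimension 1, scale Y on dimension 2; latent covariance estimated from
# posterior second moments with the mean fixed at (0, 0).
pcm_em_2d <- function(X, memb, z, wz, tol, maxit, sigma_start, dmax) {
  N <- nrow(X); Q <- length(z)
  ix <- which(memb == "X"); iy <- which(memb == "Y")
  d <- matrix(0, ncol(X), 2)
  sx <- sigma_start; sy <- sigma_start; rho <- 0
  trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  n_iter <- 0L
  z1 <- matrix(z, Q, Q); z2 <- t(z1)

  # per-dimension log-likelihood matrix: sum of item log-probabilities
  dim_loglik <- function(th, cols) {
    M <- matrix(0, N, Q)
    for (j in cols) {
      lp <- t(log(pcm_category_probs(th, d[j, ])))   # 3 x Q
      M <- M + lp[X[, j] + 1L, , drop = FALSE]
    }
    M
  }

  for (iter in seq_len(maxit)) {
    n_iter <- iter
    thx <- sx * z; thy <- sy * z
    r <- max(min(rho, 0.999), -0.999)
    w <- exp(-(z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2)))
    w <- w / sum(w)                                  # Q x Q, index (q1, q2)

    A <- dim_loglik(thx, ix)
    B <- dim_loglik(thy, iy)
    rmA <- apply(A, 1, max); rmB <- apply(B, 1, max)
    U <- exp(A - rmA); V <- exp(B - rmB)             # N x Q each
    Uw <- U %*% w                                    # N x Q: sum over q1
    denom <- rowSums(Uw * V)
    ll <- sum(rmA + rmB + log(denom))
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    post1 <- (U * (V %*% t(w))) / denom              # marginal posterior, dim 1
    post2 <- (V * Uw) / denom                        # marginal posterior, dim 2
    Exy <- rowSums((sweep(U, 2, thx, "*") %*% w) * sweep(V, 2, thy, "*")) / denom

    sxx <- mean(post1 %*% thx^2)
    syy <- mean(post2 %*% thy^2)
    sxy <- mean(Exy)
    sx <- max(sqrt(sxx), 1e-3)
    sy <- max(sqrt(syy), 1e-3)
    rho <- max(min(sxy / (sx * sy), 0.999), -0.999)

    for (j in ix) d[j, ] <- newton_item(crossprod(post1, categ_indicator(X[, j])),
                                        thx, d[j, ], dmax)
    for (j in iy) d[j, ] <- newton_item(crossprod(post2, categ_indicator(X[, j])),
                                        thy, d[j, ], dmax)
  }

  list(thresholds = d, sigma = c(theta_x = sx, theta_y = sy), rho = rho,
       loglik_trace = trace, converged = converged, n_iterations = n_iter)
}

categ_indicator <- function(x) {
  out <- matrix(0, length(x), 3)
  out[cbind(seq_along(x), x + 1L)] <- 1
  out
}

# Newton ascent on the expected complete-data log-likelihood for one
# three-category item; `counts` is Q x 3 expected category counts per node.
newton_item <- function(counts, theta, d, dmax) {
  d1 <- d[1]; d2 <- d[2]
  for (it in 1:12) {
    P <- pcm_category_probs(theta, c(d1, d2))
    nq <- rowSums(counts)
    p1 <- P[, 2]; p2 <- P[, 3]; p12 <- p1 + p2
    g1 <- sum(-(counts[, 2] + counts[, 3]) + nq * p12)
    g2 <- sum(-counts[, 3] + nq * p2)
    h11 <- sum(nq * p12 * (1 - p12))
    h22 <- sum(nq * p2 * (1 - p2))
    h12 <- sum(nq * p2 * (1 - p12))
    det <- h11 * h22 - h12^2
    if (det > 1e-12 && h11 > 1e-12) {
      s1 <- (h22 * g1 - h12 * g2) / det
      s2 <- (h11 * g2 - h12 * g1) / det
    } else {
      s1 <- g1 / (h11 + 1e-6)
      s2 <- g2 / (h22 + 1e-6)
    }
    s1 <- max(min(s1, 2), -2); s2 <- max(min(s2, 2), -2)
    d1 <- max(min(d1 + s1, dmax), -dmax)
    d2 <- max(min(d2 + s2, dmax), -dmax)
    if (abs(s1) < 1e-8 && abs(s2) < 1e-8) break
  }
  c(d1, d2)
}
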