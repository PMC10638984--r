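#' Enumerate the simulation settings grid
#'
#' Builds the full factorial grid of data-generating conditions for the
#' equating precision study: construct similarity (latent correlation
#' \code{rho_sim}), ability dispersion \code{sigma_theta}, mean-difficulty
#' shift \code{shift} between the two scales, the pair of item-location
#' dispersions \code{(sigma_delta_x, sigma_delta_y)}, sample size and scale
#' length. The full grid has 4 x 3 x 3 x 3 x 2 x 2 = 432 settings.
#'
#' Rows are ordered lexicographically by (\code{n_items_per_scale},
#' \code{n_persons}, \code{rho_sim}, \code{sigma_theta}, \code{shift},
#' dispersion pair), so setting ids are stable across calls.
#'
#' @param rho_sim,sigma_theta,shift levels of the similarity, ability
#'   dispersion and difficulty-shift factors.
#' @param sigma_delta list of length-2 numeric vectors
#'   \code{c(sigma_delta_x, sigma_delta_y)}.
#' @param n_persons,n_items_per_scale sample-size and scale-length levels.
#' @return A data frame with one row per setting and columns
#'   \code{setting_id}, \code{rho_sim}, \code{sigma_theta}, \code{shift},
#'   \code{sigma_delta_x}, \code{sigma_delta_y}, \code{n_persons},
#'   \code{n_items_per_scale}, \code{n_categories}.
#' @examples
#' g <- settings_grid()
#' nrow(g)  # 432
#' @export
settings_grid <- function(rho_sim = c(0.25, 0.5, 0.75, 1),
                          sigma_theta = c(0.5, 1, 2),
                          shift = c(0, 1, 2),
                          sigma_delta = list(c(1, 1), c(2, 2), c(1, 2)),
                          n_persons = c(500, 1000),
                          n_items_per_scale = c(10, 20)) {
  pairs <- do.call(rbind, lapply(sigma_delta, function(p) {
    stopifnot(length(p) == 2L)
    data.frame(sigma_delta_x = p[1], sigma_delta_y = p[2])
  }))
  g <- expand.grid(pair = seq_len(nrow(pairs)),
                   shift = shift,
                   sigma_theta = sigma_theta,
                   rho_sim = rho_sim,
                   n_persons = n_persons,
                   n_items_per_scale = n_items_per_scale,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$n_items_per_scale, g$n_persons, g$rho_sim,
               g$sigma_theta, g$shift, g$pair), , drop = FALSE]
  out <- data.frame(
    rho_sim = g$rho_sim,
    sigma_theta = g$sigma_theta,
    shift = g$shift,
    sigma_delta_x = pairs$sigma_delta_x[g$pair],
    sigma_delta_y = pairs$sigma_delta_y[g$pair],
    n_persons = g$n_persons,
    n_items_per_scale = g$n_items_per_scale,
    n_categories = 3L
  )
  out$setting_id <- sprintf(
    "I%02d_N%04d_r%.2f_t%.1f_d%d_s%g-%g",
    out$n_items_per_scale, out$n_persons, out$rho_sim, out$sigma_theta,
    out$shift, out$sigma_delta_x, out$sigma_delta_y)
  rownames(out) <- NULL
  out[, c("setting_id", "rho_sim", "sigma_theta", "shift",
          "sigma_delta_x", "sigma_delta_y", "n_persons",
          "n_items_per_scale", "n_categories")]
}

#' Derive a reproducible child seed
#'
#' One master seed spawns per-setting, per-repetition child seeds so that any
#' single repetition can be re-run in isolation. The scheme is a fixed
#' integer hash of (master seed, setting index, repetition index, attempt)
#' reduced modulo a Mersenne prime, so every child seed fits in a 32-bit
#' integer.
#'
#' @param master_seed integer master seed.
#' @param setting integer index of the setting (e.g. its row in the grid).
#' @param rep repetition index (1-based).
#' @param attempt redraw attempt counter (0 for the first draw).
#' @return A single integer seed in \code{[1, 2^31 - 2]}.
#' @export
child_seed <- function(master_seed, setting = 1L, rep = 1L, attempt = 0L) {
  m <- 2147483647  # 2^31 - 1
  # chained Lehmer steps with the indices injected between multiplications;
  # nearby (setting, rep, attempt) triples can then never collide
  h <- (as.numeric(master_seed) %% m)
  for (k in c(setting, rep, attempt)) {
    h <- (h + as.numeric(k)) %% m
    h <- (h * 48271 + 1) %% m
    h <- (h * 40692 + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
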