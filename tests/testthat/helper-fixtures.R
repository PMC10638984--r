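# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files.

# one row of the settings grid by id
grid_setting <- function(id) {
  g <- settings_grid()
  s <- g[g$setting_id == id, , drop = FALSE]
  stopifnot(nrow(s) == 1L)
  s
}

# a small deterministic item bank: I items per scale, locations spread
# evenly, all half-distances 0.7
toy_items <- function(I = 5, shift = 0, spread = 1) {
  loc <- c(seq(-spread, spread, length.out = I) - shift / 2,
           seq(-spread, spread, length.out = I) + shift / 2)
  scale <- rep(c("X", "Y"), each = I)
  data.frame(item = paste0(scale, "_", rep(seq_len(I), 2)), scale = scale,
             location = loc, d1 = loc - 0.7, d2 = loc + 0.7,
             stringsAsFactors = FALSE)
}

# minimal object of class "pcm" around a given item bank (for operations
# that only need thresholds, e.g. tables and ordering checks)
toy_fit <- function(items, latent_sd = 1) {
  structure(list(
    thresholds = transform(items, location = (d1 + d2) / 2),
    latent_sd = c(theta = latent_sd), latent_correlation = NULL,
    log_likelihood = NA_real_, loglik_trace = NA_real_, converged = TRUE,
    n_iterations = 0L, dimensions = 1, n_persons = 0L,
    n_items = nrow(items), unobserved_items = character(0),
    call = quote(toy_fit())
  ), class = "pcm")
}
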