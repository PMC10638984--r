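# Fixture shared by several estimation tests: moderate-size unidimensional
# sample with known generating parameters.
fit_dat <- simulate_equating_data(grid_setting("I10_N1000_r1.00_t1.0_d1_s1-1"),
                                  seed = 11)
fit_1d <- pcm(fit_dat$responses)

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  tr <- fit_1d$loglik_trace
  expect_true(fit_1d$converged)
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-1])))
})

test_that("thresholds and the latent SD recover the generating values", {
  err <- fit_1d$thresholds$location - fit_dat$items$location
  expect_lt(sqrt(mean(err^2)), 0.15)
  expect_lt(abs(mean(err)), 0.06)
  expect_equal(unname(fit_1d$latent_sd), 1, tolerance = 0.1)
})

test_that("the reported log-likelihood matches an independent recomputation", {
  X <- fit_dat$responses
  z <- seq(-6, 6, length.out = 61)
  wz <- dnorm(z); wz <- wz / sum(wz)
  th <- fit_1d$latent_sd[1] * z
  L <- matrix(0, nrow(X), length(z))
  for (i in seq_len(ncol(X))) {
    lp <- t(log(pcm_category_probs(th, unlist(fit_1d$thresholds[i, c("d1", "d2")]))))
    L <- L + lp[X[, i] + 1L, ]
  }
  m <- apply(L, 1, max)
  ll <- sum(m + log(drop(exp(L - m) %*% wz)))
  expect_equal(fit_1d$log_likelihood, ll, tolerance = 1e-8 * abs(ll))
})

test_that("estimates are invariant to person order and follow item relabeling", {
  X <- fit_dat$responses
  set.seed(21)
  Xp <- X[sample(nrow(X)), ]
  attr(Xp, "scale") <- attr(X, "scale")
  fit_p <- pcm(Xp)
  expect_equal(fit_p$thresholds$d1, fit_1d$thresholds$d1, tolerance = 1e-8)
  expect_equal(unname(fit_p$latent_sd), unname(fit_1d$latent_sd),
               tolerance = 1e-8)

  perm <- rev(seq_len(ncol(X)))
  Xc <- X[, perm]
  attr(Xc, "scale") <- attr(X, "scale")[perm]
  fit_c <- pcm(Xc)
  expect_equal(fit_c$thresholds$item, fit_1d$thresholds$item[perm])
  expect_equal(fit_c$thresholds$d2, fit_1d$thresholds$d2[perm],
               tolerance = 1e-8)
})

test_that("two-dimensional fits recover the latent correlation", {
  s <- grid_setting("I10_N1000_r0.75_t1.0_d0_s1-1")
  dat <- simulate_equating_data(s, seed = 31)
  fit <- pcm(dat$responses, dimensions = 2)
  expect_true(fit$converged)
  expect_equal(fit$latent_correlation, 0.75, tolerance = 0.1)
  expect_equal(unname(fit$latent_sd), c(1, 1), tolerance = 0.15)

  s1 <- grid_setting("I10_N1000_r1.00_t1.0_d0_s1-1")
  dat1 <- simulate_equating_data(s1, seed = 32)
  fit1 <- pcm(dat1$responses, dimensions = 2)
  expect_gt(fit1$latent_correlation, 0.95)
})

test_that("a 1-D fit on two scales approximates the rho = 1 limit of the 2-D fit", {
  s <- grid_setting("I10_N0500_r1.00_t1.0_d0_s1-1")
  dat <- simulate_equating_data(s, seed = 33)
  f1 <- pcm(dat$responses, dimensions = 1)
  f2 <- pcm(dat$responses, dimensions = 2)
  # same data, nearly unidimensional solution: log-likelihoods agree closely
  expect_gt(f2$latent_correlation, 0.95)
  expect_equal(f1$log_likelihood, f2$log_likelihood,
               tolerance = 2e-4 * abs(f1$log_likelihood))
})

test_that("degenerate inputs are signalled", {
  X <- fit_dat$responses
  Xb <- X
  Xb[, 3] <- pmin(Xb[, 3], 1L)  # category 2 never observed
  attr(Xb, "scale") <- attr(X, "scale")
  expect_warning(pcm(Xb), class = "pcmlink_unobserved")
  expect_error(pcm(Xb, on_unobserved = "error"), class = "pcmlink_unobserved")
  w <- tryCatch(pcm(Xb), pcmlink_unobserved = function(w) w)
  expect_true(colnames(X)[3] %in% w$items)
  Xc <- X
  Xc[1, 1] <- NA
  expect_error(pcm(Xc), "missing")
  expect_error(pcm(X, dimensions = 3), "1 or 2")
})

test_that("boundary-capped items leave the remaining thresholds intact", {
  X <- fit_dat$responses
  Xb <- X
  Xb[, 1] <- pmin(Xb[, 1], 1L)
  attr(Xb, "scale") <- attr(X, "scale")
  fit_b <- suppressWarnings(pcm(Xb))
  expect_equal(fit_b$unobserved_items, colnames(X)[1])
  expect_equal(fit_b$thresholds$d2[1], 12)  # at the cap
  expect_equal(fit_b$thresholds$location[-1], fit_1d$thresholds$location[-1],
               tolerance = 0.1)
})

test_that("fitted models serialize to JSON and back", {
  js <- pcm_to_json(fit_1d)
  back <- pcm_from_json(js)
  expect_equal(back$thresholds$d1, fit_1d$thresholds$d1, tolerance = 1e-12)
  expect_equal(unname(back$latent_sd), unname(fit_1d$latent_sd))
  expect_equal(back$log_likelihood, fit_1d$log_likelihood)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  pcm_to_json(fit_1d, f)
  expect_equal(pcm_from_json(f)$thresholds$d2, fit_1d$thresholds$d2)
})

test_that("simulate() draws from the fitted model", {
  sims <- simulate(fit_1d, nsim = 2, seed = 41, n_persons = 200)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(200, fit_1d$n_items))
  expect_true(all(sims[[1]] %in% 0:2))
  expect_false(identical(sims[[1]], sims[[2]]))
})
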