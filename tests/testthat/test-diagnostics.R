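# Diagnostics are evaluated against data simulated from the model (null
# behaviour) and against constructed violations.
diag_dat <- simulate_equating_data(
  grid_setting("I10_N1000_r1.00_t1.0_d0_s1-1"), seed = 71)
diag_dat$responses <- {
  x <- diag_dat$responses
  attr(x, "scale") <- diag_dat$items$scale
  x
}
diag_fit <- pcm(diag_dat$responses)

test_that("infit and outfit sit near 1 on model-consistent data", {
  fi <- item_fit(diag_fit, diag_dat$responses)
  expect_equal(nrow(fi), 20L)
  expect_true(all(fi$infit > 0 & fi$outfit > 0))
  expect_gt(mean(fi$infit), 0.95)
  expect_lt(mean(fi$infit), 1.05)
  expect_true(all(fi$infit > 0.8 & fi$infit < 1.2))
})

test_that("deterministic Guttman-style responses overfit (mean squares below 1)", {
  items <- diag_fit$thresholds
  th <- sort(rnorm(600))
  # deterministic scoring: category = steps passed at theta
  X <- sapply(seq_len(nrow(items)), function(j)
    (th > items$d1[j]) + (th > items$d2[j]))
  storage.mode(X) <- "integer"
  colnames(X) <- items$item
  attr(X, "scale") <- items$scale
  fit_g <- suppressWarnings(pcm(X, maxit = 200))
  fi <- item_fit(fit_g, X)
  expect_true(all(fi$outfit < 1))
})

test_that("empty and zero-variance item sets are rejected", {
  X <- diag_dat$responses
  Xz <- X
  Xz[, 2] <- 1L
  expect_error(suppressWarnings(item_fit(pcm_from_json(pcm_to_json(diag_fit)),
                                         Xz)), "zero response variance")
})

test_that("threshold ordering is read off the estimated thresholds", {
  fit <- toy_fit(data.frame(item = c("X_1", "X_2"), scale = "X",
                            location = c(0, 0.1), d1 = c(-0.7, 0.4),
                            d2 = c(0.7, -0.2)))
  ord <- threshold_order_check(fit)
  expect_equal(ord$ordered, c(TRUE, FALSE))
})

test_that("most simulated-default items are estimated with ordered thresholds", {
  ord <- threshold_order_check(diag_fit)
  expect_gte(mean(ord$ordered), 0.95)
})

test_that("residual correlations are symmetric, bounded, and flag duplicates", {
  rc <- residual_correlations(diag_fit, diag_dat$responses)
  expect_equal(rc$matrix, t(rc$matrix))
  expect_equal(unname(diag(rc$matrix)), rep(1, 20))
  # locally independent data: residual correlations stay small
  expect_lt(rc$max_lid, 0.15)

  # duplicating an item column produces near-perfect residual dependency
  X <- diag_dat$responses
  Xd <- cbind(X, X[, 1])
  colnames(Xd) <- c(colnames(X), "X_dup")
  attr(Xd, "scale") <- c(attr(X, "scale"), "X")
  fit_d <- pcm(Xd)
  rc_d <- residual_correlations(fit_d, Xd)
  expect_gt(rc_d$matrix["X_1", "X_dup"], 0.9)

  expect_error(residual_correlations(
    toy_fit(toy_items(1)[1, , drop = FALSE]), X), "3 items")
})

test_that("dimensionality t-tests stay near the nominal level on 1-D data", {
  dt <- dimensionality_ttests(diag_fit, diag_dat$responses)
  expect_lt(dt$percent_significant, 8)
  expect_gt(length(dt$subset_positive), 0)
  expect_gt(length(dt$subset_negative), 0)
})

test_that("dimensionality t-tests flag clearly two-dimensional data", {
  s <- grid_setting("I10_N1000_r0.25_t1.0_d0_s1-1")
  dat2 <- simulate_equating_data(s, seed = 72)
  fit2 <- pcm(dat2$responses)  # misspecified unidimensional fit
  dt2 <- dimensionality_ttests(fit2, dat2$responses)
  dt1 <- dimensionality_ttests(diag_fit, diag_dat$responses)
  expect_gt(dt2$percent_significant, dt1$percent_significant)
  expect_gt(dt2$percent_significant, 8)
})

test_that("too few items for the dimensionality split is an error", {
  items <- toy_items(2)  # 4 items total
  s <- grid_setting("I10_N0500_r1.00_t1.0_d0_s1-1")
  ab <- draw_abilities(s, seed = 73)
  X <- simulate_responses(items, ab, seed = 74)
  fit <- suppressWarnings(pcm(X))
  expect_error(dimensionality_ttests(fit, X), "at least 6 items")
})

test_that("diagnostics are invariant to person order", {
  X <- diag_dat$responses
  set.seed(75)
  perm <- sample(nrow(X))
  Xp <- X[perm, ]
  attr(Xp, "scale") <- attr(X, "scale")
  expect_equal(item_fit(diag_fit, Xp)$infit,
               item_fit(diag_fit, X)$infit, tolerance = 1e-10)
  expect_equal(residual_correlations(diag_fit, Xp)$max_lid,
               residual_correlations(diag_fit, X)$max_lid, tolerance = 1e-10)
})

test_that("the assembled report carries every step's battery and serializes", {
  memb <- attr(diag_dat$responses, "scale")
  sub <- function(sc) {
    m <- diag_dat$responses[, memb == sc]
    attr(m, "scale") <- memb[memb == sc]
    m
  }
  fit_x <- pcm(sub("X")); fit_y <- pcm(sub("Y"))
  twodim <- pcm(diag_dat$responses, dimensions = 2)
  rep <- fit_report(
    separate = list(X = list(fit = fit_x, responses = sub("X")),
                    Y = list(fit = fit_y, responses = sub("Y"))),
    concurrent = list(fit = diag_fit, responses = diag_dat$responses),
    twodim = twodim)
  expect_s3_class(rep, "pcm_fit_report")
  expect_true(is.numeric(rep$factor_correlation))
  for (b in list(rep$separate$X, rep$concurrent, rep$anchored$Y)) {
    expect_true(all(c("item_fit_ok", "thresholds_ordered", "lid",
                      "percent_significant_ttests", "targeting") %in% names(b)))
  }
  expect_output(print(rep), "Concurrent analysis")
  js <- jsonlite::fromJSON(fit_report_json(rep))
  expect_equal(js$concurrent$lid, rep$concurrent$lid, tolerance = 1e-9)
})
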