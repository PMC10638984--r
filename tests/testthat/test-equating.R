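test_that("identical item banks equate to the identity map", {
  fit <- toy_fit(toy_items(5))  # X and Y banks identical by construction
  for (m in c("eap", "tcc")) {
    tabs <- build_score_theta_tables(fit, method = m)
    expect_equal(tabs$X$theta, tabs$Y$theta, tolerance = 1e-10)
    cc <- build_concordance(tabs$X, tabs$Y)
    expect_equal(cc$equated_x, cc$raw_score)
    expect_equal(cc$equated_y, cc$raw_score)
  }
})

test_that("a harder Y bank sits higher on the common metric", {
  fit <- toy_fit(toy_items(5, shift = 1))
  tabs <- build_score_theta_tables(fit, method = "tcc")
  expect_true(all(tabs$Y$theta > tabs$X$theta))
  # and the concordance sends X scores to lower Y scores
  cc <- build_concordance(tabs$X, tabs$Y)
  inner <- cc$raw_score > 0 & cc$raw_score < 10
  expect_true(all(cc$equated_y[inner] <= cc$raw_score[inner]))
  expect_true(all(cc$equated_x[inner] >= cc$raw_score[inner]))
})

test_that("equated columns are monotone non-decreasing", {
  set.seed(61)
  for (k in 1:5) {
    items <- toy_items(6, shift = runif(1, 0, 2), spread = runif(1, 0.5, 2))
    items$d1 <- items$d1 + rnorm(12, 0, 0.2)
    items$d2 <- items$d2 + rnorm(12, 0, 0.2)
    tabs <- build_score_theta_tables(toy_fit(items))
    cc <- build_concordance(tabs$X, tabs$Y)
    expect_true(all(diff(cc$equated_x) >= 0))
    expect_true(all(diff(cc$equated_y) >= 0))
  }
})

test_that("argmin ties break toward the lower raw score", {
  tx <- data.frame(raw_score = 0:2, theta = c(-1, 0, 1), standard_error = 1)
  # theta 0 on X is exactly equidistant from Y thetas -0.5 and +0.5
  ty <- data.frame(raw_score = 0:2, theta = c(-0.5, 0.5, 1.5),
                   standard_error = 1)
  cc <- build_concordance(tx, ty)
  expect_equal(cc$equated_y[cc$raw_score == 1], 0L)
})

test_that("score transformation is a plain table lookup with range checks", {
  fit <- toy_fit(toy_items(4))
  cc <- build_concordance(score_theta_table(fit, "X"),
                          score_theta_table(fit, "Y"))
  expect_equal(true_score_transform(c(0L, 3L, 8L), cc, "XtoY"), c(0L, 3L, 8L))
  expect_error(true_score_transform(9L, cc, "XtoY"), "range")
  # round trip on a monotone concordance stays within one raw-score point
  fit2 <- toy_fit(toy_items(4, shift = 1))
  cc2 <- build_concordance(score_theta_table(fit2, "X"),
                           score_theta_table(fit2, "Y"))
  r <- 0:8
  back <- true_score_transform(true_score_transform(r, cc2, "XtoY"),
                               cc2, "YtoX")
  twice <- true_score_transform(true_score_transform(back, cc2, "XtoY"),
                                cc2, "YtoX")
  expect_true(all(abs(twice - back) <= 1))
})

test_that("identity equating returns scores unchanged, clipped to the target range", {
  expect_equal(identity_transform(c(0L, 5L, 20L), c(0L, 20L)), c(0L, 5L, 20L))
  expect_equal(identity_transform(20L, c(0L, 15L)), 15L)
  expect_equal(identity_transform(integer(0), c(0L, 20L)), integer(0))
})

test_that("concurrent calibration covers all items and matches separate fits at rho = 1", {
  s <- grid_setting("I10_N1000_r1.00_t1.0_d0_s1-1")
  s$n_persons <- 2000L
  dat <- simulate_equating_data(s, seed = 62)
  conc <- concurrent_calibrate(dat$responses)
  expect_setequal(conc$thresholds$item, dat$items$item)

  memb <- attr(dat$responses, "scale")
  sub_x <- dat$responses[, memb == "X"]
  attr(sub_x, "scale") <- rep("X", 10)
  fit_x <- pcm(sub_x)
  # unidimensional data: separate and concurrent metrics agree after centering
  d_conc <- conc$thresholds$location[conc$thresholds$scale == "X"]
  d_sep <- fit_x$thresholds$location
  expect_lt(max(abs((d_conc - mean(d_conc)) - (d_sep - mean(d_sep)))), 0.15)
})

test_that("the concordance CSV uses the three-column crosswalk layout", {
  fit <- toy_fit(toy_items(3))
  tabs <- build_score_theta_tables(fit)
  cc <- build_concordance(tabs$X, tabs$Y)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_concordance(cc, f, tables = tabs)
  out <- read.csv(f, check.names = FALSE)
  expect_equal(names(out)[1:3],
               c("Raw Scores X or Y", "Equated Scores X", "Equated Scores Y"))
  expect_equal(out[["Raw Scores X or Y"]], 0:6)
  expect_true(all(c("Theta X", "SE Y") %in% names(out)))
})

test_that("equate_scales bundles calibration, tables, concordance and precision", {
  s <- grid_setting("I10_N0500_r0.75_t1.0_d0_s1-1")
  dat <- simulate_equating_data(s, seed = 63)
  eq <- equate_scales(dat$responses)
  expect_s3_class(eq, "pcm_equating")
  expect_equal(nrow(eq$precision), 4L)
  expect_setequal(eq$precision$method, c("true_score", "identity"))
  expect_true(all(eq$precision$nrmse >= 0))
  expect_output(print(eq), "Transformation precision")
})

test_that("crosswalk reads two CSVs, matches persons by id, and writes outputs", {
  s <- grid_setting("I10_N0500_r0.75_t1.0_d0_s1-1")
  dat <- simulate_equating_data(s, seed = 64)
  memb <- attr(dat$responses, "scale")
  fx <- tempfile(fileext = ".csv"); fy <- tempfile(fileext = ".csv")
  fc <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".json")
  on.exit(unlink(c(fx, fy, fc, fr)))
  dx <- as.data.frame(dat$responses[, memb == "X"])
  dy <- as.data.frame(dat$responses[, memb == "Y"])
  dx$id <- seq_len(nrow(dx))
  set.seed(66)
  perm <- sample(nrow(dy))           # rows shuffled, true person id kept
  dy$id <- seq_len(nrow(dy))
  dy <- dy[perm, ]
  write.csv(dx, fx, row.names = FALSE); write.csv(dy, fy, row.names = FALSE)
  eq <- crosswalk(fx, fy, id_column = "id",
                  concordance_file = fc, report_file = fr)
  expect_s3_class(eq$report, "pcm_fit_report")
  expect_equal(eq$twodim$latent_correlation, 0.75, tolerance = 0.1)
  expect_true(file.exists(fc) && file.exists(fr))
  rep_json <- jsonlite::fromJSON(fr)
  expect_true(all(c("factor_correlation", "separate", "concurrent",
                    "anchored") %in% names(rep_json)))
})

test_that("identical X and Y files produce an identity crosswalk with zero error", {
  s <- grid_setting("I10_N0500_r1.00_t1.0_d0_s1-1")
  dat <- simulate_equating_data(s, seed = 65)
  memb <- attr(dat$responses, "scale")
  sub <- dat$responses[, memb == "X"]
  both <- cbind(sub, sub)
  colnames(both) <- c(paste0("X_", 1:10), paste0("Y_", 1:10))
  attr(both, "scale") <- rep(c("X", "Y"), each = 10)
  eq <- equate_scales(both)
  expect_equal(eq$concordance$equated_y, eq$concordance$raw_score)
  ts <- eq$precision[eq$precision$method == "true_score", ]
  expect_equal(ts$nrmse, c(0, 0))
})
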