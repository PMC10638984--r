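#' Concurrent calibration of two scales
#'
#' Fits one unidimensional PCM over all items of both scales, regardless of
#' the true degree of association between them. This places all item
#' thresholds on a common metric; the combined raw score is the sufficient
#' statistic for the shared ability.
#'
#' @param responses response matrix containing both scales' items (common
#'   person design: every row answered both scales).
#' @param ... passed to \code{\link{pcm}}.
#' @return A \code{"pcm"} fit.
#' @export
concurrent_calibrate <- function(responses, ...) {
  memb <- scale_membership(responses)
  if (length(unique(memb)) != 2L)
    stop("concurrent calibration expects items from two scales (X and Y)")
  pcm(responses, dimensions = 1, membership = memb, ...)
}

#' Anchored score-to-theta tables for both scales
#'
#' Per scale, maps every raw score to its anchored ability estimate under
#' the concurrent thresholds; see \code{\link{score_theta_table}} for the
#' two estimator routes. The EAP route uses the concurrent fit's latent SD
#' as the shared prior dispersion for both scales, keeping the two tables on
#' the common metric.
#'
#' @param concurrent a concurrent \code{"pcm"} fit over both scales.
#' @param method person-estimate route, \code{"eap"} (default) or
#'   \code{"tcc"}; see \code{\link{score_theta_table}}.
#' @return A list with elements \code{X} and \code{Y}, each a
#'   \code{\link{score_theta_table}}.
#' @export
build_score_theta_tables <- function(concurrent, method = c("eap", "tcc")) {
  method <- match.arg(method)
  list(X = score_theta_table(concurrent, "X", method = method),
       Y = score_theta_table(concurrent, "Y", method = method))
}

#' Build a bidirectional concordance (crosswalk) table
#'
#' For each raw score on one scale, the equated score on the other scale is
#' the raw score whose anchored ability lies nearest in absolute distance
#' (\code{argmin |theta_X - theta_Y|}); exact ties break toward the lower raw
#' score. The output uses the conventional three-column crosswalk layout: the
#' first column holds the raw score read on either scale, the second the
#' equated score on Scale X (for a raw score read on Y), the third the
#' equated score on Scale Y (for a raw score read on X).
#'
#' @param table_x,table_y score-to-theta tables from
#'   \code{\link{build_score_theta_tables}}.
#' @return A \code{concordance_table}: data frame with columns
#'   \code{raw_score}, \code{equated_x}, \code{equated_y} (\code{NA} where a
#'   raw score exceeds the source scale's range, for unequal scale lengths).
#' @export
build_concordance <- function(table_x, table_y) {
  if (nrow(table_x) == 0L || nrow(table_y) == 0L) stop("empty score-theta table")
  match_nearest <- function(theta, target_theta, target_score) {
    vapply(theta, function(t) {
      d <- abs(t - target_theta)
      target_score[which.min(d)]  # which.min takes the first (lowest score) on ties
    }, numeric(1))
  }
  max_raw <- max(max(table_x$raw_score), max(table_y$raw_score))
  raw <- 0:max_raw
  to_y <- rep(NA_real_, length(raw))
  to_x <- rep(NA_real_, length(raw))
  ix <- raw <= max(table_x$raw_score)
  iy <- raw <= max(table_y$raw_score)
  to_y[ix] <- match_nearest(table_x$theta[raw[ix] + 1L],
                            table_y$theta, table_y$raw_score)
  to_x[iy] <- match_nearest(table_y$theta[raw[iy] + 1L],
                            table_x$theta, table_x$raw_score)
  out <- data.frame(raw_score = raw,
                    equated_x = as.integer(to_x),
                    equated_y = as.integer(to_y))
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' Transform raw scores through a concordance table
#'
#' Table lookup implementing the true-score transformation: a score observed
#' on the source scale is replaced by its equated score on the target scale.
#'
#' @param raw_scores integer scores observed on the source scale.
#' @param concordance a \code{\link{build_concordance}} table.
#' @param direction \code{"XtoY"} (scores observed on X, expressed on Y) or
#'   \code{"YtoX"}.
#' @return Integer vector of transformed scores.
#' @export
true_score_transform <- function(raw_scores, concordance,
                                 direction = c("XtoY", "YtoX")) {
  direction <- match.arg(direction)
  col <- if (direction == "XtoY") "equated_y" else "equated_x"
  valid <- !is.na(concordance[[col]])
  if (any(raw_scores < 0 | raw_scores > max(concordance$raw_score[valid])))
    stop("raw scores outside the source scale's range")
  concordance[[col]][raw_scores + 1L]
}

#' Identity equating baseline
#'
#' The naive baseline that declares a score on one scale equivalent to the
#' same numeric score on the other, clipping into the target range when the
#' ranges differ.
#'
#' @param raw_scores integer scores.
#' @param target_range length-2 integer vector \code{c(min, max)} of the
#'   target scale.
#' @return Integer vector of (clipped) scores.
#' @export
identity_transform <- function(raw_scores, target_range) {
  as.integer(pmin(pmax(raw_scores, target_range[1]), target_range[2]))
}

#' Write a concordance table as CSV
#'
#' Uses the three-column crosswalk layout ("Raw Scores X or Y",
#' "Equated Scores X", "Equated Scores Y"); optionally appends the anchored
#' theta and standard-error columns of both scales.
#'
#' @param concordance a \code{\link{build_concordance}} table.
#' @param file output path.
#' @param tables optional list \code{(X, Y)} of score-theta tables whose
#'   theta/SE columns are appended.
#' @return \code{file}, invisibly.
#' @export
write_concordance <- function(concordance, file, tables = NULL) {
  out <- data.frame(`Raw Scores X or Y` = concordance$raw_score,
                    `Equated Scores X` = concordance$equated_x,
                    `Equated Scores Y` = concordance$equated_y,
                    check.names = FALSE)
  if (!is.null(tables)) {
    pad <- function(v, n) c(v, rep(NA, n - length(v)))
    n <- nrow(out)
    out$`Theta X` <- pad(tables$X$theta, n)
    out$`SE X` <- pad(tables$X$standard_error, n)
    out$`Theta Y` <- pad(tables$Y$theta, n)
    out$`SE Y` <- pad(tables$Y$standard_error, n)
  }
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance table (raw score read on either scale):\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Equate two scales end to end
#'
#' Runs the full true-score equating workflow on a common-person response
#' matrix: concurrent calibration of both scales, anchored score-to-theta
#' tables per scale, and the bidirectional concordance table. With
#' \code{diagnostics = TRUE} the Rasch fit battery and a two-dimensional fit
#' (for the construct-similarity correlation) are added.
#'
#' @param responses response matrix with \code{X_}/\code{Y_} items (or a
#'   \code{"scale"} attribute).
#' @param diagnostics run separate fits, the 2-D fit and the fit battery.
#' @param ... passed to \code{\link{pcm}} for the concurrent fit.
#' @return An object of class \code{"pcm_equating"}: list with
#'   \code{concurrent} (the fitted \code{"pcm"}), \code{tables},
#'   \code{concordance}, and precision summaries comparing the true-score
#'   and identity transformations on the calibration sample; when
#'   \code{diagnostics} is on, also \code{separate}, \code{twodim} and
#'   \code{report}.
#' @export
equate_scales <- function(responses, diagnostics = FALSE, ...) {
  memb <- scale_membership(responses)
  concurrent <- concurrent_calibrate(responses, ...)
  tables <- build_score_theta_tables(concurrent)
  concordance <- build_concordance(tables$X, tables$Y)
  rx <- raw_scores(responses, "X")
  ry <- raw_scores(responses, "Y")
  range_x <- c(0L, 2L * sum(memb == "X"))
  range_y <- c(0L, 2L * sum(memb == "Y"))
  precision <- rbind(
    precision_record(true_score_transform(rx, concordance, "XtoY"), ry,
                     range_y, "XtoY", "true_score"),
    precision_record(true_score_transform(ry, concordance, "YtoX"), rx,
                     range_x, "YtoX", "true_score"),
    precision_record(identity_transform(rx, range_y), ry,
                     range_y, "XtoY", "identity"),
    precision_record(identity_transform(ry, range_x), rx,
                     range_x, "YtoX", "identity"))
  out <- list(concurrent = concurrent, tables = tables,
              concordance = concordance, precision = precision)
  if (diagnostics) {
    sub_x <- responses[, memb == "X", drop = FALSE]
    attr(sub_x, "scale") <- memb[memb == "X"]
    sub_y <- responses[, memb == "Y", drop = FALSE]
    attr(sub_y, "scale") <- memb[memb == "Y"]
    fit_x <- pcm(sub_x, membership = memb[memb == "X"])
    fit_y <- pcm(sub_y, membership = memb[memb == "Y"])
    twodim <- pcm(responses, dimensions = 2, membership = memb)
    out$separate <- list(X = fit_x, Y = fit_y)
    out$twodim <- twodim
    out$report <- fit_report(
      separate = list(X = list(fit = fit_x, responses = sub_x),
                      Y = list(fit = fit_y, responses = sub_y)),
      concurrent = list(fit = concurrent, responses = responses),
      twodim = twodim)
  }
  class(out) <- "pcm_equating"
  out
}

#' @export
print.pcm_equating <- function(x, ...) {
  cat("True-score equating (common person design)\n")
  print(x$concurrent)
  cat("\nTransformation precision on the calibration sample:\n")
  print(x$precision, digits = 3, row.names = FALSE)
  if (!is.null(x$twodim))
    cat(sprintf("\nConstruct similarity (2-D latent correlation): %.3f\n",
                x$twodim$latent_correlation))
  invisible(x)
}

#' Crosswalk two response CSV files
#'
#' Real-data entry point: reads two CSV response matrices for the same
#' persons (matched by row order or by an \code{id} column present in both
#' files), runs the separate, two-dimensional and concurrent analyses with
#' the diagnostic battery, and returns the equating object; optionally writes
#' the concordance CSV and the JSON diagnostic report.
#'
#' @param file_x,file_y CSV files, one row per person, integer categories
#'   0..2. Column names need not be prefixed; they are tagged X_/Y_.
#' @param id_column optional id column name present in both files.
#' @param concordance_file,report_file optional output paths.
#' @return A \code{"pcm_equating"} object (with diagnostics).
#' @export
crosswalk <- function(file_x, file_y, id_column = NULL,
                      concordance_file = NULL, report_file = NULL) {
  dx <- read.csv(file_x, check.names = FALSE)
  dy <- read.csv(file_y, check.names = FALSE)
  if (!is.null(id_column)) {
    if (!(id_column %in% names(dx)) || !(id_column %in% names(dy)))
      stop("id column '", id_column, "' missing from one of the files")
    common <- intersect(dx[[id_column]], dy[[id_column]])
    if (length(common) == 0L) stop("no common person ids between the files")
    dx <- dx[match(common, dx[[id_column]]), names(dx) != id_column, drop = FALSE]
    dy <- dy[match(common, dy[[id_column]]), names(dy) != id_column, drop = FALSE]
  } else if (nrow(dx) != nrow(dy)) {
    stop("files have different numbers of rows and no id column was given")
  }
  X <- cbind(as.matrix(dx), as.matrix(dy))
  storage.mode(X) <- "integer"
  colnames(X) <- c(paste0("X_", sub("^X_", "", names(dx))),
                   paste0("Y_", sub("^Y_", "", names(dy))))
  attr(X, "scale") <- rep(c("X", "Y"), c(ncol(dx), ncol(dy)))
  eq <- equate_scales(X, diagnostics = TRUE)
  if (!is.null(concordance_file))
    write_concordance(eq$concordance, concordance_file, eq$tables)
  if (!is.null(report_file)) fit_report_json(eq$report, report_file)
  eq
}
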