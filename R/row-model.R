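#' Ground-truth plant positions of a crop row
#'
#' Along-track stem positions in millimetres, strictly increasing and
#' non-negative, with optional plant/stick labels.
#'
#' @param positions Numeric vector of along-track positions (mm).
#' @param labels Optional character vector of ids, same length.
#' @return An object of class `row_truth`.
#' @examples
#' row_truth(c(0, 300, 610), labels = c("P1", "P2", "P3"))
#' @export
row_truth <- function(positions, labels = NULL) {
  positions <- as.numeric(positions)
  if (length(positions) && (any(!is.finite(positions)) || any(positions < 0))) {
    rs_invalid("truth positions must be finite and >= 0")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    rs_invalid("truth positions must be strictly increasing")
  }
  if (!is.null(labels) && length(labels) != length(positions)) {
    rs_invalid("labels must match positions in length")
  }
  structure(list(positions = positions, labels = labels), class = "row_truth")
}

#' @export
print.row_truth <- function(x, ...) {
  cat(sprintf("<row_truth> %d positions", length(x$positions)))
  if (length(x$positions) > 1) {
    cat(sprintf(", mean spacing %.1f mm", mean(diff(x$positions))))
  }
  cat("\n")
  invisible(x)
}

#' Per-plant location estimates
#'
#' A set of along-track plant location estimates produced by one of the
#' detection methods.
#'
#' @param location Numeric vector of along-track locations (mm), all >= 0.
#' @param method One of `"beam"`, `"cluster_centre"`, `"lowest_point"`,
#'   `"stem_ground_intersection"`, `"image"`.
#' @param source_ref Optional vector identifying the interval / cluster /
#'   frame set each estimate came from.
#' @return A data.frame of class `plant_estimate` with columns `location`,
#'   `method`, `source_ref`.
#' @export
plant_estimate <- function(location,
                           method = c("beam", "cluster_centre", "lowest_point",
                                      "stem_ground_intersection", "image"),
                           source_ref = NA) {
  method <- match.arg(method)
  location <- as.numeric(location)
  if (length(location) && (any(!is.finite(location)) || any(location < 0))) {
    rs_invalid("estimate locations must be finite and >= 0")
  }
  out <- data.frame(
    location = location,
    method = rep_len(method, length(location)),
    source_ref = rep_len(source_ref, length(location))
  )
  class(out) <- c("plant_estimate", "data.frame")
  out
}

# Accept a plant_estimate data.frame, a plain data.frame with a location-ish
# column, or a bare numeric vector.
estimate_locations <- function(estimates) {
  if (is.numeric(estimates)) return(as.numeric(estimates))
  if (is.data.frame(estimates)) {
    for (col in c("location", "x_mm", "location_mm")) {
      if (col %in% names(estimates)) return(as.numeric(estimates[[col]]))
    }
  }
  rs_invalid("estimates must be numeric or a data.frame with a location column")
}

truth_positions <- function(truth) {
  if (inherits(truth, "row_truth")) return(truth$positions)
  as.numeric(truth)
}

#' Detection accuracy ratio
#'
#' The accuracy statistic used for field detection counts: the smaller of
#' the real and detected plant counts over the larger, as a percentage. It
#' is symmetric in its arguments, penalizing over- and under-detection
#' alike, and lies in (0, 100] for positive counts.
#'
#' @param n_real Number of real plants (> 0).
#' @param n_detected Number of detections (>= 0).
#' @return Unrounded percentage. Round to the nearest integer for reporting.
#' @examples
#' round(detection_accuracy(32, 41)) # 78
#' round(detection_accuracy(34, 32)) # 94
#' @export
detection_accuracy <- function(n_real, n_detected) {
  if (!is.finite(n_real) || n_real <= 0) rs_invalid("n_real must be > 0")
  if (!is.finite(n_detected) || n_detected < 0) rs_invalid("n_detected must be >= 0")
  100 * min(n_real, n_detected) / max(n_real, n_detected)
}

#' Correct-detection rate from matching counts
#'
#' Percentage of real plants that were correctly detected:
#' `100 * n_correct / (n_correct + n_false_negative)`.
#'
#' @param x A `match_report`, or the number of correct detections.
#' @param n_false_negative Number of missed plants (when `x` is a count).
#' @return Unrounded percentage.
#' @export
detection_rate <- function(x, n_false_negative = NULL) {
  if (inherits(x, "match_report")) {
    n_correct <- x$n_correct
    n_false_negative <- x$n_false_negative
  } else {
    n_correct <- x
  }
  n_real <- n_correct + n_false_negative
  if (n_real <= 0) rs_invalid("no real plants: rate undefined")
  100 * n_correct / n_real
}

match_report <- function(n_correct, n_false_positive, n_false_negative, pairs) {
  structure(
    list(
      n_correct = n_correct,
      n_false_positive = n_false_positive,
      n_false_negative = n_false_negative,
      pairs = pairs
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> correct %d, false positive %d, false negative %d\n",
              x$n_correct, x$n_false_positive, x$n_false_negative))
  if (x$n_correct > 0) {
    cat(sprintf("  mean |error| %.1f mm\n", mean(x$pairs$abs_error_mm)))
  }
  invisible(x)
}

#' Match location estimates to ground-truth plants
#'
#' One-to-one matching of estimates to true plant positions. An estimate may
#' only be paired with a truth position within half the nominal plant
#' spacing (the half-spacing rule: anything farther from every real plant is
#' a false positive). Among all one-to-one matchings the one with the
#' maximum number of pairs is chosen, ties broken by the minimum total
#' absolute error; both positions being on a line, an optimal matching is
#' non-crossing, so it is found exactly by dynamic programming over the two
#' sorted sequences.
#'
#' @param estimates A [plant_estimate] data.frame or numeric vector of
#'   locations (mm).
#' @param truth A [row_truth] or numeric vector of true positions (mm).
#' @param spacing Nominal plant spacing (mm), > 0.
#' @return A `match_report`: counts `n_correct`, `n_false_positive`,
#'   `n_false_negative`, and a data.frame `pairs` with `truth_index`,
#'   `estimate_index`, `error_mm` (signed, estimate minus truth) and
#'   `abs_error_mm`.
#' @examples
#' match_detections(c(10, 310, 590), row_truth(c(0, 300, 600)), spacing = 300)
#' @export
match_detections <- function(estimates, truth, spacing) {
  if (!is.finite(spacing) || spacing <= 0) rs_invalid("spacing must be > 0")
  est <- estimate_locations(estimates)
  tru <- truth_positions(truth)
  radius <- spacing / 2

  empty_pairs <- data.frame(truth_index = integer(0), estimate_index = integer(0),
                            error_mm = numeric(0), abs_error_mm = numeric(0))
  if (length(tru) == 0 || length(est) == 0) {
    return(match_report(0L, length(est), length(tru), empty_pairs))
  }

  to <- order(tru); eo <- order(est)
  ts <- tru[to]; es <- est[eo]
  nT <- length(ts); nE <- length(es)

  # dp over (i truths, j estimates): maximize matches, then minimize cost.
  # ptr: 0 = start, 1 = match(i,j), 2 = skip truth i, 3 = skip estimate j.
  cnt <- matrix(0L, nT + 1, nE + 1)
  cost <- matrix(0, nT + 1, nE + 1)
  ptr <- matrix(0L, nT + 1, nE + 1)
  ptr[-1, 1] <- 2L
  ptr[1, -1] <- 3L
  for (i in seq_len(nT)) {
    for (j in seq_len(nE)) {
      bc <- cnt[i, j + 1]; bw <- cost[i, j + 1]; bp <- 2L  # skip truth
      if (cnt[i + 1, j] > bc || (cnt[i + 1, j] == bc && cost[i + 1, j] < bw)) {
        bc <- cnt[i + 1, j]; bw <- cost[i + 1, j]; bp <- 3L  # skip estimate
      }
      d <- abs(es[j] - ts[i])
      if (d <= radius) {
        mc <- cnt[i, j] + 1L; mw <- cost[i, j] + d
        if (mc > bc || (mc == bc && mw < bw)) {
          bc <- mc; bw <- mw; bp <- 1L
        }
      }
      cnt[i + 1, j + 1] <- bc; cost[i + 1, j + 1] <- bw; ptr[i + 1, j + 1] <- bp
    }
  }

  i <- nT; j <- nE
  ti <- integer(0); ei <- integer(0)
  while (i > 0 || j > 0) {
    p <- ptr[i + 1, j + 1]
    if (p == 1L) {
      ti <- c(to[i], ti); ei <- c(eo[j], ei)
      i <- i - 1; j <- j - 1
    } else if (p == 2L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }

  err <- est[ei] - tru[ti]
  pairs <- data.frame(truth_index = ti, estimate_index = ei,
                      error_mm = err, abs_error_mm = abs(err))
  match_report(
    n_correct = length(ti),
    n_false_positive = length(est) - length(ti),
    n_false_negative = length(tru) - length(ti),
    pairs = pairs
  )
}

#' Consecutive spacing series
#'
#' Differences between consecutive sorted positions, the quantity shown in
#' inter-plant spacing histograms.
#'
#' @param positions Sorted numeric vector of positions (mm).
#' @return Numeric vector of length `length(positions) - 1`; empty when
#'   fewer than two positions are supplied.
#' @export
spacing_series <- function(positions) {
  positions <- as.numeric(positions)
  if (length(positions) < 2) return(numeric(0))
  if (is.unsorted(positions)) rs_invalid("positions must be sorted")
  diff(positions)
}

#' Summarize signed location errors of matched detections
#'
#' Matches estimates to truth under the half-spacing rule and reports the
#' mean and standard deviation of the signed errors (estimate minus truth;
#' positive when the estimate lies beyond the plant in the travel
#' direction). The standard deviation uses the sample (n - 1) convention
#' and is reported as 0 for a single matched pair.
#'
#' @inheritParams match_detections
#' @return An object of class `error_summary`: `mean_mm`, `std_mm`, `n`.
#' @export
summarize_error <- function(estimates, truth, spacing) {
  report <- match_detections(estimates, truth, spacing)
  if (report$n_correct == 0) {
    rs_abort("no matched pairs: error summary undefined", "rowsense_no_matches")
  }
  err <- report$pairs$error_mm
  structure(
    list(
      mean_mm = mean(err),
      std_mm = if (length(err) > 1) stats::sd(err) else 0,
      n = length(err)
    ),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d, mean %.1f mm, std %.1f mm\n",
              x$n, x$mean_mm, x$std_mm))
  invisible(x)
}
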