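#' Light-beam / encoder log
#'
#' Time-ordered records of the cumulative encoder pulse count and the
#' binary beam state (1 = beam blocked). Travel must be monotone: reverse
#' motion is rejected, not folded.
#'
#' @param pulse_count Non-decreasing integer vector of cumulative pulses.
#' @param state Vector of 0/1 beam states, same length.
#' @param timestamp_ms Optional timestamps (ms).
#' @return A data.frame of class `beam_log` with columns `timestamp_ms`,
#'   `pulse_count`, `beam_state`.
#' @export
beam_log <- function(pulse_count, state, timestamp_ms = NULL) {
  if (length(pulse_count) != length(state)) {
    rs_invalid("pulse_count and state must have the same length")
  }
  if (length(pulse_count) && any(diff(pulse_count) < 0)) {
    rs_invalid("pulse counts must be non-decreasing (reverse travel rejected)")
  }
  if (!all(state %in% c(0, 1))) rs_invalid("beam state must be 0 or 1")
  if (is.null(timestamp_ms)) timestamp_ms <- rep(NA_real_, length(pulse_count))
  out <- data.frame(timestamp_ms = timestamp_ms,
                    pulse_count = as.numeric(pulse_count),
                    beam_state = as.integer(state))
  class(out) <- c("beam_log", "data.frame")
  out
}

#' Convert encoder pulses to along-track millimetres
#'
#' @param pulse_count Non-negative pulse count(s).
#' @param config A [beam_config()].
#' @return Distance(s) in mm: `pulse_count * pulse_distance_relation`.
#' @examples
#' pulses_to_mm(100, beam_config(1.18, 100)) # 118
#' @export
pulses_to_mm <- function(pulse_count, config) {
  if (any(!is.finite(pulse_count)) || any(pulse_count < 0)) {
    rs_invalid("pulse_count must be >= 0")
  }
  pulse_count * config$pulse_distance_relation
}

#' Extract contiguous beam-blocked intervals
#'
#' Finds every maximal run of blocked samples (state 1) in a beam log and
#' converts it to along-track millimetres: the distance at the start and
#' end of the detection, the distance travelled during it, and the mean
#' distance over the in-run samples, which is taken as the stem location.
#'
#' @param log A [beam_log()].
#' @param config A [beam_config()].
#' @return A data.frame of class `detection_intervals` with columns
#'   `start_mm`, `end_mm`, `length_mm`, `midpoint_mm`.
#' @export
extract_intervals <- function(log, config) {
  empty <- data.frame(start_mm = numeric(0), end_mm = numeric(0),
                      length_mm = numeric(0), midpoint_mm = numeric(0))
  class(empty) <- c("detection_intervals", "data.frame")
  if (nrow(log) == 0) return(empty)
  if (any(diff(log$pulse_count) < 0)) {
    rs_invalid("pulse counts must be non-decreasing (reverse travel rejected)")
  }
  d <- pulses_to_mm(log$pulse_count, config)
  runs <- rle(as.integer(log$beam_state))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- runs$values == 1L
  if (!any(on)) return(empty)
  out <- data.frame(
    start_mm = d[starts[on]],
    end_mm = d[ends[on]],
    length_mm = d[ends[on]] - d[starts[on]],
    midpoint_mm = mapply(function(a, b) mean(d[a:b]), starts[on], ends[on])
  )
  class(out) <- c("detection_intervals", "data.frame")
  out
}

#' Filter out short detections
#'
#' Removes every detection whose along-track length is below the detection
#' filter (default 4 mm), eliminating blips from leaves, weeds and clods.
#'
#' @param intervals A `detection_intervals` data.frame.
#' @param config A [beam_config()].
#' @return The surviving intervals (`length_mm >= detection_filter`).
#' @export
filter_short <- function(intervals, config) {
  keep <- intervals$length_mm >= config$detection_filter
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge detection intervals into plant records
#'
#' Walks the filtered detections in along-track order. The first detection
#' seeds plant 1. Each following candidate is compared to the previous
#' potential plant's location: if it is farther than the expected plant
#' distance (theoretical + 20%), it starts a new plant; otherwise it is
#' merged into that plant and the plant is recomputed, its location becoming
#' the contributing detection midpoint closest to the theoretical midpoint
#' (the location of the plant before it, when one exists, otherwise its own
#' seeding midpoint, plus the theoretical plant distance).
#'
#' @param intervals A `detection_intervals` data.frame sorted by `start_mm`.
#' @param config A [beam_config()].
#' @return A data.frame of class `plant_records` with columns `plant_id`,
#'   `location_mm`, `distance_from_previous_mm`, `n_intervals`, and an
#'   attribute `intervals` listing the contributing interval indices per
#'   plant.
#' @export
merge_to_plants <- function(intervals, config) {
  empty <- data.frame(plant_id = integer(0), location_mm = numeric(0),
                      distance_from_previous_mm = numeric(0),
                      n_intervals = integer(0))
  class(empty) <- c("plant_records", "data.frame")
  attr(empty, "intervals") <- list()
  if (nrow(intervals) == 0) return(empty)
  if (is.unsorted(intervals$start_mm)) {
    rs_invalid("intervals must be sorted by start_mm")
  }

  mids <- intervals$midpoint_mm
  plants <- list(list(members = 1L, location = mids[1], seed = mids[1]))
  for (i in seq_along(mids)[-1]) {
    cur <- plants[[length(plants)]]
    if (mids[i] - cur$location > config$expected_plant_distance) {
      plants[[length(plants) + 1]] <- list(members = i, location = mids[i],
                                           seed = mids[i])
    } else {
      cur$members <- c(cur$members, i)
      anchor <- if (length(plants) > 1) {
        plants[[length(plants) - 1]]$location
      } else {
        cur$seed
      }
      theo_mid <- anchor + config$theoretical_plant_distance
      cand <- mids[cur$members]
      cur$location <- cand[which.min(abs(cand - theo_mid))]
      plants[[length(plants)]] <- cur
    }
  }

  loc <- vapply(plants, `[[`, numeric(1), "location")
  out <- data.frame(
    plant_id = seq_along(plants),
    location_mm = loc,
    distance_from_previous_mm = c(NA_real_, diff(loc)),
    n_intervals = vapply(plants, function(p) length(p$members), integer(1))
  )
  class(out) <- c("plant_records", "data.frame")
  attr(out, "intervals") <- lapply(plants, `[[`, "members")
  out
}

#' Stem diameter estimate from a detection interval
#'
#' The along-track length of a continuous beam interruption is the stem
#' diameter estimate; encoder quantization and the sensor latching one pulse
#' on each side make it an over-estimate by at most two pulse distances.
#'
#' @param interval One or more rows of a `detection_intervals` data.frame.
#' @return Estimated diameter(s) in mm.
#' @export
estimate_diameter <- function(interval) {
  interval$length_mm
}

#' Run the full light-beam detection chain
#'
#' Interval extraction, the short-detection filter, and expected-distance
#' merging in one call.
#'
#' @param log A [beam_log()].
#' @param config A [beam_config()].
#' @return A list of class `beam_detection`: `intervals` (raw),
#'   `detections` (filtered), `plants` (merged records), `estimates`
#'   (a [plant_estimate] of the plant locations), and `config`.
#' @export
detect_beam <- function(log, config) {
  intervals <- extract_intervals(log, config)
  detections <- filter_short(intervals, config)
  plants <- merge_to_plants(detections, config)
  structure(
    list(
      intervals = intervals,
      detections = detections,
      plants = plants,
      estimates = plant_estimate(plants$location_mm, "beam",
                                 source_ref = plants$plant_id),
      config = config
    ),
    class = "beam_detection"
  )
}

#' @export
print.beam_detection <- function(x, ...) {
  cat(sprintf("<beam_detection> %d detections (%d raw), %d plants\n",
              nrow(x$detections), nrow(x$intervals), nrow(x$plants)))
  invisible(x)
}
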