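#' Light-beam detector configuration
#'
#' Parameters of the light-beam + encoder stem detection algorithm. The
#' expected plant distance is always the theoretical inter-plant distance
#' plus a 20% margin; it is derived here and cannot be set independently.
#'
#' @param pulse_distance_relation Millimetres of platform travel per encoder
#'   pulse (1.18 on the laboratory conveyor, 0.98 on the field wheel).
#' @param theoretical_plant_distance Nominal inter-plant distance in mm
#'   (100 in the laboratory, 380 in the field trials).
#' @param detection_filter Minimum along-track length (mm) a continuous
#'   beam interruption must cover to be kept. Default 4 mm.
#' @return An object of class `beam_config`.
#' @examples
#' beam_config(1.18, 100)
#' @export
beam_config <- function(pulse_distance_relation,
                        theoretical_plant_distance,
                        detection_filter = 4) {
  vals <- c(pulse_distance_relation, theoretical_plant_distance, detection_filter)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rs_invalid("all beam_config parameters must be finite and strictly positive")
  }
  structure(
    list(
      pulse_distance_relation = pulse_distance_relation,
      detection_filter = detection_filter,
      theoretical_plant_distance = theoretical_plant_distance,
      expected_plant_distance = theoretical_plant_distance * 1.2
    ),
    class = "beam_config"
  )
}

#' Side-view LiDAR pipeline configuration
#'
#' All thresholds of the LiDAR processing chain in one validated structure.
#' Lengths are in millimetres throughout. The minimum allowed distance
#' between plant cluster centroids is fixed at 0.2 x the theoretical
#' inter-plant spacing.
#'
#' @param theoretical_spacing_mm Nominal inter-plant spacing (240 for the
#'   calibration stick row, 290 for the tomato rows).
#' @param min_range_mm Range gate: polar returns at or below this range are
#'   discarded (50 mm).
#' @param grid_step_mm Edge length of the box-grid downsampling cell (3 mm).
#' @param eval_interval_mm Along-track width of each ground-plane evaluation
#'   interval (80 mm for sticks, 96 mm for tomatoes).
#' @param msac_threshold_mm Inlier distance threshold of the MSAC plane fit
#'   (40 mm).
#' @param reference_vector Required ground-normal direction, default (0,0,1).
#' @param max_angular_distance_deg Maximum angle between a candidate plane
#'   normal and `reference_vector` (5 degrees).
#' @param min_cluster_size Clusters with fewer members are discarded (5).
#' @param histogram_jump_mm Bin width of the stem-line x histogram (4 mm).
#' @param msac_iterations Number of MSAC random samples per interval.
#' @param seed Integer seed for the stochastic stages (MSAC sampling,
#'   k-means++ initialization).
#' @param x_bounds,y_bounds Optional length-2 numeric vectors delimiting the
#'   seedbed in the platform frame; `NULL` disables that delimitation.
#' @return An object of class `lidar_config`.
#' @export
lidar_config <- function(theoretical_spacing_mm,
                         min_range_mm = 50,
                         grid_step_mm = 3,
                         eval_interval_mm = 80,
                         msac_threshold_mm = 40,
                         reference_vector = c(0, 0, 1),
                         max_angular_distance_deg = 5,
                         min_cluster_size = 5,
                         histogram_jump_mm = 4,
                         msac_iterations = 500,
                         seed = 1L,
                         x_bounds = NULL,
                         y_bounds = NULL) {
  lens <- c(theoretical_spacing_mm, min_range_mm, grid_step_mm,
            eval_interval_mm, msac_threshold_mm, histogram_jump_mm)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    rs_invalid("all lidar_config lengths must be finite and strictly positive")
  }
  if (length(reference_vector) != 3 || sum(reference_vector^2) == 0) {
    rs_invalid("reference_vector must be a non-zero length-3 vector")
  }
  for (b in list(x_bounds, y_bounds)) {
    if (!is.null(b) && (length(b) != 2 || b[1] > b[2])) {
      rs_invalid("bounds must be length-2 with lower <= upper")
    }
  }
  structure(
    list(
      theoretical_spacing_mm = theoretical_spacing_mm,
      min_distance_between_plants = 0.2 * theoretical_spacing_mm,
      min_range_mm = min_range_mm,
      grid_step_mm = grid_step_mm,
      eval_interval_mm = eval_interval_mm,
      msac_threshold_mm = msac_threshold_mm,
      reference_vector = reference_vector / sqrt(sum(reference_vector^2)),
      max_angular_distance_deg = max_angular_distance_deg,
      min_cluster_size = min_cluster_size,
      histogram_jump_mm = histogram_jump_mm,
      msac_iterations = msac_iterations,
      seed = as.integer(seed),
      x_bounds = x_bounds,
      y_bounds = y_bounds
    ),
    class = "lidar_config"
  )
}

#' Synthetic row simulation configuration
#'
#' Describes the simulated crop row and sensing platform: a raised seedbed
#' carrying a row of plants (or calibration sticks), scanned laterally by a
#' LiDAR while a ground-wheel encoder provides along-track odometry, with a
#' low light-beam crossing the stems and a side-view camera taking frames at
#' fixed time intervals.
#'
#' Defaults follow the field platform: 0.36 m/s travel, 50-Hz scans at 0.5
#' degree resolution, 195-mm plant stems, 300-mm nominal spacing. The
#' laboratory light-beam setting differs mainly in `pulse_mm` (1.18) and
#' `spacing_mm` (100).
#'
#' @param n_plants Number of plants (or sticks) in the row.
#' @param spacing_mm Nominal inter-plant spacing in mm.
#' @param spacing_jitter_mm Standard deviation of the Gaussian spacing
#'   jitter; transplanting was intentionally non-uniform.
#' @param shape `"tomato"` (stem + foliage shell) or `"stick"` (bare
#'   cylinder, zero foliage points).
#' @param stem_height_mm,stem_diameter_mm Stem cylinder dimensions
#'   (tomato defaults 195 / 10 mm).
#' @param stick_height_mm,stick_diameter_mm Stick cylinder dimensions.
#' @param foliage_radius_mm,foliage_height_mm Horizontal and vertical
#'   semi-axes of the ellipsoidal foliage shell (tomato only).
#' @param foliage_lean_mm Along-track offset of the foliage centre from the
#'   stem base; non-zero values make the canopy and the stem disagree, which
#'   is what separates the three LiDAR location methods.
#' @param speed_mm_s Platform speed (360 mm/s).
#' @param scan_hz LiDAR scan frequency (50 Hz).
#' @param angular_res_deg LiDAR angular resolution (0.5 degrees).
#' @param fov_deg Length-2 simulated angular sector of the scan plane in
#'   degrees; 0 points horizontally away from the sensor, positive angles
#'   point downward toward the bed.
#' @param pulse_mm Encoder pulse distance relation, mm per pulse
#'   (0.98 field, 1.18 laboratory).
#' @param beam_height_mm Height of the light-beam above the bed top (40 mm
#'   laboratory geometry).
#' @param noise_mm Standard deviation of the Gaussian LiDAR range noise.
#' @param sensor_height_mm Sensor height above the furrow floor.
#' @param sensor_offset_mm Lateral distance from the sensor to the row
#'   centreline.
#' @param bed_height_mm,bed_width_mm Raised seedbed dimensions.
#' @param bed_tilt Along-track slope of the bed top (dimensionless dz/dx),
#'   small but non-zero so per-interval plane fitting is non-trivial.
#' @param row_margin_mm Travel before the first and after the last plant.
#' @param missing_prob Probability that a planned plant is missing.
#' @param weed_prob Per-gap probability of a short spurious beam blip.
#' @param frame_interval_s Camera shooting interval (1 s).
#' @param mm_per_px True image scale of the simulated side-view camera.
#' @param frame_width_px Simulated frame width in pixels.
#' @param seed Integer RNG seed; every generator derives its stream from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_plants = 20,
                       spacing_mm = 300,
                       spacing_jitter_mm = 10,
                       shape = c("tomato", "stick"),
                       stem_height_mm = 195,
                       stem_diameter_mm = 10,
                       stick_height_mm = 250,
                       stick_diameter_mm = 12,
                       foliage_radius_mm = 60,
                       foliage_height_mm = 45,
                       foliage_lean_mm = 0,
                       speed_mm_s = 360,
                       scan_hz = 50,
                       angular_res_deg = 0.5,
                       fov_deg = c(-5, 60),
                       pulse_mm = 0.98,
                       beam_height_mm = 40,
                       noise_mm = 5,
                       sensor_height_mm = 800,
                       sensor_offset_mm = 800,
                       bed_height_mm = 200,
                       bed_width_mm = 400,
                       bed_tilt = 0.005,
                       row_margin_mm = 300,
                       missing_prob = 0,
                       weed_prob = 0,
                       frame_interval_s = 1,
                       mm_per_px = 0.75,
                       frame_width_px = 1920,
                       seed = 1L) {
  shape <- match.arg(shape)
  pos_fields <- c(spacing_mm, stem_height_mm, stem_diameter_mm,
                  stick_height_mm, stick_diameter_mm, speed_mm_s, scan_hz,
                  angular_res_deg, pulse_mm, sensor_height_mm,
                  sensor_offset_mm, bed_width_mm, frame_interval_s,
                  mm_per_px, frame_width_px)
  if (any(!is.finite(pos_fields)) || any(pos_fields <= 0)) {
    rs_invalid("sim_config rates and lengths must be strictly positive")
  }
  if (!is.finite(n_plants) || n_plants < 0) rs_invalid("n_plants must be >= 0")
  probs <- c(missing_prob, weed_prob)
  if (any(probs < 0 | probs > 1)) {
    rs_invalid("probabilities must lie in [0, 1]")
  }
  cfg <- as.list(environment())
  cfg$pos_fields <- NULL
  cfg$probs <- NULL
  structure(cfg, class = "sim_config")
}

#' Read or write a flat JSON configuration file
#'
#' Configuration files are flat key/value JSON documents whose keys match
#' the arguments of [beam_config()], [lidar_config()] and [sim_config()].
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path File path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) rs_invalid(paste0("config file not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) rs_invalid("config file must contain a JSON object")
  cfg
}

#' @rdname read_config
#' @param config Named list of configuration values.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Build a constructor call from a flat config list, using only the keys the
# constructor knows, and complaining about unknown keys w.r.t. all three.
config_from_list <- function(cfg, constructor) {
  known <- names(formals(constructor))
  use <- cfg[intersect(names(cfg), known)]
  do.call(constructor, use)
}
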