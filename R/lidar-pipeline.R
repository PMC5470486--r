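#' Run the full side-view LiDAR plant-localization pipeline
#'
#' Applies the complete processing chain to a set of side-view scans:
#' \enumerate{
#'   \item per-scan polar-to-Cartesian conversion with the 50-mm range gate;
#'   \item transformation to the platform frame with the side-view pose
#'     (roll 0, pitch -180, yaw 0) and the encoder x translation;
#'   \item height normalization (subtract the minimum z);
#'   \item manual seedbed delimitation (when bounds are configured);
#'   \item box-grid downsampling;
#'   \item MSAC ground-plane removal per evaluation interval;
#'   \item k-means clustering with cluster-count reduction and minimum
#'     cluster size;
#'   \item the three per-cluster location methods (cluster centre, lowest
#'     point, stem/ground-line intersection).
#' }
#'
#' The RNG is seeded from `config$seed`, making the MSAC sampling and
#' k-means initialization reproducible.
#'
#' @param scans A [scan_set()].
#' @param config A [lidar_config()].
#' @return A list of class `lidar_result`: `estimates` (data.frame
#'   `method`, `plant_id`, `x_mm`, sorted by x within method), `clusters`,
#'   `ground_model`, and `diagnostics` (point counts after each stage plus
#'   the travelled distance and initial k).
#' @export
run_lidar_pipeline <- function(scans, config) {
  if (!inherits(scans, "scan_set")) {
    rs_invalid("scans must be a scan_set")
  }
  set.seed(config$seed)
  empty_est <- data.frame(method = character(0), plant_id = integer(0),
                          x_mm = numeric(0))
  if (nrow(scans) == 0) {
    return(structure(list(estimates = empty_est,
                          clusters = structure(list(), class = "plant_clusters"),
                          ground_model = NULL,
                          diagnostics = list(n_raw = 0L)),
                     class = "lidar_result"))
  }

  parts <- split(scans, scans$scan_id)
  clouds <- lapply(parts, function(sc) {
    pts <- polar_to_cartesian(sc$angle_deg, sc$range_mm, config)
    apply_pose(pts, pose(0, -180, 0, sc$encoder_mm[1]))
  })
  cloud <- do.call(rbind, clouds)
  diag <- list(n_raw = nrow(scans), n_range_gated = nrow(cloud))

  cloud <- normalize_heights(cloud)
  cloud <- delimit_seedbed(cloud, config$x_bounds, config$y_bounds)
  diag$n_delimited <- nrow(cloud)
  cloud <- grid_downsample(cloud, config)
  diag$n_gridded <- nrow(cloud)

  extraction <- extract_aerial(cloud, config)
  aerial <- extraction$aerial
  diag$n_aerial <- nrow(aerial)

  enc <- vapply(parts, function(sc) sc$encoder_mm[1], numeric(1))
  travelled <- diff(range(enc))
  diag$travelled_mm <- travelled
  if (nrow(aerial) == 0) {
    return(structure(list(estimates = empty_est,
                          clusters = structure(list(), class = "plant_clusters"),
                          ground_model = extraction$ground_model,
                          diagnostics = diag),
                     class = "lidar_result"))
  }

  k0 <- initial_k(travelled, config$theoretical_spacing_mm)
  diag$initial_k <- k0
  clusters <- cluster_plants(aerial, k0, config)
  diag$n_clusters <- length(clusters)

  locate <- list(
    cluster_centre = function(cl) locate_centre(cl),
    lowest_point = function(cl) locate_lowest(cl),
    stem_ground_intersection = function(cl) {
      locate_stem_intersection(cl, extraction$ground_model, config)
    }
  )
  est <- do.call(rbind, lapply(names(locate), function(method) {
    x <- vapply(clusters, locate[[method]], numeric(1))
    if (length(x) == 0) return(NULL)
    ord <- order(x)
    data.frame(method = method, plant_id = seq_along(x), x_mm = x[ord])
  }))
  if (is.null(est)) est <- empty_est

  structure(
    list(estimates = est, clusters = clusters,
         ground_model = extraction$ground_model, diagnostics = diag),
    class = "lidar_result"
  )
}

#' @export
print.lidar_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<lidar_result>\n")
  for (nm in names(d)) cat(sprintf("  %s: %s\n", nm, format(d[[nm]])))
  invisible(x)
}

#' Estimates of one location method from a pipeline result
#'
#' @param result A `lidar_result`.
#' @param method One of `"cluster_centre"`, `"lowest_point"`,
#'   `"stem_ground_intersection"`.
#' @return A [plant_estimate] data.frame.
#' @export
lidar_estimates <- function(result,
                            method = c("cluster_centre", "lowest_point",
                                       "stem_ground_intersection")) {
  method <- match.arg(method)
  sub <- result$estimates[result$estimates$method == method, , drop = FALSE]
  plant_estimate(sub$x_mm, method, source_ref = sub$plant_id)
}
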