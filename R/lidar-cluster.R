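# k-means plant clustering with cluster-count reduction, and the three
# per-cluster plant location methods.

#' Initial cluster count for plant clustering
#'
#' `floor((travelled / theoretical) + 1) * 2`: deliberately about twice the
#' number of plants that fit in the travelled distance, leaving the
#' reduction loop to find the true count.
#'
#' @param travelled_mm Distance travelled along the row (mm), > 0.
#' @param theoretical_mm Theoretical inter-plant distance (mm), > 0.
#' @return Integer initial k.
#' @examples
#' initial_k(10000, 290) # 70
#' @export
initial_k <- function(travelled_mm, theoretical_mm) {
  if (!is.finite(travelled_mm) || travelled_mm <= 0 ||
      !is.finite(theoretical_mm) || theoretical_mm <= 0) {
    rs_invalid("travelled and theoretical distances must be > 0")
  }
  as.integer(floor((travelled_mm / theoretical_mm) + 1) * 2)
}

# k-means++ seeding: first centre uniform, each next centre drawn with
# probability proportional to the squared distance to the nearest centre
# already chosen. Uses the current RNG stream.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      centers[i, ] <- x[sample.int(n, 1), ]
    } else {
      centers[i, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  centers
}

# One clustering round at a given k: five replicates of Lloyd k-means, each
# seeded by k-means++, keeping the lowest-cost solution; an optional extra
# starting-centre matrix (the warm start carried through the reduction
# loop) competes on the same footing. Empty clusters are dropped, so fewer
# than k clusters may come back.
cluster_round <- function(x, k, warm_centers = NULL, replicates = 5) {
  starts <- lapply(seq_len(replicates), function(i) kmeanspp_centers(x, k))
  if (!is.null(warm_centers)) starts <- c(list(warm_centers), starts)
  best <- NULL
  best_cost <- Inf
  for (centers in starts) {
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
    keep <- fit$size > 0
    if (!any(keep)) next
    cost <- sum(fit$withinss[keep])
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(centers = fit$centers[keep, , drop = FALSE],
                   sizes = fit$size[keep],
                   assign = match(fit$cluster, which(keep)))
    }
  }
  best
}

# Merge the pair of centres closest along-track into their size-weighted
# mean, giving the warm start for the next (k - 1) round.
merge_closest_centers <- function(centers, sizes) {
  ord <- order(centers[, 1])
  gaps <- diff(centers[ord, 1])
  i <- ord[which.min(gaps)]
  j <- ord[which.min(gaps) + 1]
  w <- sizes[c(i, j)] / sum(sizes[c(i, j)])
  merged <- w[1] * centers[i, ] + w[2] * centers[j, ]
  rbind(centers[-c(i, j), , drop = FALSE], merged)
}

#' Cluster aerial points into individual plants
#'
#' k-means (squared-Euclidean, k-means++ initialization, five replicates
#' keeping the lowest-cost solution) on the 3-D aerial points, wrapped in a
#' cluster-count reduction loop: while any pair of cluster centroids is
#' closer along-track than the minimum distance between plants (0.2 x
#' theoretical spacing), k is reduced by one and the clustering repeated,
#' warm-starting from the previous centroids with the offending closest
#' pair merged (Lloyd iterations cannot move a centroid across the empty
#' space between plants, so a fresh reseed alone tends to re-split one
#' plant while merging two others). Finally, clusters smaller than the
#' minimum cluster size are excluded.
#'
#' @param aerial n x 3 matrix of aerial points.
#' @param k Initial cluster count, normally from [initial_k()].
#' @param config A [lidar_config()].
#' @return A list of class `plant_clusters`; each element has `id`,
#'   `points` (members), `centroid`, `size`. Empty (with a warning) when k
#'   is driven to zero.
#' @export
cluster_plants <- function(aerial, k, config) {
  aerial <- as_cloud(aerial)
  if (nrow(aerial) == 0) rs_invalid("aerial cloud is empty")
  k <- min(as.integer(k), nrow(aerial))
  if (k < 1) rs_invalid("k must be >= 1")

  fit <- NULL
  warm <- NULL
  while (k >= 1) {
    fit <- cluster_round(aerial, k, warm_centers = warm)
    if (is.null(fit)) {
      k <- k - 1L
      warm <- NULL
      next
    }
    cx <- sort(fit$centers[, 1])
    if (nrow(fit$centers) >= 2 && min(diff(cx)) < config$min_distance_between_plants) {
      warm <- merge_closest_centers(fit$centers, fit$sizes)
      k <- k - 1L
      fit <- NULL
    } else {
      break
    }
  }
  if (is.null(fit)) {
    warning("cluster count reduced to zero; no plants found", call. = FALSE)
    return(structure(list(), class = "plant_clusters"))
  }

  ord <- order(fit$centers[, 1])
  clusters <- list()
  for (ci in ord) {
    members <- aerial[fit$assign == ci, , drop = FALSE]
    if (nrow(members) < config$min_cluster_size) next
    clusters[[length(clusters) + 1L]] <- list(
      id = length(clusters) + 1L,
      points = members,
      centroid = colMeans(members),
      size = nrow(members)
    )
  }
  structure(clusters, class = "plant_clusters")
}

#' @export
print.plant_clusters <- function(x, ...) {
  cat(sprintf("<plant_clusters> %d clusters, sizes: %s\n", length(x),
              paste(vapply(x, `[[`, integer(1), "size"), collapse = " ")))
  invisible(x)
}

#' Plant location: centre of the cluster
#'
#' @param cluster One element of a `plant_clusters` list.
#' @return Along-track location (mm): the centroid x.
#' @export
locate_centre <- function(cluster) {
  unname(cluster$centroid[1])
}

#' Plant location: lowest point of the cluster
#'
#' @param cluster One element of a `plant_clusters` list.
#' @return Along-track location (mm): the x of the member with minimum z;
#'   ties resolved to the smallest x.
#' @export
locate_lowest <- function(cluster) {
  p <- cluster$points
  i <- which(p[, 3] == min(p[, 3]))
  min(p[i, 1])
}

#' Plant location: intersection of the stem line and the ground line
#'
#' Isolates the stem by slicing the cluster's x values into histogram bins
#' (the histogram-jump width), keeping the bin with the maximal count
#' (adjacent tied bins are merged), and further restricting to the bottom
#' half of the cluster's z range. The stem line is a least-squares line
#' through the surviving points, parameterized as x on z, which stays
#' well-conditioned for the near-vertical structures stems are; the
#' returned location is the x where it meets the interval's ground line.
#' A degenerate point set (x spread below 1 mm) uses x = median(x)
#' directly.
#'
#' Falls back to [locate_lowest()] with a warning when fewer than two
#' points survive, when no ground line exists, or when the stem line is
#' parallel to the ground line.
#'
#' @param cluster One element of a `plant_clusters` list.
#' @param ground_model The `ground_model` data.frame from [extract_aerial()].
#' @param config A [lidar_config()].
#' @return Along-track location (mm).
#' @export
locate_stem_intersection <- function(cluster, ground_model, config) {
  p <- cluster$points
  fallback <- function(why) {
    warning(sprintf("stem intersection fell back to lowest point (%s)", why),
            call. = FALSE)
    locate_lowest(cluster)
  }

  jump <- config$histogram_jump_mm
  breaks <- seq(floor(min(p[, 1])), max(p[, 1]) + jump, by = jump)
  counts <- graphics::hist(p[, 1], breaks = breaks, plot = FALSE)$counts
  top <- which(counts == max(counts))
  # merge the adjacent run of tied maximal bins containing the first maximum
  run_end <- top[1]
  while ((run_end + 1) %in% top) run_end <- run_end + 1
  x_lim <- c(breaks[top[1]], breaks[run_end + 1])

  z_cut <- min(p[, 3]) + (max(p[, 3]) - min(p[, 3])) / 2
  sel <- p[, 1] >= x_lim[1] & p[, 1] <= x_lim[2] & p[, 3] <= z_cut
  if (sum(sel) < 2) return(fallback("fewer than two stem points"))
  sp <- p[sel, , drop = FALSE]

  if (max(sp[, 1]) - min(sp[, 1]) < 1) {
    return(stats::median(sp[, 1]))
  }
  line <- ground_line_at(ground_model, unname(cluster$centroid[1]))
  if (is.null(line)) return(fallback("no ground line"))
  if (max(sp[, 3]) - min(sp[, 3]) < 1e-9) {
    return(fallback("stem line parallel to ground line"))
  }
  # stem line as x = m z + c; intersect with ground line z = a x + b
  fit <- stats::lm.fit(cbind(1, sp[, 3]), sp[, 1])
  m <- fit$coefficients[2]; c0 <- fit$coefficients[1]
  if (!is.finite(m) || abs(1 - m * line$a) < 1e-9) {
    return(fallback("stem line parallel to ground line"))
  }
  unname((m * line$b + c0) / (1 - m * line$a))
}
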