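# Delimited-text and point-cloud input/output. All CSV formats are plain
# comma-separated files with a header row; clouds are PLY (ascii or
# binary_little_endian, double precision) or 3-column XYZ text.

#' Read and write light-beam logs
#'
#' CSV columns: `timestamp_ms,pulse_count,beam_state`.
#'
#' @param path File path.
#' @return `read_beam_log()` returns a [beam_log()].
#' @export
read_beam_log <- function(path) {
  df <- read_checked(path, c("timestamp_ms", "pulse_count", "beam_state"))
  beam_log(df$pulse_count, df$beam_state, df$timestamp_ms)
}

#' @rdname read_beam_log
#' @param log A [beam_log()].
#' @export
write_beam_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write LiDAR scan logs
#'
#' Long-format CSV, one row per beam:
#' `scan_id,timestamp_ms,encoder_mm,angle_deg,range_mm`.
#'
#' @param path File path.
#' @return `read_scan_log()` returns a [scan_set()].
#' @export
read_scan_log <- function(path) {
  df <- read_checked(path, c("scan_id", "timestamp_ms", "encoder_mm",
                             "angle_deg", "range_mm"))
  scan_set(df$scan_id, df$timestamp_ms, df$encoder_mm, df$angle_deg, df$range_mm)
}

#' @rdname read_scan_log
#' @param scans A [scan_set()].
#' @export
write_scan_log <- function(scans, path) {
  utils::write.csv(as.data.frame(scans), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ground-truth rows
#'
#' Two-column CSV: `id,position_mm`.
#'
#' @param path File path.
#' @return `read_truth()` returns a [row_truth()].
#' @export
read_truth <- function(path) {
  df <- read_checked(path, c("id", "position_mm"))
  row_truth(df$position_mm, as.character(df$id))
}

#' @rdname read_truth
#' @param truth A [row_truth()].
#' @export
write_truth <- function(truth, path) {
  ids <- truth$labels
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(truth$positions))
  utils::write.csv(data.frame(id = ids, position_mm = truth$positions),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write plant location estimates
#'
#' CSV columns: `method,plant_id,x_mm`; several methods may share a file.
#'
#' @param path File path.
#' @return `read_estimates()` returns a data.frame with those columns.
#' @export
read_estimates <- function(path) {
  read_checked(path, c("method", "plant_id", "x_mm"))
}

#' @rdname read_estimates
#' @param estimates Data.frame with columns `method`, `plant_id`, `x_mm`.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates[, c("method", "plant_id", "x_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write frame metadata
#'
#' CSV columns: `frame_id,timestamp_ms,encoder_mm,stem_offset_px`; a frame
#' may contribute several rows (one per observed stem) and an empty frame
#' one row with an empty offset.
#'
#' @param path File path.
#' @return `read_frames()` returns a `frame_meta` data.frame.
#' @export
read_frames <- function(path) {
  df <- read_checked(path, c("frame_id", "timestamp_ms", "encoder_mm",
                             "stem_offset_px"))
  class(df) <- c("frame_meta", "data.frame")
  df
}

#' @rdname read_frames
#' @param frames A `frame_meta` data.frame.
#' @export
write_frames <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked <- function(path, columns) {
  if (!file.exists(path)) rs_invalid(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) rs_invalid(paste0("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  )
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    rs_invalid(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[setdiff(columns, "stem_offset_px")]))
  if (length(bad)) {
    rs_invalid(paste0(path, ": malformed row(s) at line(s) ",
                      paste(utils::head(bad + 1, 5), collapse = ", ")))
  }
  df
}

#' Write a point cloud as PLY
#'
#' Writes x/y/z as double-precision properties, either as ascii or as
#' binary_little_endian.
#'
#' @param cloud n x 3 matrix (mm).
#' @param path Output path.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @export
write_ply <- function(cloud, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  cloud <- as_cloud(cloud)
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    paste("element vertex", nrow(cloud)),
    "property double x",
    "property double y",
    "property double z",
    "end_header"
  )
  if (format == "ascii") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(cloud)) {
      writeLines(apply(cloud, 1, function(p) {
        paste(format(p, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = " ")
      }), con)
    }
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(cloud)) {
      writeBin(as.vector(t(cloud)), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY point cloud
#'
#' Supports ascii and binary_little_endian files whose vertex element
#' carries float or double x/y/z as its leading properties.
#'
#' @param path File path.
#' @return n x 3 matrix.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) rs_invalid(paste0("file not found: ", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) rs_invalid("truncated PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") rs_invalid("not a PLY file")
  fmt <- strsplit(grep("^format ", header, value = TRUE)[1], " ")[[1]][2]
  nv <- as.integer(strsplit(grep("^element vertex", header, value = TRUE)[1], " ")[[1]][3])
  props <- strsplit(grep("^property ", header, value = TRUE), " ")
  types <- vapply(props, `[`, character(1), 2)
  names_ <- vapply(props, `[`, character(1), 3)
  if (!all(c("x", "y", "z") %in% names_)) rs_invalid("PLY lacks x/y/z properties")
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (any(is.na(sizes[types]))) rs_invalid("unsupported PLY property type")

  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = nv * length(types), quiet = TRUE)
    m <- matrix(vals, ncol = length(types), byrow = TRUE)
  } else if (fmt == "binary_little_endian") {
    if (length(unique(sizes[types])) != 1) rs_invalid("mixed property sizes unsupported")
    sz <- sizes[types][1]
    vals <- readBin(con, what = "double", n = nv * length(types),
                    size = sz, endian = "little")
    m <- matrix(vals, ncol = length(types), byrow = TRUE)
  } else {
    rs_invalid(paste0("unsupported PLY format: ", fmt))
  }
  out <- m[, match(c("x", "y", "z"), names_), drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Read and write XYZ point-cloud text
#'
#' Three whitespace-separated columns, no header.
#'
#' @param path File path.
#' @return `read_xyz()` returns an n x 3 matrix.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) rs_invalid(paste0("file not found: ", path))
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  as_cloud(m)
}

#' @rdname read_xyz
#' @param cloud n x 3 matrix.
#' @export
write_xyz <- function(cloud, path) {
  cloud <- as_cloud(cloud)
  utils::write.table(format(cloud, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
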