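# Coordinate convention used throughout: listener frame with x forward
# (toward 0 degrees azimuth), y to the right, z up. Azimuth is positive to
# the right, elevation positive upward; both in degrees on every public
# surface (radians are internal only).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to the interval (-180, 180]
#'
#' The tie at exactly +/-180 degrees resolves to +180.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles in degrees.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

#' Build the 27-loudspeaker frontal array
#'
#' Thirteen sources at ear level (0 degrees elevation) from -90 to +90
#' degrees azimuth in 15 degree steps, and seven each at +28 and -28 degrees
#' elevation from -90 to +90 in 30 degree steps. Loudspeakers are numbered
#' 1..13 in azimuth starting at -90 (left); the elevated rows share the
#' numbers of the ear-level loudspeakers at the same azimuth, hence carry
#' only odd numbers. Rows are color coded by elevation.
#'
#' @param radius Source distance from the listening position in meters.
#' @param color_map Named character vector mapping elevations (as names
#'   "28", "0", "-28") to colors. The row-to-color assignment is a setup
#'   convention, not a physical property, and can be overridden.
#' @return A data.frame with columns \code{azimuth_deg}, \code{elevation_deg},
#'   \code{radius_m}, \code{color}, \code{number}.
#' @examples
#' arr <- build_source_array()
#' nrow(arr)                         # 27
#' table(arr$elevation_deg)          # 7 / 13 / 7
#' @export
build_source_array <- function(radius = 2.4,
                               color_map = c("28" = "yellow",
                                             "0" = "red",
                                             "-28" = "blue")) {
  stopifnot(radius > 0)
  rows <- list(
    data.frame(azimuth_deg = seq(-90, 90, by = 15), elevation_deg = 0),
    data.frame(azimuth_deg = seq(-90, 90, by = 30), elevation_deg = 28),
    data.frame(azimuth_deg = seq(-90, 90, by = 30), elevation_deg = -28)
  )
  arr <- do.call(rbind, rows)
  arr$radius_m <- radius
  arr$color <- unname(color_map[as.character(arr$elevation_deg)])
  arr$number <- 1L + as.integer(round((arr$azimuth_deg + 90) / 15))
  arr <- arr[order(arr$elevation_deg, arr$azimuth_deg), ]
  rownames(arr) <- NULL
  arr
}

#' Label an array source position
#'
#' @param azimuth,elevation Position in degrees; must be one of the 27 array
#'   positions.
#' @inheritParams build_source_array
#' @return A list with elements \code{color} and \code{number}.
#' @examples
#' label_source(-90, 0)   # number 1
#' label_source(0, 0)     # number 7
#' @export
label_source <- function(azimuth, elevation,
                         color_map = c("28" = "yellow",
                                       "0" = "red",
                                       "-28" = "blue")) {
  arr <- build_source_array(color_map = color_map)
  hit <- arr$azimuth_deg == azimuth & arr$elevation_deg == elevation
  if (!any(hit)) {
    stop(sprintf(
      "(%g, %g) is not an array position: elevation must be 0 (azimuth in 15 deg steps) or +/-28 (30 deg steps), azimuth in [-90, 90]",
      azimuth, elevation
    ))
  }
  list(color = arr$color[hit], number = arr$number[hit])
}

#' Convert a Cartesian direction to azimuth/elevation
#'
#' @param v Numeric length-3 vector (x forward, y right, z up); need not be
#'   normalized but must be nonzero.
#' @return Named numeric vector \code{c(azimuth, elevation)} in degrees.
#'   At the poles (|elevation| = 90) azimuth is defined as 0.
#' @export
direction_to_azel <- function(v) {
  stopifnot(length(v) == 3)
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("zero vector has no direction")
  el <- rad2deg(asin(max(-1, min(1, v[3] / n))))
  az <- if (abs(v[1]) < 1e-300 && abs(v[2]) < 1e-300) 0 else rad2deg(atan2(v[2], v[1]))
  c(azimuth = az, elevation = el)
}

#' Convert azimuth/elevation to a unit Cartesian direction
#'
#' @param azimuth,elevation Angles in degrees.
#' @return Unit length-3 numeric vector (x forward, y right, z up).
#' @export
azel_to_direction <- function(azimuth, elevation) {
  a <- deg2rad(azimuth)
  e <- deg2rad(elevation)
  c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

#' Signed pointing errors
#'
#' Azimuth error is response minus target wrapped to (-180, 180] (tie at the
#' boundary resolves to +180); elevation error is the plain difference.
#' Positive errors are rightward/upward.
#'
#' @param target_azimuth,target_elevation Target direction, degrees.
#' @param response_azimuth,response_elevation Response direction, degrees.
#' @return A data.frame with columns \code{azimuth_error} and
#'   \code{elevation_error} (degrees); vectorized over all arguments.
#' @export
signed_errors <- function(target_azimuth, target_elevation,
                          response_azimuth, response_elevation) {
  data.frame(
    azimuth_error = wrap_angle(response_azimuth - target_azimuth),
    elevation_error = response_elevation - target_elevation
  )
}

#' Export the source array
#'
#' @param arr Array as returned by [build_source_array()].
#' @param path Output file; format chosen by extension (.csv or .json).
#' @return \code{path}, invisibly.
#' @export
write_source_array <- function(arr, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(arr, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(arr, path, row.names = FALSE)
  }
  invisible(path)
}
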