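# Landmark perception: bearings and the recognition-distance annulus.

#' Bearing from the vehicle to a landmark
#'
#' Bearings are measured clockwise from north (the +y axis), in degrees in
#' \[0, 360). North is the absolute reference direction: an observer-fixed
#' reference (such as the running direction) would make the same physical
#' scene yield different place codes at different times.
#'
#' @param vehicle numeric length-2 vehicle position `(x, y)`.
#' @param landmark landmark position: a numeric length-2 vector, or a
#'   two-column matrix / data.frame with one row per landmark.
#' @return Bearing(s) in degrees, one per landmark.
#' @examples
#' bearing_to(c(0, 0), c(0, 1))    # 0   (due north)
#' bearing_to(c(0, 0), c(1, 0))    # 90  (due east)
#' bearing_to(c(0, 0), c(-1, -1))  # 225
#' @export
bearing_to <- function(vehicle, landmark) {
  if (is.data.frame(landmark)) landmark <- as.matrix(landmark)
  if (!is.matrix(landmark)) landmark <- matrix(landmark, ncol = 2)
  dx <- landmark[, 1] - vehicle[1]
  dy <- landmark[, 2] - vehicle[2]
  if (any(dx == 0 & dy == 0)) {
    stop("bearing undefined: landmark coincides with the vehicle",
         call. = FALSE)
  }
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' Perceive landmarks inside the recognition-distance annulus
#'
#' Builds the current place code: the set of landmarks whose Euclidean
#' distance from the vehicle lies in the closed interval
#' \[`d_min`, `d_max`\], each represented by its recognition label,
#' saliency, bearing from north and distance. The annulus stands in for a
#' visual recognition range; an empty place code (no landmark in range) is
#' a valid result.
#'
#' @param vehicle numeric length-2 vehicle position.
#' @param field a `landmark_field`.
#' @param d_min,d_max annulus bounds in metres, `0 <= d_min < d_max`. The
#'   baseline recognition distance is 10 m to 15 m.
#' @param step time-step index recorded with the code (default `NA`).
#' @return A `place_code`: a list with parallel vectors `id`, `saliency`,
#'   `bearing`, `distance`, plus `step` and `n` (the number of perceived
#'   landmarks).
#' @examples
#' fld <- generate_landmark_field(arena(), n = 100, seed = 7)
#' pc <- perceive(c(20, 20), fld, 10, 15)
#' pc$n
#' @export
perceive <- function(vehicle, field, d_min = 10, d_max = 15, step = NA_integer_) {
  d_min <- check_number(d_min, "d_min", lower = 0)
  d_max <- check_number(d_max, "d_max", lower = 0)
  if (d_min >= d_max) stop("`d_min` must be < `d_max`", call. = FALSE)
  dx <- field$x - vehicle[1]
  dy <- field$y - vehicle[2]
  dist <- sqrt(dx^2 + dy^2)
  keep <- which(dist >= d_min & dist <= d_max)
  new_place_code(
    id = as.integer(field$id[keep]),
    saliency = field$saliency[keep],
    bearing = if (length(keep)) (atan2(dx[keep], dy[keep]) * 180 / pi) %% 360
              else numeric(0),
    distance = dist[keep],
    step = step
  )
}

#' Construct a place code directly
#'
#' Mostly useful for tests and for supplying place codes from an external
#' perception provider; [perceive()] is the usual constructor.
#'
#' @param id integer recognition labels (unique).
#' @param saliency positive saliencies, one per landmark.
#' @param bearing bearings in degrees (wrapped into \[0, 360)).
#' @param distance distances in metres (>= 0).
#' @param step time-step index.
#' @return A `place_code`.
#' @export
new_place_code <- function(id = integer(0), saliency = numeric(0),
                           bearing = numeric(0), distance = numeric(0),
                           step = NA_integer_) {
  n <- length(id)
  stopifnot(length(saliency) == n, length(bearing) == n, length(distance) == n)
  if (anyDuplicated(id)) {
    stop("place code ids must be unique", call. = FALSE)
  }
  structure(list(id = as.integer(id), saliency = as.numeric(saliency),
                 bearing = norm_heading(as.numeric(bearing)),
                 distance = as.numeric(distance),
                 step = step, n = n),
            class = "place_code")
}

#' @export
print.place_code <- function(x, ...) {
  cat(sprintf("<place code: %d landmark(s) at step %s>\n", x$n,
              format(x$step)))
  if (x$n > 0) {
    print(data.frame(id = x$id, saliency = x$saliency,
                     bearing_deg = x$bearing, distance_m = x$distance))
  }
  invisible(x)
}

#' @export
length.place_code <- function(x) x$n
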