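#' Feature-space geometry
#'
#' The conceptual feature space is the unit square \eqn{[0,1] \times [0,1]}:
#' axis 1 (x) is the length of the molecule's upper bond, axis 2 (y) the
#' length of its lower bond. Each colour context ("blue", "green") hides one
#' goal configuration, a point in this square. Quadrants are delimited by the
#' axis midlines: Q1 = (low x, low y), Q2 = (high x, low y), Q3 = (low x,
#' high y), Q4 = (high x, high y), so the blue goal (long upper / short lower
#' bond) sits in Q2 and the green goal in Q3, and the two goals are images of
#' each other under a 180-degree rotation of the space about its centre.
#'
#' @param context character vector of contexts, `"blue"` or `"green"`.
#' @return `goal_position()`: a matrix with one `(x, y)` row per context.
#' @examples
#' goal_position("blue")
#' @export
goal_position <- function(context) {
  stopifnot(all(context %in% c("blue", "green")))
  xy <- cbind(
    x = ifelse(context == "blue", 0.75, 0.25),
    y = ifelse(context == "blue", 0.25, 0.75)
  )
  rownames(xy) <- context
  xy
}

#' Wrap an angle into [0, 360)
#' @param theta angle(s) in degrees.
#' @return angle(s) in `[0, 360)`.
#' @export
wrap_360 <- function(theta) theta %% 360

#' Wrap an angle into the signed interval (-180, 180]
#'
#' The positive side is counter-clockwise ("left" of the reference
#' direction); +180 is returned for the antipodal case, never -180.
#'
#' @param theta angle(s) in degrees.
#' @return signed angle(s) in `(-180, 180]`.
#' @export
wrap_180 <- function(theta) {
  out <- theta %% 360
  ifelse(out > 180, out - 360, out)
}

as_xy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  stopifnot(ncol(p) == 2)
  p
}

#' Allocentric bearing from one point to another
#'
#' Angle of the vector `to - from`, measured counter-clockwise from the
#' positive axis-1 (x) direction, with 0 degrees aligned to the horizontal
#' axis.
#'
#' @param from,to points as length-2 vectors or two-column matrices
#'   (recycled row-wise).
#' @return bearing(s) in degrees, `[0, 360)`.
#' @examples
#' bearing_to(c(0, 0), c(1, 0)) # 0
#' bearing_to(c(0, 0), c(0, 1)) # 90
#' @export
bearing_to <- function(from, to) {
  from <- as_xy(from); to <- as_xy(to)
  dx <- to[, 1] - from[, 1]
  dy <- to[, 2] - from[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("degenerate trial: coincident points have no bearing")
  }
  unname(wrap_360(atan2(dy, dx) * 180 / pi))
}

#' Signed egocentric goal angle
#'
#' The signed angular offset of the goal relative to the current movement
#' (morphing) direction: the wrapped difference between the bearing from
#' `start` to `goal` and the allocentric `heading`. 0 means the movement is
#' on-target; positive values mean the goal lies counter-clockwise of the
#' heading ("left" under this package's convention -- the side labels are
#' arbitrary), negative values clockwise ("right"). The antipodal case maps
#' to +180.
#'
#' @param heading allocentric movement direction(s), degrees.
#' @param start,goal points as length-2 vectors or two-column matrices.
#' @return signed offset(s) in degrees, `(-180, 180]`.
#' @examples
#' egocentric_offset(45, c(0, 0), c(1, 0)) # -45: goal to the right
#' @export
egocentric_offset <- function(heading, start, goal) {
  start <- as_xy(start); goal <- as_xy(goal)
  if (any(start[, 1] == goal[, 1] & start[, 2] == goal[, 2])) {
    stop("degenerate trial: start coincides with goal")
  }
  wrap_180(bearing_to(start, goal) - heading)
}

#' Quadrant of a point in the feature space
#'
#' Quadrants are defined by the midlines of both axes: Q1 = (x < 0.5,
#' y < 0.5), Q2 = (x > 0.5, y < 0.5), Q3 = (x < 0.5, y > 0.5),
#' Q4 = (x > 0.5, y > 0.5). Points exactly on a midline are an error (the
#' trial generator never places one there). A 180-degree rotation of the
#' space about its centre swaps Q1 with Q4 and Q2 with Q3.
#'
#' @param point point(s) as a length-2 vector or two-column matrix.
#' @return character vector of `"Q1".."Q4"`.
#' @examples
#' assign_quadrant(c(0.75, 0.25)) # "Q2", the blue goal quadrant
#' @export
assign_quadrant <- function(point) {
  p <- as_xy(point)
  if (any(p[, 1] == 0.5 | p[, 2] == 0.5)) {
    stop("point lies exactly on a quadrant midline")
  }
  if (any(p < 0 | p > 1)) stop("point outside the unit square")
  paste0("Q", 1L + (p[, 1] > 0.5) + 2L * (p[, 2] > 0.5))
}

#' Quadrant image under the 180-degree rotation of the space
#' @param quadrant character vector of `"Q1".."Q4"`.
#' @return rotated quadrant labels (Q1<->Q4, Q2<->Q3).
#' @export
rotate_quadrant <- function(quadrant) {
  map <- c(Q1 = "Q4", Q2 = "Q3", Q3 = "Q2", Q4 = "Q1")
  unname(map[quadrant])
}

#' Bin an allocentric direction into 30-degree bins
#'
#' Directions are resampled into 12 bins with centres at 0, 30, ..., 330
#' degrees and 0 aligned to the horizontal axis. A heading exactly halfway
#' between two centres (15 degrees mod 30) is assigned to the lower bin.
#'
#' @param heading direction(s) in degrees, `[0, 360)`.
#' @return nearest bin centre(s), one of `0, 30, ..., 330`.
#' @examples
#' bin_allocentric(c(29, 344, 15)) # 30, 330, 0
#' @export
bin_allocentric <- function(heading) {
  stopifnot(all(heading >= 0 & heading < 360))
  # ties at 15 mod 30 go down: ceiling(x - .5) rounds half-integers down
  idx <- ceiling(heading / 30 - 0.5) %% 12
  idx * 30
}
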