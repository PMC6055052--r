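# Circular helpers. Convention throughout the package: angles in degrees,
# wrapped to [0, 360); 0 = North, positive clockwise. With x = East and
# y = North, a heading h corresponds to the unit vector (sin h, cos h).

#' Wrap angles to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into `[0, 360)`.
#' @export
#' @examples
#' wrap_angle(c(-30, 360, 725))
wrap_angle <- function(x) x %% 360

#' Signed circular difference
#'
#' Smallest signed rotation taking `b` onto `a`, in degrees.
#'
#' @param a,b angles in degrees.
#' @return signed difference `a - b` wrapped into `(-180, 180]`.
#' @export
#' @examples
#' circular_diff(10, 350)   # 20
#' circular_diff(180, 0)    # 180
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular mean of angles (optionally weighted)
#'
#' Direction of the weighted resultant vector. Errors when the resultant is
#' (numerically) zero, in which case the mean direction is undefined.
#'
#' @param x angles in degrees.
#' @param w nonnegative weights, recycled to `length(x)`.
#' @param tol undefined-direction threshold on the mean resultant length.
#' @return mean direction in `[0, 360)`.
#' @export
circular_mean <- function(x, w = 1, tol = 1e-8) {
  w <- rep_len(w, length(x))
  s <- sum(w * sin(x * pi / 180))
  c_ <- sum(w * cos(x * pi / 180))
  r <- sqrt(s^2 + c_^2)
  if (!is.finite(r) || r <= tol * max(sum(abs(w)), 1)) {
    stop("circular mean undefined: resultant length is (near) zero")
  }
  wrap_angle(atan2(s, c_) * 180 / pi)
}

# heading -> unit displacement (dx, dy); vectorised
heading_to_vec <- function(h) {
  r <- h * pi / 180
  cbind(sin(r), cos(r))
}

# compass bearing of point `to` seen from `from` (degrees, 0 = North, CW)
bearing_to <- function(from, to) {
  wrap_angle(atan2(to[1] - from[1], to[2] - from[2]) * 180 / pi)
}
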