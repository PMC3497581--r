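# Angle helpers shared across modules.
#
# Convention (used everywhere): mathematical angles — 0 degrees along the
# positive d13C axis, counterclockwise positive, stored in [0, 360).

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees onto [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every finite value mapped into `[0, 360)`.
#' @examples
#' wrap_deg(c(-45, 360, 725))
#' @export
wrap_deg <- function(x) {
  out <- x %% 360
  # %% can return 360 for tiny negative fuzz, e.g. -1e-15 %% 360
  out[out >= 360] <- 0
  out
}

#' Angle of a displacement vector in degrees
#'
#' `atan2`-based direction of `(dx, dy)` mapped to `[0, 360)`. A zero-length
#' vector has no direction and yields `NA` (callers treat this as the
#' "undefined" flag).
#'
#' @param dx,dy numeric vectors of displacement components (recycled).
#' @return numeric vector of angles in degrees, `NA` where `dx = dy = 0`.
#' @export
vector_angle <- function(dx, dy) {
  ang <- wrap_deg(rad2deg(atan2(dy, dx)))
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}
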