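# Individualized standardized-reach targets and game impact heights.

#' Participant body dimensions
#'
#' The five lengths that individualize target and impact-height geometry, all
#' in meters.
#'
#' @param hip_height,trunk_length,arm_length,eye_height,shin_height meters;
#'   all positive, with `eye_height > hip_height > shin_height`.
#' @return list of class `body_dimensions`.
#' @export
body_dimensions <- function(hip_height, trunk_length, arm_length,
                            eye_height, shin_height) {
  v <- c(hip_height = hip_height, trunk_length = trunk_length,
         arm_length = arm_length, eye_height = eye_height,
         shin_height = shin_height)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all body dimensions must be positive finite numbers")
  if (!(eye_height > hip_height && hip_height > shin_height))
    stop("dimensions must satisfy eye_height > hip_height > shin_height")
  structure(as.list(v), class = "body_dimensions")
}

#' Standardized-reach target location
#'
#' Forward model of the individualized mid-sagittal targets: with the hips
#' flexed `hip_flexion_deg` from vertical, the shoulder flexed 90 degrees and
#' the elbow extended, the trunk vector is
#' `trunk_length * (sin(theta), cos(theta))` from the hip at `hip_height` and
#' the arm vector is `arm_length * (cos(theta), -sin(theta))` in the
#' (AP, vertical) plane. The high, middle and low targets of the baseline
#' reaching task use theta = 15, 30 and 60 degrees.
#'
#' @param dims a [body_dimensions()].
#' @param hip_flexion_deg hip flexion from vertical, degrees in (0, 90)
#'   (0 allowed as the upright limit).
#' @return named numeric vector `c(ap, ml, vertical)` in meters (`ml` = 0).
#' @export
standardized_target_location <- function(dims, hip_flexion_deg) {
  stopifnot(inherits(dims, "body_dimensions"))
  if (hip_flexion_deg < 0 || hip_flexion_deg >= 90)
    stop("hip flexion must lie in [0, 90) degrees")
  th <- deg2rad(hip_flexion_deg)
  ap <- dims$trunk_length * sin(th) + dims$arm_length * cos(th)
  vert <- dims$hip_height + dims$trunk_length * cos(th) -
    dims$arm_length * sin(th)
  c(ap = ap, ml = 0, vertical = vert)
}

#' Recover hip flexion from a standardized-reach target
#'
#' Inverse of [standardized_target_location()]: root-finds the hip-flexion
#' angle whose forward-model target matches the supplied point (the vertical
#' coordinate is strictly decreasing in the flexion angle, so the root is
#' unique). Points not on the standardized-reach locus raise a no-solution
#' error.
#'
#' @param dims a [body_dimensions()].
#' @param target 3-vector `c(ap, ml, vertical)` in meters.
#' @return hip flexion in degrees (accurate to better than 1e-6 deg).
#' @export
recover_hip_flexion <- function(dims, target) {
  stopifnot(inherits(dims, "body_dimensions"))
  vz <- function(th_deg) standardized_target_location(dims, th_deg)[["vertical"]]
  lo <- 0; hi <- 89.999
  fz <- function(th) vz(th) - target[[3]]
  if (fz(lo) < -1e-9 || fz(hi) > 1e-9)
    stop("target is not reachable by the standardized-reach construction")
  th <- if (abs(fz(lo)) < 1e-12) lo else
    uniroot(fz, c(lo, hi), tol = 1e-12)$root
  fwd <- standardized_target_location(dims, th)
  if (abs(fwd[["ap"]] - target[[1]]) > 1e-6)
    stop("no standardized-reach solution passes through the supplied point")
  th
}

#' Baseline lumbar-flexion values
#'
#' Mean lumbar flexion (degrees) a participant used to reach the high, middle
#' and low standardized targets; monotone non-decreasing with target depth.
#'
#' @param high,mid,low degrees, `low >= mid >= high >= 0`.
#' @return list of class `lumbar_baseline`.
#' @export
lumbar_baseline <- function(high, mid, low) {
  if (!(low >= mid && mid >= high && high >= 0))
    stop("baseline must satisfy low >= mid >= high >= 0")
  structure(list(high = high, mid = mid, low = low), class = "lumbar_baseline")
}

#' Impact heights for one gameplay level
#'
#' The five ball impact heights IH0..IH4 for a level: IH0 is eye height for
#' every level; IH4 is the hand height the standardized-reach forward model
#' predicts when the trunk adopts the level's baseline lumbar flexion (high
#' target for Level 1, middle for Level 2, low for Level 3); IH1-IH3 are
#' linearly interpolated between IH0 and IH4. All heights must stay at or
#' above `shin_height - 0.05` m.
#'
#' @param dims a [body_dimensions()].
#' @param baseline a [lumbar_baseline()].
#' @param level gameplay level 1-3.
#' @param flexion_map function mapping baseline lumbar flexion (deg) to the
#'   trunk-inclination angle (deg) fed to the forward model; identity by
#'   default.
#' @return list of class `impact_height_set`: `level` and named `heights`
#'   (IH0..IH4, meters, strictly decreasing).
#' @export
impact_heights_for_level <- function(dims, baseline, level,
                                     flexion_map = identity) {
  stopifnot(inherits(dims, "body_dimensions"),
            inherits(baseline, "lumbar_baseline"))
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  ang <- c(baseline$high, baseline$mid, baseline$low)[level]
  th <- flexion_map(ang)
  ih0 <- dims$eye_height
  ih4 <- standardized_target_location(dims, th)[["vertical"]]
  if (ih4 >= ih0)
    stop("computed IH4 lies at or above eye height; geometry is inconsistent")
  floor_z <- dims$shin_height - 0.05
  if (ih4 < floor_z)
    stop(sprintf("computed IH4 (%.3f m) falls below the shin floor (%.3f m)",
                 ih4, floor_z))
  heights <- ih0 + (0:4) / 4 * (ih4 - ih0)
  names(heights) <- paste0("IH", 0:4)
  structure(list(level = as.integer(level), heights = heights),
            class = "impact_height_set")
}

#' Straight-line ball flight path
#'
#' Parametric constant-speed path from the launch origin to the impact point
#' shifted laterally by `lateral_offset`; `t = 0` is launch and
#' `t = flight_time` is impact.
#'
#' @param impact_point 3-vector `c(ap, ml, vertical)` in meters (participant
#'   midline impact location).
#' @param lateral_offset ML shift of the impact point in meters (the game
#'   uses -0.20, 0 and +0.20).
#' @param flight_time seconds (positive).
#' @param launch_origin 3-vector, launch position in meters.
#' @return function of class `ball_path`: `f(t)` returning a `length(t) x 3`
#'   matrix of ball-centre positions; attributes `origin`, `impact`,
#'   `flight_time`.
#' @export
ball_path <- function(impact_point, lateral_offset = 0, flight_time = 1,
                      launch_origin = c(12, 0, 1.5)) {
  if (flight_time <= 0) stop("flight_time must be positive")
  impact <- as.numeric(impact_point) + c(0, lateral_offset, 0)
  origin <- as.numeric(launch_origin)
  f <- function(t) {
    tau <- t / flight_time
    out <- outer(1 - tau, origin) + outer(tau, impact)
    colnames(out) <- c("ap", "ml", "vertical")
    out
  }
  structure(f, origin = origin, impact = impact, flight_time = flight_time,
            class = c("ball_path", "function"))
}
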