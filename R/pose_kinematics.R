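# Rigid segment poses from marker clusters and Euler joint angles.
#
# Convention: intrinsic Euler sequence about the parent-segment axes in the
# order (1) flexion-extension about ML (+y), (2) lateral bending about
# AP (+x), (3) axial rotation about vertical (+z):
#   R = Ry(flexion) %*% Rx(lateral) %*% Rz(axial)
# Positive flexion tilts the segment top forward (+AP).

rot_flexion <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_lateral <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_axial <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || anyNA(R))
    stop("rotation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("input is not a proper orthonormal rotation (det +1)")
  invisible(TRUE)
}

#' Marker cluster template
#'
#' Describes a rigid cluster of reflective markers attached to one body
#' segment: at least 3 non-collinear template points expressed in the segment
#' frame, the trajectory-set marker names they correspond to, and optional
#' fixed joint-centre locations in the same segment frame (used to recover
#' joint positions from fitted poses).
#'
#' @param segment segment identifier (e.g. `"thigh_r"`).
#' @param template `k x 3` matrix (`k >= 3`) of marker coordinates in the
#'   segment frame, meters; points must be non-collinear.
#' @param marker_names character vector of length `k` naming the observed
#'   markers in a [trajectory_set()].
#' @param joints optional named list of 3-vectors: joint-centre locations in
#'   the segment frame.
#' @return object of class `marker_cluster`.
#' @export
marker_cluster <- function(segment, template, marker_names, joints = list()) {
  template <- as.matrix(template)
  if (nrow(template) < 3L || ncol(template) != 3L)
    stop("cluster template needs at least 3 points with 3 coordinates")
  if (length(marker_names) != nrow(template))
    stop("one marker name per template point required")
  sv <- svd(scale(template, scale = FALSE))$d
  if (sv[2] < 1e-9)
    stop(sprintf("cluster template for '%s' is collinear", segment))
  structure(list(segment = segment, template = template,
                 marker_names = marker_names, joints = joints),
            class = "marker_cluster")
}

#' Least-squares rigid pose of a marker cluster
#'
#' Per-frame orthogonal-Procrustes (Kabsch) fit of the rigid transform
#' mapping the cluster template onto the observed markers. Reflections are
#' rejected by forcing the determinant to +1. Frames with fewer than 3 valid
#' (non-missing) markers, or with a collinear valid subset, are flagged
#' unresolvable (`valid = FALSE`, pose `NA`).
#'
#' @param cluster a [marker_cluster()] (or a bare `k x 3` template matrix).
#' @param observed observed marker positions: an `n x k x 3` array, or a
#'   `k x 3` matrix for a single frame.
#' @return object of class `segment_pose`: list with `rotation`
#'   (`3 x 3 x n` array), `translation` (`n x 3`), `valid` (logical `n`).
#' @export
fit_rigid_pose <- function(cluster, observed) {
  template <- if (inherits(cluster, "marker_cluster")) cluster$template
              else as.matrix(cluster)
  k <- nrow(template)
  if (is.matrix(observed)) observed <- array(observed, c(1L, dim(observed)))
  if (length(dim(observed)) != 3L || dim(observed)[2] != k ||
      dim(observed)[3] != 3L)
    stop("observed must be an n x k x 3 array matching the template")
  n <- dim(observed)[1]
  R <- array(NA_real_, c(3, 3, n))
  tr <- matrix(NA_real_, n, 3)
  valid <- logical(n)
  for (i in seq_len(n)) {
    Q <- observed[i, , , drop = TRUE]
    if (k == 1L) Q <- matrix(Q, 1, 3)
    ok <- stats::complete.cases(Q)
    if (sum(ok) < 3L) next
    P <- template[ok, , drop = FALSE]
    Qv <- Q[ok, , drop = FALSE]
    sv_chk <- svd(scale(P, scale = FALSE))$d
    if (sv_chk[2] < 1e-9)
      stop("valid marker subset is collinear; pose is degenerate")
    pc <- colMeans(P); qc <- colMeans(Qv)
    H <- crossprod(sweep(P, 2, pc), sweep(Qv, 2, qc))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    Ri <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    R[, , i] <- Ri
    tr[i, ] <- qc - as.numeric(Ri %*% pc)
    valid[i] <- TRUE
  }
  structure(list(rotation = R, translation = tr, valid = valid,
                 segment = if (inherits(cluster, "marker_cluster"))
                   cluster$segment else NA_character_),
            class = "segment_pose")
}

#' @export
print.segment_pose <- function(x, ...) {
  cat(sprintf("<segment_pose> %s: %d frames (%d valid)\n",
              x$segment %||% "?", length(x$valid), sum(x$valid)))
  invisible(x)
}

#' Apply a segment pose to points in the segment frame
#'
#' @param pose a `segment_pose`.
#' @param point 3-vector in the segment frame.
#' @return `n x 3` matrix of lab-frame positions (`NA` rows where the pose is
#'   unresolved).
#' @export
pose_transform <- function(pose, point) {
  stopifnot(inherits(pose, "segment_pose"))
  n <- length(pose$valid)
  out <- matrix(NA_real_, n, 3)
  for (i in which(pose$valid))
    out[i, ] <- pose$rotation[, , i] %*% point + pose$translation[i, ]
  out
}

#' Relative rotation of a child segment in its parent's frame
#'
#' @param parent,child `segment_pose` objects with equal frame counts.
#' @return `3 x 3 x n` array of relative rotations (`NA` where either pose is
#'   unresolved).
#' @export
joint_rotation <- function(parent, child) {
  stopifnot(inherits(parent, "segment_pose"), inherits(child, "segment_pose"))
  n <- length(parent$valid)
  if (length(child$valid) != n)
    stop("parent and child poses must have equal frame counts")
  out <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    if (parent$valid[i] && child$valid[i])
      out[, , i] <- crossprod(parent$rotation[, , i], child$rotation[, , i])
  }
  out
}

#' Compose a rotation from Euler angles
#'
#' Intrinsic sequence flexion (ML axis), lateral bending (AP axis), axial
#' rotation (vertical axis); angles in degrees.
#'
#' @param flexion,lateral,axial angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_compose <- function(flexion, lateral, axial) {
  rot_flexion(flexion) %*% rot_lateral(lateral) %*% rot_axial(axial)
}

#' Decompose a rotation into the flexion / lateral / axial Euler sequence
#'
#' Inverse of [euler_compose()]. Rotations with the middle (lateral-bending)
#' angle within 0.5 degrees of +-90 are near gimbal lock and flagged via the
#' `"gimbal"` attribute.
#'
#' @param R proper orthonormal 3x3 rotation.
#' @return named numeric vector `c(flexion, lateral, axial)` in degrees, with
#'   logical attribute `"gimbal"`.
#' @export
euler_decompose <- function(R) {
  check_rotation(R)
  lat <- asin(max(-1, min(1, -R[2, 3])))
  flex <- atan2(R[1, 3], R[3, 3])
  ax <- atan2(R[2, 1], R[2, 2])
  out <- c(flexion = rad2deg(flex), lateral = rad2deg(lat),
           axial = rad2deg(ax))
  attr(out, "gimbal") <- abs(abs(out[["lateral"]]) - 90) < 0.5
  out
}

# Vectorized decomposition over a 3x3xn array; returns n x 3 matrix (NA rows
# propagate) plus a gimbal flag column handled by the caller.
euler_decompose_series <- function(Rarr) {
  n <- dim(Rarr)[3]
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("flexion", "lateral", "axial")))
  gimbal <- rep(NA, n)
  for (i in seq_len(n)) {
    if (anyNA(Rarr[, , i])) next
    a <- euler_decompose(Rarr[, , i])
    out[i, ] <- a
    gimbal[i] <- attr(a, "gimbal")
  }
  attr(out, "gimbal") <- gimbal
  out
}

#' Default right-side kinematic chain
#'
#' Parent/child segment pairs for the six analysed joints (ankle, knee, hip,
#' spine, shoulder, elbow) of the right side, with the sign that maps the
#' decomposed flexion component onto the anatomical flexion convention
#' (flexion positive) for each joint.
#'
#' @param side `"r"` or `"l"`.
#' @return data.frame with columns `joint`, `parent`, `child`, `flexion_sign`.
#' @export
default_chain <- function(side = "r") {
  s <- match.arg(side, c("r", "l"))
  data.frame(
    joint = c("ankle", "knee", "hip", "spine", "shoulder", "elbow"),
    parent = c(paste0("foot_", s), paste0("shank_", s), paste0("thigh_", s),
               "pelvis", "trunk", paste0("upper_arm_", s)),
    child = c(paste0("shank_", s), paste0("thigh_", s), "pelvis", "trunk",
              paste0("upper_arm_", s), paste0("forearm_", s)),
    flexion_sign = c(1, -1, 1, 1, -1, -1),
    stringsAsFactors = FALSE)
}

#' Joint-angle time series from marker trajectories
#'
#' Fits per-frame rigid poses for every segment in the chain and decomposes
#' each parent-child relative rotation into the flexion / lateral-bending /
#' axial-rotation Euler sequence. Frames with unresolvable poses propagate
#' `NA`.
#'
#' @param ts a [trajectory_set()].
#' @param clusters named list of [marker_cluster()] objects (names = segment
#'   identifiers).
#' @param chain data.frame as returned by [default_chain()].
#' @param poses optional pre-computed named list of `segment_pose` objects
#'   (skips refitting).
#' @return named list (one element per joint) of data.frames with columns
#'   `flexion`, `lateral`, `axial` (degrees) and `gimbal` (logical).
#' @export
compute_joint_angles <- function(ts, clusters, chain = default_chain(),
                                 poses = NULL) {
  stopifnot(inherits(ts, "trajectory_set"))
  need <- unique(c(chain$parent, chain$child))
  missing_seg <- setdiff(need, names(clusters))
  if (length(missing_seg))
    stop(sprintf("no marker cluster configured for segment(s): %s",
                 paste(missing_seg, collapse = ", ")))
  if (is.null(poses)) {
    poses <- lapply(need, function(seg)
      fit_rigid_pose(clusters[[seg]], observed_markers(ts, clusters[[seg]])))
    names(poses) <- need
  }
  out <- lapply(seq_len(nrow(chain)), function(i) {
    rel <- joint_rotation(poses[[chain$parent[i]]], poses[[chain$child[i]]])
    ang <- euler_decompose_series(rel)
    data.frame(flexion = chain$flexion_sign[i] * ang[, "flexion"],
               lateral = ang[, "lateral"], axial = ang[, "axial"],
               gimbal = attr(ang, "gimbal"))
  })
  names(out) <- chain$joint
  out
}

# Assemble the n x k x 3 observation array for a cluster from a trajectory set.
observed_markers <- function(ts, cluster) {
  miss <- setdiff(cluster$marker_names, ts$marker_names)
  if (length(miss))
    stop(sprintf("trajectory set lacks markers for segment '%s': %s",
                 cluster$segment, paste(miss, collapse = ", ")))
  n <- ts$frame_count
  k <- length(cluster$marker_names)
  arr <- array(NA_real_, c(n, k, 3))
  for (j in seq_len(k)) arr[, j, ] <- ts$positions[[cluster$marker_names[j]]]
  arr
}

# Lab-frame joint-centre trajectories for every joint a cluster declares.
joint_positions <- function(pose, cluster) {
  lapply(cluster$joints, function(p) pose_transform(pose, p))
}
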