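# Whole-body centre of mass from anthropometric segment parameters.

#' Anthropometric segment-parameter table
#'
#' Loads a table of per-segment body-mass fractions and centre-of-mass
#' locations (fraction of segment length from the proximal end). The shipped
#' default uses Winter-style values with head, neck, trunk and pelvis
#' consolidated into a single trunk segment and bilateral limb segments; the
#' mass fractions of the modeled set sum to 1. The table is injectable so
#' alternative parameter sources can be used.
#'
#' @param path CSV file with columns `segment`, `mass_fraction`,
#'   `com_location_fraction`; default the packaged table.
#' @return data.frame of class `anthropometric_table`.
#' @export
winter_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "winter_segments.csv",
                                package = "dodgekin")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "mass_fraction", "com_location_fraction")
  if (!all(need %in% names(tab)))
    stop("anthropometric table must have columns segment, mass_fraction, com_location_fraction")
  if (any(tab$mass_fraction <= 0 | tab$mass_fraction >= 1) ||
      any(tab$com_location_fraction <= 0 | tab$com_location_fraction >= 1))
    stop("all fractions must lie strictly in (0, 1)")
  total <- sum(tab$mass_fraction)
  if (total < 0.99 || total > 1.01)
    stop(sprintf("segment mass fractions sum to %.4f, outside [0.99, 1.01]", total))
  class(tab) <- c("anthropometric_table", "data.frame")
  tab
}

#' Segment centre of mass
#'
#' Interpolates the segment COM at `com_fraction` of the way from the
#' proximal to the distal endpoint. Coincident endpoints return the proximal
#' point with a zero-length warning.
#'
#' @param proximal,distal endpoint positions: 3-vectors or `n x 3` matrices.
#' @param com_fraction COM location as a fraction of segment length from the
#'   proximal end, in (0, 1) (the boundaries are tolerated as limits).
#' @return same shape as the inputs.
#' @export
segment_com <- function(proximal, distal, com_fraction) {
  if (com_fraction < 0 || com_fraction > 1)
    stop("com_fraction must lie in [0, 1]")
  p <- rbind(proximal); d <- rbind(distal)
  if (any(sqrt(rowSums((d - p)^2)) < 1e-12, na.rm = TRUE))
    warning("zero-length segment: COM placed at the proximal point")
  out <- p + com_fraction * (d - p)
  if (is.null(dim(proximal))) as.numeric(out) else out
}

#' Whole-body centre-of-mass trajectory
#'
#' Mass-fraction-weighted mean of the per-segment COM positions at every
#' frame, renormalized by the summed fractions of the segments supplied.
#'
#' @param segment_endpoints named list (one element per table segment), each
#'   a list with `proximal` and `distal` `n x 3` matrices in meters.
#' @param table an [winter_table()] anthropometric table.
#' @return object of class `com_trajectory`: `n x 3` matrix (AP, ML,
#'   vertical) in meters.
#' @export
whole_body_com <- function(segment_endpoints, table = winter_table()) {
  stopifnot(inherits(table, "anthropometric_table"))
  missing_seg <- setdiff(table$segment, names(segment_endpoints))
  if (length(missing_seg))
    stop(sprintf("segment endpoints missing for: %s",
                 paste(missing_seg, collapse = ", ")))
  n <- nrow(rbind(segment_endpoints[[table$segment[1]]]$proximal))
  acc <- matrix(0, n, 3)
  wsum <- 0
  for (i in seq_len(nrow(table))) {
    seg <- table$segment[i]
    ep <- segment_endpoints[[seg]]
    com <- segment_com(ep$proximal, ep$distal, table$com_location_fraction[i])
    acc <- acc + table$mass_fraction[i] * rbind(com)
    wsum <- wsum + table$mass_fraction[i]
  }
  out <- acc / wsum
  colnames(out) <- c("ap", "ml", "vertical")
  class(out) <- c("com_trajectory", class(out))
  out
}

#' COM displacement over a reach event
#'
#' Componentwise COM position difference from movement onset to target
#' contact along the AP, ML and vertical axes.
#'
#' @param traj a [whole_body_com()] trajectory.
#' @param ev a [reach_event()].
#' @return named numeric vector `c(ap, ml, vertical)` in meters.
#' @export
com_displacement <- function(traj, ev) {
  stopifnot(inherits(ev, "reach_event"))
  n <- nrow(traj)
  if (ev$onset_index < 1L || ev$contact_index > n)
    stop("event indices fall outside the COM trajectory")
  out <- traj[ev$contact_index, ] - traj[ev$onset_index, ]
  names(out) <- c("ap", "ml", "vertical")
  out
}
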