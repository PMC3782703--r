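#' Mean ROI time courses from labeled voxel series
#'
#' @param voxel_series V x T matrix of voxel time courses.
#' @param labels Integer vector of length V with 0-based ROI labels in
#'   `0..n_roi-1`.
#' @param n_roi Number of ROIs (default `max(labels) + 1`).
#' @return R x T matrix; row r is the mean over voxels labeled r-1.
#' @export
roi_timecourses <- function(voxel_series, labels, n_roi = max(labels) + 1L) {
  stopifnot(is.matrix(voxel_series), length(labels) == nrow(voxel_series),
            all(labels >= 0), all(labels < n_roi))
  counts <- tabulate(labels + 1L, n_roi)
  if (any(counts == 0L)) {
    stop("ROI(s) with no voxels: ",
         paste(which(counts == 0L) - 1L, collapse = ", "))
  }
  sums <- rowsum(voxel_series, labels, reorder = TRUE)
  sums / counts
}

#' Fisher-z association matrix from ROI time courses
#'
#' Pearson correlations between all ROI pairs, clipped to `|r| <= 1 - 1e-7`
#' (so degenerate duplicates stay finite) and Fisher-transformed with `atanh`.
#' The diagonal carries no information and is set to 0.
#'
#' @param roi_series R x T matrix with T >= 4; every row must have nonzero
#'   variance.
#' @return Symmetric R x R Fisher-z matrix.
#' @export
association_matrix <- function(roi_series) {
  stopifnot(is.matrix(roi_series), ncol(roi_series) >= 4L)
  v <- apply(roi_series, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ROI time course(s): ",
         paste(which(v == 0) - 1L, collapse = ", "))
  }
  r <- stats::cor(t(roi_series))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Euclidean distance matrix between ROI centroids
#'
#' @param rois ROI data.frame with mm centroid columns x, y, z.
#' @return Symmetric R x R matrix of distances in mm with zero diagonal.
#' @export
distance_matrix <- function(rois) {
  xyz <- as.matrix(rois[, c("x", "y", "z")])
  stopifnot(all(is.finite(xyz)))
  as.matrix(stats::dist(xyz))
}

#' Strength-by-distance bin specification
#'
#' @param z_spacing Bin width on the Fisher-z axis (default 0.05).
#' @param d_spacing Bin width on the distance axis in mm (default 5).
#' @param z_origin,d_origin Bin-edge anchors (default 0).
#' @return List of class `fcloo_bin_spec`.
#' @export
bin_spec <- function(z_spacing = 0.05, d_spacing = 5,
                     z_origin = 0, d_origin = 0) {
  stopifnot(z_spacing > 0, d_spacing > 0)
  structure(list(z_spacing = z_spacing, d_spacing = d_spacing,
                 z_origin = z_origin, d_origin = d_origin),
            class = "fcloo_bin_spec")
}

#' Assign connections to strength-by-distance bins
#'
#' Each connection is binned by the floor rule
#' `floor((value - origin) / spacing)` on both axes (half-open intervals
#' `[edge, edge + spacing)`; negative Fisher-z values index negative bins).
#' The reference strengths must come from a cohort disjoint from the cohort
#' being classified — a caller contract mirroring the use of an independent
#' reference sample for connection strength.
#'
#' @param reference_strength Per-connection Fisher-z strength from an
#'   independent reference cohort (canonical connection order).
#' @param distances Per-connection Euclidean distance in mm (canonical order).
#' @param spec A [bin_spec()].
#' @return data.frame with integer columns `z_bin` and `d_bin`, one row per
#'   connection.
#' @export
assign_strength_distance_bins <- function(reference_strength, distances,
                                          spec = bin_spec()) {
  stopifnot(inherits(spec, "fcloo_bin_spec"),
            length(reference_strength) == length(distances))
  data.frame(
    z_bin = as.integer(floor((reference_strength - spec$z_origin) / spec$z_spacing)),
    d_bin = as.integer(floor((distances - spec$d_origin) / spec$d_spacing)))
}

#' Per-connection distances in canonical order
#'
#' Convenience wrapper returning the distance of every connection as a vector
#' aligned with the canonical connection enumeration.
#'
#' @param rois ROI data.frame.
#' @return Numeric vector of length `n_connections(nrow(rois))`.
#' @export
connection_distances <- function(rois) {
  matrix_to_connections(distance_matrix(rois))
}
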