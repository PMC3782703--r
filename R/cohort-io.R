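PHENO_COLUMNS <- c(
  "subject_id", "site", "diagnosis", "age", "gender", "handedness", "eyes",
  "n_volumes_acquired", "n_volumes_retained",
  "ados_social_comm", "adi_r_social", "adi_r_verbal",
  "verbal_iq", "performance_iq", "srs_total", "vineland_composite"
)
BEHAVIOR_MEASURES <- c(
  "ados_social_comm", "adi_r_social", "adi_r_verbal",
  "verbal_iq", "performance_iq", "srs_total", "vineland_composite"
)
DIAGNOSIS_LEVELS <- c("autism", "control")
GENDER_LEVELS <- c("male", "female")
HANDEDNESS_LEVELS <- c("right", "left", "ambidextrous")
EYES_LEVELS <- c("open", "closed", "unknown")

parse_handedness <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  num <- suppressWarnings(as.numeric(x))
  isnum <- !is.na(num)
  # quantitative laterality scores: sign decides the categorical label
  out[isnum & num > 0] <- "right"
  out[isnum & num < 0] <- "left"
  out[isnum & num == 0] <- "ambidextrous"
  lw <- tolower(x)
  out[!isnum & lw %in% c("right", "r")] <- "right"
  out[!isnum & lw %in% c("left", "l")] <- "left"
  out[!isnum & lw %in% c("ambidextrous", "ambi", "a")] <- "ambidextrous"
  bad <- !isnum & !(lw %in% c("", "na", "nan")) & is.na(out)
  if (any(bad)) {
    stop("unrecognized handedness value(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Read a phenotype table
#'
#' Reads a tab- or comma-separated phenotype table with a header row naming the
#' documented columns (subject_id, site, diagnosis, age, gender, handedness,
#' eyes, n_volumes_acquired, n_volumes_retained, and the behavioral measures).
#' Empty cells or "NA" are missing values. Quantitative handedness scores are
#' converted to categorical labels: positive values become right-handed,
#' negative left-handed, and zero ambidextrous.
#'
#' Rows whose diagnosis or gender is not an allowed level are rejected with a
#' warning naming the subject; a duplicated subject_id is an error.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the header (tab if present, otherwise comma).
#' @return A data.frame with one row per subject and the documented columns.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          check.names = FALSE)
  missing_cols <- setdiff(c("subject_id", "site", "diagnosis", "age"), names(df))
  if (length(missing_cols)) {
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(PHENO_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, PHENO_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  df$site <- as.character(df$site)
  df$diagnosis <- tolower(as.character(df$diagnosis))
  df$gender <- tolower(as.character(df$gender))
  bad <- !(df$diagnosis %in% DIAGNOSIS_LEVELS) |
    (!is.na(df$gender) & !(df$gender %in% GENDER_LEVELS))
  if (any(bad)) {
    warning("rejecting ", sum(bad), " row(s) with unknown diagnosis/gender level: ",
            paste(df$subject_id[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df$handedness <- parse_handedness(df$handedness)
  df$eyes <- tolower(as.character(df$eyes))
  df$eyes[is.na(df$eyes)] <- "unknown"
  if (!all(df$eyes %in% EYES_LEVELS)) stop("unknown eyes level")
  for (col in c("age", "n_volumes_acquired", "n_volumes_retained", BEHAVIOR_MEASURES)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(!is.finite(df$age) | df$age <= 0)) stop("age must be a positive number")
  both <- !is.na(df$n_volumes_retained) & !is.na(df$n_volumes_acquired)
  if (any(df$n_volumes_retained[both] > df$n_volumes_acquired[both])) {
    stop("n_volumes_retained exceeds n_volumes_acquired")
  }
  rownames(df) <- NULL
  df
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]; missing values are written as empty cells so
#' a write/read round trip preserves every field and missingness pattern.
#'
#' @param phenotypes Phenotype data.frame.
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @export
write_phenotypes <- function(phenotypes, path, sep = "\t") {
  utils::write.table(phenotypes, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Impute missing categorical handedness by nearest neighbors
#'
#' Subjects lacking a handedness label are assigned the majority label among
#' their `k` nearest neighbors. The feature space uses the covariates that are
#' guaranteed present: standardized age, a gender indicator, and one-hot site
#' indicators (Euclidean distance). Ties in the vote are broken toward the
#' globally more frequent class; known labels are never altered.
#'
#' @param phenotypes Phenotype data.frame (see [read_phenotypes()]).
#' @param k Neighbor count (default 5).
#' @return The phenotype data.frame with `handedness` fully populated.
#' @export
impute_handedness <- function(phenotypes, k = 5L) {
  hand <- phenotypes$handedness
  known <- !is.na(hand)
  if (!any(known)) stop("all handedness values are missing; cannot impute")
  if (all(known)) return(phenotypes)
  if (sum(known) < k) stop("fewer than k records with known handedness")

  age <- phenotypes$age
  feat <- cbind((age - mean(age)) / ifelse(stats::sd(age) > 0, stats::sd(age), 1),
                as.numeric(phenotypes$gender == "female"))
  for (s in unique(phenotypes$site)) feat <- cbind(feat, as.numeric(phenotypes$site == s))

  freq <- sort(table(hand[known]), decreasing = TRUE)
  global_majority <- names(freq)[1L]
  kn_idx <- which(known)
  for (m in which(!known)) {
    d <- sqrt(colSums((t(feat[kn_idx, , drop = FALSE]) - feat[m, ])^2))
    nb <- kn_idx[order(d, kn_idx)[seq_len(k)]]
    votes <- table(hand[nb])
    top <- names(votes)[votes == max(votes)]
    hand[m] <- if (length(top) == 1L) top else {
      if (global_majority %in% top) global_majority else sort(top)[1L]
    }
  }
  phenotypes$handedness <- hand
  phenotypes
}

#' Construct lattice ROIs from a binary mask
#'
#' Partitions space into half-open cubic cells of side `spacing` (anchored at
#' `origin`) and keeps every cell whose center falls inside the mask, mirroring
#' a regular lattice parcellation of a gray-matter mask at 5-mm resolution.
#' Each ROI records the number of mask voxels falling in its cell.
#'
#' @param mask 3-D logical array.
#' @param voxel_size Voxel edge length in mm (scalar, isotropic).
#' @param spacing Lattice spacing in mm (default 5).
#' @param origin mm coordinate of the corner of voxel (1,1,1) (default c(0,0,0)).
#' @param z_range Optional c(zmin, zmax) in mm; cells with centroid z outside
#'   the range are dropped (default unrestricted).
#' @return A data.frame with columns `roi_id` (0-based), `x`, `y`, `z`
#'   (centroid mm) and `n_voxels`.
#' @export
build_lattice_rois <- function(mask, voxel_size, spacing = 5,
                               origin = c(0, 0, 0), z_range = c(-Inf, Inf)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, spacing > 0, voxel_size > 0)
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  # voxel centers in mm
  centers <- sweep((idx - 0.5) * voxel_size, 2L, origin, "+")
  cell <- floor(centers / spacing)  # integer cell coordinates per voxel
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  counts <- table(key)
  uk <- do.call(rbind, lapply(strsplit(names(counts), " "), as.numeric))
  centroid <- (uk + 0.5) * spacing
  # a cell is an ROI only if its centroid itself is covered by the mask
  vox <- floor(sweep(centroid, 2L, origin, "-") / voxel_size) + 1L
  dims <- dim(mask)
  inside <- vox[, 1L] >= 1 & vox[, 1L] <= dims[1L] &
    vox[, 2L] >= 1 & vox[, 2L] <= dims[2L] &
    vox[, 3L] >= 1 & vox[, 3L] <= dims[3L]
  covered <- inside
  covered[inside] <- mask[vox[inside, , drop = FALSE]]
  covered <- covered & centroid[, 3L] >= z_range[1L] & centroid[, 3L] <= z_range[2L]
  if (!any(covered)) stop("no lattice point falls inside the mask")
  centroid <- centroid[covered, , drop = FALSE]
  nv <- as.integer(counts)[covered]
  ord <- order(centroid[, 1L], centroid[, 2L], centroid[, 3L])
  data.frame(roi_id = seq_along(nv) - 1L,
             x = centroid[ord, 1L], y = centroid[ord, 2L], z = centroid[ord, 3L],
             n_voxels = nv[ord])
}

#' Read / write ROI centroid tables
#'
#' Four-column delimited tables (roi_id, x, y, z in mm), with an optional
#' fifth n_voxels column.
#'
#' @param path File path.
#' @return `read_roi_set`: data.frame with roi_id (0-based), x, y, z
#'   and (if present) n_voxels.
#' @export
read_roi_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("roi_id", "x", "y", "z") %in% names(df)))
  if (nrow(df) < 2L) stop("an ROI set needs at least 2 ROIs")
  if (anyDuplicated(df[, c("x", "y", "z")])) stop("duplicate ROI centroids")
  df[order(df$roi_id), , drop = FALSE]
}

#' @param rois ROI data.frame.
#' @rdname read_roi_set
#' @export
write_roi_set <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association matrix
#'
#' The primary container is binary: an 8-byte little-endian float64 header
#' holding the matrix order R, followed by the R x R values as row-major
#' little-endian float64 — round-trips are bit exact. A tab-delimited text
#' dialect (17 significant digits) is provided for human-readable fixtures.
#' The diagonal is not meaningful and is stored as 0.
#'
#' @param mat Symmetric R x R numeric matrix of Fisher-z values (diagonal
#'   ignored).
#' @param path Output path.
#' @param format "binary" (default) or "text".
#' @export
write_assoc_matrix <- function(mat, path, format = c("binary", "text")) {
  format <- match.arg(format)
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  diag(mat) <- 0
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(nrow(mat)), con, size = 8L, endian = "little")
    writeBin(as.numeric(t(mat)), con, size = 8L, endian = "little")
  } else {
    lines <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an association matrix
#'
#' Counterpart of [write_assoc_matrix()]. Symmetry is enforced on read with a
#' maximum allowed asymmetry of 1e-10; non-square payloads and non-finite
#' off-diagonal entries are errors.
#'
#' @param path Input path.
#' @param format "binary" (default) or "text".
#' @return Symmetric R x R matrix with a 0 diagonal.
#' @export
read_assoc_matrix <- function(path, format = c("binary", "text")) {
  format <- match.arg(format)
  if (format == "binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    R <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
    if (!length(R) || R != round(R) || R < 2) stop("corrupt matrix header")
    vals <- readBin(con, "numeric", n = R * R + 1L, size = 8L, endian = "little")
    if (length(vals) != R * R) stop("matrix payload is not square (R = ", R, ")")
    mat <- matrix(vals, nrow = R, byrow = TRUE)
  } else {
    rows <- strsplit(readLines(path), "\t", fixed = TRUE)
    R <- length(rows)
    if (any(lengths(rows) != R)) stop("matrix payload is not square")
    mat <- matrix(as.numeric(unlist(rows)), nrow = R, byrow = TRUE)
  }
  off <- mat[row(mat) != col(mat)]
  if (any(!is.finite(off))) stop("non-finite off-diagonal entries")
  if (max(abs(mat - t(mat))) > 1e-10) {
    stop("matrix asymmetry exceeds 1e-10")
  }
  diag(mat) <- 0
  mat
}

#' Flatten a symmetric matrix to the canonical connection vector
#'
#' @param mat Symmetric R x R matrix.
#' @return Numeric vector of length `n_connections(R)` in lexicographic (i, j),
#'   i < j order.
#' @export
matrix_to_connections <- function(mat) {
  t(mat)[lower.tri(mat)]
}

#' Expand a connection vector to a symmetric matrix
#'
#' @param values Connection vector in canonical order.
#' @param n_roi Number of ROIs.
#' @return Symmetric R x R matrix with 0 diagonal.
#' @export
connections_to_matrix <- function(values, n_roi) {
  stopifnot(length(values) == n_connections(n_roi))
  mat <- matrix(0, n_roi, n_roi)
  mat[lower.tri(mat)] <- values
  mat <- t(mat)
  mat[lower.tri(mat)] <- values
  mat
}

#' Assemble a cohort dataset
#'
#' Bundles phenotypes, per-subject connectivity and ROI geometry into the unit
#' the classifier consumes. Connectivity is held as an n_subjects x
#' n_connections matrix in the canonical connection order (one row per subject,
#' matching the phenotype rows).
#'
#' @param phenotypes Phenotype data.frame.
#' @param values n_subjects x n_connections numeric matrix of Fisher-z values.
#' @param rois ROI data.frame (roi_id, x, y, z).
#' @return An object of class `fcloo_cohort`.
#' @export
cohort_dataset <- function(phenotypes, values, rois) {
  stopifnot(is.data.frame(phenotypes), is.matrix(values))
  R <- nrow(rois)
  if (ncol(values) != n_connections(R)) {
    stop("values has ", ncol(values), " columns; expected n_connections(",
         R, ") = ", n_connections(R))
  }
  if (nrow(values) != nrow(phenotypes)) {
    stop("one connectivity row per phenotype record required")
  }
  if (!all(DIAGNOSIS_LEVELS %in% phenotypes$diagnosis)) {
    stop("both diagnoses must be present in a cohort")
  }
  if (length(unique(phenotypes$site)) < 2L) {
    warning("single-site cohort: site offsets will be 0")
  }
  if (any(!is.finite(values))) stop("non-finite connectivity values")
  structure(list(phenotypes = phenotypes, values = values, rois = rois),
            class = "fcloo_cohort")
}

#' @export
print.fcloo_cohort <- function(x, ...) {
  ph <- x$phenotypes
  cat("fcloo cohort: ", nrow(ph), " subjects (",
      sum(ph$diagnosis == "autism"), " autism / ",
      sum(ph$diagnosis == "control"), " control), ",
      length(unique(ph$site)), " site(s), ",
      nrow(x$rois), " ROIs, ",
      format_connection_count(nrow(x$rois)), " connections per subject\n",
      sep = "")
  invisible(x)
}

#' Extract one subject's association matrix
#'
#' @param cohort An `fcloo_cohort`.
#' @param subject Subject id or row index.
#' @return Symmetric R x R Fisher-z matrix.
#' @export
assoc_matrix <- function(cohort, subject) {
  i <- if (is.character(subject)) {
    match(subject, cohort$phenotypes$subject_id)
  } else as.integer(subject)
  if (is.na(i) || i < 1L || i > nrow(cohort$values)) stop("unknown subject")
  connections_to_matrix(cohort$values[i, ], nrow(cohort$rois))
}
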