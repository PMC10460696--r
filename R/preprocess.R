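#' Assemble the pooled study matrix
#'
#' Binds all images into one protein x voxel matrix over the study-wide
#' protein index. Proteins not quantified in an image are `NA` in all of that
#' image's voxels. Columns are named `"<image_id>_r<row>_c<col>"`.
#'
#' @param study A [voxel_study()].
#' @param metric Distance metric for the accompanying voxel table.
#' @return List with `abundance` (matrix, proteins x total voxels) and
#'   `voxels` (data.frame: `column`, `image_id`, `row`, `col`, `label`,
#'   `distance_um`).
#' @export
assemble_study <- function(study, metric = "euclidean_centroid_um") {
  stopifnot(inherits(study, "voxel_study"))
  idx <- study$protein_index
  mats <- lapply(study$images, function(im) {
    m <- matrix(NA_real_, length(idx), ncol(im$abundance),
                dimnames = list(idx, paste0(im$image_id, "_", colnames(im$abundance))))
    m[rownames(im$abundance), ] <- im$abundance
    m
  })
  ab <- do.call(cbind, unname(mats))
  meta <- voxel_metadata(study, metric)
  meta$column <- paste0(meta$image_id, sprintf("_r%d_c%d", meta$row, meta$col))
  stopifnot(identical(meta$column, colnames(ab)))
  list(abundance = ab,
       voxels = meta[, c("column", "image_id", "row", "col", "label", "distance_um")])
}

#' Missingness accounting per voxel and per image
#'
#' Counts missing entries per voxel over the study-wide protein index (a
#' protein absent from an entire image is missing in each of its voxels) and
#' summarises each image by the median of its per-voxel counts.
#'
#' @param study A [voxel_study()].
#' @return List with `voxels` (data.frame: `image_id`, `row`, `col`,
#'   `n_missing`, `fraction_missing`) and `images` (data.frame: `image_id`,
#'   `median_n_missing`, `median_fraction_missing`).
#' @export
missingness_summary <- function(study) {
  if (!inherits(study, "voxel_study") || length(study$images) == 0L)
    stop("`study` must be a non-empty voxel_study", call. = FALSE)
  asm <- assemble_study(study)
  n_prot <- nrow(asm$abundance)
  vox <- asm$voxels
  vox$n_missing <- colSums(is.na(asm$abundance))
  vox$fraction_missing <- vox$n_missing / n_prot
  per_image <- vapply(split(vox$n_missing, vox$image_id), stats::median, numeric(1L))
  per_image <- per_image[unique(vox$image_id)]
  list(voxels = vox[, c("image_id", "row", "col", "n_missing", "fraction_missing")],
       images = data.frame(image_id = names(per_image),
                           median_n_missing = unname(per_image),
                           median_fraction_missing = unname(per_image) / n_prot,
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' Impute missing values with the protein-wise median
#'
#' Every missing entry of a protein is replaced by the median of that
#' protein's observed values pooled across all voxels of all images; observed
#' entries are never changed, so the operation is idempotent. Even-count
#' medians are the midpoint of the central pair. Proteins observed nowhere
#' cannot be imputed; they are dropped with a warning.
#'
#' No cross-plex centering is applied here or anywhere else in the default
#' pipeline; per-plex median centering is available separately via
#' [median_center_plexes()] for users who want to evaluate it.
#'
#' @param x A numeric matrix (proteins x voxels, `NA` = missing) or a
#'   [voxel_study()] (assembled with [assemble_study()] first).
#' @param ... Unused.
#' @return Completed numeric matrix with the same dimnames (minus any
#'   dropped all-missing proteins).
#' @export
impute_median <- function(x, ...) UseMethod("impute_median")

#' @export
impute_median.matrix <- function(x, ...) {
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warning(sprintf("dropping %d protein(s) observed in no voxel: %s",
                    sum(all_missing),
                    paste(utils::head(rownames(x)[all_missing], 5L), collapse = ", ")),
            call. = FALSE)
    x <- x[!all_missing, , drop = FALSE]
  }
  med <- apply(x, 1L, stats::median, na.rm = TRUE)
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss) > 0L) x[miss] <- med[miss[, 1L]]
  x
}

#' @export
impute_median.voxel_study <- function(x, ...) {
  impute_median(assemble_study(x)$abundance)
}

#' Median-center each plex
#'
#' Subtracts each image's median observed log2 value from all of its voxels.
#' This cross-plex centering is deliberately OFF in the default pipeline
#' (batch structure is instead handled by the image covariate in the
#' differential model); the function exists so the evaluation that led to
#' that choice can be reproduced.
#'
#' @param mat Protein x voxel matrix.
#' @param image_ids Character vector, the image of each column.
#' @return Matrix of the same shape.
#' @export
median_center_plexes <- function(mat, image_ids) {
  stopifnot(is.matrix(mat), length(image_ids) == ncol(mat))
  for (im in unique(image_ids)) {
    cols <- image_ids == im
    mat[, cols] <- mat[, cols] - stats::median(mat[, cols], na.rm = TRUE)
  }
  mat
}

#' PCA embedding of voxels
#'
#' Scores each voxel (column) on the first `k` principal components of the
#' completed matrix, mean-centered per protein, ordered by decreasing
#' explained variance.
#'
#' @param mat Completed (no missing entries) protein x voxel matrix.
#' @param k Number of components (default 2).
#' @return List with `scores` (voxels x k matrix), `var_explained`
#'   (fractions for all returned components; sums to 1) and `k`.
#' @export
pca_embedding <- function(mat, k = 2L) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix must be completed (no missing values) before PCA",
                       call. = FALSE)
  k <- as.integer(k)
  if (k > ncol(mat))
    stop(sprintf("requested %d components for %d voxels", k, ncol(mat)), call. = FALSE)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], var_explained = ve, k = k)
}
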