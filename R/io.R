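#' Write a study to a matrix TSV and a voxel metadata TSV
#'
#' The abundance matrix is written proteins x voxels with columns named
#' `"<image_id>_r<row>_c<col>"`; missing values are written as `NA`. The
#' metadata sidecar holds one row per voxel: image_id, row, col, label,
#' distance_um plus the voxel pitch.
#'
#' @param study A [voxel_study()].
#' @param matrix_file,metadata_file Output paths.
#' @param metric Distance metric for the metadata.
#' @return Invisibly, the two paths.
#' @export
write_study <- function(study, matrix_file, metadata_file,
                        metric = "euclidean_centroid_um") {
  asm <- assemble_study(study, metric)
  mat <- data.frame(protein = rownames(asm$abundance), asm$abundance,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(voxel_metadata(study, metric), metadata_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_file, metadata_file))
}

#' Read a study from a matrix TSV and a voxel metadata TSV
#'
#' Validates that matrix columns and metadata rows agree, that protein ids
#' are unique, and that every image has exactly one islet voxel. Empty cells
#' and `"NA"` are both read as missing.
#'
#' @param matrix_file Proteins x voxels TSV (first column `protein`).
#' @param metadata_file Voxel metadata TSV (see [voxel_metadata()]).
#' @param connectivity Annotation connectivity for the reconstructed grids.
#' @return A [voxel_study()].
#' @export
read_study <- function(matrix_file, metadata_file,
                       connectivity = c("8-neighbor", "4-neighbor")) {
  connectivity <- match.arg(connectivity)
  raw <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (names(raw)[1L] != "protein")
    stop("matrix file must have 'protein' as its first column", call. = FALSE)
  if (anyDuplicated(raw$protein))
    stop(sprintf("duplicated protein row(s) in matrix file: %s",
                 paste(unique(raw$protein[duplicated(raw$protein)]), collapse = ", ")),
         call. = FALSE)
  ab <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(ab) <- raw$protein
  meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col", "label")
  if (!all(need %in% names(meta)))
    stop(sprintf("metadata file must contain columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  meta$column <- paste0(meta$image_id, sprintf("_r%d_c%d", meta$row, meta$col))
  if (!identical(sort(meta$column), sort(colnames(ab))))
    stop("matrix columns and metadata voxels do not match", call. = FALSE)
  problems <- character(0)
  images <- lapply(unique(meta$image_id), function(im) {
    sub <- meta[meta$image_id == im, , drop = FALSE]
    islet <- sub[sub$label == "islet", , drop = FALSE]
    if (nrow(islet) != 1L) {
      problems <<- c(problems, sprintf("image '%s' has %d islet voxels", im, nrow(islet)))
      return(NULL)
    }
    grid <- voxel_grid(max(sub$row) + 1L, max(sub$col) + 1L,
                       islet = c(islet$row, islet$col),
                       voxel_width_um = if ("voxel_width_um" %in% names(sub))
                         sub$voxel_width_um[1L] else 200,
                       voxel_height_um = if ("voxel_height_um" %in% names(sub))
                         sub$voxel_height_um[1L] else 300)
    vc <- voxel_coords(grid)
    cols <- paste0(im, "_", vc$voxel)
    missing_cols <- setdiff(cols, colnames(ab))
    if (length(missing_cols)) {
      problems <<- c(problems, sprintf("image '%s' is not a complete %d x %d grid",
                                       im, grid$n_rows, grid$n_cols))
      return(NULL)
    }
    m <- ab[, cols, drop = FALSE]
    colnames(m) <- vc$voxel
    m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
    proteome_image(im, m, grid, connectivity)
  })
  if (length(problems))
    stop(paste(c("study validation failed:", problems), collapse = "\n  "),
         call. = FALSE)
  voxel_study(images)
}

#' Write a ground-truth table
#'
#' @param truth The `truth` element of [generate_study()].
#' @param path Output TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$classes
  df$plex_shift <- NA_real_
  utils::write.table(df[, c("protein", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
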