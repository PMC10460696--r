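#' Voxel grid geometry for one proteome image
#'
#' A proteome image is a rectangular grid of laser-dissected tissue voxels
#' (default 3 x 3) in which exactly one voxel contains the islet. Voxel pitch
#' defaults to the dissection size of roughly 200 um x 300 um per voxel.
#' Coordinates are 0-based `(row, col)`, row-major.
#'
#' @param n_rows,n_cols Grid dimensions (default 3 x 3).
#' @param islet Integer vector `c(row, col)` of the islet-containing voxel,
#'   0-based.
#' @param voxel_width_um,voxel_height_um Physical voxel pitch in micrometres
#'   (column and row direction respectively); must be strictly positive.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(islet = c(0, 1))
#' table(annotate_voxels(g))
#' @export
voxel_grid <- function(n_rows = 3L, n_cols = 3L, islet = c(0L, 1L),
                       voxel_width_um = 200, voxel_height_um = 300) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!(is.numeric(voxel_width_um) && voxel_width_um > 0) ||
      !(is.numeric(voxel_height_um) && voxel_height_um > 0))
    stop("voxel dimensions must be strictly positive", call. = FALSE)
  islet <- as.integer(islet)
  if (length(islet) != 2L || anyNA(islet))
    stop("`islet` must be an integer (row, col) pair", call. = FALSE)
  if (islet[1L] < 0L || islet[1L] >= n_rows || islet[2L] < 0L || islet[2L] >= n_cols)
    stop(sprintf("islet coordinate (%d, %d) lies outside the %d x %d grid",
                 islet[1L], islet[2L], n_rows, n_cols), call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, islet = islet,
         voxel_width_um = voxel_width_um, voxel_height_um = voxel_height_um),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d, voxel %g x %g um, islet at (%d, %d)\n",
              x$n_rows, x$n_cols, x$voxel_width_um, x$voxel_height_um,
              x$islet[1L], x$islet[2L]))
  invisible(x)
}

#' Row-major voxel coordinate table for a grid
#'
#' @param grid A [voxel_grid()].
#' @return A data.frame with columns `row`, `col` (0-based) and `voxel`
#'   (name `"r<row>_c<col>"`), one row per voxel in row-major order.
#' @export
voxel_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  row <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  data.frame(row = row, col = col,
             voxel = sprintf("r%d_c%d", row, col),
             stringsAsFactors = FALSE)
}

#' Annotate voxels as islet / proximal / distal
#'
#' The islet-containing voxel is labelled `islet`, voxels adjacent to it under
#' the chosen connectivity are `proximal`, and all remaining voxels `distal`.
#' With 8-connectivity and an islet voxel in the middle of a grid edge this
#' yields the canonical 1 islet / 5 proximal / 3 distal split of a 3 x 3
#' image.
#'
#' @param grid A [voxel_grid()].
#' @param connectivity `"8-neighbor"` (default; diagonals are adjacent) or
#'   `"4-neighbor"`.
#' @return A factor of length `n_rows * n_cols` with levels
#'   `islet`, `proximal`, `distal`, named by voxel (`"r<row>_c<col>"`),
#'   row-major.
#' @export
annotate_voxels <- function(grid, connectivity = c("8-neighbor", "4-neighbor")) {
  stopifnot(inherits(grid, "voxel_grid"))
  connectivity <- match.arg(connectivity)
  vc <- voxel_coords(grid)
  dr <- abs(vc$row - grid$islet[1L])
  dc <- abs(vc$col - grid$islet[2L])
  adjacent <- if (connectivity == "8-neighbor") {
    pmax(dr, dc) == 1L
  } else {
    dr + dc == 1L
  }
  lab <- ifelse(dr == 0L & dc == 0L, "islet",
                ifelse(adjacent, "proximal", "distal"))
  stats::setNames(factor(lab, levels = c("islet", "proximal", "distal")),
                  vc$voxel)
}

#' Distance of every voxel to the islet voxel
#'
#' @param grid A [voxel_grid()].
#' @param metric `"euclidean_centroid_um"` (default): Euclidean distance
#'   between voxel centroids using the physical voxel pitch, in micrometres;
#'   or `"grid_chebyshev"`: Chebyshev (chessboard) distance in grid units.
#' @return Named numeric vector (names `"r<row>_c<col>"`, row-major); zero
#'   exactly at the islet voxel.
#' @export
voxel_distances <- function(grid, metric = c("euclidean_centroid_um", "grid_chebyshev")) {
  stopifnot(inherits(grid, "voxel_grid"))
  metric <- match.arg(metric)
  vc <- voxel_coords(grid)
  dr <- vc$row - grid$islet[1L]
  dc <- vc$col - grid$islet[2L]
  d <- switch(metric,
    euclidean_centroid_um = sqrt((dc * grid$voxel_width_um)^2 +
                                 (dr * grid$voxel_height_um)^2),
    grid_chebyshev = pmax(abs(dr), abs(dc))
  )
  stats::setNames(d, vc$voxel)
}

#' Distance of one voxel to the islet voxel
#'
#' @inheritParams voxel_distances
#' @param voxel Integer `c(row, col)` coordinate, 0-based.
#' @return Non-negative scalar distance.
#' @export
voxel_distance <- function(grid, voxel, metric = c("euclidean_centroid_um", "grid_chebyshev")) {
  stopifnot(inherits(grid, "voxel_grid"))
  voxel <- as.integer(voxel)
  if (length(voxel) != 2L || anyNA(voxel) ||
      voxel[1L] < 0L || voxel[1L] >= grid$n_rows ||
      voxel[2L] < 0L || voxel[2L] >= grid$n_cols)
    stop("`voxel` must be a valid (row, col) coordinate on the grid", call. = FALSE)
  unname(voxel_distances(grid, metric)[sprintf("r%d_c%d", voxel[1L], voxel[2L])])
}

#' Construct a proteome image
#'
#' One TMT plex: a voxel grid with a protein x voxel matrix of log2 reporter
#' abundances (missing entries `NA`) and the region annotation derived from
#' the islet position.
#'
#' @param image_id Character scalar identifier, unique within a study.
#' @param abundance Numeric matrix, proteins x voxels. Column names must be
#'   the row-major voxel names `"r<row>_c<col>"` of `grid`; row names are the
#'   protein identifiers (unique).
#' @param grid A [voxel_grid()].
#' @param connectivity Passed to [annotate_voxels()].
#' @return An object of class `proteome_image` with elements `image_id`,
#'   `grid`, `abundance`, `labels` (factor per voxel) and `connectivity`.
#' @export
proteome_image <- function(image_id, abundance, grid,
                           connectivity = c("8-neighbor", "4-neighbor")) {
  connectivity <- match.arg(connectivity)
  stopifnot(inherits(grid, "voxel_grid"), is.matrix(abundance))
  if (!is.character(image_id) || length(image_id) != 1L || is.na(image_id) ||
      !nzchar(image_id))
    stop("`image_id` must be a non-empty character scalar", call. = FALSE)
  vc <- voxel_coords(grid)
  if (ncol(abundance) != nrow(vc))
    stop(sprintf("image '%s': %d abundance columns for %d grid voxels",
                 image_id, ncol(abundance), nrow(vc)), call. = FALSE)
  if (is.null(colnames(abundance)) || !identical(colnames(abundance), vc$voxel))
    stop(sprintf("image '%s': abundance columns must be named %s",
                 image_id, paste(vc$voxel, collapse = ", ")), call. = FALSE)
  if (is.null(rownames(abundance)))
    stop(sprintf("image '%s': abundance rows must be named by protein", image_id),
         call. = FALSE)
  if (anyDuplicated(rownames(abundance)))
    stop(sprintf("image '%s': duplicated protein identifiers: %s", image_id,
                 paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
                       collapse = ", ")), call. = FALSE)
  structure(
    list(image_id = image_id, grid = grid, abundance = abundance,
         labels = annotate_voxels(grid, connectivity),
         connectivity = connectivity),
    class = "proteome_image"
  )
}

#' @export
print.proteome_image <- function(x, ...) {
  cat(sprintf("<proteome_image> '%s': %d proteins x %d voxels (%d missing), islet at (%d, %d)\n",
              x$image_id, nrow(x$abundance), ncol(x$abundance),
              sum(is.na(x$abundance)), x$grid$islet[1L], x$grid$islet[2L]))
  invisible(x)
}

#' Construct a study from a collection of proteome images
#'
#' The study is the unit of pooled inference: its protein index is the union
#' of protein identifiers across images, and all downstream stages operate on
#' the pooled protein x voxel matrix.
#'
#' @param images List of [proteome_image()] objects with unique `image_id`s.
#' @return An object of class `voxel_study` with elements `images` (named
#'   list) and `protein_index` (sorted character vector).
#' @export
voxel_study <- function(images) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list of proteome_image objects", call. = FALSE)
  ok <- vapply(images, inherits, logical(1L), what = "proteome_image")
  if (!all(ok))
    stop("all elements of `images` must be proteome_image objects", call. = FALSE)
  ids <- vapply(images, function(im) im$image_id, character(1L))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated image_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  names(images) <- ids
  protein_index <- sort(unique(unlist(lapply(images, function(im) rownames(im$abundance)),
                                      use.names = FALSE)))
  structure(list(images = images, protein_index = protein_index),
            class = "voxel_study")
}

#' @export
print.voxel_study <- function(x, ...) {
  nv <- sum(vapply(x$images, function(im) ncol(im$abundance), integer(1L)))
  cat(sprintf("<voxel_study> %d images, %d voxels, %d proteins in the union index\n",
              length(x$images), nv, length(x$protein_index)))
  invisible(x)
}

#' Per-voxel metadata table for a study
#'
#' @param study A [voxel_study()].
#' @param metric Distance metric passed to [voxel_distances()].
#' @return A data.frame with one row per voxel: `image_id`, `row`, `col`,
#'   `label`, `distance_um`, plus the voxel pitch columns `voxel_width_um`
#'   and `voxel_height_um` so the geometry round-trips through file I/O.
#' @export
voxel_metadata <- function(study, metric = "euclidean_centroid_um") {
  stopifnot(inherits(study, "voxel_study"))
  do.call(rbind, lapply(study$images, function(im) {
    vc <- voxel_coords(im$grid)
    data.frame(image_id = im$image_id, row = vc$row, col = vc$col,
               label = as.character(im$labels),
               distance_um = unname(voxel_distances(im$grid, metric)),
               voxel_width_um = im$grid$voxel_width_um,
               voxel_height_um = im$grid$voxel_height_um,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
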