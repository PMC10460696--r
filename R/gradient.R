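#' Per-protein variance scores
#'
#' Sample variance (n - 1 denominator) of each protein across all voxels of
#' the completed study matrix; ranking proteins by this score and running
#' [enrichment_in_order()] identifies the pathways whose members vary most
#' across the images.
#'
#' @param mat Completed protein x voxel matrix (>= 2 voxels).
#' @return Named numeric vector of variances.
#' @export
protein_variance_scores <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L)
    stop("need at least 2 voxels to compute variances", call. = FALSE)
  apply(mat, 1L, stats::var)
}

# cache for permutation-index matrices and exact Spearman null distributions
.perm_cache <- new.env(parent = emptyenv())

# all n! permutations of 1..n as an (n! x n) integer matrix, cached
perm_index_matrix <- function(n) {
  key <- sprintf("perms_%d", n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1L, 1L)
  if (n > 1L) {
    for (k in 2L:n) {
      P <- do.call(rbind, lapply(seq_len(k), function(pos) {
        if (pos == 1L) cbind(k, P)
        else if (pos == k) cbind(P, k)
        else cbind(P[, seq_len(pos - 1L), drop = FALSE], k,
                   P[, pos:(k - 1L), drop = FALSE])
      }))
    }
  }
  storage.mode(P) <- "integer"
  .perm_cache[[key]] <- P
  P
}

# sorted |rho| over all n! pairings of the rank vectors rx and rd (exact
# permutation null of the Spearman correlation, valid under ties via
# mid-ranks); depends only on the multisets of rx and rd, which keys the cache
spearman_null_abs <- function(rx, rd) {
  n <- length(rx)
  key <- paste("null", n, paste(signif(sort(rx), 12), collapse = ","),
               paste(signif(sort(rd), 12), collapse = ","), sep = "|")
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- perm_index_matrix(n)
  rdc <- rd - mean(rd)
  rxc <- rx - mean(rx)
  denom <- sqrt(sum(rxc^2) * sum(rdc^2))
  V <- matrix(rx[P], nrow(P), n)
  rho <- as.numeric((V %*% rdc) / denom)
  out <- sort(abs(rho))
  .perm_cache[[key]] <- out
  out
}

#' Exact permutation test for a Spearman correlation
#'
#' Spearman rho between `x` and `d` (mid-ranks under ties) with a two-sided
#' p-value obtained by full enumeration of all `n!` orderings when
#' `n <= exact_max_n`, and by the t-approximation with `n - 2` df otherwise.
#' Nine voxels are far below the asymptotic regime, hence the exact default.
#'
#' @param x,d Numeric vectors of equal length `n >= 3`.
#' @param exact_max_n Largest `n` for exact enumeration (default 9; `9! =
#'   362880` orderings).
#' @return List with `rho`, `p`, `stat` (signed normal quantile of the
#'   two-sided p, the "z-score of the test statistic" used as the protein
#'   score downstream), `n` and `method`.
#' @export
spearman_perm_test <- function(x, d, exact_max_n = 9L) {
  keep <- !is.na(x) & !is.na(d)
  x <- x[keep]; d <- d[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(d) == 0) stop("distances are all constant", call. = FALSE)
  if (stats::var(x) == 0)
    return(list(rho = NA_real_, p = NA_real_, stat = NA_real_, n = n,
                method = "constant"))
  rx <- rank(x); rd <- rank(d)
  rho <- stats::cor(rx, rd)
  if (n <= exact_max_n) {
    null_abs <- spearman_null_abs(rx, rd)
    nperm <- length(null_abs)
    p <- (nperm - findInterval(abs(rho) - 1e-10, null_abs)) / nperm
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  stat <- sign(rho) * stats::qnorm(1 - p / 2)
  list(rho = rho, p = p, stat = stat, n = n, method = method)
}

#' Distance correlation of every protein in one image
#'
#' Spearman rank correlation of each protein's abundance with the voxel
#' distance to the islet voxel, with exact permutation p-values (see
#' [spearman_perm_test()]). Proteins with fewer than 3 observed voxels or
#' zero abundance variance are returned with `NA` statistics and flagged.
#'
#' @param image A [proteome_image()], or a numeric matrix (proteins x voxels)
#'   supplied together with `distances`.
#' @param metric Distance metric (see [voxel_distances()]); ignored when
#'   `distances` is given.
#' @param distances Optional numeric vector of per-voxel distances overriding
#'   the grid geometry.
#' @param image_id Identifier used in the output when `image` is a bare
#'   matrix.
#' @return A `distance_corr` data.frame: `image_id`, `protein`, `rho`,
#'   `stat`, `p`, `n`, `flag` (`"ok"`, `"constant"` or `"too_few"`).
#' @export
distance_correlation <- function(image, metric = "euclidean_centroid_um",
                                 distances = NULL, image_id = "image") {
  if (inherits(image, "proteome_image")) {
    mat <- image$abundance
    if (is.null(distances)) distances <- voxel_distances(image$grid, metric)
    image_id <- image$image_id
  } else {
    mat <- image
    if (is.null(distances))
      stop("`distances` must be supplied when `image` is a matrix", call. = FALSE)
  }
  stopifnot(is.matrix(mat), length(distances) == ncol(mat))
  if (stats::var(distances) == 0)
    stop("distances are all constant", call. = FALSE)
  np <- nrow(mat)
  nv <- ncol(mat)
  n_obs <- rowSums(!is.na(mat))
  rho <- p <- rep(NA_real_, np)
  flag <- rep("ok", np)
  flag[n_obs < 3L] <- "too_few"
  row_var <- apply(mat, 1L, function(x) stats::var(x[!is.na(x)]))
  flag[flag == "ok" & row_var == 0] <- "constant"
  scored <- which(flag == "ok")

  # fast vectorized path for fully observed proteins: Spearman rho from row
  # ranks; exact p via the shared permutation null (all untied rank rows share
  # one null distribution), tie patterns fall through to the general test
  complete_rows <- scored[n_obs[scored] == nv]
  if (length(complete_rows) && nv <= 9L) {
    R <- t(apply(mat[complete_rows, , drop = FALSE], 1L, rank))
    rd <- rank(distances)
    rdc <- rd - mean(rd)
    Rc <- R - rowMeans(R)
    rr <- as.numeric((Rc %*% rdc) / (sqrt(rowSums(Rc^2)) * sqrt(sum(rdc^2))))
    rho[complete_rows] <- rr
    tied <- apply(R, 1L, anyDuplicated) > 0L
    if (any(!tied)) {
      null_abs <- spearman_null_abs(seq_len(nv), rd)
      nperm <- length(null_abs)
      p[complete_rows[!tied]] <-
        (nperm - findInterval(abs(rr[!tied]) - 1e-10, null_abs)) / nperm
    }
    for (i in complete_rows[tied])
      p[i] <- spearman_perm_test(mat[i, ], distances)$p
  }
  remaining <- scored[is.na(p[scored])]
  for (i in remaining) {
    st <- spearman_perm_test(mat[i, ], distances)
    rho[i] <- st$rho
    p[i] <- st$p
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(image_id = image_id, protein = rownames(mat), rho = rho,
                    stat = sign(rho) * stats::qnorm(1 - p / 2), p = p,
                    n = n_obs, flag = flag, stringsAsFactors = FALSE)
  out$stat[is.na(rho)] <- NA_real_
  out$p[flag != "ok"] <- NA_real_
  class(out) <- c("distance_corr", "data.frame")
  out
}

#' Per-image rank enrichment of the distance-correlation statistic
#'
#' Runs [distance_correlation()] on every image of a completed study and
#' feeds each image's signed correlation statistics into
#' [enrichment_in_order()]. Constant or under-observed proteins are excluded
#' from the ranking.
#'
#' @param completed Completed study matrix from [impute_median()].
#' @param voxels Voxel table from [assemble_study()] (columns `column`,
#'   `image_id`, `distance_um`).
#' @param pathways Named list of pathway sets.
#' @return List with `correlations` (pooled `distance_corr` table) and
#'   `enrichments` (named list of per-image `enrichment_result`s).
#' @export
image_distance_enrichments <- function(completed, voxels, pathways) {
  stopifnot(is.matrix(completed), all(colnames(completed) == voxels$column))
  imgs <- unique(voxels$image_id)
  corrs <- list(); enr <- list()
  for (im in imgs) {
    cols <- voxels$image_id == im
    dc <- distance_correlation(completed[, cols, drop = FALSE],
                               distances = voxels$distance_um[cols], image_id = im)
    corrs[[im]] <- dc
    ok <- dc$flag == "ok"
    enr[[im]] <- enrichment_in_order(stats::setNames(dc$stat[ok], dc$protein[ok]),
                                     pathways)
  }
  corr <- do.call(rbind, corrs)
  rownames(corr) <- NULL
  class(corr) <- c("distance_corr", "data.frame")
  list(correlations = corr, enrichments = enr)
}

#' Cross-image consensus of distance-enriched pathways
#'
#' A pathway is flagged when its rank enrichment is significant (BH-adjusted
#' p < `alpha` within each image by default; set `use_adjusted = FALSE` for
#' raw p) in at least `min_images` of the images.
#'
#' @param enrichments Named list of per-image `enrichment_result`s from
#'   [image_distance_enrichments()].
#' @param alpha Per-image significance level (default 0.05).
#' @param min_images Minimum number of significant images (default 4).
#' @param use_adjusted Use BH-adjusted per-image p-values (default TRUE).
#' @return A `consensus_result` list: `summary` (data.frame: `set`,
#'   `n_significant`, `flagged`), `z` and `p` (pathway x image matrices; `p`
#'   holds the per-image p-values actually thresholded).
#' @export
consensus_pathways <- function(enrichments, alpha = 0.05, min_images = 4L,
                               use_adjusted = TRUE) {
  n_images <- length(enrichments)
  if (min_images > n_images)
    stop(sprintf("min_images (%d) exceeds the number of images (%d)",
                 min_images, n_images), call. = FALSE)
  sets <- unique(unlist(lapply(enrichments, function(e) e$set), use.names = FALSE))
  zmat <- pmat <- matrix(NA_real_, length(sets), n_images,
                         dimnames = list(sets, names(enrichments)))
  for (im in names(enrichments)) {
    e <- enrichments[[im]]
    zmat[e$set, im] <- e$z
    pmat[e$set, im] <- if (use_adjusted) e$adj_p else e$p
  }
  n_sig <- rowSums(pmat < alpha, na.rm = TRUE)
  summary <- data.frame(set = sets, n_significant = as.integer(n_sig),
                        flagged = n_sig >= min_images,
                        stringsAsFactors = FALSE, row.names = NULL)
  summary <- summary[order(-summary$n_significant, summary$set), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary, z = zmat, p = pmat,
                 alpha = alpha, min_images = as.integer(min_images)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d pathways x %d images; %d flagged (significant in >= %d images at alpha = %g)\n",
              nrow(x$z), ncol(x$z), sum(x$summary$flagged), x$min_images, x$alpha))
  invisible(x)
}

#' Abundance-by-distance profiles of a pathway's correlated proteins
#'
#' For a chosen pathway, returns — per image — the member proteins whose raw
#' distance-correlation p is below `p_threshold`, with their abundances
#' ordered by voxel distance (the data behind per-pathway profile plots).
#'
#' @param pathway Pathway name.
#' @param pathways Named list of pathway sets.
#' @param correlations Pooled `distance_corr` table.
#' @param completed Completed study matrix.
#' @param voxels Voxel table from [assemble_study()].
#' @param p_threshold Raw-p threshold (default 0.05).
#' @return Data.frame: `image_id`, `protein`, `distance_um`, `abundance`,
#'   `rho`, `p`, ordered by image, protein and distance.
#' @export
pathway_protein_profiles <- function(pathway, pathways, correlations, completed,
                                     voxels, p_threshold = 0.05) {
  if (!pathway %in% names(pathways))
    stop(sprintf("pathway '%s' not found in the collection", pathway), call. = FALSE)
  members <- pathways[[pathway]]
  hits <- correlations[correlations$protein %in% members &
                       !is.na(correlations$p) &
                       correlations$p < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(image_id = character(0), protein = character(0),
                      distance_um = numeric(0), abundance = numeric(0),
                      rho = numeric(0), p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    im <- hits$image_id[i]; pr <- hits$protein[i]
    cols <- voxels$image_id == im
    ord <- order(voxels$distance_um[cols])
    data.frame(image_id = im, protein = pr,
               distance_um = voxels$distance_um[cols][ord],
               abundance = completed[pr, voxels$column[cols][ord]],
               rho = hits$rho[i], p = hits$p[i],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out[order(out$image_id, out$protein, out$distance_um), , drop = FALSE]
}
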