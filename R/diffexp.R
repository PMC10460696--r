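#' Region contrasts supported by the pooled model
#'
#' @return Character vector of contrast names.
#' @export
region_contrasts <- function() {
  c("islet_vs_proximal", "islet_vs_distal", "islet_vs_rest", "proximal_vs_distal")
}

contrast_matrix <- function(contrasts) {
  defs <- list(
    islet_vs_proximal  = c(islet = 1, proximal = -1,   distal = 0),
    islet_vs_distal    = c(islet = 1, proximal = 0,    distal = -1),
    islet_vs_rest      = c(islet = 1, proximal = -0.5, distal = -0.5),
    proximal_vs_distal = c(islet = 0, proximal = 1,    distal = -1)
  )
  bad <- setdiff(contrasts, names(defs))
  if (length(bad))
    stop(sprintf("unknown contrast(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  do.call(cbind, defs[contrasts])
}

#' Pooled differential expression between region labels
#'
#' Fits, per protein, the linear model `abundance ~ region + image` by least
#' squares over all pooled voxels. The image/plex term absorbs the TMT batch
#' structure so that each image acts as a biological replicate for the region
#' effects (the islet region has only a single voxel per image). Per-protein
#' residual variances are shrunk towards a pooled prior with the standard
#' empirical-Bayes inverse-chi-square scheme (limma's moderated t); setting
#' `moderate = FALSE` gives ordinary t-statistics from the same fits.
#' P-values are adjusted per contrast with Benjamini-Hochberg.
#'
#' @param mat Completed protein x voxel matrix.
#' @param labels Region label per column (factor or character with values
#'   islet/proximal/distal).
#' @param image_ids Image/plex of each column.
#' @param contrasts Subset of [region_contrasts()] (default all four;
#'   `islet_vs_rest` compares islet against the mean of proximal and distal).
#' @param moderate Apply empirical-Bayes variance moderation (default TRUE).
#' @param include_image Include the image covariate (default TRUE). Omitting
#'   it is only useful to demonstrate the plex-shift miscalibration it
#'   prevents.
#' @return A `de_table` data.frame: `protein`, `contrast`, `logFC`, `t`, `p`,
#'   `adj_p`, `df_total`, `df_prior`.
#' @export
fit_region_model <- function(mat, labels, image_ids,
                             contrasts = region_contrasts(),
                             moderate = TRUE, include_image = TRUE) {
  stopifnot(is.matrix(mat), length(labels) == ncol(mat),
            length(image_ids) == ncol(mat))
  if (anyNA(mat))
    stop("matrix must be completed (impute first)", call. = FALSE)
  region <- factor(as.character(labels), levels = c("islet", "proximal", "distal"))
  if (anyNA(region))
    stop("labels must be islet/proximal/distal", call. = FALSE)
  image <- factor(image_ids)
  cm <- contrast_matrix(contrasts)
  used <- rownames(cm)[rowSums(cm != 0) > 0]
  for (lv in used) {
    imgs <- unique(image[region == lv])
    if (length(imgs) == 0L)
      stop(sprintf("design error: region level '%s' has no voxels", lv), call. = FALSE)
    if (include_image && nlevels(image) > 1L && length(imgs) == 1L)
      stop(sprintf("design error: region level '%s' is confounded with image '%s'",
                   lv, as.character(imgs)), call. = FALSE)
  }
  design <- if (include_image && nlevels(image) > 1L) {
    stats::model.matrix(~ 0 + region + image)
  } else {
    stats::model.matrix(~ 0 + region)
  }
  colnames(design) <- sub("^region", "", colnames(design))
  if (qr(design)$rank < ncol(design))
    stop("design error: design matrix is rank deficient (region confounded with image)",
         call. = FALSE)
  fit <- limma::lmFit(mat, design)
  cm_full <- matrix(0, ncol(design), ncol(cm),
                    dimnames = list(colnames(design), colnames(cm)))
  cm_full[rownames(cm), ] <- cm
  fit2 <- limma::contrasts.fit(fit, cm_full)

  if (moderate) {
    eb <- limma::eBayes(fit2)
    tt <- eb$t
    pp <- eb$p.value
    df_total <- rep(eb$df.total, length.out = nrow(mat))
    df_prior <- eb$df.prior
    s2 <- eb$s2.post
  } else {
    s2 <- fit2$sigma^2
    se <- sqrt(s2) * fit2$stdev.unscaled
    tt <- fit2$coefficients / se
    df_total <- fit2$df.residual
    pp <- 2 * stats::pt(-abs(tt), df = df_total)
    df_prior <- 0
  }
  # degenerate variances: zero residual variance is replaced by the prior
  # scale through moderation, but when that is itself (near) zero the t is
  # meaningless -- identical groups then give logFC 0 -> t = 0, p = 1
  degen <- (if (moderate) sqrt(s2) else fit2$sigma) < 1e-10
  bad <- !is.finite(tt) | matrix(degen, nrow(tt), ncol(tt))
  if (any(bad)) {
    zero_fc <- bad & abs(fit2$coefficients) < 1e-10
    tt[zero_fc] <- 0
    pp[zero_fc] <- 1
    inf_fc <- bad & !zero_fc
    tt[inf_fc] <- sign(fit2$coefficients[inf_fc]) * Inf
    pp[inf_fc] <- 0
  }
  out <- do.call(rbind, lapply(colnames(cm), function(cn) {
    data.frame(protein = rownames(mat), contrast = cn,
               logFC = fit2$coefficients[, cn], t = tt[, cn], p = pp[, cn],
               adj_p = stats::p.adjust(pp[, cn], method = "BH"),
               df_total = df_total,
               df_prior = rep(df_prior, length.out = nrow(mat)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("de_table", "data.frame")
  out
}

#' Significant proteins of one contrast
#'
#' @param de A `de_table` from [fit_region_model()].
#' @param contrast Contrast name.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @param direction `"both"`, `"up"` (logFC > 0) or `"down"` (logFC < 0).
#' @return Character vector of protein ids.
#' @export
significant_proteins <- function(de, contrast, threshold = 0.05,
                                 direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!contrast %in% de$contrast)
    stop(sprintf("unknown contrast '%s'", contrast), call. = FALSE)
  sub <- de[de$contrast == contrast & de$adj_p < threshold, , drop = FALSE]
  sub <- switch(direction, both = sub,
                up = sub[sub$logFC > 0, , drop = FALSE],
                down = sub[sub$logFC < 0, , drop = FALSE])
  sub$protein
}

#' Intersection counts of contrast significance sets (upset-style)
#'
#' For every non-empty combination of the given contrasts, counts the
#' proteins significant in exactly that combination; the counts therefore sum
#' to the size of the union of the significance sets.
#'
#' @param de A `de_table`.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @param contrasts Contrasts to include (default: all present in `de`).
#' @return Data.frame with `combination` (contrast names joined by `&`),
#'   `degree` and `count`, sorted by decreasing count.
#' @export
overlap_counts <- function(de, threshold = 0.05, contrasts = unique(de$contrast)) {
  bad <- setdiff(contrasts, unique(de$contrast))
  if (length(bad))
    stop(sprintf("unknown contrast(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  sets <- lapply(contrasts, function(cn) significant_proteins(de, cn, threshold))
  names(sets) <- contrasts
  universe <- unique(unlist(sets, use.names = FALSE))
  if (length(universe) == 0L)
    return(data.frame(combination = character(0), degree = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, contrasts))
  pattern <- apply(membership, 1L, function(z) paste(contrasts[z], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}
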