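#' Read a pathway collection from a GMT file
#'
#' @param path Path to a GMT file (tab-separated: set name, description,
#'   member ids...).
#' @param source Optional source tag (e.g. "KEGG", "Reactome", "GOBP",
#'   "synthetic") stored as an attribute.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path, source = NA_character_) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT file", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("GMT file contains empty sets", call. = FALSE)
  attr(sets, "source") <- source
  sets
}

#' Write a pathway collection to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (second GMT column; defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation (membership) enrichment of a selected protein set
#'
#' For each pathway, a one-sided hypergeometric test of over-representation
#' of the selected proteins among the pathway members, both restricted to the
#' quantified background. Sets with no member in the background are reported
#' untested (`NA` statistics) and excluded from the BH adjustment.
#'
#' @param selected Character vector of selected proteins; must be a subset of
#'   `background`.
#' @param background Character vector, the quantified-protein universe.
#' @param pathways Named list of character vectors (see [read_gmt()]).
#' @return An `enrichment_result` data.frame: `set`, `n_members_in_background`,
#'   `n_selected_in_set`, `expected`, `z`, `p`, `adj_p`, `direction`.
#' @export
enrichment_in_sets <- function(selected, background, pathways) {
  selected <- unique(selected)
  background <- unique(background)
  extra <- setdiff(selected, background)
  if (length(extra))
    stop(sprintf("`selected` must be a subset of `background` (%d offender(s), e.g. %s)",
                 length(extra), extra[1L]), call. = FALSE)
  N <- length(background)
  n_sel <- length(selected)
  rows <- lapply(names(pathways), function(nm) {
    members <- intersect(unique(pathways[[nm]]), background)
    m <- length(members)
    if (m == 0L)
      return(data.frame(set = nm, n_members_in_background = 0L,
                        n_selected_in_set = NA_integer_, expected = NA_real_,
                        z = NA_real_, p = NA_real_, direction = NA_character_,
                        stringsAsFactors = FALSE))
    k <- length(intersect(selected, members))
    expected <- n_sel * m / N
    vr <- n_sel * (m / N) * (1 - m / N) * (N - n_sel) / max(N - 1, 1)
    z <- if (vr > 0) (k - expected) / sqrt(vr) else 0
    p <- stats::phyper(k - 1L, m, N - m, n_sel, lower.tail = FALSE)
    data.frame(set = nm, n_members_in_background = m, n_selected_in_set = k,
               expected = expected, z = z, p = p,
               direction = if (k >= expected) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  tested <- !is.na(out$p)
  out$adj_p[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# tie-corrected normal-approximation rank-sum z for the in-set ranks;
# positive z = in-set proteins concentrated at high scores
rank_sum_z <- function(ranks_in_set, all_ranks) {
  N <- length(all_ranks)
  m <- length(ranks_in_set)
  n_out <- N - m
  W <- sum(ranks_in_set)
  mu <- m * (N + 1) / 2
  ties <- table(all_ranks)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  vr <- m * n_out / 12 * ((N + 1) - tie_term)
  if (vr <= 0) return(c(z = 0, W = W))
  c(z = (W - mu) / sqrt(vr), W = W)
}

#' Rank-ordered enrichment of a per-protein scoring
#'
#' Proteins are ranked by score (mid-ranks for ties); for each pathway the
#' in-set ranks are compared with the out-of-set ranks by a tie-corrected
#' normal-approximation rank-sum test. The signed z is positive when in-set
#' proteins concentrate at high scores; p-values are two-sided and
#' BH-adjusted across tested sets. Sets with fewer than 2 scored members (or
#' fewer than 2 scored non-members) are skipped with a warning.
#'
#' @param scores Named numeric vector of per-protein scores (>= 2 proteins).
#' @param pathways Named list of character vectors.
#' @return An `enrichment_result` data.frame: `set`, `n_members_in_background`,
#'   `mean_rank`, `z`, `p`, `adj_p`, `direction`.
#' @export
enrichment_in_order <- function(scores, pathways) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L)
    stop("need scores for at least 2 proteins", call. = FALSE)
  ranks <- rank(scores)  # mid-ranks for ties
  N <- length(ranks)
  skipped <- character(0)
  rows <- lapply(names(pathways), function(nm) {
    members <- intersect(unique(pathways[[nm]]), names(scores))
    m <- length(members)
    if (m < 2L || N - m < 2L) {
      skipped <<- c(skipped, nm)
      return(data.frame(set = nm, n_members_in_background = m,
                        mean_rank = NA_real_, z = NA_real_, p = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    }
    rs <- rank_sum_z(ranks[members], ranks)
    z <- unname(rs["z"])
    data.frame(set = nm, n_members_in_background = m,
               mean_rank = unname(rs["W"]) / m, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               direction = if (z >= 0) "high" else "low",
               stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning(sprintf("skipped %d set(s) with < 2 scored members or non-members: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5L), collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  tested <- !is.na(out$p)
  out$adj_p[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}
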