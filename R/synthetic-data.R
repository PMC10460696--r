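#' Configuration for the synthetic study generator
#'
#' The defaults emulate the structure of the real study: seven images, each a
#' 3 x 3 grid with the islet voxel at an edge-middle position, ~2000 proteins
#' with a small fraction of islet markers (elevated only in the islet voxel)
#' and of distance-gradient proteins (abundance varying linearly with the
#' physical distance to the islet), a per-plex location shift, Gaussian
#' measurement noise, and abundance-dependent (left-censoring flavoured)
#' missingness.
#'
#' @param n_images Number of images / TMT plexes (default 7).
#' @param n_proteins Number of proteins (default 2000).
#' @param frac_islet_markers Fraction of proteins that are islet markers
#'   (default 0.02).
#' @param frac_gradient Fraction of proteins with a distance gradient
#'   (default 0.05).
#' @param islet_effect Log2 elevation of markers in the islet voxel
#'   (default 2.0).
#' @param gradient_slope Log2 change per micrometre of distance for gradient
#'   proteins (default -0.002, i.e. decreasing away from the islet; the sign
#'   is configurable).
#' @param plex_shift_sd SD of the per-image plex location shift, log2 units
#'   (default 0.3).
#' @param noise_sd SD of per-entry Gaussian noise, log2 units (default 0.5).
#' @param missing_rate_base Missingness probability at the baseline reference
#'   abundance (default 0.02).
#' @param missing_abundance_coupling Logistic slope coupling missingness to
#'   low true abundance, per log2 unit (default 0.8; 0 gives MCAR).
#' @param baseline_sd SD of per-protein baseline log2 abundances (default 1.2).
#' @param seed Integer seed; one global seed drives all generators, with
#'   per-image substreams derived deterministically from it.
#' @param n_rows,n_cols,voxel_width_um,voxel_height_um Grid geometry, passed
#'   to [voxel_grid()].
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 7L, n_proteins = 2000L,
                             frac_islet_markers = 0.02, frac_gradient = 0.05,
                             islet_effect = 2.0, gradient_slope = -0.002,
                             plex_shift_sd = 0.3, noise_sd = 0.5,
                             missing_rate_base = 0.02,
                             missing_abundance_coupling = 0.8,
                             baseline_sd = 1.2, seed = 1L,
                             n_rows = 3L, n_cols = 3L,
                             voxel_width_um = 200, voxel_height_um = 300) {
  cfg <- list(n_images = as.integer(n_images), n_proteins = as.integer(n_proteins),
              frac_islet_markers = frac_islet_markers, frac_gradient = frac_gradient,
              islet_effect = islet_effect, gradient_slope = gradient_slope,
              plex_shift_sd = plex_shift_sd, noise_sd = noise_sd,
              missing_rate_base = missing_rate_base,
              missing_abundance_coupling = missing_abundance_coupling,
              baseline_sd = baseline_sd, seed = as.integer(seed),
              n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              voxel_width_um = voxel_width_um, voxel_height_um = voxel_height_um)
  if (cfg$n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  for (f in c("frac_islet_markers", "frac_gradient", "missing_rate_base")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must be a proportion in [0, 1]", f), call. = FALSE)
  }
  if (cfg$frac_islet_markers + cfg$frac_gradient > 1)
    stop("frac_islet_markers + frac_gradient must be <= 1", call. = FALSE)
  for (f in c("plex_shift_sd", "noise_sd", "baseline_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("%s must be >= 0", f), call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic per-stream sub-seed derived from the global seed, kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) %% 65011 * 33029 + stream * 7919) %% 2147483647)
}

# edge-middle islet positions of a grid (falls back to any non-corner border
# voxel on grids without exact edge middles)
edge_middle_positions <- function(n_rows, n_cols) {
  mr <- (n_rows - 1L) %/% 2L
  mc <- (n_cols - 1L) %/% 2L
  pos <- list(c(0L, mc), c(mr, 0L), c(mr, n_cols - 1L), c(n_rows - 1L, mc))
  unique(pos)
}

#' Generate a synthetic study with known ground truth
#'
#' Simulates `n_images` proteome images sharing one protein index. The true
#' (noiseless) abundance of protein p in voxel v of image i is
#' `baseline_p + shift_i + islet_effect * [p is marker & v is islet]
#'  + gradient_slope * distance(v) * [p is gradient protein]`;
#' observed values add `N(0, noise_sd^2)` noise, and each entry is dropped
#' with probability `plogis(qlogis(missing_rate_base) -
#' missing_abundance_coupling * (true - baseline_mean))`, so low-abundance
#' entries are more likely to be missing.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `study` ([voxel_study()]) and `truth`, a list
#'   with `classes` (data.frame protein/class, class one of `islet_marker`,
#'   `gradient`, `background`), `plex_shifts` (named per image),
#'   `islet_positions` (list of (row, col) per image), and `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  proteins <- sprintf("P%0*d", nchar(as.character(cfg$n_proteins)), seq_len(cfg$n_proteins))

  set.seed(derive_seed(cfg$seed, 0L))
  n_mark <- round(cfg$frac_islet_markers * cfg$n_proteins)
  n_grad <- round(cfg$frac_gradient * cfg$n_proteins)
  cls <- rep("background", cfg$n_proteins)
  idx <- sample.int(cfg$n_proteins, n_mark + n_grad)
  cls[idx[seq_len(n_mark)]] <- "islet_marker"
  if (n_grad > 0) cls[idx[n_mark + seq_len(n_grad)]] <- "gradient"
  baseline <- stats::rnorm(cfg$n_proteins, mean = 0, sd = cfg$baseline_sd)
  plex_shifts <- stats::rnorm(cfg$n_images, mean = 0, sd = cfg$plex_shift_sd)
  image_ids <- sprintf("image%d", seq_len(cfg$n_images))
  names(plex_shifts) <- image_ids
  positions <- edge_middle_positions(cfg$n_rows, cfg$n_cols)
  islet_idx <- sample.int(length(positions), cfg$n_images, replace = TRUE)

  is_marker <- cls == "islet_marker"
  is_grad <- cls == "gradient"
  images <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    set.seed(derive_seed(cfg$seed, i))
    grid <- voxel_grid(cfg$n_rows, cfg$n_cols, islet = positions[[islet_idx[i]]],
                       voxel_width_um = cfg$voxel_width_um,
                       voxel_height_um = cfg$voxel_height_um)
    d <- voxel_distances(grid, "euclidean_centroid_um")
    nv <- length(d)
    truth_mat <- matrix(baseline + plex_shifts[i], cfg$n_proteins, nv)
    islet_col <- which(names(d) == sprintf("r%d_c%d", grid$islet[1L], grid$islet[2L]))
    truth_mat[is_marker, islet_col] <- truth_mat[is_marker, islet_col] + cfg$islet_effect
    truth_mat[is_grad, ] <- truth_mat[is_grad, ] +
      outer(rep(cfg$gradient_slope, sum(is_grad)), d)
    obs <- truth_mat + matrix(stats::rnorm(cfg$n_proteins * nv, sd = cfg$noise_sd),
                              cfg$n_proteins, nv)
    p_miss <- stats::plogis(stats::qlogis(cfg$missing_rate_base) -
                            cfg$missing_abundance_coupling * truth_mat)
    obs[matrix(stats::runif(cfg$n_proteins * nv), cfg$n_proteins, nv) < p_miss] <- NA_real_
    dimnames(obs) <- list(proteins, names(d))
    images[[i]] <- proteome_image(image_ids[i], obs, grid)
  }

  truth <- list(
    classes = data.frame(protein = proteins, class = cls, stringsAsFactors = FALSE),
    plex_shifts = plex_shifts,
    islet_positions = stats::setNames(positions[islet_idx], image_ids),
    baseline = stats::setNames(baseline, proteins),
    config = cfg
  )
  list(study = voxel_study(images), truth = truth)
}

#' Expected missing fraction under the generator's dropout model
#'
#' Monte-Carlo expectation of the overall missing fraction implied by a
#' configuration, integrating over the baseline-abundance distribution
#' (effects and plex shifts ignored; they are small perturbations of the
#' baseline). Used to check the realized missingness of generated studies.
#'
#' @param config A [synthetic_config()].
#' @param n_draws Monte-Carlo sample size.
#' @return Scalar expected missing fraction.
#' @export
expected_missing_fraction <- function(config, n_draws = 1e5) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 999999L))
  b <- stats::rnorm(n_draws, 0, config$baseline_sd)
  mean(stats::plogis(stats::qlogis(config$missing_rate_base) -
                     config$missing_abundance_coupling * b))
}

#' Generate a pathway collection matched to a synthetic ground truth
#'
#' Emits one set holding exactly the islet-marker proteins, one holding the
#' gradient proteins, and `n_random_sets` uniformly drawn sets, suitable for
#' exercising both enrichment modes with known positives.
#'
#' @param truth The `truth` element returned by [generate_study()].
#' @param n_random_sets Number of random decoy sets (default 50).
#' @param set_size_range Integer range of random set sizes (default 10..50).
#' @param seed Seed for the random sets; defaults to a substream of the
#'   generating config's seed.
#' @return Named list of character vectors (a pathway collection as returned
#'   by [read_gmt()]), with attribute `source = "synthetic"`.
#' @export
generate_pathways <- function(truth, n_random_sets = 50L,
                              set_size_range = c(10L, 50L),
                              seed = derive_seed(truth$config$seed, 100001L)) {
  proteins <- truth$classes$protein
  set_size_range <- as.integer(set_size_range)
  if (max(set_size_range) > length(proteins))
    stop("set sizes exceed the number of proteins", call. = FALSE)
  sets <- list(
    islet_markers = truth$classes$protein[truth$classes$class == "islet_marker"],
    gradient_proteins = truth$classes$protein[truth$classes$class == "gradient"]
  )
  sets <- sets[vapply(sets, length, integer(1L)) > 0L]
  if (n_random_sets > 0L) {
    set.seed(seed)
    sizes <- sample(seq(set_size_range[1L], set_size_range[2L]), n_random_sets,
                    replace = TRUE)
    rnd <- lapply(sizes, function(k) sort(sample(proteins, k)))
    names(rnd) <- sprintf("random_set_%03d", seq_len(n_random_sets))
    sets <- c(sets, rnd)
  }
  attr(sets, "source") <- "synthetic"
  sets
}

#' Generate a synthetic weighted interactome
#'
#' Plants a connected chain over the islet-marker proteins (confidence 0.90),
#' attaches `n_hubs` hidden "hub" proteins (non-markers) that bridge distant
#' markers with very high confidence edges (0.99) — so each hub lies on a
#' shortest confidence-weighted path between two markers, exercising
#' Steiner-node recovery — and adds background edges between uniformly drawn
#' protein pairs at `background_density` with confidences drawn from
#' `confidence_range`.
#'
#' @param truth The `truth` element returned by [generate_study()].
#' @param background_density Probability of a background edge per protein pair
#'   (default 5e-4).
#' @param confidence_range Range of background edge confidences
#'   (default c(0.4, 0.95); kept below the planted confidences so the planted
#'   hub shortcuts stay on shortest paths).
#' @param n_hubs Number of hidden hub proteins (default 2).
#' @param seed Seed; defaults to a substream of the generating config's seed.
#' @return A data.frame edge list with columns `node1`, `node2`, `confidence`
#'   and attribute `hubs` (the planted hub protein ids).
#' @export
generate_interactome <- function(truth, background_density = 5e-4,
                                 confidence_range = c(0.4, 0.95), n_hubs = 2L,
                                 seed = derive_seed(truth$config$seed, 100002L)) {
  if (!is.numeric(background_density) || background_density < 0 || background_density > 1)
    stop("background_density must be in [0, 1]", call. = FALSE)
  proteins <- truth$classes$protein
  markers <- truth$classes$protein[truth$classes$class == "islet_marker"]
  others <- setdiff(proteins, markers)
  set.seed(seed)
  chain_order <- sample(markers)
  edges <- data.frame(node1 = character(0), node2 = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  if (length(chain_order) >= 2L)
    edges <- data.frame(node1 = chain_order[-length(chain_order)],
                        node2 = chain_order[-1L],
                        confidence = 0.90, stringsAsFactors = FALSE)
  hubs <- character(0)
  if (n_hubs > 0L && length(chain_order) >= 4L && length(others) >= n_hubs) {
    hubs <- sample(others, n_hubs)
    for (h in hubs) {
      a <- sample(seq_len(length(chain_order) - 3L), 1L)
      b <- a + 3L  # >= 3 chain steps apart: the 2-edge hub route is shorter
      edges <- rbind(edges, data.frame(node1 = c(h, h),
                                       node2 = chain_order[c(a, b)],
                                       confidence = 0.99,
                                       stringsAsFactors = FALSE))
    }
  }
  n_pairs <- length(proteins) * (length(proteins) - 1) / 2
  n_bg <- stats::rbinom(1L, round(n_pairs), background_density)
  if (n_bg > 0L) {
    i <- sample(proteins, n_bg, replace = TRUE)
    j <- sample(proteins, n_bg, replace = TRUE)
    keep <- i != j
    bg <- data.frame(node1 = pmin(i[keep], j[keep]), node2 = pmax(i[keep], j[keep]),
                     confidence = stats::runif(sum(keep), confidence_range[1L],
                                               confidence_range[2L]),
                     stringsAsFactors = FALSE)
    edges <- rbind(edges, bg)
  }
  edges <- normalize_edges(edges)
  attr(edges, "hubs") <- hubs
  edges
}

# canonical form: undirected, no self-loops, duplicates collapsed to max
# confidence, sorted lexicographically
normalize_edges <- function(edges) {
  stopifnot(all(c("node1", "node2", "confidence") %in% names(edges)))
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  keep <- a != b
  df <- data.frame(node1 = a[keep], node2 = b[keep],
                   confidence = edges$confidence[keep], stringsAsFactors = FALSE)
  key <- paste(df$node1, df$node2, sep = "\r")
  conf <- tapply(df$confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(node1 = vapply(parts, `[`, "", 1L),
                    node2 = vapply(parts, `[`, "", 2L),
                    confidence = as.numeric(conf), stringsAsFactors = FALSE)
  out <- out[order(out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
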