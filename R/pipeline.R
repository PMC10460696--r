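#' Default pipeline configuration
#'
#' Flat, sectioned key-value configuration for the end-to-end pipeline, with
#' the study-design defaults: annotation connectivity and distance metric,
#' significance level 0.05, cross-image consensus at >= 4 images, and PCSF
#' parameters beta = 1, omega = median prize, epsilon = 0.01. Serialisable to
#' and from YAML.
#'
#' @param seed Global seed.
#' @param outdir Output directory for [run_pipeline()].
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, outdir = "isletgrid_results") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = unclass(synthetic_config(seed = seed)),
    annotation = list(connectivity = "8-neighbor",
                      metric = "euclidean_centroid_um"),
    preprocess = list(center_plexes = FALSE),
    diffexp = list(alpha = 0.05, moderate = TRUE, include_image = TRUE,
                   network_contrast = "islet_vs_rest"),
    enrichment = list(n_random_sets = 50L, set_size_min = 10L, set_size_max = 50L),
    gradient = list(alpha = 0.05, min_images = 4L, use_adjusted = TRUE,
                    profile_p_threshold = 0.05),
    network = list(beta = 1, omega = NA, epsilon = 0.01,
                   background_density = 5e-4)
  ), class = "pipeline_config")
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, a `pipeline_config`; values missing from the
#'   file keep their defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (key in names(user[[section]])) cfg[[section]][[key]] <- user[[section]][[key]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg$synthetic <- do.call(synthetic_config, cfg$synthetic)
  cfg$synthetic <- unclass(cfg$synthetic)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, outdir, expr) {
  stage_log(stage, "started")
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (unless a study is supplied) -> preprocess -> differential
#' expression -> set enrichment -> variance and distance gradient analyses ->
#' network integration, writing every stage's tables as TSV plus a JSON run
#' manifest into `config$outdir`. Identical configuration and seed produce
#' byte-identical outputs; any stage failure aborts with a stage-named error
#' and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A `pipeline_config` (see [default_config()]) or a path to a
#'   YAML file.
#' @param study Optional pre-built [voxel_study()]; when supplied, pathways
#'   and an interactome must be supplied too (`pathways`, `interactome`),
#'   otherwise all three are simulated from `config$synthetic`.
#' @param pathways,interactome Optional pathway list / edge-list data.frame
#'   accompanying `study`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), study = NULL,
                         pathways = NULL, interactome = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  manifest <- list(
    package = "isletgrid",
    package_version = as.character(utils::packageVersion("isletgrid")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    counts = list(), files = character(0))
  add_file <- function(name, path) {
    manifest$files[[name]] <<- basename(path)
    path
  }

  truth <- NULL
  if (is.null(study)) {
    run_stage("simulate", outdir, {
      scfg <- do.call(synthetic_config, config$synthetic)
      sim <- generate_study(scfg)
      study <- sim$study
      truth <- sim$truth
      pathways <- generate_pathways(truth,
                                     n_random_sets = config$enrichment$n_random_sets,
                                     set_size_range = c(config$enrichment$set_size_min,
                                                        config$enrichment$set_size_max))
      interactome <- generate_interactome(truth,
                                           background_density = config$network$background_density)
      write_study(study, add_file("abundance", file.path(outdir, "abundance.tsv")),
                  add_file("voxel_metadata", file.path(outdir, "voxel_metadata.tsv")),
                  metric = config$annotation$metric)
      write_gmt(pathways, add_file("pathways", file.path(outdir, "pathways.gmt")))
      write_interactome(interactome,
                        add_file("interactome", file.path(outdir, "interactome.tsv")))
      write_ground_truth(truth,
                         add_file("ground_truth", file.path(outdir, "ground_truth.tsv")))
      stage_log("simulate", "%d images, %d proteins", length(study$images),
                length(study$protein_index))
    })
  } else {
    if (is.null(pathways) || is.null(interactome))
      stop("`pathways` and `interactome` must accompany a supplied study", call. = FALSE)
  }

  asm <- completed <- NULL
  run_stage("preprocess", outdir, {
    miss <- missingness_summary(study)
    write_tsv(miss$voxels, add_file("missingness_voxels",
                                    file.path(outdir, "missingness_voxels.tsv")))
    write_tsv(miss$images, add_file("missingness_images",
                                    file.path(outdir, "missingness_images.tsv")))
    asm <- assemble_study(study, config$annotation$metric)
    ab <- asm$abundance
    if (isTRUE(config$preprocess$center_plexes))
      ab <- median_center_plexes(ab, asm$voxels$image_id)
    completed <- impute_median(ab)
    pca <- pca_embedding(completed, k = 2L)
    write_tsv(data.frame(column = rownames(pca$scores), pca$scores,
                         image_id = asm$voxels$image_id, label = asm$voxels$label,
                         check.names = FALSE),
              add_file("pca_scores", file.path(outdir, "pca_scores.tsv")))
    stage_log("preprocess", "completed matrix %d x %d", nrow(completed), ncol(completed))
  })

  de <- NULL
  run_stage("diffexp", outdir, {
    vox <- asm$voxels
    keep <- vox$column  # completed may have dropped all-missing proteins only
    de <- fit_region_model(completed, vox$label, vox$image_id,
                            moderate = isTRUE(config$diffexp$moderate),
                            include_image = isTRUE(config$diffexp$include_image))
    write_tsv(de, add_file("de_table", file.path(outdir, "de_table.tsv")))
    ov <- overlap_counts(de, threshold = config$diffexp$alpha)
    write_tsv(ov, add_file("overlap_counts", file.path(outdir, "overlap_counts.tsv")))
    for (cn in unique(de$contrast))
      manifest$counts$significant[[cn]] <-
        length(significant_proteins(de, cn, config$diffexp$alpha))
    stage_log("diffexp", "%d contrasts fitted", length(unique(de$contrast)))
  })

  run_stage("enrichment", outdir, {
    sel <- significant_proteins(de, config$diffexp$network_contrast,
                                config$diffexp$alpha)
    es <- enrichment_in_sets(sel, rownames(completed), pathways)
    write_tsv(es, add_file("enrichment_sets", file.path(outdir, "enrichment_sets.tsv")))
    ev <- enrichment_in_order(protein_variance_scores(completed), pathways)
    write_tsv(ev, add_file("enrichment_variance",
                           file.path(outdir, "enrichment_variance.tsv")))
    stage_log("enrichment", "%d pathways tested", nrow(es))
  })

  cons <- NULL
  run_stage("gradient", outdir, {
    ide <- image_distance_enrichments(completed, asm$voxels, pathways)
    write_tsv(ide$correlations, add_file("distance_correlations",
                                         file.path(outdir, "distance_correlations.tsv")))
    cons <- consensus_pathways(ide$enrichments, alpha = config$gradient$alpha,
                                min_images = config$gradient$min_images,
                                use_adjusted = isTRUE(config$gradient$use_adjusted))
    write_tsv(cons$summary, add_file("consensus_summary",
                                     file.path(outdir, "consensus_summary.tsv")))
    write_tsv(data.frame(set = rownames(cons$z), cons$z, check.names = FALSE),
              add_file("consensus_z", file.path(outdir, "consensus_z.tsv")))
    flagged <- cons$summary$set[cons$summary$flagged]
    manifest$counts$consensus_flagged <- length(flagged)
    for (fs in utils::head(flagged, 5L)) {
      prof <- pathway_protein_profiles(fs, pathways, ide$correlations, completed,
                                       asm$voxels,
                                       p_threshold = config$gradient$profile_p_threshold)
      write_tsv(prof, add_file(paste0("profiles_", fs),
                               file.path(outdir, sprintf("profiles_%s.tsv", fs))))
    }
    stage_log("gradient", "%d pathways flagged by consensus", length(flagged))
  })

  run_stage("network", outdir, {
    omega <- config$network$omega
    if (is.null(omega) || is.na(omega)) omega <- NULL
    for (dir_tag in c("up_in_islet", "down_in_islet")) {
      prizes <- build_prizes(de, config$diffexp$network_contrast, dir_tag,
                             threshold = config$diffexp$alpha)
      manifest$counts$prized[[dir_tag]] <- sum(prizes > 0)
      if (sum(prizes > 0) == 0L) {
        stage_log("network", "no %s proteins; skipping", dir_tag)
        next
      }
      sol <- solve_pcsf(interactome, prizes, beta = config$network$beta,
                        omega = omega, epsilon = config$network$epsilon)
      paths <- write_solution(sol, file.path(outdir, paste0("network_", dir_tag)),
                              prizes, de)
      for (p in paths) add_file(basename(p), p)
      manifest$counts$network_nodes[[dir_tag]] <- nrow(sol$nodes)
      manifest$counts$network_steiner[[dir_tag]] <- sum(sol$nodes$flag == "steiner")
      stage_log("network", "%s: %d nodes (%d steiner), objective %.3f", dir_tag,
                nrow(sol$nodes), sum(sol$nodes$flag == "steiner"), sol$objective)
    }
  })

  manifest$counts$n_images <- length(study$images)
  manifest$counts$n_voxels <- sum(vapply(study$images,
                                         function(im) ncol(im$abundance), integer(1L)))
  manifest$counts$n_proteins <- length(study$protein_index)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest$files[["manifest"]] <- basename(manifest_path)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  stage_log("done", "outputs in %s", outdir)
  invisible(manifest)
}
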