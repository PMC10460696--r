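test_that("variance scores use the n-1 sample variance and rank planted signal high", {
  m <- matrix(c(0, 2, 1, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("v1", "v2")))
  v <- protein_variance_scores(m)
  expect_equal(unname(v["a"]), 2)   # var of {0, 2}
  expect_equal(unname(v["b"]), 0)   # constant protein
  expect_error(protein_variance_scores(m[, 1, drop = FALSE]), "2 voxels")
  # planted islet markers are more variable than background on default data
  sim <- small_sim(seed = 17L)
  asm <- assemble_study(sim$study)
  comp <- impute_median(asm$abundance)
  vs <- protein_variance_scores(comp)
  cls <- sim$truth$classes
  rk <- rank(vs)[cls$protein[cls$protein %in% names(vs)]]
  expect_gt(mean(rk[cls$class == "islet_marker"], na.rm = TRUE),
            mean(rk[cls$class == "background"], na.rm = TRUE))
})

test_that("exact permutation p for extreme rho equals the enumerated tail", {
  # rho = 1 on 9 untied values: only the identity and reversal reach |rho| = 1
  st <- spearman_perm_test(1:9, 1:9)
  expect_equal(st$rho, 1)
  expect_equal(st$p, 2 / factorial(9))
  expect_equal(st$method, "exact")
  st_neg <- spearman_perm_test(9:1, 1:9)
  expect_equal(st_neg$rho, -1)
  expect_equal(st_neg$p, 2 / factorial(9))
  # small-n sanity: full enumeration at n = 4 against a direct oracle
  x <- c(2, 1, 4, 3); d <- c(10, 20, 30, 40)
  obs <- cor(x, d, method = "spearman")
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  null_rho <- apply(perms, 1L, function(pp) cor(x[pp], d, method = "spearman"))
  p_oracle <- mean(abs(null_rho) >= abs(obs) - 1e-12)
  expect_equal(spearman_perm_test(x, d)$p, p_oracle)
})

test_that("Spearman rho is invariant to monotone transforms and flips sign with distance", {
  set.seed(3)
  x <- rnorm(9); d <- voxel_distances(voxel_grid(islet = c(0, 1)))
  a <- spearman_perm_test(x, d)
  b <- spearman_perm_test(exp(x), d)          # monotone transform of x
  expect_equal(a$rho, b$rho); expect_equal(a$p, b$p)
  cc <- spearman_perm_test(x, rank(d)^3)       # monotone transform of d
  expect_equal(a$rho, cc$rho)
  neg <- spearman_perm_test(x, -d)
  expect_equal(neg$rho, -a$rho)
  expect_equal(neg$p, a$p)
})

test_that("per-image distance correlation flags degenerate proteins and recovers gradients", {
  cfg <- synthetic_config(seed = 5L, n_proteins = 40L, noise_sd = 0,
                          plex_shift_sd = 0, missing_rate_base = 0,
                          missing_abundance_coupling = 0, frac_gradient = 0.2)
  sim <- generate_study(cfg)
  im <- sim$study$images[[1L]]
  im$abundance[1L, ] <- 7  # constant protein
  dc <- distance_correlation(im)
  expect_equal(dc$flag[1L], "constant")
  expect_true(is.na(dc$rho[1L]))
  gp <- sim$truth$classes$protein[sim$truth$classes$class == "gradient"]
  gp <- setdiff(gp, rownames(im$abundance)[1L])
  expect_equal(dc$rho[dc$protein %in% gp], rep(-1, length(gp)))
  expect_error(distance_correlation(im$abundance, distances = rep(1, 9)), "constant")
})

test_that("distance negation negates rho and the order-enrichment z", {
  sim <- small_sim(seed = 19L)
  asm <- assemble_study(sim$study)
  comp <- impute_median(asm$abundance)
  cols <- asm$voxels$image_id == "image1"
  d <- asm$voxels$distance_um[cols]
  dc1 <- distance_correlation(comp[, cols], distances = d, image_id = "image1")
  dc2 <- distance_correlation(comp[, cols], distances = -d, image_id = "image1")
  ok <- dc1$flag == "ok"
  expect_equal(dc2$rho[ok], -dc1$rho[ok])
  expect_equal(dc2$p[ok], dc1$p[ok])
  pw <- generate_pathways(sim$truth, n_random_sets = 5L, set_size_range = c(5L, 15L))
  e1 <- enrichment_in_order(setNames(dc1$stat[ok], dc1$protein[ok]), pw)
  e2 <- enrichment_in_order(setNames(dc2$stat[ok], dc2$protein[ok]), pw)
  expect_equal(e2$z, -e1$z, tolerance = 1e-6)
})

test_that("consensus flags follow the at-least-k-images rule and its monotonicities", {
  mk_enr <- function(p_adj, z = 1) {
    structure(data.frame(set = names(p_adj), n_members_in_background = 10L,
                         mean_rank = 5, z = z, p = p_adj, adj_p = p_adj,
                         direction = "high", stringsAsFactors = FALSE),
              class = c("enrichment_result", "data.frame"))
  }
  enr <- lapply(1:7, function(i) {
    mk_enr(c(always = 0.001,
             three_of_seven = if (i <= 3) 0.01 else 0.5,
             never = 0.8))
  })
  names(enr) <- sprintf("image%d", 1:7)
  cons <- consensus_pathways(enr, alpha = 0.05, min_images = 4L)
  fl <- setNames(cons$summary$flagged, cons$summary$set)
  expect_true(fl[["always"]])
  expect_false(fl[["three_of_seven"]])  # 3 of 7 misses the 4-image bar
  expect_false(fl[["never"]])
  # flagged for any min_images <= n_images when significant everywhere
  for (k in 1:7) {
    ck <- consensus_pathways(enr, min_images = k)
    expect_true(ck$summary$flagged[ck$summary$set == "always"])
  }
  # monotone in alpha and in min_images
  n_sig_loose <- consensus_pathways(enr, alpha = 0.6)$summary
  n_sig_tight <- consensus_pathways(enr, alpha = 0.005)$summary
  for (s in c("always", "three_of_seven", "never"))
    expect_lte(n_sig_tight$n_significant[n_sig_tight$set == s],
               n_sig_loose$n_significant[n_sig_loose$set == s])
  expect_error(consensus_pathways(enr, min_images = 8L), "exceeds")
})

test_that("pathway profiles return significant members ordered by distance", {
  sim <- small_sim(seed = 23L)
  asm <- assemble_study(sim$study)
  comp <- impute_median(asm$abundance)
  pw <- generate_pathways(sim$truth, n_random_sets = 2L, set_size_range = c(5L, 10L))
  ide <- image_distance_enrichments(comp, asm$voxels, pw)
  prof_all <- pathway_protein_profiles("gradient_proteins", pw, ide$correlations,
                                       comp, asm$voxels, p_threshold = 1.0)
  scored <- ide$correlations[ide$correlations$protein %in% pw$gradient_proteins &
                             ide$correlations$flag == "ok", ]
  expect_equal(nrow(prof_all), sum(scored$p < 1) * 9L)  # every scored member, all voxels
  prof_none <- pathway_protein_profiles("gradient_proteins", pw, ide$correlations,
                                        comp, asm$voxels, p_threshold = 0)
  expect_equal(nrow(prof_none), 0L)
  prof <- pathway_protein_profiles("gradient_proteins", pw, ide$correlations,
                                   comp, asm$voxels, p_threshold = 0.05)
  expect_true(all(prof$p < 0.05))
  # distances non-decreasing within each (image, protein) block
  for (key in unique(paste(prof$image_id, prof$protein))[1:3]) {
    blk <- prof[paste(prof$image_id, prof$protein) == key, ]
    expect_true(all(diff(blk$distance_um) >= 0))
  }
  expect_error(pathway_protein_profiles("nope", pw, ide$correlations, comp,
                                        asm$voxels), "not found")
})
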