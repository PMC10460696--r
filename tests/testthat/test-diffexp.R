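# small balanced design shared across tests: 2 images x 9 voxels
de_fixture <- function(seed = 1L, n_prot = 60L, effect = 0) {
  set.seed(seed)
  g1 <- voxel_grid(islet = c(0, 1))
  g2 <- voxel_grid(islet = c(1, 0))
  lab <- c(as.character(annotate_voxels(g1)), as.character(annotate_voxels(g2)))
  img <- rep(c("i1", "i2"), each = 9L)
  m <- matrix(rnorm(n_prot * 18L), n_prot, 18L,
              dimnames = list(sprintf("p%03d", seq_len(n_prot)),
                              paste0(img, "_", seq_len(18L))))
  m[seq_len(n_prot %/% 4L), lab == "islet"] <-
    m[seq_len(n_prot %/% 4L), lab == "islet"] + effect
  list(mat = m, labels = lab, image_ids = img)
}

test_that("moderated fit agrees with an independent per-protein OLS oracle", {
  fx <- de_fixture(seed = 7L, effect = 1.5)
  de <- fit_region_model(fx$mat, fx$labels, fx$image_ids, moderate = FALSE)
  # ordinary-least-squares oracle via lm() per protein
  for (p in c("p001", "p030", "p060")) {
    df <- data.frame(y = fx$mat[p, ],
                     region = factor(fx$labels, c("islet", "proximal", "distal")),
                     image = factor(fx$image_ids))
    fit <- lm(y ~ 0 + region + image, data = df, contrasts = NULL)
    co <- summary(fit)$coefficients
    lfc <- co["regionislet", 1] - co["regionproximal", 1]
    row <- de[de$protein == p & de$contrast == "islet_vs_proximal", ]
    expect_equal(row$logFC, unname(lfc), tolerance = 1e-10)
    # ordinary t from the lm covariance
    cvec <- c(1, -1, 0, rep(0, length(coef(fit)) - 3))
    se <- sqrt(drop(t(cvec) %*% vcov(fit) %*% cvec))
    expect_equal(row$t, unname(lfc / se), tolerance = 1e-10)
    expect_equal(row$p, unname(2 * pt(-abs(lfc / se), df = fit$df.residual)),
                 tolerance = 1e-10)
  }
})

test_that("moderated t approaches the ordinary t as the prior df vanishes", {
  fx <- de_fixture(seed = 2L)
  plain <- fit_region_model(fx$mat, fx$labels, fx$image_ids, moderate = FALSE)
  mod <- fit_region_model(fx$mat, fx$labels, fx$image_ids, moderate = TRUE)
  expect_equal(mod$logFC, plain$logFC)  # moderation touches variances only
  # manual moderation with the fitted prior reproduces the moderated t from
  # the ordinary statistics
  d0 <- mod$df_prior[1L]
  dr <- plain$df_total[1L]
  s2 <- (plain$logFC / plain$t)^2  # squared SE; proportional to s^2 per protein
  expect_true(d0 > 0)
  # as d0 -> 0 the shrunken variance equals the residual variance: check the
  # algebraic limit on one protein
  i <- which(plain$contrast == "islet_vs_distal")[5L]
  s2_resid <- (plain$logFC[i] / plain$t[i])^2
  s2_post_limit <- (0 * 1 + dr * s2_resid) / (0 + dr)
  expect_equal(s2_post_limit, s2_resid)
  expect_equal(plain$logFC[i] / sqrt(s2_post_limit), plain$t[i])
})

test_that("null data yield calibrated raw p-values and BH monotonicity", {
  fx <- de_fixture(seed = 3L, n_prot = 400L, effect = 0)
  de <- fit_region_model(fx$mat, fx$labels, fx$image_ids)
  for (cn in region_contrasts()) {
    sub <- de[de$contrast == cn, ]
    expect_lt(mean(sub$p < 0.05), 0.10)
    expect_true(all(sub$adj_p >= sub$p - 1e-15))
    expect_true(all(sub$adj_p >= 0 & sub$adj_p <= 1))
    # BH adjusted p is monotone non-decreasing in raw-p rank
    ord <- order(sub$p)
    expect_true(all(diff(sub$adj_p[ord]) >= -1e-15))
  }
})

test_that("identical region values give logFC 0 and p 1", {
  g <- voxel_grid(islet = c(0, 1))
  lab <- as.character(annotate_voxels(g))
  m <- matrix(rep(c(5, 5, 5), each = 9), 3, 9, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), voxel_coords(g)$voxel))
  de <- fit_region_model(m, lab, rep("i1", 9), contrasts = "islet_vs_rest")
  expect_equal(de$logFC, rep(0, 3))
  expect_true(all(de$t == 0))
  expect_true(all(de$p == 1))
})

test_that("confounded designs are rejected with the offending term named", {
  fx <- de_fixture()
  # islet voxels only in image 1: region confounded with image
  lab <- fx$labels
  lab[10:18][lab[10:18] == "islet"] <- "proximal"
  expect_error(fit_region_model(fx$mat, lab, fx$image_ids), "confounded")
})

test_that("overlap counts match brute-force enumeration over combinations", {
  sim <- small_sim(seed = 5L)
  asm <- assemble_study(sim$study)
  comp <- impute_median(asm$abundance)
  de <- fit_region_model(comp, asm$voxels$label, asm$voxels$image_id)
  ov <- overlap_counts(de, threshold = 0.05)
  sets <- lapply(region_contrasts(), function(cn) significant_proteins(de, cn, 0.05))
  names(sets) <- region_contrasts()
  # brute force over all 15 combinations
  univ <- unique(unlist(sets))
  expect_equal(sum(ov$count), length(univ))
  for (i in seq_len(nrow(ov))) {
    inset <- strsplit(ov$combination[i], "&", fixed = TRUE)[[1L]]
    outset <- setdiff(region_contrasts(), inset)
    brute <- sum(vapply(univ, function(p) {
      all(vapply(inset, function(cn) p %in% sets[[cn]], logical(1L))) &&
        !any(vapply(outset, function(cn) p %in% sets[[cn]], logical(1L)))
    }, logical(1L)))
    expect_equal(ov$count[i], brute)
  }
  # single contrast: one bar with the significant count
  ov1 <- overlap_counts(de, contrasts = "islet_vs_rest")
  expect_equal(sum(ov1$count), length(sets$islet_vs_rest))
  expect_error(overlap_counts(de, contrasts = "nope"), "unknown contrast")
})

test_that("disjoint significance sets intersect in zero proteins", {
  de <- data.frame(protein = rep(c("a", "b", "c", "d"), 2),
                   contrast = rep(c("islet_vs_rest", "proximal_vs_distal"), each = 4),
                   logFC = 1, t = 1,
                   p = c(0.001, 0.001, 0.9, 0.9, 0.9, 0.9, 0.001, 0.001),
                   adj_p = c(0.004, 0.004, 0.9, 0.9, 0.9, 0.9, 0.004, 0.004),
                   df_total = 10, df_prior = 0)
  class(de) <- c("de_table", "data.frame")
  ov <- overlap_counts(de, threshold = 0.05)
  expect_true(all(ov$degree == 1L))
  expect_equal(sum(ov$count), 4L)
})
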