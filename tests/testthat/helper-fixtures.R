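# Shared fixture builders (all data generated in code).

# tiny hand-checkable two-image study: 3 proteins x 9 voxels per image
toy_study <- function(missing = TRUE) {
  g1 <- voxel_grid(islet = c(0L, 1L))
  g2 <- voxel_grid(islet = c(1L, 0L))
  vox <- voxel_coords(g1)$voxel
  m1 <- matrix(seq_len(27) / 10, nrow = 3, dimnames = list(c("A", "B", "C"), vox))
  m2 <- matrix(seq(28, 54) / 10, nrow = 3, dimnames = list(c("A", "B", "D"), vox))
  if (missing) {
    m1["A", "r0_c0"] <- NA
    m2["D", "r2_c2"] <- NA
  }
  voxel_study(list(proteome_image("img1", m1, g1),
                   proteome_image("img2", m2, g2)))
}

# reduced-size synthetic study for unit tests (default study conditions
# otherwise)
small_sim <- function(seed = 1L, ...) {
  generate_study(synthetic_config(seed = seed, n_proteins = 300L, ...))
}
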