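test_that("edge costs decrease strictly in confidence with a positive floor", {
  expect_equal(edge_cost(1.0), 0.01)
  expect_equal(edge_cost(0.5), 0.51)
  conf <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(edge_cost(conf)) < 0))
  expect_true(all(edge_cost(conf) > 0))
  expect_error(edge_cost(0), "\\(0, 1\\]")
  expect_error(edge_cost(1.2), "\\(0, 1\\]")
})

test_that("prizes are |logFC| of significant proteins in the requested direction", {
  de <- data.frame(protein = c("a", "b", "c", "d"),
                   contrast = "islet_vs_rest",
                   logFC = c(2.0, -1.5, 0.8, -3.0),
                   t = 1, p = c(0.001, 0.001, 0.2, 0.04),
                   adj_p = c(0.004, 0.004, 0.4, 0.06),
                   df_total = 10, df_prior = 0)
  class(de) <- c("de_table", "data.frame")
  up <- build_prizes(de, "islet_vs_rest", "up_in_islet")
  dn <- build_prizes(de, "islet_vs_rest", "down_in_islet")
  expect_equal(up[["a"]], 2.0)
  expect_equal(sum(up > 0), 1L)
  expect_equal(dn[["b"]], 1.5)   # |logFC| of the downregulated protein
  expect_equal(sum(dn > 0), 1L)  # d misses the adjusted threshold
  expect_error(build_prizes(de, "nope", "up_in_islet"), "unknown contrast")
  # cross-module consistency with the significant sets
  sim <- small_sim(seed = 31L)
  asm <- assemble_study(sim$study)
  comp <- impute_median(asm$abundance)
  det <- fit_region_model(comp, asm$voxels$label, asm$voxels$image_id)
  for (dir_tag in c("up_in_islet", "down_in_islet")) {
    pz <- build_prizes(det, "islet_vs_rest", dir_tag)
    expect_equal(sum(pz > 0),
                 length(significant_proteins(det, "islet_vs_rest", 0.05,
                                             if (dir_tag == "up_in_islet") "up" else "down")))
  }
})

test_that("the two-terminal worked instance is solved to optimality", {
  edges <- data.frame(node1 = "A", node2 = "B", confidence = 0.81)  # cost 0.2
  prizes <- c(A = 5, B = 5)
  sol <- solve_pcsf(edges, prizes, beta = 1)
  expect_equal(nrow(sol$edges), 1L)
  expect_setequal(sol$nodes$id, c("A", "B"))
  expect_equal(sol$objective, 0.2)
  expect_equal(sol$objective, brute_force_pcsf(edges, prizes))
})

test_that("a prized node too expensive to capture stays a singleton", {
  # only incident edge costs more than any reachable gain
  edges <- data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
                      confidence = c(0.05, 0.05))  # costs 0.96
  prizes <- c(A = 0.5, C = 0.5)
  sol <- solve_pcsf(edges, prizes)
  expect_equal(nrow(sol$edges), 0L)
  expect_setequal(sol$singletons, c("A", "C"))
  expect_equal(sol$objective, sol$objective_empty)
})

test_that("heuristic matches brute force on small random instances", {
  n_exact <- 0L
  for (s in 1:100) {
    inst <- random_pcsf_instance(s)
    opt <- brute_force_pcsf(inst$edges, inst$prizes)
    sol <- suppressWarnings(solve_pcsf(inst$edges, inst$prizes))
    expect_lte(sol$objective, 2 * opt + 1e-9)
    expect_lte(sol$objective, sol$objective_empty + 1e-9)
    expect_gte(sol$objective, opt - 1e-9)  # oracle is a true lower bound
    if (abs(sol$objective - opt) < 1e-9) n_exact <- n_exact + 1L
  }
  expect_gte(n_exact, 80L)
})

test_that("solutions are forests whose leaves earn their keep", {
  for (s in c(2L, 9L, 23L, 48L, 86L)) {
    inst <- random_pcsf_instance(s)
    sol <- suppressWarnings(solve_pcsf(inst$edges, inst$prizes))
    if (nrow(sol$edges) == 0L) next
    g <- igraph::graph_from_data_frame(sol$edges[, 1:2], directed = FALSE)
    # forest: |E| = |V| - number of trees
    expect_equal(igraph::ecount(g),
                 igraph::vcount(g) - igraph::components(g)$no)
    deg <- igraph::degree(g)
    for (leaf in names(deg)[deg == 1L]) {
      if (leaf %in% names(inst$prizes)) next  # prized leaf
      # unprized leaf: must be the capture partner of an adjacent prized node
      nb <- igraph::neighbors(g, leaf)$name
      expect_true(any(nb %in% names(inst$prizes)))
    }
  }
})

test_that("scaling prizes up never shrinks the set of captured prized nodes", {
  for (s in 1:25) {
    inst <- random_pcsf_instance(s)
    sol1 <- suppressWarnings(solve_pcsf(inst$edges, inst$prizes))
    sol3 <- suppressWarnings(solve_pcsf(inst$edges, inst$prizes * 3))
    cap1 <- sol1$nodes$id[sol1$nodes$flag == "terminal"]
    cap3 <- sol3$nodes$id[sol3$nodes$flag == "terminal"]
    expect_gte(length(cap3), length(cap1))
  }
})

test_that("planted hidden hubs surface as Steiner nodes when markers are prized", {
  sim <- small_sim(seed = 37L)
  net <- generate_interactome(sim$truth, background_density = 1e-3)
  markers <- sim$truth$classes$protein[sim$truth$classes$class == "islet_marker"]
  prizes <- setNames(rep(2, length(markers)), markers)
  sol <- solve_pcsf(net, prizes)
  steiner <- sol$nodes$id[sol$nodes$flag == "steiner"]
  expect_gt(length(intersect(attr(net, "hubs"), steiner)), 0L)
  # all markers captured: they form a connected planted subgraph
  expect_setequal(sol$nodes$id[sol$nodes$flag == "terminal"], markers)
  # solution containing only prized nodes has zero steiner flags
  cls <- classify_nodes(sol, prizes)
  expect_equal(sum(cls$flag == "terminal"), length(markers))
  expect_lte(sum(cls$flag == "terminal"), sum(prizes > 0))
})

test_that("interactome files round-trip and input validation works", {
  edges <- data.frame(node1 = c("b", "a", "a"), node2 = c("c", "b", "b"),
                      confidence = c(0.5, 0.9, 0.7))
  path <- tempfile(fileext = ".tsv")
  write_interactome(edges, path)
  back <- read_interactome(path)
  expect_equal(back$node1, c("a", "b"))
  expect_equal(back$confidence, c(0.9, 0.5))  # duplicate collapsed to max
  # headerless file
  writeLines(c("x\ty\t0.8", "y\tz\t0.3"), path)
  back2 <- read_interactome(path)
  expect_equal(nrow(back2), 2L)
  writeLines(c("x\ty\t1.8"), path)
  expect_error(read_interactome(path), "\\(0, 1\\]")
  expect_error(solve_pcsf(edges, c(a = 0)), "no positive prizes")
})
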