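# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (and igraph, which the solver uses).

# Exhaustive prize-collecting Steiner forest optimum by enumeration over all
# acyclic edge subsets: objective = sum of chosen edge costs + beta * sum of
# prizes of prized nodes touched by no chosen edge. Feasible for <= ~14 edges.
brute_force_pcsf <- function(edges, prizes, beta = 1, epsilon = 0.01) {
  prizes <- prizes[prizes > 0]
  cost <- 1 - edges$confidence + epsilon
  m <- nrow(edges)
  nodes <- sort(unique(c(edges$node1, edges$node2)))
  a <- match(edges$node1, nodes)
  b <- match(edges$node2, nodes)
  total <- sum(prizes)
  prize_vec <- numeric(length(nodes))
  hit <- match(names(prizes), nodes)
  prize_vec[hit[!is.na(hit)]] <- prizes[!is.na(hit)]
  best <- beta * total
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    parent <- seq_along(nodes)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    acyclic <- TRUE
    for (i in sel) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    touched <- unique(c(a[sel], b[sel]))
    obj <- sum(cost[sel]) + beta * (total - sum(prize_vec[touched]))
    if (obj < best) best <- obj
  }
  best
}

# Random tiny PCSF instance: <= max_nodes nodes, <= max_edges edges on a
# connected-ish random graph, about half the nodes prized.
random_pcsf_instance <- function(seed, max_nodes = 9L, max_edges = 14L) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1L)
  nodes <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(combn(nodes, 2L))
  m <- sample(seq(n - 1L, min(max_edges, nrow(all_pairs))), 1L)
  pick <- sample(nrow(all_pairs), m)
  edges <- data.frame(node1 = all_pairs[pick, 1L], node2 = all_pairs[pick, 2L],
                      confidence = round(runif(m, 0.05, 0.95), 3),
                      stringsAsFactors = FALSE)
  n_prized <- sample(2:max(2L, n %/% 2L), 1L)
  prizes <- setNames(round(runif(n_prized, 0.2, 3), 3),
                     sample(nodes, n_prized))
  list(edges = edges, prizes = prizes)
}

# Direct O(n * voxels) recount of per-voxel missing entries over a study's
# union protein index, independent of assemble_study().
recount_missing <- function(study) {
  idx <- study$protein_index
  out <- list()
  for (im in study$images) {
    for (v in colnames(im$abundance)) {
      n_miss <- 0L
      for (p in idx) {
        val <- if (p %in% rownames(im$abundance)) im$abundance[p, v] else NA_real_
        if (is.na(val)) n_miss <- n_miss + 1L
      }
      out[[paste(im$image_id, v)]] <- n_miss
    }
  }
  unlist(out)
}
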