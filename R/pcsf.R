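#' Read a weighted interactome edge list
#'
#' Three tab-separated columns (node1, node2, confidence), header optional.
#' Self-loops are removed and duplicate edges collapsed to their maximum
#' confidence; confidences must lie in (0, 1].
#'
#' @param path Path to the edge-list TSV.
#' @return Data.frame with columns `node1`, `node2`, `confidence`, sorted
#'   lexicographically.
#' @export
read_interactome <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1L,
                             colClasses = "character")
  has_header <- ncol(first) >= 3L && is.na(suppressWarnings(as.numeric(first[[3L]])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("interactome file must have 3 columns: node1, node2, confidence",
         call. = FALSE)
  df <- df[, 1:3]
  names(df) <- c("node1", "node2", "confidence")
  df$confidence <- as.numeric(df$confidence)
  if (anyNA(df$confidence) || any(df$confidence <= 0 | df$confidence > 1))
    stop("edge confidences must lie in (0, 1]", call. = FALSE)
  normalize_edges(df)
}

#' Write an interactome edge list
#'
#' @param edges Data.frame with columns `node1`, `node2`, `confidence`.
#' @param path Output path.
#' @export
write_interactome <- function(edges, path) {
  utils::write.table(edges[, c("node1", "node2", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge cost from an interaction confidence
#'
#' `cost = 1 - confidence + epsilon`: strictly decreasing in confidence with
#' a small positive floor so even perfect-confidence edges carry a cost.
#'
#' @param confidence Numeric in (0, 1].
#' @param epsilon Positive floor (default 0.01).
#' @return Positive cost(s).
#' @export
edge_cost <- function(confidence, epsilon = 0.01) {
  if (any(is.na(confidence)) || any(confidence <= 0 | confidence > 1))
    stop("confidence must lie in (0, 1]", call. = FALSE)
  1 - confidence + epsilon
}

#' Prizes from a differential-expression table
#'
#' Proteins passing the adjusted-p threshold with the required sign of logFC
#' receive prize `|logFC|`; all others zero. Up- and down-regulated proteins
#' are scored as separate assignments, yielding two networks.
#'
#' @param de A `de_table` from [fit_region_model()].
#' @param contrast Contrast name (e.g. `"islet_vs_rest"`).
#' @param direction `"up_in_islet"` (logFC > 0) or `"down_in_islet"`.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @return Named numeric vector of prizes (>= 0) over all proteins of the
#'   contrast, with attribute `direction`.
#' @export
build_prizes <- function(de, contrast, direction = c("up_in_islet", "down_in_islet"),
                         threshold = 0.05) {
  direction <- match.arg(direction)
  if (!contrast %in% de$contrast)
    stop(sprintf("unknown contrast '%s'", contrast), call. = FALSE)
  sub <- de[de$contrast == contrast, , drop = FALSE]
  sig <- sub$adj_p < threshold &
    (if (direction == "up_in_islet") sub$logFC > 0 else sub$logFC < 0)
  prizes <- stats::setNames(ifelse(sig, abs(sub$logFC), 0), sub$protein)
  attr(prizes, "direction") <- direction
  prizes
}

# deterministic Kruskal minimum spanning forest on an edge data.frame with
# columns from, to, weight; ties broken lexicographically
kruskal_msf <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  keep <- integer(0)
  if (nrow(edges) > 0L) {
    ord <- order(edges$weight, edges$from, edges$to)
    for (i in ord) {
      ra <- find(edges$from[i]); rb <- find(edges$to[i])
      if (ra != rb) {
        parent[[ra]] <- rb
        keep <- c(keep, i)
      }
    }
  }
  edges[keep, , drop = FALSE]
}

#' Solve the prize-collecting Steiner forest problem (heuristic)
#'
#' Finds a low-cost forest in the interactome capturing high-prize
#' (differentially expressed) proteins, possibly through unprized Steiner
#' nodes. The objective is `sum of edge costs + beta * sum of prizes of
#' uncaptured prized nodes`, where a prized node is captured when it is
#' touched by at least one solution edge.
#'
#' The heuristic follows the classic rooted construction: a dummy root is
#' joined to every prized node at cost `omega` (larger `omega` merges prized
#' nodes into fewer trees); the terminals (prized nodes plus root) are merged
#' through their shortest cost-weighted paths (MST of the metric closure,
#' re-expanded and re-spanned); finally strong pruning removes every subtree
#' whose edge cost exceeds the prize it captures, so each leaf of each
#' returned tree is a prized node. Node processing order is lexicographic,
#' making the solution deterministic.
#'
#' Prized proteins absent from the interactome are dropped with a warning
#' (they remain uncaptured in the objective); prized nodes whose capture
#' never pays off are returned as singleton trees.
#'
#' @param interactome Edge-list data.frame (`node1`, `node2`, `confidence`).
#' @param prizes Named numeric vector of non-negative prizes (see
#'   [build_prizes()]); at least one must be positive.
#' @param beta Prize scaling (> 0, default 1).
#' @param omega Dummy-edge cost (> 0); default: the median positive prize.
#' @param epsilon Edge-cost floor (see [edge_cost()]).
#' @return A `steiner_solution` list: `nodes` (data.frame `id`, `flag`
#'   terminal/steiner, `prize`, `captured`), `edges` (data.frame `node1`,
#'   `node2`, `confidence`, `cost`), `singletons` (uncaptured prized nodes),
#'   `dropped` (prized nodes absent from the interactome), `objective`,
#'   `objective_empty`, and the parameters.
#' @export
solve_pcsf <- function(interactome, prizes, beta = 1, omega = NULL,
                       epsilon = 0.01) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  prizes <- prizes[prizes > 0]
  if (length(prizes) == 0L)
    stop("no positive prizes: nothing to connect", call. = FALSE)
  prizes <- prizes[order(names(prizes))]
  edges <- normalize_edges(interactome)
  edges$cost <- edge_cost(edges$confidence, epsilon)
  graph_nodes <- sort(unique(c(edges$node1, edges$node2)))
  dropped <- setdiff(names(prizes), graph_nodes)
  if (length(dropped))
    warning(sprintf("%d prized protein(s) absent from the interactome dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")), call. = FALSE)
  terminals <- intersect(names(prizes), graph_nodes)
  objective_empty <- beta * sum(prizes)
  if (is.null(omega)) omega <- stats::median(prizes)
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0", call. = FALSE)

  empty_solution <- function() {
    structure(list(
      nodes = data.frame(id = character(0), flag = character(0),
                         prize = numeric(0), stringsAsFactors = FALSE),
      edges = data.frame(node1 = character(0), node2 = character(0),
                         confidence = numeric(0), cost = numeric(0),
                         stringsAsFactors = FALSE),
      singletons = terminals, dropped = dropped,
      objective = objective_empty, objective_empty = objective_empty,
      beta = beta, omega = omega, epsilon = epsilon),
      class = "steiner_solution")
  }
  if (length(terminals) == 0L) return(empty_solution())

  root <- ".__root__"
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = edges$node1, to = edges$node2,
                     weight = edges$cost, stringsAsFactors = FALSE),
          data.frame(from = root, to = terminals, weight = omega,
                     stringsAsFactors = FALSE)),
    directed = FALSE)

  # 1. metric closure over terminals + root, MST of the closure
  tset <- c(root, terminals)
  D <- igraph::distances(g, v = tset, to = tset, weights = igraph::E(g)$weight)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  closure <- data.frame(from = tset[ij[, 1L]], to = tset[ij[, 2L]],
                        weight = D[ij], stringsAsFactors = FALSE)
  closure <- closure[is.finite(closure$weight), , drop = FALSE]
  ctree <- kruskal_msf(tset, closure)

  # 2. expand closure edges to shortest paths, take MST of the expansion
  sub_edges <- character(0)
  for (i in seq_len(nrow(ctree))) {
    sp <- igraph::shortest_paths(g, from = ctree$from[i], to = ctree$to[i],
                                 weights = igraph::E(g)$weight, output = "epath")
    sub_edges <- c(sub_edges, igraph::as_ids(sp$epath[[1L]]))
  }
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::as_ids(igraph::E(g)) %in%
                                                      unique(sub_edges)])
  sdf <- igraph::as_data_frame(sub, what = "edges")
  tree <- kruskal_msf(unique(c(sdf$from, sdf$to)), sdf)

  # 3. strong pruning from the root: drop any subtree whose cost exceeds the
  # prize it captures (dummy edges carry no real cost at the root)
  adjacency <- list()
  for (i in seq_len(nrow(tree))) {
    a <- tree$from[i]; b <- tree$to[i]; w <- tree$weight[i]
    adjacency[[a]] <- rbind(adjacency[[a]],
                            data.frame(u = b, w = w, stringsAsFactors = FALSE))
    adjacency[[b]] <- rbind(adjacency[[b]],
                            data.frame(u = a, w = w, stringsAsFactors = FALSE))
  }
  prize_of <- function(v) if (!is.na(p <- prizes[v])) beta * unname(p) else 0

  kept_edges <- data.frame(node1 = character(0), node2 = character(0),
                           cost = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(adjacency[[root]])) {
    # iterative post-order worth computation (worth = captured prize minus
    # cost of the retained subtree below each node)
    worth <- new.env(parent = emptyenv())
    kept <- new.env(parent = emptyenv())
    stack <- list(list(v = root, parent = NA_character_, phase = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- adjacency[[fr$v]]
      children <- if (is.null(nb)) character(0) else {
        keep <- is.na(fr$parent) | nb$u != fr$parent
        nb$u[keep]
      }
      children <- sort(children)
      if (fr$phase == 1L) {
        stack[[length(stack) + 1L]] <- list(v = fr$v, parent = fr$parent, phase = 2L)
        for (ch in children)
          stack[[length(stack) + 1L]] <- list(v = ch, parent = fr$v, phase = 1L)
      } else {
        w_v <- prize_of(fr$v)
        keep_ch <- character(0)
        for (ch in children) {
          w_edge <- nb$w[nb$u == ch][1L]
          real_edge_cost <- if (fr$v == root) 0 else w_edge
          net <- worth[[ch]] - real_edge_cost
          if (fr$v == root) {
            # at the root, keep a child only if its real tree is worthwhile
            if (worth[[ch]] > 0) keep_ch <- c(keep_ch, ch)
          } else if (net > 0) {
            w_v <- w_v + net
            keep_ch <- c(keep_ch, ch)
          }
        }
        worth[[fr$v]] <- w_v
        kept[[fr$v]] <- keep_ch
      }
    }
    # collect kept real edges by walking down from the root's kept children
    walk <- as.list(if (is.null(kept[[root]])) character(0) else kept[[root]])
    while (length(walk)) {
      v <- walk[[1L]]; walk[[1L]] <- NULL
      for (ch in kept[[v]]) {
        w_edge <- adjacency[[v]]$w[adjacency[[v]]$u == ch][1L]
        kept_edges <- rbind(kept_edges,
                            data.frame(node1 = min(v, ch), node2 = max(v, ch),
                                       cost = w_edge, stringsAsFactors = FALSE))
        walk[[length(walk) + 1L]] <- ch
      }
    }
  }

  # per-tree refinement: a merged tree is disbanded when serving each of its
  # prized nodes individually (capture via its cheapest incident edge, or
  # forfeit of its prize, whichever is cheaper) beats the tree's edge cost
  min_capture <- function(v) {
    inc <- edges[edges$node1 == v | edges$node2 == v, , drop = FALSE]
    if (nrow(inc) == 0L) return(Inf)
    min(inc$cost)
  }
  if (nrow(kept_edges) > 0L) {
    g_kept <- igraph::graph_from_data_frame(kept_edges[, c("node1", "node2")],
                                            directed = FALSE)
    comp <- igraph::components(g_kept)$membership
    for (k in unique(comp)) {
      members <- names(comp)[comp == k]
      in_comp <- kept_edges$node1 %in% members
      tree_cost <- sum(kept_edges$cost[in_comp])
      term_members <- intersect(members, terminals)
      alt <- sum(vapply(term_members, function(v)
        min(beta * prizes[[v]], min_capture(v)), numeric(1L)))
      if (alt < tree_cost - 1e-12)
        kept_edges <- kept_edges[!in_comp, , drop = FALSE]
    }
  }

  # capture step: a prized node still untouched after pruning collects its
  # prize whenever its cheapest incident edge costs less than beta * prize --
  # the neighbour (possibly unprized) joins as its capture partner
  touched <- unique(c(kept_edges$node1, kept_edges$node2))
  for (v in setdiff(terminals, touched)) {
    if (v %in% touched) next  # captured as an earlier node's partner
    inc <- edges[edges$node1 == v | edges$node2 == v, , drop = FALSE]
    if (nrow(inc) == 0L) next
    other <- ifelse(inc$node1 == v, inc$node2, inc$node1)
    ord <- order(inc$cost, other)
    if (beta * prizes[v] > inc$cost[ord[1L]]) {
      kept_edges <- rbind(kept_edges,
                          data.frame(node1 = min(v, other[ord[1L]]),
                                     node2 = max(v, other[ord[1L]]),
                                     cost = inc$cost[ord[1L]],
                                     stringsAsFactors = FALSE))
      touched <- c(touched, v, other[ord[1L]])
    }
  }
  sol_nodes <- sort(unique(c(kept_edges$node1, kept_edges$node2)))
  captured <- intersect(terminals, sol_nodes)
  singletons <- setdiff(terminals, sol_nodes)
  edge_key <- paste(edges$node1, edges$node2)
  kept_edges$confidence <- edges$confidence[match(paste(kept_edges$node1,
                                                       kept_edges$node2), edge_key)]
  kept_edges <- kept_edges[order(kept_edges$node1, kept_edges$node2),
                           c("node1", "node2", "confidence", "cost"), drop = FALSE]
  rownames(kept_edges) <- NULL
  objective <- sum(kept_edges$cost) +
    beta * sum(prizes[setdiff(names(prizes), captured)])
  nodes <- data.frame(
    id = sol_nodes,
    flag = ifelse(sol_nodes %in% names(prizes), "terminal", "steiner"),
    prize = ifelse(sol_nodes %in% names(prizes), prizes[sol_nodes], 0),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = kept_edges, singletons = singletons,
                 dropped = dropped, objective = objective,
                 objective_empty = objective_empty,
                 beta = beta, omega = omega, epsilon = epsilon),
            class = "steiner_solution")
}

#' @export
print.steiner_solution <- function(x, ...) {
  cat(sprintf("<steiner_solution> %d nodes (%d terminal, %d steiner), %d edges, %d singleton prized node(s); objective %.4g (empty: %.4g)\n",
              nrow(x$nodes), sum(x$nodes$flag == "terminal"),
              sum(x$nodes$flag == "steiner"), nrow(x$edges),
              length(x$singletons), x$objective, x$objective_empty))
  invisible(x)
}

#' Classify solution nodes as terminal or Steiner
#'
#' Terminal nodes carry a positive prize (measured differential proteins);
#' Steiner nodes are zero-prize proteins the solver added to connect them
#' (implicated, not detected as differential).
#'
#' @param solution A `steiner_solution`.
#' @param prizes The prize vector used to solve it.
#' @param de Optional `de_table` to annotate logFC (matched on protein and
#'   taken from the contrast with the largest |logFC| if several).
#' @return Data.frame: `id`, `flag`, `prize`, `logFC` (NA for Steiner nodes
#'   absent from `de`).
#' @export
classify_nodes <- function(solution, prizes, de = NULL) {
  stopifnot(inherits(solution, "steiner_solution"))
  out <- solution$nodes
  out$prize <- ifelse(out$id %in% names(prizes),
                      unname(prizes[out$id]), 0)
  out$flag <- ifelse(out$prize > 0, "terminal", "steiner")
  out$logFC <- rep(NA_real_, nrow(out))
  if (!is.null(de)) {
    agg <- de[order(-abs(de$logFC)), , drop = FALSE]
    agg <- agg[!duplicated(agg$protein), , drop = FALSE]
    out$logFC <- agg$logFC[match(out$id, agg$protein)]
  }
  out
}

#' Write a Steiner solution to text files
#'
#' Emits a node table TSV (`id`, `flag`, `prize`, `logFC`), an edge table TSV
#' (`node1`, `node2`, `confidence`, `cost`), and a standard text graph export
#' (GraphML) for visualization tools.
#'
#' @param solution A `steiner_solution`.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @param prizes,de Passed to [classify_nodes()].
#' @return Invisibly, the vector of written paths.
#' @export
write_solution <- function(solution, prefix, prizes, de = NULL) {
  nodes <- classify_nodes(solution, prizes, de)
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", ".graphml"))
  utils::write.table(nodes, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(solution$edges, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(nodes) > 0L) {
    g <- igraph::graph_from_data_frame(
      solution$edges[, c("node1", "node2", "cost")],
      directed = FALSE,
      vertices = nodes[, c("id", "flag", "prize")])
    igraph::write_graph(g, paths[3L], format = "graphml")
  } else {
    writeLines("<graphml/>", paths[3L])
  }
  invisible(paths)
}
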