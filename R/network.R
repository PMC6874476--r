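# The network of transitions between uninvadable dynamically stable states:
# red edges are possible regime shifts (overlapping feasible ranges), blue
# edges are smooth transitions (shared feasibility boundaries).

#' Regime-shift (overlap) edges
#'
#' Two stable states admit a regime shift iff at least one sampled supply
#' vector has both feasible. Edge weight counts the shared samples.
#'
#' @param report a [monte_carlo_feasibility()] report.
#' @param stable_ids indices (rows of `report$states`) of the uninvadable
#'   dynamically stable states.
#' @return data.frame `from`, `to`, `weight` (`from < to`, indices into
#'   `report$states`).
#' @export
build_overlap_edges <- function(report, stable_ids) {
  sets <- sample_state_sets(report, stable_ids)$sets
  pair_keys <- unlist(lapply(sets, function(s) {
    if (length(s) < 2) return(NULL)
    p <- combn(sort(stable_ids[s]), 2)
    paste(p[1, ], p[2, ])
  }))
  if (length(pair_keys) == 0) {
    return(data.frame(from = integer(0), to = integer(0), weight = integer(0)))
  }
  tab <- table(pair_keys)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
             weight = as.integer(tab), row.names = NULL)
}

#' Shared-boundary (smooth transition) pairs
#'
#' Probes each face of a stable state's feasibility region. A state stops
#' being feasible where one entry of its solution vector X crosses zero:
#' either a species goes continuously extinct or a non-limiting metabolite
#' concentration vanishes (the species using it switches its limiting
#' resource). For each X entry in turn, the remaining entries are drawn from
#' U(0, 1], the chosen entry is set to -0.01, and the conservation laws map
#' this vector to supply rates lying just across that face. Any other stable
#' state feasible there shares a boundary with the probed one. Feasibility at
#' a supply vector depends only on the signs of R^-1 phi and is invariant
#' under positive rescaling of phi, so the probe supplies are tested directly
#' regardless of where they fall relative to the sampling box.
#'
#' @param pool a [species_pool()].
#' @param states integer state matrix of the stable states.
#' @param config a [model_config()].
#' @param n_draws ensemble size per (state, zeroed X entry) pair.
#' @param seed integer seed.
#' @return data.frame `from`, `to`, `hits` (`from < to`, row indices into
#'   `states`).
#' @export
detect_boundary_pairs <- function(pool, states, config = model_config(),
                                  n_draws = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(states)
  D <- pool$K + pool$M
  Rs <- lapply(seq_len(n), function(p) build_resource_matrix(pool, states[p, ]))
  Rinvs <- lapply(Rs, solve)
  hits <- new.env()
  for (p in seq_len(n)) {
    for (k in seq_len(D)) {
      X <- matrix(1 - runif(D * n_draws), nrow = D)   # U(0, 1]
      X[k, ] <- -0.01
      phi <- config$delta * (Rs[[p]] %*% X)
      for (q in seq_len(n)) {
        if (q == p) next
        Xq <- Rinvs[[q]] %*% (phi / config$delta)
        nhit <- sum(colSums(Xq <= config$feas_tol) == 0L)
        if (nhit > 0) {
          key <- paste(min(p, q), max(p, q))
          hits[[key]] <- (if (is.null(hits[[key]])) 0L else hits[[key]]) + nhit
        }
      }
    }
  }
  keys <- ls(hits)
  if (length(keys) == 0) {
    return(data.frame(from = integer(0), to = integer(0), hits = integer(0)))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
             hits = vapply(keys, function(k) hits[[k]], integer(1)),
             row.names = NULL)
}

#' Assemble the transition network
#'
#' Nodes are the uninvadable dynamically stable states; red edges are regime
#' shifts (feasible-range overlaps), blue edges are smooth transitions (shared
#' boundaries not already red). Modules are Louvain communities of the
#' regime-shift graph.
#'
#' @param pool a [species_pool()].
#' @param report a [monte_carlo_feasibility()] report over all candidate
#'   states.
#' @param labels stability labels (from [infer_stability()] or direct tests)
#'   aligned with `report$states`.
#' @param config a [model_config()].
#' @param boundary run the boundary search for blue edges?
#' @param n_draws boundary ensemble size.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (boundary draws and Louvain).
#' @return object of class `transition_network`: list with `nodes`
#'   (data.frame: `state_id`, `fraction`, `richness`, `module`), `red_edges`,
#'   `blue_edges`, and `graph` (igraph, edge attribute `type`).
#' @export
build_transition_network <- function(pool, report, labels,
                                     config = model_config(),
                                     boundary = TRUE, n_draws = 1000,
                                     resolution = 1.5, seed = 1) {
  stable_ids <- which(labels$label == "stable")
  red <- build_overlap_edges(report, stable_ids)
  blue <- if (boundary) {
    b <- detect_boundary_pairs(pool, report$states[stable_ids, , drop = FALSE],
                               config, n_draws = n_draws, seed = seed)
    b$from <- stable_ids[b$from]
    b$to <- stable_ids[b$to]
    red_key <- paste(red$from, red$to)
    b[!(paste(b$from, b$to) %in% red_key), , drop = FALSE]
  } else {
    data.frame(from = integer(0), to = integer(0), hits = integer(0))
  }
  nodes <- data.frame(
    state_id = stable_ids,
    fraction = report$fraction[stable_ids],
    richness = state_richness(report$states[stable_ids, , drop = FALSE])
  )
  g <- igraph::graph_from_data_frame(
    rbind(
      data.frame(from = as.character(red$from), to = as.character(red$to),
                 type = rep("red", nrow(red))),
      data.frame(from = as.character(blue$from), to = as.character(blue$to),
                 type = rep("blue", nrow(blue)))
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(stable_ids))
  )
  nodes$module <- partition_modules(red, nodes$state_id,
                                    resolution = resolution, seed = seed)
  structure(list(nodes = nodes, red_edges = red, blue_edges = blue, graph = g),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf(
    "transition network: %d stable states, %d regime-shift edges, %d boundary edges, %d modules\n",
    nrow(x$nodes), nrow(x$red_edges), nrow(x$blue_edges),
    length(unique(x$nodes$module))
  ))
  invisible(x)
}

#' Module partition of the regime-shift graph
#'
#' Louvain modularity maximisation on the red-edge (regime shift) graph at the
#' given resolution. Nodes without any regime-shift edge each form their own
#' module. Greedy modularity is not unique; the seed fixes the partition.
#'
#' @param red_edges data.frame `from`, `to` (state indices).
#' @param node_ids all node ids (isolated ones included).
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return integer module id per node, aligned with `node_ids`.
#' @export
partition_modules <- function(red_edges, node_ids, resolution = 1.5, seed = 1) {
  if (nrow(red_edges) == 0) return(seq_along(node_ids))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(red_edges$from), to = as.character(red_edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(node_ids))
  )
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  as.integer(memb[as.character(node_ids)])
}
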