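#' MCODE parameters
#'
#' Cutoffs of the dense-cluster search, with the defaults used for the
#' study's network analysis: node score cutoff 0.2, degree cutoff 4, k-core 4,
#' maximum depth 100, haircut on, fluff off.
#'
#' @param node_score_cutoff In `[0, 1)`: a vertex may join a cluster when its
#'   weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param degree_cutoff Minimum degree for a vertex to receive non-zero
#'   weight.
#' @param k_core A finished cluster must contain a k-core of at least this
#'   order.
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @param haircut Remove singly-connected vertices from each cluster.
#' @param fluff Unused placeholder for the classic fluff post-processing
#'   (kept off).
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, degree_cutoff = 4,
                         k_core = 4, max_depth = 100,
                         haircut = TRUE, fluff = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    config_error("node_score_cutoff must lie in [0, 1)")
  }
  if (degree_cutoff < 1) config_error("degree_cutoff must be >= 1")
  if (k_core < 2) config_error("k_core must be >= 2")
  structure(as.list(environment()), class = "mcode_params")
}

#' Build a score-thresholded interaction network
#'
#' Keeps edges with combined score at or above the threshold (0.7, the
#' "high confidence" STRING cutoff, by default) and returns a simple
#' undirected igraph. Nodes named in `nodes` are retained even if they end up
#' isolated; otherwise only endpoints of surviving edges appear.
#'
#' @param edges Edge tibble from [read_edge_table()] or
#'   [synthetic_edge_table()].
#' @param min_score Minimum combined score in `[0, 1]`.
#' @param nodes Optional character vector of the node universe to retain.
#' @return An undirected igraph with edge attribute `combined_score`.
#' @export
build_network <- function(edges, min_score = 0.7, nodes = NULL) {
  keep <- edges$combined_score >= min_score
  kept <- edges[keep, , drop = FALSE]
  vertices <- if (is.null(nodes)) {
    sort(unique(c(kept$node_a, kept$node_b)))
  } else {
    sort(unique(c(toupper(nodes), kept$node_a, kept$node_b)))
  }
  g <- igraph::graph_from_data_frame(
    kept[, c("node_a", "node_b", "combined_score")],
    directed = FALSE,
    vertices = data.frame(name = vertices)
  )
  igraph::simplify(g, edge.attr.comb = "max")
}

simple_density <- function(n, m) if (n < 2) 0 else 2 * m / (n * (n - 1))

#' MCODE vertex weighting
#'
#' Each vertex with degree at or above the degree cutoff is weighted by the
#' structure of its closed neighborhood: the highest k-core of the
#' neighborhood subgraph is found, and the weight is that core number times
#' the density of the core subgraph. Vertices below the degree cutoff (and
#' isolated vertices) get weight 0. Deterministic.
#'
#' @param network An igraph from [build_network()].
#' @param params An [mcode_params()].
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(network, params = mcode_params()) {
  deg <- igraph::degree(network)
  w <- stats::setNames(numeric(igraph::vcount(network)), igraph::V(network)$name)
  for (v in which(deg >= params$degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(network, v)))
    sub <- igraph::induced_subgraph(network, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    core_nodes <- which(core >= k)
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    w[v] <- k * simple_density(length(core_nodes), igraph::ecount(core_sub))
  }
  w
}

#' MCODE dense-cluster detection
#'
#' Seeds are taken in decreasing weight order (ties broken by vertex name).
#' From each unvisited seed, a breadth-first expansion up to `max_depth`
#' admits unvisited neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`; once a growing cluster has two or
#' more members, a candidate must additionally be adjacent to at least two
#' current members, which keeps expansion from chaining across single bridge
#' edges between otherwise unrelated dense regions. All vertices touched by an
#' expansion are marked visited, so each vertex belongs to at most one
#' cluster. With `haircut` on, singly-connected vertices are iteratively
#' removed from each candidate; candidates whose highest k-core falls below
#' `k_core` are discarded. Cluster score is density times node count on the
#' induced simple subgraph; clusters are ranked by score, then size, then
#' lexicographically smallest member.
#'
#' @param network An igraph from [build_network()].
#' @param params An [mcode_params()].
#' @return A `tmt_clusters` tibble: `rank`, `score`, `n_nodes`, `n_edges`,
#'   `seed`, `members` (list-column, sorted).
#' @export
mcode_find_clusters <- function(network, params = mcode_params()) {
  names <- igraph::V(network)$name
  w <- mcode_vertex_weights(network, params)
  adj <- igraph::as_adj_list(network)
  adj <- lapply(adj, function(nb) sort(as.integer(nb)))
  order_idx <- order(-w, names)
  visited <- logical(length(names))

  candidates <- list()
  for (seed in order_idx) {
    if (visited[seed]) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (nb in adj[[u]]) {
          if (visited[nb] || nb %in% members) next
          if (w[nb] < threshold) next
          if (length(members) >= 2 && sum(adj[[nb]] %in% members) < 2) next
          members <- c(members, nb)
          nxt <- c(nxt, nb)
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    visited[members] <- TRUE
    candidates[[length(candidates) + 1]] <- list(seed = seed, members = members)
  }

  rows <- purrr::map_dfr(candidates, function(cand) {
    members <- cand$members
    if (params$haircut) {
      repeat {
        sub <- igraph::induced_subgraph(network, members)
        low <- igraph::degree(sub) < 2
        if (!any(low) || all(low)) break
        members <- members[!low]
      }
    }
    if (length(members) < 2) return(NULL)
    sub <- igraph::induced_subgraph(network, members)
    if (max(igraph::coreness(sub)) < params$k_core) return(NULL)
    m <- as.integer(igraph::ecount(sub))
    n <- length(members)
    tibble::tibble(
      score = simple_density(n, m) * n,
      n_nodes = n, n_edges = m,
      seed = names[cand$seed],
      members = list(sort(names[members]))
    )
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(
      rank = integer(), score = numeric(), n_nodes = integer(),
      n_edges = integer(), seed = character(), members = list()
    )
    return(structure(rows, class = c("tmt_clusters", class(rows))))
  }
  first_member <- vapply(rows$members, `[[`, character(1), 1)
  ord <- order(-rows$score, -rows$n_nodes, first_member)
  rows <- rows[ord, ]
  rows <- dplyr::mutate(rows, rank = dplyr::row_number(), .before = 1)
  structure(rows, class = c("tmt_clusters", class(rows)))
}

#' @export
tidy.tmt_clusters <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(members = purrr::map_chr(.data$members, paste, collapse = ";"))
}
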