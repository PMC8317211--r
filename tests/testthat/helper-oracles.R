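# Independent reference implementations used as oracles. These are written
# against plain adjacency matrices / exhaustive enumeration and share no code
# with the package's implementations.

# exact hypergeometric upper tail by enumerating every possible draw
ref_hyper_enum <- function(k, set, universe, n_query) {
  draws <- utils::combn(length(universe), n_query)
  in_set <- universe %in% set
  hits <- apply(draws, 2, function(idx) sum(in_set[idx]))
  mean(hits >= k)
}

# core numbers by iterative minimum-degree peeling
ref_core_numbers <- function(A) {
  n <- nrow(A)
  if (n == 0) return(integer(0))
  deg <- rowSums(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0
  for (step in seq_len(n)) {
    cand <- which(alive)
    i <- cand[which.min(deg[cand])]
    k <- max(k, deg[i])
    core[i] <- k
    alive[i] <- FALSE
    nb <- which(A[i, ] == 1 & alive)
    deg[nb] <- deg[nb] - 1
  }
  core
}

ref_density <- function(n, m) if (n < 2) 0 else 2 * m / (n * (n - 1))

ref_mcode_weights <- function(A, params) {
  n <- nrow(A)
  w <- numeric(n)
  deg <- rowSums(A)
  for (v in seq_len(n)) {
    if (deg[v] < params$degree_cutoff) next
    nb <- sort(c(v, which(A[v, ] == 1)))
    S <- A[nb, nb, drop = FALSE]
    core <- ref_core_numbers(S)
    k <- max(core)
    cn <- which(core >= k)
    m <- sum(S[cn, cn]) / 2
    w[v] <- k * ref_density(length(cn), m)
  }
  w
}

# reference cluster search: same admission rules, plain-matrix implementation.
# vertex order is the row order of A (assumed sorted by name).
ref_mcode <- function(A, names, params) {
  n <- nrow(A)
  w <- ref_mcode_weights(A, params)
  visited <- rep(FALSE, n)
  out <- list()
  for (seed in order(-w, names)) {
    if (visited[seed]) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (nb in which(A[u, ] == 1)) {
          if (visited[nb] || nb %in% members) next
          if (w[nb] < threshold) next
          if (length(members) >= 2 && sum(A[nb, members]) < 2) next
          members <- c(members, nb)
          nxt <- c(nxt, nb)
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    visited[members] <- TRUE
    if (params$haircut) {
      repeat {
        S <- A[members, members, drop = FALSE]
        low <- rowSums(S) < 2
        if (!any(low) || all(low)) break
        members <- members[!low]
      }
    }
    if (length(members) < 2) next
    S <- A[members, members, drop = FALSE]
    if (max(ref_core_numbers(S)) < params$k_core) next
    m <- sum(S) / 2
    nn <- length(members)
    out[[length(out) + 1]] <- list(
      score = ref_density(nn, m) * nn,
      n_nodes = nn, n_edges = m,
      members = sort(names[members])
    )
  }
  if (!length(out)) return(out)
  first <- vapply(out, function(cl) cl$members[1], character(1))
  scores <- vapply(out, `[[`, numeric(1), "score")
  sizes <- vapply(out, `[[`, numeric(1), "n_nodes")
  out[order(-scores, -sizes, first)]
}

# random simple graph as an edge tibble + adjacency matrix over sorted names
random_graph <- function(n_nodes, p_edge, seed) {
  withr::with_seed(seed, {
    names <- sprintf("N%02d", seq_len(n_nodes))
    A <- matrix(0L, n_nodes, n_nodes, dimnames = list(names, names))
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        if (stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- 1L
      }
    }
    idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    edges <- tibble::tibble(
      node_a = names[idx[, 1]], node_b = names[idx[, 2]],
      combined_score = 1
    )
    list(A = A, names = names, edges = edges)
  })
}

edges_from_pairs <- function(pairs) {
  tibble::tibble(
    node_a = vapply(pairs, `[[`, character(1), 1),
    node_b = vapply(pairs, `[[`, character(1), 2),
    combined_score = 1
  )
}

clique_edges <- function(members) {
  cmb <- utils::combn(sort(members), 2)
  tibble::tibble(node_a = cmb[1, ], node_b = cmb[2, ], combined_score = 1)
}
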