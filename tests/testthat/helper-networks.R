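# Small network constructors and independent oracles used across tests.

# build a flow_network from an edge list given as c("A->B" = 1, ...)
make_net <- function(edges, nodes = NULL, imports = 0, exports = 0,
                     respiration = 0, element = "C") {
  pairs <- strsplit(names(edges), "->", fixed = TRUE)
  if (is.null(nodes))
    nodes <- unique(unlist(pairs))
  Tm <- matrix(0, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  for (i in seq_along(edges))
    Tm[pairs[[i]][1], pairs[[i]][2]] <- edges[[i]]
  flow_network(Tm, imports = imports, exports = exports,
               respiration = respiration, element = element)
}

# balanced A -> B -> C chain: import 1 at A, respiration 1 at C
chain_net <- function() {
  make_net(c("A->B" = 1, "B->C" = 1),
           imports = c(A = 1), respiration = c(C = 1))
}

# A feeds B and C equally
fan_net <- function(w = 0.5) {
  make_net(c("A->B" = w, "A->C" = w),
           imports = c(A = 2 * w), respiration = c(B = w, C = w))
}

# --- oracle: trophic positions by explicit walk expansion --------------
# Expands TP_i = sum over walks from i down to a basal node of
# (product of diet fractions) * (walk length + basal TP), truncating
# walk prefixes whose probability mass drops below `cut`.  Independent
# of the linear solve in trophic_positions().
oracle_tp <- function(net, basal, cut = 1e-12) {
  nodes <- net$nodes
  ingest <- colSums(net$T)
  f <- function(i, j) net$T[j, i] / ingest[i]   # fraction of i's diet from j
  walk <- function(i, mass, len) {
    if (i %in% names(basal)) return(mass * (len + basal[[i]]))
    if (mass < cut) return(mass * (len + 1))    # truncate: bounded error
    tot <- 0
    for (j in nodes[net$T[, i] > 0])
      tot <- tot + walk(j, mass * f(i, j), len + 1)
    tot
  }
  vapply(nodes, function(i) walk(i, 1, 0), numeric(1))
}

# --- oracle: exhaustive simple-path enumeration ------------------------
# All simple paths between two nodes of a symmetrized weighted graph;
# returns minimal hop count and the maximal summed relative strength
# among the minimum-hop paths.
oracle_paths <- function(W, f, from, to) {
  n <- nrow(W)
  best <- list(d = Inf, score = -Inf)
  visit <- function(v, seen, hops, score) {
    if (v == to) {
      if (hops < best$d || (hops == best$d && score > best$score))
        best <<- list(d = hops, score = score)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !seen[u])
        visit(u, `[<-`(seen, u, TRUE), hops + 1, score + f[v, u])
    }
  }
  seen <- rep(FALSE, n); seen[from] <- TRUE
  visit(from, seen, 0, 0)
  best
}

# --- oracle: weighted clustering by literal triple enumeration ---------
oracle_clustering_q <- function(W, i) {
  adj <- W > 0
  nb <- which(adj[i, ])
  if (length(nb) < 2) return(0)
  tot <- 0
  for (j in nb) for (k in nb)
    if (j != k && adj[j, k]) tot <- tot + (W[i, j] + W[i, k]) / 2
  tot / (sum(W[i, ]) * (length(nb) - 1))
}

# random connected-ish small flow network for property sweeps
random_small_net <- function(n_nodes, p_link = 0.5) {
  nodes <- LETTERS[seq_len(n_nodes)]
  Tm <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i != j && stats::runif(1) < p_link)
      Tm[i, j] <- stats::runif(1, 0.1, 5)
  }
  flow_network(Tm, imports = stats::setNames(rep(1, n_nodes), nodes),
               exports = stats::setNames(rep(1, n_nodes), nodes))
}
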