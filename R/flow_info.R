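#' Flow diversity, average mutual information and overhead
#'
#' Information-theoretic summary of a flow distribution.  Over the
#' selected flow set with total TST, the flow diversity is the Shannon
#' entropy of the flows, H_flow = -sum (T_ij/TST) log(T_ij/TST); the
#' average mutual information AMI = sum (T_ij/TST) log(T_ij TST /
#' (T_i. T_.j)) measures how strongly the flow pattern couples source
#' and target nodes (T_i. and T_.j are node output and input
#' throughputs over the same selection); and the conditional entropy
#' Phi = H_flow - AMI is the relative overhead, the residual uncertainty
#' in the flow pattern.  All three are reported in bits by default and
#' are invariant under global rescaling of the flows.
#'
#' @inheritParams select_flows
#' @param base logarithm base (default 2, bits).
#' @return A list with \code{TST}, \code{H_flow}, \code{AMI} and
#'   \code{Phi}.
#' @export
#' @examples
#' Tm <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' Tm["A", "B"] <- 1; Tm["B", "C"] <- 1
#' net <- flow_network(Tm, imports = c(A = 1), respiration = c(C = 1))
#' flow_information(net)   # chain: H_flow = AMI = 1 bit, Phi = 0
flow_information <- function(net, selection = c("trophic_detrital",
                                                "full_throughput"),
                             base = 2) {
  fl <- select_flows(net, selection)
  if (nrow(fl) == 0L) stop("empty flow set")
  tst <- sum(fl$flow)
  p <- fl$flow / tst
  out_tot <- tapply(fl$flow, fl$from, sum)
  in_tot <- tapply(fl$flow, fl$to, sum)
  H <- -sum(p * log(p, base = base))
  ami <- sum(p * log(fl$flow * tst /
                       (out_tot[fl$from] * in_tot[fl$to]), base = base))
  list(TST = tst, H_flow = H, AMI = ami, Phi = H - ami)
}

#' Weighted link density and weighted connectance
#'
#' The effective number of flow connections per node, Conn_w =
#' base^(Phi/2), where Phi is the conditional entropy (overhead) of the
#' selected flow distribution, and its normalization C_w = Conn_w / S by
#' the number S of nodes touching at least one selected flow.  By
#' convention connectance only counts feeding links, so the default flow
#' set excludes external in-/outputs, storage and respiration.  For
#' perfectly uniform flows on a k-regular directed graph, Conn_w equals
#' the binary link density L/S exactly.  The exponent base follows the
#' entropy base (bits by default) so that the index is internally
#' consistent.
#'
#' @inheritParams flow_information
#' @return A list with \code{Conn_w}, \code{C_w}, \code{S} and the
#'   underlying \code{Phi}.
#' @export
weighted_connectance <- function(net, selection = c("trophic_detrital",
                                                    "full_throughput"),
                                 base = 2) {
  selection <- match.arg(selection)
  fi <- flow_information(net, selection, base = base)
  fl <- select_flows(net, selection)
  S <- length(unique(c(fl$from, fl$to)))
  conn <- base^(fi$Phi / 2)
  list(Conn_w = conn, C_w = conn / S, S = S, Phi = fi$Phi)
}

#' The ascendency family of network indices
#'
#' Quantifies the information content and activity of the energy-flow
#' network: ascendency Asc = TST * AMI, its upper bound the development
#' capacity K_dev = TST * H_flow, the overhead L_over = K_dev - Asc, the
#' relative ascendency Asc_rel = AMI / H_flow in [0, 1], and the fitness
#' F = -Asc_rel ln(Asc_rel) (natural log, k = 1), which is maximal at
#' Asc_rel = 1/e (about 0.36) and taken as 0 at both boundaries.
#' Defaults to the full throughput flow set (boundary flows included);
#' the weighted connectance reported alongside uses its own default
#' feeding-link selection.
#'
#' @inheritParams flow_information
#' @param connectance_selection flow set for the embedded
#'   \code{\link{weighted_connectance}} call.
#' @return A list (class \code{info_summary}) with \code{TST},
#'   \code{H_flow}, \code{AMI}, \code{Phi}, \code{Conn_w}, \code{C_w},
#'   \code{Asc}, \code{K_dev}, \code{L_over}, \code{Asc_rel}, \code{F}.
#' @export
ascendency_suite <- function(net, selection = c("full_throughput",
                                                "trophic_detrital"),
                             base = 2,
                             connectance_selection = "trophic_detrital") {
  selection <- match.arg(selection)
  fi <- flow_information(net, selection, base = base)
  if (fi$H_flow == 0)
    stop("flow diversity is zero: relative ascendency undefined")
  cw <- weighted_connectance(net, connectance_selection, base = base)
  asc_rel <- fi$AMI / fi$H_flow
  F <- if (asc_rel <= 0 || asc_rel >= 1) 0 else -asc_rel * log(asc_rel)
  structure(list(TST = fi$TST, H_flow = fi$H_flow, AMI = fi$AMI,
                 Phi = fi$Phi, Conn_w = cw$Conn_w, C_w = cw$C_w,
                 Asc = fi$TST * fi$AMI, K_dev = fi$TST * fi$H_flow,
                 L_over = fi$TST * (fi$H_flow - fi$AMI),
                 Asc_rel = asc_rel, F = F),
            class = "info_summary")
}

#' @export
print.info_summary <- function(x, ...) {
  cat(sprintf(paste0("TST %.4g | H_flow %.3f AMI %.3f Phi %.3f bits | ",
                     "Conn_w %.3f C_w %.3f | Asc %.4g K_dev %.4g ",
                     "Asc_rel %.3f F %.3f\n"),
              x$TST, x$H_flow, x$AMI, x$Phi, x$Conn_w, x$C_w,
              x$Asc, x$K_dev, x$Asc_rel, x$F))
  invisible(x)
}

# symmetrized weighted adjacency of the internal flow graph
# (self-loops excluded from the graph; kept only in the binary link count)
.symmetric_web <- function(net) {
  W <- net$T + t(net$T)
  diag(W) <- 0
  keep <- rowSums(W) > 0
  list(W = W[keep, keep, drop = FALSE],
       L = sum(net$T > 0),                       # directed binary links
       S = sum(colSums(net$T) + rowSums(net$T) > 0))
}

# relative edge strength: flow divided by the larger endpoint's total flow
.relative_strengths <- function(W) {
  s <- rowSums(W)
  f <- W / outer(s, s, pmax)
  f[W == 0] <- 0
  f
}

#' Weighted characteristic path length
#'
#' Average shortest distance between pairs of distinct nodes on the
#' symmetrized flow graph (edge weight = flow i->j plus flow j->i;
#' self-loops ignored).  The distance d_ij is the number of links on the
#' selected path; among the minimum-hop paths connecting a pair, the one
#' maximizing the summed relative flow strength f (edge flow over the
#' larger endpoint's total flow) is selected, which breaks ties but
#' leaves the hop count itself topological.  D is the mean d_ij over
#' reachable pairs (unreachable pairs are excluded and counted);
#' D_norm = D / (ln S / ln Conn_bin) compares D against the expected
#' path length of a random graph with the same binary link density
#' Conn_bin = L/S.
#'
#' @param net a \code{\link{flow_network}}.
#' @return A list with \code{D}, \code{D_norm}, \code{n_pairs},
#'   \code{n_unreachable}, \code{Conn_bin}, and matrices \code{d} (hop
#'   distances) and \code{score} (maximal summed relative flow strength
#'   among minimum-hop paths).
#' @export
weighted_path_length <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  sw <- .symmetric_web(net)
  W <- sw$W
  n <- nrow(W)
  if (n < 2) stop("fewer than two flow-carrying nodes")
  f <- .relative_strengths(W)
  adj <- W > 0
  d <- matrix(Inf, n, n, dimnames = dimnames(W))
  score <- matrix(-Inf, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    # BFS layers from i with layered max-sum-f dynamic programming
    dist <- rep(Inf, n); best <- rep(-Inf, n)
    dist[i] <- 0; best[i] <- 0
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ])
        for (u in nb) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[v] + 1
            nxt <- c(nxt, u)
          }
          if (dist[u] == dist[v] + 1)
            best[u] <- max(best[u], best[v] + f[v, u])
        }
      }
      frontier <- unique(nxt)
    }
    d[i, ] <- dist; score[i, ] <- best
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[pairs]
  unreach <- sum(is.infinite(dd))
  if (unreach > 0)
    warning(unreach, " unreachable node pair(s) excluded from D")
  dd <- dd[is.finite(dd)]
  if (!length(dd)) stop("no reachable pairs")
  D <- mean(dd)
  conn_bin <- sw$L / sw$S
  if (conn_bin <= 1) {
    warning("binary link density L/S must exceed 1: D_norm undefined")
    dnorm <- NA_real_
  } else {
    dnorm <- D / (log(sw$S) / log(conn_bin))
  }
  list(D = D, D_norm = dnorm,
       n_pairs = length(dd), n_unreachable = unreach,
       Conn_bin = conn_bin, d = d, score = score)
}

#' Weighted average clustering coefficient
#'
#' Barrat-style local clustering on the symmetrized flow graph: for node
#' i, q_i sums (f_ij + f_ik)/2 over ordered pairs of neighbors (j, k)
#' that are themselves connected, normalized by s_i (K_i - 1) where s_i
#' is i's total edge flow and K_i its degree; 0 <= q_i <= 1, nodes with
#' degree < 2 contribute 0, self-loops never close a triangle.  Q is the
#' mean q_i; Q_norm = Q / C_bin compares it against the clustering of a
#' random graph with the binary connectance C_bin = L/S^2 of the
#' directed web.
#'
#' @param net a \code{\link{flow_network}}.
#' @return A list with \code{Q}, \code{Q_norm}, \code{C_bin} and the
#'   per-node vector \code{q}.
#' @export
weighted_clustering <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  sw <- .symmetric_web(net)
  W <- sw$W
  n <- nrow(W)
  if (n == 0) stop("empty graph")
  adj <- W > 0
  deg <- rowSums(adj)
  s <- rowSums(W)
  q <- stats::setNames(numeric(n), rownames(W))
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(adj[i, ])
    tot <- 0
    for (j in nb) for (k in nb)
      if (j != k && adj[j, k]) tot <- tot + (W[i, j] + W[i, k]) / 2
    q[i] <- tot / (s[i] * (deg[i] - 1))
  }
  Q <- mean(q)
  c_bin <- sw$L / sw$S^2
  list(Q = Q, Q_norm = Q / c_bin, C_bin = c_bin, q = q)
}
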