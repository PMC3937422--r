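#' Construct a mass-balanced flow network
#'
#' A flow network holds one phase's internal flow matrix for one element
#' (carbon or phosphorus) together with the boundary flows of every node:
#' imports, exports, respiration and the two nonnegative biomass storage
#' terms.  All flows are in mass of element per area and day (by default
#' ug element m^-2 d^-1).  Mass balance requires, for every node, that the
#' sum of ingoing flows (internal inflows + import + storage release)
#' equals the sum of outgoing flows (internal outflows + export +
#' respiration + storage accrual); see \code{\link{validate_mass_balance}}.
#'
#' @param T square numeric matrix of internal flows, \code{T[i, j]} is the
#'   flow from node \code{i} to node \code{j}; dimnames give the node
#'   labels (row and column names must agree).
#' @param imports,exports,respiration,storage_in,storage_out numeric
#'   vectors of boundary flows per node (recycled from scalars, names
#'   optional but must match the node set when given). Missing terms
#'   default to zero.
#' @param element \code{"C"} or \code{"P"}. Phosphorus networks carry no
#'   respiratory loss (\code{respiration} must be all zero).
#' @param phase phase label (free-form, typically one of
#'   \code{\link{phase_axis}}).
#' @param units unit string recorded as metadata.
#' @return An object of class \code{flow_network}.
#' @export
#' @examples
#' Tm <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' Tm["A", "B"] <- 1
#' net <- flow_network(Tm, imports = c(A = 1), respiration = c(B = 1))
#' validate_mass_balance(net)
flow_network <- function(T, imports = 0, exports = 0, respiration = 0,
                         storage_in = 0, storage_out = 0,
                         element = c("C", "P"), phase = NA_character_,
                         units = "ug m-2 d-1") {
  element <- match.arg(element)
  if (!is.matrix(T) || nrow(T) != ncol(T))
    stop("`T` must be a square matrix of internal flows")
  nodes <- rownames(T)
  if (is.null(nodes) || !identical(nodes, colnames(T)))
    stop("`T` must carry identical row and column names (the node labels)")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (any(T < 0)) stop("negative flow in internal flow matrix")
  fix <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(as.numeric(x), length(nodes)), nodes)
    else {
      full <- stats::setNames(numeric(length(nodes)), nodes)
      if (is.null(names(x))) {
        if (length(x) != length(nodes))
          stop("unnamed `", what, "` must have one entry per node")
        full[] <- x
      } else {
        bad <- setdiff(names(x), nodes)
        if (length(bad))
          stop("unknown node in `", what, "`: ", paste(bad, collapse = ", "))
        full[names(x)] <- x
      }
      x <- full
    }
    if (any(x < 0)) stop("negative flow in `", what, "`")
    x
  }
  net <- structure(list(
    element = element, phase = phase, nodes = nodes, T = T,
    imports = fix(imports, "imports"), exports = fix(exports, "exports"),
    respiration = fix(respiration, "respiration"),
    storage_in = fix(storage_in, "storage_in"),
    storage_out = fix(storage_out, "storage_out"),
    units = units), class = "flow_network")
  if (element == "P" && any(net$respiration > 0))
    stop("phosphorus networks carry no respiratory loss (respiration must be 0)")
  if ("PDOM" %in% nodes && net$respiration[["PDOM"]] > 0)
    stop("respiration of the detritus pool PDOM must be 0")
  net
}

#' @export
print.flow_network <- function(x, ...) {
  nl <- sum(x$T > 0)
  cat(sprintf("<flow_network> element %s, phase %s: %d nodes, %d internal links\n",
              x$element, x$phase, length(x$nodes), nl))
  tst <- tryCatch(total_system_throughput(x, "full_throughput"),
                  error = function(e) NA_real_)
  cat(sprintf("  TST (all flows): %.4g %s\n", tst, x$units))
  invisible(x)
}

# virtual boundary node labels used in the full-throughput flow set
.boundary_labels <- c(input = "<input>", export = "<export>",
                      respiration = "<respiration>", storage = "<storage>")

#' Select a flow set from a network
#'
#' Pure filter returning the multiset of flows a given index is computed
#' over.  \code{"trophic_detrital"} keeps only the internal flows (feeding
#' and detrital links).  \code{"full_throughput"} additionally includes
#' imports, exports, respiration and biomass storage flows, represented as
#' flows from/to virtual boundary nodes (\code{"<input>"},
#' \code{"<export>"}, \code{"<respiration>"}, \code{"<storage>"}) so that
#' boundary terms enter node throughputs exactly once.  Zero flows are
#' dropped.
#'
#' @param net a \code{\link{flow_network}}.
#' @param selection \code{"trophic_detrital"} or \code{"full_throughput"}.
#' @return A data.frame with columns \code{from}, \code{to}, \code{flow}.
#' @export
select_flows <- function(net, selection = c("trophic_detrital",
                                            "full_throughput")) {
  selection <- match.arg(selection)
  stopifnot(inherits(net, "flow_network"))
  idx <- which(net$T > 0, arr.ind = TRUE)
  fl <- data.frame(from = net$nodes[idx[, 1]], to = net$nodes[idx[, 2]],
                   flow = net$T[idx], stringsAsFactors = FALSE)
  if (selection == "full_throughput") {
    add <- function(x, from, to) {
      keep <- x > 0
      if (!any(keep)) return(NULL)
      data.frame(from = if (is.null(from)) names(x)[keep] else from,
                 to = if (is.null(to)) names(x)[keep] else to,
                 flow = unname(x[keep]), stringsAsFactors = FALSE)
    }
    fl <- rbind(fl,
                add(net$imports, .boundary_labels[["input"]], NULL),
                add(net$exports, NULL, .boundary_labels[["export"]]),
                add(net$respiration, NULL, .boundary_labels[["respiration"]]),
                add(net$storage_in, .boundary_labels[["storage"]], NULL),
                add(net$storage_out, NULL, .boundary_labels[["storage"]]))
  }
  rownames(fl) <- NULL
  fl
}

#' Validate the per-node mass balance of a flow network
#'
#' For every node the residual (inflows + import + storage release) minus
#' (outflows + export + respiration + storage accrual) is computed; the
#' node passes if its absolute residual does not exceed \code{rtol} times
#' the larger of its total inputs and outputs.
#'
#' @param net a \code{\link{flow_network}}.
#' @param rtol relative tolerance. The default \code{1e-6} suits
#'   synthetically constructed networks; imported empirical networks
#'   typically only balance to a few percent (use e.g. \code{rtol = 0.05}).
#' @return A data.frame (class \code{balance_report}) with per-node
#'   \code{inputs}, \code{outputs}, \code{residual} and \code{pass}, plus
#'   attributes \code{pass} (overall) and \code{worst} (node with the
#'   largest relative residual).
#' @export
validate_mass_balance <- function(net, rtol = 1e-6) {
  stopifnot(inherits(net, "flow_network"))
  inputs <- colSums(net$T) + net$imports + net$storage_in
  outputs <- rowSums(net$T) + net$exports + net$respiration + net$storage_out
  residual <- inputs - outputs
  scale <- pmax(inputs, outputs)
  rel <- ifelse(scale > 0, abs(residual) / scale, 0)
  rep <- data.frame(node = net$nodes, inputs = unname(inputs),
                    outputs = unname(outputs), residual = unname(residual),
                    rel_residual = unname(rel),
                    pass = unname(rel <= rtol | scale == 0),
                    stringsAsFactors = FALSE)
  attr(rep, "pass") <- all(rep$pass)
  attr(rep, "worst") <- rep$node[which.max(rep$rel_residual)]
  attr(rep, "rtol") <- rtol
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Mass balance %s (rtol %g); worst node: %s (rel. residual %.3g)\n",
              if (attr(x, "pass")) "PASS" else "FAIL", attr(x, "rtol"),
              attr(x, "worst"), max(x$rel_residual)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Total system throughput
#'
#' The sum of the selected flow set.  With \code{"full_throughput"} this
#' is the classical TST: every internal flow plus every boundary flow
#' (imports, exports, respiration, storage), each counted once.
#'
#' @inheritParams select_flows
#' @return A single number in the network's units.
#' @export
total_system_throughput <- function(net,
                                    selection = c("trophic_detrital",
                                                  "full_throughput")) {
  fl <- select_flows(net, selection)
  if (nrow(fl) == 0L) stop("empty selection: no positive flows in network")
  sum(fl$flow)
}

#' Aggregate a flow network to a coarser node resolution
#'
#' Flows are summed within supernode pairs; flows internal to a supernode
#' become self-loops (retained and flagged via attribute
#' \code{self_loops}); boundary flows are summed.  Aggregation conserves
#' TST and every boundary total exactly, and preserves mass balance.
#'
#' @param net a \code{\link{flow_network}}.
#' @param mapping named character vector: node label -> supernode label;
#'   must cover every node of \code{net}.
#' @return A \code{flow_network} on the supernodes.
#' @export
aggregate_network <- function(net, mapping) {
  stopifnot(inherits(net, "flow_network"))
  missing <- setdiff(net$nodes, names(mapping))
  if (length(missing))
    stop("mapping missing node(s): ", paste(missing, collapse = ", "))
  sup <- mapping[net$nodes]
  supnodes <- unique(unname(sup))
  A <- outer(supnodes, sup, "==") * 1  # supernode x node indicator
  Tagg <- A %*% net$T %*% t(A)
  dimnames(Tagg) <- list(supnodes, supnodes)
  aggv <- function(v) stats::setNames(as.vector(A %*% v), supnodes)
  out <- flow_network(Tagg, imports = aggv(net$imports),
                      exports = aggv(net$exports),
                      respiration = aggv(net$respiration),
                      storage_in = aggv(net$storage_in),
                      storage_out = aggv(net$storage_out),
                      element = net$element, phase = net$phase,
                      units = net$units)
  attr(out, "self_loops") <- supnodes[diag(Tagg) > 0]
  out
}

#' Disaggregate an 8-group network onto the 24-guild resolution
#'
#' The flows between the 24 guilds were not directly measurable; each
#' group-to-group flow is therefore divided uniformly among the
#' guild-level feeding links it covers: equally among the consumer
#' group's guilds with at least one diet link into the resource group,
#' then, within each such consumer guild, equally among its resource
#' guilds in that group.  Detrital group flows and boundary flows are
#' split equally among the guilds of the group.  Group-pair totals and
#' all boundary totals are conserved exactly, so re-aggregating the
#' result reproduces the input network.
#'
#' Note the disaggregated network is generally not mass-balanced per
#' guild (only per group): the uniform split is a structural
#' approximation used for the small-world indices, not a budget.
#'
#' @param net8 a \code{\link{flow_network}} on the 8 groups + PDOM.
#' @param guilds guild table as returned by \code{\link{lc_guilds}}.
#' @return A \code{flow_network} on the 24 guilds + PDOM.
#' @export
disaggregate_flows <- function(net8, guilds = lc_guilds()) {
  stopifnot(inherits(net8, "flow_network"))
  map <- lc_aggregation_map("24to8")
  gnodes <- c(guilds$name, "PDOM")
  group_of <- map[gnodes]
  Tg <- matrix(0, length(gnodes), length(gnodes),
               dimnames = list(gnodes, gnodes))
  # guild-level diet links (resource name -> consumer name), 0 = PDOM
  res_names <- lapply(guilds$diet, function(d)
    ifelse(d == 0L, "PDOM", guilds$name[match(d, guilds$id)]))
  names(res_names) <- guilds$name
  idx <- which(net8$T > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    src <- net8$nodes[idx[r, 1]]; dst <- net8$nodes[idx[r, 2]]
    flow <- net8$T[idx[r, 1], idx[r, 2]]
    if (dst == "PDOM") {
      members <- gnodes[group_of == src & gnodes != "PDOM"]
      Tg[members, "PDOM"] <- Tg[members, "PDOM"] + flow / length(members)
      next
    }
    consumers <- guilds$name[guilds$group == dst]
    # resources of each consumer guild inside the source group
    res_in_src <- lapply(res_names[consumers], function(rn)
      rn[group_of[rn] == src])
    consumers <- consumers[lengths(res_in_src) > 0]
    res_in_src <- res_in_src[lengths(res_in_src) > 0]
    if (!length(consumers))
      stop("group flow ", src, " -> ", dst,
           " has no compatible guild-level link")
    share_c <- flow / length(consumers)
    for (ci in seq_along(consumers)) {
      rs <- res_in_src[[ci]]
      Tg[rs, consumers[ci]] <- Tg[rs, consumers[ci]] + share_c / length(rs)
    }
  }
  splitv <- function(v) {
    out <- stats::setNames(numeric(length(gnodes)), gnodes)
    for (grp in net8$nodes) {
      members <- gnodes[group_of == grp]
      out[members] <- out[members] + v[[grp]] / length(members)
    }
    out
  }
  flow_network(Tg, imports = splitv(net8$imports),
               exports = splitv(net8$exports),
               respiration = splitv(net8$respiration),
               storage_in = splitv(net8$storage_in),
               storage_out = splitv(net8$storage_out),
               element = net8$element, phase = net8$phase, units = net8$units)
}

#' Read and write flow networks as CSV pairs
#'
#' The on-disk form is a pair of plain CSV files: an edge file with
#' columns \code{source,target,flow} and a node file with columns
#' \code{node,import,export,respiration,storage_in,storage_out} plus the
#' metadata columns \code{element}, \code{phase} and \code{units}
#' (constant per file).  Missing boundary columns default to 0.
#'
#' @param edge_file,node_file paths to the two CSV files.
#' @return \code{read_flow_network} returns a \code{\link{flow_network}};
#'   \code{write_flow_network} invisibly returns the two paths.
#' @export
read_flow_network <- function(edge_file, node_file) {
  ed <- tryCatch(utils::read.csv(edge_file, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed edge CSV '", edge_file,
                                          "': ", conditionMessage(e)))
  nd <- tryCatch(utils::read.csv(node_file, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed node CSV '", node_file,
                                          "': ", conditionMessage(e)))
  need <- c("source", "target", "flow")
  if (!all(need %in% names(ed)))
    stop("edge file must have columns source,target,flow")
  if (!"node" %in% names(nd)) stop("node file must have a 'node' column")
  if (any(is.na(ed$flow)))
    stop("malformed edge CSV: non-numeric flow in row ",
         which(is.na(ed$flow))[1])
  if (any(ed$flow < 0))
    stop("negative flow in edge row ", which(ed$flow < 0)[1])
  if (anyDuplicated(ed[c("source", "target")]))
    stop("duplicate (source,target) pair in edge file")
  nodes <- nd$node
  unknown <- setdiff(unique(c(ed$source, ed$target)), nodes)
  if (length(unknown))
    stop("edge file references unknown node(s): ",
         paste(unknown, collapse = ", "))
  Tm <- matrix(0, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  Tm[cbind(match(ed$source, nodes), match(ed$target, nodes))] <- ed$flow
  col <- function(nm) {
    if (nm %in% names(nd)) stats::setNames(nd[[nm]], nodes)
    else stats::setNames(numeric(length(nodes)), nodes)
  }
  meta <- function(nm, default) {
    if (nm %in% names(nd)) as.character(nd[[nm]][1]) else default
  }
  flow_network(Tm, imports = col("import"), exports = col("export"),
               respiration = col("respiration"),
               storage_in = col("storage_in"),
               storage_out = col("storage_out"),
               element = meta("element", "C"),
               phase = meta("phase", NA_character_),
               units = meta("units", "ug m-2 d-1"))
}

#' @rdname read_flow_network
#' @param net a \code{\link{flow_network}} to write.
#' @export
write_flow_network <- function(net, edge_file, node_file) {
  stopifnot(inherits(net, "flow_network"))
  fl <- select_flows(net, "trophic_detrital")
  utils::write.csv(data.frame(source = fl$from, target = fl$to,
                              flow = fl$flow),
                   edge_file, row.names = FALSE, quote = FALSE)
  nd <- data.frame(node = net$nodes, import = unname(net$imports),
                   export = unname(net$exports),
                   respiration = unname(net$respiration),
                   storage_in = unname(net$storage_in),
                   storage_out = unname(net$storage_out),
                   element = net$element, phase = net$phase,
                   units = net$units)
  utils::write.csv(nd, node_file, row.names = FALSE, quote = FALSE)
  invisible(c(edge_file, node_file))
}
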