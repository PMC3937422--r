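#' Flow-weighted trophic positions and fractional trophic levels
#'
#' Solves the flow-weighted trophic position of every node,
#' TP_i = 1 + sum_j f_ij TP_j, where f_ij is the fraction of consumer i's
#' total ingestion obtained from resource j.  Basal nodes are fixed:
#' by default the detritus pool PDOM sits at trophic position 0,
#' phytoplankton and heterotrophic bacteria (nodes \code{"Phy"} and
#' \code{"Bac"} when present, plus any node without ingestion) at 1.
#' Cycles, including cannibalistic self-loops, are handled by the linear
#' solve.  The fractional level weights p_i(k) (the share of node i's
#' flow rooted at integer level k) are propagated as
#' p_i(k) = sum_j f_ij p_j(k-1) and satisfy sum_k p_i(k) = 1 and
#' TP_i = sum_k k p_i(k).
#'
#' @param net a \code{\link{flow_network}}; trophic positions use the
#'   internal (trophic + detrital) flows.
#' @param basal optional named numeric vector fixing trophic positions of
#'   basal nodes (integer levels). Defaults as described above.
#' @param tol truncation tolerance for the fractional-level expansion.
#' @return An object of class \code{trophic_decomposition}: a list with
#'   \code{tp} (named vector of trophic positions), \code{levels} (matrix
#'   node x integer level of fractional weights, column names "0","1",...)
#'   and \code{f} (the diet-fraction matrix, consumers in rows).
#' @export
#' @examples
#' Tm <- matrix(0, 2, 2, dimnames = list(c("P", "H"), c("P", "H")))
#' Tm["P", "H"] <- 1
#' net <- flow_network(Tm, imports = c(P = 1), respiration = c(H = 1))
#' trophic_positions(net)$tp   # P at 1, H at 2
trophic_positions <- function(net, basal = NULL, tol = 1e-13) {
  stopifnot(inherits(net, "flow_network"))
  nodes <- net$nodes
  ingest <- colSums(net$T)
  if (is.null(basal)) {
    basal <- stats::setNames(rep(1, sum(ingest == 0)), nodes[ingest == 0])
    for (nm in intersect(c("Phy", "Bac"), nodes)) basal[nm] <- 1
    if ("PDOM" %in% nodes) basal["PDOM"] <- 0
  }
  bad <- setdiff(names(basal), nodes)
  if (length(bad)) stop("unknown basal node(s): ", paste(bad, collapse = ", "))
  fixed <- nodes %in% names(basal)
  cons <- nodes[!fixed]
  zero <- cons[ingest[cons] == 0]
  if (length(zero))
    stop("consumer with zero total ingestion: ", paste(zero, collapse = ", "))
  # f[i, j]: fraction of i's ingestion coming from j
  f <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (length(cons))
    f[cons, ] <- t(net$T[, cons, drop = FALSE]) / ingest[cons]
  tp <- stats::setNames(numeric(length(nodes)), nodes)
  tp[names(basal)] <- basal
  if (length(cons)) {
    A <- diag(length(cons)) - f[cons, cons, drop = FALSE]
    rhs <- 1 + f[cons, names(basal), drop = FALSE] %*% basal
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("singular trophic system (closed consumer loop with no basal path)"))
    tp[cons] <- sol[, 1]
  }
  # fractional level weights: p(0) and p(1) seed the fixed nodes, then
  # p_i(k) = sum_j f_ij p_j(k-1) for the consumers
  if (any(!basal %in% c(0, 1)))
    stop("fixed basal trophic positions must be integer 0 or 1")
  kmax <- 5000L
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[names(basal)[basal == 0]] <- 1
  p1 <- as.vector(f %*% p0)
  p1[match(names(basal)[basal == 1], nodes)] <- 1
  P <- cbind(`0` = p0, `1` = p1)
  rownames(P) <- nodes
  k <- 1L
  repeat {
    nxt <- as.vector(f %*% P[, ncol(P)])
    if (all(nxt < tol) || k >= kmax) break
    P <- cbind(P, nxt)
    colnames(P)[ncol(P)] <- as.character(k + 1L)
    k <- k + 1L
  }
  structure(list(tp = tp, levels = P, f = f, basal = basal),
            class = "trophic_decomposition")
}

#' Mean trophic position of the consumer community
#'
#' Weighted mean of the flow-weighted trophic positions over a consumer
#' set (by default the six consumer groups of the grazing chain: HNF,
#' Cil, Rot, HerbCru, CarnCru, Fish, when present).  Weighting by
#' consumer biomass is the default reading; pass \code{weights = NULL}
#' for the unweighted mean.
#'
#' @param dec a \code{trophic_decomposition} from
#'   \code{\link{trophic_positions}}.
#' @param weights named numeric weights (e.g. biomasses) or \code{NULL}
#'   for equal weighting.
#' @param consumers character vector of consumer node labels.
#' @return The mean trophic position (unitless).
#' @export
mean_trophic_position <- function(dec, weights = NULL, consumers = NULL) {
  stopifnot(inherits(dec, "trophic_decomposition"))
  nodes <- names(dec$tp)
  if (is.null(consumers)) {
    default <- c("HNF", "Cil", "Rot", "HerbCru", "CarnCru", "Fish")
    consumers <- if (any(default %in% nodes)) intersect(default, nodes)
                 else setdiff(nodes, names(dec$basal))
  }
  if (!length(consumers)) stop("empty consumer set")
  bad <- setdiff(consumers, nodes)
  if (length(bad)) stop("unknown consumer(s): ", paste(bad, collapse = ", "))
  tp <- dec$tp[consumers]
  if (is.null(weights)) return(mean(tp))
  w <- weights[consumers]
  if (any(is.na(w))) stop("missing weight for some consumers")
  sum(w * tp) / sum(w)
}

#' Biomass or production pyramid over integer trophic levels
#'
#' Distributes a per-node quantity (biomass or production) over integer
#' trophic levels using the fractional level weights of
#' \code{\link{trophic_positions}}: level_k = sum_i quantity_i p_i(k).
#' The pyramid total equals the input total exactly.  With
#' \code{chain = "grazing"} the detrital pathway is excluded (PDOM and
#' the bacteria are dropped and consumer diets renormalized over the
#' remaining resources); with \code{chain = "detritus"} the pyramid is
#' rooted in the bacteria (PDOM and the phytoplankton dropped).
#'
#' @inheritParams trophic_positions
#' @param quantity named nonnegative vector per node (nodes missing from
#'   the chain are ignored).
#' @param chain \code{"full"}, \code{"grazing"} or \code{"detritus"}.
#' @return Named numeric vector: amount per integer trophic level.
#' @export
trophic_pyramid <- function(net, quantity,
                            chain = c("full", "grazing", "detritus"),
                            basal = NULL) {
  chain <- match.arg(chain)
  stopifnot(inherits(net, "flow_network"))
  drop <- switch(chain, full = character(0),
                 grazing = c("PDOM", "Bac"),
                 detritus = c("PDOM", "Phy"))
  keep <- setdiff(net$nodes, drop)
  if (length(drop)) {
    net <- flow_network(net$T[keep, keep, drop = FALSE],
                        imports = net$imports[keep],
                        exports = net$exports[keep],
                        respiration = if (net$element == "P") 0
                                      else net$respiration[keep],
                        storage_in = net$storage_in[keep],
                        storage_out = net$storage_out[keep],
                        element = net$element, phase = net$phase,
                        units = net$units)
    if (!is.null(basal)) basal <- basal[intersect(names(basal), keep)]
  }
  dec <- trophic_positions(net, basal = basal)
  q <- quantity[intersect(names(quantity), net$nodes)]
  if (any(is.na(q))) stop("quantity missing for some nodes")
  P <- dec$levels[names(q), , drop = FALSE]
  lev <- as.vector(t(P) %*% q)
  stats::setNames(lev, colnames(P))
}

#' Trophic transfer efficiency from a production pyramid
#'
#' The average production ratio across trophic levels 1-3: the mean of
#' P2/P1 and P3/P2.  Efficiencies compose multiplicatively across
#' transfer steps, so the geometric mean (= sqrt(P3/P1)) is the default;
#' an arithmetic mean is available.
#'
#' @param pyramid named vector of production per integer level (names
#'   "1", "2", ...), e.g. from \code{\link{trophic_pyramid}}.
#' @param levels the levels spanned (default 1:3).
#' @param type \code{"geometric"} or \code{"arithmetic"}.
#' @return Transfer efficiency as a fraction.
#' @export
#' @examples
#' transfer_efficiency_production(c(`1` = 100, `2` = 30, `3` = 9))  # 0.30
transfer_efficiency_production <- function(pyramid, levels = 1:3,
                                           type = c("geometric",
                                                    "arithmetic")) {
  type <- match.arg(type)
  p <- pyramid[as.character(levels)]
  if (any(is.na(p) | p <= 0))
    stop("zero or missing production at a required trophic level")
  ratios <- p[-1] / p[-length(p)]
  if (type == "geometric") exp(mean(log(ratios))) else mean(ratios)
}

#' Trophic transfer efficiency from the size spectrum and PPMR
#'
#' In pelagic systems the transfer efficiency can be estimated from the
#' slope of the normalized biomass size spectrum (SSS) and the
#' predator-prey body mass ratio, via the steady-state relation
#' B_{k+1}/B_k = TE * PPMR^A between adjacent trophic levels (A = the
#' magnitude of the allometric exponent of mass-specific production):
#' TE = PPMR^(SSS + 1 - A) under the normalized-spectrum convention.
#' A Sheldon spectrum (SSS = -1) with A = 0.25 and PPMR = 1e4 gives
#' TE = 1e4^(-0.25) = 0.1.
#'
#' @param sss slope of the normalized biomass size spectrum.
#' @param ppmr predator-prey body mass ratio (> 1).
#' @param A magnitude of the allometric exponent (default 0.25).
#' @return Transfer efficiency as a fraction.
#' @export
transfer_efficiency_from_spectrum <- function(sss, ppmr, A = 0.25) {
  if (ppmr <= 1) stop("PPMR must exceed 1")
  ppmr^(sss + 1 - A)
}

#' Weighted geometric mean predator-prey body mass ratio
#'
#' PPMR = prod(ppmr_i ^ w_i) over the four dietary-group ratios
#' (carnivore:herbivore, carnivore:omnivore, herbivore:well-edible
#' autotroph, herbivore:less-edible autotroph), with weights summing to
#' one (defaults in \code{\link{lc_ppmr_weights}}).
#'
#' @param ppmrs positive body mass ratios.
#' @param w weights summing to 1 (within 1e-9).
#' @return The weighted geometric mean ratio.
#' @export
weighted_ppmr <- function(ppmrs, w = lc_ppmr_weights()) {
  if (length(ppmrs) != length(w)) stop("ppmrs and weights differ in length")
  if (any(ppmrs <= 0)) stop("PPMRs must be positive")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  prod(ppmrs^w)
}

#' Build a biomass size spectrum
#'
#' Sums biomass into integer log2 size classes (class m spans body masses
#' [2^m, 2^(m+1)) pgC).
#'
#' @param biomass nonnegative biomass per guild.
#' @param size_class integer log2 body-mass class per guild.
#' @return A data.frame with columns \code{size_class} and \code{biomass}.
#' @export
size_spectrum <- function(biomass, size_class) {
  if (length(biomass) != length(size_class))
    stop("biomass and size_class differ in length")
  if (any(biomass < 0)) stop("negative biomass")
  agg <- tapply(biomass, size_class, sum)
  data.frame(size_class = as.integer(names(agg)),
             biomass = as.numeric(agg))
}

#' Slope of the normalized biomass size spectrum
#'
#' Biomass per class is normalized by the linear class width 2^m, and the
#' spectrum slope is the ordinary least-squares slope of log2(normalized
#' biomass) against the class index m, over non-empty classes.  Equal
#' biomass across classes (a Sheldon spectrum) gives a slope of -1.
#'
#' @param spectrum a data.frame from \code{\link{size_spectrum}} (columns
#'   \code{size_class}, \code{biomass}).
#' @return The spectrum slope (SSS).
#' @export
size_spectrum_slope <- function(spectrum) {
  sp <- spectrum[spectrum$biomass > 0, ]
  if (nrow(sp) < 2) stop("need at least 2 non-empty size classes")
  y <- log2(sp$biomass) - sp$size_class   # log2(B / 2^m)
  unname(stats::coef(stats::lm(y ~ sp$size_class))[2])
}

#' Mass-specific metabolic activity
#'
#' The system's mass-specific metabolic rate P_tot/B_tot (total
#' production over total biomass, d^-1) together with the per-group P/B
#' ratios.
#'
#' @param production,biomass named nonnegative vectors per group.
#' @return A list with \code{PB_tot} and the vector \code{PB}.
#' @export
metabolic_activity <- function(production, biomass) {
  if (length(production) != length(biomass))
    stop("production and biomass differ in length")
  if (sum(biomass) <= 0) stop("zero total biomass")
  list(PB_tot = sum(production) / sum(biomass),
       PB = production / biomass)
}

#' Fit the allometric exponent of mass-specific production
#'
#' Log-log OLS of P/B against body mass recovers the exponent A of the
#' scaling law P/B ~ M^A (metabolic theory predicts A = -0.25).
#'
#' @param pb positive mass-specific production rates.
#' @param mass positive body masses.
#' @return The fitted exponent.
#' @export
allometric_exponent <- function(pb, mass) {
  keep <- pb > 0 & mass > 0
  if (sum(keep) < 2) stop("need at least 2 positive (P/B, mass) pairs")
  unname(stats::coef(stats::lm(log(pb[keep]) ~ log(mass[keep])))[2])
}

#' System residence time
#'
#' The mean time an element spends in the system, operationalized as
#' total stock over total outflow: SRT = sum(biomass) / sum(exports +
#' respiration).  For phosphorus networks respiration is zero, so the
#' residence time reduces to stock over export.
#'
#' @param net a \code{\link{flow_network}}.
#' @param biomass named stock per node, in the element's mass units per
#'   area (nodes absent from the vector count as zero stock).
#' @return Residence time in days.
#' @export
system_residence_time <- function(net, biomass) {
  stopifnot(inherits(net, "flow_network"))
  outflow <- sum(net$exports) + sum(net$respiration)
  if (outflow <= 0) stop("zero system outflow")
  b <- biomass[intersect(names(biomass), net$nodes)]
  sum(b) / outflow
}

#' Diet composition by resource class
#'
#' For each consumer, the fraction of its total ingestion obtained from
#' each resource class (e.g. herbivory = ingestion of autotrophs,
#' bacterivory = ingestion of bacteria, carnivory = ingestion of
#' animals), plus the same fractions pooled over all requested
#' consumers.
#'
#' @param net a \code{\link{flow_network}}.
#' @param resource_classes named character vector: node -> class label.
#' @param consumers consumer node labels (default: every node with
#'   positive ingestion that is not the detritus pool).
#' @return A matrix (consumers + row \code{"pooled"}) x classes of
#'   ingestion fractions; each row sums to 1.
#' @export
diet_composition <- function(net, resource_classes, consumers = NULL) {
  stopifnot(inherits(net, "flow_network"))
  ingest <- colSums(net$T)
  if (is.null(consumers))
    consumers <- setdiff(net$nodes[ingest > 0], "PDOM")
  if (any(ingest[consumers] == 0))
    stop("zero ingestion for consumer(s): ",
         paste(consumers[ingest[consumers] == 0], collapse = ", "))
  bad <- setdiff(net$nodes[rowSums(net$T[, consumers, drop = FALSE]) > 0],
                 names(resource_classes))
  if (length(bad))
    stop("no resource class for node(s): ", paste(bad, collapse = ", "))
  classes <- sort(unique(resource_classes[names(resource_classes) %in%
                                            net$nodes]))
  out <- matrix(0, length(consumers) + 1L, length(classes),
                dimnames = list(c(consumers, "pooled"), classes))
  for (cl in classes) {
    rs <- intersect(names(resource_classes)[resource_classes == cl],
                    net$nodes)
    flows <- colSums(net$T[rs, consumers, drop = FALSE])
    out[consumers, cl] <- flows / ingest[consumers]
    out["pooled", cl] <- sum(flows) / sum(ingest[consumers])
  }
  out
}

#' Stoichiometry (C:P) of consumer diets
#'
#' The food quality of each consumer's realized diet: the ratio of its
#' total carbon ingestion to its total phosphorus ingestion across
#' matched carbon and phosphorus flow networks.
#'
#' @param netC,netP matched \code{\link{flow_network}}s (same node set,
#'   same positive internal link set) for carbon and phosphorus.
#' @param consumers consumer node labels (default as in
#'   \code{\link{diet_composition}}).
#' @return Named vector of diet C:P ratios (ugC/ugP) per consumer.
#' @export
diet_stoichiometry <- function(netC, netP, consumers = NULL) {
  stopifnot(inherits(netC, "flow_network"), inherits(netP, "flow_network"))
  if (!identical(netC$nodes, netP$nodes))
    stop("topology mismatch: node sets differ")
  if (!identical(unname(netC$T > 0), unname(netP$T > 0)))
    stop("topology mismatch: link sets differ")
  ingC <- colSums(netC$T); ingP <- colSums(netP$T)
  if (is.null(consumers)) consumers <- setdiff(netC$nodes[ingC > 0], "PDOM")
  zero <- consumers[ingP[consumers] == 0]
  if (length(zero))
    stop("zero P ingestion for consumer(s): ", paste(zero, collapse = ", "))
  ingC[consumers] / ingP[consumers]
}

#' Node production from a balanced flow network
#'
#' Operational production of each node: the part of its output that is
#' passed on as living biomass, i.e. internal outflows excluding the
#' detrital return to PDOM, plus exports and biomass accrual.  (For
#' primary producers this equals gross input minus respiration and
#' exudation.)
#'
#' @param net a \code{\link{flow_network}}.
#' @return Named vector of production per node.
#' @export
node_production <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  Tm <- net$T
  if ("PDOM" %in% net$nodes) Tm[, "PDOM"] <- 0
  rowSums(Tm) + net$exports + net$storage_out
}
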