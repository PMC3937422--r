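#' Configuration of the synthetic seasonal scenario
#'
#' Parameters of the stochastic generator that emulates the seasonal
#' structure of a temperate-lake plankton food web on the standardized
#' 7-phase axis: a spring bloom with high throughput and few strong
#' basal flows, a clear-water phase dominated by a keystone herbivorous
#' crustacean, and an even, well-connected late-succession flow pattern.
#'
#' Per-phase knobs (vectors of length 7, ordered as
#' \code{\link{phase_axis}}):
#' \describe{
#'   \item{tst_multiplier}{scales the gross primary production driving
#'     each phase's network (dimensionless; applied to \code{gpp0}).}
#'   \item{alpha}{Dirichlet concentration of consumer diet fractions;
#'     small alpha gives few strong diet links (uneven flows), large
#'     alpha even diets.}
#'   \item{exploitation}{multiplier on the consumers' harvest fractions;
#'     rises over succession as grazers exploit their prey spectrum more
#'     fully.}
#'   \item{cp_phyt}{phytoplankton C:P ratio (ugC/ugP), rising over the
#'     season as phosphorus depletes.}
#'   \item{biomass_amplitude}{total plankton biomass per phase, ugC m-2.}
#'   \item{dominance}{share of the expected community held by the
#'     keystone crustacean guild (Dap) per phase; high only during the
#'     CWP.}
#' }
#' Group-level fractions: \code{respiration_frac} and
#' \code{egestion_frac} of each group's intake (their sum must stay
#' below 1; bacteria return no detritus), \code{harvest} base harvest
#' fraction per consumer, \code{cp} C:P per group for the phosphorus
#' network, \code{keystone_factor} boosting the keystone grazer's
#' harvest during the CWP (0 or 1 disables).
#'
#' @param seed integer seed; all generator draws derive from it.
#' @param ... overrides for any of the default entries.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    phases = phase_axis(),
    gpp0 = 1e6,                                   # ugC m-2 d-1 at multiplier 1
    tst_multiplier = c(0.30, 2.20, 2.50, 1.20, 1.00, 0.80, 0.40),
    alpha          = c(30, 25, 35, 45, 60, 90, 30),
    exploitation   = c(0.50, 0.34, 0.50, 0.70, 0.85, 1.00, 0.55),
    cp_phyt        = c(120, 100, 140, 180, 250, 280, 200),
    biomass_amplitude = c(0.3, 0.8, 1.6, 0.9, 1.8, 1.4, 0.5) * 5e6,
    dominance      = c(0.05, 0.05, 0.08, 0.72, 0.08, 0.08, 0.05),
    keystone_factor = 1.25,
    respiration_frac = c(Phy = 0.35, Bac = 0.50, HNF = 0.30, Cil = 0.30,
                         Rot = 0.30, HerbCru = 0.30, CarnCru = 0.30,
                         Fish = 0.30),
    egestion_frac = c(Phy = 0.25, Bac = 0.00, HNF = 0.25, Cil = 0.25,
                      Rot = 0.25, HerbCru = 0.25, CarnCru = 0.25,
                      Fish = 0.25),
    harvest = c(Bac = 0.60, HNF = 0.50, Cil = 0.50, Rot = 0.40,
                HerbCru = 0.60, CarnCru = 0.50, Fish = 0.30),
    cp = c(Phy = NA, Bac = 50, HNF = 100, Cil = 110, Rot = 120,
           HerbCru = 90, CarnCru = 110, Fish = 130, PDOM = 250),
    biomass_concentration = 80,
    samples_per_week = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (any(cfg$respiration_frac + cfg$egestion_frac >= 1))
    stop("infeasible budget: respiration + egestion fractions must stay below 1")
  if (any(cfg$alpha <= 0)) stop("Dirichlet concentration alpha must be > 0")
  if (any(cfg$harvest <= 0 | cfg$harvest > 1))
    stop("harvest fractions must lie in (0, 1]")
  class(cfg) <- "scenario_config"
  cfg
}

# symmetric Dirichlet draw, guarded against gamma underflow so that every
# topological link keeps strictly positive flow
.rdirichlet <- function(n, alpha) {
  x <- pmax(stats::rgamma(n, shape = alpha), 1e-12)
  x / sum(x)
}

.phase_seed <- function(cfg, phase_index) {
  (abs(cfg$seed) %% 100000L) * 7919L + phase_index
}

#' Generate one mass-balanced flow network
#'
#' Builds a carbon flow network on the 8-group + PDOM topology of
#' \code{\link{lc_group_links}} for one seasonal phase.  Each consumer's
#' diet fractions are drawn from a symmetric Dirichlet over its
#' topological resources; gross primary production (scaled by the
#' phase's throughput multiplier) is propagated up the web with
#' availability-aware harvest fractions (a consumer never removes more
#' than its harvest share of what a resource has left), and every node's
#' budget is closed exactly by respiration, egestion to PDOM and export
#' of the unconsumed remainder, so the per-node mass balance holds to
#' machine precision.  The detrital loop (egestion feeding PDOM which
#' feeds the bacteria which feed grazers) is resolved by fixed-point
#' iteration of the linear propagation.
#'
#' @param topology link set as from \code{\link{lc_group_links}}.
#' @param cfg a \code{\link{scenario_config}}.
#' @param phase phase label or index on \code{cfg$phases}.
#' @param element \code{"C"} or \code{"P"}; the phosphorus network is
#'   derived from the carbon draw via the per-group C:P ratios, with
#'   deficits closed by phosphorus import (luxury uptake).
#' @return A \code{\link{flow_network}}.
#' @export
generate_balanced_network <- function(topology = lc_group_links(),
                                      cfg = scenario_config(),
                                      phase = 1, element = c("C", "P")) {
  element <- match.arg(element)
  pidx <- if (is.character(phase)) match(phase, cfg$phases) else as.integer(phase)
  if (is.na(pidx) || pidx < 1 || pidx > length(cfg$phases))
    stop("unknown phase: ", phase)
  netC <- .generate_carbon_network(topology, cfg, pidx)
  if (element == "C") netC else derive_phosphorus_network(netC, cfg)
}

.generate_carbon_network <- function(topology, cfg, pidx) {
  set.seed(.phase_seed(cfg, pidx))
  nodes <- lc_group_names()
  trophic <- topology[topology$type == "trophic", ]
  consumers <- unique(trophic$to)
  diets <- split(trophic$from, trophic$to)[consumers]
  alpha <- cfg$alpha[pidx]
  resp <- cfg$respiration_frac
  eg <- cfg$egestion_frac
  d <- lapply(diets, function(res)
    stats::setNames(.rdirichlet(length(res), alpha), res))
  # cap within-group feeding (group-level self-loops: intraguild predation,
  # cannibalism) at half of the consumer's own production so budgets close
  for (cons in names(d)) {
    if (cons %in% names(d[[cons]])) {
      cap <- 0.5 * (1 - resp[cons] - eg[cons])
      dc <- d[[cons]]
      if (dc[cons] > cap) {
        excess <- dc[cons] - cap
        dc[cons] <- cap
        others <- setdiff(names(dc), cons)
        dc[others] <- dc[others] + excess * dc[others] / sum(dc[others])
        d[[cons]] <- dc / sum(dc)
      }
    }
  }
  # harvest fractions with the CWP keystone reallocation
  h <- cfg$harvest * cfg$exploitation[pidx]
  if (cfg$phases[pidx] == "CWP" && cfg$keystone_factor > 1)
    h["HerbCru"] <- min(0.97, h["HerbCru"] * cfg$keystone_factor)
  gpp <- cfg$gpp0 * cfg$tst_multiplier[pidx]
  order_c <- c("Bac", "HNF", "Cil", "Rot", "HerbCru", "CarnCru", "Fish")
  living <- setdiff(nodes, c("PDOM", "Bac"))
  propagate <- function(pdom_in) {
    Tm <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
    avail <- stats::setNames(numeric(length(nodes)), nodes)
    avail["Phy"] <- (1 - resp["Phy"] - eg["Phy"]) * gpp
    avail["PDOM"] <- pdom_in
    intake <- stats::setNames(numeric(length(nodes)), nodes)
    intake["Phy"] <- gpp
    for (cons in order_c) {
      dc <- d[[cons]]
      ext <- setdiff(names(dc), cons)
      # largest intake such that no external diet item exceeds the
      # harvest share of what that resource currently offers; the
      # within-group share is fed from the consumer's own production
      U <- h[cons] * min(avail[ext] / dc[ext])
      if (!is.finite(U) || U < 0) U <- 0
      flows <- U * dc
      Tm[names(dc), cons] <- flows
      avail[ext] <- avail[ext] - flows[ext]
      intake[cons] <- U
      avail[cons] <- (1 - resp[cons] - eg[cons]) * U -
        if (cons %in% names(dc)) flows[cons] else 0
    }
    list(Tm = Tm, intake = intake,
         pdom_out = sum(eg[living] * intake[living]))
  }
  pdom_in <- 0
  for (iter in 1:200) {
    st <- propagate(pdom_in)
    if (abs(st$pdom_out - pdom_in) <= 1e-13 * max(1, st$pdom_out)) break
    pdom_in <- st$pdom_out
  }
  st <- propagate(st$pdom_out)
  Tm <- st$Tm
  intake <- st$intake
  # detrital returns (every living group except the bacteria)
  Tm[living, "PDOM"] <- eg[living] * intake[living]
  # exact budget closure: unconsumed remainder is exported
  imports <- stats::setNames(numeric(length(nodes)), nodes)
  imports["Phy"] <- gpp
  respiration <- stats::setNames(numeric(length(nodes)), nodes)
  respiration[names(resp)] <- resp * intake[names(resp)]
  inputs <- colSums(Tm) + imports
  outputs <- rowSums(Tm) + respiration
  exports <- inputs - outputs
  exports[exports < 0 & exports > -1e-9 * max(inputs)] <- 0
  if (any(exports < 0)) stop("infeasible budget: negative export")
  flow_network(Tm, imports = imports, exports = exports,
               respiration = respiration,
               element = "C", phase = cfg$phases[pidx])
}

#' Derive the phosphorus network from a carbon network
#'
#' Internal phosphorus flows follow the carbon flows divided by the C:P
#' ratio of the flowing (source) material; phosphorus carries no
#' respiratory loss.  Each node's phosphorus budget is closed exactly:
#' surplus phosphorus is exported, deficits (which arise where a node's
#' intake is P-poorer than its own stoichiometry, as for bacteria) are
#' met by a phosphorus import representing dissolved-P uptake.
#'
#' @param netC a carbon \code{\link{flow_network}} on the group topology.
#' @param cfg a \code{\link{scenario_config}} (supplies the C:P table;
#'   the phytoplankton C:P is phase-dependent).
#' @return A phosphorus \code{\link{flow_network}}.
#' @export
derive_phosphorus_network <- function(netC, cfg = scenario_config()) {
  stopifnot(inherits(netC, "flow_network"), netC$element == "C")
  cp <- cfg$cp
  pidx <- match(netC$phase, cfg$phases)
  cp["Phy"] <- cfg$cp_phyt[if (is.na(pidx)) 4 else pidx]
  missing <- setdiff(netC$nodes, names(cp))
  if (length(missing)) stop("no C:P ratio for: ", paste(missing, collapse = ", "))
  Tp <- netC$T / cp[netC$nodes]          # divide rows by source C:P
  imports <- netC$imports / cp[netC$nodes]
  inputs <- colSums(Tp) + imports
  outputs <- rowSums(Tp)
  exports <- stats::setNames(pmax(inputs - outputs, 0), netC$nodes)
  imports <- imports + pmax(outputs - inputs, 0)
  flow_network(Tp, imports = imports, exports = exports, respiration = 0,
               element = "P", phase = netC$phase, units = netC$units)
}

#' Generate the full seasonal scenario
#'
#' One mass-balanced carbon and phosphorus network per phase of the
#' 7-phase axis: spring phases get high throughput and concentrated
#' (low-alpha) basal flows, the clear-water phase concentrates ingestion
#' through the keystone herbivorous crustaceans, late phases get even,
#' well-exploited flows at lower throughput.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return A list with elements \code{C} and \code{P}, each a named list
#'   of 7 \code{\link{flow_network}}s, and \code{cfg}.
#' @export
generate_seasonal_scenario <- function(cfg = scenario_config()) {
  topo <- lc_group_links()
  C <- lapply(seq_along(cfg$phases), function(i)
    .generate_carbon_network(topo, cfg, i))
  names(C) <- cfg$phases
  P <- lapply(C, derive_phosphorus_network, cfg = cfg)
  list(C = C, P = P, cfg = cfg)
}

# day-of-year spans of the 7 phases (approximate climatology)
.phase_breaks <- c(0, 59, 105, 135, 165, 250, 310, 366)

#' Map day-of-year to seasonal phase
#'
#' @param doy integer day of year (1-365).
#' @return Factor of phase labels on the 7-phase axis.
#' @export
phase_of_day <- function(doy) {
  cut(doy, breaks = .phase_breaks, labels = phase_axis())
}

#' Generate a seasonal guild biomass series
#'
#' Weekly biomass snapshots of the 24 guilds over one year.  Per phase,
#' relative biomasses are drawn from a Dirichlet whose mean profile
#' tracks the seasonal narrative: well-edible algae dominate the spring
#' bloom, the keystone crustacean guild (Dap) dominates the clear-water
#' phase (driving functional diversity to its seasonal minimum), and
#' late-succession communities are even (high diversity).  Absolute
#' biomass follows the per-phase amplitude.  Fish biomass is a small,
#' slowly varying add-on (fish enter the eco-exergy and trophic-position
#' calculations, not the plankton diversity).
#'
#' @param guilds guild table from \code{\link{lc_guilds}}.
#' @param cfg a \code{\link{scenario_config}}.
#' @return A list with \code{times} (day of year), \code{phase} (label
#'   per time), and \code{B} (time x 24 guild biomass matrix, ugC m-2).
#' @export
generate_biomass_series <- function(guilds = lc_guilds(),
                                    cfg = scenario_config()) {
  set.seed(.phase_seed(cfg, 777L))
  times <- seq(4, 364, by = 7)
  phs <- as.character(phase_of_day(times))
  plank <- guilds$name[1:20]
  fish <- guilds$name[21:24]
  B <- matrix(0, length(times), 24, dimnames = list(NULL, guilds$name))
  base <- stats::setNames(rep(1 / 20, 20), plank)
  for (ti in seq_along(times)) {
    pidx <- match(phs[ti], cfg$phases)
    m <- base
    if (cfg$phases[pidx] == "Early Spring") {
      # spring bloom: well-edible algae dominate
      m[] <- 0.65 / 18
      m[c("Alg1", "Alg5")] <- 0.35 / 2
    }
    dom <- cfg$dominance[pidx]
    m <- (1 - dom) * m / sum(m)
    m["Dap"] <- m["Dap"] + dom
    conc <- cfg$biomass_concentration * m
    rel <- .rdirichlet_vec(conc)
    B[ti, plank] <- rel * cfg$biomass_amplitude[pidx]
    # fish: ~4% of plankton biomass, split over the four fish guilds
    B[ti, fish] <- cfg$biomass_amplitude[pidx] * 0.04 *
      c(0.15, 0.2, 0.45, 0.2) * stats::runif(4, 0.8, 1.2)
  }
  list(times = times, phase = phs, B = B)
}

# Dirichlet with a vector of concentrations
.rdirichlet_vec <- function(conc) {
  x <- pmax(stats::rgamma(length(conc), shape = conc), 1e-12)
  x / sum(x)
}
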