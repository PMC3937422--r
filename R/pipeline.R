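#' Phase means and annual statistics of an index series
#'
#' Averages an index series onto the standardized 7-phase axis: the
#' phase mean is the arithmetic mean of the values falling into the
#' phase, and the annual statistics are the mean and standard deviation
#' of the (available) phase means.
#'
#' @param values numeric index values.
#' @param phases phase label per value (on \code{\link{phase_axis}}).
#' @return A list with \code{phase_means} (named, NA for empty phases),
#'   \code{annual_mean} and \code{annual_sd}; empty phases are excluded
#'   from the annual statistics with a warning.
#' @export
phase_statistics <- function(values, phases) {
  if (length(values) != length(phases))
    stop("values and phases differ in length")
  ax <- phase_axis()
  bad <- setdiff(unique(phases), ax)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  pm <- vapply(ax, function(p) {
    v <- values[phases == p]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  if (anyNA(pm))
    warning("empty phase(s) excluded from annual statistics: ",
            paste(ax[is.na(pm)], collapse = ", "))
  list(phase_means = pm,
       annual_mean = mean(pm, na.rm = TRUE),
       annual_sd = stats::sd(pm[!is.na(pm)]))
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a vector by its range: V_norm = (V - min V) / (max V - min V).
#'
#' @param values numeric vector with max > min.
#' @return The rescaled vector (minimum 0, maximum 1).
#' @export
minmax_normalize <- function(values) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("degenerate range: max equals min")
  (values - rng[1]) / diff(rng)
}

#' Composite index of successional progress
#'
#' The arithmetic mean, per phase, of the min-max-normalized transfer
#' efficiency, inverted metabolic activity (1 - normalized P/B),
#' functional diversity and (optionally) weighted connectance.  All four
#' components are oriented so that successional progress increases the
#' composite; it is invariant to affine rescaling of any input series.
#'
#' @param te,pb,h_bio,c_w per-phase index vectors of equal length.
#' @param include_cw include the weighted connectance (set \code{FALSE}
#'   to get the three-index variant used when flow data are missing).
#' @return Per-phase composite values in [0, 1].
#' @export
composite_index <- function(te, pb, h_bio, c_w = NULL, include_cw = TRUE) {
  n <- length(te)
  if (length(pb) != n || length(h_bio) != n ||
      (include_cw && length(c_w) != n))
    stop("index vectors differ in length")
  parts <- list(minmax_normalize(te), 1 - minmax_normalize(pb),
                minmax_normalize(h_bio))
  if (include_cw) parts <- c(parts, list(minmax_normalize(c_w)))
  Reduce(`+`, parts) / length(parts)
}

#' Spearman rank correlation between two index series
#'
#' Rank correlation with mid-ranks for ties and a two-sided p-value from
#' the asymptotic t approximation.
#'
#' @param x,y paired numeric series (at least 4 points).
#' @return A list with \code{rho} and \code{p}.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series differ in length")
  if (length(x) < 4) stop("need at least 4 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Classify the seasonal trend of a phase-mean series
#'
#' Labels the growing-season shape of an index (phases 2-6, excluding
#' the abiotically forced winter phases): \code{"const"} if the relative
#' range is below \code{rel_tol}, otherwise by the number of sign
#' changes of consecutive phase differences: 0 -> \code{"up"} or
#' \code{"down"}, 1 -> \code{"uni"} (unimodal), 2 or more -> \code{"bi"}.
#'
#' @param phase_means named per-phase values (7 phases).
#' @param phases_used indices of the phases entering the classification.
#' @param rel_tol relative-change threshold for \code{"const"}.
#' @return One of \code{"const"}, \code{"up"}, \code{"down"},
#'   \code{"uni"}, \code{"bi"}.
#' @export
classify_trend <- function(phase_means, phases_used = 2:6, rel_tol = 0.05) {
  v <- phase_means[phases_used]
  if (anyNA(v)) stop("missing phase means in classification window")
  scale <- mean(abs(v))
  if (scale == 0 || diff(range(v)) / scale < rel_tol) return("const")
  d <- diff(v)
  d <- d[d != 0]
  if (!length(d)) return("const")
  changes <- sum(diff(sign(d)) != 0)
  if (changes == 0) return(if (d[1] > 0) "up" else "down")
  if (changes == 1) return("uni")
  "bi"
}

# units of the reported indices
.index_units <- c(
  H_bio = "bits", sigma = "1/d", CP_diet = "ugC/ugP", SRT_C = "d",
  SRT_P = "d", TP = "-", PB = "1/d", PPMR = "-", TE = "-", C_w = "-",
  H_flow = "bits", D_norm = "-", Q_norm = "-", Asc_rel = "-",
  Ex_sp = "Ex/gC", SSS = "-")

#' Compute all per-phase succession indices for a seasonal scenario
#'
#' Runs every system-level index over matched per-phase carbon and
#' phosphorus networks and a guild biomass series: functional diversity
#' (H_bio, 20 plankton guilds), succession rate (sigma, weekly
#' snapshots), pooled herbivore diet C:P, system residence times for C
#' and P, biomass-weighted mean trophic position of the six consumer
#' groups, metabolic activity P_tot/B_tot (7 plankton groups), weighted
#' PPMR, transfer efficiency across grazing-chain levels 1-3, weighted
#' connectance and flow diversity, small-world indices on the
#' disaggregated 24-guild web, relative ascendency and specific
#' eco-exergy.
#'
#' @param scen output of \code{\link{generate_seasonal_scenario}} (or a
#'   list with the same shape built from files).
#' @param bio output of \code{\link{generate_biomass_series}}.
#' @param guilds guild table.
#' @return A data.frame with columns \code{phase}, \code{index},
#'   \code{value}, \code{units}.
#' @export
compute_index_series <- function(scen, bio, guilds = lc_guilds()) {
  cfg <- scen$cfg
  phases <- phase_axis()
  herb_groups <- c("Cil", "Rot", "HerbCru")
  consumer_groups <- c("HNF", "Cil", "Rot", "HerbCru", "CarnCru", "Fish")
  plank_groups <- c("Phy", "Bac", "HNF", "Cil", "Rot", "HerbCru", "CarnCru")
  group_of <- lc_aggregation_map("24to8")
  exw <- lc_exergy_weights()
  rows <- list()
  add <- function(phase, index, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      phase = phase, index = index, value = unname(value),
      units = unname(.index_units[index]), stringsAsFactors = FALSE)
  for (p in phases) {
    netC <- scen$C[[p]]
    netP <- scen$P[[p]]
    sel <- bio$phase == p
    Bp <- bio$B[sel, , drop = FALSE]
    Bmean <- colMeans(Bp)
    # biomass-based indices on the 20 plankton guilds
    add(p, "H_bio", shannon_diversity(Bmean[guilds$name[1:20]]))
    if (sum(sel) >= 2) {
      idx <- which(sel)
      sig <- mean(vapply(seq_len(sum(sel) - 1), function(i) {
        b1 <- bio$B[idx[i], 1:20]; b2 <- bio$B[idx[i + 1], 1:20]
        succession_rate(b1 / sum(b1), b2 / sum(b2),
                        dt = bio$times[idx[i + 1]] - bio$times[idx[i]])
      }, numeric(1)))
      add(p, "sigma", sig)
    }
    add(p, "Ex_sp", eco_exergy(Bmean, exw)$Ex_sp)
    # group-level stocks (ugC m-2)
    stockC <- tapply(Bmean, group_of[guilds$name], sum)[
      setdiff(lc_group_names(), "PDOM")]
    cp <- cfg$cp
    cp["Phy"] <- cfg$cp_phyt[match(p, phases)]
    stockP <- stockC / cp[names(stockC)]
    # flow-based indices
    add(p, "CP_diet", sum(colSums(netC$T[, herb_groups])) /
          sum(colSums(netP$T[, herb_groups])))
    add(p, "SRT_C", system_residence_time(netC, stockC))
    add(p, "SRT_P", system_residence_time(netP, stockP))
    dec <- trophic_positions(netC)
    add(p, "TP", mean_trophic_position(dec, weights = stockC,
                                       consumers = consumer_groups))
    prod <- node_production(netC)
    add(p, "PB", sum(prod[plank_groups]) / sum(stockC[plank_groups]))
    add(p, "PPMR", .ppmr_from_biomass(Bmean, guilds))
    pyr <- trophic_pyramid(netC, prod, chain = "grazing")
    add(p, "TE", transfer_efficiency_production(pyr))
    asc <- ascendency_suite(netC)
    add(p, "C_w", asc$C_w)
    add(p, "H_flow", asc$H_flow)
    add(p, "Asc_rel", asc$Asc_rel)
    net24 <- disaggregate_flows(netC, guilds)
    add(p, "D_norm", weighted_path_length(net24)$D_norm)
    add(p, "Q_norm", weighted_clustering(net24)$Q_norm)
    sp <- size_spectrum(Bmean[guilds$name[1:20]], guilds$size_class[1:20])
    add(p, "SSS", size_spectrum_slope(sp))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# biomass-weighted mean body mass per dietary group -> weighted PPMR
.ppmr_from_biomass <- function(biomass, guilds) {
  mass <- 2^guilds$size_class            # pgC
  wmean <- function(ids) {
    b <- biomass[guilds$name[ids]]
    if (sum(b) == 0) return(NA_real_)
    sum(b * mass[ids]) / sum(b)
  }
  carn <- which(guilds$dietary_group %in% "Carn")
  omni <- which(guilds$dietary_group %in% "Omni")
  herb <- which(guilds$dietary_group %in% "Herb")
  well <- which(guilds$edibility == "well-edible")
  less <- which(guilds$edibility %in% c("less-edible", "specialist-only"))
  ppmrs <- c(carn_herb = wmean(carn) / wmean(herb),
             carn_omni = wmean(carn) / wmean(omni),
             herb_auto_well = wmean(herb) / wmean(well),
             herb_auto_less = wmean(herb) / wmean(less))
  weighted_ppmr(ppmrs, lc_ppmr_weights())
}

#' Run the full succession analysis on a synthetic scenario
#'
#' Generates (or accepts) a seasonal scenario, computes every index per
#' phase, and summarizes them in the standard report layout: per-index
#' trend class over phases 2-6, early (phases 2/3), intermediate (phase
#' 4) and late (phases 5/6) values, and the annual mean and standard
#' deviation across the 7 phase means.  Winter phases (1 and 7) enter
#' the annual statistics but not the trend classification, since they
#' are dominated by abiotic forcing.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @param scen,bio optionally, a pre-generated scenario and biomass
#'   series (both generated from \code{cfg} when NULL).
#' @return A list with \code{series} (the long per-phase index table),
#'   \code{report} (one row per index: trend, early/intermediate/late,
#'   annual mean and sd, units) and \code{composite} (per-phase
#'   composite succession index, with and without C_w).
#' @export
run_full_analysis <- function(cfg = scenario_config(), scen = NULL,
                              bio = NULL) {
  if (is.null(scen)) scen <- generate_seasonal_scenario(cfg)
  if (is.null(bio)) bio <- generate_biomass_series(lc_guilds(), cfg)
  series <- compute_index_series(scen, bio)
  phases <- phase_axis()
  idxs <- unique(series$index)
  rep_rows <- lapply(idxs, function(ix) {
    s <- series[series$index == ix, ]
    pm <- stats::setNames(s$value[match(phases, s$phase)], phases)
    data.frame(index = ix,
               trend = classify_trend(pm),
               early = sprintf("%.3g/%.3g", pm[2], pm[3]),
               intermediate = sprintf("%.3g", pm[4]),
               late = sprintf("%.3g/%.3g", pm[5], pm[6]),
               annual_mean = mean(pm, na.rm = TRUE),
               annual_sd = stats::sd(pm[!is.na(pm)]),
               units = s$units[1], stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  get <- function(ix) {
    s <- series[series$index == ix, ]
    s$value[match(phases, s$phase)]
  }
  comp <- data.frame(
    phase = phases,
    composite = composite_index(get("TE"), get("PB"), get("H_bio"),
                                get("C_w")),
    composite_no_cw = composite_index(get("TE"), get("PB"), get("H_bio"),
                                      include_cw = FALSE))
  list(series = series, report = report, composite = comp)
}
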