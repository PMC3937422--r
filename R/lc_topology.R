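#' Lake Constance guild table (24 functional guilds)
#'
#' The pelagic Lake Constance food web resolved into 24 functional guilds
#' (20 plankton guilds and 4 fish guilds).  Guilds are aggregated into 8
#' major functional groups (Phy, Bac, HNF, Cil, Rot, HerbCru, CarnCru,
#' Fish), 5 trophic compartments (Auto, Bac, Herb, Bactv, Carn) and 4
#' dietary groups (Auto, Herb, Omni, Carn).  Size class is log2 of the
#' average body mass in pgC; \code{diet} lists the resource guild ids
#' (\code{0} denotes the detritus pool PDOM).
#'
#' Mixed-diet consumers are assigned to compartments and dietary groups by
#' their dominant feeding type (B = bacterivore, H = herbivore, C =
#' carnivore, O = omnivore); field studies typically allocate such
#' consumers fractionally, which a static table cannot express.
#'
#' @return A data.frame with one row per guild and columns \code{id},
#'   \code{name}, \code{group}, \code{compartment}, \code{dietary_group},
#'   \code{size_class}, \code{diet} (list column of integer resource ids,
#'   0 = PDOM), \code{edibility} and \code{feeding_type}.
#' @export
#' @examples
#' g <- lc_guilds()
#' g$diet[[18]]   # the generalist herbivorous crustaceans eat guilds 1-16
lc_guilds <- function() {
  diet <- list(
    integer(0), integer(0), integer(0), integer(0), integer(0), integer(0),
    0L,                       # Bac <- PDOM
    6:7,                      # HNF
    6:7,                      # Cil1
    c(1L, 5:8),               # Cil2
    c(1:2, 5L, 8L),           # Cil3
    c(1L, 5L, 8L),            # Cil4
    c(1:2, 4:5, 8:11),        # Cil5
    c(1L, 5:8),               # Rot1
    c(1:5, 8:9),              # Rot2
    c(1:5, 8:9),              # Rot3
    c(2:4, 8:16),             # Asp
    1:16,                     # Dap
    c(1:5, 8:19),             # Cyc (includes 19 -> 19 cannibalism)
    17:18,                    # Lep
    14:19,                    # Fish1
    18:20,                    # Fish2
    18:20,                    # Fish3
    18:22                     # Fish4
  )
  feeding <- c(rep("producer", 6), "osmotroph",
               "B", "B", "B/H", "H", "H", "O", "B/H", "H/O", "O", "C",
               "H/O", "C/O", "C", "C", "C", "C", "C")
  # dominant-diet membership in the 4 dietary groups used for PPMR
  dietary <- c(rep("Auto", 6), NA,
               "Herb", "Herb", "Herb", "Herb", "Herb", "Omni", "Herb",
               "Omni", "Omni", "Carn", "Omni", "Omni", "Carn",
               "Carn", "Carn", "Carn", "Carn")
  compartment <- c(rep("Auto", 6), "Bac",
                   "Bactv", "Bactv", "Herb", "Herb", "Herb", "Herb",
                   "Herb", "Herb", "Herb", "Carn", "Herb", "Carn",
                   "Carn", "Carn", "Carn", "Carn", "Carn")
  edib <- c("well-edible", "less-edible", "specialist-only", "less-edible",
            "well-edible", "less-edible", rep("n/a", 18))
  data.frame(
    id   = 1:24,
    name = c("Alg1", "Alg2", "Alg3", "Alg4", "Alg5", "APP", "Bac", "HNF",
             "Cil1", "Cil2", "Cil3", "Cil4", "Cil5", "Rot1", "Rot2",
             "Rot3", "Asp", "Dap", "Cyc", "Lep", "Fish1", "Fish2",
             "Fish3", "Fish4"),
    group = c(rep("Phy", 6), "Bac", "HNF", rep("Cil", 5), rep("Rot", 4),
              "HerbCru", "CarnCru", "CarnCru", rep("Fish", 4)),
    compartment = compartment,
    dietary_group = dietary,
    size_class = c(6L, 8L, 5L, 7L, 3L, -2L, -6L, 3L, 8L, 11L, 12L, 13L,
                   16L, 14L, 15L, 16L, 16L, 23L, 20L, 26L, 40L, 42L,
                   45L, 46L),
    diet = I(diet),
    edibility = edib,
    feeding_type = feeding,
    stringsAsFactors = FALSE
  )
}

#' Lake Constance group-level link set (8 groups + PDOM)
#'
#' Link structure of the intermediate food-web resolution on which the
#' mass-balanced flow networks live: 25 trophic links (including the
#' detrital uptake PDOM -> Bac and the CarnCru cannibalism self-loop) and
#' 7 detrital flows returning dead organic matter of every group except
#' the bacteria to PDOM.
#'
#' @return A data.frame with columns \code{from}, \code{to} (group labels)
#'   and \code{type} (\code{"trophic"} or \code{"detrital"}).
#' @export
lc_group_links <- function() {
  groups <- lc_group_names()
  # group-level diets: consumer -> resource ids (9 = PDOM)
  diets <- list(Bac = 9L, HNF = 1:2, Cil = 1:4, Rot = 1:5, HerbCru = 1:5,
                CarnCru = c(1L, 4:7), Fish = 5:7)
  from <- character(0); to <- character(0)
  for (cons in names(diets)) {
    from <- c(from, groups[diets[[cons]]])
    to <- c(to, rep(cons, length(diets[[cons]])))
  }
  trophic <- data.frame(from = from, to = to, type = "trophic",
                        stringsAsFactors = FALSE)
  detr <- data.frame(from = setdiff(groups[1:8], "Bac"), to = "PDOM",
                     type = "detrital", stringsAsFactors = FALSE)
  rbind(trophic, detr)
}

#' @rdname lc_group_links
#' @export
lc_group_names <- function() {
  c("Phy", "Bac", "HNF", "Cil", "Rot", "HerbCru", "CarnCru", "Fish", "PDOM")
}

#' Aggregation mappings between food-web resolutions
#'
#' Node -> supernode mappings for the hierarchical aggregation levels of
#' the Lake Constance web: 24 guilds -> 8 groups and 8 groups -> 5 trophic
#' compartments.  PDOM maps to itself at every level.
#'
#' @param level \code{"24to8"} or \code{"8to5"}.
#' @return A named character vector mapping node labels to supernode labels.
#' @export
lc_aggregation_map <- function(level = c("24to8", "8to5")) {
  level <- match.arg(level)
  if (level == "24to8") {
    g <- lc_guilds()
    m <- c(stats::setNames(g$group, g$name), PDOM = "PDOM")
  } else {
    m <- c(Phy = "Auto", Bac = "Bac", HNF = "Bactv", Cil = "Herb",
           Rot = "Herb", HerbCru = "Herb", CarnCru = "Carn", Fish = "Carn",
           PDOM = "PDOM")
  }
  m
}

#' Eco-exergy equivalence factors for the Lake Constance groups
#'
#' Group-specific beta factors expressing the proteome information content
#' of each organism group relative to detritus (reference energy 18.7 kJ
#' per g detritus): bacteria 8.5, phytoplankton 20, unicellular
#' zooplankton (HNF, ciliates) 39, rotifers 163, crustaceans 232 and fish
#' 499.
#'
#' @return A named numeric vector of beta factors per guild (names are the
#'   guild names of \code{\link{lc_guilds}}), with the detritus reference
#'   energy attached as attribute \code{reference_kJ_per_g}.
#' @export
lc_exergy_weights <- function() {
  g <- lc_guilds()
  beta_by_group <- c(Phy = 20, Bac = 8.5, HNF = 39, Cil = 39, Rot = 163,
                     HerbCru = 232, CarnCru = 232, Fish = 499)
  w <- stats::setNames(beta_by_group[g$group], g$name)
  attr(w, "reference_kJ_per_g") <- 18.7
  w
}

#' Dietary-group weights for the mean predator-prey body mass ratio
#'
#' Weights of the four predator-prey body mass ratios entering the
#' weighted geometric mean: carnivores over herbivores (0.1), carnivores
#' over omnivores (0.1), herbivores over well-edible autotrophs (0.4) and
#' herbivores over less-edible autotrophs (0.4).  The weights were
#' established from the mass-balanced flow networks as ingestion fractions
#' of the respective dietary group.
#'
#' @return A named numeric vector summing to one.
#' @export
lc_ppmr_weights <- function() {
  c(carn_herb = 0.1, carn_omni = 0.1,
    herb_auto_well = 0.4, herb_auto_less = 0.4)
}

#' Full Lake Constance topology fixture
#'
#' Convenience bundle of all shipped topology fixtures: the 24-guild
#' table, the 8-group link set, the aggregation mappings, the eco-exergy
#' equivalence factors and the PPMR weights.
#'
#' @return A list with elements \code{guilds}, \code{group_links},
#'   \code{map_24to8}, \code{map_8to5}, \code{exergy_weights},
#'   \code{ppmr_weights}.
#' @export
lc_topology <- function() {
  list(guilds = lc_guilds(),
       group_links = lc_group_links(),
       map_24to8 = lc_aggregation_map("24to8"),
       map_8to5 = lc_aggregation_map("8to5"),
       exergy_weights = lc_exergy_weights(),
       ppmr_weights = lc_ppmr_weights())
}

#' The standardized seven-phase seasonal axis
#'
#' The year is divided into 7 standardized phases to average out
#' interannual variability: 1 Late Winter, 2 Early Spring, 3 Late Spring,
#' 4 Clear Water Phase (CWP), 5 Summer, 6 Autumn, 7 Early Winter.
#'
#' @return A character vector of the 7 phase labels, in order.
#' @export
phase_axis <- function() {
  c("Late Winter", "Early Spring", "Late Spring", "CWP",
    "Summer", "Autumn", "Early Winter")
}
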