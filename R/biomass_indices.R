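#' Shannon diversity of a biomass distribution
#'
#' Functional diversity H = -sum(b_i log(b_i)) over the relative biomasses
#' b_i = B_i / B_tot, with 0 log 0 taken as 0.  Reported in bits (log base
#' 2) by default, matching the convention used for seasonal plankton
#' succession; H is maximal (log2 S) for a perfectly even community and 0
#' when a single guild holds all biomass.
#'
#' @param biomass nonnegative biomass vector over guilds.
#' @param base logarithm base (default 2, i.e. bits).
#' @return Diversity in units of log \code{base}.
#' @export
#' @examples
#' shannon_diversity(rep(1, 20))            # log2(20) = 4.32 bits
#' shannon_diversity(c(0.5, 0.25, 0.25))    # 1.5 bits
shannon_diversity <- function(biomass, base = 2) {
  if (any(biomass < 0)) stop("negative biomass")
  tot <- sum(biomass)
  if (tot <= 0) stop("all-zero biomass vector")
  b <- biomass / tot
  b <- b[b > 0]
  -sum(b * log(b, base = base))
}

#' Succession rate of a community
#'
#' The per-day speed of compositional change between two community
#' snapshots: sigma = sum_i |b2_i - b1_i| / dt over relative biomasses.
#' Ranges from 0 (no change) to 2/dt (complete guild turnover).
#'
#' @param b1,b2 relative-biomass vectors (each summing to 1 within 1e-9),
#'   over the same guild set (names, when present, must agree).
#' @param dt time between the snapshots in days.
#' @return Succession rate in d^-1.
#' @export
succession_rate <- function(b1, b2, dt) {
  if (length(b1) != length(b2))
    stop("mismatched guild sets: vectors differ in length")
  if (!is.null(names(b1)) && !is.null(names(b2)) &&
      !identical(names(b1), names(b2)))
    stop("mismatched guild sets: names differ")
  if (abs(sum(b1) - 1) > 1e-9 || abs(sum(b2) - 1) > 1e-9)
    stop("relative-biomass vectors must sum to 1")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  sum(abs(b2 - b1)) / dt
}

#' Eco-exergy and specific eco-exergy
#'
#' Eco-exergy weights each guild's biomass by a group-specific
#' equivalence factor beta expressing the information content of its
#' proteome relative to detritus: Ex = sum(beta_i * B_i) (in g detritus
#' equivalents per area when B is in gC per area).  The specific
#' eco-exergy Ex_sp = Ex / B_tot is the organismal-complexity content per
#' unit biomass and is bounded by the smallest and largest beta present.
#'
#' @param biomass nonnegative biomass vector; names must match
#'   \code{weights} when both are named.
#' @param weights named numeric vector of beta factors (default the Lake
#'   Constance factors of \code{\link{lc_exergy_weights}}).
#' @return A list with elements \code{Ex} and \code{Ex_sp} (\code{Ex_sp}
#'   is \code{NaN} with a warning when total biomass is zero).
#' @export
#' @examples
#' w <- lc_exergy_weights()
#' b <- stats::setNames(numeric(24), names(w)); b["Fish3"] <- 1
#' eco_exergy(b, w)$Ex_sp   # 499: the fish equivalence factor
eco_exergy <- function(biomass, weights = lc_exergy_weights()) {
  if (any(biomass < 0)) stop("negative biomass")
  if (!is.null(names(biomass))) {
    bad <- setdiff(names(biomass), names(weights))
    if (length(bad))
      stop("no equivalence factor for guild(s): ", paste(bad, collapse = ", "))
    weights <- weights[names(biomass)]
  } else if (length(biomass) != length(weights)) {
    stop("biomass and weights differ in length")
  }
  Ex <- sum(as.numeric(weights) * biomass)
  tot <- sum(biomass)
  if (tot == 0) {
    warning("zero total biomass: specific eco-exergy undefined")
    return(list(Ex = 0, Ex_sp = NaN))
  }
  list(Ex = Ex, Ex_sp = Ex / tot)
}
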