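# Closed-form labeling mathematics: binomial isotopologue probabilities,
# carbon-pool mass balance, carboxylation dilution, delta-notation
# conversion, yield energetics.

#' Binomial isotopologue probability
#'
#' Probability that exactly \code{k} of the \code{n} carbon positions of a
#' molecule carry 13C when every position is labeled independently with
#' probability \code{p}:
#' \deqn{p_k = p^k (1-p)^{n-k} \binom{n}{k}.}
#' Coefficients are computed via \code{lchoose} so that large molecules
#' (n > 20) do not overflow.
#'
#' @param p probability that a carbon position is 13C (0-1).
#' @param n number of carbon positions (>= 1).
#' @param k number of labeled positions (0 <= k <= n).
#' @return The probability of the \eqn{M+k} isotopologue.
#' @examples
#' binomialPk(0.039, 3, 1)  # 0.108
#' binomialPk(0.051, 3, 1)  # 0.138
#' @seealso [binomialMID()] for the full distribution.
#' @export
binomialPk <- function(p, n, k) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]")
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 1L) stop("'n' must be >= 1")
  if (any(k < 0L) || any(k > n)) stop("'k' must satisfy 0 <= k <= n")
  # work in log space only for the coefficient; p^k at the edges needs the
  # 0^0 = 1 convention, which R's ^ honors
  exp(lchoose(n, k)) * p^k * (1 - p)^(n - k)
}

#' Binomial mass isotopomer distribution
#'
#' The full distribution over \eqn{M+0 \ldots M+n} for a molecule whose
#' \code{n} carbons are labeled independently with probability \code{p}.
#'
#' @inheritParams binomialPk
#' @return Numeric vector of length \code{n + 1} summing to 1.
#' @examples
#' binomialMID(0.1, 2)  # c(0.81, 0.18, 0.01)
#' @export
binomialMID <- function(p, n) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  v <- binomialPk(p, n, 0:n)
  v / sum(v)
}

#' Carbon pool table of the reference culture bottle
#'
#' The carbon pools of a 150 mL culture: naphthalene-derived carbon
#' (3.45 mmol C, i.e. the CO2 ultimately produced by complete substrate
#' oxidation), bicarbonate buffer (4.5 mmol C = 30 mM in 150 mL) and
#' headspace CO2 (0.8 mmol C). Enrichment columns give the excess 13C atom
#' fraction above natural abundance per pool for the requested tracer
#' setting (10 atom% label).
#'
#' @param tracer \code{"naphthalene_U13C"}, \code{"bicarbonate_13C"} or
#'   \code{"unlabeled"}.
#' @param tracerAtomFraction mole fraction of labeled substrate.
#' @return data.frame with columns \code{name}, \code{carbonAmount} (mmol C)
#'   and \code{enrichment} (excess 13C fraction).
#' @examples
#' referencePools("bicarbonate_13C")
#' @export
referencePools <- function(tracer = c("naphthalene_U13C", "bicarbonate_13C",
                                  "unlabeled"),
                       tracerAtomFraction = 0.10) {
  tracer <- match.arg(tracer)
  enr <- switch(tracer,
    naphthalene_U13C = c(tracerAtomFraction, 0, 0),
    bicarbonate_13C = c(0, tracerAtomFraction, 0),
    unlabeled = c(0, 0, 0)
  )
  data.frame(
    name = c("naphthalene", "bicarbonate", "headspace"),
    carbonAmount = c(3.45, 4.5, 0.8),
    enrichment = enr,
    stringsAsFactors = FALSE
  )
}

#' Maximum pool enrichment by mass balance
#'
#' Excess 13C enrichment of the combined carbon pools when a given amount of
#' labeled carbon is distributed over all of them:
#' \eqn{{}^{13}C / \sum_i C_i}. With the reference bottle pools
#' (3.45 + 4.5 + 0.8 mmol C) this gives 5.1\% for 0.45 mmol 13C
#' (bicarbonate tracer) and 3.9\% for 0.345 mmol (naphthalene tracer).
#'
#' @param labeledAmount mmol of excess 13C.
#' @param pools data.frame with a \code{carbonAmount} column (mmol C), as
#'   from [referencePools()].
#' @return Enrichment fraction in [0, 1].
#' @examples
#' poolMaxEnrichment(0.45, referencePools())   # 0.0514 -> 5.1 %
#' poolMaxEnrichment(0.345, referencePools())  # 0.0394 -> 3.9 %
#' @export
poolMaxEnrichment <- function(labeledAmount, pools) {
  if (is.null(pools) || !NROW(pools))
    stop("'pools' must contain at least one carbon pool")
  total <- sum(pools$carbonAmount)
  if (!is.finite(total) || total <= 0)
    stop("total pool carbon must be positive")
  if (labeledAmount < 0 || labeledAmount > total)
    stop("'labeledAmount' must lie in [0, total pool carbon]")
  labeledAmount / total
}

#' Dilution of tracer label by substrate carboxylation
#'
#' When a C10 substrate is activated by carboxylation with CO2 labeled at
#' \code{tracerEnrichment}, only one of the \code{productCarbons} carbons of
#' the product can carry the label, so the per-carbon incorporation is
#' \eqn{\mathrm{tracer}/\mathrm{carbons}} (0.9\% for 10 atom\% CO2 and a
#' C11 acid).
#'
#' @param tracerEnrichment excess enrichment of the carboxylating CO2 pool.
#' @param productCarbons carbon count of the carboxylation product (>= 1).
#' @return Per-carbon enrichment fraction.
#' @examples
#' carboxylationDilution(0.10, 11)  # 0.009
#' @export
carboxylationDilution <- function(tracerEnrichment, productCarbons) {
  productCarbons <- as.integer(productCarbons)
  if (is.na(productCarbons) || productCarbons < 1L)
    stop("'productCarbons' must be >= 1")
  if (tracerEnrichment < 0 || tracerEnrichment > 1)
    stop("'tracerEnrichment' must lie in [0, 1]")
  tracerEnrichment / productCarbons
}

#' VPDB reference 13C/12C ratio
#'
#' @return The VPDB isotope ratio 0.0111802 used as the default reference
#'   for delta-notation conversion.
#' @export
vpdbRatio <- function() 0.0111802

#' Convert delta notation to isotope-amount fraction
#'
#' \eqn{x = R/(1+R)} with \eqn{R = R_{ref}(1 + \delta/1000)}. The default
#' reference is the VPDB ratio.
#'
#' @param deltaPerMil delta 13C value in per mil (> -1000).
#' @param referenceRatio 13C/12C ratio of the standard.
#' @return 13C isotope-amount fraction.
#' @examples
#' deltaToAtomFraction(0)      # the standard itself
#' deltaToAtomFraction(-9.7)   # a typical reference gas
#' @export
deltaToAtomFraction <- function(deltaPerMil, referenceRatio = vpdbRatio()) {
  if (!is.finite(referenceRatio) || referenceRatio <= 0)
    stop("'referenceRatio' must be positive")
  if (any(deltaPerMil <= -1000))
    stop("'deltaPerMil' must be > -1000")
  r <- referenceRatio * (1 + deltaPerMil / 1000)
  r / (1 + r)
}

#' Convert isotope-amount fraction to delta notation
#'
#' Inverse of [deltaToAtomFraction()]; the round trip is exact to numerical
#' precision.
#'
#' @param atomFraction 13C isotope-amount fraction (0 <= x < 1).
#' @param referenceRatio 13C/12C ratio of the standard.
#' @return delta 13C in per mil.
#' @export
atomFractionToDelta <- function(atomFraction, referenceRatio = vpdbRatio()) {
  if (!is.finite(referenceRatio) || referenceRatio <= 0)
    stop("'referenceRatio' must be positive")
  if (any(atomFraction < 0) || any(atomFraction >= 1))
    stop("'atomFraction' must lie in [0, 1)")
  r <- atomFraction / (1 - atomFraction)
  1000 * (r / referenceRatio - 1)
}

#' Inorganic-carbon enrichment as substrate oxidation proceeds
#'
#' Well-mixed instantaneous pool-mixing model: as a fraction \code{x} of the
#' substrate (naphthalene) pool is oxidized, its carbon (with the tracer's
#' enrichment) joins the inorganic pools (bicarbonate + headspace), moving
#' the inorganic excess enrichment from its initial value towards the
#' all-pool mass-balance bound at complete oxidation. No isotope
#' fractionation and no headspace/aqueous disequilibrium are modeled;
#' enrichment always refers to total CO2 in the bottle.
#'
#' @param fractionOxidized numeric vector in [0, 1]: fraction of the
#'   substrate pool oxidized to CO2.
#' @param tracer a \linkS4class{TracerExperiment}; its pools must contain a
#'   \code{"naphthalene"} pool and at least one inorganic pool.
#' @return data.frame with columns \code{fractionOxidized},
#'   \code{enrichment} (inorganic excess enrichment),
#'   \code{labeledInorganic} and \code{labeledOrganic} (mmol excess 13C, for
#'   conservation checks).
#' @examples
#' te <- tracerExperiment("naphthalene_U13C")
#' co2EnrichmentTimecourse(c(0, 0.5, 1), te)
#' @export
co2EnrichmentTimecourse <- function(fractionOxidized, tracer) {
  if (any(fractionOxidized < 0 | fractionOxidized > 1))
    stop("'fractionOxidized' must lie in [0, 1]")
  p <- tracer@pools
  isNaph <- p$name == "naphthalene"
  if (!any(isNaph))
    stop("tracer pools must contain a 'naphthalene' pool")
  if (all(isNaph))
    stop("tracer pools must contain at least one inorganic pool")
  naphC <- sum(p$carbonAmount[isNaph])
  naphLab <- sum(p$carbonAmount[isNaph] * p$enrichment[isNaph])
  inorgC0 <- sum(p$carbonAmount[!isNaph])
  inorgLab0 <- sum(p$carbonAmount[!isNaph] * p$enrichment[!isNaph])
  x <- fractionOxidized
  labeledInorganic <- inorgLab0 + x * naphLab
  inorganicC <- inorgC0 + x * naphC
  data.frame(
    fractionOxidized = x,
    enrichment = labeledInorganic / inorganicC,
    labeledInorganic = labeledInorganic,
    labeledOrganic = (1 - x) * naphLab
  )
}

#' Biomass yield from ATP stoichiometry
#'
#' Gram biomass formed per gram substrate:
#' \eqn{\mathrm{ATP/substrate} \times Y_{ATP} / M_{substrate}}. With 3 ATP
#' per naphthalene, 10 g biomass per mol ATP and M = 128.17 g/mol this gives
#' the 0.23 g/g upper bound for anaerobic naphthalene oxidizers.
#'
#' @param atpPerSubstrate mol ATP conserved per mol substrate (> 0).
#' @param yieldPerMolAtp g biomass per mol ATP (> 0).
#' @param substrateMolarMass substrate molar mass in g/mol (> 0); defaults
#'   to naphthalene, 128.17 g/mol.
#' @return g biomass per g substrate.
#' @examples
#' biomassYield(3, 10)  # ~0.23
#' biomassYield(2, 10)  # ~0.16
#' @export
biomassYield <- function(atpPerSubstrate, yieldPerMolAtp,
                         substrateMolarMass = 128.17) {
  vals <- c(atpPerSubstrate, yieldPerMolAtp, substrateMolarMass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be positive")
  atpPerSubstrate * yieldPerMolAtp / substrateMolarMass
}
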