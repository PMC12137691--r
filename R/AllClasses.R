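#' @import methods
NULL

#' Measured GC-MS fragment
#'
#' Describes a single fragment monitored in selected-ion mode: how many
#' carbons of the original analyte skeleton it contains, its nominal
#' \eqn{M+0} mass, and how many mass channels (\eqn{M+0 \ldots M+K}) are
#' recorded. Non-skeleton atoms (derivatization reagent, Si, H, N, O) are
#' described only as free text; their isotope contribution is fitted
#' empirically, never modeled theoretically.
#'
#' @slot name fragment identifier, e.g. \code{"alanine"}.
#' @slot skeletonCarbons number of analyte carbons in the fragment.
#' @slot fragmentMass nominal m/z of the \eqn{M+0} channel.
#' @slot nChannels number of recorded mass channels (\eqn{K+1}).
#' @slot reagentNote free-text description of the non-skeleton composition.
#' @exportClass FragmentSpec
setClass("FragmentSpec",
  representation(
    name = "character",
    skeletonCarbons = "integer",
    fragmentMass = "numeric",
    nChannels = "integer",
    reagentNote = "character"
  )
)

setValidity("FragmentSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@skeletonCarbons) != 1L || is.na(object@skeletonCarbons) ||
      object@skeletonCarbons < 1L)
    msg <- c(msg, "'skeletonCarbons' must be a single integer >= 1")
  if (length(object@nChannels) != 1L || is.na(object@nChannels) ||
      object@nChannels < object@skeletonCarbons + 1L)
    msg <- c(msg, "'nChannels' must be >= skeletonCarbons + 1")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSpec
#'
#' @param name fragment identifier.
#' @param skeletonCarbons number of analyte carbons in the fragment.
#' @param fragmentMass nominal m/z of \eqn{M+0}.
#' @param nChannels number of mass channels recorded; the default
#'   \code{skeletonCarbons + 5} spans the skeleton isotopologues plus four
#'   extra shifts for reagent isotopes (Si, reagent C) of TBDMS fragments.
#' @param reagentNote free text describing non-skeleton atoms.
#' @return A \linkS4class{FragmentSpec}.
#' @examples
#' fragmentSpec("alanine", 3, 260)
#' @export
fragmentSpec <- function(name, skeletonCarbons, fragmentMass,
                         nChannels = skeletonCarbons + 5L,
                         reagentNote = "") {
  new("FragmentSpec",
    name = as.character(name),
    skeletonCarbons = as.integer(skeletonCarbons),
    fragmentMass = as.numeric(fragmentMass),
    nChannels = as.integer(nChannels),
    reagentNote = as.character(reagentNote)
  )
}

#' Mass isotopomer distribution
#'
#' Non-negative fractional abundances over the mass channels
#' \eqn{M+0 \ldots M+K} of a fragment, summing to one.
#'
#' @slot fragment the \linkS4class{FragmentSpec} the distribution refers to.
#' @slot fractions numeric vector over \eqn{M+0 \ldots M+K}.
#' @exportClass MID
setClass("MID",
  representation(fragment = "FragmentSpec", fractions = "numeric")
)

setValidity("MID", function(object) {
  f <- object@fractions
  msg <- character()
  if (any(!is.finite(f))) msg <- c(msg, "fractions must be finite")
  if (any(f < -1e-12)) msg <- c(msg, "fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct a MID
#'
#' @param fragment a \linkS4class{FragmentSpec}.
#' @param fractions abundances over \eqn{M+0 \ldots M+K}; normalized to unit
#'   sum (raw SIM intensities are accepted).
#' @return A \linkS4class{MID}.
#' @export
newMID <- function(fragment, fractions) {
  fractions <- as.numeric(fractions)
  if (any(fractions < 0))
    stop("MID fractions must be non-negative")
  s <- sum(fractions)
  if (s <= 0) stop("MID fractions must have positive sum")
  new("MID", fragment = fragment, fractions = fractions / s)
}

#' Natural-abundance / reagent correction model for one fragment
#'
#' Holds the two ingredients of the three-step correction: the theoretical
#' skeleton natural-abundance matrix and the empirically fitted mass-shift
#' distribution of all non-skeleton atoms (the "reagent vector").
#'
#' @slot fragment the \linkS4class{FragmentSpec}.
#' @slot skeletonMatrix lower-triangular convolution matrix mapping skeleton
#'   isotopologue fractions to mass channels under natural abundance.
#' @slot reagentVector fitted mass-shift distribution of non-skeleton atoms.
#' @slot pNat natural 13C abundance used to build the matrix.
#' @slot residual relative residual norm of the reagent fit.
#' @slot flagged TRUE when the reagent fit residual exceeded its threshold
#'   (signals a mis-specified fragment).
#' @exportClass CorrectionModel
setClass("CorrectionModel",
  representation(
    fragment = "FragmentSpec",
    skeletonMatrix = "matrix",
    reagentVector = "numeric",
    pNat = "numeric",
    residual = "numeric",
    flagged = "logical"
  )
)

setValidity("CorrectionModel", function(object) {
  msg <- character()
  rv <- object@reagentVector
  if (length(rv)) {
    if (any(rv < -1e-12)) msg <- c(msg, "reagentVector must be non-negative")
    if (abs(sum(rv) - 1) > 1e-6)
      msg <- c(msg, "reagentVector must sum to 1")
  }
  cs <- colSums(object@skeletonMatrix)
  if (any(cs > 1 + 1e-9))
    msg <- c(msg, "skeletonMatrix columns must each sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' Per-fragment 13C excess above natural abundance
#'
#' The end product of the correction pipeline: isotopologue excess fractions
#' (\eqn{M+1, M+2, \ldots}) with natural abundance and reagent isotopes
#' removed, the mean per-carbon enrichment, and replicate spread.
#'
#' @slot fragment the \linkS4class{FragmentSpec}.
#' @slot excess numeric vector of excess fractions for \eqn{M+1 \ldots M+n}
#'   (n = skeleton carbons).
#' @slot meanEnrichment per-carbon 13C excess,
#'   \eqn{\sum_k k\,e_k / n}.
#' @slot sd per-component standard deviation over biological replicates;
#'   length-0 when not available (pooled samples).
#' @slot replicates matrix of per-biological-replicate excess vectors
#'   (replicates in rows); may have zero rows.
#' @slot tracer tracer setting label the result was measured under.
#' @exportClass ExcessResult
setClass("ExcessResult",
  representation(
    fragment = "FragmentSpec",
    excess = "numeric",
    meanEnrichment = "numeric",
    sd = "numeric",
    replicates = "matrix",
    tracer = "character"
  ),
  prototype(
    sd = numeric(0),
    replicates = matrix(numeric(0), nrow = 0, ncol = 0),
    tracer = NA_character_
  )
)

setValidity("ExcessResult", function(object) {
  msg <- character()
  n <- object@fragment@skeletonCarbons
  if (length(object@excess) != n)
    msg <- c(msg, "excess must have one component per skeleton carbon")
  if (any(abs(object@excess) > 1 + 1e-9))
    msg <- c(msg, "excess components must lie in [-1, 1]")
  me <- sum(seq_len(n) * object@excess) / n
  if (abs(me - object@meanEnrichment) > 1e-9)
    msg <- c(msg, "meanEnrichment must equal sum(k * excess_k) / n")
  if (length(object@sd) && length(object@sd) != length(object@excess))
    msg <- c(msg, "sd must be empty or match excess length")
  if (length(msg)) msg else TRUE
})

#' Construct an ExcessResult
#'
#' @param fragment a \linkS4class{FragmentSpec}.
#' @param excess excess fractions for \eqn{M+1 \ldots M+n}.
#' @param sd optional per-component sd over biological replicates.
#' @param replicates optional matrix of per-replicate excess vectors.
#' @param tracer optional tracer setting label.
#' @return An \linkS4class{ExcessResult}.
#' @export
excessResult <- function(fragment, excess, sd = numeric(0),
                         replicates = NULL, tracer = NA_character_) {
  n <- fragment@skeletonCarbons
  excess <- as.numeric(excess)
  if (length(excess) != n)
    stop("'excess' must have ", n, " components (M+1 ... M+", n, ")")
  if (is.null(replicates))
    replicates <- matrix(numeric(0), nrow = 0, ncol = n)
  new("ExcessResult",
    fragment = fragment,
    excess = excess,
    meanEnrichment = sum(seq_len(n) * excess) / n,
    sd = as.numeric(sd),
    replicates = replicates,
    tracer = as.character(tracer)
  )
}

#' Tracer experiment configuration
#'
#' Identity of the 13C tracer, its atom fraction, and the carbon pools of
#' the culture bottle (in mmol carbon with their excess enrichment above
#' natural abundance).
#'
#' @slot tracer \code{"naphthalene_U13C"}, \code{"bicarbonate_13C"} or
#'   \code{"unlabeled"}.
#' @slot tracerAtomFraction mole fraction of labeled substrate (e.g. 0.10).
#' @slot pools data.frame with columns \code{name}, \code{carbonAmount}
#'   (mmol C) and \code{enrichment} (excess 13C atom fraction, 0-1).
#' @slot effectiveCo2Enrichment effective excess enrichment of the CO2 pool
#'   feeding anabolism; defaults to the full-oxidation mass-balance bound.
#' @exportClass TracerExperiment
setClass("TracerExperiment",
  representation(
    tracer = "character",
    tracerAtomFraction = "numeric",
    pools = "data.frame",
    effectiveCo2Enrichment = "numeric"
  )
)

setValidity("TracerExperiment", function(object) {
  msg <- character()
  if (!object@tracer %in% c("naphthalene_U13C", "bicarbonate_13C", "unlabeled"))
    msg <- c(msg, "unknown tracer identity")
  if (object@tracerAtomFraction < 0 || object@tracerAtomFraction > 1)
    msg <- c(msg, "tracerAtomFraction must lie in [0, 1]")
  p <- object@pools
  need <- c("name", "carbonAmount", "enrichment")
  if (!all(need %in% names(p))) {
    msg <- c(msg, "pools must have columns name, carbonAmount, enrichment")
  } else {
    if (any(p$carbonAmount < 0)) msg <- c(msg, "pool carbonAmount must be >= 0")
    if (any(p$enrichment < 0 | p$enrichment > 1))
      msg <- c(msg, "pool enrichment must lie in [0, 1]")
  }
  if (object@effectiveCo2Enrichment < 0 || object@effectiveCo2Enrichment > 1)
    msg <- c(msg, "effectiveCo2Enrichment must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Metabolic scenario for the provenance of anabolic acetyl-CoA
#'
#' @slot name one of \code{"direct_assimilation"},
#'   \code{"chemoorganoautotrophic"}, \code{"carboxyl_exchange"},
#'   \code{"mixture"}.
#' @slot mixtureFraction fraction f of anabolic acetyl-CoA built de novo
#'   from CO2 (used by \code{"mixture"} only).
#' @slot exchangeCompleteness completeness of the carboxyl exchange
#'   (used by \code{"carboxyl_exchange"} only).
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(
    name = "character",
    mixtureFraction = "numeric",
    exchangeCompleteness = "numeric"
  ),
  prototype(mixtureFraction = NA_real_, exchangeCompleteness = 1)
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@name %in% c("direct_assimilation", "chemoorganoautotrophic",
                          "carboxyl_exchange", "mixture"))
    msg <- c(msg, "unknown scenario name")
  if (object@name == "mixture" &&
      (is.na(object@mixtureFraction) || object@mixtureFraction < 0 ||
       object@mixtureFraction > 1))
    msg <- c(msg, "mixtureFraction must lie in [0, 1] for scenario 'mixture'")
  if (object@exchangeCompleteness < 0 || object@exchangeCompleteness > 1)
    msg <- c(msg, "exchangeCompleteness must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioSpec
#'
#' @param name scenario name; see \linkS4class{ScenarioSpec}.
#' @param mixtureFraction fraction of anabolic acetyl-CoA from CO2 fixation
#'   (scenario \code{"mixture"}).
#' @param exchangeCompleteness completeness of carboxyl exchange
#'   (scenario \code{"carboxyl_exchange"}).
#' @return A \linkS4class{ScenarioSpec}.
#' @examples
#' scenarioSpec("chemoorganoautotrophic")
#' scenarioSpec("mixture", mixtureFraction = 0.8)
#' @export
scenarioSpec <- function(name, mixtureFraction = NA_real_,
                         exchangeCompleteness = 1) {
  new("ScenarioSpec",
    name = name,
    mixtureFraction = as.numeric(mixtureFraction),
    exchangeCompleteness = as.numeric(exchangeCompleteness)
  )
}

#' Spectrophotometric assay configuration
#'
#' Everything needed to turn an absorbance slope into a specific activity:
#' chromophore extinction coefficient, cuvette geometry, cell-free extract
#' (cfe) dose and protein content, evaluation window, and the sign of the
#' absorbance change (formation vs. consumption of the chromophore).
#'
#' @slot enzyme enzyme (or coupled reaction) name.
#' @slot direction \code{"oxidative"} or \code{"reductive"}.
#' @slot wavelength detection wavelength in nm.
#' @slot extinctionCoefficient chromophore extinction in mM^-1 cm^-1.
#' @slot pathLength optical path length in cm.
#' @slot assayVolume assay volume in mL.
#' @slot cfeFraction volume fraction of cell-free extract in the assay.
#' @slot proteinConc protein concentration of the cfe in mg/mL.
#' @slot evaluationTime evaluation window in min.
#' @slot sign +1 when the chromophore is formed (absorbance rises with
#'   activity), -1 when it is consumed.
#' @slot coupled TRUE for combined assays whose rate cannot be attributed
#'   to a single enzyme.
#' @exportClass AssayConfig
setClass("AssayConfig",
  representation(
    enzyme = "character",
    direction = "character",
    wavelength = "numeric",
    extinctionCoefficient = "numeric",
    pathLength = "numeric",
    assayVolume = "numeric",
    cfeFraction = "numeric",
    proteinConc = "numeric",
    evaluationTime = "numeric",
    sign = "numeric",
    coupled = "logical"
  ),
  prototype(pathLength = 1, assayVolume = 1, sign = 1, coupled = FALSE)
)

setValidity("AssayConfig", function(object) {
  msg <- character()
  pos <- c(
    wavelength = object@wavelength,
    extinctionCoefficient = object@extinctionCoefficient,
    pathLength = object@pathLength,
    assayVolume = object@assayVolume,
    cfeFraction = object@cfeFraction,
    proteinConc = object@proteinConc,
    evaluationTime = object@evaluationTime
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("positive value required for: ",
                         paste(bad, collapse = ", ")))
  if (!object@direction %in% c("oxidative", "reductive"))
    msg <- c(msg, "direction must be 'oxidative' or 'reductive'")
  if (!object@sign %in% c(-1, 1))
    msg <- c(msg, "sign must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Construct an AssayConfig
#'
#' @param enzyme enzyme (or coupled reaction) name.
#' @param direction \code{"oxidative"} or \code{"reductive"}.
#' @param wavelength detection wavelength (nm).
#' @param extinctionCoefficient chromophore extinction (mM^-1 cm^-1).
#' @param evaluationTime evaluation window (min).
#' @param cfeFraction volume fraction of cell-free extract.
#' @param proteinConc protein concentration of the cfe (mg/mL).
#' @param pathLength optical path (cm).
#' @param assayVolume assay volume (mL).
#' @param sign +1 chromophore formed, -1 consumed.
#' @param coupled TRUE for combined (multi-enzyme) assays.
#' @return An \linkS4class{AssayConfig}.
#' @export
assayConfig <- function(enzyme, direction, wavelength, extinctionCoefficient,
                        evaluationTime, cfeFraction, proteinConc,
                        pathLength = 1, assayVolume = 1, sign = 1,
                        coupled = FALSE) {
  new("AssayConfig",
    enzyme = enzyme, direction = direction,
    wavelength = as.numeric(wavelength),
    extinctionCoefficient = as.numeric(extinctionCoefficient),
    pathLength = as.numeric(pathLength),
    assayVolume = as.numeric(assayVolume),
    cfeFraction = as.numeric(cfeFraction),
    proteinConc = as.numeric(proteinConc),
    evaluationTime = as.numeric(evaluationTime),
    sign = as.numeric(sign),
    coupled = isTRUE(coupled)
  )
}
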