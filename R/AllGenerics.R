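# Accessor generics and show methods.

#' @rdname FragmentSpec-class
#' @param object a package object.
#' @export
setGeneric("fragmentName", function(object) standardGeneric("fragmentName"))

#' @rdname FragmentSpec-class
#' @export
setGeneric("skeletonCarbons", function(object) standardGeneric("skeletonCarbons"))

#' @rdname MID-class
#' @param object a package object.
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname ExcessResult-class
#' @param object a package object.
#' @export
setGeneric("excess", function(object) standardGeneric("excess"))

#' @rdname ExcessResult-class
#' @export
setGeneric("meanEnrichment", function(object) standardGeneric("meanEnrichment"))

#' @rdname CorrectionModel-class
#' @param object a package object.
#' @export
setGeneric("reagentVector", function(object) standardGeneric("reagentVector"))

#' @describeIn FragmentSpec-class fragment name.
setMethod("fragmentName", "FragmentSpec", function(object) object@name)

#' @describeIn FragmentSpec-class number of analyte carbons.
setMethod("skeletonCarbons", "FragmentSpec", function(object)
  object@skeletonCarbons)

#' @describeIn MID-class underlying fragment name.
setMethod("fragmentName", "MID", function(object) object@fragment@name)

#' @describeIn MID-class fractional abundances over the mass channels.
setMethod("fractions", "MID", function(object) object@fractions)

#' @describeIn ExcessResult-class excess fractions for M+1 ... M+n.
setMethod("excess", "ExcessResult", function(object) object@excess)

#' @describeIn ExcessResult-class per-carbon 13C excess.
setMethod("meanEnrichment", "ExcessResult", function(object)
  object@meanEnrichment)

#' @describeIn ExcessResult-class underlying fragment name.
setMethod("fragmentName", "ExcessResult", function(object)
  object@fragment@name)

#' @describeIn CorrectionModel-class fitted non-skeleton mass-shift
#'   distribution.
setMethod("reagentVector", "CorrectionModel", function(object)
  object@reagentVector)

setMethod("show", "FragmentSpec", function(object) {
  cat("FragmentSpec '", object@name, "': ", object@skeletonCarbons,
      " skeleton C, M+0 at m/z ", object@fragmentMass, ", ",
      object@nChannels, " channels\n", sep = "")
})

setMethod("show", "MID", function(object) {
  cat("MID for '", object@fragment@name, "' (",
      length(object@fractions), " channels)\n", sep = "")
  v <- signif(object@fractions, 4)
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(v)
})

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel for '", object@fragment@name, "' (p_nat = ",
      object@pNat, ")\n", sep = "")
  v <- signif(object@reagentVector, 4)
  names(v) <- paste0("+", seq_along(v) - 1L)
  cat("  reagent vector:\n")
  print(v)
  cat("  reagent-fit relative residual: ", signif(object@residual, 3),
      if (object@flagged) "  [FLAGGED]" else "", "\n", sep = "")
})

setMethod("show", "ExcessResult", function(object) {
  cat("ExcessResult for '", object@fragment@name, "'",
      if (!is.na(object@tracer)) paste0(" [", object@tracer, "]"), "\n",
      sep = "")
  v <- signif(100 * object@excess, 3)
  names(v) <- paste0("M+", seq_along(v), " (%)")
  print(v)
  if (length(object@sd)) {
    s <- signif(100 * object@sd, 3)
    names(s) <- paste0("sd M+", seq_along(s), " (pp)")
    print(s)
  } else {
    cat("  (sd not available: pooled sample)\n")
  }
  cat("  mean per-carbon enrichment: ",
      signif(100 * object@meanEnrichment, 3), " %\n", sep = "")
})

setMethod("show", "TracerExperiment", function(object) {
  cat("TracerExperiment: ", object@tracer, " at ",
      100 * object@tracerAtomFraction, " atom%\n", sep = "")
  print(object@pools)
  cat("  effective CO2 excess enrichment: ",
      signif(100 * object@effectiveCo2Enrichment, 3), " %\n", sep = "")
})

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec '", object@name, "'", sep = "")
  if (object@name == "mixture")
    cat(" (f = ", object@mixtureFraction, ")", sep = "")
  if (object@name == "carboxyl_exchange")
    cat(" (completeness = ", object@exchangeCompleteness, ")", sep = "")
  cat("\n")
})

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig '", object@enzyme, "' (", object@direction, "): ",
      object@wavelength, " nm, eps = ", object@extinctionCoefficient,
      " mM^-1 cm^-1, window ", object@evaluationTime, " min",
      if (object@coupled) " [coupled]", "\n", sep = "")
})
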