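# Reduction of spectrophotometric absorbance traces to specific
# activities (nmol min^-1 mg^-1 protein) with propagated uncertainty.

#' Ordinary least-squares slope of an absorbance trace
#'
#' @param trace data.frame with columns \code{time_min} and
#'   \code{absorbance}.
#' @param window evaluation window in min: points with
#'   \code{time_min <= window} are used (default: all points).
#' @return List with \code{slope} (delta A per min) and \code{se}
#'   (standard error of the slope).
#' @examples
#' tr <- data.frame(time_min = 0:10, absorbance = 0.1 + 0.01 * 0:10)
#' linearSlope(tr)$slope  # 0.01
#' @export
linearSlope <- function(trace, window = NULL) {
  need <- c("time_min", "absorbance")
  if (!all(need %in% names(trace)))
    stop("trace must have columns time_min and absorbance")
  t <- trace$time_min
  a <- trace$absorbance
  if (!is.null(window)) {
    if (window <= min(t))
      stop("evaluation window lies outside the trace")
    keep <- t <= window
    t <- t[keep]; a <- a[keep]
  }
  if (length(t) < 3L)
    stop("at least 3 points are required in the evaluation window")
  fit <- stats::lm(a ~ t)
  slope <- unname(stats::coef(fit)[2L])
  # closed-form slope standard error (summary.lm warns on perfect fits)
  sxx <- sum((t - mean(t))^2)
  s2 <- sum(stats::residuals(fit)^2) / (length(t) - 2L)
  list(slope = slope, se = sqrt(s2 / sxx))
}

#' Specific activity from an absorbance slope
#'
#' Beer-Lambert conversion of a control-corrected absorbance slope into a
#' specific activity:
#' \deqn{a = \mathrm{sign} \cdot \frac{(s - s_0)\,1000\,V}
#'   {\varepsilon\, l \cdot V\, \phi\, c_{prot}}}
#' in nmol min^-1 mg^-1 protein, where \eqn{s - s_0} is the net slope
#' (delta A/min), \eqn{\varepsilon} the extinction coefficient
#' (mM^-1 cm^-1), \eqn{l} the path (cm), \eqn{V} the assay volume (mL),
#' \eqn{\phi} the cfe volume fraction and \eqn{c_{prot}} the cfe protein
#' concentration (mg/mL); the factor 1000 converts \eqn{\mu}mol to nmol.
#' Consumption assays (sign -1) negate the slope. A net activity below
#' \code{-tolerance} in rate units is reported as 0 with a flag.
#'
#' @param slope measured slope (delta A/min).
#' @param config an \linkS4class{AssayConfig}.
#' @param controlSlope slope of the substrate-omitted control (default 0).
#' @param slopeSe optional standard error of the net slope, propagated to
#'   the activity.
#' @param tolerance negative-activity tolerance (default 1e-9).
#' @return List with \code{activity} (nmol min^-1 mg^-1),
#'   \code{uncertainty} (same units, from \code{slopeSe}),
#'   \code{controlSubtracted} and \code{clippedNegative} flags.
#' @export
specificActivity <- function(slope, config, controlSlope = 0,
                             slopeSe = NA_real_, tolerance = 1e-9) {
  validObject(config)
  net <- config@sign * (slope - controlSlope)
  proteinMg <- config@assayVolume * config@cfeFraction * config@proteinConc
  conv <- 1000 * config@assayVolume /
    (config@extinctionCoefficient * config@pathLength * proteinMg)
  act <- net * conv
  clipped <- FALSE
  if (act < 0) {
    if (act < -abs(tolerance) * conv) clipped <- TRUE
    act <- 0
  }
  list(
    activity = act,
    uncertainty = if (is.na(slopeSe)) NA_real_ else abs(slopeSe) * conv,
    controlSubtracted = controlSlope != 0,
    clippedNegative = clipped
  )
}

#' Protein concentration by Bradford calibration
#'
#' Fits the linear calibration of standard concentrations against
#' absorbance and inverse-predicts the sample concentration; the
#' uncertainty combines the calibration standard error with the spread of
#' replicate sample absorbances.
#'
#' @param calibration data.frame with columns \code{concentration} (mg/mL)
#'   and \code{absorbance} (>= 3 standards).
#' @param sampleAbs one or more replicate absorbances of the sample.
#' @return List with \code{concentration} (mg/mL), \code{uncertainty}, and
#'   \code{extrapolated} (TRUE when the sample lies outside the calibration
#'   range, with a warning).
#' @export
bradfordProtein <- function(calibration, sampleAbs) {
  need <- c("concentration", "absorbance")
  if (!all(need %in% names(calibration)))
    stop("calibration must have columns concentration and absorbance")
  if (nrow(calibration) < 3L)
    stop("at least 3 calibration standards are required")
  fit <- stats::lm(absorbance ~ concentration, data = calibration)
  b <- stats::coef(fit)
  if (!is.finite(b[2L]) || abs(b[2L]) < 1e-12)
    stop("degenerate calibration: zero slope")
  mAbs <- mean(sampleAbs)
  conc <- (mAbs - b[1L]) / b[2L]
  extrapolated <- mAbs < min(calibration$absorbance) ||
    mAbs > max(calibration$absorbance)
  if (extrapolated)
    warning("sample absorbance outside the calibration range; ",
            "extrapolating")
  seAbs <- if (length(sampleAbs) >= 2L)
    stats::sd(sampleAbs) / sqrt(length(sampleAbs)) else 0
  # residual sd computed directly (summary.lm warns on exact fits)
  sigma <- sqrt(sum(stats::residuals(fit)^2) /
                  max(1L, nrow(calibration) - 2L))
  unc <- sqrt(seAbs^2 + sigma^2) / abs(b[2L])
  list(concentration = unname(conc), uncertainty = unname(unc),
       extrapolated = extrapolated)
}

#' Combine replicate and protein-measurement uncertainty
#'
#' Quadrature combination of the replicate standard deviation of the
#' activities with the relative uncertainty of the protein concentration
#' (itself measured in triplicate):
#' \eqn{\sqrt{sd^2 + (\bar a \cdot u_{prot}/c_{prot})^2}}.
#'
#' @param activities numeric vector of replicate activities (>= 2).
#' @param proteinRelSd relative sd of the protein concentration (e.g. 0.1
#'   for 10\%).
#' @return Combined uncertainty in activity units.
#' @examples
#' combineUncertainty(c(94, 94, 94), 0.1)  # 9.4 (10% relative)
#' @export
combineUncertainty <- function(activities, proteinRelSd = 0) {
  if (length(activities) < 2L)
    stop("at least 2 replicate activities are required")
  sqrt(stats::sd(activities)^2 + (mean(activities) * proteinRelSd)^2)
}

#' Reference assay configurations
#'
#' The spectrophotometric assay set of the reference study: TCA-cycle
#' enzymes in both directions plus the two key carbonyl-branch activities
#' of the Wood-Ljungdahl pathway, with standard literature extinction
#' coefficients (NADH/NADPH 340 nm: 6.22, reduced methyl viologen 600 nm:
#' 13.7, TNB 412 nm: 14.15, fumarate 250 nm: 1.45 mM^-1 cm^-1; all
#' overridable), 1 cm path, 1 mL assay volume, the published cfe fractions
#' and evaluation windows. Protein concentrations are stored per mL of cfe
#' so that the cuvette holds the published total protein. The reverse
#' citrate synthase entry is a spectrophotometric-style surrogate
#' configuration for the trace simulator.
#'
#' @return Named list of \linkS4class{AssayConfig} objects.
#' @export
defaultAssayConfigs <- function() {
  eNADH <- 6.22; eMV <- 13.7; eTNB <- 14.15; eFum <- 1.45
  cfg <- function(enzyme, direction, wl, eps, tmin, cfe, totalProteinMg,
                  sign = 1, coupled = FALSE)
    assayConfig(enzyme, direction, wl, eps, tmin, cfe,
                proteinConc = totalProteinMg / cfe, sign = sign,
                coupled = coupled)
  list(
    citrate_synthase_ox = cfg("citrate synthase", "oxidative",
      412, eTNB, 60, 0.18, 1.0),
    aconitase_idh_ox = cfg("aconitase + isocitrate dehydrogenase",
      "oxidative", 340, eNADH, 1, 0.20, 1.0, coupled = TRUE),
    ogor_ox = cfg("2-oxoglutarate:ferredoxin oxidoreductase", "oxidative",
      600, eMV, 1, 0.20, 0.6),
    succinate_dh_ox = cfg("succinate dehydrogenase", "oxidative",
      250, eFum, 9, 0.20, 0.9),
    fumarase_mdh_ox = cfg("fumarase + malate dehydrogenase", "oxidative",
      340, eNADH, 30, 0.20, 0.6, coupled = TRUE),
    malate_dh_ox = cfg("malate dehydrogenase", "oxidative",
      340, eNADH, 5, 0.10, 0.9),
    isocitrate_dh_red = cfg("isocitrate dehydrogenase", "reductive",
      340, eNADH, 1, 0.10, 1.2, sign = -1),
    succinate_dh_red = cfg("succinate dehydrogenase", "reductive",
      600, eMV, 0.7, 0.20, 1.2, sign = -1),
    fumarase_red = cfg("fumarase", "reductive",
      250, eFum, 60, 0.20, 1.1, sign = -1),
    malate_dh_red = cfg("malate dehydrogenase", "reductive",
      340, eNADH, 5, 0.23, 0.9, sign = -1),
    co_dehydrogenase = cfg("carbon monoxide dehydrogenase", "oxidative",
      600, eMV, 0.5, 0.20, 0.6),
    formate_dehydrogenase = cfg("formate dehydrogenase", "oxidative",
      600, eMV, 0.5, 0.20, 1.5),
    citrate_synthase_rev = cfg("citrate synthase", "reductive",
      412, eTNB, 60, 0.18, 1.0, sign = -1)
  )
}

#' Dimensional audit of the activity formula
#'
#' Composes the physical dimensions of every factor of the
#' [specificActivity()] formula (exponents over mol, L, min, mg, cm and
#' absorbance) and checks that the result is nmol min^-1 mg^-1 protein.
#'
#' @param config an \linkS4class{AssayConfig}.
#' @return TRUE invisibly; errors if the dimensions do not compose.
#' @export
auditActivityUnits <- function(config) {
  validObject(config)
  dims <- function(mol = 0, L = 0, min = 0, mg = 0, cm = 0, A = 0)
    c(mol = mol, L = L, min = min, mg = mg, cm = cm, A = A)
  slope <- dims(A = 1, min = -1)               # delta A per min
  epsilon <- dims(A = 1, mol = -1, L = 1, cm = -1)  # A per mM per cm
  path <- dims(cm = 1)
  volume <- dims(L = 1)                        # mL (scale only)
  protein <- dims(mg = 1)                      # V * phi * c_prot
  out <- slope - epsilon - path + volume - protein
  target <- dims(mol = 1, min = -1, mg = -1)   # nmol min^-1 mg^-1
  if (!isTRUE(all.equal(out, target)))
    stop("activity formula dimensions do not reduce to nmol min^-1 mg^-1")
  invisible(TRUE)
}

#' Reduce replicate traces to an activity table row
#'
#' Convenience wrapper: slopes of sample and control traces within the
#' configured window, conversion to specific activity per replicate, and
#' uncertainty combining the replicate spread with the protein-measurement
#' error.
#'
#' @param traces list of sample trace data.frames (one per replicate).
#' @param config an \linkS4class{AssayConfig}.
#' @param controlTraces optional list of control traces (matched or
#'   recycled; default none).
#' @param proteinRelSd relative sd of the protein concentration.
#' @return List with \code{activity} (mean), \code{uncertainty},
#'   \code{replicates} and \code{config}.
#' @export
reduceAssay <- function(traces, config, controlTraces = NULL,
                        proteinRelSd = 0) {
  ctlSlope <- if (length(controlTraces))
    mean(vapply(controlTraces, function(tr)
      linearSlope(tr, window = config@evaluationTime)$slope, numeric(1)))
  else 0
  acts <- vapply(traces, function(tr) {
    s <- linearSlope(tr, window = config@evaluationTime)
    specificActivity(s$slope, config, controlSlope = ctlSlope,
                     slopeSe = s$se)$activity
  }, numeric(1))
  unc <- if (length(acts) >= 2L) combineUncertainty(acts, proteinRelSd)
         else NA_real_
  list(activity = mean(acts), uncertainty = unc, replicates = acts,
       config = config)
}
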