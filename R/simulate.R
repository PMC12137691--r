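# Seeded synthetic-data generator: the exact adjoint of the correction
# pipeline plus the noise structure of the tracer experiment (3 biological
# x 3 technical replicates, biological sd ~0.3 percentage points on the
# excess scale, technical reproducibility up to 2.5% on the intensity
# scale), and absorbance traces for the enzyme assays.

#' Default reagent mass-shift distributions for the simulator
#'
#' A plausible TBDMS-fragment shift distribution (two Si atoms plus reagent
#' carbons spread the natural spectrum over M+0..M+3) and a light one for
#' the FAME McLafferty fragment (one ester methyl carbon). These are free
#' parameters of the simulator; real instruments fit them per run via
#' [fitReagentVector()], and every generated dataset co-emits the vector it
#' used so recovery tests are self-consistent.
#'
#' @return Named list of numeric vectors, keyed by fragment name.
#' @export
defaultReagentVectors <- function() {
  list(
    alanine = c(0.80, 0.13, 0.06, 0.01),
    aspartate = c(0.76, 0.15, 0.08, 0.01),
    glutamate = c(0.76, 0.15, 0.08, 0.01),
    mclafferty = c(0.985, 0.012, 0.003)
  )
}

#' Noise model of the tracer experiment
#'
#' @param technicalCv relative sd of technical replicates on the intensity
#'   scale (default 0.025, the upper end of the 0.0-2.5\% reproducibility
#'   range).
#' @param biologicalSdPp absolute sd of excess between biological
#'   replicates, in percentage points (default 0.3).
#' @param seed integer seed.
#' @return List with the three fields, validated.
#' @export
noiseModel <- function(technicalCv = 0.025, biologicalSdPp = 0.3,
                       seed = 1L) {
  if (technicalCv < 0 || biologicalSdPp < 0)
    stop("noise parameters must be >= 0")
  list(technicalCv = technicalCv, biologicalSdPp = biologicalSdPp,
       seed = as.integer(seed))
}

#' Experiment design of the tracer study
#'
#' @param nBiological biological replicates per setting (default 3).
#' @param nTechnical technical (GC-MS) replicates per culture (default 3).
#' @param tracers character vector of tracer settings to simulate; the
#'   default covers both labeled settings plus the unlabeled control.
#' @param fragments fragment list (default [defaultFragments()]).
#' @return List with the four fields, validated.
#' @export
experimentDesign <- function(nBiological = 3L, nTechnical = 3L,
                             tracers = c("naphthalene_U13C",
                                         "bicarbonate_13C", "unlabeled"),
                             fragments = defaultFragments()) {
  if (nBiological < 1L || nTechnical < 1L)
    stop("replicate counts must be >= 1")
  list(nBiological = as.integer(nBiological),
       nTechnical = as.integer(nTechnical),
       tracers = tracers, fragments = fragments)
}

#' Forward model: skeleton labeling to observed MID
#'
#' The exact adjoint of the correction pipeline: the skeleton labeling
#' distribution is convolved with the natural-abundance distribution of the
#' unlabeled skeleton positions (the lower-triangular matrix of
#' [buildSkeletonMatrix()]) and then with the reagent mass-shift vector,
#' truncated to the fragment's channels and renormalized.
#'
#' @param skeletonMid numeric vector over skeleton species
#'   \eqn{M+0 \ldots M+n}: the labeling distribution on the excess scale.
#' @param fragment a \linkS4class{FragmentSpec}.
#' @param reagentVector mass-shift distribution of the non-skeleton atoms.
#' @param pNat natural 13C abundance.
#' @return A \linkS4class{MID} over the fragment's channels.
#' @export
forwardModel <- function(skeletonMid, fragment,
                         reagentVector =
                           defaultReagentVectors()[[fragment@name]],
                         pNat = 0.0111) {
  nC <- fragment@skeletonCarbons
  skeletonMid <- as.numeric(skeletonMid)
  if (length(skeletonMid) != nC + 1L)
    stop("'skeletonMid' must have ", nC + 1L, " components")
  if (is.null(reagentVector))
    stop("no reagent vector for fragment '", fragment@name, "'")
  S <- buildSkeletonMatrix(fragment, pNat, nChannels = nC + 1L)
  withNat <- as.numeric(S %*% skeletonMid)
  full <- .convMass(withNat, reagentVector / sum(reagentVector))
  K1 <- fragment@nChannels
  obs <- full[seq_len(min(K1, length(full)))]
  if (length(obs) < K1) obs <- c(obs, rep(0, K1 - length(obs)))
  lost <- 1 - sum(obs)
  if (lost > 1e-4)
    warning("channel truncation lost ", signif(lost, 3),
            " of spectral mass for fragment '", fragment@name, "'")
  newMID(fragment, obs)
}

# skeleton labeling distribution from an excess vector (M+1..M+n)
.excessToSkeleton <- function(excess) {
  excess <- pmax(excess, 0)
  if (sum(excess) > 1) excess <- excess / sum(excess)
  c(1 - sum(excess), excess)
}

#' Generate a synthetic SIM intensity dataset
#'
#' For every tracer setting, fragment, biological and technical replicate:
#' the skeleton labeling distribution is predicted from the scenario
#' ([predictMetaboliteMID()]), biological jitter (Gaussian, sd
#' \code{biologicalSdPp}, truncated at zero and applied only to components
#' with incorporated label) is added to the excess components per culture,
#' the forward model produces channel fractions, and multiplicative
#' Gaussian technical noise (cv \code{technicalCv}) plus an arbitrary
#' intensity scale produce SIM intensities. The same seed and configuration
#' always reproduce the identical table.
#'
#' @param design from [experimentDesign()].
#' @param scenario a \linkS4class{ScenarioSpec} (ignored for the unlabeled
#'   control, which is always at zero excess).
#' @param tracers named list of \linkS4class{TracerExperiment} configs for
#'   the labeled settings.
#' @param noise from [noiseModel()].
#' @param maps atom maps (default [defaultAtomMaps()]).
#' @param intensityScale arbitrary total-intensity scale (default 1e6).
#' @param dilution passed to [predictMetaboliteMID()].
#' @param plantedExcess optional named list (fragment name -> excess vector
#'   for \eqn{M+1 \ldots M+n}) that overrides the scenario prediction for
#'   every labeled tracer setting; used for round-trip recovery studies.
#' @return List with \code{data} (long data.frame: \code{tracer},
#'   \code{fragment}, \code{replicate_bio}, \code{replicate_tech},
#'   \code{channel}, \code{intensity}) and \code{manifest} (scenario, seed,
#'   noise, reagent vectors, per-replicate true excess vectors, clip
#'   count).
#' @examples
#' sim <- generateDataset(experimentDesign(),
#'                        scenarioSpec("chemoorganoautotrophic"),
#'                        noise = noiseModel(seed = 7))
#' head(sim$data)
#' @export
generateDataset <- function(design = experimentDesign(),
                            scenario = scenarioSpec("chemoorganoautotrophic"),
                            tracers = list(
                              naphthalene_U13C =
                                tracerExperiment("naphthalene_U13C"),
                              bicarbonate_13C =
                                tracerExperiment("bicarbonate_13C")),
                            noise = noiseModel(),
                            maps = defaultAtomMaps(design$fragments),
                            intensityScale = 1e6,
                            dilution = 1,
                            plantedExcess = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(noise$seed)

  reagents <- defaultReagentVectors()
  rows <- vector("list", 0L)
  truth <- vector("list", 0L)
  nClipped <- 0L
  for (tr in design$tracers) {
    for (fname in names(design$fragments)) {
      frag <- design$fragments[[fname]]
      map <- maps[[fname]]
      baseSkeleton <- if (tr == "unlabeled") {
        c(1, rep(0, frag@skeletonCarbons))
      } else if (!is.null(plantedExcess)) {
        if (is.null(plantedExcess[[fname]]))
          stop("no planted excess for fragment '", fname, "'")
        .excessToSkeleton(plantedExcess[[fname]])
      } else {
        te <- tracers[[tr]]
        if (is.null(te)) stop("no tracer config for '", tr, "'")
        predictMetaboliteMID(map, scenario, te, dilution = dilution)
      }
      baseExcess <- baseSkeleton[-1L]
      for (b in seq_len(design$nBiological)) {
        jit <- stats::rnorm(length(baseExcess), 0,
                            noise$biologicalSdPp / 100)
        # biological variation needs incorporated label: components that
        # are structurally zero under the scenario do not jitter
        jit[baseExcess <= 0] <- 0
        exB <- pmax(baseExcess + jit, 0)
        skel <- .excessToSkeleton(exB)
        truth[[paste(tr, fname, b, sep = ".")]] <- skel[-1L]
        clean <- fractions(forwardModel(skel, frag,
                                        reagentVector = reagents[[fname]]))
        for (tch in seq_len(design$nTechnical)) {
          fac <- 1 + stats::rnorm(length(clean), 0, noise$technicalCv)
          intens <- intensityScale * clean * fac
          nClipped <- nClipped + sum(intens < 0)
          intens <- pmax(intens, 0)
          rows[[length(rows) + 1L]] <- data.frame(
            tracer = tr, fragment = fname, replicate_bio = b,
            replicate_tech = tch, channel = 0:(frag@nChannels - 1L),
            intensity = intens, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (nClipped > 0L)
    warning(nClipped, " negative intensities clipped to 0")
  list(
    data = do.call(rbind, rows),
    manifest = list(
      scenario = scenario@name,
      mixtureFraction = scenario@mixtureFraction,
      exchangeCompleteness = scenario@exchangeCompleteness,
      seed = noise$seed,
      noise = noise[c("technicalCv", "biologicalSdPp")],
      design = list(nBiological = design$nBiological,
                    nTechnical = design$nTechnical,
                    tracers = design$tracers),
      reagentVectors = reagents[names(design$fragments)],
      trueExcess = truth,
      dilution = dilution,
      nClipped = nClipped
    )
  )
}

#' Simulate a spectrophotometric assay trace
#'
#' Linear absorbance ramp whose slope encodes the requested specific
#' activity under the assay configuration (Beer-Lambert, see
#' [specificActivity()]), with Gaussian absorbance noise. The inverse of
#' the trace-reduction arithmetic, for round-trip tests.
#'
#' @param activity specific activity in nmol min^-1 mg^-1 protein (>= 0).
#' @param config an \linkS4class{AssayConfig}.
#' @param times sampling times in min (default: the evaluation window at
#'   0.1 min steps).
#' @param noiseSd sd of the absorbance noise (default 0).
#' @param seed integer seed.
#' @param baseline starting absorbance.
#' @return data.frame with columns \code{time_min} and \code{absorbance}.
#' @export
generateAssayTrace <- function(activity, config,
                               times = seq(0, config@evaluationTime,
                                           by = config@evaluationTime / 60),
                               noiseSd = 0, seed = 1L, baseline = 0.1) {
  if (activity < 0) stop("'activity' must be >= 0")
  proteinMg <- config@assayVolume * config@cfeFraction * config@proteinConc
  # activity [nmol/min/mg] -> slope [A/min]; 1 mM = 1000 nmol/mL
  slope <- config@sign * activity * proteinMg *
    config@extinctionCoefficient * config@pathLength /
    (1000 * config@assayVolume)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  absb <- baseline + slope * times + stats::rnorm(length(times), 0, noiseSd)
  data.frame(time_min = times, absorbance = absb)
}
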