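# Scenario-based prediction of skeleton isotopologue distributions and
# inference of the autotrophic fraction of anabolic acetyl-CoA.

#' Construct a TracerExperiment
#'
#' @param tracer tracer identity.
#' @param tracerAtomFraction mole fraction of labeled substrate (default
#'   0.10, the 10 atom\% settings).
#' @param pools carbon pool table; defaults to [referencePools()] for the
#'   chosen tracer.
#' @param effectiveCo2Enrichment excess enrichment of the CO2 pool feeding
#'   anabolism. Defaults to the full-oxidation mass-balance bound
#'   ([poolMaxEnrichment()] of the labeled carbon over all pools): 3.9\%
#'   for the naphthalene tracer, 5.1\% for the bicarbonate tracer. The
#'   enrichment rises over time as substrate oxidation proceeds
#'   ([co2EnrichmentTimecourse()]); supply a time-averaged value here to
#'   use one.
#' @return A \linkS4class{TracerExperiment}.
#' @examples
#' tracerExperiment("bicarbonate_13C")  # effective CO2 enrichment 5.1 %
#' @export
tracerExperiment <- function(tracer = c("naphthalene_U13C",
                                        "bicarbonate_13C", "unlabeled"),
                             tracerAtomFraction = 0.10,
                             pools = referencePools(tracer, tracerAtomFraction),
                             effectiveCo2Enrichment = NULL) {
  tracer <- match.arg(tracer)
  if (is.null(effectiveCo2Enrichment)) {
    labeled <- sum(pools$carbonAmount * pools$enrichment)
    effectiveCo2Enrichment <- poolMaxEnrichment(labeled, pools)
  }
  new("TracerExperiment",
    tracer = tracer,
    tracerAtomFraction = as.numeric(tracerAtomFraction),
    pools = pools,
    effectiveCo2Enrichment = as.numeric(effectiveCo2Enrichment)
  )
}

#' Reference GC-MS fragments
#'
#' The four fragments of the reference experiment: the TBDMS
#' \eqn{[M-57]^+} fragments of alanine (m/z 260, 3 skeleton C), aspartate
#' (418, 4 C) and glutamate (432, 5 C), and the McLafferty fragment of
#' fatty acid methyl esters (m/z 74, skeleton carbons C1 + C2 of the fatty
#' acid; the ester methyl carbon belongs to the reagent).
#'
#' @return Named list of \linkS4class{FragmentSpec} objects.
#' @export
defaultFragments <- function() {
  list(
    alanine = fragmentSpec("alanine", 3, 260,
      reagentNote = "2x TBDMS minus tBu: Si2, C9, H22, N, O2"),
    aspartate = fragmentSpec("aspartate", 4, 418,
      reagentNote = "3x TBDMS minus tBu: Si3, C14, H34, N, O4"),
    glutamate = fragmentSpec("glutamate", 5, 432,
      reagentNote = "3x TBDMS minus tBu: Si3, C14, H34, N, O4"),
    mclafferty = fragmentSpec("mclafferty", 2, 74,
      reagentNote = "FAME McLafferty m/z 74: ester methyl C, H6, O2")
  )
}

#' Metabolite atom-provenance maps
#'
#' Per-carbon provenance of the observed metabolites: an intact acetyl pair
#' (\code{acetyl_C1} carboxyl, \code{acetyl_C2} methyl) plus carbons fixed
#' from the CO2 pool. Alanine (pyruvate): acetyl pair + 1 CO2; aspartate
#' (oxaloacetate): acetyl pair + 2 CO2; glutamate (2-oxoglutarate via the
#' reductive TCA reading): acetyl pair + 3 CO2/OAA-derived carbons; the
#' fatty-acid McLafferty fragment is one acetyl pair. The maps are data and
#' can be overridden.
#'
#' @param fragments fragment list, as from [defaultFragments()].
#' @return Named list; each element has \code{metabolite}, \code{carbons}
#'   (provenance tags) and \code{fragment} (a \linkS4class{FragmentSpec}).
#' @export
defaultAtomMaps <- function(fragments = defaultFragments()) {
  mk <- function(metabolite, carbons, fragment) {
    if (length(carbons) != fragment@skeletonCarbons)
      stop("atom map for '", metabolite, "' has ", length(carbons),
           " carbons; fragment has ", fragment@skeletonCarbons)
    list(metabolite = metabolite, carbons = carbons, fragment = fragment)
  }
  list(
    alanine = mk("alanine",
      c("acetyl_C1", "acetyl_C2", "co2_fixed"), fragments$alanine),
    aspartate = mk("aspartate",
      c("acetyl_C1", "acetyl_C2", "co2_fixed", "co2_fixed"),
      fragments$aspartate),
    glutamate = mk("glutamate",
      c("acetyl_C1", "acetyl_C2", "co2_fixed", "co2_fixed", "co2_fixed"),
      fragments$glutamate),
    mclafferty = mk("fatty acid", c("acetyl_C1", "acetyl_C2"),
      fragments$mclafferty)
  )
}

#' Predict the acetyl-unit isotopologue distribution under a scenario
#'
#' Excess-scale distribution over \eqn{\{M+0, M+1, M+2\}} of the two-carbon
#' acetyl unit of anabolic acetyl-CoA:
#' \itemize{
#'   \item \code{direct_assimilation}: the pair is taken intact from the
#'     substrate, so under a uniformly labeled tracer both carbons are
#'     co-labeled with probability \code{tracerAtomFraction}
#'     (\eqn{M+2} = tracer fraction);
#'   \item \code{chemoorganoautotrophic}: both carbons are fixed
#'     independently from the CO2 pool at
#'     \code{effectiveCo2Enrichment} (binomial, n = 2; at 10 atom\% the
#'     statistically coupled \eqn{M+2} is only ~1\%);
#'   \item \code{carboxyl_exchange}: the methyl carbon keeps the substrate
#'     label while the carboxyl carbon exchanges with the CO2 pool
#'     (complete exchange of an unlabeled pool leaves \eqn{M+1} = tracer
#'     fraction, \eqn{M+2} = 0);
#'   \item \code{mixture}: \eqn{f} autotrophic + \eqn{(1-f)} direct.
#' }
#'
#' @param scenario a \linkS4class{ScenarioSpec}.
#' @param tracer a \linkS4class{TracerExperiment}.
#' @param acetylCoupling for the direct component: \code{"intact"} (both
#'   carbons from one substrate molecule, the default) or
#'   \code{"independent"}.
#' @return Numeric vector \code{c(M0, M1, M2)} summing to 1 (excess scale:
#'   natural abundance is not included).
#' @examples
#' naph <- tracerExperiment("naphthalene_U13C")
#' predictAcetylMID(scenarioSpec("direct_assimilation"), naph)   # M+2 = 0.10
#' co2 <- tracerExperiment("bicarbonate_13C",
#'                         effectiveCo2Enrichment = 0.10)
#' predictAcetylMID(scenarioSpec("chemoorganoautotrophic"), co2)
#' @export
predictAcetylMID <- function(scenario, tracer,
                             acetylCoupling = c("intact", "independent")) {
  acetylCoupling <- match.arg(acetylCoupling)
  co2 <- tracer@effectiveCo2Enrichment
  if (!is.finite(co2))
    stop("effective CO2 enrichment is not resolved for this tracer")
  # substrate-derived label on the acetyl carbons: only the naphthalene
  # tracer labels them directly
  tSub <- if (tracer@tracer == "naphthalene_U13C")
    tracer@tracerAtomFraction else 0

  direct <- if (acetylCoupling == "intact")
    c(1 - tSub, 0, tSub)
  else
    binomialMID(tSub, 2)

  autotrophic <- binomialMID(co2, 2)

  pred <- switch(scenario@name,
    direct_assimilation = direct,
    chemoorganoautotrophic = autotrophic,
    carboxyl_exchange = {
      ec <- scenario@exchangeCompleteness
      exchanged <- .convMass(c(1 - tSub, tSub), c(1 - co2, co2))
      ec * exchanged + (1 - ec) * direct
    },
    mixture = {
      f <- scenario@mixtureFraction
      f * autotrophic + (1 - f) * direct
    }
  )
  names(pred) <- paste0("M+", 0:2)
  pred
}

#' Predict the skeleton isotopologue distribution of a metabolite
#'
#' Composes the scenario's acetyl-unit distribution with independent
#' CO2-derived carbons (each labeled at the tracer's effective CO2
#' enrichment) by discrete convolution over the metabolite's
#' atom-provenance tags.
#'
#' @param map one element of [defaultAtomMaps()].
#' @param scenario a \linkS4class{ScenarioSpec}.
#' @param tracer a \linkS4class{TracerExperiment}.
#' @param dilution factor in (0, 1] applied uniformly to the predicted
#'   excess components, modeling carryover of unlabeled pre-culture biomass
#'   (default 1: no dilution).
#' @param acetylCoupling passed to [predictAcetylMID()].
#' @return Numeric vector over \eqn{M+0 \ldots M+n} (n = skeleton carbons)
#'   summing to 1.
#' @examples
#' co2 <- tracerExperiment("bicarbonate_13C")  # effective enrichment 5.1 %
#' m <- defaultAtomMaps()$alanine
#' predictMetaboliteMID(m, scenarioSpec("chemoorganoautotrophic"), co2)
#' # M+1 = 0.138
#' @export
predictMetaboliteMID <- function(map, scenario, tracer, dilution = 1,
                                 acetylCoupling = c("intact",
                                                    "independent")) {
  acetylCoupling <- match.arg(acetylCoupling)
  tags <- map$carbons
  nC <- map$fragment@skeletonCarbons
  if (length(tags) != nC)
    stop("atom map has ", length(tags), " carbons; fragment '",
         map$fragment@name, "' has ", nC)
  nAcetyl <- sum(tags %in% c("acetyl_C1", "acetyl_C2"))
  if (nAcetyl %% 2L != 0L)
    stop("acetyl carbons must come in C1/C2 pairs")
  co2 <- tracer@effectiveCo2Enrichment
  mid <- 1
  for (i in seq_len(nAcetyl / 2L))
    mid <- .convMass(mid, predictAcetylMID(scenario, tracer,
                                           acetylCoupling = acetylCoupling))
  for (i in seq_len(sum(tags == "co2_fixed")))
    mid <- .convMass(mid, c(1 - co2, co2))
  if (length(mid) != nC + 1L)
    stop("atom map provenance tags do not span the fragment skeleton")
  if (dilution < 1) {
    mid[-1L] <- dilution * mid[-1L]
    mid[1L] <- 1 - sum(mid[-1L])
  }
  names(mid) <- paste0("M+", 0:nC)
  mid
}

# predicted excess components (M+1 ... M+n) for one metabolite map
.predictedExcess <- function(map, scenario, tracer, ...) {
  predictMetaboliteMID(map, scenario, tracer, ...)[-1L]
}

#' Infer the autotrophic fraction of anabolic acetyl-CoA
#'
#' Finds the mixture fraction \eqn{f} (share of anabolic acetyl-CoA built
#' de novo from CO2 rather than taken intact from the substrate) that best
#' explains the observed excess values, by least squares over all supplied
#' metabolites and tracer settings. A coarse grid bounds the optimum, which
#' is then refined by golden-section search; uncertainty comes from a
#' seeded bootstrap over biological replicates.
#'
#' @param observed list of \linkS4class{ExcessResult} objects (with
#'   \code{@tracer} set and, for the bootstrap, \code{@replicates}
#'   populated).
#' @param maps named list of atom maps ([defaultAtomMaps()]); matched to
#'   results by fragment name.
#' @param tracers named list of \linkS4class{TracerExperiment} objects,
#'   keyed by tracer label.
#' @param components which excess components enter the objective
#'   (default \eqn{M+1} and \eqn{M+2}, the measured ones).
#' @param gridStep step of the coarse f grid (default 0.01).
#' @param nBoot bootstrap resamples (default 1000; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @param dilution passed to [predictMetaboliteMID()].
#' @return List with \code{f} (point estimate), \code{ci} (2.5/97.5
#'   percentile interval, when bootstrapped), \code{objective} (residual
#'   sum of squares at the optimum), \code{identifiable} (FALSE when all
#'   observations are zero) and \code{bootstrap} (the resampled
#'   estimates).
#' @export
fitMixtureFraction <- function(observed, maps, tracers,
                               components = 1:2, gridStep = 0.01,
                               nBoot = 1000, seed = 1, dilution = 1) {
  obsFor <- function(results) {
    lapply(results, function(r) {
      key <- r@fragment@name
      map <- maps[[key]]
      if (is.null(map)) stop("no atom map for fragment '", key, "'")
      tr <- tracers[[r@tracer]]
      if (is.null(tr)) stop("no tracer config for '", r@tracer, "'")
      comp <- intersect(components, seq_along(r@excess))
      # the mixture prediction is linear in f, so its two endpoints
      # determine it everywhere
      p0 <- .predictedExcess(map,
        scenarioSpec("mixture", mixtureFraction = 0), tr,
        dilution = dilution)[comp]
      p1 <- .predictedExcess(map,
        scenarioSpec("mixture", mixtureFraction = 1), tr,
        dilution = dilution)[comp]
      list(comp = comp, y = r@excess[comp], p0 = p0, p1 = p1)
    })
  }
  sse <- function(f, items) {
    s <- 0
    for (it in items)
      s <- s + sum((it$y - (f * it$p1 + (1 - f) * it$p0))^2)
    s
  }
  fitOnce <- function(items) {
    grid <- seq(0, 1, by = gridStep)
    vals <- vapply(grid, sse, numeric(1), items = items)
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    if (lo == hi) return(lo)
    opt <- stats::optimize(sse, c(lo, hi), items = items, tol = 1e-6)
    # the endpoints can beat the interior optimum at the boundary
    cand <- c(opt$minimum, lo, hi)
    cand[which.min(vapply(cand, sse, numeric(1), items = items))]
  }

  items <- obsFor(observed)
  identifiable <- any(vapply(items, function(it) any(abs(it$y) > 1e-10),
                             logical(1)))
  if (!identifiable)
    return(list(f = NA_real_, ci = c(NA_real_, NA_real_),
                objective = NA_real_, identifiable = FALSE,
                bootstrap = numeric(0)))
  f <- fitOnce(items)

  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  canBoot <- all(vapply(observed, function(r) nrow(r@replicates) >= 2L,
                        logical(1)))
  if (nBoot > 0 && canBoot) {
    boot <- local({
      # private RNG stream so callers' seeds are not disturbed
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      vapply(seq_len(nBoot), function(b) {
        res <- lapply(observed, function(r) {
          idx <- sample.int(nrow(r@replicates), replace = TRUE)
          excessResult(r@fragment,
                       colMeans(r@replicates[idx, , drop = FALSE]),
                       tracer = r@tracer)
        })
        fitOnce(obsFor(res))
      }, numeric(1))
    })
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  list(f = f, ci = ci, objective = sse(f, items),
       identifiable = TRUE, bootstrap = boot)
}

#' Classify the metabolism from excess values under both tracers
#'
#' Applies the qualitative decision rules of the tracer experiment:
#' \enumerate{
#'   \item naphthalene tracer, acetyl-proxy fragment: \eqn{M+2 \approx}
#'     tracer fraction implies direct assimilation of the substrate-derived
#'     acetyl unit;
#'   \item naphthalene tracer: \eqn{M+1} near the complete-exchange
#'     prediction (the tracer fraction when the CO2 pool is unlabeled,
#'     shifted by the pool's own enrichment otherwise) with \eqn{M+2} near
#'     the correspondingly small exchange prediction implies carboxyl
#'     exchange (label retained only on the methyl carbon);
#'   \item \eqn{M+1 > M+2} for every fragment under both tracers, with the
#'     CO2-tracer \eqn{M+1} consistent with the binomial prediction at the
#'     pool enrichment, implies chemoorganoautotrophy (anabolic acetyl-CoA
#'     from CO2 fixation).
#' }
#' Carboxyl-exchange data also satisfy the generic \eqn{M+1 > M+2} pattern,
#' so the more specific exchange rule takes precedence; genuinely
#' contradictory evidence (e.g. both the direct and exchange signatures) or
#' no matching rule yields \code{"ambiguous"}.
#'
#' "\eqn{\approx}" means within \code{nSd} combined standard deviations or
#' \code{relTol} relative, whichever is larger; "consistent with the pool
#' enrichment" means clearly nonzero, at least \code{minPoolRatio} of the
#' binomial prediction, and not above it beyond tolerance (observed values
#' sit below the prediction when unlabeled pre-culture biomass persists).
#'
#' @param observed list of \linkS4class{ExcessResult} objects covering both
#'   tracer settings (tracer labels \code{"naphthalene_U13C"} and
#'   \code{"bicarbonate_13C"}).
#' @param tracers named list of \linkS4class{TracerExperiment} configs.
#' @param maps atom maps, matched by fragment name.
#' @param acetylFragment name of the fragment that reports the acetyl unit
#'   directly (default \code{"mclafferty"}).
#' @param nSd,relTol,minPoolRatio,zeroTol classification thresholds; see
#'   Details.
#' @return List with \code{label} (scenario name or \code{"ambiguous"}),
#'   \code{rules} (logical outcomes of the three rules) and
#'   \code{evidence} (data.frame of the inequalities examined).
#' @export
classifyMetabolism <- function(observed,
                               tracers = list(
                                 naphthalene_U13C =
                                   tracerExperiment("naphthalene_U13C"),
                                 bicarbonate_13C =
                                   tracerExperiment("bicarbonate_13C")),
                               maps = defaultAtomMaps(),
                               acetylFragment = "mclafferty",
                               nSd = 2, relTol = 0.2,
                               minPoolRatio = 0.3, zeroTol = 0.005) {
  labs <- vapply(observed, function(r) r@tracer, character(1))
  if (!all(c("naphthalene_U13C", "bicarbonate_13C") %in% labs))
    stop("both tracer settings are required for classification")

  sdOf <- function(r, k) {
    if (length(r@sd) >= k && is.finite(r@sd[k]) && r@sd[k] > 0) r@sd[k]
    else 0.003  # fallback: reference biological sd of 0.3 pp
  }
  approxEq <- function(x, target, s) {
    tol <- max(nSd * s, relTol * abs(target))
    abs(x - target) <= tol
  }
  approxZero <- function(x, s) abs(x) <= max(nSd * s, zeroTol)

  naph <- observed[labs == "naphthalene_U13C"]
  co2 <- observed[labs == "bicarbonate_13C"]
  tNaph <- tracers$naphthalene_U13C@tracerAtomFraction
  cPool <- tracers$bicarbonate_13C@effectiveCo2Enrichment

  evidence <- list()
  note <- function(rule, check, value, target, pass)
    evidence[[length(evidence) + 1L]] <<- data.frame(
      rule = rule, check = check, value = value, target = target,
      pass = pass, stringsAsFactors = FALSE)

  # rules 1 & 2 read the acetyl unit off the 2-carbon proxy fragment
  acet <- Filter(function(r) r@fragment@name == acetylFragment, naph)
  ruleDirect <- FALSE
  ruleExchange <- FALSE
  if (length(acet)) {
    a <- acet[[1L]]
    ruleDirect <- approxEq(a@excess[2L], tNaph, sdOf(a, 2L))
    note("direct", "naphthalene acetyl M+2 ~ tracer fraction",
         a@excess[2L], tNaph, ruleDirect)
    # complete-exchange M+1 signature: equals the tracer fraction when the
    # CO2 pool is unlabeled, but shifts with the pool's own enrichment
    exPred <- predictAcetylMID(scenarioSpec("carboxyl_exchange"),
                               tracers$naphthalene_U13C)
    ex1 <- approxEq(a@excess[1L], exPred[2L], sdOf(a, 1L))
    # complete exchange still couples methyl label with pool-derived
    # carboxyl label, so its M+2 is small but not exactly zero
    ex2 <- abs(a@excess[2L] - exPred[3L]) <=
      max(nSd * sdOf(a, 2L), relTol * exPred[3L], zeroTol)
    ruleExchange <- ex1 && ex2
    note("carboxyl_exchange",
         "naphthalene acetyl M+1 ~ complete-exchange prediction",
         a@excess[1L], exPred[2L], ex1)
    note("carboxyl_exchange",
         "naphthalene acetyl M+2 ~ complete-exchange prediction",
         a@excess[2L], exPred[3L], ex2)
  }

  # rule 3: M+1 dominance everywhere + CO2-tracer consistency with pool
  dominance <- all(vapply(observed, function(r)
    length(r@excess) < 2L || r@excess[1L] > r@excess[2L], logical(1)))
  note("chemoorganoautotrophic", "M+1 > M+2 for all fragments, both tracers",
       as.numeric(dominance), 1, dominance)
  consistent <- TRUE
  for (r in co2) {
    map <- maps[[r@fragment@name]]
    if (is.null(map)) next
    n <- map$fragment@skeletonCarbons
    predM1 <- binomialPk(cPool, n, 1)
    ok <- r@excess[1L] > max(nSd * sdOf(r, 1L), zeroTol) &&
      r@excess[1L] >= minPoolRatio * predM1 &&
      r@excess[1L] <= predM1 + max(nSd * sdOf(r, 1L), relTol * predM1)
    note("chemoorganoautotrophic",
         paste0("CO2-tracer M+1 of ", r@fragment@name,
                " consistent with pool enrichment"),
         r@excess[1L], predM1, ok)
    consistent <- consistent && ok
  }
  ruleAutotroph <- dominance && consistent

  rules <- c(direct_assimilation = ruleDirect,
             carboxyl_exchange = ruleExchange,
             chemoorganoautotrophic = ruleAutotroph)
  label <- if (ruleDirect && ruleExchange) "ambiguous"
    else if (ruleDirect) "direct_assimilation"
    else if (ruleExchange) "carboxyl_exchange"   # subsumes M+1 dominance
    else if (ruleAutotroph) "chemoorganoautotrophic"
    else "ambiguous"
  list(label = label, rules = rules,
       evidence = do.call(rbind, evidence))
}
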