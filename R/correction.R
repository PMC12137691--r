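# Three-step correction of measured SIM intensities into 13C excess:
#   1. fit the derivatization-reagent mass-shift distribution against an
#      unlabeled natural-abundance standard,
#   2. deconvolve the reagent contribution from the enriched sample to get
#      the absolute skeleton isotopologue distribution,
#   3. deconvolve skeleton natural abundance to get excess values.
# All fits are non-negative least squares with post-normalization: the
# unknowns are physical fractions, and unconstrained solutions go negative
# at low signal.

# discrete mass-shift convolution of two abundance vectors
.convMass <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# non-negative least squares; returns solution and relative residual
.nnls <- function(A, b) {
  fit <- pracma::lsqnonneg(A, b)
  nb <- sqrt(sum(b^2))
  list(x = fit$x, relResidual = if (nb > 0) fit$resid.norm / nb else 0)
}

#' Natural-abundance matrix of the skeleton carbons
#'
#' Builds the lower-triangular convolution matrix that maps skeleton
#' isotopologue fractions to mass channels under natural 13C abundance.
#' Column \eqn{j} (skeleton species \eqn{M+j}) is the binomial
#' mass-shift distribution of the remaining \eqn{n-j} unlabeled carbons at
#' \code{pNat}, offset by \eqn{j} channels: a carbon that already carries
#' the label cannot also shift naturally.
#'
#' @param fragment a \linkS4class{FragmentSpec}.
#' @param pNat natural 13C abundance (default 0.0111).
#' @param nChannels number of rows (mass channels); defaults to the
#'   fragment's channel count.
#' @return A \code{nChannels x (skeletonCarbons + 1)} matrix whose columns
#'   each sum to 1 up to channel truncation.
#' @examples
#' ala <- fragmentSpec("alanine", 3, 260)
#' buildSkeletonMatrix(ala)[, 1]  # 0.9889^3, 3 * 0.9889^2 * 0.0111, ...
#' @export
buildSkeletonMatrix <- function(fragment, pNat = 0.0111,
                                nChannels = fragment@nChannels) {
  if (!is.finite(pNat) || pNat < 0 || pNat >= 0.5)
    stop("'pNat' must lie in [0, 0.5)")
  nC <- fragment@skeletonCarbons
  nChannels <- as.integer(nChannels)
  M <- matrix(0, nrow = nChannels, ncol = nC + 1L)
  for (j in 0:nC) {
    rem <- nC - j
    dist <- if (rem == 0L) 1 else binomialPk(pNat, rem, 0:rem)
    rows <- j + seq_along(dist)
    keep <- rows <= nChannels
    M[rows[keep], j + 1L] <- dist[keep]
    if (sum(dist[keep]) < 1 - 1e-6)
      stop("'nChannels' too small to hold the natural-abundance ",
           "distribution of skeleton species M+", j)
  }
  dimnames(M) <- list(paste0("M+", 0:(nChannels - 1L)), paste0("S", 0:nC))
  M
}

#' Step 1: fit the derivatization-reagent mass-shift distribution
#'
#' The measured spectrum of an unlabeled natural-abundance standard is the
#' convolution of the skeleton natural-abundance distribution with the
#' (unknown) mass-shift distribution of all non-skeleton atoms. This fit
#' recovers that distribution empirically by non-negative least squares;
#' nothing about Si/H/N/O/reagent-carbon isotopes is assumed
#' theoretically.
#'
#' @param fragment a \linkS4class{FragmentSpec}.
#' @param referenceMid \linkS4class{MID} of unlabeled natural-abundance
#'   material for the same fragment.
#' @param pNat natural 13C abundance.
#' @param residualThreshold relative residual above which the model is
#'   flagged as mis-specified (default 0.05).
#' @return A \linkS4class{CorrectionModel} holding the skeleton matrix, the
#'   normalized reagent vector, the fit residual and the warning flag.
#' @export
fitReagentVector <- function(fragment, referenceMid, pNat = 0.0111,
                             residualThreshold = 0.05) {
  if (!identical(fragment@name, referenceMid@fragment@name))
    stop("reference MID is for fragment '", referenceMid@fragment@name,
         "', not '", fragment@name, "'")
  nC <- fragment@skeletonCarbons
  K1 <- fragment@nChannels
  ref <- fractions(referenceMid)
  if (length(ref) != K1)
    stop("reference MID has ", length(ref), " channels; fragment declares ",
         K1)
  skel <- buildSkeletonMatrix(fragment, pNat, nChannels = K1)
  natDist <- skel[, 1L]               # natural distribution of all carbons
  nReagent <- K1 - nC                 # max reagent shift fitting in channels
  A <- matrix(0, nrow = K1, ncol = nReagent)
  base <- binomialPk(pNat, nC, 0:nC)
  for (j in seq_len(nReagent)) {
    rows <- (j - 1L) + seq_along(base)
    keep <- rows <= K1
    A[rows[keep], j] <- base[keep]
  }
  fit <- .nnls(A, ref)
  d <- fit$x
  if (sum(d) <= 0) stop("degenerate reagent fit: all-zero solution")
  d <- d / sum(d)
  flagged <- fit$relResidual > residualThreshold
  if (flagged)
    warning("reagent fit residual ", signif(fit$relResidual, 3),
            " exceeds threshold ", residualThreshold,
            " for fragment '", fragment@name,
            "' (mis-specified fragment?)")
  new("CorrectionModel",
    fragment = fragment,
    skeletonMatrix = skel,
    reagentVector = d,
    pNat = pNat,
    residual = fit$relResidual,
    flagged = flagged
  )
}

#' Step 2: absolute skeleton isotopologue distribution of a sample
#'
#' Deconvolves the fitted reagent contribution from an enriched sample's
#' measured MID. The Toeplitz matrix of the reagent vector maps skeleton
#' species to mass channels; the non-negative least-squares solution,
#' normalized to unit sum, is the absolute skeleton distribution
#' (natural + artificial 13C together).
#'
#' @param model a \linkS4class{CorrectionModel} from [fitReagentVector()].
#' @param sampleMid \linkS4class{MID} of the enriched sample (same
#'   fragment).
#' @return Numeric vector of length \code{skeletonCarbons + 1}: absolute
#'   abundances of skeleton species \eqn{M+0 \ldots M+n}.
#' @export
fitAbsoluteEnrichment <- function(model, sampleMid) {
  frag <- model@fragment
  if (!identical(frag@name, sampleMid@fragment@name))
    stop("sample MID is for fragment '", sampleMid@fragment@name,
         "', not '", frag@name, "'")
  s <- fractions(sampleMid)
  K1 <- frag@nChannels
  if (length(s) != K1)
    stop("sample MID has ", length(s), " channels; fragment declares ", K1)
  nC <- frag@skeletonCarbons
  d <- model@reagentVector
  Tm <- matrix(0, nrow = K1, ncol = nC + 1L)
  for (j in 0:nC) {
    rows <- j + seq_along(d)
    keep <- rows <= K1
    Tm[rows[keep], j + 1L] <- d[keep]
  }
  fit <- .nnls(Tm, s)
  a <- fit$x
  if (sum(a) <= 0) stop("degenerate absolute-enrichment fit")
  a / sum(a)
}

#' Step 3: 13C excess values
#'
#' Deconvolves skeleton natural abundance from the absolute distribution
#' (matrix as in step 1, restricted to skeleton space) and reports the
#' normalized components \eqn{k \ge 1} as excess. When an unlabeled-control
#' result is supplied its excess is subtracted component-wise, removing any
#' residual bias shared with the control cultures.
#'
#' @param absoluteDistribution vector over skeleton species
#'   \eqn{M+0 \ldots M+n} from [fitAbsoluteEnrichment()].
#' @param fragment the \linkS4class{FragmentSpec}.
#' @param pNat natural 13C abundance.
#' @param control optional \linkS4class{ExcessResult} of the unlabeled
#'   control, subtracted component-wise.
#' @param tracer optional tracer label stored in the result.
#' @param negativeTolerance components below this value after control
#'   subtraction trigger a warning (default -0.02: signals control/sample
#'   mismatch).
#' @return An \linkS4class{ExcessResult} (single measurement; no sd).
#' @export
computeExcess <- function(absoluteDistribution, fragment, pNat = 0.0111,
                          control = NULL, tracer = NA_character_,
                          negativeTolerance = -0.02) {
  nC <- fragment@skeletonCarbons
  a <- as.numeric(absoluteDistribution)
  if (length(a) != nC + 1L)
    stop("'absoluteDistribution' must have ", nC + 1L, " components")
  a <- a / sum(a)
  S <- buildSkeletonMatrix(fragment, pNat, nChannels = nC + 1L)
  fit <- .nnls(S, a)
  e <- fit$x
  if (sum(e) <= 0) stop("degenerate excess fit")
  e <- e / sum(e)
  exc <- e[-1L]
  if (!is.null(control)) {
    if (!identical(control@fragment@name, fragment@name))
      stop("control is for fragment '", control@fragment@name, "'")
    exc <- exc - control@excess
    if (any(exc < negativeTolerance))
      warning("control subtraction drove excess below ",
              negativeTolerance, " for fragment '", fragment@name,
              "' (control/sample mismatch?)")
  }
  excessResult(fragment, exc, tracer = tracer)
}

#' Aggregate replicate excess results
#'
#' Mean over biological replicates of technical-replicate means, with the
#' standard deviation taken over the biological means (the convention of
#' triplicate cultures measured in technical triplicates). For pooled
#' samples (a single biological unit, as for fatty acids) the sd is
#' omitted.
#'
#' @param results list of \linkS4class{ExcessResult} objects for the same
#'   fragment (one per measurement).
#' @param bioReplicate vector (same length) assigning each measurement to a
#'   biological replicate; defaults to a single pooled unit.
#' @return An \linkS4class{ExcessResult} with per-biological-replicate
#'   excess vectors in \code{@replicates} and, for >= 2 biological
#'   replicates, per-component sd.
#' @export
aggregateReplicates <- function(results, bioReplicate = NULL) {
  if (!length(results)) stop("'results' must contain at least one result")
  frag <- results[[1L]]@fragment
  tracer <- results[[1L]]@tracer
  for (r in results)
    if (!identical(r@fragment@name, frag@name))
      stop("inconsistent fragments in 'results'")
  if (is.null(bioReplicate)) bioReplicate <- rep(1L, length(results))
  if (length(bioReplicate) != length(results))
    stop("'bioReplicate' must have one entry per result")
  ex <- do.call(rbind, lapply(results, excess))
  bioMeans <- do.call(rbind, lapply(split.data.frame(ex, bioReplicate),
                                    colMeans))
  m <- colMeans(bioMeans)
  sdv <- if (nrow(bioMeans) >= 2L) apply(bioMeans, 2L, stats::sd)
         else numeric(0)
  excessResult(frag, m, sd = sdv, replicates = bioMeans, tracer = tracer)
}

#' Correct a full SIM dataset to excess values
#'
#' Runs the three-step correction over a long-format SIM intensity table:
#' fits the reagent vector per fragment from the unlabeled-control
#' measurements, corrects every measurement of every labeled tracer
#' setting, optionally subtracts the control excess, and aggregates
#' replicates.
#'
#' @param simTable data.frame with columns \code{tracer}, \code{fragment},
#'   \code{replicate_bio}, \code{replicate_tech}, \code{channel} (0-based
#'   mass shift) and \code{intensity}, as produced by [generateDataset()]
#'   or read by [readSimCsv()].
#' @param fragments named list of \linkS4class{FragmentSpec} objects; the
#'   default covers the four reference fragments.
#' @param pNat natural 13C abundance.
#' @param controlTracer tracer label of the unlabeled control setting.
#' @param subtractControl one of \code{"excess"} (subtract the control's
#'   corrected excess, the default), \code{"intensity"} (subtract the
#'   control's deviation from its model reconstruction at the intensity
#'   level before correction) or \code{"none"}.
#' @return A list with elements \code{excess} (named list
#'   \code{tracer.fragment} of aggregated \linkS4class{ExcessResult}),
#'   \code{models} (per-fragment \linkS4class{CorrectionModel}) and
#'   \code{report} (data.frame of residuals and flags).
#' @export
correctDataset <- function(simTable, fragments = defaultFragments(),
                           pNat = 0.0111, controlTracer = "unlabeled",
                           subtractControl = c("excess", "intensity",
                                               "none")) {
  subtractControl <- match.arg(subtractControl)
  need <- c("tracer", "fragment", "replicate_bio", "replicate_tech",
            "channel", "intensity")
  miss <- setdiff(need, names(simTable))
  if (length(miss))
    stop("simTable is missing column(s): ", paste(miss, collapse = ", "))
  if (!controlTracer %in% simTable$tracer)
    stop("no '", controlTracer, "' measurements to fit the reagent vector")

  midOf <- function(sub, frag) {
    sub <- sub[order(sub$channel), , drop = FALSE]
    if (!identical(as.integer(sub$channel), 0:(frag@nChannels - 1L)))
      stop("fragment '", frag@name, "': channels must be 0..",
           frag@nChannels - 1L)
    newMID(frag, sub$intensity)
  }
  # per-measurement MIDs averaged over technical replicates
  bioMids <- function(tr, frag) {
    sub <- simTable[simTable$tracer == tr & simTable$fragment == frag@name, ,
                    drop = FALSE]
    if (!nrow(sub)) return(NULL)
    lapply(split(sub, sub$replicate_bio), function(bs) {
      mids <- lapply(split(bs, bs$replicate_tech), midOf, frag = frag)
      newMID(frag, rowMeans(do.call(cbind, lapply(mids, fractions))))
    })
  }

  tracers <- setdiff(unique(simTable$tracer), controlTracer)
  models <- list()
  out <- list()
  rows <- list()
  for (frag in fragments) {
    ctl <- bioMids(controlTracer, frag)
    if (is.null(ctl)) next
    refFrac <- rowMeans(do.call(cbind, lapply(ctl, fractions)))
    reference <- newMID(frag, refFrac)
    model <- fitReagentVector(frag, reference, pNat = pNat)
    models[[frag@name]] <- model
    # reconstruction of the reference from the fitted model; the control's
    # deviation from it is measurement idiosyncrasy shared with samples
    recon <- .convMass(binomialPk(pNat, frag@skeletonCarbons,
                                  0:frag@skeletonCarbons),
                       model@reagentVector)[seq_len(frag@nChannels)]
    controlDev <- refFrac - recon / sum(recon)
    ctlExcess <- aggregateReplicates(
      lapply(ctl, function(m)
        computeExcess(fitAbsoluteEnrichment(model, m), frag, pNat,
                      tracer = controlTracer)),
      bioReplicate = seq_along(ctl)
    )
    for (tr in tracers) {
      mids <- bioMids(tr, frag)
      if (is.null(mids)) next
      if (subtractControl == "intensity") {
        # remove the control's deviation from its model reconstruction
        # before correction (the intensity-level reading of control
        # subtraction)
        mids <- lapply(mids, function(m)
          newMID(frag, pmax(fractions(m) - controlDev, 0)))
      }
      perBio <- lapply(mids, function(m) {
        ab <- fitAbsoluteEnrichment(model, m)
        computeExcess(ab, frag, pNat,
                      control = if (subtractControl == "excess") ctlExcess,
                      tracer = tr)
      })
      agg <- aggregateReplicates(perBio, bioReplicate = seq_along(perBio))
      out[[paste(tr, frag@name, sep = ".")]] <- agg
      rows[[length(rows) + 1L]] <- data.frame(
        tracer = tr, fragment = frag@name,
        reagentResidual = model@residual, flagged = model@flagged,
        stringsAsFactors = FALSE
      )
    }
  }
  list(excess = out, models = models,
       report = do.call(rbind, rows))
}
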