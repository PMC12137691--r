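# Three-step correction: skeleton matrix, reagent fit, absolute
# enrichment, excess, replicate aggregation.

test_that("skeleton matrix columns are shifted natural-abundance binomials", {
  ala <- fragmentSpec("alanine", 3, 260)
  S <- buildSkeletonMatrix(ala, 0.0111)
  # column 0: binomial of all three carbons at natural abundance
  expect_equal(S[1:4, 1],
               c(0.967068262369, 0.032564842893, 0.000365527107,
                 1.367631e-06),
               tolerance = 1e-9, ignore_attr = TRUE)
  # every column sums to 1 (no truncation at the default channel count)
  expect_equal(unname(colSums(S)), rep(1, 4), tolerance = 1e-9)
  # lower-triangular in channel space: no mass below the label shift
  for (j in 1:3) expect_true(all(S[seq_len(j), j + 1] == 0))
  # a labeled carbon cannot also shift naturally: column n is a delta
  expect_equal(unname(S[4, 4]), 1, tolerance = 1e-12)
})

test_that("skeleton matrix handles the degenerate limits", {
  ala <- fragmentSpec("alanine", 3, 260)
  S0 <- buildSkeletonMatrix(ala, 0, nChannels = 4)
  expect_equal(S0, diag(4), ignore_attr = TRUE)
  expect_error(buildSkeletonMatrix(ala, 0.6), "pNat")
  expect_error(buildSkeletonMatrix(ala, 0.0111, nChannels = 2),
               "too small")
})

test_that("reagent fit recovers a known convolution exactly", {
  ala <- fragmentSpec("alanine", 3, 260)
  reagent <- c(0.80, 0.13, 0.06, 0.01)
  ref <- forwardModel(c(1, 0, 0, 0), ala, reagentVector = reagent)
  model <- fitReagentVector(ala, ref)
  d <- reagentVector(model)
  expect_equal(d[1:4], reagent, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(d[-(1:4)]) < 1e-8))
  expect_lt(model@residual, 1e-8)
  expect_false(model@flagged)
})

test_that("a shift-free reagent leaves the pure natural spectrum", {
  ala <- fragmentSpec("alanine", 3, 260)
  ref <- forwardModel(c(1, 0, 0, 0), ala, reagentVector = c(1, 0, 0, 0))
  model <- fitReagentVector(ala, ref)
  expect_equal(reagentVector(model)[1], 1, tolerance = 1e-8)
  expect_equal(fractions(ref)[1:4], binomialMID(0.0111, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reagent fit is unbiased under multiplicative noise", {
  set.seed(21)
  ala <- fragmentSpec("alanine", 3, 260)
  reagent <- c(0.80, 0.13, 0.06, 0.01)
  clean <- fractions(forwardModel(c(1, 0, 0, 0), ala,
                                  reagentVector = reagent))
  rec <- replicate(100, {
    noisy <- clean * (1 + rnorm(length(clean), 0, 0.01))
    reagentVector(fitReagentVector(ala, newMID(ala, pmax(noisy, 0))))[1:4]
  })
  se <- apply(rec, 1, sd) / sqrt(ncol(rec))
  expect_true(all(abs(rowMeans(rec) - reagent) <= 3 * se + 2e-4))
})

test_that("absolute enrichment recovers planted skeleton distributions", {
  glu <- fragmentSpec("glutamate", 5, 432)
  reagent <- c(0.76, 0.15, 0.08, 0.01)
  skel <- c(0.916, 0.064, 0.020, 0, 0, 0)
  ref <- forwardModel(c(1, rep(0, 5)), glu, reagentVector = reagent)
  model <- fitReagentVector(glu, ref)
  # noise-free sample: recovery to numerical precision
  smp <- forwardModel(skel, glu, reagentVector = reagent)
  # forwardModel composes natural abundance; step 2 only removes the
  # reagent, so compare against the natural-convolved skeleton
  S <- buildSkeletonMatrix(glu, 0.0111, nChannels = 6)
  expect_equal(fitAbsoluteEnrichment(model, smp),
               as.numeric(S %*% skel), tolerance = 1e-8,
               ignore_attr = TRUE)
  # 10% M+2 spike, no natural abundance: direct recovery
  model0 <- fitReagentVector(
    glu, forwardModel(c(1, rep(0, 5)), glu, reagentVector = reagent,
                      pNat = 0),
    pNat = 0)
  spike <- forwardModel(c(0.9, 0, 0.1, 0, 0, 0), glu,
                        reagentVector = reagent, pNat = 0)
  ab <- fitAbsoluteEnrichment(model0, spike)
  expect_equal(ab[3], 0.1, tolerance = 1e-6)
  expect_error(fitAbsoluteEnrichment(model,
    newMID(fragmentSpec("other", 5, 432), rep(1, 10))), "other")
})

test_that("the full three-step round trip recovers planted excess", {
  frags <- defaultFragments()
  plants <- plantedTable2()
  for (fname in names(plants)) {
    frag <- frags[[fname]]
    planted <- plants[[fname]]
    reagent <- defaultReagentVectors()[[fname]]
    skel <- c(1 - sum(planted), planted)
    ref <- forwardModel(c(1, rep(0, frag@skeletonCarbons)), frag,
                        reagentVector = reagent)
    model <- fitReagentVector(frag, ref)
    smp <- forwardModel(skel, frag, reagentVector = reagent)
    res <- computeExcess(fitAbsoluteEnrichment(model, smp), frag)
    expect_equal(excess(res), planted, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # unlabeled material has zero excess
    res0 <- computeExcess(fitAbsoluteEnrichment(model, ref), frag)
    expect_true(all(abs(excess(res0)) < 1e-6))
  }
})

test_that("mean enrichment is the weighted per-carbon excess", {
  glu <- defaultFragments()$glutamate
  r <- excessResult(glu, c(0.064, 0.020, 0, 0, 0))
  expect_equal(meanEnrichment(r), (1 * 0.064 + 2 * 0.020) / 5,
               tolerance = 1e-12)
})

test_that("correction is invariant to overall intensity scaling", {
  sim <- generateDataset(
    experimentDesign(tracers = c("naphthalene_U13C", "unlabeled")),
    noise = noiseModel(seed = 4))
  scaled <- sim$data
  scaled$intensity <- scaled$intensity * 37.5
  a <- correctDataset(sim$data)
  b <- correctDataset(scaled)
  for (k in names(a$excess))
    expect_equal(excess(a$excess[[k]]), excess(b$excess[[k]]),
                 tolerance = 1e-9)
})

test_that("replicate aggregation follows the 3x3 convention", {
  ala <- defaultFragments()$alanine
  one <- excessResult(ala, c(0.078, 0, 0), tracer = "bicarbonate_13C")
  nine <- rep(list(one), 9)
  agg <- aggregateReplicates(nine, bioReplicate = rep(1:3, each = 3))
  expect_equal(excess(agg), c(0.078, 0, 0), ignore_attr = TRUE)
  expect_equal(agg@sd, rep(0, 3), ignore_attr = TRUE)
  expect_identical(nrow(agg@replicates), 3L)
  # pooled sample: no sd, as for the fatty-acid measurements
  pooled <- aggregateReplicates(list(one, one, one))
  expect_identical(length(pooled@sd), 0L)
  other <- excessResult(defaultFragments()$mclafferty, c(0.1, 0))
  expect_error(aggregateReplicates(list(one, other)), "inconsistent")
})

test_that("biological sd is recovered through the pipeline", {
  # biological jitter only; technical noise off isolates the sd pathway
  des <- experimentDesign(tracers = c("bicarbonate_13C", "unlabeled"),
                          fragments = defaultFragments()["alanine"])
  maps <- defaultAtomMaps()["alanine"]
  sds <- vapply(1:50, function(s) {
    sim <- generateDataset(des, noise = noiseModel(technicalCv = 0,
                                                   biologicalSdPp = 0.3,
                                                   seed = s),
                           maps = maps)
    corr <- correctDataset(sim$data, fragments = des$fragments)
    corr$excess[["bicarbonate_13C.alanine"]]@sd[1]
  }, numeric(1))
  # E[sd] of 3 Gaussian draws is sigma * c4(3) = 0.003 * 0.8862
  c4 <- 0.8862269
  se <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - 0.003 * c4), 3 * se + 2e-4)
})

test_that("the McLafferty reagent vector absorbs the ester methyl carbon", {
  mcl <- defaultFragments()$mclafferty
  reagent <- defaultReagentVectors()$mclafferty
  ref <- forwardModel(c(1, 0, 0), mcl, reagentVector = reagent)
  model <- fitReagentVector(mcl, ref)
  # the fitted vector carries the reagent-carbon isotopes
  expect_equal(reagentVector(model)[1:3], reagent, tolerance = 1e-8,
               ignore_attr = TRUE)
  # planting label on the skeleton never shifts the reagent vector: the
  # reagent is fit from the unlabeled standard only, and the labeled
  # sample still deconvolves exactly
  smp <- forwardModel(c(0.868, 0.110, 0.022), mcl, reagentVector = reagent)
  res <- computeExcess(fitAbsoluteEnrichment(model, smp), mcl)
  expect_equal(excess(res), c(0.110, 0.022), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("control subtraction flags large negative excess", {
  ala <- defaultFragments()$alanine
  ctl <- excessResult(ala, c(0.05, 0, 0))
  expect_warning(
    computeExcess(c(1, 0, 0, 0), ala, pNat = 0, control = ctl),
    "mismatch")
})
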