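# Synthetic-data generator: determinism, noise calibration, forward model.

test_that("identical seed and config give byte-identical tables", {
  a <- generateDataset(noise = noiseModel(seed = 42))
  b <- generateDataset(noise = noiseModel(seed = 42))
  expect_identical(a$data, b$data)
  expect_identical(a$manifest$trueExcess, b$manifest$trueExcess)
  c <- generateDataset(noise = noiseModel(seed = 43))
  expect_false(identical(a$data, c$data))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateDataset(noise = noiseModel(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("zero noise collapses every replicate onto the forward model", {
  des <- experimentDesign(tracers = c("bicarbonate_13C", "unlabeled"))
  sim <- generateDataset(des, noise = noiseModel(technicalCv = 0,
                                                 biologicalSdPp = 0,
                                                 seed = 1))
  d <- sim$data
  maps <- defaultAtomMaps()
  co2 <- tracerExperiment("bicarbonate_13C")
  for (fname in names(des$fragments)) {
    frag <- des$fragments[[fname]]
    sub <- d[d$tracer == "bicarbonate_13C" & d$fragment == fname, ]
    mats <- split(sub$intensity, paste(sub$replicate_bio,
                                       sub$replicate_tech))
    for (m in mats[-1]) expect_equal(m, mats[[1]], tolerance = 1e-12)
    skel <- predictMetaboliteMID(maps[[fname]],
                                 scenarioSpec("chemoorganoautotrophic"),
                                 co2)
    expected <- fractions(forwardModel(skel, frag))
    expect_equal(mats[[1]] / sum(mats[[1]]), expected, tolerance = 1e-12)
  }
})

test_that("empirical technical cv matches the configured value", {
  des <- experimentDesign(nBiological = 1L, nTechnical = 200L,
                          tracers = "bicarbonate_13C",
                          fragments = defaultFragments()["alanine"])
  sim <- generateDataset(des, noise = noiseModel(technicalCv = 0.025,
                                                 biologicalSdPp = 0,
                                                 seed = 8),
                         maps = defaultAtomMaps()["alanine"])
  d <- sim$data
  cvs <- vapply(split(d$intensity, d$channel), function(x)
    sd(x) / mean(x), numeric(1))
  # pool the per-channel estimates; keep channels with real signal
  keep <- vapply(split(d$intensity, d$channel), mean, numeric(1)) > 1
  expect_lt(abs(mean(cvs[keep]) - 0.025), 0.1 * 0.025)
})

test_that("planted excess vectors pass through the generator unchanged", {
  des <- experimentDesign(tracers = c("naphthalene_U13C", "unlabeled"))
  planted <- plantedTable2()
  sim <- generateDataset(des, plantedExcess = planted,
                         noise = noiseModel(technicalCv = 0,
                                            biologicalSdPp = 0, seed = 1))
  corr <- correctDataset(sim$data)
  for (fname in names(planted)) {
    r <- corr$excess[[paste0("naphthalene_U13C.", fname)]]
    expect_equal(excess(r), planted[[fname]], tolerance = 1e-6,
                 ignore_attr = TRUE,
                 label = paste("recovery for", fname))
  }
})

test_that("an unlabeled culture measured as sample shows no spurious excess", {
  # plant zero excess under a labeled tracer name: the pipeline sees an
  # enriched sample that is in truth natural-abundance material
  des <- experimentDesign(tracers = c("naphthalene_U13C", "unlabeled"))
  zeros <- lapply(defaultFragments(), function(f)
    rep(0, f@skeletonCarbons))
  vals <- unlist(lapply(1:10, function(s) {
    sim <- generateDataset(des, plantedExcess = zeros,
                           noise = noiseModel(seed = s))
    corr <- correctDataset(sim$data)
    unlist(lapply(corr$excess, function(r) abs(excess(r))))
  }))
  # each corrected component stays below the biological sd scale
  expect_gte(mean(vals < 0.003), 0.95)
})

test_that("scaling intensities leaves corrected values unchanged", {
  des <- experimentDesign(tracers = c("bicarbonate_13C", "unlabeled"),
                          fragments = defaultFragments()["alanine"])
  sim <- generateDataset(des, noise = noiseModel(seed = 12),
                         maps = defaultAtomMaps()["alanine"],
                         intensityScale = 1)
  sim2 <- sim
  sim2$data$intensity <- sim2$data$intensity * 1e6
  a <- correctDataset(sim$data, fragments = des$fragments)
  b <- correctDataset(sim2$data, fragments = des$fragments)
  expect_equal(excess(a$excess[[1]]), excess(b$excess[[1]]),
               tolerance = 1e-9)
})

test_that("forward model is the identity in the degenerate limit", {
  ala <- fragmentSpec("alanine", 3, 260)
  obs <- forwardModel(c(1, 0, 0, 0), ala, reagentVector = c(1, 0),
                      pNat = 0)
  expect_equal(fractions(obs), c(1, rep(0, 7)), tolerance = 1e-12)
})

test_that("forward model warns when channel truncation loses mass", {
  tight <- fragmentSpec("tight", 3, 260, nChannels = 4)
  expect_warning(
    forwardModel(c(1, 0, 0, 0), tight,
                 reagentVector = c(0.5, 0.2, 0.2, 0.1)),
    "truncation")
})

test_that("the autotrophic simulation reproduces M+1 dominance", {
  sim <- generateDataset(noise = noiseModel(seed = 2))
  corr <- correctDataset(sim$data)
  for (k in names(corr$excess)) {
    r <- corr$excess[[k]]
    expect_gt(excess(r)[1], excess(r)[2])
  }
})

test_that("assay traces encode the requested activity", {
  cfg <- defaultAssayConfigs()$co_dehydrogenase
  flat <- generateAssayTrace(0, cfg, noiseSd = 0)
  expect_equal(diff(range(flat$absorbance)), 0, tolerance = 1e-12)
  tr <- generateAssayTrace(2.0, cfg, noiseSd = 0)
  s <- linearSlope(tr, window = cfg@evaluationTime)
  act <- specificActivity(s$slope, cfg)
  expect_equal(act$activity, 2.0, tolerance = 1e-9)
  # determinism under a seed
  n1 <- generateAssayTrace(1, cfg, noiseSd = 0.01, seed = 5)
  n2 <- generateAssayTrace(1, cfg, noiseSd = 0.01, seed = 5)
  expect_identical(n1, n2)
})

test_that("low activities are recovered from noisy 60-min windows", {
  # reverse citrate synthase regime: tiny slope over a long window
  cfg <- defaultAssayConfigs()$citrate_synthase_rev
  recov <- vapply(1:50, function(s) {
    tr <- generateAssayTrace(0.05, cfg, noiseSd = 0.002, seed = s)
    sl <- linearSlope(tr, window = cfg@evaluationTime)
    specificActivity(sl$slope, cfg)$activity
  }, numeric(1))
  expect_lt(abs(mean(recov) - 0.05), 0.2 * 0.05)
})
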