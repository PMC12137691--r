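# Scenario predictions, mixture-fraction inference, classification.

test_that("acetyl-unit predictions reproduce the expected signatures", {
  naph <- tracerExperiment("naphthalene_U13C")
  # direct assimilation: the intact pair carries the tracer fraction as M+2
  expect_equal(predictAcetylMID(scenarioSpec("direct_assimilation"), naph),
               c(0.9, 0, 0.1), tolerance = 1e-12, ignore_attr = TRUE)
  # de novo from a 10 atom% CO2 pool: statistical coupling gives ~1% M+2
  co2at10 <- tracerExperiment("bicarbonate_13C",
                              effectiveCo2Enrichment = 0.10)
  expect_equal(predictAcetylMID(scenarioSpec("chemoorganoautotrophic"),
                                co2at10),
               c(0.81, 0.18, 0.01), tolerance = 1e-12, ignore_attr = TRUE)
  # complete carboxyl exchange against an unlabeled CO2 pool: M+1 only
  naph0 <- tracerExperiment("naphthalene_U13C",
                            effectiveCo2Enrichment = 0)
  expect_equal(predictAcetylMID(scenarioSpec("carboxyl_exchange"), naph0),
               c(0.9, 0.1, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # no enrichment anywhere: everything at M+0
  un <- tracerExperiment("unlabeled")
  for (sc in c("direct_assimilation", "chemoorganoautotrophic",
               "carboxyl_exchange"))
    expect_equal(predictAcetylMID(scenarioSpec(sc), un),
                 c(1, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("metabolite predictions reproduce the binomial worked examples", {
  maps <- defaultAtomMaps()
  auto <- scenarioSpec("chemoorganoautotrophic")
  # alanine under the bicarbonate tracer: all three carbons at 5.1%
  co2 <- tracerExperiment("bicarbonate_13C",
                          effectiveCo2Enrichment = 0.051)
  expect_equal(round(100 * predictMetaboliteMID(maps$alanine, auto,
                                                co2)[["M+1"]], 1), 13.8)
  # at the naphthalene-tracer bound of 3.9%
  at39 <- tracerExperiment("naphthalene_U13C",
                           effectiveCo2Enrichment = 0.039)
  expect_equal(round(100 * predictMetaboliteMID(maps$alanine, auto,
                                                at39)[["M+1"]], 1), 10.8)
  # fatty-acid fragment under direct assimilation: the pair propagates
  naph <- tracerExperiment("naphthalene_U13C")
  fa <- predictMetaboliteMID(maps$mclafferty,
                             scenarioSpec("direct_assimilation"), naph)
  expect_equal(fa[["M+2"]], 0.10, tolerance = 1e-12)
  expect_equal(fa[["M+1"]], 0, tolerance = 1e-12)
  # zero enrichment: delta at M+0
  un <- tracerExperiment("unlabeled")
  for (m in maps) {
    v <- predictMetaboliteMID(m, auto, un)
    expect_equal(v[[1]], 1, tolerance = 1e-12)
  }
})

test_that("predicted MIDs are proper distributions across a property grid", {
  maps <- defaultAtomMaps()
  scs <- list(scenarioSpec("direct_assimilation"),
              scenarioSpec("chemoorganoautotrophic"),
              scenarioSpec("carboxyl_exchange", exchangeCompleteness = 0.5),
              scenarioSpec("mixture", mixtureFraction = 0.3))
  for (tf in c(0, 0.1, 0.5, 1)) {
    for (ce in c(0, 0.051, 0.3)) {
      te <- tracerExperiment("naphthalene_U13C", tracerAtomFraction = tf,
                             effectiveCo2Enrichment = ce)
      for (sc in scs) {
        for (m in maps) {
          v <- predictMetaboliteMID(m, sc, te)
          expect_equal(sum(v), 1, tolerance = 1e-12)
          expect_true(all(v >= -1e-15))
        }
      }
    }
  }
})

test_that("mixture predictions are linear in the mixture fraction", {
  maps <- defaultAtomMaps()
  naph <- tracerExperiment("naphthalene_U13C")
  p0 <- predictMetaboliteMID(maps$glutamate,
                             scenarioSpec("mixture", 0), naph)
  p1 <- predictMetaboliteMID(maps$glutamate,
                             scenarioSpec("mixture", 1), naph)
  for (f in seq(0, 1, by = 0.125)) {
    pf <- predictMetaboliteMID(maps$glutamate,
                               scenarioSpec("mixture", f), naph)
    expect_equal(pf, f * p1 + (1 - f) * p0, tolerance = 1e-12)
  }
})

test_that("predictions agree with atom-level Monte-Carlo simulation", {
  set.seed(31)
  N <- 2e5
  naph <- tracerExperiment("naphthalene_U13C")
  co2 <- naph@effectiveCo2Enrichment
  t <- naph@tracerAtomFraction
  map <- defaultAtomMaps()$alanine
  simulate <- function(drawPair) {
    pair <- drawPair()
    fixed <- rbinom(N, 1, co2)
    shifts <- pair + fixed
    tabulate(shifts + 1L, nbins = 4L) / N
  }
  cases <- list(
    direct_assimilation = function() 2L * rbinom(N, 1, t),
    chemoorganoautotrophic = function() rbinom(N, 1, co2) + rbinom(N, 1, co2),
    carboxyl_exchange = function() rbinom(N, 1, t) + rbinom(N, 1, co2),
    mixture = function() {
      deNovo <- rbinom(N, 1, 0.6) == 1L
      ifelse(deNovo, rbinom(N, 1, co2) + rbinom(N, 1, co2),
             2L * rbinom(N, 1, t))
    }
  )
  scs <- list(
    direct_assimilation = scenarioSpec("direct_assimilation"),
    chemoorganoautotrophic = scenarioSpec("chemoorganoautotrophic"),
    carboxyl_exchange = scenarioSpec("carboxyl_exchange"),
    mixture = scenarioSpec("mixture", mixtureFraction = 0.6)
  )
  for (nm in names(cases)) {
    emp <- simulate(cases[[nm]])
    theo <- predictMetaboliteMID(map, scs[[nm]], naph)
    sigma <- sqrt(theo * (1 - theo) / N)
    expect_true(all(abs(emp - theo) <= 3 * sigma + 1e-12),
                label = paste("MC agreement for", nm))
  }
})

test_that("mixture fraction is recovered without bias at zero noise", {
  maps <- defaultAtomMaps()
  tracers <- bothTracers()
  for (f0 in c(0, 0.25, 0.5, 0.75, 1)) {
    obs <- predictedObservations(scenarioSpec("mixture", f0), tracers)
    fit <- fitMixtureFraction(obs, maps, tracers, nBoot = 0)
    expect_true(fit$identifiable)
    tol <- if (f0 %in% c(0, 1)) 1e-3 else 0.02
    expect_lt(abs(fit$f - f0), tol + 1e-9)
  }
})

test_that("grid plus golden-section matches an exhaustive fine grid", {
  maps <- defaultAtomMaps()
  tracers <- bothTracers()
  # perturb the pure-autotroph observations so the optimum is interior
  obs <- predictedObservations(scenarioSpec("mixture", 0.8), tracers)
  obs <- lapply(obs, function(r) {
    ex <- excess(r)
    ex[1] <- ex[1] + 0.004
    excessResult(r@fragment, ex, tracer = r@tracer)
  })
  fit <- fitMixtureFraction(obs, maps, tracers, nBoot = 0)
  sseAt <- function(f) {
    sc <- scenarioSpec("mixture", f)
    sum(vapply(obs, function(r) {
      pred <- predictMetaboliteMID(maps[[r@fragment@name]], sc,
                                   tracers[[r@tracer]])[-1][1:2]
      sum((excess(r)[1:2] - pred)^2)
    }, numeric(1)))
  }
  grid <- seq(0, 1, by = 1e-4)
  brute <- grid[which.min(vapply(grid, sseAt, numeric(1)))]
  expect_lt(abs(fit$f - brute), 1e-4 + 1e-9)
})

test_that("degenerate all-zero observations are flagged unidentifiable", {
  maps <- defaultAtomMaps()
  tracers <- bothTracers()
  obs <- lapply(defaultFragments(), function(fr)
    excessResult(fr, rep(0, fr@skeletonCarbons),
                 tracer = "naphthalene_U13C"))
  fit <- fitMixtureFraction(unname(obs), maps, tracers, nBoot = 0)
  expect_false(fit$identifiable)
  expect_true(is.na(fit$f))
})

test_that("the bootstrap yields a seeded, reproducible interval", {
  maps <- defaultAtomMaps()
  tracers <- bothTracers()
  set.seed(55)
  obs <- lapply(predictedObservations(scenarioSpec("mixture", 0.8),
                                      tracers, replicate = TRUE),
                function(r) {
    reps <- r@replicates + matrix(rnorm(length(r@replicates), 0, 0.002),
                                  nrow = nrow(r@replicates))
    excessResult(r@fragment, colMeans(reps), replicates = reps,
                 tracer = r@tracer)
  })
  f1 <- fitMixtureFraction(obs, maps, tracers, nBoot = 50, seed = 9)
  f2 <- fitMixtureFraction(obs, maps, tracers, nBoot = 50, seed = 9)
  expect_identical(f1$bootstrap, f2$bootstrap)
  expect_length(f1$ci, 2L)
  expect_true(f1$ci[1] <= f1$f && f1$f <= f1$ci[2])
})

test_that("classification recognizes the reference excess table", {
  cls <- classifyMetabolism(table2ExcessResults())
  expect_identical(cls$label, "chemoorganoautotrophic")
  expect_true(cls$rules[["chemoorganoautotrophic"]])
  expect_false(cls$rules[["direct_assimilation"]])
})

test_that("classification separates simulated pure scenarios", {
  sims <- list(direct_assimilation = scenarioSpec("direct_assimilation"),
               carboxyl_exchange = scenarioSpec("carboxyl_exchange"))
  for (nm in names(sims)) {
    obs <- predictedObservations(sims[[nm]])
    expect_identical(classifyMetabolism(obs)$label, nm,
                     label = paste("label for", nm))
  }
  # all-zero excess: no rule can fire
  zero <- unlist(lapply(c("naphthalene_U13C", "bicarbonate_13C"),
    function(tr) lapply(defaultFragments(), function(fr)
      excessResult(fr, rep(0, fr@skeletonCarbons), tracer = tr))),
    recursive = FALSE)
  expect_identical(classifyMetabolism(unname(zero))$label, "ambiguous")
  expect_error(classifyMetabolism(zero[1:4]), "both tracer")
})
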