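# Shared fixtures: planted excess vectors shaped like the published
# excess table, and small convenience wrappers.

plantedTable2 <- function() {
  list(
    alanine = c(0.078, 0, 0),
    aspartate = c(0.113, 0.005, 0, 0),
    glutamate = c(0.064, 0.020, 0, 0, 0),
    mclafferty = c(0.110, 0.022)
  )
}

bothTracers <- function() {
  list(
    naphthalene_U13C = tracerExperiment("naphthalene_U13C"),
    bicarbonate_13C = tracerExperiment("bicarbonate_13C")
  )
}

# build ExcessResult observations directly from scenario predictions
# (bypasses the correction pipeline; for fitting/classification tests)
predictedObservations <- function(scenario, tracers = bothTracers(),
                                  maps = defaultAtomMaps(),
                                  replicate = FALSE) {
  out <- list()
  for (tr in names(tracers)) {
    for (m in names(maps)) {
      ex <- predictMetaboliteMID(maps[[m]], scenario, tracers[[tr]])[-1]
      reps <- if (replicate)
        matrix(rep(ex, 3), nrow = 3, byrow = TRUE) else NULL
      out[[paste(tr, m, sep = ".")]] <-
        excessResult(maps[[m]]$fragment, ex, replicates = reps, tracer = tr)
    }
  }
  unname(out)
}
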