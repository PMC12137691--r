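# File I/O, configuration, bundled fixtures, and the demo pipeline.

#' Read a SIM intensity table
#'
#' CSV dialect: comma separator, dot decimal, mandatory header with columns
#' \code{tracer}, \code{fragment}, \code{replicate_bio},
#' \code{replicate_tech}, \code{channel} (0-based mass shift) and
#' \code{intensity}.
#'
#' @param path CSV file path.
#' @return data.frame in the pipeline's long format.
#' @export
readSimCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tracer", "fragment", "replicate_bio", "replicate_tech",
            "channel", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SIM CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$intensity)))
    stop("SIM CSV contains non-finite intensities")
  if (any(df$intensity < 0))
    stop("SIM CSV contains negative intensities")
  df
}

#' Write a SIM intensity table
#'
#' Numbers are serialized at full precision; the write/read round trip is
#' lossless.
#'
#' @param data data.frame in the long SIM format.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeSimCsv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an excess report
#'
#' Emits a CSV mirroring the excess-table layout (fragment, tracer, M+1 %,
#' M+2 %, sd in percentage points; display values rounded to one decimal)
#' plus a JSON sidecar with full-precision values, correction residuals and
#' flags.
#'
#' @param corrected result of [correctDataset()].
#' @param csvPath output CSV path.
#' @param jsonPath optional JSON report path (default: csvPath with
#'   \code{.json}).
#' @return The CSV path, invisibly.
#' @export
writeExcessReport <- function(corrected, csvPath,
                              jsonPath = sub("\\.csv$", ".json", csvPath)) {
  rows <- lapply(names(corrected$excess), function(key) {
    r <- corrected$excess[[key]]
    data.frame(
      tracer = r@tracer,
      fragment = r@fragment@name,
      M1_percent = round(100 * r@excess[1L], 1),
      M2_percent = if (length(r@excess) >= 2L)
        round(100 * r@excess[2L], 1) else NA_real_,
      sd_M1_pp = if (length(r@sd)) round(100 * r@sd[1L], 1) else NA_real_,
      sd_M2_pp = if (length(r@sd) >= 2L) round(100 * r@sd[2L], 1)
                 else NA_real_,
      mean_enrichment_percent = round(100 * r@meanEnrichment, 1),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), csvPath, row.names = FALSE,
                   quote = FALSE)
  full <- lapply(corrected$excess, function(r) list(
    tracer = r@tracer, fragment = r@fragment@name,
    excess = as.numeric(r@excess), sd = as.numeric(r@sd),
    meanEnrichment = r@meanEnrichment))
  jsonlite::write_json(
    list(excess = full,
         report = corrected$report),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read an experiment configuration
#'
#' YAML or JSON (decided by file extension) with equivalent schemas.
#' Recognized top-level keys: \code{tracer}, \code{tracerAtomFraction},
#' \code{pools} (list of name/carbonAmount/enrichment records),
#' \code{effectiveCo2Enrichment}, \code{pNat}, \code{seed}, \code{noise}
#' (technicalCv/biologicalSdPp). Unknown keys are rejected.
#'
#' @param path file path (.yaml/.yml or .json).
#' @return Named list of configuration values.
#' @export
readExperimentConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
  known <- c("tracer", "tracerAtomFraction", "pools",
             "effectiveCo2Enrichment", "pNat", "seed", "noise")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$noise)) {
    badNoise <- setdiff(names(cfg$noise),
                        c("technicalCv", "biologicalSdPp", "seed"))
    if (length(badNoise))
      stop("unknown noise key(s): ", paste(badNoise, collapse = ", "))
  }
  cfg
}

#' Bundled excess-table fixture
#'
#' Published M+1/M+2 excess values (percent, with biological sd in
#' percentage points) of alanine, aspartate, glutamate and two fatty acids
#' under both tracer settings. Values below the detection bound are stored
#' at the bound with \code{censored = TRUE}. Fatty acids were measured on
#' pooled cultures, so their sd is absent.
#'
#' @return data.frame with columns \code{compound}, \code{fragment},
#'   \code{fragment_mass}, \code{tracer}, \code{M1_percent},
#'   \code{M2_percent}, \code{sd_M1_pp}, \code{sd_M2_pp},
#'   \code{censored}.
#' @export
table2Excess <- function() {
  path <- system.file("extdata", "table2_excess.csv",
                      package = "tracerMID", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(df$M1_percent >= 0), all(df$M2_percent >= 0),
            all(df$M1_percent <= 100), all(df$M2_percent <= 100))
  df
}

#' Bundled enzyme-activity fixture
#'
#' Published specific activities (nmol min^-1 mg^-1 protein) of TCA-cycle
#' and Wood-Ljungdahl enzymes in cell-free extracts, used to parameterize
#' the assay-trace simulator. These are fixtures, not reproducible targets:
#' the underlying raw traces are not deposited.
#'
#' @return data.frame with columns \code{assay}, \code{enzyme},
#'   \code{direction}, \code{activity}, \code{uncertainty},
#'   \code{coupled}.
#' @export
table1Activities <- function() {
  path <- system.file("extdata", "table1_activities.csv",
                      package = "tracerMID", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(df$activity >= 0), all(df$uncertainty >= 0))
  df
}

#' Excess results from the bundled excess table
#'
#' Converts the [table2Excess()] fixture into \linkS4class{ExcessResult}
#' objects (components beyond M+2 set to zero, as they were not reported)
#' for use with [classifyMetabolism()] and [fitMixtureFraction()]. The two
#' fatty acids are mapped onto the shared McLafferty fragment; the C16:1
#' entry is used.
#'
#' @param fragments fragment list.
#' @return List of \linkS4class{ExcessResult} objects.
#' @export
table2ExcessResults <- function(fragments = defaultFragments()) {
  df <- table2Excess()
  keep <- df$fragment %in% names(fragments) &
    !duplicated(paste(df$fragment, df$tracer))
  df <- df[keep, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    frag <- fragments[[df$fragment[i]]]
    n <- frag@skeletonCarbons
    ex <- c(df$M1_percent[i], df$M2_percent[i], rep(0, max(0, n - 2L))) / 100
    sdv <- if (is.na(df$sd_M1_pp[i])) numeric(0)
      else c(df$sd_M1_pp[i], df$sd_M2_pp[i], rep(0, max(0, n - 2L))) / 100
    excessResult(frag, ex[seq_len(n)],
                 sd = if (length(sdv)) sdv[seq_len(n)] else numeric(0),
                 tracer = df$tracer[i])
  })
}

#' Run the full in-silico tracer study
#'
#' Simulates both tracer settings plus the unlabeled control under the
#' chemoorganoautotrophic scenario at the reference pool sizes, corrects
#' the SIM intensities to excess values, classifies the metabolism, fits
#' the mixture fraction, and (optionally) writes an excess-table report, a
#' predicted-vs-observed summary and a machine-readable run manifest.
#'
#' @param outDir output directory; \code{NULL} (default) writes nothing.
#' @param seed integer seed controlling every random draw.
#' @param scenario generating \linkS4class{ScenarioSpec}.
#' @param noise noise model (default: reference noise at the given seed).
#' @param nBoot bootstrap resamples for the mixture fit.
#' @return List with \code{simulated}, \code{corrected},
#'   \code{classification}, \code{mixtureFit} and \code{summary}
#'   (predicted-vs-observed data.frame).
#' @examples
#' \donttest{
#' demo <- runDemo(seed = 7)
#' demo$classification$label
#' }
#' @export
runDemo <- function(outDir = NULL, seed = 7L,
                    scenario = scenarioSpec("chemoorganoautotrophic"),
                    noise = noiseModel(seed = seed), nBoot = 200) {
  tracers <- list(
    naphthalene_U13C = tracerExperiment("naphthalene_U13C"),
    bicarbonate_13C = tracerExperiment("bicarbonate_13C")
  )
  design <- experimentDesign()
  sim <- generateDataset(design, scenario, tracers, noise)
  corrected <- correctDataset(sim$data)
  observed <- unname(corrected$excess)
  classification <- classifyMetabolism(observed, tracers)
  maps <- defaultAtomMaps(design$fragments)
  fit <- fitMixtureFraction(observed, maps, tracers, nBoot = nBoot,
                            seed = seed)
  summaryRows <- lapply(observed, function(r) {
    map <- maps[[r@fragment@name]]
    pred <- .predictedExcess(map, scenario, tracers[[r@tracer]])
    data.frame(
      tracer = r@tracer, fragment = r@fragment@name,
      predicted_M1 = 100 * pred[1L],
      observed_M1 = 100 * r@excess[1L],
      predicted_M2 = if (length(pred) >= 2L) 100 * pred[2L] else NA_real_,
      observed_M2 = if (length(r@excess) >= 2L) 100 * r@excess[2L]
                    else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  summaryDf <- do.call(rbind, summaryRows)
  rownames(summaryDf) <- NULL
  out <- list(simulated = sim, corrected = corrected,
              classification = classification, mixtureFit = fit,
              summary = summaryDf)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSimCsv(sim$data, file.path(outDir, "sim_intensities.csv"))
    writeExcessReport(corrected, file.path(outDir, "excess_report.csv"))
    utils::write.csv(summaryDf,
                     file.path(outDir, "expected_vs_observed.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- list(
      seed = seed,
      scenario = scenario@name,
      noise = noise[c("technicalCv", "biologicalSdPp")],
      classification = classification$label,
      mixtureFraction = fit$f,
      configHash = sum(utf8ToInt(paste(scenario@name, seed,
                                       noise$technicalCv,
                                       noise$biologicalSdPp)))
    )
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
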