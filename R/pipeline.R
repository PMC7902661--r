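# 32-bit FNV-1a over a string; provenance fingerprinting only.
# The multiply is split 16/16 bits so it stays exact in double arithmetic.
fnv1a <- function(s) {
  h <- 0x811c9dc5
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic run — seeds, population
#' sizes, the query design, panel reference bands, smoothing — and computes a
#' config hash that is stamped into every stage output so artifacts are
#' traceable to the exact configuration.
#'
#' @param outDir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param nCellsReference,nCellsQuery cells per reference / query population.
#' @param queryProfile name of the built-in profile the query population is
#'   drawn from (default `"Y102-like"`).
#' @param referenceBands panel reference bands.
#' @param smoothing spline smoothing parameter for the multivariate path.
#' @param interCellCV,intraCellCV,noiseSD generator variation settings.
#' @return list of class `pipelineConfig` (with `hash`).
#' @export
pipelineConfig <- function(outDir, seed = 1L, nCellsReference = 40L,
                           nCellsQuery = 20L, queryProfile = "Y102-like",
                           referenceBands = c(932, 971, 1060, 1085, 1445, 1473),
                           smoothing = 0.65, interCellCV = 0.10,
                           intraCellCV = 0.05, noiseSD = 0.5) {
  stopifnot(is.character(outDir), length(outDir) == 1L,
            seed == as.integer(seed), nCellsReference >= 1,
            nCellsQuery >= 1, smoothing >= 0, smoothing <= 1,
            interCellCV >= 0, intraCellCV >= 0, noiseSD >= 0)
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              nCellsReference = as.integer(nCellsReference),
              nCellsQuery = as.integer(nCellsQuery),
              queryProfile = queryProfile,
              referenceBands = referenceBands, smoothing = smoothing,
              interCellCV = interCellCV, intraCellCV = intraCellCV,
              noiseSD = noiseSD)
  # hash the scientific configuration; the output location is incidental
  keep <- setdiff(sort(names(cfg)), "outDir")
  cfg$hash <- fnv1a(jsonlite::toJSON(cfg[keep], digits = NA))
  class(cfg) <- "pipelineConfig"
  cfg
}

stageSidecar <- function(cfg, stage, extra = list()) {
  c(list(stage = stage, configHash = cfg$hash, seed = cfg$seed), extra)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order, each writing its artifacts under
#' `config$outDir/<stage>/` together with a JSON provenance sidecar naming
#' the config hash. Later stages read the in-memory state produced by
#' earlier ones; `classify` run without `panels` in the same call loads
#' `panels/panels.json` from a previous run and errors with an actionable
#' message when it is absent. A failed stage removes its partial output
#' directory before rethrowing.
#'
#' Stages: `simulate` (reference + query populations), `preprocess`
#' (baselining and converged averages), `fit` (band intensities), `panels`
#' (reference biomarker panels), `classify` (query vs panels).
#'
#' @param config a [pipelineConfig()].
#' @param stages character subset of the stages above, in pipeline order.
#' @return invisible list with the final in-memory state (populations,
#'   averages, fits, panels, classification).
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "preprocess", "fit",
                                   "panels", "classify")) {
  stopifnot(inherits(config, "pipelineConfig"))
  allStages <- c("simulate", "preprocess", "fit", "panels", "classify")
  stopifnot(all(stages %in% allStages))
  stages <- allStages[allStages %in% stages]
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  state <- list()

  runStage <- function(stage, body) {
    sdir <- file.path(config$outDir, stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    tryCatch(body(sdir), error = function(e) {
      unlink(sdir, recursive = TRUE)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  profiles <- referenceProfiles(interCellCV = config$interCellCV,
                                intraCellCV = config$intraCellCV)
  acq <- acquisitionModel(noiseSD = config$noiseSD)
  seeds <- withLocalSeed(config$seed,
                         sample.int(.Machine$integer.max,
                                    length(profiles) + 1L))

  if ("simulate" %in% stages) {
    runStage("simulate", function(sdir) {
      pops <- list()
      for (i in seq_along(profiles)) {
        nm <- names(profiles)[i]
        pops[[nm]] <- samplePopulation(profiles[[i]], acq,
                                       config$nCellsReference, seeds[i])
        writePopulation(pops[[nm]], file.path(sdir, nm),
                        provenance = stageSidecar(config, "simulate"))
      }
      if (!config$queryProfile %in% names(profiles))
        stop("unknown query profile: ", config$queryProfile)
      query <- samplePopulation(profiles[[config$queryProfile]], acq,
                                config$nCellsQuery,
                                seeds[length(seeds)])
      writePopulation(query, file.path(sdir, "query"),
                      provenance = stageSidecar(config, "simulate"))
      state$populations <<- pops
      state$query <<- query
    })
  }

  if ("preprocess" %in% stages) {
    if (is.null(state$populations)) stop("preprocess requires simulate")
    runStage("preprocess", function(sdir) {
      state$averages <<- lapply(state$populations, function(p)
        averageSpectra(pirPreprocess(p)))
      state$queryAverage <<- averageSpectra(pirPreprocess(state$query))
      for (nm in names(state$averages))
        writeAverageSpectrum(state$averages[[nm]],
                             file.path(sdir, paste0(nm, "_average.csv")),
                             provenance = stageSidecar(config, "preprocess"))
      writeAverageSpectrum(state$queryAverage,
                           file.path(sdir, "query_average.csv"),
                           provenance = stageSidecar(config, "preprocess"))
    })
  }

  if ("fit" %in% stages) {
    if (is.null(state$averages)) stop("fit requires preprocess")
    runStage("fit", function(sdir) {
      state$fits <<- lapply(state$averages, fitBands)
      state$queryFits <<- fitBands(state$queryAverage)
      tab <- do.call(rbind, c(
        lapply(names(state$fits), function(nm)
          cbind(source = nm, state$fits[[nm]])),
        list(cbind(source = "query", state$queryFits))))
      utils::write.csv(tab, file.path(sdir, "fits.csv"), row.names = FALSE)
      jsonlite::write_json(stageSidecar(config, "fit"),
                           file.path(sdir, "fit.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  if ("panels" %in% stages) {
    if (is.null(state$fits)) stop("panels requires fit")
    runStage("panels", function(sdir) {
      refPIRs <- lapply(state$fits, allPairsPIRs)
      state$panels <<- buildPanels(refPIRs,
                                   referenceBands = config$referenceBands)
      writePanels(state$panels, file.path(sdir, "panels.json"),
                  provenance = stageSidecar(
                    config, "panels",
                    list(n = vapply(state$populations, nSpectra, integer(1)))))
    })
  }

  if ("classify" %in% stages) {
    if (is.null(state$panels)) {
      panelPath <- file.path(config$outDir, "panels", "panels.json")
      if (!file.exists(panelPath))
        stop("classify requires panels: run the 'panels' stage first ",
             "(no ", panelPath, ")")
      state$panels <- readPanels(panelPath)
    }
    if (is.null(state$queryFits)) stop("classify requires fit")
    runStage("classify", function(sdir) {
      queryPIRs <- allPairsPIRs(state$queryFits, source = "query")
      state$classification <<- classifyAgainstPanels(queryPIRs, state$panels)
      writeMatchTable(list(query = state$classification),
                      file.path(sdir, "match_table.csv"))
      utils::write.csv(state$classification$overall$perPIR,
                       file.path(sdir, "match_audit.csv"), row.names = FALSE)
      jsonlite::write_json(stageSidecar(config, "classify"),
                           file.path(sdir, "classify.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  invisible(state)
}
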