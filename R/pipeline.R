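# End-to-end pipeline: load/clean -> regions + periods -> raster metrics ->
# correlograms per region -> shape metrics -> classifications -> fractions,
# transitions, combined combinations -> tables (+ optional plots).

.defaultConfig <- function() {
  list(
    input = NULL, duration = NULL,
    excludedWindows = NULL, removedUnits = character(),
    regionLength = 420, regions = NULL, treatments = NULL,
    range = 1, binWidth = 0.001, referenceSubset = NULL,
    sparsityThreshold = 0,
    alpha = 0.05, smoothWindow = 1, minProminence = NULL,
    chi2Variant = "pearson", centerBin = "split",
    maxPeaks = 4, peakTimeMode = "timescale",
    includeAutocorrelograms = FALSE,
    grouping = "period",
    outputDir = "correloscope_out", cacheDir = NULL, plots = FALSE
  )
}

#' Load and validate a run configuration
#'
#' Accepts a list, or a path to a YAML or JSON file, and fills unset fields
#' with package defaults. The configuration round-trips through
#' serialization unchanged (it is stored verbatim in the run manifest).
#'
#' @param config list or file path.
#' @return validated configuration list.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.defaultConfig()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.defaultConfig(), config)
  if (is.null(cfg$input)) stop("config must name an input")
  cfg
}

.correlogramCacheKey <- function(rec, regions, cfg) {
  rlang::hash(list(trains = rec@trains, regions = regions,
                   range = cfg$range, binWidth = cfg$binWidth,
                   referenceSubset = cfg$referenceSubset,
                   sparsityThreshold = cfg$sparsityThreshold))
}

#' Decide which pipeline stages can be replayed from cache
#'
#' Correlogram construction is the expensive stage; its cached result is
#' reused iff the input raster, the region definitions and the correlogram
#' settings (range, bin width, reference subset, sparsity threshold) are
#' unchanged -- a hash over exactly those inputs is the cache key. Metric
#' and classification stages are always recomputed: changing, say, only
#' the significance cutoff alpha reuses the correlograms. Changing the bin
#' width changes the key and forces a full recompute.
#'
#' @param rec the (cleaned) \linkS4class{SpikeRecording}.
#' @param regions region frame the run will use.
#' @param cfg configuration list from [loadRunConfig()].
#' @param cacheDir cache directory (or \code{NULL} for no cache).
#' @param forceReuse fail instead of recomputing when the key misses.
#' @return list with \code{correlograms} ("reuse" or "recompute"),
#'   \code{key}, and \code{file}.
#' @export
cacheOrRecompute <- function(rec, regions, cfg, cacheDir = cfg$cacheDir,
                             forceReuse = FALSE) {
  key <- .correlogramCacheKey(rec, regions, cfg)
  file <- if (!is.null(cacheDir))
    file.path(cacheDir, paste0("correlograms_", key, ".rds"))
  hit <- !is.null(cacheDir) && file.exists(file)
  if (forceReuse && !hit)
    stop("cache miss with reuse forced: correlogram settings changed")
  list(correlograms = if (hit) "reuse" else "recompute",
       key = key, file = file)
}

#' Run the full correlogram analysis pipeline
#'
#' Executes, in order: load/clean, region and period assignment, raster
#' metrics, all-pairs correlograms per region, shape metrics, metric
#' distribution export, classification, class fractions, transition
#' probabilities, and combined classification combinations. Every output
#' table is written as headered CSV under \code{outputDir}, along with a
#' \code{manifest.json} recording the configuration, per-file content
#' hashes, stage status and elapsed time. Identical configuration and
#' input give byte-identical tables.
#'
#' @param config configuration list or YAML/JSON path (see
#'   [loadRunConfig()]); \code{input} may be a raster CSV path or a
#'   \linkS4class{SpikeRecording}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all computed tables and the manifest.
#' @export
runPipeline <- function(config, quiet = TRUE) {
  t0 <- Sys.time()
  cfg <- loadRunConfig(config)
  out <- cfg$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$cacheDir))
    dir.create(cfg$cacheDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- "load"
  res <- tryCatch({
    rec <- if (methods::is(cfg$input, "SpikeRecording")) cfg$input
           else readRasterCSV(cfg$input, duration = cfg$duration)
    if (!is.null(cfg$treatments)) {
      tt <- as.data.frame(cfg$treatments)
      rec@treatments <- tt[order(tt$time), , drop = FALSE]
      methods::validObject(rec)
    }
    if (!is.null(cfg$excludedWindows) || length(cfg$removedUnits))
      rec <- applyCleaning(rec, cfg$excludedWindows, cfg$removedUnits)

    stage <- "regions"
    regions <- if (!is.null(cfg$regions)) manualRegions(cfg$regions)
               else autoRegions(recordingDuration(rec), cfg$regionLength)
    periods <- assignPeriods(regions, treatments(rec),
                             duration = recordingDuration(rec))

    stage <- "raster_metrics"
    fc <- firingCounts(rec, regions, periods)
    ih <- isiHistogram(rec)
    rtDf <- if (recordingDuration(rec) >= 60) {
      rt <- rateTrace(rec)
      data.frame(window_start = rt$windowStart, mean = rt$mean, sd = rt$sd)
    } else data.frame(window_start = numeric(), mean = numeric(),
                      sd = numeric())

    stage <- "correlograms"
    spec <- correlogramSpec(cfg$range, cfg$binWidth,
                            referenceSubset = cfg$referenceSubset)
    decision <- cacheOrRecompute(rec, regions, cfg)
    if (decision$correlograms == "reuse") {
      say("correlograms: cache hit")
      csets <- readRDS(decision$file)
    } else {
      csets <- lapply(seq_len(nrow(regions)), function(i)
        correlogramSet(rec, regions[i, ], spec,
                       sparsityThreshold = cfg$sparsityThreshold))
      if (!is.null(decision$file)) saveRDS(csets, decision$file)
    }

    stage <- "shape_metrics"
    params <- metricParams(cfg$alpha, cfg$smoothWindow, cfg$minProminence,
                           cfg$chi2Variant, cfg$centerBin)
    metrics <- do.call(rbind, lapply(csets, shapeMetrics, params = params))

    stage <- "classify"
    records <- classifyCorrelograms(metrics, alpha = cfg$alpha,
                                    maxPeaks = cfg$maxPeaks,
                                    peakTimeMode = cfg$peakTimeMode,
                                    range = cfg$range)
    fractions <- do.call(rbind, lapply(c("uniformity", "peaks", "lf"),
      function(s) cbind(scheme = s,
                        classFractions(records, s,
                                       cfg$includeAutocorrelograms))))
    stage <- "transitions"
    transitions <- if (nrow(regions) >= 2L) {
      do.call(rbind, lapply(c("uniformity", "peaks", "lf"), function(s)
        cbind(scheme = s,
              transitionProbabilities(records, s, step = cfg$grouping,
                                      periods = periods,
                                      includeAutocorrelograms =
                                        cfg$includeAutocorrelograms))))
    } else NULL
    stage <- "combos"
    combos <- combinedComboTable(records, periods,
                                 cfg$includeAutocorrelograms)

    stage <- "write"
    tables <- list(firing_counts = fc, isi_hist = ih, rate_trace = rtDf,
                   regions = merge(regions, periods, by = "index"),
                   metrics = metrics, classes = records,
                   fractions = fractions, combos = combos)
    if (!is.null(transitions))
      tables[[paste0("transitions_", cfg$grouping)]] <- transitions
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(out, paste0(nm, ".csv")),
                       row.names = FALSE)
    if (isTRUE(cfg$plots)) {
      stage <- "plots"
      .writePlots(out, metrics, fractions, combos)
    }
    tables
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  files <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1L)) &
                 names(cfg) != "input"],
    input = if (is.character(cfg$input)) cfg$input else "in-memory recording",
    elapsed_s = elapsed,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say(sprintf("pipeline complete in %.1f s", elapsed))
  res$manifest <- manifest
  invisible(res)
}

.writePlots <- function(out, metrics, fractions, combos) {
  for (r in unique(metrics$region)) {
    g <- plotMetricHeatmap(metrics, region = r, metric = "area_left")
    ggplot2::ggsave(file.path(out, sprintf("heatmap_area_region%02d.png", r)),
                    g, width = 6, height = 5, dpi = 120)
  }
  ggplot2::ggsave(file.path(out, "metric_distributions.png"),
                  plotMetricDistributions(metrics, "area_left"),
                  width = 8, height = 4, dpi = 120)
  ggplot2::ggsave(file.path(out, "class_fractions.png"),
                  plotClassFractions(fractions), width = 8, height = 6,
                  dpi = 120)
  ggplot2::ggsave(file.path(out, "combo_heatmap.png"),
                  plotComboHeatmap(combos), width = 8, height = 5, dpi = 120)
}
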