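## End-to-end orchestration: simulate -> mask -> indices -> composites ->
## trends -> match -> classify -> report, driven by one declarative YAML
## config holding every study threshold.

.default_config <- function() {
  list(
    seed = 42L,
    pa = list(n_states = 2L, n_tr = 3L, n_wls = 6L),
    scene = list(width = 24L, height = 24L, pixel_size = 500,
                 years = c(1984L, 2012L), obs_per_year = 12L,
                 cloud_fraction = 0.05, water_fraction = 0.0,
                 noise_sd = 0.01),
    thresholds = list(rainfall_window = 500, wls_min_area = 75,
                      min_points_per_epoch = 5L,
                      max_insufficient_fraction = 0.20,
                      robust_min_fraction = 0.20,
                      substantial_threshold = 15),
    options = list(declaration_epoch = "after",
                   distance_metric = "boundary",
                   estimator = "theil-sen",
                   timestamp_mode = "subset-mean",
                   epoch_mode = "both")
  )
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
    attr(cfg, "path") <- config
    cfg
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
}

.merge_config <- function(cfg) {
  def <- .default_config()
  for (sec in names(def)) {
    if (is.list(def[[sec]])) {
      for (k in names(def[[sec]]))
        if (is.null(cfg[[sec]][[k]])) cfg[[sec]][[k]] <- def[[sec]][[k]]
    } else if (is.null(cfg[[sec]])) cfg[[sec]] <- def[[sec]]
  }
  cfg
}

.config_to_analysis <- function(cfg) {
  th <- cfg$thresholds
  op <- cfg$options
  analysisConfig(
    rainfallWindow = th$rainfall_window,
    wlsMinArea = th$wls_min_area,
    minPointsPerEpoch = th$min_points_per_epoch,
    maxInsufficientFraction = th$max_insufficient_fraction,
    robustMinFraction = th$robust_min_fraction,
    substantialThreshold = th$substantial_threshold,
    declarationEpoch = op$declaration_epoch,
    distanceMetric = op$distance_metric,
    estimator = op$estimator,
    timestampMode = op$timestamp_mode
  )
}

#' Validate a pipeline configuration
#'
#' Checks the threshold ranges (the [AnalysisConfig-class] invariants), the
#' PA counts, the scene geometry and the epoch options of a YAML pipeline
#' config, reporting every problem found.
#'
#' @param config Path to a YAML config file, or an equivalent list. Missing
#'   entries take the bundled defaults.
#' @return `list(valid = TRUE/FALSE, errors = character())`.
#' @examples
#' validateConfig(list(seed = 1))$valid
#' @export
validateConfig <- function(config) {
  cfg <- .merge_config(.read_config(config))
  errors <- character()
  add <- function(e) errors <<- c(errors, e)
  ac <- tryCatch(.config_to_analysis(cfg), error = function(e) {
    add(conditionMessage(e)); NULL
  })
  pa <- cfg$pa
  if (pa$n_states < 1) add("pa.n_states must be >= 1")
  if (pa$n_tr < 0 || pa$n_wls < 0) add("pa.n_tr and pa.n_wls must be >= 0")
  sc <- cfg$scene
  spec <- tryCatch({
    sceneSpec(sc$width, sc$height, sc$pixel_size,
              years = unlist(sc$years), obsPerYear = sc$obs_per_year,
              cloudFraction = sc$cloud_fraction,
              waterFraction = sc$water_fraction,
              noiseSD = sc$noise_sd, seed = cfg$seed)
    NULL
  }, error = function(e) add(conditionMessage(e)))
  if (!cfg$options$epoch_mode %in% c("both", "after-only"))
    add("options.epoch_mode must be 'both' or 'after-only'")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    add("seed must be a single integer")
  list(valid = length(errors) == 0L, errors = errors)
}

.write_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

## Analyse one PA: simulate its scene, run the per-pixel pipeline, return
## slopes plus per-epoch sufficiency.
.analyse_pa <- function(paRow, declYear, cfg, ac, paSeed) {
  sc <- cfg$scene
  spec <- sceneSpec(sc$width, sc$height, sc$pixel_size,
                    years = unlist(sc$years), obsPerYear = sc$obs_per_year,
                    cloudFraction = sc$cloud_fraction,
                    waterFraction = sc$water_fraction,
                    noiseSD = sc$noise_sd, seed = paSeed)
  sim <- simulateStack(spec, simulateTruth(spec, declYear, seed = paSeed + 1L))
  idx <- computeIndices(applyQAMask(sim$stack, quiet = TRUE))
  comp <- buildComposites(idx, fraction = ac@robustMinFraction,
                          timestampMode = ac@timestampMode)
  sm <- estimateEpochSlopes(comp, declYear,
                            minPoints = ac@minPointsPerEpoch,
                            estimator = ac@estimator,
                            declarationEpoch = ac@declarationEpoch)
  v <- slopeValid(sm)
  suff <- list()
  for (ep in c("before", "after")) {
    cols <- paste(c("b", "d"), ep, sep = "_")
    ok <- v[, cols[1]] & v[, cols[2]]
    suff[[ep]] <- paSufficiency(ok, rep(TRUE, length(ok)),
                                ac@maxInsufficientFraction)
  }
  list(slopes = sm, sufficiency = suff)
}

#' Run the full BACI pipeline from a config
#'
#' Executes every stage — PA-table simulation, matching, per-PA scene
#' simulation, QA masking, index computation, annual composites, epoch-wise
#' Sen's slopes, sufficiency filtering, condition classification, pair
#' comparison and reporting — and writes the tabular outputs (PA table,
#' matched pairs, per-PA compositions, pair comparisons, ternary exports,
#' sufficiency log) as CSV plus a JSON run manifest to `outDir`. Identical
#' configs yield byte-identical CSV outputs. Epochs follow each TR's
#' declaration year for both members of a pair; a pair enters the
#' before-to-after (change) analysis only when both members pass the
#' area-sufficiency rule in both epochs.
#'
#' @param config Path to a YAML config file or an equivalent list; missing
#'   entries take the bundled defaults (`.` see the packaged
#'   `demo_config.yaml`).
#' @param outDir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return The run manifest, invisibly.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  cfgPath <- if (is.character(config)) config else NULL
  cfg <- .merge_config(.read_config(config))
  chk <- validateConfig(cfg)
  if (!chk$valid)
    stop("invalid config:\n  ", paste(chk$errors, collapse = "\n  "))
  ac <- .config_to_analysis(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  paTab <- stage("simulate-pa", {
    p <- cfg$pa
    generatePATable(p$n_states, p$n_tr, p$n_wls, seed = cfg$seed)
  })
  log("simulate-pa", "%d PAs (%d TR, %d WLS) in %d states",
      nrow(paTab), sum(paTab$status == "TR"), sum(paTab$status == "WLS"),
      cfg$pa$n_states)
  files["pa_table"] <- .write_csv(paTab, outDir, "pa_table.csv")

  m <- stage("match", matchPairs(paTab, ac))
  log("match", "%d pairs matched, %d TRs unmatched",
      nrow(m$pairs), length(m$unmatched))
  files["matched_pairs"] <- .write_csv(m$pairs, outDir, "matched_pairs.csv")
  files["unmatched"] <- .write_csv(
    data.frame(tr_id = m$unmatched), outDir, "unmatched_trs.csv")

  compAfter <- list(); compChange <- list()
  cmpAfter <- list(); cmpChange <- list()
  suffRows <- list()
  both <- cfg$options$epoch_mode == "both"
  for (i in seq_len(nrow(m$pairs))) {
    pr <- m$pairs[i, ]
    tr <- paTab[paTab$id == pr$tr_id, ]
    wls <- paTab[paTab$id == pr$wls_id, ]
    declYear <- tr$declaration_year
    res <- list(
      TR = stage("analyse", .analyse_pa(tr, declYear, cfg, ac,
        paSeed = (cfg$seed + 101L * i) %% .Machine$integer.max)),
      WLS = stage("analyse", .analyse_pa(wls, declYear, cfg, ac,
        paSeed = (cfg$seed + 101L * i + 50L) %% .Machine$integer.max))
    )
    ids <- c(TR = tr$id, WLS = wls$id)
    for (side in names(res)) {
      for (ep in c("before", "after")) {
        s <- res[[side]]$sufficiency[[ep]]
        suffRows[[length(suffRows) + 1L]] <- data.frame(
          pa_id = ids[[side]], epoch = ep,
          insufficient_fraction = attr(s, "insufficientFraction"),
          retained = as.logical(s))
      }
    }
    okAfter <- as.logical(res$TR$sufficiency$after) &&
      as.logical(res$WLS$sufficiency$after)
    log("classify", "pair %s-%s (decl %d): after-sufficient %s",
        tr$id, wls$id, declYear, okAfter)
    if (okAfter) {
      cA <- lapply(names(res), function(side)
        composition(classifyPixels(res[[side]]$slopes, "after"),
                    paId = ids[[side]]))
      names(cA) <- names(res)
      compAfter <- c(compAfter, cA)
      cmpAfter[[length(cmpAfter) + 1L]] <- comparePair(cA$TR, cA$WLS, ac)
    }
    okChange <- both && okAfter &&
      as.logical(res$TR$sufficiency$before) &&
      as.logical(res$WLS$sufficiency$before)
    if (okChange) {
      cC <- lapply(names(res), function(side)
        composition(classifyPixels(res[[side]]$slopes, "change"),
                    paId = ids[[side]]))
      names(cC) <- names(res)
      compChange <- c(compChange, cC)
      cmpChange[[length(cmpChange) + 1L]] <- comparePair(cC$TR, cC$WLS, ac)
    }
  }
  bindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  compAfterDf <- bindOr(compAfter, data.frame())
  files["compositions_after"] <-
    .write_csv(compAfterDf, outDir, "compositions_after.csv")
  files["comparisons_after"] <-
    .write_csv(bindOr(cmpAfter, data.frame()), outDir,
               "pair_comparisons_after.csv")
  files["ternary_after"] <-
    .write_csv(ternaryExport(compAfterDf), outDir, "ternary_after.csv")
  if (both) {
    compChangeDf <- bindOr(compChange, data.frame())
    files["compositions_change"] <-
      .write_csv(compChangeDf, outDir, "compositions_change.csv")
    files["comparisons_change"] <-
      .write_csv(bindOr(cmpChange, data.frame()), outDir,
                 "pair_comparisons_change.csv")
    files["ternary_change"] <-
      .write_csv(ternaryExport(compChangeDf), outDir, "ternary_change.csv")
  }
  files["sufficiency"] <-
    .write_csv(bindOr(suffRows, data.frame()), outDir, "pa_sufficiency.csv")

  manifest <- list(
    package = "baciveg",
    version = as.character(utils::packageVersion("baciveg")),
    seed = cfg$seed,
    config_hash = if (!is.null(cfgPath))
      unname(tools::md5sum(cfgPath)) else NA_character_,
    epoch_mode = cfg$options$epoch_mode,
    n_pairs = nrow(m$pairs),
    n_unmatched = length(m$unmatched),
    outputs = as.list(files),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("report", "wrote %d output files to %s", length(files) + 1L, outDir)
  invisible(manifest)
}
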