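#' @include energy.R nma.R geometry.R states.R synthetic.R
NULL

## Pipeline orchestration: YAML config -> staged analysis -> TSV reports.
## Every output table carries a header with the package version, a config
## hash and all non-default model parameters, and reruns with identical
## config + seed produce byte-identical table bodies.

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

.validationError <- function(msg) {
  stop(structure(class = c("ribostateValidationError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a pipeline configuration
#'
#' Checks that referenced paths exist, that the states stage has exactly one
#' of explicit `thresholds` or a `derive` directive, and normalizes
#' defaults. Raises a condition of class `ribostateValidationError` before
#' any stage runs.
#'
#' @param config list (parsed YAML) or path to a YAML file.
#' @return normalized config list
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .validationError(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$stages) || !length(config$stages))
    .validationError("config must list at least one stage")
  known <- c("simulate", "energy", "decompose", "entropy", "geometry",
             "states", "report")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    .validationError(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  for (p in c(config$energy$structure, config$energy$parameters,
              unlist(config$energy$replicas)))
    if (!is.null(p) && !file.exists(p))
      .validationError(sprintf("referenced file does not exist: %s", p))
  if ("states" %in% config$stages) {
    hasThr <- !is.null(config$states$thresholds)
    hasDer <- !is.null(config$states$derive)
    if (hasThr == hasDer)
      .validationError(
        "states stage needs exactly one of 'thresholds' or 'derive'")
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.modelFromConfig <- function(config) {
  ov <- config$energy$model
  if (is.null(ov)) ov <- list()
  do.call(energyModelParams, ov)
}

.stageLog <- function(logFile, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order: simulate, energy, decompose,
#' entropy, geometry, states, report. Results accumulate in a list; the
#' report stage writes TSV tables via [writeReportTables()]. A stage failure
#' aborts with the stage name; artifacts written so far are preserved.
#'
#' @param config list or YAML path (see [validateConfig()]).
#' @param seed optional integer overriding the config seed.
#' @param outDir output directory (default `config$output_dir` or ".").
#' @return (invisibly) list of stage results
#' @export
runPipeline <- function(config, seed = NULL, outDir = NULL) {
  config <- validateConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(outDir)) outDir <- config$output_dir
  if (is.null(outDir)) outDir <- "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  cat(sprintf("ribostate %s run, seed %d\n",
              as.character(utils::packageVersion("ribostate")),
              config$seed), file = logFile)
  params <- .modelFromConfig(config)
  results <- list(config = config, params = params)
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      .runStage(stage, config, params, results, outDir, logFile),
      error = function(e) {
        if (inherits(e, "ribostateValidationError")) stop(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      })
    results <- res
    .stageLog(logFile, stage,
              sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0))
  }
  invisible(results)
}

.runStage <- function(stage, config, params, results, outDir, logFile) {
  switch(stage,
    simulate = {
      sc <- config$simulate$two_state
      if (!is.null(sc)) {
        results$twoState <- makeTwoStateSeries(
          nFrames = sc$n_frames %||% 10000L,
          pStayOpen = sc$p_stay_open %||% 0.98,
          pStayClosed = sc$p_stay_closed %||% 0.98,
          meanOpen = sc$mean_open %||% 22.98,
          meanClosed = sc$mean_closed %||% 20.59,
          emissionSd = sc$emission_sd %||% 0.6,
          seed = config$seed)
        .stageLog(logFile, stage,
                  sprintf("two-state series: %d frames",
                          length(results$twoState$distance)))
      }
      results
    },
    energy = {
      ec <- config$energy
      ## the structure file is typically the multi-model trajectory itself;
      ## the model-1 warning is expected here
      loaded <- suppressWarnings(readPDB(ec$structure))
      sys <- readParameters(loaded$system, ec$parameters)
      rec <- selectAtoms(sys, ec$receptor)
      lig <- selectAtoms(sys, ec$ligand)
      trajFiles <- ec$replicas %||% list(ec$structure)
      frac <- ec$snapshot_fraction %||% 0.5
      stride <- ec$snapshot_stride %||% 1L
      comps <- list(); frames <- list()
      for (r in seq_along(trajFiles)) {
        traj <- readTrajectory(trajFiles[[r]],
                               frameInterval = ec$frame_interval %||% 10,
                               replicaId = r)
        nf <- nFrames(traj)
        keep <- seq(max(1L, floor(nf * (1 - frac)) + 1L), nf, by = stride)
        for (i in keep) {
          cmp <- snapshotBindingComponents(sys, getFrame(traj, i), rec,
                                           lig, params)
          cmp$replica <- r
          comps[[length(comps) + 1L]] <- cmp
          frames[[length(frames) + 1L]] <- getFrame(traj, i)
        }
      }
      results$system <- sys
      results$receptor <- rec
      results$ligand <- lig
      results$snapshots <- frames
      results$components <- do.call(rbind, comps)
      .stageLog(logFile, stage,
                sprintf("%d snapshots over %d replica(s)",
                        nrow(results$components), length(trajFiles)))
      results
    },
    decompose = {
      results$decomposition <- perResidueDecomposition(
        results$system, results$snapshots, results$receptor,
        results$ligand, params)
      results
    },
    entropy = {
      en <- config$entropy %||% list()
      results$entropy <- entropyTerm(
        results$system, results$snapshots, results$receptor,
        results$ligand, T = en$temperature %||% 300, params = params,
        thin = en$thin %||% 10L)
      results
    },
    geometry = {
      gc_ <- config$geometry %||% list()
      sys <- results$system
      traj <- new("Trajectory", frames = results$snapshots,
                  frameInterval = config$energy$frame_interval %||% 10,
                  replicaId = 1L)
      if (!is.null(gc_$rmsd_selection)) {
        sel <- selectAtoms(sys, gc_$rmsd_selection)
        results$rmsd <- rmsdSeries(traj, sel)
        results$rmsf <- rmsfProfile(traj, sys, sel)
      }
      if (!is.null(gc_$distances)) {
        results$distances <- lapply(gc_$distances, function(dd)
          distanceSeries(sys, traj, selectAtoms(sys, dd$groupA),
                         selectAtoms(sys, dd$groupB), label = dd$label))
        names(results$distances) <-
          vapply(gc_$distances, `[[`, "", "label")
      }
      results
    },
    states = {
      sc <- config$states
      series <- if (identical(sc$series, "two_state"))
        results$twoState$distance
      else if (!is.null(sc$series_label))
        as.numeric(results$distances[[sc$series_label]])
      else stop("states stage: no input series configured")
      thr <- if (!is.null(sc$thresholds))
        stateThresholds(sc$thresholds$closed_max, sc$thresholds$open_min)
      else deriveThresholds(results$distances[[sc$derive$bound_label]],
                            results$distances[[sc$derive$apo_label]],
                            sc$derive$window_fraction %||% 0.5)
      results$states <- classifyStates(series, thr)
      p <- statePercent(results$states)
      .stageLog(logFile, stage,
                sprintf("open %.2f%% / middle %.2f%% / closed %.2f%%",
                        p[["pct_open"]], p[["pct_middle"]],
                        p[["pct_closed"]]))
      results
    },
    report = {
      writeReportTables(results, outDir)
      results
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tsvHeader <- function(results) {
  c(sprintf("# ribostate %s",
            as.character(utils::packageVersion("ribostate"))),
    sprintf("# config_hash %s", .configHash(results$config)),
    sprintf("# seed %d", results$config$seed))
}

.writeTSV <- function(df, file, header) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write report tables
#'
#' Emits whatever the results list contains: an energy table (rows = energy
#' terms, `mean +/- se` cells), a per-residue decomposition table, a state
#' report (percentages and thresholds; with a correlation footer when a
#' multi-ligand summary table is present), distance summaries and the RMSF
#' profile. Headers carry the package version, config hash and seed.
#'
#' @param results list from [runPipeline()], or hand-assembled: recognized
#'   elements are `binding` (a [BindingFreeEnergyResult] or named list of
#'   them), `decomposition`, `states`, `stateTable` (data.frame `ligand`,
#'   `pct_open`, `pct_closed`, `distance`), `distances`, `rmsf`.
#' @param outDir output directory.
#' @return invisibly, character vector of files written
#' @export
writeReportTables <- function(results, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- if (!is.null(results$config)) .tsvHeader(results) else
    sprintf("# ribostate %s",
            as.character(utils::packageVersion("ribostate")))
  written <- character()
  emit <- function(df, name) {
    f <- file.path(outDir, name)
    .writeTSV(df, f, hdr)
    written <<- c(written, f)
  }
  binding <- results$binding
  if (is.null(binding) && !is.null(results$components) &&
      !is.null(results$entropy))
    binding <- aggregateReplicas(results$components, results$entropy$TdS,
                                 results$entropy$se)
  if (!is.null(binding)) {
    if (is(binding, "BindingFreeEnergyResult"))
      binding <- list(complex = binding)
    cells <- vapply(binding, function(b)
      ifelse(is.na(b@se), sprintf("%.2f", b@means),
             sprintf("%.2f +/- %.2f", b@means, b@se)),
      character(length(binding[[1L]]@means)))
    df <- data.frame(term = names(binding[[1L]]@means), cells)
    names(df) <- c("term", names(binding))
    emit(df, "energy_table.tsv")
  }
  if (!is.null(results$decomposition))
    emit(results$decomposition, "residue_decomposition.tsv")
  if (!is.null(results$states)) {
    s <- results$states
    p <- statePercent(s)
    emit(data.frame(pct_open = p[["pct_open"]],
                    pct_middle = p[["pct_middle"]],
                    pct_closed = p[["pct_closed"]],
                    closed_max = s@closedMax, open_min = s@openMin,
                    thresholds = s@source),
         "state_report.tsv")
  }
  if (!is.null(results$stateTable)) {
    st <- results$stateTable
    df <- data.frame(ligand = as.character(st$ligand),
                     pct_open = sprintf("%.2f", st$pct_open),
                     pct_closed = sprintf("%.2f", st$pct_closed),
                     distance = sprintf("%.2f", st$distance))
    if (nrow(st) >= 3L)
      df <- rbind(df, data.frame(
        ligand = "R",
        pct_open = sprintf("%.4f", pearsonR(st$distance, st$pct_open)),
        pct_closed = sprintf("%.4f", pearsonR(st$distance, st$pct_closed)),
        distance = ""))
    emit(df, "state_table.tsv")
  }
  if (!is.null(results$distances)) {
    df <- do.call(rbind, lapply(names(results$distances), function(k) {
      x <- results$distances[[k]]
      data.frame(label = k, mean = attr(x, "mean"), sd = attr(x, "sd"))
    }))
    emit(df, "distance_summary.tsv")
  }
  if (!is.null(results$rmsf)) emit(results$rmsf, "rmsf_profile.tsv")
  invisible(written)
}
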