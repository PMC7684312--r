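# End-to-end orchestration: simulate -> preprocess -> (raw | normalized)
# extract -> reproducibility screening (inter + intra arms) -> five-step
# filter -> clustering / representatives -> ROC, with all table/figure
# analogs written as plain CSV plus a JSON run manifest.

#' Default pipeline configuration
#'
#' A fully serializable list driving \code{\link{runPipeline}}. The default
#' mirrors the reference study layout: 3 single-tissue phantoms, 9
#' two-layer volunteers in three groups, 3 scanners, and the four
#' acquisition-parameter sweeps (3-level TR-like, 4-level TE-like, 4-level
#' ST-like, 4-level AM-like).
#'
#' @param seed master seed.
#' @return named list of configuration fields.
#' @export
defaultPipelineConfig <- function(seed = 20260101L) {
  list(nKiwi = 3L, nVolunteer = 9L, seed = as.integer(seed),
       sweepNames = c("TR", "TE", "ST", "AM"),
       targetSpacing = 1, levels = 256L, offsets = c(1L, 4L, 7L),
       histBins = 256L, arms = c("raw", "normalized"),
       cvCutoffs = c(0.1, 0.15), qcdCutoffs = c(10, 15),
       selectionCV = 0.1, selectionQCD = 10, k = 8L,
       writeVolumes = FALSE)
}

#' Scaled-down demonstration configuration
#'
#' One single-tissue phantom and two two-layer subjects across the full
#' three-scanner panel with the two 4-level sweeps (TE-like and AM-like);
#' small enough for an end-to-end run on one CPU in a few minutes while
#' exercising every stage.
#'
#' @param seed master seed.
#' @return configuration list.
#' @export
demoPipelineConfig <- function(seed = 20260101L) {
  cfg <- defaultPipelineConfig(seed)
  cfg$nKiwi <- 1L
  cfg$nVolunteer <- 2L
  cfg$sweepNames <- c("TE", "AM")
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(path))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @return \code{writePipelineConfig}: the path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Screen one subset of a feature table, guarding against missing sessions.
screenSubset <- function(tab, cvCutoffs, qcdCutoffs) {
  screenFeatures(tab, cvCutoffs = cvCutoffs, qcdCutoffs = qcdCutoffs)
}

#' Run the full analysis pipeline
#'
#' Executes every stage from study simulation to ROC evaluation and writes
#' the table/figure analogs as CSV files plus a JSON run manifest into
#' \code{outDir}. Two runs with the same configuration and seed produce
#' byte-identical outputs. Any stage failure aborts with the stage name;
#' artifacts written before the failure are preserved.
#'
#' @param config configuration list (see \code{\link{defaultPipelineConfig}}).
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory artifacts: study manifest,
#'   feature tables, screening results, five-step filters, clusterings,
#'   representatives and ROC tables.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir, quiet = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[radirep] ", ...)
  stage <- "init"
  onFail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                             conditionMessage(e), call. = FALSE)
  tryCatch({
    stage <- "simulate"
    say("simulating study (seed ", config$seed, ")")
    dflt <- defaultParameterSweeps()
    design <- studyDesign(nKiwi = config$nKiwi, nVolunteer = config$nVolunteer,
                          sweeps = dflt$sweeps[config$sweepNames],
                          sweepLabels = dflt$labels[config$sweepNames],
                          masterSeed = config$seed)
    study <- generateStudy(design)
    utils::write.csv(study$manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
    if (isTRUE(config$writeVolumes))
      writeStudyNifti(study, file.path(outDir, "volumes"))

    stage <- "reference"
    refId <- study$manifest$session_id[study$manifest$arm == "inter"][1]
    refSess <- study$sessions[[refId]]
    refRs <- resampleIsotropic(refSess$image, refSess$masks$voi,
                               config$targetSpacing)
    landmarks <- computeLandmarks(refRs$image, refRs$mask, referenceId = refId)
    writeLandmarkJSON(landmarks, file.path(outDir, "reference_landmarks.json"))

    stage <- "extract"
    catalog <- defaultFeatureCatalog()
    tables <- list()
    for (arm in config$arms) {
      say("extracting features, ", arm, " arm (",
          length(study$sessions), " sessions)")
      ref <- if (arm == "normalized") landmarks else NULL
      tab <- extractStudyFeatures(study$sessions, reference = ref,
                                  catalog = catalog,
                                  targetSpacing = config$targetSpacing,
                                  levels = config$levels,
                                  offsets = config$offsets,
                                  histBins = config$histBins)
      tables[[arm]] <- tab
      utils::write.csv(tab, file.path(outDir, paste0("features_", arm, ".csv")),
                       row.names = FALSE)
    }

    stage <- "screen"
    screens <- list()
    recordRows <- list()
    table1 <- list()
    table2 <- list()
    levelTests <- list()
    for (arm in config$arms) {
      tab <- tables[[arm]]
      interTab <- tab[tab$arm == "inter", ]
      scr <- screenSubset(interTab, config$cvCutoffs, config$qcdCutoffs)
      screens[[arm]]$inter <- scr
      recordRows[[length(recordRows) + 1L]] <-
        cbind(arm = arm, scope = "inter", scr$records)
      t1 <- merge(scr$counts, scr$summary, by = "group")
      table1[[length(table1) + 1L]] <- cbind(arm = arm, t1)
      sweeps <- unique(tab$sweep[tab$arm == "intra"])
      sweeps <- sweeps[!is.na(sweeps)]
      for (sw in sweeps) {
        swTab <- tab[tab$arm == "intra" & tab$sweep == sw, ]
        scrS <- screenSubset(swTab, config$cvCutoffs, config$qcdCutoffs)
        screens[[arm]]$intra[[sw]] <- scrS
        recordRows[[length(recordRows) + 1L]] <-
          cbind(arm = arm, scope = sw, scrS$records)
        cvCounts <- scrS$counts[scrS$counts$index == "CV", ]
        table2[[length(table2) + 1L]] <-
          cbind(arm = arm, sweep = sw,
                merge(cvCounts, scrS$summary[, c("group", "meanCV", "sdCV")],
                      by = "group"))
        # high vs low parameter levels over per-feature mean CVs
        lv <- sort(unique(swTab$level))
        if (length(lv) >= 3L) {
          nh <- ceiling(length(lv) / 2)
          lowLv <- lv[seq_len(nh)]
          highLv <- lv[(length(lv) - nh + 1L):length(lv)]
          cvHalf <- function(keep) {
            s <- screenSubset(swTab[swTab$level %in% keep, ],
                              config$cvCutoffs, config$qcdCutoffs)
            r <- s$records
            tapply(r$meanCV, r$feature, mean)
          }
          hi <- cvHalf(highLv)
          lo <- cvHalf(lowLv)
          feats <- intersect(names(hi), names(lo))
          tt <- compareParameterLevels(hi[feats], lo[feats])
          levelTests[[length(levelTests) + 1L]] <- data.frame(
            arm = arm, sweep = sw, statistic = tt$statistic,
            p.value = tt$p.value, meanHigh = tt$meanHigh, meanLow = tt$meanLow)
        }
      }
    }
    utils::write.csv(do.call(rbind, recordRows),
                     file.path(outDir, "reproducibility_records.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, table1),
                     file.path(outDir, "table1_inter_counts.csv"),
                     row.names = FALSE)
    if (length(table2))
      utils::write.csv(do.call(rbind, table2),
                       file.path(outDir, "table2_intra_counts.csv"),
                       row.names = FALSE)
    if (length(levelTests))
      utils::write.csv(do.call(rbind, levelTests),
                       file.path(outDir, "parameter_level_tests.csv"),
                       row.names = FALSE)

    stage <- "select"
    filters <- list()
    clusterings <- list()
    repsByArm <- list()
    volunteerCVByArm <- list()
    survRows <- list()
    clusterRows <- list()
    repRows <- list()
    for (arm in config$arms) {
      scr <- screens[[arm]]
      interRec <- scr$inter$records
      kiwiInter <- interRec[interRec$group == "G.0", ]
      volInter <- interRec[interRec$group != "G.0", ]
      intraRec <- do.call(rbind, lapply(scr$intra, `[[`, "records"))
      kiwiIntra <- intraRec[intraRec$group == "G.0", ]
      volIntra <- intraRec[intraRec$group != "G.0", ]
      flt <- fiveStepFilter(kiwiInter, kiwiIntra, volInter, volIntra,
                            cvCutoff = config$selectionCV,
                            qcdCutoff = config$selectionQCD)
      filters[[arm]] <- flt
      for (stp in names(flt$steps))
        if (length(flt$steps[[stp]]))
          survRows[[length(survRows) + 1L]] <- data.frame(
            arm = arm, step = stp, feature = flt$steps[[stp]])
      volCV <- tapply(volInter$meanCV, volInter$feature, mean)
      volunteerCVByArm[[arm]] <- volCV
      surv <- flt$survivors
      if (length(surv) >= 2L) {
        tab <- tables[[arm]]
        volSessions <- tab$arm == "inter" & tab$group != "G.0"
        fm <- as.matrix(tab[volSessions, surv, drop = FALSE])
        cl <- withCallingHandlers(
          clusterFeatures(fm, k = config$k),
          warning = function(w) {
            say("clustering (", arm, " arm): ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        clusterings[[arm]] <- cl
        clusterRows[[length(clusterRows) + 1L]] <- data.frame(
          arm = arm, feature = names(cl$assignment),
          cluster = unname(cl$assignment))
        reps <- pickRepresentatives(cl, volCV, catalogOrder = names(catalog))
      } else {
        reps <- if (length(surv))
          data.frame(cluster = 1L, feature = surv,
                     cv = unname(volCV[surv]), stringsAsFactors = FALSE)
        else NULL
        say("arm ", arm, ": fewer than 2 survivors (emptied at step ",
            filters[[arm]]$emptiedAt, "); clustering skipped")
      }
      repsByArm[[arm]] <- reps
      if (!is.null(reps))
        repRows[[length(repRows) + 1L]] <- cbind(arm = arm, reps)
    }
    if (length(survRows))
      utils::write.csv(do.call(rbind, survRows),
                       file.path(outDir, "five_step_survivors.csv"),
                       row.names = FALSE)
    if (length(clusterRows))
      utils::write.csv(do.call(rbind, clusterRows),
                       file.path(outDir, "cluster_assignments.csv"),
                       row.names = FALSE)
    if (length(repRows))
      utils::write.csv(do.call(rbind, repRows),
                       file.path(outDir, "representatives.csv"),
                       row.names = FALSE)

    stage <- "roc"
    rocOut <- NULL
    allReps <- unique(unlist(lapply(repsByArm, function(r) r$feature)))
    cervixInter <- study$manifest$layout == "cervix" & study$manifest$arm == "inter"
    if (length(allReps) && any(cervixInter)) {
      say("ROC evaluation over ", length(allReps), " representatives")
      ids <- study$manifest$session_id[cervixInter]
      tissueTables <- list()
      for (arm in config$arms) {
        ref <- if (arm == "normalized") landmarks else NULL
        rows <- list()
        for (tiss in c("inner", "outer")) {
          tt <- extractStudyFeatures(study$sessions[ids], reference = ref,
                                     catalog = catalog,
                                     targetSpacing = config$targetSpacing,
                                     maskName = tiss, levels = config$levels,
                                     offsets = config$offsets,
                                     histBins = config$histBins)
          tt$tissue <- tiss
          rows[[tiss]] <- tt
        }
        tissueTables[[arm]] <- do.call(rbind, rows)
      }
      rocOut <- evaluateRepresentatives(tissueTables, allReps,
                                        cvByArm = volunteerCVByArm,
                                        catalog = catalog, seed = config$seed)
      if (!is.null(rocOut$roc))
        utils::write.csv(rocOut$roc, file.path(outDir, "roc_results.csv"),
                         row.names = FALSE)
      if (!is.null(rocOut$cvPairs))
        utils::write.csv(rocOut$cvPairs, file.path(outDir, "cv_boxplot.csv"),
                         row.names = FALSE)
    }

    stage <- "manifest"
    runManifest <- list(
      package = "radirep",
      package_version = as.character(utils::packageVersion("radirep")),
      catalog_version = catalogVersion(catalog),
      seed = config$seed,
      config = config[setdiff(names(config), "seed")],
      n_sessions = nrow(study$manifest),
      session_ids = study$manifest$session_id)
    jsonlite::write_json(runManifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("done: ", outDir)
    invisible(list(manifest = study$manifest, landmarks = landmarks,
                   tables = tables, screens = screens, filters = filters,
                   clusterings = clusterings, representatives = repsByArm,
                   volunteerCV = volunteerCVByArm, roc = rocOut))
  }, error = onFail)
}
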