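#' @include AllClasses.R mutate.R hbonds.R stability.R trajectory.R
NULL

#' Assemble a pipeline run configuration
#'
#' @param wtActive,wtInactive wild-type structures of the two
#'   conformational states: file paths, PDB text, or
#'   [PDBStructure-class] objects. Either may be `NULL`; the affected
#'   sections are then marked `"not run"`.
#' @param mutation a [mutationSpec()].
#' @param analysis an [AnalysisConfig-class].
#' @param protocol an [MDProtocol-class] provenance record.
#' @param mutActive,mutInactive optional variant structures. When absent
#'   the variant is produced by [applyMutation()]; fixture-built variants
#'   (e.g. from [makeEnmFixturePair()]) can be supplied directly.
#' @param springEdits optional list with elements `active` and/or
#'   `inactive`: spring-edit data.frames applied to the variant's elastic
#'   network (fixture hook; see [buildENM()]).
#' @param trajectories optional named list with any of `wt_active`,
#'   `wt_inactive`, `mut_active`, `mut_inactive`: multi-model PDB paths,
#'   text, or lists of structures.
#' @param chainA,chainB protomer chains of the dimer.
#' @param seed seed for every stochastic step (bootstrap intervals).
#' @param outputDir optional directory for [writeReportBundle()].
#' @return a `RunConfig` list.
#' @export
runConfig <- function(wtActive = NULL, wtInactive = NULL, mutation,
                      analysis = analysisConfig(), protocol = mdProtocol(),
                      mutActive = NULL, mutInactive = NULL,
                      springEdits = list(),
                      trajectories = list(), chainA = "A", chainB = "B",
                      seed = 1, outputDir = NULL) {
  stopifnot(inherits(mutation, "MutationSpec"),
            is(analysis, "AnalysisConfig"), is(protocol, "MDProtocol"))
  cfg <- list(wtActive = wtActive, wtInactive = wtInactive,
              mutation = mutation, analysis = analysis, protocol = protocol,
              mutActive = mutActive, mutInactive = mutInactive,
              springEdits = springEdits,
              trajectories = trajectories, chainA = chainA, chainB = chainB,
              seed = as.integer(seed), outputDir = outputDir)
  class(cfg) <- "RunConfig"
  cfg
}

.loadStructure <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is(x, "PDBStructure")) return(x)
  if (is.character(x)) {
    s <- parsePDB(x)
    if (length(s) != 1L)
      warning(sprintf("%s: multi-model input, using the first model", what),
              call. = FALSE)
    return(s[[1L]])
  }
  stop("cannot interpret ", what, " as a structure", call. = FALSE)
}

.ensureHydrogens <- function(structure, config) {
  if (config@hbondMode == "strict" &&
      !any(atoms(structure)$element == "H"))
    addPolarHydrogens(structure, config)
  else structure
}

#' Run the full dimer-stability analysis pipeline
#'
#' Orchestrates the whole workflow for a point variant of a homodimer:
#' for each provided conformational state, mutate the wild type, detect
#' static interface hydrogen bonds and water bridges and diff the two
#' networks, locate the mutation site relative to the interface, compute
#' the elastic-network stability proxy, and, where trajectories are
#' supplied, the per-frame bridge series, summaries and block-bootstrap
#' comparisons between conditions. Sections whose inputs are absent are
#' reported as `"not run"`, never silently omitted. The whole run is
#' deterministic for a fixed configuration and seed.
#'
#' @param config a [runConfig()].
#' @return a `ReportBundle` list with elements `provenance`, `states`
#'   (per-state hbond diff, interface info, stability), `trajectories`,
#'   `comparisons`, `warnings`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  ac <- config$analysis
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  states <- list()
  for (state in c("active", "inactive")) {
    src <- if (state == "active") config$wtActive else config$wtInactive
    if (is.null(src)) {
      states[[state]] <- list(status = "not run",
                              reason = "no wild-type structure provided")
      next
    }
    wt <- .ensureHydrogens(.loadStructure(src, state), ac)
    mut_src <- if (state == "active") config$mutActive else config$mutInactive
    clash <- NA_real_
    if (is.null(mut_src)) {
      built <- applyMutation(wt, config$mutation)
      mut <- .ensureHydrogens(built$structure, ac)
      clash <- built$clashScore
      if (clash > 0)
        note(sprintf("%s: post-mutation clash score %.4f at %s%d", state,
                     clash, config$mutation$chain, config$mutation$resseq))
    } else {
      mut <- .ensureHydrogens(.loadStructure(mut_src, paste0("mut ", state)),
                              ac)
    }

    iface <- interfaceResidues(wt, config$chainA, config$chainB,
                               ac@interfaceCutoff, ac)
    site <- residueKey(config$mutation$chain, config$mutation$resseq,
                       config$mutation$icode)

    hb_wt <- findHBonds(wt, ac)
    hb_mut <- findHBonds(mut, ac)
    br_wt <- findWaterBridges(wt, config$chainA, config$chainB, ac,
                              hbonds = hb_wt)
    br_mut <- findWaterBridges(mut, config$chainA, config$chainB, ac,
                               hbonds = hb_mut)
    dif <- diffHBonds(hbondSignatures(hb_wt, br_wt),
                      hbondSignatures(hb_mut, br_mut))

    edits <- config$springEdits[[state]]
    enm_mut <- if (is.null(edits)) NULL
               else buildENM(mut, springEdits = edits, config = ac)
    stab <- stateStability(wt, mut, stateLabel = state, config = ac,
                           chainA = config$chainA, chainB = config$chainB,
                           enmMut = enm_mut)
    warnings_log <- c(warnings_log, stab@params$warnings)

    states[[state]] <- list(
      status = "ok",
      interface = list(residues = iface,
                       mutation_site = site,
                       site_on_interface = site %in% iface),
      bridges = list(wt = countBridges(br_wt, ac@bridgeMetric),
                     mut = countBridges(br_mut, ac@bridgeMetric),
                     wt_pairs = countBridges(br_wt, "pairs"),
                     mut_pairs = countBridges(br_mut, "pairs")),
      hbond_diff = dif,
      stability = stab,
      clash_score = clash)
  }

  cond_labels <- c(wt_active = "WT-active", wt_inactive = "WT-inactive",
                   mut_active = "VAR-active", mut_inactive = "VAR-inactive")
  traj <- list()
  for (cond in names(cond_labels)) {
    frames <- config$trajectories[[cond]]
    if (is.null(frames)) {
      traj[[cond]] <- list(status = "not run",
                           reason = "no trajectory provided")
      next
    }
    ser <- bridgeTimeSeries(frames, config$chainA, config$chainB, ac,
                            saveInterval = config$protocol@saveInterval,
                            sourceLabel = cond_labels[[cond]])
    nf_exp <- expectedFrames(config$protocol)
    if (length(ser@counts) != nf_exp)
      note(sprintf("%s: %d frames, protocol expects %d", cond,
                   length(ser@counts), nf_exp))
    traj[[cond]] <- list(status = "ok", series = ser,
                         summary = summarizeSeries(
                           ser, blockLen = min(5L, length(ser@counts)),
                           seed = config$seed))
  }

  comparisons <- list()
  for (state in c("active", "inactive")) {
    a <- traj[[paste0("mut_", state)]]
    b <- traj[[paste0("wt_", state)]]
    key <- paste0("mut_vs_wt_", state)
    if (identical(a$status, "ok") && identical(b$status, "ok")) {
      comparisons[[key]] <- compareStates(a$series, b$series,
                                          seed = config$seed)
    } else {
      comparisons[[key]] <- list(status = "not run",
                                 reason = "both trajectories required")
    }
  }

  bundle <- list(
    provenance = list(
      mutation = unclass(config$mutation),
      analysis = .configProvenance(ac),
      enm = list(cutoff = 13, gamma = 1, epsilon = 0.5, wE = 1, wS = 1,
                 temperature = config$protocol@temperature),
      protocol = list(temperature = config$protocol@temperature,
                      pressure = config$protocol@pressure,
                      timestep_fs = config$protocol@timestep,
                      production_ns = config$protocol@production,
                      save_interval_ns = config$protocol@saveInterval,
                      expected_frames = expectedFrames(config$protocol)),
      chains = c(config$chainA, config$chainB),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("dimerstab"))),
    states = states,
    trajectories = traj,
    comparisons = comparisons,
    warnings = warnings_log)
  class(bundle) <- "ReportBundle"
  if (!is.null(config$outputDir)) writeReportBundle(bundle, config$outputDir)
  bundle
}

# Machine-readable rendering of a bundle (plain lists / vectors only).
.bundleAsList <- function(bundle) {
  conv_state <- function(st) {
    if (!identical(st$status, "ok")) return(st)
    s <- st$stability
    list(status = "ok",
         interface = st$interface,
         bridges = st$bridges,
         hbond_diff = lapply(st$hbond_diff, as.character),
         clash_score = st$clash_score,
         stability = list(state = s@stateLabel, ddg_proxy = s@ddgProxy,
                          dds_vib = s@ddsVib,
                          delta_contacts = s@deltaContacts,
                          per_residue_dds = as.list(s@perResidueDds)))
  }
  conv_traj <- function(tr) {
    if (!identical(tr$status, "ok")) return(tr)
    list(status = "ok",
         label = tr$series@sourceLabel,
         metric = tr$series@metric,
         time_ns = tr$series@frameTimes,
         counts = tr$series@counts,
         mean = tr$summary$mean, sd = tr$summary$sd,
         ci95 = tr$summary$ci95)
  }
  list(provenance = bundle$provenance,
       states = lapply(bundle$states, conv_state),
       trajectories = lapply(bundle$trajectories, conv_traj),
       comparisons = bundle$comparisons,
       warnings = as.list(bundle$warnings))
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (machine-readable, byte-stable for a fixed
#' configuration and seed), `report.txt` (human-readable summary built
#' from the same numbers), per-state per-residue entropy TSVs and
#' per-condition bridge series TSVs.
#'
#' @param bundle result of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(.bundleAsList(bundle), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, null = "null")
  writeLines(json, file.path(dir, "report.json"))

  txt <- c("dimer interface stability report", "")
  for (state in names(bundle$states)) {
    st <- bundle$states[[state]]
    if (!identical(st$status, "ok")) {
      txt <- c(txt, sprintf("[%s] not run: %s", state, st$reason))
      next
    }
    s <- st$stability
    txt <- c(txt,
             sprintf("[%s] mutation site %s on interface: %s", state,
                     st$interface$mutation_site,
                     st$interface$site_on_interface),
             sprintf("[%s] bridges (%s): WT %d -> variant %d", state,
                     s@params$bridge_metric, st$bridges$wt, st$bridges$mut),
             sprintf("[%s] hbond diff: %d conserved, %d added, %d removed",
                     state, length(st$hbond_diff$conserved),
                     length(st$hbond_diff$added),
                     length(st$hbond_diff$removed)),
             sprintf("[%s] ddG proxy %+.4f kcal/mol, ddS_vib %+.4f cal/(mol K)",
                     state, s@ddgProxy, s@ddsVib))
    pr <- data.frame(residue = names(s@perResidueDds),
                     dds_vib = as.numeric(s@perResidueDds))
    utils::write.table(pr, file.path(dir, sprintf("per_residue_dds_%s.tsv",
                                                  state)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cond in names(bundle$trajectories)) {
    tr <- bundle$trajectories[[cond]]
    if (!identical(tr$status, "ok")) {
      txt <- c(txt, sprintf("[traj %s] not run: %s", cond, tr$reason))
      next
    }
    txt <- c(txt, sprintf("[traj %s] mean %.2f (sd %.2f) over %d frames",
                          cond, tr$summary$mean, tr$summary$sd,
                          length(tr$series@counts)))
    writeSeriesTSV(tr$series, file.path(dir, sprintf("series_%s.tsv", cond)))
  }
  for (key in names(bundle$comparisons)) {
    cp <- bundle$comparisons[[key]]
    if (!is.null(cp$meanDiff))
      txt <- c(txt, sprintf("[compare %s] mean diff %+.3f, 95%% CI [%.3f, %.3f]",
                            key, cp$meanDiff, cp$ci95[1L], cp$ci95[2L]))
  }
  if (length(bundle$warnings))
    txt <- c(txt, "", "warnings:", paste(" -", bundle$warnings))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
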