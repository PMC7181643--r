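# Configuration, seeding and the end-to-end scenario runner tying
# clock -> dynamics -> poolseq -> inference. Units are fixed: days, mM
# glutamate-equivalents, cells (whole culture) and mL.

scenarioNames <- c("single_culture", "coculture", "subculture_split",
                   "pulse_feeding", "full_experiment")

#' Default run configuration
#'
#' Every parameter defaults to the study condition: 10-mL cultures starved
#' at 1e6 cells/mL, 0.1% mutant contamination for co-cultures, six
#' subcultures of 1e7 cells, 1000 colonies in pools of 100 at 5000x in
#' duplicate, a 0.1% calling floor, and twice-daily 20-uM pulses.
#'
#' @param scenario one of `"single_culture"`, `"coculture"`,
#'   `"subculture_split"`, `"pulse_feeding"`, `"full_experiment"`.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(scenario = "full_experiment") {
  scenario <- match.arg(scenario, scenarioNames)
  list(
    scenario = scenario,
    seed = 1L,
    clock = list(mu_growth = 2e-10, genome_length = 1.257e7,
                 lambda_q = 0.6 / 90),
    catalog = list(include_pmc1 = FALSE),
    dynamics = list(days = 90, n0 = 1e7, volume = 10, dt = 0.5,
                    mutant_profile = "sapk_delay", mutant_fraction = 0.001,
                    engage_threshold = 0.03, complete_requirement = 0.105,
                    recycling_efficiency = 1),
    split = list(n_sub = 6L, cells_per_sub = 1e7, days = 60,
                 growth_generations = 27, gasp_effect_prob = 0.01,
                 expansion_onset = 21),
    pulses = list(amount = 0.020, per_day = 2L, days = 5),
    poolseq = list(n_colonies = 1000L, pool_size = 100L, coverage = 5000L,
                   seq_error = 2e-4, pcr_errors_per_batch = 3,
                   min_freq = 0.001, min_depth = 5000L)
  )
}

checkKnownKeys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(cfg[[k]])) {
      if (!is.list(cfg[[k]])) stop("config key ", path, k, " must be a block",
                                   call. = FALSE)
      checkKnownKeys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      mergeConfig(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML file (or accepts a list), fills defaults, rejects unknown
#' keys, and enforces cross-field constraints (non-negative seed, positive
#' durations and volumes, engage threshold not exceeding the completion
#' requirement, probabilities in range).
#'
#' @param config path to a YAML file, a list, or `NULL` (all defaults).
#' @param scenario default scenario when the config does not name one.
#' @return normalized configuration list.
#' @export
validateConfig <- function(config = NULL, scenario = "full_experiment") {
  cfg <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    out <- yaml::read_yaml(config)
    if (is.null(out)) list() else out
  } else if (is.list(config)) config
  else stop("config must be a path, a list, or NULL", call. = FALSE)
  base <- defaultRunConfig(if (!is.null(cfg$scenario)) cfg$scenario else
    scenario)
  checkKnownKeys(cfg, base)
  cfg <- mergeConfig(base, cfg)
  if (!cfg$scenario %in% scenarioNames) {
    stop("scenario must be one of: ", paste(scenarioNames, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$seed < 0) stop("seed must be non-negative", call. = FALSE)
  dyn <- cfg$dynamics
  for (k in c("days", "n0", "volume", "dt")) {
    if (dyn[[k]] <= 0) stop("dynamics.", k, " must be positive", call. = FALSE)
  }
  if (dyn$engage_threshold > dyn$complete_requirement) {
    stop("dynamics.engage_threshold must not exceed complete_requirement",
         call. = FALSE)
  }
  if (dyn$mutant_fraction < 0 || dyn$mutant_fraction >= 1) {
    stop("dynamics.mutant_fraction must be in [0, 1)", call. = FALSE)
  }
  ps <- cfg$poolseq
  if (ps$min_freq <= 0 || ps$min_freq > 1) {
    stop("poolseq.min_freq must be in (0, 1]", call. = FALSE)
  }
  cfg
}

pulseSchedule <- function(p) {
  times <- seq(0, p$days - 1 / p$per_day, by = 1 / p$per_day)
  data.frame(time = times, amount = p$amount)
}

#' Run a configured scenario end to end
#'
#' Executes the configured pipeline deterministically given the seed (one
#' master seed spawns per-stage substreams) and, when `outDir` is given,
#' writes tidy TSV artifacts plus a JSON provenance manifest (scenario,
#' seed, full parameter set, package version).
#'
#' `full_experiment` chains the stages of the resequencing design: starve a
#' culture, derive its survivor allele table, pick 1000 colonies, sequence
#' them in duplicate batches at day 1 and at the harvest day, call variants
#' and summarize the mutant fraction.
#'
#' @param config a configuration from \code{\link{validateConfig}} (paths
#'   and plain lists are validated first).
#' @param outDir optional output directory.
#' @return list of scenario outputs (trajectories, allele tables, read
#'   counts, calls, summaries; see the vignette).
#' @export
runScenario <- function(config = NULL, outDir = NULL) {
  cfg <- validateConfig(config)
  seed <- cfg$seed
  catalog <- defaultCatalog(includePmc1 = isTRUE(cfg$catalog$include_pmc1))
  clk <- clockParams(muGrowth = cfg$clock$mu_growth,
                     genomeLength = cfg$clock$genome_length,
                     lambdaQ = cfg$clock$lambda_q)
  dyn <- cfg$dynamics
  out <- switch(cfg$scenario,
    single_culture = {
      traj <- runSingleCulture("wild_type", days = dyn$days, n0 = dyn$n0,
                               volume = dyn$volume, dt = dyn$dt,
                               seed = childSeed(seed, "dynamics"))
      list(trajectory = traj, phases = segmentPhases(traj))
    },
    coculture = {
      traj <- runCoculture(dyn$mutant_profile,
                           mutantFraction = dyn$mutant_fraction,
                           days = dyn$days, n0 = dyn$n0,
                           volume = dyn$volume, dt = dyn$dt,
                           seed = childSeed(seed, "dynamics"))
      list(trajectory = traj,
           expansion = fitExpansion(traj, window = c(30, 60)))
    },
    pulse_feeding = {
      p <- cfg$pulses
      lab <- c("wild_type", "sapk_delay", "mapk")
      trajs <- lapply(seq_along(lab), function(i) {
        runPulseFeeding(lab[i], pulses = pulseSchedule(p), days = p$days,
                        seed = childSeed(seed, paste0("pulse", i)))
      })
      names(trajs) <- lab
      list(trajectories = trajs)
    },
    subculture_split = {
      sp <- cfg$split
      split <- runSubcultureSplit(nSub = sp$n_sub,
                                  cellsPerSub = sp$cells_per_sub,
                                  days = sp$days,
                                  growthGenerations = sp$growth_generations,
                                  params = clk, catalog = catalog,
                                  gaspEffectProb = sp$gasp_effect_prob,
                                  expansionOnset = sp$expansion_onset,
                                  recyclingEfficiency =
                                    dyn$recycling_efficiency,
                                  seed = childSeed(seed, "split"))
      ps <- cfg$poolseq
      callsPerSub <- lapply(seq_len(sp$n_sub), function(s) {
        sub <- split$alleles[split$alleles$subculture == s, , drop = FALSE]
        colonies <- sampleColonies(sub, n = ps$n_colonies,
                                   poolSize = ps$pool_size,
                                   seed = childSeed(seed, paste0("col", s)))
        reads <- simulateReads(colonies, alleleInfo = sub,
                               coverage = ps$coverage,
                               seqError = ps$seq_error,
                               pcrErrorsPerBatch = ps$pcr_errors_per_batch,
                               catalog = catalog,
                               seed = childSeed(seed, paste0("seq", s)))
        callVariants(reads, minFreq = ps$min_freq, minDepth = ps$min_depth,
                     hotspotRegistry = hotspots(catalog))
      })
      origin <- classifyOrigin(callsPerSub,
                               hotspotRegistry = hotspots(catalog))
      list(split = split, calls = callsPerSub, origin = origin,
           summaries = vapply(callsPerSub, summarizeCulture, numeric(1)))
    },
    full_experiment = {
      sp <- cfg$split
      culture <- runSubcultureSplit(nSub = 1L, cellsPerSub = sp$cells_per_sub,
                                    days = sp$days,
                                    growthGenerations = sp$growth_generations,
                                    params = clk, catalog = catalog,
                                    gaspEffectProb = sp$gasp_effect_prob,
                                    expansionOnset = sp$expansion_onset,
                                    recyclingEfficiency =
                                      dyn$recycling_efficiency,
                                    seed = childSeed(seed, "culture"))
      ps <- cfg$poolseq
      # day 1: preexisting mutant cells only, none above the calling floor
      day1Freq <- stats::setNames(numeric(0), character(0))
      pre <- culture$truth[culture$truth$origin == "growth", , drop = FALSE]
      day1Colonies <- sampleColonies(day1Freq, n = ps$n_colonies,
                                     poolSize = ps$pool_size,
                                     seed = childSeed(seed, "col1"))
      day1Reads <- simulateReads(day1Colonies, coverage = ps$coverage,
                                 seqError = ps$seq_error,
                                 pcrErrorsPerBatch = ps$pcr_errors_per_batch,
                                 catalog = catalog,
                                 seed = childSeed(seed, "seq1"))
      day1Calls <- callVariants(day1Reads, minFreq = ps$min_freq,
                                minDepth = ps$min_depth,
                                hotspotRegistry = hotspots(catalog))
      sub <- culture$alleles
      colonies <- sampleColonies(sub, n = ps$n_colonies,
                                 poolSize = ps$pool_size,
                                 seed = childSeed(seed, "col60"))
      reads <- simulateReads(colonies, alleleInfo = sub,
                             coverage = ps$coverage,
                             seqError = ps$seq_error,
                             pcrErrorsPerBatch = ps$pcr_errors_per_batch,
                             catalog = catalog,
                             seed = childSeed(seed, "seq60"))
      calls <- callVariants(reads, minFreq = ps$min_freq,
                            minDepth = ps$min_depth,
                            hotspotRegistry = hotspots(catalog))
      list(culture = culture, day1_calls = day1Calls, reads = reads,
           calls = calls, mutant_fraction = summarizeCulture(calls),
           preexisting = pre)
    })
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeScenarioArtifacts(out, cfg, outDir)
  }
  out
}

writeScenarioArtifacts <- function(out, cfg, outDir) {
  manifest <- list(scenario = cfg$scenario, seed = cfg$seed, config = cfg,
                   package_version = as.character(utils::packageVersion(
                     "starveGASP")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeTab <- function(x, name) {
    utils::write.table(x, file.path(outDir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out$trajectory)) {
    writeTab(trajectoryTable(out$trajectory), "trajectory.tsv")
  }
  if (!is.null(out$trajectories)) {
    for (nm in names(out$trajectories)) {
      writeTab(trajectoryTable(out$trajectories[[nm]]),
               sprintf("trajectory_%s.tsv", nm))
    }
  }
  if (!is.null(out$split)) writeTab(out$split$alleles, "alleles.tsv")
  if (!is.null(out$culture)) writeTab(out$culture$alleles, "alleles.tsv")
  if (!is.null(out$calls)) {
    if (is.data.frame(out$calls)) writeTab(out$calls, "calls.tsv")
    else for (s in seq_along(out$calls)) {
      writeTab(out$calls[[s]], sprintf("calls_sub%d.tsv", s))
    }
  }
  if (!is.null(out$reads)) writeTab(out$reads, "read_counts.tsv")
  if (!is.null(out$origin)) writeTab(out$origin, "origin_calls.tsv")
  invisible(outDir)
}
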