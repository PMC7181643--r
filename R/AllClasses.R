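#' @import methods
NULL

EFFECT_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                    "inframe_indel", "silent")
MUTATION_TYPES <- c("SNV", "insertion", "deletion", "duplication")
PATHWAYS       <- c("SAPK", "MAPK", "DOWNSTREAM", "OTHER")
CELL_STATES    <- c("G0", "engaged", "dividing", "ghost", "dead")

# reference density (cells/mL) at which the glutamate thresholds were measured
REFERENCE_DENSITY <- 4e6

# replication-licensed cells switch to a high-affinity, higher-capacity
# nitrogen importer (imports go to biomass: mass rises without division)
ENGAGED_AFFINITY_FACTOR <- 10
ENGAGED_CAPACITY_FACTOR <- 3

# completion rate (per day) once the pool covers a full replication round
# for the whole culture AND reaches quiescence-exit concentrations:
# replete exit rather than trickle scavenging
FAST_EXIT_RATE <- 3
FAST_EXIT_MIN <- 0.02

# rate (per day) at which a failed replication checkpoint resolves
CHECKPOINT_RATE <- 1

# above this concentration (mM) engaged cells stop futile assimilation:
# imports go to the replication round itself
ENGAGED_SOAK_MAX <- 0.1

#' Mutational target catalog
#'
#' Holds the genes of interest (name, length, pathway, tolerated effect
#' classes) and their hotspot sites (homonucleotide runs and direct repeats).
#' Coordinates are 1-based within each gene; there is no strand handling
#' because the readout is amplicon-level.
#'
#' @slot genes data.frame with columns `gene`, `length`, `pathway`,
#'   `tolerated_effects` (comma-separated effect classes).
#' @slot hotspots data.frame with columns `gene`, `position`, `kind`
#'   (`homonucleotide_run` or `direct_repeat`), `unit_length`,
#'   `run_or_repeat_count`, `rate_multiplier`.
#' @export
setClass("TargetCatalog",
         representation(genes = "data.frame", hotspots = "data.frame"))

setValidity("TargetCatalog", function(object) {
  g <- object@genes
  h <- object@hotspots
  msgs <- character()
  need <- c("gene", "length", "pathway", "tolerated_effects")
  if (!all(need %in% names(g))) {
    return(paste("genes must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(g$gene)) msgs <- c(msgs, "duplicate gene names")
  if (any(g$length <= 0)) msgs <- c(msgs, "gene lengths must be positive")
  if (!all(g$pathway %in% PATHWAYS)) {
    msgs <- c(msgs, paste("pathway must be one of", paste(PATHWAYS, collapse = ", ")))
  }
  for (i in seq_len(nrow(g))) {
    eff <- strsplit(g$tolerated_effects[i], ",", fixed = TRUE)[[1]]
    eff <- trimws(eff)
    if (!all(eff %in% EFFECT_CLASSES)) {
      msgs <- c(msgs, sprintf("gene %s: unknown effect class", g$gene[i]))
    }
    # quiescence constraint: SAPK function cannot be fully eliminated, so
    # loss-of-function classes are not tolerated in SAPK genes except win1
    # (whose loss is buffered by the paralogous MAPKKK)
    if (g$pathway[i] == "SAPK" && g$gene[i] != "win1" &&
        any(c("nonsense", "frameshift_indel") %in% eff)) {
      msgs <- c(msgs, sprintf(
        "SAPK gene %s (non-win1) must not tolerate nonsense/frameshift_indel",
        g$gene[i]))
    }
  }
  if (nrow(h)) {
    needh <- c("gene", "position", "kind", "unit_length",
               "run_or_repeat_count", "rate_multiplier")
    if (!all(needh %in% names(h))) {
      return(paste("hotspots must have columns:", paste(needh, collapse = ", ")))
    }
    if (!all(h$gene %in% g$gene)) msgs <- c(msgs, "hotspot in unknown gene")
    if (!all(h$kind %in% c("homonucleotide_run", "direct_repeat"))) {
      msgs <- c(msgs, "hotspot kind must be homonucleotide_run or direct_repeat")
    }
    if (any(h$rate_multiplier < 1)) msgs <- c(msgs, "rate_multiplier must be >= 1")
    if (any(h$kind == "homonucleotide_run" & h$unit_length != 1L)) {
      msgs <- c(msgs, "homonucleotide_run hotspots must have unit_length 1")
    }
    len <- g$length[match(h$gene, g$gene)]
    if (any(h$position < 1 | h$position > len, na.rm = TRUE)) {
      msgs <- c(msgs, "hotspot positions must lie within [1, gene length]")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Mutation clock parameters
#'
#' Rates and spectra for the two mutational regimes: replication-coupled
#' mutagenesis during growth and the time-linear accumulation in quiescence
#' (indels about as frequent as SNVs, deletions dominating insertions).
#'
#' @slot muGrowth mutations per nucleotide per generation.
#' @slot genomeLength nucleotides.
#' @slot lambdaQ mutations per genome per day in quiescence.
#' @slot spectrumGrowth,spectrumQuiescence named probability vectors over
#'   mutation types (`SNV`, `insertion`, `deletion`, `duplication`).
#' @slot targetFraction probability that a mutation falls in the catalog
#'   genes (`NA` means: compute from catalog length / genome length).
#' @slot snvEffectProbs named probabilities for `missense`, `nonsense`,
#'   `silent` given an SNV in a gene.
#' @slot indelSizeP geometric parameter for indel sizes (size = 1 + Geom).
#' @export
setClass("ClockParams",
         representation(muGrowth = "numeric", genomeLength = "numeric",
                        lambdaQ = "numeric", spectrumGrowth = "numeric",
                        spectrumQuiescence = "numeric",
                        targetFraction = "numeric",
                        snvEffectProbs = "numeric", indelSizeP = "numeric"))

setValidity("ClockParams", function(object) {
  msgs <- character()
  for (nm in c("muGrowth", "genomeLength", "lambdaQ")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0) msgs <- c(msgs, paste(nm, "must be >= 0"))
  }
  for (nm in c("spectrumGrowth", "spectrumQuiescence")) {
    s <- slot(object, nm)
    if (!all(MUTATION_TYPES %in% names(s)) || any(s < 0) ||
        abs(sum(s) - 1) > 1e-8) {
      msgs <- c(msgs, paste(nm, "must be a probability vector over mutation types"))
    }
  }
  s <- object@snvEffectProbs
  if (!all(c("missense", "nonsense", "silent") %in% names(s)) ||
      any(s < 0) || abs(sum(s) - 1) > 1e-8) {
    msgs <- c(msgs, "snvEffectProbs must be probabilities over missense/nonsense/silent")
  }
  tf <- object@targetFraction
  if (length(tf) != 1L || (!is.na(tf) && (tf < 0 || tf > 1))) {
    msgs <- c(msgs, "targetFraction must be in [0,1] or NA")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-class phenotype parameters for the starvation simulator
#'
#' @slot label class label.
#' @slot engageThreshold mM glutamate-equivalents (at the 4e6 cells/mL
#'   reference density) needed before G0 cells commit to S phase.
#' @slot completeRequirement mM per 4e6 cells/mL needed to carry one full
#'   replication round to completion.
#' @slot pDeathOnAbort probability an engaged cell that cannot complete
#'   replication becomes a ghost at each attempt.
#' @slot entryDelay days between first perceiving trace nitrogen and
#'   responding to it.
#' @slot basalDeath data.frame (`start`, `rate`): piecewise-constant basal
#'   death rate per day, calibrated to the three viability phases.
#' @slot doublingTime days per division once nitrogen suffices.
#' @slot engageRate per-day rate at which eligible G0 cells engage.
#' @export
setClass("PhenotypeParams",
         representation(label = "character", engageThreshold = "numeric",
                        completeRequirement = "numeric",
                        pDeathOnAbort = "numeric", entryDelay = "numeric",
                        basalDeath = "data.frame", doublingTime = "numeric",
                        engageRate = "numeric"))

setValidity("PhenotypeParams", function(object) {
  msgs <- character()
  if (object@pDeathOnAbort < 0 || object@pDeathOnAbort > 1) {
    msgs <- c(msgs, "pDeathOnAbort must be in [0,1]")
  }
  if (object@engageThreshold < 0 || object@completeRequirement < 0) {
    msgs <- c(msgs, "thresholds must be >= 0")
  }
  if (object@engageThreshold > object@completeRequirement) {
    msgs <- c(msgs, "engageThreshold must not exceed completeRequirement")
  }
  bd <- object@basalDeath
  if (!all(c("start", "rate") %in% names(bd)) || any(bd$rate < 0) ||
      is.unsorted(bd$start)) {
    msgs <- c(msgs, "basalDeath must have sorted 'start' and non-negative 'rate'")
  }
  if (object@doublingTime <= 0) msgs <- c(msgs, "doublingTime must be > 0")
  if (object@entryDelay < 0) msgs <- c(msgs, "entryDelay must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Population state of a starved culture
#'
#' Cell counts are absolute (whole culture of `volume` mL); the nitrogen pool
#' is a concentration in mM glutamate-equivalents. The mass-balance identity
#' `nitrogen + cumulativeConsumed == initialNitrogen + cumulativeReleased +
#' cumulativeAdded` holds to accumulation tolerance at every step.
#'
#' @slot t days since quiescence entry.
#' @slot counts matrix (classes x states G0/engaged/dividing/ghost/dead).
#' @slot classes list of \linkS4class{PhenotypeParams}, one per row of counts.
#' @slot nitrogen,initialNitrogen mM.
#' @slot cumulativeReleased,cumulativeConsumed,cumulativeAdded mM.
#' @slot volume culture volume, mL.
#' @slot firstSignal per-class time (days) at which trace nitrogen was first
#'   perceived (`NA` if never); starts the entry-delay clock.
#' @slot divisions cumulative completed divisions (for the OD proxy).
#' @slot completed per-class cumulative completed divisions.
#' @slot rho nitrogen released per dead cell, mM*mL.
#' @slot uptakeVmax,uptakeKs Michaelis-Menten maintenance uptake parameters
#'   (mM*mL per cell per day; mM).
#' @export
setClass("PopulationState",
         representation(t = "numeric", counts = "matrix", classes = "list",
                        nitrogen = "numeric", initialNitrogen = "numeric",
                        cumulativeReleased = "numeric",
                        cumulativeConsumed = "numeric",
                        cumulativeAdded = "numeric", volume = "numeric",
                        firstSignal = "numeric", divisions = "numeric",
                        completed = "numeric", rho = "numeric",
                        uptakeVmax = "numeric", uptakeKs = "numeric"))

setValidity("PopulationState", function(object) {
  msgs <- character()
  if (any(object@counts < -1e-9)) msgs <- c(msgs, "all counts must be >= 0")
  if (!identical(colnames(object@counts), CELL_STATES)) {
    msgs <- c(msgs, paste("counts columns must be", paste(CELL_STATES, collapse = ", ")))
  }
  if (object@nitrogen < -1e-12) msgs <- c(msgs, "nitrogen must be >= 0")
  if (length(object@classes) != nrow(object@counts)) {
    msgs <- c(msgs, "one PhenotypeParams per counts row required")
  }
  bal <- object@nitrogen + object@cumulativeConsumed -
    (object@initialNitrogen + object@cumulativeReleased + object@cumulativeAdded)
  if (abs(bal) > 1e-9 * max(1, object@initialNitrogen + object@cumulativeAdded +
                              object@cumulativeReleased)) {
    msgs <- c(msgs, sprintf("nitrogen mass balance violated by %.3g mM", bal))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Colony-forming-unit trajectory of a simulated culture
#'
#' @slot times observation times, days.
#' @slot cfu matrix (times x classes) of colony-forming units (live cells:
#'   G0 + engaged + dividing; ghosts never form colonies).
#' @slot nitrogen mM pool at each observation.
#' @slot ghostFraction ghosts / (ghosts + live) at each observation.
#' @slot odProxy arbitrary mass-proxy units (monotone in biomass).
#' @slot finalState the \linkS4class{PopulationState} at the horizon.
#' @export
setClass("CFUTrajectory",
         representation(times = "numeric", cfu = "matrix",
                        nitrogen = "numeric", ghostFraction = "numeric",
                        odProxy = "numeric", finalState = "ANY"))

setValidity("CFUTrajectory", function(object) {
  if (nrow(object@cfu) != length(object@times)) {
    return("cfu must have one row per time point")
  }
  if (any(object@cfu < 0)) return("cfu must be >= 0")
  TRUE
})
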