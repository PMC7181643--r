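# Nutrient-recycling birth-death dynamics of nitrogen-starved cultures.
#
# One rule set produces all observed behaviors:
#  * wild-type commits to S phase only above its measured engagement
#    threshold (0.03 mM at 4e6 cells/mL), so in an unfed starved culture it
#    never engages and declines by its phase-calibrated basal death;
#  * S/MAPK mutants commit at trace nitrogen (the hypomorphic pathway lowers
#    the exit threshold), sty1-class mutants after a 3-day delay;
#  * completing a replication round requires the pool to cover the full
#    per-cell budget (0.105 mM per 4e6 cells/mL) of the class's engaged
#    cohort: a rare clone living off nitrogen recycled from dying
#    neighbours can afford it, a bulk population cannot;
#  * engaged cells that cannot complete abort; with a proficient MAPK
#    module the abort kills (ghost cells), mutants survive it;
#  * every death or ghost returns a configurable fraction of one division's
#    nitrogen to the pool; live cells clear traces by Michaelis-Menten
#    maintenance uptake.

#' Phenotype parameter constructor
#'
#' @param label class label.
#' @param engageThreshold mM (at the 4e6 cells/mL reference) to commit to
#'   S phase.
#' @param completeRequirement mM per 4e6 cells/mL for one full replication
#'   round.
#' @param pDeathOnAbort ghost probability per failed completion attempt.
#' @param entryDelay days between first trace-nitrogen signal and response.
#' @param basalDeath data.frame (`start`, `rate`): piecewise-constant death
#'   rate per day.
#' @param doublingTime days per division when nitrogen suffices.
#' @param engageRate per-day G0-to-engaged rate when gated open.
#' @return A \linkS4class{PhenotypeParams}.
#' @export
phenotypeParams <- function(label,
                            engageThreshold = 0.03,
                            completeRequirement = 0.105,
                            pDeathOnAbort = 0.9,
                            entryDelay = 0,
                            basalDeath = data.frame(start = 0, rate = 0),
                            doublingTime = 3,
                            engageRate = 2) {
  new("PhenotypeParams", label = label, engageThreshold = engageThreshold,
      completeRequirement = completeRequirement,
      pDeathOnAbort = pDeathOnAbort, entryDelay = entryDelay,
      basalDeath = basalDeath, doublingTime = doublingTime,
      engageRate = engageRate)
}

setMethod("show", "PhenotypeParams", function(object) {
  cat(sprintf(
    "PhenotypeParams '%s': engage>=%.3g mM, complete %.3g mM/4e6/mL, p(abort death)=%.2g, delay %g d, doubling %g d\n",
    object@label, object@engageThreshold, object@completeRequirement,
    object@pDeathOnAbort, object@entryDelay, object@doublingTime))
})

# basal death schedules calibrated so the wild-type CFU curve reproduces the
# three viability phases (maintenance to ~day 20, rapid decline to ~day 50,
# then stabilization) and SAPK-mutant single cultures decline to ~1% of the
# inoculum before plateauing
wtDeathSchedule   <- function() data.frame(start = c(0, 20, 50),
                                           rate = c(0.002, 0.14, 0.006))
sapkDeathSchedule <- function() data.frame(start = c(0, 3, 30),
                                           rate = c(0.010, 0.165, 0.002))

#' Built-in phenotype profiles
#'
#' The genotype-to-phenotype mapping: wild-type engages only at its measured
#' threshold and is killed (MAPK-mediated) when it aborts; SAPK hypomorphs
#' (win1/wis4/wis1/sty1 alleles) sense traces, sty1-class alleles delay
#' entry by 3 days, and they die fast in pure starvation (stress-sensitive)
#' but survive aborts; MAPK-module and downstream mutants (mkh1, pek1,
#' pmk1, sgf73, tif452) behave like wild-type in pure culture but are
#' protected against abort death.
#'
#' @param profile one of `"wild_type"`, `"sapk"`, `"sapk_delay"` (sty1-like),
#'   `"mapk"`.
#' @param label optional label override.
#' @return A \linkS4class{PhenotypeParams}.
#' @export
phenotypeProfile <- function(profile = c("wild_type", "sapk", "sapk_delay",
                                         "mapk"),
                             label = NULL) {
  profile <- match.arg(profile)
  p <- switch(profile,
    wild_type = phenotypeParams("wild_type", engageThreshold = 0.03,
                                pDeathOnAbort = 0.9, entryDelay = 0,
                                basalDeath = wtDeathSchedule()),
    sapk = phenotypeParams("sapk", engageThreshold = 1e-5,
                           pDeathOnAbort = 0, entryDelay = 0,
                           basalDeath = sapkDeathSchedule()),
    sapk_delay = phenotypeParams("sapk_delay", engageThreshold = 1e-5,
                                 pDeathOnAbort = 0, entryDelay = 3,
                                 basalDeath = sapkDeathSchedule()),
    mapk = phenotypeParams("mapk", engageThreshold = 1e-5,
                           pDeathOnAbort = 0, entryDelay = 0,
                           basalDeath = wtDeathSchedule()))
  if (!is.null(label)) p@label <- label
  p
}

#' Map a mutated gene to its phenotype profile
#'
#' @param gene gene name.
#' @param catalog A \linkS4class{TargetCatalog}.
#' @return profile name understood by \code{\link{phenotypeProfile}}.
#' @export
phenotypeForGene <- function(gene, catalog = defaultCatalog()) {
  g <- genes(catalog)
  pw <- g$pathway[match(gene, g$gene)]
  if (is.na(pw)) stop("unknown gene: ", gene, call. = FALSE)
  if (pw == "SAPK") {
    if (gene == "sty1") "sapk_delay" else "sapk"
  } else "mapk"
}

scheduleRate <- function(sched, t) {
  sched$rate[findInterval(t, sched$start)]
}

#' Initialize a population state
#'
#' @param classes list of \linkS4class{PhenotypeParams}.
#' @param n0 initial G0 cell counts (whole culture), one per class.
#' @param volume culture volume, mL.
#' @param nitrogen initial nitrogen pool, mM (0 for EMM-N).
#' @param rho nitrogen released per dead or ghost cell, mM*mL; default one
#'   division's budget (death recycles one division's worth of nitrogen).
#' @param uptakeVmax,uptakeKs Michaelis-Menten maintenance uptake.
#' @return A \linkS4class{PopulationState}.
#' @export
populationState <- function(classes, n0, volume = 10, nitrogen = 0,
                            rho = 0.105 / REFERENCE_DENSITY,
                            uptakeVmax = 5e-9, uptakeKs = 5e-4) {
  stopifnot(length(classes) == length(n0))
  counts <- matrix(0, nrow = length(classes), ncol = length(CELL_STATES),
                   dimnames = list(vapply(classes, function(c) c@label,
                                          character(1)), CELL_STATES))
  counts[, "G0"] <- n0
  new("PopulationState", t = 0, counts = counts, classes = classes,
      nitrogen = nitrogen, initialNitrogen = nitrogen,
      cumulativeReleased = 0, cumulativeConsumed = 0, cumulativeAdded = 0,
      volume = volume, firstSignal = rep(NA_real_, length(classes)),
      divisions = 0, completed = rep(0, length(classes)), rho = rho,
      uptakeVmax = uptakeVmax, uptakeKs = uptakeKs)
}

setMethod("show", "PopulationState", function(object) {
  live <- sum(object@counts[, c("G0", "engaged", "dividing")])
  cat(sprintf(
    "PopulationState at day %.1f: %d classes, %.3g live cells, %.3g ghosts, N=%.3g mM\n",
    object@t, nrow(object@counts), live, sum(object@counts[, "ghost"]),
    object@nitrogen))
})

#' Live (colony-forming) cells per class
#' @param state A \linkS4class{PopulationState}.
#' @export
liveCounts <- function(state) {
  rowSums(state@counts[, c("G0", "engaged", "dividing"), drop = FALSE])
}

#' Advance a population state by one time step
#'
#' Applies, in order: (1) basal death (binomial per class and state) with
#' nitrogen release; (2) maintenance uptake of the pool by live cells;
#' (3) nitrogen-gated G0-to-engaged transitions for classes past their entry
#' delay; (4) completion attempts at the class division rate - attempts
#' complete (consuming one per-cell budget each, capped by the pool) when
#' the pool covers the engaged cohort's full budget, otherwise they abort
#' and become ghosts with the class's abort-death probability; completed
#' divisions return two G0 daughters. Nitrogen mass balance is preserved
#' exactly.
#'
#' @param state A \linkS4class{PopulationState}.
#' @param dt step, days (> 0).
#' @param deterministic use mean-field (expected-value) updates instead of
#'   binomial sampling.
#' @param addNitrogen mM to add to the pool at the start of the step
#'   (pulse feeding).
#' @param consume if `FALSE`, uptake and replication consumption are
#'   switched off (used to verify unmetabolized accumulation).
#' @return the advanced \linkS4class{PopulationState}.
#' @export
stepPopulation <- function(state, dt, deterministic = FALSE,
                           addNitrogen = 0, consume = TRUE) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  cnt <- state@counts
  nC <- nrow(cnt)
  vol <- state@volume
  N <- state@nitrogen
  released <- 0; consumed <- 0
  if (addNitrogen > 0) {
    N <- N + addNitrogen
    state@cumulativeAdded <- state@cumulativeAdded + addNitrogen
  }
  # with consumption switched off the run verifies pure pulse accumulation:
  # no uptake, no stoichiometric cost, and no release crediting either
  rhoConc <- if (consume) state@rho / vol else 0   # mM per dead cell

  # (1) basal death of live states
  for (i in seq_len(nC)) {
    r <- scheduleRate(state@classes[[i]]@basalDeath, state@t)
    if (r <= 0) next
    p <- 1 - exp(-r * dt)
    for (st in c("G0", "engaged")) {
      d <- drawBinom(cnt[i, st], p, deterministic)
      cnt[i, st] <- cnt[i, st] - d
      cnt[i, "dead"] <- cnt[i, "dead"] + d
      released <- released + d * rhoConc
    }
  }
  N <- N + released

  # (2) nitrogen uptake (Michaelis-Menten per cell): quiescent G0 cells sip
  # at the maintenance affinity; replication-licensed (engaged) cells
  # switch to a high-affinity importer (same capacity, lower Ks) and
  # assimilate nitrogen into biomass whether or not they ever complete a
  # division (cultures gain mass without gaining cell number). Exponential
  # within-step decay, capped at the saturated import capacity.
  dG0 <- sum(cnt[, "G0"]) / vol
  dEng <- sum(cnt[, "engaged"]) / vol
  if (consume && N > 0 && (dG0 + dEng) > 0) {
    vmax <- state@uptakeVmax
    # futile assimilation by engaged cells operates under trickle
    # conditions only; at replete, quiescence-exit concentrations imports
    # are committed to the replication round (counted stoichiometrically)
    vmaxEng <- if (N < ENGAGED_SOAK_MAX) ENGAGED_CAPACITY_FACTOR * vmax
      else vmax
    rate <- dG0 * vmax / (state@uptakeKs + N) +
      dEng * vmaxEng / (state@uptakeKs / ENGAGED_AFFINITY_FACTOR + N)
    up <- min(N * (1 - exp(-rate * dt)),
              (dG0 * vmax + dEng * vmaxEng) * dt)
    N <- N - up
    consumed <- consumed + up
  }

  # (3) nitrogen-gated engagement: the threshold is a sensing concentration
  # (class-specific; wild-type commits only at its measured 0.03 mM)
  tNow <- state@t
  for (i in seq_len(nC)) {
    cl <- state@classes[[i]]
    gate <- max(cl@engageThreshold, 1e-12)
    if (N >= gate) {
      if (is.na(state@firstSignal[i])) state@firstSignal[i] <- tNow
      if (tNow >= state@firstSignal[i] + cl@entryDelay) {
        e <- drawBinom(cnt[i, "G0"], 1 - exp(-cl@engageRate * dt),
                       deterministic)
        cnt[i, "G0"] <- cnt[i, "G0"] - e
        cnt[i, "engaged"] <- cnt[i, "engaged"] + e
      }
    }
  }

  # (4) completion attempts / aborts
  costConc <- 0.105 / REFERENCE_DENSITY / vol  # mM per completed division
  cnt[, "dividing"] <- 0
  for (i in seq_len(nC)) {
    cl <- state@classes[[i]]
    if (cnt[i, "engaged"] <= 0) next
    # division attempt rate calibrated (Euler-Lotka for the two-stage
    # G0 -> engaged -> 2 G0 cycle) so the realized CFU doubling time in
    # exponential expansion equals doublingTime
    lam <- log(2) / cl@doublingTime
    kdiv <- lam * (cl@engageRate + lam) / max(cl@engageRate - lam, 1e-6)
    # cells that already completed their round (daughters) no longer add
    # to the replication demand of the class
    demandCells <- max(sum(cnt[i, c("G0", "engaged")]) -
                         2 * state@completed[i], cnt[i, "engaged"])
    # under nutrient-replete conditions (pool covers one replication round
    # for every demanding cell) division is a quiescence exit, not trickle
    # scavenging: cells complete at the fast exit rate
    bulkNeed <- cl@completeRequirement * (demandCells / vol) /
      REFERENCE_DENSITY
    if (N >= bulkNeed && N >= FAST_EXIT_MIN) kdiv <- max(kdiv, FAST_EXIT_RATE)
    # checkpoint-proficient cells (abort kills: pDeathOnAbort > 0) complete
    # a round only when the pool could have supported the whole cohort that
    # engaged - failed (ghost) cells count, which is what the bulk
    # completion measurement captures; checkpoint-deficient scavengers
    # commit cell by cell, so their gate scales with the engaged cohort
    gateDensity <- if (cl@pDeathOnAbort > 0) {
      demandCells + cnt[i, "ghost"]
    } else cnt[i, "engaged"]
    cohortNeed <- cl@completeRequirement *
      (gateDensity / vol) / REFERENCE_DENSITY
    # a failed checkpoint resolves on the S-phase timescale, faster than
    # the scavenging division cycle
    if (N < cohortNeed && cl@pDeathOnAbort > 0) {
      kdiv <- max(kdiv, CHECKPOINT_RATE)
    }
    attempts <- drawBinom(cnt[i, "engaged"], 1 - exp(-kdiv * dt),
                          deterministic)
    if (attempts <= 0) next
    afford <- if (consume) floor(N / costConc) else Inf
    if (N >= cohortNeed && afford >= 1) {
      comp <- min(attempts, afford)
      use <- if (consume) comp * costConc else 0
      N <- N - use
      consumed <- consumed + use
      # division completes within the step: the mother leaves the engaged
      # pool and two G0 daughters appear ("dividing" stays a transient
      # bookkeeping state so CFU = G0 + engaged + dividing never
      # double-counts)
      cnt[i, "engaged"] <- cnt[i, "engaged"] - comp
      cnt[i, "G0"] <- cnt[i, "G0"] + 2 * comp
      state@divisions <- state@divisions + comp
      state@completed[i] <- state@completed[i] + comp
      rest <- attempts - comp
      if (rest > 0) {
        gh <- drawBinom(rest, cl@pDeathOnAbort, deterministic)
        cnt[i, "engaged"] <- cnt[i, "engaged"] - gh
        cnt[i, "ghost"] <- cnt[i, "ghost"] + gh
        released <- released + gh * rhoConc
        N <- N + gh * rhoConc
      }
    } else {
      gh <- drawBinom(attempts, cl@pDeathOnAbort, deterministic)
      cnt[i, "engaged"] <- cnt[i, "engaged"] - gh
      cnt[i, "ghost"] <- cnt[i, "ghost"] + gh
      released <- released + gh * rhoConc
      N <- N + gh * rhoConc
    }
  }

  state@counts <- cnt
  state@nitrogen <- N
  state@cumulativeReleased <- state@cumulativeReleased + released
  state@cumulativeConsumed <- state@cumulativeConsumed + consumed
  state@t <- state@t + dt
  state
}

buildTrajectory <- function(states, classes) {
  labels <- vapply(classes, function(c) c@label, character(1))
  times <- vapply(states, function(s) s@t, numeric(1))
  cfu <- t(vapply(states, function(s) {
    rowSums(s@counts[, c("G0", "engaged", "dividing"), drop = FALSE])
  }, numeric(length(labels))))
  if (length(labels) == 1L) cfu <- matrix(cfu, ncol = 1L)
  colnames(cfu) <- labels
  nit <- vapply(states, function(s) s@nitrogen, numeric(1))
  ghost <- vapply(states, function(s) {
    g <- sum(s@counts[, "ghost"])
    l <- sum(s@counts[, c("G0", "engaged", "dividing")])
    if (g + l == 0) 0 else g / (g + l)
  }, numeric(1))
  # mass proxy: every cell ever made keeps its mass (ghosts and corpses
  # included) and assimilated nitrogen adds biomass even without division
  costCell <- 0.105 / REFERENCE_DENSITY  # mM*mL per cell-division budget
  od <- vapply(states, function(s) {
    sum(s@counts) + s@cumulativeConsumed * s@volume / costCell
  }, numeric(1))
  new("CFUTrajectory", times = times, cfu = cfu, nitrogen = nit,
      ghostFraction = ghost, odProxy = od,
      finalState = states[[length(states)]])
}

setMethod("show", "CFUTrajectory", function(object) {
  cat(sprintf("CFUTrajectory: %d time points over %.0f days, classes: %s\n",
              length(object@times), max(object@times),
              paste(colnames(object@cfu), collapse = ", ")))
})

#' @describeIn CFUTrajectory observation times (days)
#' @param x A `CFUTrajectory`.
#' @export
trajectoryTimes <- function(x) x@times

#' @describeIn CFUTrajectory CFU matrix (times x classes)
#' @export
cfu <- function(x) x@cfu

#' @describeIn CFUTrajectory nitrogen pool series (mM)
#' @export
nitrogenSeries <- function(x) x@nitrogen

#' @describeIn CFUTrajectory ghost fraction series
#' @export
ghostFraction <- function(x) x@ghostFraction

#' Tidy data.frame export of a trajectory
#' @param trajectory A \linkS4class{CFUTrajectory}.
#' @return data.frame with columns time, class, cfu, nitrogen,
#'   ghost_fraction, od_proxy.
#' @export
trajectoryTable <- function(trajectory) {
  cl <- colnames(trajectory@cfu)
  do.call(rbind, lapply(seq_along(cl), function(j) {
    data.frame(time = trajectory@times, class = cl[j],
               cfu = trajectory@cfu[, j], nitrogen = trajectory@nitrogen,
               ghost_fraction = trajectory@ghostFraction,
               od_proxy = trajectory@odProxy, stringsAsFactors = FALSE)
  }))
}

runCulture <- function(state, days, dt = 0.5, obsInterval = 1,
                       deterministic = FALSE, seed = NULL,
                       pulses = NULL, consume = TRUE,
                       refreshEvery = NULL) {
  withSeed(seed, {
    states <- list(state)
    obsTimes <- state@t
    nextObs <- state@t + obsInterval
    nextRefresh <- if (is.null(refreshEvery)) Inf else refreshEvery
    pulseGiven <- if (is.null(pulses)) logical(0) else logical(nrow(pulses))
    while (state@t < days - 1e-9) {
      if (state@t >= nextRefresh - 1e-9) {
        # medium refresh: the accumulated pool is discarded with the spent
        # medium (booked as consumed so mass balance holds)
        state@cumulativeConsumed <- state@cumulativeConsumed + state@nitrogen
        state@nitrogen <- 0
        nextRefresh <- nextRefresh + refreshEvery
      }
      add <- 0
      if (!is.null(pulses)) {
        due <- which(!pulseGiven & pulses$time <= state@t + 1e-9)
        if (length(due)) {
          add <- sum(pulses$amount[due])
          pulseGiven[due] <- TRUE
        }
      }
      state <- stepPopulation(state, dt, deterministic = deterministic,
                              addNitrogen = add, consume = consume)
      if (state@t >= nextObs - 1e-9 || state@t >= days - 1e-9) {
        states[[length(states) + 1L]] <- state
        nextObs <- nextObs + obsInterval
      }
    }
    buildTrajectory(states, state@classes)
  })
}

#' Simulate a single-genotype starved culture
#'
#' Default calibration: a wild-type culture holds a ~20-day plateau
#' (phase I), declines rapidly (phase II) and stabilizes around day 50
#' (phase III); SAPK-mutant cultures decline to roughly 1\% of the inoculum
#' and plateau; MAPK-module and sgf73-class cultures track wild-type.
#'
#' @param class A \linkS4class{PhenotypeParams} or profile name.
#' @param days horizon (> 0).
#' @param n0 inoculum, cells (default 1e7 = 1e6/mL in 10 mL).
#' @param volume mL.
#' @param dt step, days.
#' @param obsInterval days between recorded points.
#' @param deterministic mean-field mode.
#' @param rho nitrogen released per dead cell, mM*mL.
#' @param refreshEvery if set, the medium is replaced every this many days:
#'   the accumulated nitrogen pool is discarded, strongly suppressing
#'   recycling-driven expansion (the trickle released between refreshes
#'   remains available).
#' @param seed optional seed.
#' @return A \linkS4class{CFUTrajectory}.
#' @export
runSingleCulture <- function(class = "wild_type", days = 90, n0 = 1e7,
                             volume = 10, dt = 0.5, obsInterval = 1,
                             deterministic = FALSE,
                             rho = 0.105 / REFERENCE_DENSITY,
                             refreshEvery = NULL, seed = NULL) {
  stopifnotScalar(days, "days", min = 1e-9)
  if (is.character(class)) class <- phenotypeProfile(class)
  st <- populationState(list(class), n0, volume = volume, rho = rho)
  runCulture(st, days, dt = dt, obsInterval = obsInterval,
             deterministic = deterministic, seed = seed,
             refreshEvery = refreshEvery)
}

#' Simulate a wild-type/mutant co-culture (GASP assay)
#'
#' 99.9\% wild-type contaminated with 0.1\% marked mutant at day 1 of
#' quiescence. The mutant first dies with single-culture kinetics; once
#' wild-type deaths release trace nitrogen (around days 20-30) it engages
#' replication and expands exponentially at its configured doubling time,
#' exceeding its inoculum - and, for SAPK mutants, the wild-type - by about
#' two months.
#'
#' @param mutant A \linkS4class{PhenotypeParams} or profile name.
#' @param mutantFraction initial mutant fraction (0 < f < 1; 0 degenerates
#'   to a pure wild-type culture).
#' @param wt wild-type \linkS4class{PhenotypeParams}.
#' @inheritParams runSingleCulture
#' @return A \linkS4class{CFUTrajectory} with classes `wild_type` and the
#'   mutant label.
#' @export
runCoculture <- function(mutant = "sapk", mutantFraction = 0.001, days = 90,
                         n0 = 1e7, volume = 10, dt = 0.5, obsInterval = 1,
                         deterministic = FALSE,
                         wt = phenotypeProfile("wild_type"),
                         rho = 0.105 / REFERENCE_DENSITY,
                         refreshEvery = NULL, seed = NULL) {
  if (mutantFraction < 0 || mutantFraction >= 1) {
    stop("mutantFraction must be in [0, 1)", call. = FALSE)
  }
  if (is.character(mutant)) mutant <- phenotypeProfile(mutant)
  if (mutantFraction == 0) {
    return(runSingleCulture(wt, days = days, n0 = n0, volume = volume,
                            dt = dt, obsInterval = obsInterval,
                            deterministic = deterministic, rho = rho,
                            refreshEvery = refreshEvery, seed = seed))
  }
  nMut <- round(n0 * mutantFraction)
  st <- populationState(list(wt, mutant), c(n0 - nMut, nMut),
                        volume = volume, rho = rho)
  runCulture(st, days, dt = dt, obsInterval = obsInterval,
             deterministic = deterministic, seed = seed,
             refreshEvery = refreshEvery)
}

#' Simulate trace-nitrogen pulse feeding of a quiescent culture
#'
#' Mimics the twice-daily glutamate additions (20 uM each, at most 200 uM
#' after 10 additions if nothing is metabolized) given to 3-day-old
#' quiescent cultures at 4e6 cells/mL. With consumption enabled, wild-type
#' cells engage replication once the pool crosses their threshold, cannot
#' complete, and are progressively killed (rising ghost fraction, falling
#' CFU) while their mass proxy still rises; abort-protected mutants retain
#' CFU; sty1-class mutants delay engagement by their entry delay.
#'
#' @param class A \linkS4class{PhenotypeParams} or profile name.
#' @param pulses data.frame with columns `time` (days) and `amount` (mM);
#'   default: 20 uM twice a day for 5 days.
#' @param consume if `FALSE`, nitrogen is only added, never consumed (the
#'   pool then equals the cumulative pulse sum).
#' @param days horizon.
#' @param n0 cells (default 4e7 = 4e6/mL in 10 mL).
#' @inheritParams runSingleCulture
#' @return A \linkS4class{CFUTrajectory}.
#' @export
runPulseFeeding <- function(class = "wild_type",
                            pulses = data.frame(time = seq(0, 3, by = 0.5),
                                                amount = 0.020),
                            consume = TRUE, days = 4.5, n0 = 4e7, volume = 10,
                            dt = 0.5, obsInterval = 0.5,
                            deterministic = FALSE,
                            rho = 0.105 / REFERENCE_DENSITY, seed = NULL) {
  if (any(pulses$amount < 0)) stop("pulse amounts must be >= 0", call. = FALSE)
  if (is.character(class)) class <- phenotypeProfile(class)
  st <- populationState(list(class), n0, volume = volume, rho = rho)
  runCulture(st, days, dt = dt, obsInterval = obsInterval,
             deterministic = deterministic, seed = seed, pulses = pulses,
             consume = consume)
}

#' Replication capacity of a cell population at a nitrogen concentration
#'
#' Thresholds measured at 4e6 wild-type cells per mL (engage the first
#' S phase: 0.03 mM; complete one replication round: 0.09-0.12 mM, midpoint
#' 0.105) scale linearly with cell density.
#'
#' @param cellsPerMl cell density (> 0).
#' @param conc mM glutamate-equivalents.
#' @param engageThreshold,completeRequirement reference-density thresholds.
#' @return `"none"`, `"engage_only"` or `"complete"`.
#' @examples
#' nitrogenBudget(4e6, 0.02)  # "none"
#' nitrogenBudget(4e6, 0.12)  # "complete"
#' nitrogenBudget(8e6, 0.12)  # "engage_only" (budgets double with density)
#' @export
nitrogenBudget <- function(cellsPerMl, conc, engageThreshold = 0.03,
                           completeRequirement = 0.105) {
  stopifnotScalar(cellsPerMl, "cellsPerMl", min = 1e-12)
  stopifnotScalar(conc, "conc", min = 0)
  scale <- cellsPerMl / REFERENCE_DENSITY
  if (conc < engageThreshold * scale) "none"
  else if (conc < completeRequirement * scale) "engage_only"
  else "complete"
}
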