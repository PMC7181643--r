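test_that("a step with no nitrogen and no death changes only time", {
  cl <- phenotypeParams("idle", basalDeath = data.frame(start = 0, rate = 0))
  st <- populationState(list(cl), 1e6)
  st2 <- stepPopulation(st, 0.5)
  expect_equal(st2@t, 0.5)
  expect_equal(st2@counts, st@counts)
  expect_equal(st2@nitrogen, 0)
  expect_error(stepPopulation(st, 0), "positive")
  expect_error(stepPopulation(st, -1), "positive")
})

test_that("nitrogen mass balance holds over thousands of random steps", {
  set.seed(314)
  classes <- list(phenotypeProfile("wild_type"), phenotypeProfile("sapk"),
                  phenotypeProfile("mapk"))
  st <- populationState(classes, c(5e5, 3e5, 2e5), nitrogen = 0.01)
  for (i in 1:2000) {
    st <- stepPopulation(st, dt = runif(1, 0.1, 1),
                         addNitrogen = rbinom(1, 1, 0.05) * runif(1, 0, 0.05))
    bal <- st@nitrogen + st@cumulativeConsumed -
      (st@initialNitrogen + st@cumulativeReleased + st@cumulativeAdded)
    expect_lt(abs(bal), 1e-9)
  }
  expect_true(validObject(st))
})

test_that("a sub-completion nitrogen pulse ghosts engaged wild-type cells", {
  wt <- phenotypeProfile("wild_type")
  wt@basalDeath <- data.frame(start = 0, rate = 0)
  st <- populationState(list(wt), 4e7, nitrogen = 0)
  # hold the pool above the engage threshold but below the completion budget
  for (i in 1:10) {
    st <- stepPopulation(st, 0.5, addNitrogen = max(0, 0.05 - st@nitrogen))
  }
  expect_gt(st@counts[1, "ghost"], 0)
  expect_equal(st@counts[1, "dead"], 0)
  expect_lt(sum(st@counts[1, c("G0", "engaged", "dividing")]), 4e7)
})

test_that("wild-type cultures show the three viability phases", {
  wt <- runSingleCulture("wild_type", days = 90, seed = 1)
  seg <- segmentPhases(wt)
  expect_false(seg$degenerate)
  expect_lt(abs(seg$breakpoints[1] - 20), 3)
  expect_lt(abs(seg$breakpoints[2] - 50), 6)
  expect_lt(seg$slopes["II"], seg$slopes["I"])
  expect_lt(seg$slopes["II"], seg$slopes["III"])
  final <- sum(cfu(wt)[nrow(cfu(wt)), ]) / 1e7
  expect_gt(final, 0.004); expect_lt(final, 0.03)
})

test_that("SAPK mutant cultures plateau near 1% while MAPK-class track wild-type", {
  sa <- runSingleCulture("sapk_delay", days = 90, seed = 2)
  fr <- sum(cfu(sa)[nrow(cfu(sa)), ]) / 1e7
  expect_gt(fr, 0.005); expect_lt(fr, 0.02)
  # plateau: little change between day 45 and day 90
  tms <- trajectoryTimes(sa)
  expect_lt(abs(log10(sum(cfu(sa)[tms == 90, ]) /
                        sum(cfu(sa)[tms == 45, ]))), 0.3)
  mk <- runSingleCulture("mapk", days = 90, seed = 3)
  wt <- runSingleCulture("wild_type", days = 90, seed = 3)
  frM <- sum(cfu(mk)[nrow(cfu(mk)), ]) / 1e7
  frW <- sum(cfu(wt)[nrow(cfu(wt)), ]) / 1e7
  expect_lt(abs(log10(frM / frW)), 0.3)
})

test_that("co-cultured mutants decline, then expand past their inoculum", {
  co <- runCoculture("sapk_delay", mutantFraction = 0.001, days = 90,
                     seed = 4)
  tms <- trajectoryTimes(co)
  m <- cfu(co)[, "sapk_delay"]
  expect_lt(m[tms == 20], m[tms == 0])        # early death like singles
  expect_gt(m[tms == 40], m[tms == 30])       # expansion under way
  expect_gt(m[tms == 60], m[tms == 0])        # exceeds the inoculum
  expect_gt(m[tms == 60], cfu(co)[tms == 60, "wild_type"])  # takeover
  fit <- fitExpansion(co, window = c(30, 60))
  expect_lt(abs(fit$doubling_time - 3) / 3, 0.15)
  # degenerate fraction: pure wild-type culture
  co0 <- runCoculture("sapk_delay", mutantFraction = 0, days = 70, seed = 5)
  expect_equal(colnames(cfu(co0)), "wild_type")
})

test_that("without nitrogen recycling no class ever expands", {
  co <- runCoculture("sapk_delay", mutantFraction = 0.001, days = 90,
                     rho = 0, seed = 6)
  for (j in seq_len(ncol(cfu(co)))) {
    expect_true(all(diff(cfu(co)[, j]) <= 0))
  }
  expect_equal(max(nitrogenSeries(co)), 0)
})

test_that("raising the abort-death probability never helps wild-type survival", {
  surv <- vapply(c(0.2, 0.6, 0.9), function(p) {
    wt <- phenotypeProfile("wild_type")
    wt@pDeathOnAbort <- p
    tr <- runPulseFeeding(wt, deterministic = TRUE)
    sum(cfu(tr)[nrow(cfu(tr)), ])
  }, numeric(1))
  expect_true(all(diff(surv) <= 1e-6))
})

test_that("mean-field and stochastic modes agree for large populations", {
  det <- runSingleCulture("wild_type", days = 60, deterministic = TRUE)
  tms <- trajectoryTimes(det)
  sto <- lapply(1:5, function(s) runSingleCulture("wild_type", days = 60,
                                                  seed = 100 + s))
  for (d in c(10, 30, 55)) {
    mDet <- sum(cfu(det)[tms == d, ])
    mSto <- vapply(sto, function(tr) sum(cfu(tr)[tms == d, ]), numeric(1))
    se <- sd(mSto) / sqrt(5)
    expect_lt(abs(mean(mSto) - mDet), max(3 * se, 0.01 * mDet))
  }
})

test_that("pulse feeding kills wild-type while mass still rises and mutants persist", {
  wt <- runPulseFeeding("wild_type", seed = 7)
  tms <- trajectoryTimes(wt)
  expect_lt(sum(cfu(wt)[tms == 4, ]), sum(cfu(wt)[tms == 0, ]))
  expect_gt(ghostFraction(wt)[tms == 3], 0.1)
  expect_gt(wt@odProxy[tms == 4], wt@odProxy[tms == 0])
  mk <- runPulseFeeding("mapk", seed = 8)
  expect_gt(sum(cfu(mk)[tms == 4, ]) / sum(cfu(mk)[tms == 0, ]), 0.95)
  # sty1-class delays engagement by its entry delay
  sa <- runPulseFeeding("sapk_delay", seed = 9)
  fs <- sa@finalState
  expect_gte(fs@firstSignal[1] + 3,
             3)  # engagement cannot start before the delay elapses
  eng <- vapply(seq_along(tms), function(i) ghostFraction(sa)[i], numeric(1))
  expect_gt(sum(cfu(sa)[tms == 4, ]) / sum(cfu(sa)[tms == 0, ]), 0.8)
})

test_that("unconsumed pulses accumulate to their exact sum", {
  pulses <- data.frame(time = seq(0, 4.5, by = 0.5), amount = 0.020)
  tr <- runPulseFeeding("wild_type", pulses = pulses, consume = FALSE,
                        days = 5.5, seed = 10)
  expect_equal(max(nitrogenSeries(tr)), 0.200, tolerance = 1e-12)
})

test_that("a single 0.2 mM addition lets every class replicate without killing", {
  for (prof in c("wild_type", "mapk")) {
    st <- populationState(list(phenotypeProfile(prof)), 4e7)
    tr <- starveGASP:::runCulture(st, 3,
                                  pulses = data.frame(time = 0, amount = 0.2),
                                  seed = 11)
    fs <- tr@finalState
    expect_gt(fs@divisions, 0.8 * 4e7)          # the whole cohort replicates
    # no net killing: ghosts stay marginal (late second-round attempts on
    # the exhausted pool) and live cells end far above the inoculum
    expect_lt(fs@counts[1, "ghost"] / sum(fs@counts), 0.05)
    expect_gt(sum(fs@counts[1, c("G0", "engaged", "dividing")]), 4e7)
  }
})

test_that("nitrogen budget classifies capacity with density scaling", {
  expect_equal(nitrogenBudget(4e6, 0.02), "none")
  expect_equal(nitrogenBudget(4e6, 0.05), "engage_only")
  expect_equal(nitrogenBudget(4e6, 0.12), "complete")
  expect_equal(nitrogenBudget(8e6, 0.12), "engage_only")
  expect_equal(nitrogenBudget(2e6, 0.06), "complete")
  expect_error(nitrogenBudget(0, 0.1), "cellsPerMl")
})

test_that("subculture splits partition preexisting alleles and keep de novo ones private", {
  sp <- runSubcultureSplit(nSub = 6, seed = 123)
  al <- sp$alleles
  # de novo non-hotspot alleles are private to one subculture
  dn <- al[al$origin == "quiescence" & !al$hotspot, ]
  if (nrow(dn)) {
    shared <- table(dn$allele)
    expect_lt(mean(shared > 1), 0.02)
  }
  # survivor bookkeeping
  expect_true(all(sp$survivors >= sp$wtSurvivors))
  expect_true(all(al$frequency > 0 & al$frequency <= 1))
  # truth covers every allele in the table
  expect_true(all(al$allele %in% sp$truth$allele))
})

test_that("the split requires enough parent cells and supports nSub = 1", {
  cl <- phenotypeProfile("wild_type")
  parent <- populationState(list(cl), 1e6)
  expect_error(runSubcultureSplit(parent = parent, nSub = 6,
                                  cellsPerSub = 1e7), "insufficient")
  sp <- runSubcultureSplit(nSub = 1, cellsPerSub = 1e7, seed = 9)
  expect_true(all(sp$alleles$subculture == 1))
  expect_length(sp$survivors, 1L)
})

test_that("medium refresh discards the pool and suppresses GASP expansion", {
  ref <- runCoculture("sapk_delay", mutantFraction = 0.001, days = 80,
                      refreshEvery = 14, seed = 31)
  unref <- runCoculture("sapk_delay", mutantFraction = 0.001, days = 80,
                        seed = 31)
  tms <- trajectoryTimes(ref)
  # expansion shrinks several-fold (trickle between refreshes remains)
  expect_lt(cfu(ref)[tms == 60, "sapk_delay"],
            0.5 * cfu(unref)[tms == 60, "sapk_delay"])
  expect_lt(max(nitrogenSeries(ref)), max(nitrogenSeries(unref)))
  # mass balance still holds after refreshes
  fs <- ref@finalState
  expect_lt(abs(fs@nitrogen + fs@cumulativeConsumed -
                  fs@initialNitrogen - fs@cumulativeReleased -
                  fs@cumulativeAdded), 1e-9)
})
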