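callRow <- function(allele, gene = "sty1", position = 100) {
  data.frame(gene = gene, position = position, allele = allele,
             stringsAsFactors = FALSE)
}

test_that("origin classification applies the sharing and hotspot rules", {
  hot <- hotspots(defaultCatalog())
  inAll <- lapply(1:6, function(s) callRow("sty1:100:SNV:1"))
  oc <- classifyOrigin(inAll, hot)
  expect_equal(oc$verdict, "preexisting")
  expect_equal(oc$n_subcultures_detected, 6L)

  private <- c(list(callRow("sty1:100:SNV:1")),
               lapply(1:5, function(s) callRow("x", "mkh1", 9)[0, ]))
  oc <- classifyOrigin(private, hot)
  expect_equal(oc$verdict, "de_novo")

  # the mkh1-640 homonucleotide-run allele recurs in 3/6: ambiguous
  mkh <- callRow("mkh1:640:insertion:1", "mkh1", 640)
  tabs <- c(lapply(1:3, function(s) mkh),
            lapply(1:3, function(s) mkh[0, ]))
  oc <- classifyOrigin(tabs, hot)
  expect_equal(oc$verdict, "hotspot_ambiguous")

  expect_error(classifyOrigin(list(callRow("a")), hot), "two subcultures")
  bad <- list(callRow("k", "sty1", 1), callRow("k", "mkh1", 2))
  expect_error(classifyOrigin(bad, hot), "inconsistent")
})

test_that("origin classification is >= 95% accurate on ground-truth splits", {
  nOK <- 0L; nTot <- 0L
  for (rep in 1:100) {
    sp <- runSubcultureSplit(nSub = 6, seed = 5000 + rep)
    det <- sp$alleles[sp$alleles$frequency >= 0.001, , drop = FALSE]
    calls <- lapply(1:6, function(s) {
      det[det$subculture == s, c("gene", "position", "allele")]
    })
    oc <- classifyOrigin(calls, hotspots(defaultCatalog()))
    oc$true <- sp$truth$origin[match(oc$allele, sp$truth$allele)]
    oc <- oc[oc$verdict != "hotspot_ambiguous", , drop = FALSE]
    ok <- (oc$verdict == "preexisting" & oc$true == "growth") |
      (oc$verdict == "de_novo" & oc$true == "quiescence")
    nOK <- nOK + sum(ok); nTot <- nTot + nrow(oc)
  }
  expect_gt(nTot, 1000L)
  expect_gte(nOK / nTot, 0.95)
})

test_that("phase segmentation is exact on noiseless piecewise data", {
  d <- piecewiseCfu(seq(0, 90, by = 5))
  seg <- segmentPhases(d)
  expect_false(seg$degenerate)
  expect_equal(seg$breakpoints, c(20, 50))
  expect_equal(unname(seg$slopes), c(0, -0.06, -0.003), tolerance = 1e-6)
})

test_that("phase segmentation flags flat or single-slope data and degrades gracefully", {
  flat <- data.frame(time = seq(0, 90, by = 5), cfu = 1e6)
  expect_true(segmentPhases(flat)$degenerate)
  mono <- data.frame(time = seq(0, 90, by = 5),
                     cfu = 1e7 * 10^(-0.02 * seq(0, 90, by = 5)))
  expect_true(segmentPhases(mono)$degenerate)
  expect_error(segmentPhases(piecewiseCfu(seq(0, 30, by = 3))), "60")
  # breakpoint error grows with noise but stays bounded at moderate noise
  set.seed(42)
  errs <- vapply(c(0.01, 0.1), function(sdev) {
    mean(vapply(1:8, function(i) {
      d <- piecewiseCfu(seq(0, 90, by = 3))
      d$cfu <- d$cfu * 10^rnorm(nrow(d), 0, sdev)
      abs(segmentPhases(d)$breakpoints[1] - 20)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(errs[1], errs[2] + 3)
  expect_lt(errs[1], 4)
})

test_that("expansion fitting recovers doubling times and flags declines", {
  d <- data.frame(time = seq(30, 60, by = 3))
  d$cfu <- 1000 * 2^((d$time - 30) / 3)
  fit <- fitExpansion(d, window = c(30, 60))
  expect_equal(fit$doubling_time, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  dec <- data.frame(time = seq(30, 60, by = 3))
  dec$cfu <- 1000 * 2^(-(dec$time - 30) / 5)
  fitD <- fitExpansion(dec, window = c(30, 60))
  expect_true(fitD$declining)
  expect_true(is.na(fitD$doubling_time))
  expect_error(fitExpansion(d[1:3, ], window = c(30, 60)), ">= 4")
  dz <- d; dz$cfu[4] <- 0
  expect_error(fitExpansion(dz, window = c(30, 60)), "nonpositive")
})

test_that("burden statistics report mean, zero class, dispersion and Poisson fit", {
  st <- burdenStats(c(0, 0, 1, 1))
  expect_equal(st$mean, 0.5)
  expect_equal(st$zero_fraction, 0.5)
  z <- burdenStats(rep(0, 10))
  expect_true(z$flagged)
  expect_true(is.na(z$poisson_dispersion))
  expect_error(burdenStats(integer(0)), "non-empty")
})

test_that("the Poisson test rejects over-dispersed burden mixtures with power > 0.9", {
  set.seed(7)
  rejected <- vapply(1:40, function(i) {
    x <- ifelse(runif(1000) < 0.5, 0L, rpois(1000, 2))
    burdenStats(x)$poisson_gof_p < 0.01
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("spectrum summaries tabulate types and audit the SAPK constraint", {
  p <- clockParams(targetFraction = 1)
  ev <- realizeMutations(4000, p, defaultCatalog(), "quiescence", t = 1,
                         seed = 31)
  sm <- spectrumSummary(ev)
  expect_gt(sm$type_counts[["deletion"]], sm$type_counts[["insertion"]])
  expect_equal(sum(sm$type_counts), 4000)
  expect_equal(nrow(sm$violations), 0L)  # enforced upstream, audited here
  forged <- data.frame(gene = "sty1", position = 10, mtype = "deletion",
                       size = 1, effect = "frameshift_indel",
                       stringsAsFactors = FALSE)
  expect_equal(nrow(spectrumSummary(forged)$violations), 1L)
  emptyTab <- spectrumSummary(ev[0, ])
  expect_true(all(emptyTab$type_counts == 0))
})

test_that("minimum doubling counts follow the frequency-ratio closed form", {
  # 9.6% -> 43.5% implies at least log2(0.435/0.096) ~ 2.18 divisions
  md <- minDoublings(0.096, 0.435)
  expect_equal(md$doublings, log2(0.435 / 0.096))
  expect_equal(md$doublings, 2.18, tolerance = 0.005)
  expect_false(md$declined)
  expect_equal(minDoublings(0.3, 0.3)$doublings, 0)
  dec <- minDoublings(0.4, 0.2)
  expect_true(dec$declined)
  expect_error(minDoublings(0, 0.5), "frequencies")
  expect_error(minDoublings(0.1, 0.5, N1 = -1), "sizes")
  # population sizes shift the bound
  expect_equal(minDoublings(0.1, 0.1, N1 = 1e7, N2 = 4e7)$doublings, 2)
})

test_that("likelihood mode demands statistically implausible recurrence", {
  hot <- hotspots(defaultCatalog())
  mkh <- callRow("mkh1:640:insertion:1", "mkh1", 640)
  plain <- callRow("sty1:100:SNV:1")
  tabs <- lapply(1:6, function(s) if (s <= 3) rbind(mkh, plain) else mkh[0, ])
  # sharing mode: hotspot blanket exemption, non-hotspot sharing = preexisting
  sh <- classifyOrigin(tabs, hot)
  expect_equal(sh$verdict[sh$allele == "mkh1:640:insertion:1"],
               "hotspot_ambiguous")
  expect_equal(sh$verdict[sh$allele == "sty1:100:SNV:1"], "preexisting")
  # likelihood mode: a 50x hotspot in 3/6 is explicable by independent
  # origin at baseRate 1e-2/multiplier scale, the non-hotspot allele is not
  lk <- classifyOrigin(tabs, hot, mode = "likelihood", baseRate = 1e-3)
  expect_equal(lk$verdict[lk$allele == "mkh1:640:insertion:1"],
               "hotspot_ambiguous")
  expect_equal(lk$verdict[lk$allele == "sty1:100:SNV:1"], "preexisting")
  # with a high base rate even non-hotspot recurrence is ambiguous
  lk2 <- classifyOrigin(tabs, hot, mode = "likelihood", baseRate = 0.5)
  expect_equal(lk2$verdict[lk2$allele == "sty1:100:SNV:1"],
               "hotspot_ambiguous")
})
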