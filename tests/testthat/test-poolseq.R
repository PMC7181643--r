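test_that("colony sampling follows survivor frequencies and pool structure", {
  col <- sampleColonies(c(wtOnly = 0), n = 1000, seed = 1)
  expect_true(all(col$clone == "WT"))
  expect_equal(max(col$pool), 10L)          # 1000 colonies in pools of 100
  expect_equal(unname(table(col$pool)[1]), 100L)
  # a clone at 40% lands within binomial error of 400/1000
  hits <- vapply(1:20, function(s) {
    sum(sampleColonies(c("sty1:1:SNV:1" = 0.4), n = 1000,
                       seed = s)$clone != "WT")
  }, numeric(1))
  expect_true(all(abs(hits - 400) < 3 * sqrt(1000 * 0.4 * 0.6)))
  expect_error(sampleColonies(c(a = 0.5), n = 0), "positive")
  expect_error(sampleColonies(c(a = 1.5)), "sum")
})

test_that("read simulation reflects colony frequencies and batch structure", {
  # no mutants, no errors: empty table
  col <- sampleColonies(stats::setNames(numeric(0), character(0)),
                        n = 1000, seed = 2)
  rd <- simulateReads(col, seqError = 0, pcrErrorsPerBatch = 0,
                      noiseSites = 0, seed = 3)
  expect_equal(nrow(rd), 0L)
  # one colony in 1000 at 5000x: expected 5 alt reads per batch
  col$clone[1] <- "sty1:553:SNV:1"
  alt <- unlist(lapply(1:40, function(s) {
    rd <- simulateReads(col, seqError = 0, pcrErrorsPerBatch = 0,
                        noiseSites = 0, seed = s)
    rd$alt_reads
  }))
  expect_lt(abs(mean(alt) - 5), 3 * sqrt(5 / length(alt)))
  # PCR artifacts are batch-private by construction
  rdp <- simulateReads(col, seqError = 0, pcrErrorsPerBatch = 5,
                       noiseSites = 0, seed = 9)
  art <- rdp[grepl(":p[AB]", rdp$allele), ]
  expect_gt(nrow(art), 0)
  expect_true(all(table(art$allele) == 1L))
})

test_that("the caller enforces the floor, depth gate and duplicate concordance", {
  # 0.05% in both batches: below the floor, no call
  expect_equal(nrow(callVariants(twoBatchTable(3, 2))), 0L)
  # batch-A-only allele at 2%: amplification artifact, excluded
  onebatch <- twoBatchTable(100, 0)[1, , drop = FALSE]
  expect_equal(nrow(callVariants(onebatch)), 0L)
  expect_equal(nrow(callVariants(twoBatchTable(100, 0))), 0L)
  # 9.6% in both batches: called at ~9.6%
  calls <- callVariants(twoBatchTable(480, 480))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$frequency, 0.096)
  # depth gates on the lower batch
  low <- twoBatchTable(480, 480); low$depth <- c(5000, 4000)
  expect_equal(nrow(callVariants(low)), 0L)
  # per-batch floor mode is stricter
  mixed <- twoBatchTable(8, 3)
  expect_equal(nrow(callVariants(mixed)), 1L)
  expect_equal(nrow(callVariants(mixed, perBatchFloor = TRUE)), 0L)
  # zero-depth rows are skipped with a warning
  zd <- twoBatchTable(480, 480); zd$depth[1] <- 0
  expect_warning(callVariants(zd), "zero-depth")
})

test_that("caller output is invariant to row order and batch relabeling", {
  col <- sampleColonies(c("sgf73:896:insertion:1" = 0.1,
                          "sty1:553:SNV:2" = 0.05), n = 1000, seed = 5)
  rd <- simulateReads(col, seed = 6)
  base <- callVariants(rd)
  shuffled <- rd[sample(nrow(rd)), ]
  expect_equal(callVariants(shuffled), base)
  relabeled <- rd
  relabeled$batch <- ifelse(rd$batch == "A", "B", "A")
  swapped <- callVariants(relabeled)
  expect_equal(swapped$allele, base$allele)
  expect_equal(swapped$frequency, base$frequency)
  expect_equal(swapped$freq_A, base$freq_B)
})

test_that("duplicate concordance suppresses error-floor false calls", {
  ncalls <- 0L; nsites <- 0L
  for (rep in 1:20) {
    col <- sampleColonies(stats::setNames(numeric(0), character(0)),
                          n = 1000, seed = rep)
    rd <- simulateReads(col, noiseSites = 200, seed = 100 + rep)
    ncalls <- ncalls + nrow(callVariants(rd))
    nsites <- nsites + 200L
  }
  expect_lt(ncalls / nsites, 1e-3)
})

test_that("an allele carried by two colonies is reliably called", {
  hit <- 0L; tries <- 0L
  for (rep in 1:150) {
    col <- sampleColonies(c(x = 0.002), n = 1000, seed = 2000 + rep)
    if (sum(col$clone == "x") < 2) next
    col$clone[col$clone == "x"] <- "sty1:553:SNV:1"
    rd <- simulateReads(col, noiseSites = 0, pcrErrorsPerBatch = 0,
                        seed = 4000 + rep)
    hit <- hit + ("sty1:553:SNV:1" %in% callVariants(rd)$allele)
    tries <- tries + 1L
  }
  expect_gt(tries, 50L)
  expect_gte(hit / tries, 0.97)
})

test_that("culture summaries add disjoint clone frequencies with a cap", {
  empty <- callVariants(twoBatchTable(0, 0))
  expect_equal(summarizeCulture(empty), 0)
  calls <- rbind(callVariants(twoBatchTable(500, 500)),
                 callVariants(twoBatchTable(1000, 1000,
                                            allele = "mkh1:640:insertion:1",
                                            gene = "mkh1", position = 640)))
  expect_equal(summarizeCulture(calls), 0.3)
  big <- calls; big$frequency <- c(0.7, 0.6)
  expect_equal(summarizeCulture(big), 1)
})

test_that("end-to-end readout recovers known clone frequencies", {
  truth <- c("sgf73:896:insertion:1" = 0.20, "sty1:553:SNV:1" = 0.10,
             "mkh1:640:insertion:1" = 0.05)
  est <- vapply(1:10, function(s) {
    col <- sampleColonies(truth, n = 1000, seed = s)
    rd <- simulateReads(col, seed = 50 + s)
    summarizeCulture(callVariants(rd))
  }, numeric(1))
  tot <- sum(truth)
  se <- sqrt(tot * (1 - tot) / 1000)
  expect_lt(abs(mean(est) - tot), 3 * se / sqrt(10) + 0.005)
})
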