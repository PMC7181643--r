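test_that("default catalog carries the named genes and hotspot sites", {
  cat <- defaultCatalog()
  g <- genes(cat)
  expect_setequal(g$gene, c("win1", "wis4", "wis1", "sty1", "mkh1", "pek1",
                            "pmk1", "sgf73", "tif452"))
  h <- hotspots(cat)
  sgf <- h[h$gene == "sgf73", ]
  expect_equal(sgf$kind, "homonucleotide_run")
  expect_equal(sgf$run_or_repeat_count, 8)
  mkh <- h[h$gene == "mkh1", ]
  expect_equal(mkh$run_or_repeat_count, 7)
  w <- h[h$gene == "win1", ]
  expect_setequal(w$unit_length, c(17, 13))
  expect_true(all(w$kind == "direct_repeat"))

  catP <- defaultCatalog(includePmc1 = TRUE)
  expect_true("pmc1" %in% genes(catP)$gene)
  expect_equal(genes(catP)$pathway[genes(catP)$gene == "pmc1"], "OTHER")
})

test_that("SAPK genes other than win1 never tolerate loss of function", {
  cat <- defaultCatalog()
  g <- genes(cat)
  for (gn in g$gene[g$pathway == "SAPK" & g$gene != "win1"]) {
    expect_false(isViableInQuiescence(cat, gn, "nonsense"))
    expect_false(isViableInQuiescence(cat, gn, "frameshift_indel"))
    expect_true(isViableInQuiescence(cat, gn, "missense"))
    expect_true(isViableInQuiescence(cat, gn, "inframe_indel"))
  }
  expect_true(isViableInQuiescence(cat, "win1", "frameshift_indel"))
  expect_true(isViableInQuiescence(cat, "mkh1", "frameshift_indel"))
  expect_false(isViableInQuiescence(cat, "sty1", "nonsense"))
})

test_that("catalog validation rejects malformed definitions", {
  expect_error(targetCatalog(
    data.frame(gene = "x", length = 0, pathway = "OTHER",
               tolerated_effects = "missense")), "positive")
  expect_error(targetCatalog(
    data.frame(gene = c("x", "x"), length = c(10, 10),
               pathway = "OTHER", tolerated_effects = "missense")),
    "duplicate")
  expect_error(targetCatalog(
    data.frame(gene = "sty1", length = 100, pathway = "SAPK",
               tolerated_effects = "missense,nonsense")), "win1")
  expect_error(targetCatalog(
    data.frame(gene = "x", length = 100, pathway = "OTHER",
               tolerated_effects = "missense"),
    data.frame(gene = "x", position = 200, kind = "homonucleotide_run",
               unit_length = 1, run_or_repeat_count = 8,
               rate_multiplier = 50)), "within")
  expect_error(targetCatalog(
    data.frame(gene = "x", length = 100, pathway = "OTHER",
               tolerated_effects = "missense"),
    data.frame(gene = "x", position = 10, kind = "homonucleotide_run",
               unit_length = 2, run_or_repeat_count = 8,
               rate_multiplier = 50)), "unit_length")
})

test_that("catalog TSV round-trip is the identity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cat0 <- defaultCatalog()
  writeCatalog(cat0, path)
  cat1 <- loadCatalog(path)
  expect_equal(genes(cat1), genes(cat0))
  h0 <- hotspots(cat0)[order(hotspots(cat0)$gene, hotspots(cat0)$position), ]
  h1 <- hotspots(cat1)[order(hotspots(cat1)$gene, hotspots(cat1)$position), ]
  rownames(h0) <- rownames(h1) <- NULL
  expect_equal(h1, h0)
})

test_that("loading reports malformed rows and single-row files parse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlength\tpathway\ttolerated_effects\thotspots",
               "geneX\t1000\tOTHER\tmissense,silent\t"), path)
  cat1 <- loadCatalog(path)
  expect_equal(nrow(genes(cat1)), 1L)

  writeLines(c("gene\tlength\tpathway\ttolerated_effects\thotspots",
               "geneX\t0\tOTHER\tmissense\t"), path)
  expect_error(loadCatalog(path), "positive")

  writeLines(c("gene\tlength\tpathway\ttolerated_effects\thotspots",
               "geneX\t100\tOTHER\tmissense\tbadspec"), path)
  expect_error(loadCatalog(path), "line 2")
})

test_that("homonucleotide runs are auto-detected from FASTA", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fa")
  seq <- paste0(paste(rep("ACGT", 20), collapse = ""),   # 80 nt, no run
                paste(rep("A", 8), collapse = ""),        # run at 81
                paste(rep("GTCA", 3), collapse = ""))
  writeLines(c(">geneX", seq), fa)
  cat0 <- targetCatalog(
    data.frame(gene = "geneX", length = nchar(seq), pathway = "OTHER",
               tolerated_effects = "missense,silent"))
  cat1 <- addHotspotsFromFasta(cat0, fa, minRun = 7)
  h <- hotspots(cat1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$position, 81)
  expect_equal(h$run_or_repeat_count, 8)
})
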