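# Targeted resequencing readout: 1000 colonies picked into pools of 100,
# target genes PCR-amplified in two independent batches (duplicates exclude
# amplification artifacts), sequenced to >= 5000x. The caller requires
# concordant support in both batches and a mean batch frequency of at least
# the 0.1% floor; one mutant colony among 1000 contributes exactly 0.1%
# allele frequency, the detection floor.

#' Sample survivor colonies into pools
#'
#' Colonies are drawn multinomially from survivor clone frequencies (each
#' colony contributes an approximately equal number of cells to its pool).
#'
#' @param frequencies named numeric vector of clone frequencies among
#'   survivors (alleles; the remainder is unmutated background) or the
#'   `alleles` table of one subculture from
#'   \code{\link{runSubcultureSplit}}.
#' @param n number of colonies (default 1000).
#' @param poolSize colonies per pool (default 100).
#' @param seed optional seed.
#' @return data.frame with columns `colony`, `pool`, `clone` (allele key or
#'   `"WT"`).
#' @export
sampleColonies <- function(frequencies, n = 1000L, poolSize = 100L,
                           seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (is.data.frame(frequencies)) {
    f <- frequencies$frequency
    names(f) <- frequencies$allele
    frequencies <- f
  }
  if (any(frequencies < 0) || sum(frequencies) > 1 + 1e-9) {
    stop("clone frequencies must be non-negative and sum to <= 1",
         call. = FALSE)
  }
  probs <- c(frequencies, WT = max(0, 1 - sum(frequencies)))
  withSeed(seed, {
    clone <- sample(names(probs), n, replace = TRUE, prob = probs)
    data.frame(colony = seq_len(n),
               pool = (seq_len(n) - 1L) %/% poolSize + 1L,
               clone = clone, stringsAsFactors = FALSE)
  })
}

#' Simulate duplicate-batch read counts over a colony pool
#'
#' True alternate-read counts are binomial in the colony frequency of each
#' allele at the given coverage, independently in the two PCR batches.
#' Sequencing noise adds reads of each allele at `seqError / 3` per base in
#' both batches; PCR amplification artifacts inject batch-private spurious
#' alleles (these are what the duplicate design exists to remove).
#'
#' @param colonies data.frame from \code{\link{sampleColonies}}.
#' @param alleleInfo optional data.frame mapping allele keys to `gene` and
#'   `position` (taken from an `alleles` table); keys of the form
#'   `gene:pos:type:size` are parsed automatically when absent.
#' @param coverage reads per site per batch (default 5000).
#' @param seqError per-base sequencing error rate (split evenly over three
#'   alternative alleles).
#' @param pcrErrorsPerBatch expected number of batch-private spurious
#'   alleles per batch.
#' @param catalog A \linkS4class{TargetCatalog} (for placing PCR artifacts).
#' @param noiseSites number of mutation-free sites carried through with
#'   sequencing-noise reads (so the caller is exercised against the error
#'   floor).
#' @param seed optional seed.
#' @return data.frame: `gene`, `position`, `allele`, `batch` (`"A"`/`"B"`),
#'   `alt_reads`, `depth`.
#' @export
simulateReads <- function(colonies, alleleInfo = NULL, coverage = 5000L,
                          seqError = 2e-4, pcrErrorsPerBatch = 3,
                          catalog = defaultCatalog(), noiseSites = 200L,
                          seed = NULL) {
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  n <- nrow(colonies)
  tab <- table(colonies$clone[colonies$clone != "WT"])
  keys <- names(tab)
  parseKey <- function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      list(gene = parts[1], position = suppressWarnings(as.numeric(parts[2])))
    } else list(gene = key, position = NA_real_)
  }
  withSeed(seed, {
    rows <- list()
    addRow <- function(gene, pos, allele, batch, alt, depth) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, position = pos, allele = allele, batch = batch,
        alt_reads = alt, depth = depth, stringsAsFactors = FALSE)
    }
    for (key in keys) {
      f <- as.numeric(tab[[key]]) / n
      info <- if (!is.null(alleleInfo) && key %in% alleleInfo$allele) {
        i <- match(key, alleleInfo$allele)
        list(gene = alleleInfo$gene[i], position = alleleInfo$position[i])
      } else parseKey(key)
      for (batch in c("A", "B")) {
        alt <- stats::rbinom(1L, coverage, f) +
          stats::rbinom(1L, coverage, seqError / 3)
        addRow(info$gene, info$position, key, batch, min(alt, coverage),
               coverage)
      }
    }
    # sequencing noise at mutation-free sites: one representative error
    # allele per screened site so the caller sees the error floor
    g <- genes(catalog)
    nNoise <- as.integer(noiseSites)
    if (seqError > 0 && nNoise > 0) {
      gi <- sample.int(nrow(g), nNoise, replace = TRUE, prob = g$length)
      pos <- vapply(g$length[gi], function(L) sample.int(L, 1L), integer(1))
      for (j in seq_len(nNoise)) {
        key <- sprintf("%s:%d:SNV:e%d", g$gene[gi[j]], pos[j], j)
        for (batch in c("A", "B")) {
          alt <- stats::rbinom(1L, coverage, seqError / 3)
          if (alt > 0) addRow(g$gene[gi[j]], pos[j], key, batch, alt, coverage)
        }
      }
    }
    # PCR artifacts: batch-private by construction
    for (batch in c("A", "B")) {
      nArt <- stats::rpois(1L, pcrErrorsPerBatch)
      if (nArt == 0L) next
      gi <- sample.int(nrow(g), nArt, replace = TRUE, prob = g$length)
      for (j in seq_len(nArt)) {
        pos <- sample.int(g$length[gi[j]], 1L)
        key <- sprintf("%s:%d:SNV:p%s%d", g$gene[gi[j]], pos, batch, j)
        alt <- 1L + stats::rpois(1L, coverage * 0.002)
        addRow(g$gene[gi[j]], pos, key, batch, min(alt, coverage), coverage)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(), position = numeric(),
                 allele = character(), batch = character(),
                 alt_reads = integer(), depth = integer(),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Call low-frequency variants with duplicate-batch concordance
#'
#' A call requires, for the same allele: support in both PCR batches (at
#' least `minBatchReads` alternate reads each - batch-private alleles are
#' amplification artifacts and are excluded), depth of at least `minDepth`
#' in both batches (the lower batch depth gates), and a mean batch
#' frequency of at least `minFreq` (default 0.1%, one colony among 1000).
#' Setting `perBatchFloor = TRUE` instead requires each batch to clear
#' `minFreq` on its own.
#'
#' @param table read-count data.frame from \code{\link{simulateReads}} (or
#'   a TSV with the same columns).
#' @param minFreq detection floor as allele frequency (default 0.001).
#' @param minDepth minimum per-batch depth (default 5000).
#' @param minBatchReads minimum alternate reads per batch for concordance.
#' @param perBatchFloor require `minFreq` in each batch separately.
#' @param hotspotRegistry optional hotspot table (`gene`, `position`) used
#'   to flag calls at hotspot sites.
#' @return data.frame of calls: `gene`, `position`, `allele`, `frequency`
#'   (mean of batch frequencies), `freq_A`, `freq_B`, `depth_A`, `depth_B`,
#'   `hotspot`, `confirmed`.
#' @export
callVariants <- function(table, minFreq = 0.001, minDepth = 5000L,
                         minBatchReads = 2L, perBatchFloor = FALSE,
                         hotspotRegistry = NULL) {
  need <- c("gene", "position", "allele", "batch", "alt_reads", "depth")
  if (!all(need %in% names(table))) {
    stop("read-count table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- table$depth <= 0
  if (any(bad)) {
    warning(sprintf("skipping %d zero-depth rows", sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  if (!nrow(table)) {
    return(data.frame(gene = character(), position = numeric(),
                      allele = character(), frequency = numeric(),
                      freq_A = numeric(), freq_B = numeric(),
                      depth_A = numeric(), depth_B = numeric(),
                      hotspot = logical(), confirmed = logical(),
                      stringsAsFactors = FALSE))
  }
  calls <- list()
  for (key in unique(table$allele)) {
    rows <- table[table$allele == key, , drop = FALSE]
    a <- rows[rows$batch == "A", , drop = FALSE]
    b <- rows[rows$batch == "B", , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next               # batch-private: excluded
    altA <- sum(a$alt_reads); depA <- sum(a$depth)
    altB <- sum(b$alt_reads); depB <- sum(b$depth)
    if (min(depA, depB) < minDepth) next
    if (altA < minBatchReads || altB < minBatchReads) next
    fA <- altA / depA; fB <- altB / depB
    ok <- if (perBatchFloor) (fA >= minFreq && fB >= minFreq) else
      ((fA + fB) / 2 >= minFreq)
    if (!ok) next
    hot <- FALSE
    if (!is.null(hotspotRegistry) && nrow(hotspotRegistry)) {
      hot <- any(hotspotRegistry$gene == rows$gene[1] &
                   hotspotRegistry$position == rows$position[1])
    }
    calls[[length(calls) + 1L]] <- data.frame(
      gene = rows$gene[1], position = rows$position[1], allele = key,
      frequency = (fA + fB) / 2, freq_A = fA, freq_B = fB,
      depth_A = depA, depth_B = depB, hotspot = hot, confirmed = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene = character(), position = numeric(),
               allele = character(), frequency = numeric(),
               freq_A = numeric(), freq_B = numeric(), depth_A = numeric(),
               depth_B = numeric(), hotspot = logical(),
               confirmed = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$position, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of the surviving population carrying any targeted-gene mutation
#'
#' Sum of call frequencies, capped at 1; calls are treated as mutually
#' exclusive clones (a survivor carries at most one driver allele).
#'
#' @param calls data.frame from \code{\link{callVariants}}.
#' @return numeric fraction in [0, 1].
#' @export
summarizeCulture <- function(calls) {
  if (!nrow(calls)) return(0)
  min(1, sum(calls$frequency))
}

#' Write a read-count table or call table to TSV
#' @param table data.frame.
#' @param path output file.
#' @export
writePoolTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export variant calls as a VCF-like file
#'
#' Symbolic ALT alleles for indels; INFO carries per-batch frequencies and
#' depths.
#'
#' @param calls data.frame from \code{\link{callVariants}}.
#' @param path output file.
#' @export
writeCallsVcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"mean batch frequency\">",
               "##INFO=<ID=FA,Number=1,Type=Float,Description=\"batch A frequency\">",
               "##INFO=<ID=FB,Number=1,Type=Float,Description=\"batch B frequency\">",
               "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"batch A depth\">",
               "##INFO=<ID=DPB,Number=1,Type=Integer,Description=\"batch B depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    parts <- strsplit(calls$allele[i], ":", fixed = TRUE)[[1]]
    alt <- if (length(parts) >= 4L && parts[3] != "SNV") {
      sprintf("<%s:%s>", toupper(substr(parts[3], 1, 3)), parts[4])
    } else "N"
    writeLines(sprintf(
      "%s\t%d\t%s\tN\t%s\t.\tPASS\tAF=%.6f;FA=%.6f;FB=%.6f;DPA=%d;DPB=%d",
      calls$gene[i], as.integer(calls$position[i]), calls$allele[i], alt,
      calls$frequency[i], calls$freq_A[i], calls$freq_B[i],
      as.integer(calls$depth_A[i]), as.integer(calls$depth_B[i])), con)
  }
  invisible(path)
}
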