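# Mutational target space: nine S/MAPK-related genes, their tolerated effect
# classes in quiescence, and the indel hotspots recurrently hit in
# independent cultures.

tolerated <- function(...) paste(c(...), collapse = ",")
ALL_EFFECTS  <- tolerated(EFFECT_CLASSES)
SAPK_EFFECTS <- tolerated("missense", "inframe_indel", "silent")

#' Construct a target catalog
#'
#' @param genes data.frame with columns `gene`, `length`, `pathway`,
#'   `tolerated_effects`.
#' @param hotspots data.frame of hotspot sites (may be empty).
#' @return A \linkS4class{TargetCatalog}.
#' @export
targetCatalog <- function(genes, hotspots = emptyHotspots()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$length <- as.numeric(genes$length)
  hotspots <- as.data.frame(hotspots, stringsAsFactors = FALSE)
  new("TargetCatalog", genes = genes, hotspots = hotspots)
}

emptyHotspots <- function() {
  data.frame(gene = character(), position = numeric(), kind = character(),
             unit_length = numeric(), run_or_repeat_count = numeric(),
             rate_multiplier = numeric(), stringsAsFactors = FALSE)
}

#' Bundled default catalog of the nine target genes
#'
#' SAPK module (win1, wis4, wis1, sty1), MAPK module (mkh1, pek1, pmk1) and
#' the downstream targets sgf73 and tif452, with the recurrently mutated
#' hotspot sites: the 8-adenine run in sgf73 (position 896), the 7-adenine
#' run in mkh1 (position 640), and the 17-bp and 13-bp direct-repeat
#' duplication sites in win1 (positions 1273 and 394). Gene lengths are
#' order-of-magnitude CDS sizes; they only set relative mutational target
#' weights and can be overridden via \code{\link{loadCatalog}}. The vacuolar
#' calcium transporter pmc1 (remotely S/MAPK-related) can be appended as a
#' tenth, OTHER-pathway entry.
#'
#' All SAPK genes except win1 tolerate only missense, in-frame indels and
#' silent changes: loss-of-function SAPK alleles do not survive quiescence.
#'
#' @param includePmc1 logical; append pmc1.
#' @param hotspotMultiplierRun,hotspotMultiplierRepeat rate multipliers for
#'   homonucleotide-run and direct-repeat hotspots.
#' @return A \linkS4class{TargetCatalog}.
#' @examples
#' cat <- defaultCatalog()
#' genes(cat)$gene
#' @export
defaultCatalog <- function(includePmc1 = FALSE,
                           hotspotMultiplierRun = 50,
                           hotspotMultiplierRepeat = 20) {
  genes <- data.frame(
    gene    = c("win1", "wis4", "wis1", "sty1", "mkh1", "pek1", "pmk1",
                "sgf73", "tif452"),
    length  = c(4300, 4200, 1800, 1050, 3400, 1100, 1300, 1100, 750),
    pathway = c("SAPK", "SAPK", "SAPK", "SAPK", "MAPK", "MAPK", "MAPK",
                "DOWNSTREAM", "DOWNSTREAM"),
    tolerated_effects = c(ALL_EFFECTS, SAPK_EFFECTS, SAPK_EFFECTS,
                          SAPK_EFFECTS, ALL_EFFECTS, ALL_EFFECTS,
                          ALL_EFFECTS, ALL_EFFECTS, ALL_EFFECTS),
    stringsAsFactors = FALSE)
  if (includePmc1) {
    genes <- rbind(genes, data.frame(
      gene = "pmc1", length = 3500, pathway = "OTHER",
      tolerated_effects = ALL_EFFECTS, stringsAsFactors = FALSE))
  }
  hotspots <- data.frame(
    gene = c("sgf73", "mkh1", "win1", "win1"),
    position = c(896, 640, 1273, 394),
    kind = c("homonucleotide_run", "homonucleotide_run",
             "direct_repeat", "direct_repeat"),
    unit_length = c(1, 1, 17, 13),
    run_or_repeat_count = c(8, 7, 2, 2),
    rate_multiplier = c(hotspotMultiplierRun, hotspotMultiplierRun,
                        hotspotMultiplierRepeat, hotspotMultiplierRepeat),
    stringsAsFactors = FALSE)
  targetCatalog(genes, hotspots)
}

#' @describeIn TargetCatalog gene table accessor
#' @param x A `TargetCatalog`.
#' @export
genes <- function(x) x@genes

#' @describeIn TargetCatalog hotspot table accessor
#' @export
hotspots <- function(x) x@hotspots

#' Total catalog length in base pairs
#' @param x A \linkS4class{TargetCatalog}.
#' @export
catalogLength <- function(x) sum(genes(x)$length)

setMethod("show", "TargetCatalog", function(object) {
  g <- genes(object)
  cat(sprintf("TargetCatalog: %d genes, %d hotspot sites, %d bp total\n",
              nrow(g), nrow(hotspots(object)), sum(g$length)))
  cat("  pathways:", paste(sprintf("%s=%d", names(table(g$pathway)),
                                   table(g$pathway)), collapse = " "), "\n")
})

toleratedEffects <- function(catalog, gene) {
  g <- genes(catalog)
  i <- match(gene, g$gene)
  if (is.na(i)) stop(sprintf("gene '%s' is not in the catalog", gene), call. = FALSE)
  trimws(strsplit(g$tolerated_effects[i], ",", fixed = TRUE)[[1]])
}

#' Is a mutation effect class viable in quiescence for a given gene?
#'
#' SAPK-pathway functions cannot be fully eliminated in quiescence: nonsense
#' and frameshift alleles of SAPK genes (win1 excepted, being buffered by a
#' paralogous kinase) never appear among survivors.
#'
#' @param catalog A \linkS4class{TargetCatalog}.
#' @param gene Gene name (must be in the catalog).
#' @param effect One of the effect classes.
#' @return logical.
#' @examples
#' isViableInQuiescence(defaultCatalog(), "sty1", "nonsense")   # FALSE
#' isViableInQuiescence(defaultCatalog(), "mkh1", "frameshift_indel") # TRUE
#' @export
isViableInQuiescence <- function(catalog, gene, effect) {
  effect <- match.arg(effect, EFFECT_CLASSES)
  effect %in% toleratedEffects(catalog, gene)
}

#' Write a catalog to TSV
#'
#' Columns: gene, length, pathway, tolerated_effects (comma list), hotspots
#' (semicolon-separated `kind:pos:unit:count:multiplier`).
#'
#' @param catalog A \linkS4class{TargetCatalog}.
#' @param path output file.
#' @export
writeCatalog <- function(catalog, path) {
  g <- genes(catalog)
  h <- hotspots(catalog)
  spec <- vapply(g$gene, function(gn) {
    hi <- h[h$gene == gn, , drop = FALSE]
    if (!nrow(hi)) return("")
    paste(sprintf("%s:%d:%d:%d:%g", hi$kind, as.integer(hi$position),
                  as.integer(hi$unit_length),
                  as.integer(hi$run_or_repeat_count), hi$rate_multiplier),
          collapse = ";")
  }, character(1))
  out <- data.frame(gene = g$gene, length = g$length, pathway = g$pathway,
                    tolerated_effects = g$tolerated_effects,
                    hotspots = spec, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a catalog from TSV
#'
#' Inverse of \code{\link{writeCatalog}}; validates all catalog invariants.
#'
#' @param path TSV file with header gene, length, pathway, tolerated_effects,
#'   hotspots.
#' @return A \linkS4class{TargetCatalog}.
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "length", "pathway", "tolerated_effects")
  if (!all(need %in% names(tab))) {
    stop("catalog TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hs <- emptyHotspots()
  if ("hotspots" %in% names(tab)) {
    for (i in seq_len(nrow(tab))) {
      spec <- tab$hotspots[i]
      if (is.na(spec) || !nzchar(spec)) next
      for (one in strsplit(spec, ";", fixed = TRUE)[[1]]) {
        parts <- strsplit(one, ":", fixed = TRUE)[[1]]
        if (length(parts) != 5L) {
          stop(sprintf("malformed hotspot spec on line %d: '%s'", i + 1L, one),
               call. = FALSE)
        }
        num <- suppressWarnings(as.numeric(parts[2:5]))
        if (anyNA(num)) {
          stop(sprintf("malformed hotspot spec on line %d: '%s'", i + 1L, one),
               call. = FALSE)
        }
        hs <- rbind(hs, data.frame(
          gene = tab$gene[i], position = num[1], kind = parts[1],
          unit_length = num[2], run_or_repeat_count = num[3],
          rate_multiplier = num[4], stringsAsFactors = FALSE))
      }
    }
  }
  len <- suppressWarnings(as.numeric(tab$length))
  bad <- which(is.na(len))
  if (length(bad)) {
    stop(sprintf("malformed length on line %d", bad[1] + 1L), call. = FALSE)
  }
  targetCatalog(tab[, need], hs)
}

#' Auto-detect homonucleotide-run hotspots from gene sequences
#'
#' Scans a FASTA of gene sequences (one record per catalog gene) and
#' registers every run of `minRun` or more identical nucleotides as a
#' homonucleotide-run hotspot at the run's first base.
#'
#' @param catalog A \linkS4class{TargetCatalog}.
#' @param fasta Path to a FASTA file; record names must match catalog genes.
#' @param minRun Minimum run length to call a hotspot (default 7).
#' @param multiplier Rate multiplier assigned to detected runs.
#' @return The catalog with detected hotspots appended (duplicates of
#'   existing gene/position pairs are skipped).
#' @export
addHotspotsFromFasta <- function(catalog, fasta, minRun = 7, multiplier = 50) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA hotspot detection", call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  g <- genes(catalog)
  h <- hotspots(catalog)
  for (gn in intersect(names(seqs), g$gene)) {
    s <- strsplit(as.character(seqs[[gn]]), "")[[1]]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$lengths >= minRun)
    for (k in keep) {
      if (any(h$gene == gn & h$position == starts[k])) next
      h <- rbind(h, data.frame(
        gene = gn, position = starts[k], kind = "homonucleotide_run",
        unit_length = 1, run_or_repeat_count = r$lengths[k],
        rate_multiplier = multiplier, stringsAsFactors = FALSE))
    }
  }
  targetCatalog(g, h)
}
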