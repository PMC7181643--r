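# small fixtures shared across tests

# one-gene catalog with a single homonucleotide-run hotspot, for closed-form
# placement checks
oneGeneCatalog <- function(len = 1000, hotspotPos = 500, multiplier = 50) {
  targetCatalog(
    data.frame(gene = "geneX", length = len, pathway = "OTHER",
               tolerated_effects = paste(starveGASP:::EFFECT_CLASSES,
                                         collapse = ","),
               stringsAsFactors = FALSE),
    data.frame(gene = "geneX", position = hotspotPos,
               kind = "homonucleotide_run", unit_length = 1,
               run_or_repeat_count = 8, rate_multiplier = multiplier,
               stringsAsFactors = FALSE))
}

# read-count table for one allele observed in both batches
twoBatchTable <- function(altA, altB, depth = 5000, gene = "sty1",
                          position = 553, allele = "sty1:553:SNV:1") {
  data.frame(gene = gene, position = position, allele = allele,
             batch = c("A", "B"), alt_reads = c(altA, altB),
             depth = depth, stringsAsFactors = FALSE)
}

# exact piecewise-linear log10 CFU data with two breakpoints
piecewiseCfu <- function(times, b = c(20, 50), s = c(0, -0.06, -0.003),
                         lev0 = 7) {
  y <- lev0 + s[1] * pmin(times, b[1]) +
    s[2] * pmax(pmin(times, b[2]) - b[1], 0) +
    s[3] * pmax(times - b[2], 0)
  data.frame(time = times, cfu = 10^y)
}
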