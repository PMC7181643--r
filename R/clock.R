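# Mutation accumulation clock: replication-coupled during growth,
# time-linear during quiescence ("one clock ticks per division, the other
# per day"). Mutation counts are Poisson in both regimes; only the mean
# differs: n_generations * mu * L during growth, lambda_q * days in G0.

#' Clock parameter constructor
#'
#' Defaults encode the fission-yeast rates: a growth mutation rate of
#' 2e-10 per nucleotide per generation over a 12.57-Mb genome, and a
#' quiescence rate of 0.6/90 mutations per genome per day, i.e. 0.6
#' mutations per genome after three months of nitrogen starvation with
#' about half of all genomes mutation-free (e^-0.6 ~ 0.55). The quiescence
#' spectrum has indels roughly as frequent as SNVs with deletions
#' dominating insertions; the growth spectrum is SNV-dominated.
#'
#' @param muGrowth mutations/nt/generation.
#' @param genomeLength nucleotides.
#' @param lambdaQ mutations/genome/day in quiescence. Cultures whose medium
#'   is never refreshed accumulate roughly twice the refreshed-medium
#'   burden; pass `2 * 0.6 / 90` to model that regime.
#' @param spectrumGrowth,spectrumQuiescence named probability vectors over
#'   `SNV`, `insertion`, `deletion`, `duplication`.
#' @param targetFraction probability a mutation hits the catalog genes;
#'   `NA` (default) derives it as catalog length / genome length.
#' @param snvEffectProbs probabilities of missense/nonsense/silent for an
#'   SNV landing in a gene.
#' @param indelSizeP geometric size parameter; indel size = 1 + Geom(p).
#' @return A \linkS4class{ClockParams}.
#' @export
clockParams <- function(muGrowth = 2e-10,
                        genomeLength = 1.257e7,
                        lambdaQ = 0.6 / 90,
                        spectrumGrowth = c(SNV = 0.85, insertion = 0.05,
                                           deletion = 0.08, duplication = 0.02),
                        spectrumQuiescence = c(SNV = 0.50, insertion = 0.15,
                                               deletion = 0.30, duplication = 0.05),
                        targetFraction = NA_real_,
                        snvEffectProbs = c(missense = 0.70, nonsense = 0.05,
                                           silent = 0.25),
                        indelSizeP = 0.7) {
  new("ClockParams", muGrowth = muGrowth, genomeLength = genomeLength,
      lambdaQ = lambdaQ,
      spectrumGrowth = spectrumGrowth[MUTATION_TYPES],
      spectrumQuiescence = spectrumQuiescence[MUTATION_TYPES],
      targetFraction = targetFraction, snvEffectProbs = snvEffectProbs,
      indelSizeP = indelSizeP)
}

setMethod("show", "ClockParams", function(object) {
  cat(sprintf(
    "ClockParams: mu_growth=%.2g/nt/gen over %.3g nt; lambda_q=%.4g/genome/day\n",
    object@muGrowth, object@genomeLength, object@lambdaQ))
  cat("  quiescence spectrum:",
      paste(sprintf("%s=%.2f", names(object@spectrumQuiescence),
                    object@spectrumQuiescence), collapse = " "), "\n")
})

resolveTargetFraction <- function(params, catalog) {
  if (!is.na(params@targetFraction)) return(params@targetFraction)
  min(1, catalogLength(catalog) / params@genomeLength)
}

#' Sample per-genome mutation burdens from the growth clock
#'
#' Poisson with mean `nGenerations * muGrowth * genomeLength`.
#'
#' @param nGenerations number of cell divisions since the founder.
#' @param params A \linkS4class{ClockParams}.
#' @param n number of genomes to draw.
#' @param seed optional integer seed.
#' @return integer vector of length `n`.
#' @export
sampleGrowthBurden <- function(nGenerations, params = clockParams(), n = 1L,
                               seed = NULL) {
  stopifnotScalar(nGenerations, "nGenerations", min = 0)
  withSeed(seed, stats::rpois(n, nGenerations * params@muGrowth * params@genomeLength))
}

#' Sample per-genome mutation burdens from the quiescence clock
#'
#' Poisson with mean `lambdaQ * days`: the time-linear accumulation regime
#' of non-dividing cells, modelled as a homogeneous Poisson process from
#' quiescence entry.
#'
#' @param days days spent in quiescence.
#' @inheritParams sampleGrowthBurden
#' @return integer vector of length `n`.
#' @export
sampleQuiescenceBurden <- function(days, params = clockParams(), n = 1L,
                                   seed = NULL) {
  stopifnotScalar(days, "days", min = 0)
  withSeed(seed, stats::rpois(n, params@lambdaQ * days))
}

# position weights within a gene for a given mutation type: homonucleotide
# runs multiply the local indel rate, direct repeats the local duplication
# rate; SNV placement is uniform.
positionWeights <- function(len, hs, mtype) {
  w <- rep(1, len)
  if (nrow(hs)) {
    if (mtype %in% c("insertion", "deletion")) {
      sel <- hs$kind == "homonucleotide_run"
    } else if (mtype == "duplication") {
      sel <- hs$kind == "direct_repeat"
    } else sel <- rep(FALSE, nrow(hs))
    w[hs$position[sel]] <- w[hs$position[sel]] + (hs$rate_multiplier[sel] - 1)
  }
  w
}

sampleIndelSize <- function(n, p) 1L + stats::rgeom(n, p)

realizeOne <- function(params, catalog, origin, t, enforceViability) {
  spectrum <- if (origin == "growth") params@spectrumGrowth else
    params@spectrumQuiescence
  tf <- resolveTargetFraction(params, catalog)
  g <- genes(catalog)
  h <- hotspots(catalog)
  for (i in seq_len(1000L)) {
    mtype <- sample(MUTATION_TYPES, 1L, prob = spectrum)
    inTarget <- stats::runif(1) < tf
    if (!inTarget) {
      size <- switch(mtype, SNV = 1L, sampleIndelSize(1L, params@indelSizeP))
      return(data.frame(gene = "INTERGENIC", position = NA_real_,
                        mtype = mtype, size = size, effect = NA_character_,
                        origin = origin, t_occurrence = t, hotspot = FALSE,
                        stringsAsFactors = FALSE))
    }
    gi <- sample.int(nrow(g), 1L, prob = g$length)
    gn <- g$gene[gi]
    hg <- h[h$gene == gn, , drop = FALSE]
    pos <- sample.int(g$length[gi], 1L,
                      prob = positionWeights(g$length[gi], hg, mtype))
    isHot <- any(hg$position == pos &
                   ((mtype %in% c("insertion", "deletion") &
                       hg$kind == "homonucleotide_run") |
                      (mtype == "duplication" & hg$kind == "direct_repeat")))
    if (mtype == "SNV") {
      size <- 1L
      effect <- sample(names(params@snvEffectProbs), 1L,
                       prob = params@snvEffectProbs)
    } else if (mtype == "duplication") {
      size <- if (isHot) {
        as.integer(hg$unit_length[hg$position == pos][1])
      } else sampleIndelSize(1L, params@indelSizeP) + 1L
      effect <- if (size %% 3L == 0L) "inframe_indel" else "frameshift_indel"
    } else {
      size <- sampleIndelSize(1L, params@indelSizeP)
      effect <- if (size %% 3L == 0L) "inframe_indel" else "frameshift_indel"
    }
    # selection in quiescence: a non-tolerated effect class kills its clone,
    # so realized (surviving) mutations are conditioned on viability by
    # rejection; an approximation keeping the clock and the population
    # dynamics decoupled
    if (enforceViability && !isViableInQuiescence(catalog, gn, effect)) next
    return(data.frame(gene = gn, position = as.numeric(pos), mtype = mtype,
                      size = size, effect = effect, origin = origin,
                      t_occurrence = t, hotspot = isHot,
                      stringsAsFactors = FALSE))
  }
  stop("viability rejection failed to converge; check catalog tolerances",
       call. = FALSE)
}

#' Realize mutation events (type, placement, effect class)
#'
#' Draws the mutation type from the origin-appropriate spectrum, assigns it
#' to a catalog gene with probability `targetFraction` (genes weighted by
#' length, in-gene positions weighted by hotspot multipliers for the
#' compatible mutation type), and derives the effect class (indels:
#' frameshift unless size is a multiple of 3; SNVs: missense/nonsense/silent
#' draw). For quiescence-origin events, effect classes that are not
#' tolerated in the hit gene are rejected and the event redrawn, modelling
#' selection against loss of essential quiescence functions.
#'
#' @param n number of events.
#' @param params A \linkS4class{ClockParams}.
#' @param catalog A \linkS4class{TargetCatalog}.
#' @param origin `"growth"` or `"quiescence"`.
#' @param t occurrence time(s), days since quiescence entry (negative for
#'   growth-phase events); recycled to length `n`.
#' @param enforceViability apply the viability rejection (default: only for
#'   quiescence-origin events).
#' @param seed optional integer seed.
#' @return data.frame of mutation events with columns `id`, `gene`,
#'   `position`, `mtype`, `size`, `effect`, `origin`, `t_occurrence`,
#'   `hotspot`.
#' @export
realizeMutations <- function(n, params = clockParams(),
                             catalog = defaultCatalog(),
                             origin = c("quiescence", "growth"),
                             t = if (origin == "growth") -1 else 0,
                             enforceViability = (origin == "quiescence"),
                             seed = NULL) {
  origin <- match.arg(origin)
  if (nrow(genes(catalog)) == 0L) stop("catalog is empty", call. = FALSE)
  if (origin == "growth" && any(t >= 0)) {
    stop("growth-origin events must have negative t_occurrence", call. = FALSE)
  }
  if (origin == "quiescence" && any(t < 0)) {
    stop("quiescence-origin events must have t_occurrence >= 0", call. = FALSE)
  }
  t <- rep_len(t, n)
  withSeed(seed, {
    if (n == 0L) {
      out <- realizeOne(params, catalog, origin, 0, FALSE)[0, ]
    } else {
      out <- do.call(rbind, lapply(seq_len(n), function(i) {
        realizeOne(params, catalog, origin, t[i], enforceViability)
      }))
    }
    if (nrow(out)) out <- cbind(id = sprintf("m%06d", seq_len(nrow(out))), out)
    out
  })
}

#' Histogram of per-genome mutation burdens
#'
#' @param genomes either a list of per-genome event data.frames (burden =
#'   number of rows) or an integer vector of burdens.
#' @return named integer vector: counts per burden value.
#' @export
burdenHistogram <- function(genomes) {
  burdens <- if (is.list(genomes) && !is.data.frame(genomes)) {
    vapply(genomes, function(g) if (is.null(g)) 0L else nrow(g), integer(1))
  } else as.integer(genomes)
  if (!length(burdens)) return(integer(0))
  tab <- table(factor(burdens, levels = 0:max(burdens)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Serialize mutation events to TSV
#' @param events data.frame from \code{\link{realizeMutations}}.
#' @param path output file.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export mutation events as a minimal VCF-like file
#'
#' CHROM is the gene name, POS the within-gene coordinate; indel and
#' duplication alleles are written as symbolic ALTs (`<DEL:3>` etc.) since
#' the model is allele-level, not nucleotide-resolved.
#'
#' @param events data.frame from \code{\link{realizeMutations}}.
#' @param path output file.
#' @export
writeEventsVcf <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"growth or quiescence\">",
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"effect class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  ev <- events[events$gene != "INTERGENIC", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    alt <- switch(ev$mtype[i],
                  SNV = "N",
                  insertion = sprintf("<INS:%d>", ev$size[i]),
                  deletion = sprintf("<DEL:%d>", ev$size[i]),
                  duplication = sprintf("<DUP:%d>", ev$size[i]))
    writeLines(sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tORIGIN=%s;EFFECT=%s",
                       ev$gene[i], as.integer(ev$position[i]), ev$id[i], alt,
                       ev$origin[i], ev$effect[i]), con)
  }
  invisible(path)
}
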