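# Subculture-split experiment: a clonal culture grown for a limited number
# of generations is starved for one day, split into parallel subcultures,
# and resequenced after two months. Growth-origin (preexisting) mutations
# are partitioned across subcultures at the split; quiescence-origin
# mutations arise independently within each subculture afterwards. Survivor
# allele frequencies come from a lineage-level branching sketch: each
# founder cell survives the death phase with the probability implied by its
# phenotype's basal-death schedule, then its clone expands from the
# nutrient-release onset at the configured doubling time (Yule process, so
# clone sizes are geometric about their mean), capped by the recycled
# nitrogen budget.

schedIntegral <- function(sched, t0, t1) {
  if (t1 <= t0) return(0)
  brk <- c(sched$start, Inf)
  tot <- 0
  for (i in seq_len(nrow(sched))) {
    lo <- max(t0, brk[i]); hi <- min(t1, brk[i + 1L])
    if (hi > lo) tot <- tot + sched$rate[i] * (hi - lo)
  }
  tot
}

survivalFraction <- function(sched, t0, t1) exp(-schedIntegral(sched, t0, t1))

# vectorized allele realization for mutations already assigned to genes;
# SNV alleles carry one of three alternative bases so that independent hits
# at the same position are usually distinguishable
realizeAlleles <- function(geneIdx, params, catalog, origin, ts) {
  n <- length(geneIdx)
  g <- genes(catalog)
  h <- hotspots(catalog)
  spectrum <- if (origin == "growth") params@spectrumGrowth else
    params@spectrumQuiescence
  mtype <- sample(MUTATION_TYPES, n, replace = TRUE, prob = spectrum)
  pos <- integer(n); size <- integer(n); isHot <- logical(n)
  wclass <- ifelse(mtype == "SNV", "snv",
                   ifelse(mtype == "duplication", "dup", "indel"))
  for (gi in unique(geneIdx)) {
    L <- g$length[gi]
    hg <- h[h$gene == g$gene[gi], , drop = FALSE]
    for (wc in c("snv", "indel", "dup")) {
      sel <- which(geneIdx == gi & wclass == wc)
      if (!length(sel)) next
      mt <- if (wc == "indel") "deletion" else
        if (wc == "dup") "duplication" else "SNV"
      w <- positionWeights(L, hg, mt)
      pos[sel] <- sample.int(L, length(sel), replace = TRUE, prob = w)
      if (wc == "indel") {
        hotPos <- hg$position[hg$kind == "homonucleotide_run"]
      } else if (wc == "dup") {
        hotPos <- hg$position[hg$kind == "direct_repeat"]
      } else hotPos <- integer(0)
      isHot[sel] <- pos[sel] %in% hotPos
      if (wc == "dup" && any(isHot[sel])) {
        hs <- sel[isHot[sel]]
        size[hs] <- hg$unit_length[match(pos[hs], hg$position)]
      }
    }
  }
  effect <- character(n)
  snv <- mtype == "SNV"
  size[snv] <- sample.int(3L, sum(snv), replace = TRUE)  # alt-base index
  effect[snv] <- sample(names(params@snvEffectProbs), sum(snv),
                        replace = TRUE, prob = params@snvEffectProbs)
  ind <- !snv & size == 0L
  size[ind] <- sampleIndelSize(sum(ind), params@indelSizeP) +
    as.integer(mtype[ind] == "duplication")
  effect[!snv] <- ifelse(size[!snv] %% 3L == 0L, "inframe_indel",
                         "frameshift_indel")
  data.frame(allele = sprintf("%s:%d:%s:%d", g$gene[geneIdx], pos, mtype,
                              size),
             gene = g$gene[geneIdx], position = pos, mtype = mtype,
             size = size, effect = effect, hotspot = isHot,
             t_occurrence = ts, stringsAsFactors = FALSE)
}

yuleCloneSizes <- function(founders, meanPerFounder) {
  out <- founders
  grow <- founders > 0 & meanPerFounder > 1
  if (any(grow)) {
    out[grow] <- founders[grow] +
      stats::rnbinom(sum(grow), size = founders[grow],
                     prob = 1 / meanPerFounder[grow])
  }
  out
}

viabilityMatrix <- function(catalog) {
  g <- genes(catalog)
  m <- matrix(FALSE, nrow(g), length(EFFECT_CLASSES),
              dimnames = list(g$gene, EFFECT_CLASSES))
  for (i in seq_len(nrow(g))) {
    m[i, trimws(strsplit(g$tolerated_effects[i], ",")[[1]])] <- TRUE
  }
  m
}

#' Simulate a subculture-split resequencing experiment
#'
#' A culture of `nSub * cellsPerSub` cells (grown for `growthGenerations`
#' divisions, accumulating replication-coupled mutations) is split on day 1
#' of quiescence into `nSub` subcultures; each then accumulates
#' quiescence-origin mutations independently. Growth-origin mutant cells
#' are multinomially partitioned at the split, so shared alleles mark
#' preexisting mutations, while non-hotspot quiescence alleles are private
#' to one subculture. Survivor allele tables at the horizon come from the
#' lineage model described in the package vignette: founders survive the
#' death phase according to their phenotype's basal-death schedule, then
#' expand from the nutrient-release onset at the configured doubling time;
#' only viable, non-silent mutations that confer the expansion phenotype
#' (probability `gaspEffectProb`; hotspot alleles always) found clones.
#'
#' @param parent optional \linkS4class{PopulationState}; if supplied, its
#'   live count must cover `nSub * cellsPerSub`.
#' @param nSub number of subcultures (1 = an unsplit culture).
#' @param cellsPerSub cells per subculture at the split.
#' @param days harvest time, days of quiescence.
#' @param growthGenerations divisions before quiescence entry.
#' @param params A \linkS4class{ClockParams}.
#' @param catalog A \linkS4class{TargetCatalog}.
#' @param wt wild-type \linkS4class{PhenotypeParams} (sets background
#'   survival).
#' @param gaspEffectProb probability that a viable, non-silent target-gene
#'   mutation confers the expansion (GASP) phenotype.
#' @param expansionOnset day at which recycled nitrogen first supports
#'   mutant replication (entry delays add per class).
#' @param recyclingEfficiency births supported per death; caps total
#'   clonal expansion.
#' @param seed optional seed.
#' @return list with `alleles` (per-subculture survivor allele table with
#'   cells and frequency among survivors), `survivors` (per-subculture
#'   survivor totals), `truth` (allele-level ground truth: origin, hotspot,
#'   fate), and `wtSurvivors` (wild-type survivors per subculture).
#' @export
runSubcultureSplit <- function(parent = NULL, nSub = 6L, cellsPerSub = 1e7,
                               days = 60, growthGenerations = 27,
                               params = clockParams(),
                               catalog = defaultCatalog(),
                               wt = phenotypeProfile("wild_type"),
                               gaspEffectProb = 0.01,
                               expansionOnset = 21,
                               recyclingEfficiency = 1,
                               seed = NULL) {
  nSub <- as.integer(nSub)
  if (nSub < 1L) stop("nSub must be >= 1", call. = FALSE)
  if (!is.null(parent)) {
    if (sum(liveCounts(parent)) < nSub * cellsPerSub) {
      stop("parent live count is insufficient for the requested split",
           call. = FALSE)
    }
  }
  withSeed(seed, {
    g <- genes(catalog)
    tf <- resolveTargetFraction(params, catalog)
    muCat <- params@muGrowth * params@genomeLength * tf
    totalCells <- nSub * cellsPerSub

    profiles <- vapply(g$gene, phenotypeForGene, character(1),
                       catalog = catalog)
    phen <- lapply(c(wild_type = "wild_type", sapk = "sapk",
                     sapk_delay = "sapk_delay", mapk = "mapk"),
                   phenotypeProfile)
    viab <- viabilityMatrix(catalog)
    onsetOf <- vapply(profiles, function(p) {
      expansionOnset + phen[[p]]@entryDelay
    }, numeric(1))

    fates <- function(al) {
      ok <- viab[cbind(match(al$gene, rownames(viab)), match(al$effect,
                                                             colnames(viab)))]
      ifelse(!ok, "dead",
             ifelse(al$effect == "silent", "neutral",
                    ifelse(al$hotspot | stats::runif(nrow(al)) <
                             gaspEffectProb, "expanding", "neutral")))
    }

    # ---- growth-origin (preexisting) mutations, Luria-Delbruck genealogy
    G <- as.integer(growthGenerations)
    gens <- integer(0)
    for (gen in seq_len(G)) {
      k <- stats::rpois(1L, totalCells * 2^(-(G - gen + 1L)) * muCat)
      gens <- c(gens, rep.int(gen, k))
    }
    nG <- length(gens)
    growth <- NULL
    if (nG) {
      geneIdx <- sample.int(nrow(g), nG, replace = TRUE, prob = g$length)
      growth <- realizeAlleles(geneIdx, params, catalog, "growth",
                               -(G - gens + 1))
      growth$fate <- fates(growth)
      growth$cloneSize <- 2^(G - gens)
    }

    alleleParts <- list()
    truthParts <- list()
    if (nG) {
      truthParts[["growth"]] <- data.frame(
        allele = growth$allele, gene = growth$gene, origin = "growth",
        hotspot = growth$hotspot, fate = growth$fate,
        stringsAsFactors = FALSE)
      exp_ <- which(growth$fate == "expanding")
      for (k in exp_) {
        split <- as.vector(stats::rmultinom(1L, growth$cloneSize[k],
                                            rep(1 / nSub, nSub)))
        prof <- phen[[profiles[[growth$gene[k]]]]]
        onset <- onsetOf[[growth$gene[k]]]
        pSurv <- survivalFraction(prof@basalDeath, 0, onset)
        m <- 2^((days - onset) / prof@doublingTime)
        surv <- stats::rbinom(nSub, split, pSurv)
        cells <- yuleCloneSizes(surv, rep(m, nSub))
        has <- which(cells > 0)
        if (length(has)) {
          alleleParts[[length(alleleParts) + 1L]] <- data.frame(
            subculture = has,
            growth[k, c("allele", "gene", "position", "mtype", "size",
                        "effect", "hotspot", "t_occurrence")],
            origin = "growth", cells = cells[has], row.names = NULL,
            stringsAsFactors = FALSE)
        }
      }
    }

    # ---- quiescence-origin mutations, independent within each subculture
    grid <- seq(0.25, days - 0.25, by = 0.5)
    wSurv <- vapply(grid, function(t) survivalFraction(wt@basalDeath, 0, t),
                    numeric(1))
    lambdaTot <- cellsPerSub * sum(wSurv) * 0.5 * params@lambdaQ * tf
    # founder survival to expansion onset, per profile and arising time
    pSurvGrid <- lapply(phen, function(p) {
      on <- expansionOnset + p@entryDelay
      vapply(grid, function(t) {
        if (t >= on) 1 else survivalFraction(p@basalDeath, t, on)
      }, numeric(1))
    })
    for (s in seq_len(nSub)) {
      nMut <- stats::rpois(1L, lambdaTot)
      if (nMut == 0L) next
      ti <- sample.int(length(grid), nMut, replace = TRUE, prob = wSurv)
      geneIdx <- sample.int(nrow(g), nMut, replace = TRUE, prob = g$length)
      pS <- vapply(seq_len(nMut), function(k) {
        pSurvGrid[[profiles[[geneIdx[k]]]]][ti[k]]
      }, numeric(1))
      keep <- stats::runif(nMut) < pS   # founder survived to expansion
      if (!any(keep)) next
      al <- realizeAlleles(geneIdx[keep], params, catalog, "quiescence",
                           grid[ti[keep]])
      al$fate <- fates(al)
      truthParts[[length(truthParts) + 1L]] <- data.frame(
        allele = al$allele, gene = al$gene, origin = "quiescence",
        hotspot = al$hotspot, fate = al$fate, stringsAsFactors = FALSE)
      exp_ <- al$fate == "expanding"
      if (!any(exp_)) next
      al <- al[exp_, , drop = FALSE]
      start <- pmax(al$t_occurrence, onsetOf[al$gene])
      m <- 2^((days - start) /
                vapply(al$gene, function(gn) {
                  phen[[profiles[[gn]]]]@doublingTime
                }, numeric(1)))
      cells <- yuleCloneSizes(rep(1L, nrow(al)), m)
      alleleParts[[length(alleleParts) + 1L]] <- data.frame(
        subculture = s,
        al[, c("allele", "gene", "position", "mtype", "size", "effect",
               "hotspot", "t_occurrence")],
        origin = "quiescence", cells = cells, row.names = NULL,
        stringsAsFactors = FALSE)
    }

    empty <- data.frame(subculture = integer(), allele = character(),
                        gene = character(), position = numeric(),
                        mtype = character(), size = numeric(),
                        effect = character(), hotspot = logical(),
                        t_occurrence = numeric(), origin = character(),
                        cells = numeric(), stringsAsFactors = FALSE)
    alleles <- if (length(alleleParts)) do.call(rbind, alleleParts) else empty

    # aggregate identical alleles within a subculture (hotspot recurrence)
    if (nrow(alleles)) {
      key <- paste(alleles$subculture, alleles$allele)
      agg <- rowsum(alleles$cells, key)
      first <- alleles[!duplicated(key), , drop = FALSE]
      first$cells <- agg[match(paste(first$subculture, first$allele),
                               rownames(agg)), 1L]
      alleles <- first
    }

    fwt <- survivalFraction(wt@basalDeath, 0, days)
    wtSurvivors <- stats::rbinom(nSub, as.integer(cellsPerSub), fwt)

    # recycled-nitrogen budget: at most recyclingEfficiency births per death
    survivors <- numeric(nSub)
    for (s in seq_len(nSub)) {
      idx <- which(alleles$subculture == s)
      cap <- recyclingEfficiency * (cellsPerSub - wtSurvivors[s])
      tot <- sum(alleles$cells[idx])
      if (tot > cap && tot > 0) {
        alleles$cells[idx] <- floor(alleles$cells[idx] * cap / tot)
      }
      survivors[s] <- wtSurvivors[s] + sum(alleles$cells[idx])
    }
    alleles$frequency <- if (nrow(alleles)) {
      alleles$cells / survivors[alleles$subculture]
    } else numeric(0)
    alleles <- alleles[alleles$cells > 0, , drop = FALSE]
    rownames(alleles) <- NULL

    truth <- if (length(truthParts)) do.call(rbind, truthParts) else
      data.frame(allele = character(), gene = character(),
                 origin = character(), hotspot = logical(),
                 fate = character(), stringsAsFactors = FALSE)
    truth <- truth[!duplicated(truth$allele), , drop = FALSE]
    rownames(truth) <- NULL

    list(alleles = alleles, survivors = survivors, truth = truth,
         wtSurvivors = wtSurvivors)
  })
}
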