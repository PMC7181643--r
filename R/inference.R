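# Analysis stages applied to simulated (or user-supplied) outputs: origin
# classification of alleles across subcultures, viability-phase
# segmentation, clonal-expansion fitting, and burden/spectrum statistics.

#' Classify allele origin from subculture sharing
#'
#' Mutations arising during growth are partitioned at the split and show up
#' in several subcultures; mutations arising independently during
#' starvation are private to one. Registered hotspot sites recur by
#' independent origin, so their sharing pattern is uninformative:
#' an allele found in two or more subcultures that is not a hotspot is
#' classified `preexisting`; an allele in exactly one subculture `de_novo`;
#' any registered hotspot allele `hotspot_ambiguous`.
#'
#' A stricter likelihood mode (`mode = "likelihood"`) replaces the blanket
#' hotspot exemption by an explicit independent-origin test: with a
#' per-subculture probability `baseRate` that a given specific allele
#' arises and expands independently (multiplied by the hotspot rate
#' multiplier at registered sites), an allele seen in k of n subcultures is
#' called `preexisting` only when the binomial probability of >= k
#' independent recurrences falls below `alpha`; recurrent alleles that are
#' explicable by independent origin are `hotspot_ambiguous`.
#'
#' @param callsPerSubculture list (length >= 2) of call data.frames, one per
#'   subculture, each with columns `gene`, `position`, `allele` (and
#'   optionally `frequency`).
#' @param hotspotRegistry data.frame (`gene`, `position`) of hotspot sites
#'   with their `rate_multiplier`, e.g. `hotspots(defaultCatalog())`.
#' @param mode `"sharing"` (default rule) or `"likelihood"` (stricter).
#' @param baseRate likelihood mode: probability a given specific allele
#'   independently arises and is detected in one subculture.
#' @param alpha likelihood mode: significance level for rejecting
#'   independent origin.
#' @return data.frame: `allele`, `gene`, `position`, `verdict`,
#'   `n_subcultures_detected`, `evidence`.
#' @export
classifyOrigin <- function(callsPerSubculture,
                           hotspotRegistry = hotspots(defaultCatalog()),
                           mode = c("sharing", "likelihood"),
                           baseRate = 1e-4, alpha = 1e-3) {
  mode <- match.arg(mode)
  if (length(callsPerSubculture) < 2L) {
    stop("at least two subcultures are required", call. = FALSE)
  }
  need <- c("gene", "position", "allele")
  for (tab in callsPerSubculture) {
    if (!all(need %in% names(tab))) {
      stop("each call table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  all <- do.call(rbind, lapply(seq_along(callsPerSubculture), function(s) {
    tab <- callsPerSubculture[[s]]
    if (!nrow(tab)) return(NULL)
    data.frame(subculture = s, allele = tab$allele, gene = tab$gene,
               position = tab$position, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(allele = character(), gene = character(),
                      position = numeric(), verdict = character(),
                      n_subcultures_detected = integer(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  # the same allele key must always map to one (gene, position)
  chk <- unique(all[, c("allele", "gene", "position")])
  if (anyDuplicated(chk$allele)) {
    stop("inconsistent allele descriptors across subcultures", call. = FALSE)
  }
  nCultures <- length(callsPerSubculture)
  out <- lapply(unique(all$allele), function(key) {
    rows <- all[all$allele == key, , drop = FALSE]
    nSub <- length(unique(rows$subculture))
    hotIdx <- if (!is.null(hotspotRegistry) && nrow(hotspotRegistry) > 0) {
      which(hotspotRegistry$gene == rows$gene[1] &
              hotspotRegistry$position == rows$position[1])
    } else integer(0)
    hot <- length(hotIdx) > 0
    if (mode == "sharing") {
      if (hot) {
        verdict <- "hotspot_ambiguous"
        evidence <- sprintf(
          "registered hotspot site; detected in %d subculture(s), recurrence explicable by independent origin",
          nSub)
      } else if (nSub >= 2L) {
        verdict <- "preexisting"
        evidence <- sprintf(
          "detected in %d subcultures; independent origin of identical non-hotspot alleles is implausible",
          nSub)
      } else {
        verdict <- "de_novo"
        evidence <- "private to one subculture"
      }
    } else {
      mult <- if (hot && "rate_multiplier" %in% names(hotspotRegistry)) {
        hotspotRegistry$rate_multiplier[hotIdx[1]]
      } else 1
      p1 <- min(1, baseRate * mult)
      pIndep <- stats::pbinom(nSub - 1L, nCultures, p1, lower.tail = FALSE)
      if (nSub >= 2L && pIndep < alpha) {
        verdict <- "preexisting"
        evidence <- sprintf(
          "detected in %d/%d subcultures; P(independent recurrence) = %.2g < %g",
          nSub, nCultures, pIndep, alpha)
      } else if (nSub >= 2L) {
        verdict <- "hotspot_ambiguous"
        evidence <- sprintf(
          "recurrence in %d/%d subcultures explicable by independent origin (P = %.2g)",
          nSub, nCultures, pIndep)
      } else {
        verdict <- "de_novo"
        evidence <- "private to one subculture"
      }
    }
    data.frame(allele = key, gene = rows$gene[1], position = rows$position[1],
               verdict = verdict, n_subcultures_detected = nSub,
               evidence = evidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment a CFU trajectory into three viability phases
#'
#' Fits a continuous two-breakpoint piecewise-linear model to log10 CFU by
#' exhaustive search over the observation-time grid, minimizing the
#' residual sum of squares. Starved wild-type cultures show maintenance
#' (phase I), rapid decline (phase II) and stabilization (phase III).
#'
#' @param traj A \linkS4class{CFUTrajectory} or data.frame with columns
#'   `time` and `cfu` (total CFU used for a trajectory object).
#' @param minPointsPerSegment minimum observations per segment.
#' @return list: `breakpoints` (two days), `slopes` (log10 CFU/day per
#'   phase), `rss`, `degenerate` (TRUE when a single line fits essentially
#'   as well, e.g. flat or single-slope data).
#' @export
segmentPhases <- function(traj, minPointsPerSegment = 3L) {
  if (is(traj, "CFUTrajectory")) {
    d <- data.frame(time = traj@times, cfu = rowSums(traj@cfu))
  } else d <- traj[, c("time", "cfu")]
  d <- d[is.finite(d$cfu), , drop = FALSE]
  if (nrow(d) < 9L || diff(range(d$time)) < 60) {
    stop("need >= 9 points spanning >= 60 days", call. = FALSE)
  }
  y <- log10(pmax(d$cfu, 0.5))
  t <- d$time
  n <- length(t)
  grid <- t[-c(1L, n)]
  best <- list(rss = Inf)
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (j <= i) next
      b1 <- grid[i]; b2 <- grid[j]
      if (sum(t <= b1) < minPointsPerSegment ||
          sum(t > b1 & t <= b2) < minPointsPerSegment ||
          sum(t > b2) < minPointsPerSegment) next
      X <- cbind(1, t, pmax(t - b1, 0), pmax(t - b2, 0))
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        beta <- fit$coefficients
        best <- list(rss = rss, breakpoints = c(b1, b2),
                     slopes = c(beta[2], beta[2] + beta[3],
                                beta[2] + beta[3] + beta[4]))
      }
    }
  }
  if (!is.finite(best$rss)) stop("no admissible breakpoint pair", call. = FALSE)
  lin <- stats::lm.fit(cbind(1, t), y)
  rssLin <- sum(lin$residuals^2)
  degenerate <- rssLin < 1e-12 || (rssLin - best$rss) < 0.05 * max(rssLin, 1e-12)
  names(best$slopes) <- c("I", "II", "III")
  list(breakpoints = best$breakpoints, slopes = best$slopes, rss = best$rss,
       degenerate = degenerate)
}

#' Fit exponential clonal expansion and recover the doubling time
#'
#' Least squares on log2 CFU versus time inside the window (default days
#' 30-60, where co-cultured mutants expand); doubling time is the
#' reciprocal slope.
#'
#' @param traj A \linkS4class{CFUTrajectory} or data.frame (`time`, `cfu`);
#'   for a trajectory, `class` selects the column (default: last class,
#'   i.e. the marked mutant).
#' @param window c(start, end) days.
#' @param class class name within a trajectory object.
#' @return list: `window`, `doubling_time` (days; `NA` with
#'   `declining = TRUE` for a negative slope), `slope` (log2/day),
#'   `r_squared`, `n`.
#' @export
fitExpansion <- function(traj, window = c(30, 60), class = NULL) {
  if (is(traj, "CFUTrajectory")) {
    if (is.null(class)) class <- colnames(traj@cfu)[ncol(traj@cfu)]
    d <- data.frame(time = traj@times, cfu = traj@cfu[, class])
  } else d <- traj[, c("time", "cfu")]
  d <- d[d$time >= window[1] & d$time <= window[2], , drop = FALSE]
  if (nrow(d) < 4L) stop("need >= 4 points in the window", call. = FALSE)
  if (any(d$cfu <= 0)) stop("nonpositive CFU in the window", call. = FALSE)
  fit <- stats::lm(log2(cfu) ~ time, data = d)
  slope <- unname(stats::coef(fit)[2])
  y <- log2(d$cfu)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  list(window = window,
       doubling_time = if (slope > 0) 1 / slope else NA_real_,
       slope = slope, declining = slope <= 0, r_squared = r2, n = nrow(d))
}

#' Burden summary statistics against the Poisson expectation
#'
#' @param burdens integer vector of per-genome mutation counts.
#' @return list: `mean`, `zero_fraction`, `poisson_dispersion`
#'   (variance/mean; `NA` with `flagged = TRUE` when undefined, e.g. all
#'   zeros), `poisson_gof_p` (chi-square goodness of fit against
#'   Poisson(mean), tail bins pooled to expected counts >= 5).
#' @export
burdenStats <- function(burdens) {
  if (!length(burdens)) stop("burdens must be non-empty", call. = FALSE)
  m <- mean(burdens)
  zf <- mean(burdens == 0)
  if (m == 0) {
    return(list(mean = 0, zero_fraction = 1, poisson_dispersion = NA_real_,
                poisson_gof_p = NA_real_, flagged = TRUE))
  }
  disp <- stats::var(burdens) / m
  kmax <- max(burdens)
  obs <- tabulate(factor(burdens, levels = 0:kmax), nbins = kmax + 1L)
  expd <- length(burdens) *
    c(stats::dpois(0:(kmax - 1), m), stats::ppois(kmax - 1, m,
                                                  lower.tail = FALSE))
  if (kmax == 0) expd <- length(burdens)
  # pool tail bins until each expected count is at least 5
  while (length(expd) > 2L && expd[length(expd)] < 5) {
    k <- length(expd)
    expd[k - 1L] <- expd[k - 1L] + expd[k]; expd <- expd[-k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]; obs <- obs[-k]
  }
  p <- if (length(expd) > 2L) {
    chi <- sum((obs - expd)^2 / expd)
    stats::pchisq(chi, df = length(expd) - 2L, lower.tail = FALSE)
  } else NA_real_
  list(mean = m, zero_fraction = zf, poisson_dispersion = disp,
       poisson_gof_p = p, flagged = FALSE)
}

#' Mutation-spectrum summary and SAPK-constraint audit
#'
#' Tabulates mutation types and the per-gene effect-class table, and flags
#' any loss-of-function allele (nonsense or frameshift) in a SAPK gene
#' other than win1 as a model violation: such alleles are never tolerated
#' in quiescence.
#'
#' @param events data.frame of mutation events or variant calls carrying
#'   `mtype`/`gene`/`effect` columns (calls from \code{\link{callVariants}}
#'   are accepted when joined to their allele metadata).
#' @param catalog A \linkS4class{TargetCatalog} for the audit.
#' @return list: `type_counts` (named counts over SNV/insertion/deletion/
#'   duplication), `effect_table` (gene x effect class), `violations`
#'   (data.frame of offending alleles).
#' @export
spectrumSummary <- function(events, catalog = defaultCatalog()) {
  typeCounts <- vapply(MUTATION_TYPES, function(mt) {
    if (!nrow(events)) 0L else sum(events$mtype == mt)
  }, integer(1))
  inGene <- if (nrow(events)) {
    events[events$gene %in% genes(catalog)$gene & !is.na(events$effect), ,
           drop = FALSE]
  } else events
  effectTable <- if (nrow(inGene)) {
    table(factor(inGene$gene, levels = genes(catalog)$gene),
          factor(inGene$effect, levels = EFFECT_CLASSES))
  } else {
    table(factor(character(), levels = genes(catalog)$gene),
          factor(character(), levels = EFFECT_CLASSES))
  }
  g <- genes(catalog)
  sapk <- g$gene[g$pathway == "SAPK" & g$gene != "win1"]
  violations <- if (nrow(inGene)) {
    inGene[inGene$gene %in% sapk &
             inGene$effect %in% c("nonsense", "frameshift_indel"), ,
           drop = FALSE]
  } else inGene
  list(type_counts = typeCounts, effect_table = effectTable,
       violations = violations)
}

#' Minimum number of doublings implied by a frequency change
#'
#' A clone moving from frequency `f1` in a population of size `N1` to `f2`
#' in `N2` must have divided at least `log2((f2 N2) / (f1 N1))` times; with
#' equal population sizes this is `log2(f2 / f1)`. A negative value (net
#' decline) is returned with `declined = TRUE`.
#'
#' @param f1,f2 clone frequencies (0 < f <= 1).
#' @param N1,N2 population sizes (> 0).
#' @return list: `doublings`, `declined`.
#' @examples
#' minDoublings(0.096, 0.435)$doublings  # ~2.18
#' @export
minDoublings <- function(f1, f2, N1 = 1, N2 = 1) {
  for (v in list(f1 = f1, f2 = f2)) if (v <= 0 || v > 1) {
    stop("frequencies must be in (0, 1]", call. = FALSE)
  }
  if (N1 <= 0 || N2 <= 0) stop("population sizes must be > 0", call. = FALSE)
  d <- log2((f2 * N2) / (f1 * N1))
  list(doublings = d, declined = d < 0)
}
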