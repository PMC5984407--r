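# Genome-exchange diagnostics: divergent alleles, carrier frequencies,
# rarefied allelic richness, alternative alleles, centroid-dispersion
# partitioning.

#' Mutation steps between two allele sizes
#'
#' @param a,b allele sizes in bp (vectorized).
#' @param motif repeat-unit length in bp (> 0).
#' @return nonnegative integer number of single-repeat steps,
#'   `round(|a - b| / motif)`.
#' @export
mutationSteps <- function(a, b, motif) {
  if (any(motif <= 0)) stop("motif length must be positive")
  as.integer(round(abs(a - b) / motif))
}

#' Detect highly divergent alleles
#'
#' Per locus, alleles are clustered by single-linkage with mutation-step
#' gaps below `gap_threshold`; the main cluster is the largest connected
#' set, and every allele outside it is flagged divergent, with the gap to
#' its nearest main-cluster allele reported.  Two equal-size largest
#' clusters are an error requiring manual designation.
#'
#' @param alleles named list locus -> integer allele sizes (e.g. the names
#'   of an [estimateAlleleFrequencies()] locus table), or an
#'   `AlleleFrequencyTable`.
#' @param motifs named integer vector of motif lengths per locus, or a
#'   locus table.
#' @param gap_threshold minimum step gap flagging divergence (default 8).
#' @return named list locus -> data.frame(`allele`, `gap`); loci without
#'   divergent alleles get a zero-row data.frame.
#' @export
detectDivergentAlleles <- function(alleles, motifs, gap_threshold = 8) {
  if (inherits(alleles, "AlleleFrequencyTable")) {
    if (length(alleles$tables) > 1)
      stop("use a global-scope frequency table for divergence detection")
    alleles <- lapply(alleles$tables[[1]],
                      function(f) as.integer(names(f)))
  }
  if (is.data.frame(motifs)) {
    motifs <- stats::setNames(motifs$motif, motifs$name)
  }
  out <- lapply(names(alleles), function(loc) {
    a <- sort(unique(alleles[[loc]]))
    motif <- motifs[[loc]]
    if (length(a) < 2)
      return(data.frame(allele = integer(0), gap = integer(0)))
    # single-linkage components on the sorted alleles: a gap of >=
    # threshold steps between neighbors separates components
    gaps <- mutationSteps(a[-1], a[-length(a)], motif)
    comp <- cumsum(c(1L, gaps >= gap_threshold))
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes == max(sizes)])
    if (length(big) > 1)
      stop("two equal-size allele clusters at locus ", loc,
           "; designate the main cluster manually")
    main <- a[comp == big]
    flagged <- a[comp != big]
    gap <- vapply(flagged, function(x)
      min(mutationSteps(x, main, motif)), integer(1))
    data.frame(allele = flagged, gap = gap)
  })
  names(out) <- names(alleles)
  out
}

#' Divergent-allele carrier frequency at a locus
#'
#' With `denominator = "copies"` (default): the percentage of haplome copy
#' slots at the locus occupied by divergent alleles, unresolved
#' multiplicities split uniformly over the observed alleles (an individual
#' of copy number c showing k distinct alleles contributes c/k slots to
#' each).  With `denominator = "individuals"`: the percentage of
#' individuals carrying at least one divergent allele.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes called.
#' @param divergent integer vector of divergent allele sizes at the locus
#'   (e.g. one entry of [detectDivergentAlleles()]).
#' @param locus isolocus name.
#' @param ids individuals to include (default all).
#' @param denominator `"copies"` or `"individuals"`.
#' @return percentage, or `NA` when no individual has data at the locus.
#' @export
carrierFrequency <- function(dataset, divergent, locus, ids = NULL,
                             denominator = c("copies", "individuals")) {
  denominator <- match.arg(denominator)
  if (!is.null(ids)) dataset <- dataset[ids, ]
  j <- match(locus, dataset@loci$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  hap <- dataset@loci$haplome[j]
  ind <- dataset@individuals
  g <- dataset@genotypes[, j]
  have <- lengths(g) > 0
  if (!any(have)) return(NA_real_)
  if (denominator == "individuals")
    return(100 * mean(vapply(g[have], function(a)
      any(a %in% divergent), logical(1))))
  slots <- 0; hit <- 0
  for (i in which(have)) {
    k <- length(g[[i]])
    cn <- if (hap %in% c("J", "L") && ind$biotype[i] != "UNCALLED")
      max(haplomePloidy(ind$biotype[i], hap), k) else k
    slots <- slots + cn
    hit <- hit + cn / k * sum(g[[i]] %in% divergent)
  }
  100 * hit / slots
}

#' Probability of sampling no divergent-allele carrier
#'
#' `(1 - p)^n` for a mean per-copy carrier frequency `p` and `n` sampled
#' individuals; monotone decreasing in both arguments.
#'
#' @param p_mean mean carrier frequency as a proportion in `[0, 1]` (mean
#'   over loci of the per-locus carrier frequency).
#' @param n number of individuals sampled.
#' @return probability.
#' @export
probNoCarrier <- function(p_mean, n) {
  stopifnot(p_mean >= 0, p_mean <= 1, n >= 0)
  (1 - p_mean)^n
}

#' Haplome copy count of a group
#'
#' Sum over individuals of the copies of the haplome implied by their
#' biotype (LL = 2 L / 0 J, LJ = 1/1, LLJ = 2/1, LLLJ = 3/1).  UNCALLED
#' individuals are excluded with a warning.
#'
#' @param biotypes character vector of biotypes (or an
#'   [MsatDataset-class], in which case all its individuals are used).
#' @param haplome `"J"` or `"L"`.
#' @return integer total copy count.
#' @export
weightedHaplomeCount <- function(biotypes, haplome) {
  if (is(biotypes, "MsatDataset")) biotypes <- biotypes@individuals$biotype
  bad <- biotypes == "UNCALLED"
  if (any(bad)) {
    warning(sum(bad), " UNCALLED individual(s) excluded from haplome count")
    biotypes <- biotypes[!bad]
  }
  if (length(biotypes) == 0) return(0L)
  sum(haplomePloidy(biotypes, haplome))
}

#' Weighted ploidy level of a group
#'
#' [weightedHaplomeCount()] divided by group size: the mean number of
#' copies of the haplome per individual.
#'
#' @inheritParams weightedHaplomeCount
#' @return real ploidy level.
#' @export
weightedPloidyLevel <- function(biotypes, haplome) {
  if (is(biotypes, "MsatDataset")) biotypes <- biotypes@individuals$biotype
  if (length(biotypes) == 0) stop("weighted ploidy of an empty group")
  weightedHaplomeCount(biotypes, haplome) / length(biotypes)
}

#' Rarefied allele count (hypergeometric allelic richness)
#'
#' Expected number of distinct alleles in a subsample of `n_rarefy` copies
#' drawn without replacement from the observed copies:
#' `sum_a [1 - C(N - N_a, n) / C(N, n)]`.  Counts may be fractional (from
#' uniform splitting of unresolved multiplicities); the binomial
#' coefficients are then evaluated through the gamma function.
#'
#' @param counts numeric vector of copy counts per allele.
#' @param n_rarefy subsample size (`> 0`, `<= sum(counts)`).
#' @return expected distinct allele count.
#' @export
rarefiedAlleleCount <- function(counts, n_rarefy) {
  if (n_rarefy <= 0) stop("rarefaction size must be positive")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n_rarefy > N + 1e-9) stop("rarefaction size exceeds total copies")
  sum(vapply(counts, function(na) {
    if (N - na < n_rarefy) return(1)
    1 - exp(lchoose(N - na, n_rarefy) - lchoose(N, n_rarefy))
  }, numeric(1)))
}

# weighted allele copy counts at one isolocus for a set of individuals:
# each individual's copy number split uniformly over its distinct alleles
alleleCopyCounts <- function(dataset, j, rows) {
  hap <- dataset@loci$haplome[j]
  ind <- dataset@individuals
  counts <- numeric(0)
  for (i in rows) {
    a <- dataset@genotypes[[i, j]]
    if (length(a) == 0) next
    cn <- if (hap %in% c("J", "L") && ind$biotype[i] != "UNCALLED")
      max(haplomePloidy(ind$biotype[i], hap), length(a)) else length(a)
    for (x in a) {
      key <- as.character(x)
      counts[key] <- (if (key %in% names(counts)) counts[key] else 0) +
        cn / length(a)
    }
  }
  counts
}

#' Alternative alleles per locus
#'
#' The ploidy-controlled excess of allelic richness over what strict
#' clonality would produce: per locus, the rarefied allele count of the
#' unit minus its clonal baseline, floored at zero, averaged over the
#' locus set.  The default baseline is the distinct-allele count of the
#' unit's consensus (modal) genotype at the locus -- the count clonal
#' propagation of the modal genotype alone would show;
#' `baseline = "min-individual"` instead uses the smallest distinct-allele
#' count among the unit's scored individuals.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes called.
#' @param ids individuals forming the unit (e.g. one group at one site).
#' @param haplome `"J"` or `"L"`: which isolocus set to average over.
#' @param n_rarefy rarefaction size in haplome copies; defaults to the
#'   unit's own weighted haplome count (no rarefaction).  When comparing
#'   units, pass the minimum weighted haplome count across the compared
#'   units.
#' @param baseline `"consensus"` or `"min-individual"`.
#' @return mean number of alternative alleles per locus.
#' @export
alternativeAlleles <- function(dataset, ids, haplome,
                               n_rarefy = NULL,
                               baseline = c("consensus", "min-individual")) {
  baseline <- match.arg(baseline)
  idx <- isoLoci(dataset, haplome)
  rows <- match(ids, dataset@individuals$id)
  if (anyNA(rows)) stop("unknown individual id")
  if (is.null(n_rarefy))
    n_rarefy <- weightedHaplomeCount(
      dataset@individuals$biotype[rows], haplome)
  cons <- consensusGenotype(dataset, ids, dataset@loci$name[idx])
  vals <- numeric(0)
  for (j in idx) {
    counts <- alleleCopyCounts(dataset, j, rows)
    if (length(counts) == 0) {
      warning("locus ", dataset@loci$name[j],
              " unscored in the unit; skipped")
      next
    }
    nr <- min(n_rarefy, sum(counts))
    rich <- rarefiedAlleleCount(counts, nr)
    base <- if (baseline == "consensus")
      length(cons[[dataset@loci$name[j]]])
    else min(lengths(Filter(length, dataset@genotypes[rows, j])))
    vals <- c(vals, max(rich - base, 0))
  }
  if (length(vals) == 0) stop("no scored locus in the unit")
  mean(vals)
}

#' Alternative-allele report per group and site
#'
#' For every (group, site) unit with at least `min_size` individuals,
#' reports the weighted haplome count, weighted ploidy level, rarefied
#' allele count and mean alternative alleles per locus for the J and L
#' isolocus sets.  The rarefaction size is the minimum weighted haplome
#' count across all reported units and both haplomes (so units of
#' different size and ploidy are compared on an equal number of copies);
#' pass `n_rarefy` to override.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes and groups
#'   assigned.
#' @param min_size smallest unit reported (default 5).
#' @param n_rarefy optional fixed rarefaction size.
#' @param baseline see [alternativeAlleles()].
#' @return data.frame with one row per (group, site, haplome).
#' @export
alternativeAlleleReport <- function(dataset, min_size = 5, n_rarefy = NULL,
                                    baseline = "consensus") {
  ind <- dataset@individuals
  keep <- ind$group %in% setdiff(GROUPS, c("X", "UNASSIGNED")) &
    ind$biotype %in% c("LJ", "LLJ", "LLLJ")
  combos <- unique(data.frame(group = ind$group[keep],
                              site = ind$site[keep]))
  units <- lapply(seq_len(nrow(combos)), function(k)
    ind$id[keep & ind$group == combos$group[k] & ind$site == combos$site[k]])
  big <- lengths(units) >= min_size
  combos <- combos[big, , drop = FALSE]
  units <- units[big]
  if (length(units) == 0) stop("no unit reaches the minimum size")
  counts <- unlist(lapply(units, function(ids) {
    bt <- ind$biotype[match(ids, ind$id)]
    c(weightedHaplomeCount(bt, "J"), weightedHaplomeCount(bt, "L"))
  }))
  if (is.null(n_rarefy)) n_rarefy <- min(counts)
  rows <- list()
  for (u in seq_along(units)) {
    ids <- units[[u]]
    bt <- ind$biotype[match(ids, ind$id)]
    for (hap in c("J", "L")) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = combos$group[u], site = combos$site[u], haplome = hap,
        n_individuals = length(ids),
        haplome_count = weightedHaplomeCount(bt, hap),
        ploidy_level = weightedPloidyLevel(bt, hap),
        n_rarefy = n_rarefy,
        alt_alleles = alternativeAlleles(dataset, ids, hap,
                                         n_rarefy = n_rarefy,
                                         baseline = baseline))
    }
  }
  do.call(rbind, rows)
}

#' Partition genetic dispersion within and among sites
#'
#' Principal-coordinates embedding of the distance matrix with both
#' positive and negative eigenvalue axes retained (squared distances to a
#' centroid are the positive-axis contribution minus the negative-axis
#' contribution, floored at zero -- the standard treatment of semi-metric
#' distances in multivariate dispersion analysis).  Per group: `total` is
#' the mean distance of members to the group centroid, `intra` the mean
#' distance to their own (group x site) centroid, and `inter = total -
#' intra`; percentages are relative to total.  Groups with a single
#' member get NA.
#'
#' @param m symmetric labeled distance matrix.
#' @param groups group label per individual (matrix order).
#' @param sites site label per individual.
#' @return list with `partition` (data.frame: group, n, total, inter,
#'   intra, pct_inter, pct_intra), `dist_to_group_centroid` and
#'   `dist_to_site_centroid` (named per-individual vectors, for
#'   [compareDispersions()]).
#' @export
dispersionPartition <- function(m, groups, sites) {
  checkSymmetricMatrix(m)
  stopifnot(length(groups) == nrow(m), length(sites) == nrow(m))
  d <- stats::as.dist(m)
  if (max(m) == 0) {
    dTot <- dIntra <- rep(0, nrow(m))
  } else {
    bdTot <- vegan::betadisper(d, groups, type = "centroid")
    cell <- interaction(groups, sites, drop = TRUE)
    bdIntra <- vegan::betadisper(d, cell, type = "centroid")
    dTot <- bdTot$distances
    dIntra <- bdIntra$distances
  }
  names(dTot) <- names(dIntra) <- rownames(m)
  part <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    if (sum(sel) < 2)
      return(data.frame(group = g, n = sum(sel), total = NA_real_,
                        inter = NA_real_, intra = NA_real_,
                        pct_inter = NA_real_, pct_intra = NA_real_))
    tot <- mean(dTot[sel])
    intra <- mean(dIntra[sel])
    inter <- tot - intra
    if (inter < 0) {
      warning("negative inter-site dispersion for group ", g,
              " floored at 0")
      inter <- 0; intra <- tot
    }
    pin <- if (tot > 0) 100 * intra / tot else NA_real_
    data.frame(group = g, n = sum(sel), total = tot, inter = inter,
               intra = intra,
               pct_inter = if (is.na(pin)) NA_real_ else 100 - pin,
               pct_intra = pin)
  }))
  rownames(part) <- NULL
  list(partition = part, dist_to_group_centroid = dTot,
       dist_to_site_centroid = dIntra)
}

# compact letter display by insert-absorb from a logical "significantly
# different" pairwise matrix
compactLetters <- function(sig) {
  lv <- rownames(sig)
  cols <- list(lv)  # each column: set of levels sharing a letter
  for (i in seq_along(lv)) for (j in seq_len(i - 1)) {
    if (!sig[i, j]) next
    for (k in seq_along(cols)) {
      if (all(c(lv[i], lv[j]) %in% cols[[k]])) {
        a <- setdiff(cols[[k]], lv[i])
        b <- setdiff(cols[[k]], lv[j])
        cols[[k]] <- a
        if (!any(vapply(cols, function(x) all(b %in% x), logical(1))))
          cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in others
    keep <- !vapply(seq_along(cols), function(k)
      any(vapply(seq_along(cols), function(l)
        l != k && all(cols[[k]] %in% cols[[l]]) &&
          length(cols[[k]]) < length(cols[[l]]), logical(1))), logical(1))
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, function(x) min(match(x, lv)), numeric(1)))
  cols <- cols[ord]
  vapply(lv, function(g)
    paste(letters[which(vapply(cols, function(x) g %in% x, logical(1)))],
          collapse = ""), character(1))
}

#' Compare group dispersions by ANOVA and Tukey HSD
#'
#' One-way ANOVA on per-individual distances to their group centroid,
#' followed by Tukey honest significant differences and a compact letter
#' display (groups sharing no letter differ at `alpha`).
#'
#' @param distances named per-individual distances to centroid (e.g. from
#'   [dispersionPartition()]).
#' @param groups group label per individual.
#' @param alpha significance level for the letter display.
#' @return list with `F`, `p`, `tukey` (data.frame of pairwise
#'   comparisons) and `letters` (named character vector).  With zero
#'   within-group variance everywhere, `F` and `p` are NA.
#' @export
compareDispersions <- function(distances, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two members")
  df <- data.frame(y = as.numeric(distances), g = groups)
  if (all(tapply(df$y, df$g, stats::sd) == 0)) {
    lv <- levels(groups)
    same <- length(unique(tapply(df$y, df$g, mean))) == 1
    return(list(F = NA_real_, p = NA_real_, tukey = NULL,
                letters = stats::setNames(
                  if (same) rep("a", length(lv)) else letters[seq_along(lv)],
                  lv)))
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  lv <- levels(groups)
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lv, lv))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (k in seq_along(prs)) {
    a <- prs[[k]][1]; b <- prs[[k]][2]
    sig[a, b] <- sig[b, a] <- tk[k, "p adj"] < alpha
  }
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = as.data.frame(tk), letters = compactLetters(sig))
}
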