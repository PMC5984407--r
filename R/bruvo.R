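# Bruvo-type genotype distances under the stepwise mutation model, with
# genome-addition / genome-loss handling of unequal ploidy and
# allele-frequency-weighted imputation of partial heterozygotes.

# permutation index matrices for k = 1..4, computed once
permCache <- new.env(parent = emptyenv())
allPerms <- function(k) {
  key <- as.character(k)
  if (!is.null(permCache[[key]])) return(permCache[[key]])
  if (k == 1) p <- matrix(1L, 1, 1)
  else {
    sub <- allPerms(k - 1)
    p <- do.call(rbind, lapply(seq_len(k), function(i) {
      rest <- seq_len(k)[-i]
      cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    }))
  }
  storage.mode(p) <- "integer"
  permCache[[key]] <- p
  p
}

#' Single-allele dissimilarity under the stepwise mutation model
#'
#' `1 - 2^(-x)` where `x = |a - b| / motif` is the number of single-repeat
#' mutation steps separating two allele sizes.  A size difference that is
#' not a whole number of repeat units (fragment-size jitter) is rounded to
#' the nearest whole step with a warning.
#'
#' @param a,b allele sizes in bp (vectorized).
#' @param motif repeat-unit length in bp (> 0).
#' @return dissimilarity in `[0, 1)`.
#' @export
alleleStepDistance <- function(a, b, motif) {
  if (motif <= 0) stop("motif length must be positive")
  if (any(a < 0) || any(b < 0)) stop("allele sizes must be nonnegative")
  x <- abs(a - b) / motif
  r <- round(x)
  if (any(abs(x - r) > 1e-9))
    warning("allele difference not a whole number of repeat units; ",
            "rounded to the nearest step")
  1 - 2^(-r)
}

# minimum over one-to-one allele assignments of the mean per-pair
# step distance; x, y equal-length integer multisets
bruvoCore <- function(x, y, motif) {
  k <- length(x)
  d <- 1 - 2^(-round(abs(outer(x, y, "-")) / motif))
  if (k == 1) return(d[1, 1])
  perms <- allPerms(k)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    s <- sum(d[cbind(seq_len(k), perms[r, ])])
    if (s < best) best <- s
  }
  best / k
}

# ordered tuples (rows) of length d over pool values
orderedTuples <- function(pool, d) {
  if (d == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(pool), d), KEEP.OUT.ATTRS = FALSE))
}

#' Bruvo genotype distance with genome addition and loss
#'
#' For genotypes of equal ploidy `k` the distance is the minimum over all
#' one-to-one allele assignments of the mean single-allele step distance
#' (exhaustive enumeration; `k <= 4`).  For unequal ploidy the smaller
#' multiset is completed with virtual alleles: under the genome-addition
#' model the virtual alleles are copies of the smaller genotype's own
#' alleles, under the genome-loss model they are copies of the larger
#' genotype's alleles.  All completions (virtual alleles drawn
#' independently from the relevant allele set) are evaluated as
#' equal-ploidy distances and averaged; when both models are requested the
#' final distance is the mean of the two model averages.
#'
#' @param g1,g2 integer allele multisets (full copy-number expansion, with
#'   repeats for homozygous copies).  An empty genotype yields `NA`.
#' @param motif repeat-unit length in bp.
#' @param model character subset of `c("add", "loss")`; default both.
#' @return dissimilarity in `[0, 1]`, or `NA_real_` for missing data.
#' @export
bruvoGenotypeDistance <- function(g1, g2, motif,
                                  model = c("add", "loss")) {
  model <- match.arg(model, several.ok = TRUE)
  if (length(g1) == 0 || length(g2) == 0) return(NA_real_)
  if (any(c(g1, g2) < 0)) stop("allele sizes must be nonnegative")
  if (length(g1) > MAX_PLOIDY || length(g2) > MAX_PLOIDY)
    stop("ploidy above ", MAX_PLOIDY, " not supported")
  if (length(g1) == length(g2)) return(bruvoCore(g1, g2, motif))
  if (length(g1) < length(g2)) { s <- g1; l <- g2 } else { s <- g2; l <- g1 }
  d <- length(l) - length(s)
  completionMean <- function(pool) {
    tuples <- orderedTuples(unique(pool), d)
    mean(apply(tuples, 1, function(v) bruvoCore(c(s, v), l, motif)))
  }
  vals <- c(add = if ("add" %in% model) completionMean(s) else NA_real_,
            loss = if ("loss" %in% model) completionMean(l) else NA_real_)
  mean(vals[model])
}

#' Estimate isolocus allele frequencies
#'
#' Each individual contributes weight equal to its haplome copy number at
#' the isolocus (from its biotype), split uniformly over its observed
#' distinct alleles: a triploid L-genotype showing `{A, B}` contributes
#' 1.5 copies to each (one certain copy plus the unresolved third split
#' 0.5/0.5).  Frequencies are normalized per locus within each scope unit.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes called.
#' @param loci isolocus names (default: all J and L isoloci).
#' @param scope `"per-site"`, `"global"` or `"per-group"`.
#' @return object of class `AlleleFrequencyTable`: list with elements
#'   `scope` and `tables` (named list unit -> locus -> named frequency
#'   vector).
#' @export
estimateAlleleFrequencies <- function(dataset, loci = NULL,
                                      scope = c("per-site", "global",
                                                "per-group")) {
  scope <- match.arg(scope)
  if (is.null(loci))
    loci <- dataset@loci$name[dataset@loci$haplome %in% c("J", "L")]
  jn <- match(loci, dataset@loci$name)
  if (anyNA(jn)) stop("unknown locus: ", paste(loci[is.na(jn)], collapse = ","))
  ind <- dataset@individuals
  unit <- switch(scope,
                 "global"    = rep("global", nrow(ind)),
                 "per-site"  = ind$site,
                 "per-group" = ind$group)
  g <- dataset@genotypes
  tables <- lapply(split(seq_len(nrow(ind)), unit), function(rows) {
    tab <- lapply(seq_along(jn), function(k) {
      j <- jn[k]
      hap <- dataset@loci$haplome[j]
      counts <- numeric(0)
      for (i in rows) {
        a <- g[[i, j]]
        if (length(a) == 0) next
        cn <- if (hap %in% c("J", "L") && ind$biotype[i] != "UNCALLED")
          max(haplomePloidy(ind$biotype[i], hap), length(a))
        else length(a)
        w <- rep(cn / length(a), length(a))
        for (t in seq_along(a)) {
          key <- as.character(a[t])
          counts[key] <- if (key %in% names(counts))
            counts[key] + w[t] else w[t]
        }
      }
      if (length(counts) == 0) return(NULL)
      counts <- counts[order(as.integer(names(counts)))]
      counts / sum(counts)
    })
    names(tab) <- loci
    tab[!vapply(tab, is.null, logical(1))]
  })
  structure(list(scope = scope, tables = tables),
            class = "AlleleFrequencyTable")
}

lookupFreqs <- function(freqs, unit, locus) {
  if (is.null(freqs)) return(NULL)
  tab <- freqs$tables[[unit]]
  if (is.null(tab)) tab <- freqs$tables[[1]]
  tab[[locus]]
}

# all completions (full multisets) of an observed genotype to copy number
# `cn`, with weights from reference frequencies: the unresolved copies are
# drawn independently from the observed alleles, each completion weighted
# by the product of the reference frequencies of the duplicated alleles
# and renormalized.  Returns list(genotypes = list of multisets,
# weights = numeric).
completeGenotype <- function(obs, cn, f = NULL) {
  k <- length(obs)
  if (k == 0 || cn <= k)
    return(list(genotypes = list(obs), weights = 1))
  d <- cn - k
  tuples <- orderedTuples(obs, d)
  if (is.null(f)) {
    w <- rep(1, nrow(tuples))
  } else {
    miss <- setdiff(as.character(obs), names(f))
    if (length(miss)) {
      warning("allele(s) absent from frequency table assigned the minimum ",
              "observed frequency: ", paste(miss, collapse = ", "))
      f[miss] <- min(f)
    }
    w <- apply(tuples, 1, function(v) prod(f[as.character(v)]))
    if (sum(w) == 0) w <- rep(1, length(w))
  }
  list(genotypes = lapply(seq_len(nrow(tuples)),
                          function(r) c(obs, unname(tuples[r, ]))),
       weights = w / sum(w))
}

#' Frequency-weighted Bruvo distance for partial heterozygotes
#'
#' When a polyploid genotype shows fewer distinct alleles than its copy
#' number, the unresolved copies are imputed: every completion to full
#' copy number using the observed alleles is enumerated and weighted by
#' the product of the reference allele frequencies of the duplicated
#' alleles (renormalized over completions).  The distance is the weighted
#' mean of [bruvoGenotypeDistance()] over all completion pairs.  An
#' unambiguous pair reduces exactly to [bruvoGenotypeDistance()].
#'
#' @param g1,g2 observed distinct allele vectors.
#' @param p1,p2 copy numbers (ploidy at this isolocus).
#' @param motif repeat-unit length in bp.
#' @param f1,f2 named reference frequency vectors for each genotype's
#'   population (`NULL` for uniform weighting).  Alleles absent from the
#'   table are assigned the minimum observed frequency with a warning.
#' @param model see [bruvoGenotypeDistance()].
#' @return dissimilarity in `[0, 1]`, `NA` for missing data.
#' @export
weightedPartialHetDistance <- function(g1, g2, p1, p2, motif,
                                       f1 = NULL, f2 = NULL,
                                       model = c("add", "loss")) {
  if (length(g1) == 0 || length(g2) == 0) return(NA_real_)
  c1 <- completeGenotype(g1, p1, f1)
  c2 <- completeGenotype(g2, p2, f2)
  total <- 0
  for (i in seq_along(c1$genotypes))
    for (j in seq_along(c2$genotypes))
      total <- total + c1$weights[i] * c2$weights[j] *
        bruvoGenotypeDistance(c1$genotypes[[i]], c2$genotypes[[j]],
                              motif, model)
  total
}

#' Pairwise Bruvo distance matrix over an isolocus set
#'
#' Per-locus distances use the biotype-implied haplome copy numbers, with
#' frequency-weighted imputation of partial heterozygotes, and are
#' averaged over the loci where both individuals have data.  Origin-
#' unresolved (`U`) isoloci are never included.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes called.
#' @param haplome `"J"`, `"L"` or `"LJ"` (both).
#' @param model see [bruvoGenotypeDistance()].
#' @param freqs an `AlleleFrequencyTable` for imputation weighting, or
#'   `NULL` to estimate one at `freq_scope` from the dataset.
#' @param freq_scope scope passed to [estimateAlleleFrequencies()] when
#'   `freqs` is NULL.
#' @param by_locus return the individuals x individuals x loci array of
#'   per-locus distances instead of their mean (used by the locus
#'   bootstrap).
#' @return symmetric labeled distance matrix with zero diagonal (or a 3-d
#'   array when `by_locus`).
#' @export
bruvoDistanceMatrix <- function(dataset, haplome = c("LJ", "J", "L"),
                                model = c("add", "loss"), freqs = NULL,
                                freq_scope = "per-site", by_locus = FALSE) {
  haplome <- match.arg(haplome)
  model <- match.arg(model, several.ok = TRUE)
  want <- if (haplome == "LJ") c("J", "L") else haplome
  idx <- isoLoci(dataset, want)
  if (length(idx) == 0) stop("no isoloci for haplome ", haplome)
  ind <- dataset@individuals
  n <- nrow(ind)
  if (n < 2) stop("need at least two individuals")
  if (any(ind$biotype == "UNCALLED"))
    stop("all individuals must have a called biotype")
  if (is.null(freqs))
    freqs <- estimateAlleleFrequencies(dataset,
                                       loci = dataset@loci$name[idx],
                                       scope = freq_scope)
  unit <- switch(freqs$scope, "global" = rep("global", n),
                 "per-site" = ind$site, "per-group" = ind$group)
  g <- dataset@genotypes
  perLocus <- array(NA_real_, dim = c(n, n, length(idx)),
                    dimnames = list(ind$id, ind$id, dataset@loci$name[idx]))
  for (k in seq_along(idx)) {
    j <- idx[k]
    motif <- dataset@loci$motif[j]
    hap <- dataset@loci$haplome[j]
    locName <- dataset@loci$name[j]
    # completion sets per individual, computed once
    comp <- lapply(seq_len(n), function(i) {
      a <- g[[i, j]]
      if (length(a) == 0) return(NULL)
      cn <- max(haplomePloidy(ind$biotype[i], hap), length(a))
      if (cn == 0) return(NULL)
      completeGenotype(a, cn, lookupFreqs(freqs, unit[i], locName))
    })
    for (i1 in seq_len(n - 1)) {
      if (is.null(comp[[i1]])) next
      for (i2 in (i1 + 1):n) {
        if (is.null(comp[[i2]])) next
        total <- 0
        for (a1 in seq_along(comp[[i1]]$genotypes))
          for (a2 in seq_along(comp[[i2]]$genotypes))
            total <- total + comp[[i1]]$weights[a1] *
              comp[[i2]]$weights[a2] *
              bruvoGenotypeDistance(comp[[i1]]$genotypes[[a1]],
                                    comp[[i2]]$genotypes[[a2]],
                                    motif, model)
        perLocus[i1, i2, k] <- perLocus[i2, i1, k] <- total
      }
    }
    perLocus[cbind(seq_len(n), seq_len(n), k)] <- 0
  }
  if (by_locus) return(perLocus)
  meanLocusDistance(perLocus)
}

# mean over the locus dimension, requiring at least one shared locus
meanLocusDistance <- function(perLocus) {
  m <- apply(perLocus, c(1, 2), mean, na.rm = TRUE)
  nShared <- apply(!is.na(perLocus), c(1, 2), sum)
  if (any(nShared == 0)) {
    bad <- which(nShared == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("individuals %s and %s share no scored locus",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  diag(m) <- 0
  m
}
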