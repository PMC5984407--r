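# Haplome partitioning: isolocus splitting, biotype calling, group
# assignment via diagnostic J-alleles.

inRange <- function(a, lo, hi) !is.na(lo) & a >= lo & a <= hi

#' Split genotypes into J- and L-isoloci
#'
#' Each discriminating locus is replaced by its isoloci: a `<locus>-J`
#' and/or `<locus>-L` column holding the alleles falling inside the
#' species-diagnostic size range.  Alleles outside both ranges at a
#' SPLIT_BY_RANGE locus go to an `<locus>-U` column with a warning;
#' NON_DISCRIMINATING loci are carried over unchanged as `U` isoloci.
#' Allele conservation holds per individual and locus: J + L + U alleles
#' equal the input alleles.
#'
#' @param dataset an [MsatDataset-class] with raw loci.
#' @return an [MsatDataset-class] whose loci are isoloci (the `haplome`
#'   column is `"J"`, `"L"` or `"U"`).
#' @export
splitIsoloci <- function(dataset) {
  loc <- dataset@loci
  if (!all(is.na(loc$haplome)))
    stop("dataset is already split into isoloci")
  g <- dataset@genotypes
  n <- nrow(g)
  cols <- list()     # list of list(def=row, alleles=list of vectors)
  unassigned <- 0L
  for (j in seq_len(nrow(loc))) {
    def <- loc[j, , drop = FALSE]
    rule <- def$rule
    take <- function(hap, sel) {
      d <- def
      d$name <- if (rule == "NON_DISCRIMINATING") def$name else
        paste0(def$name, "-", hap)
      d$haplome <- hap
      alle <- lapply(seq_len(n), function(i) g[[i, j]][sel(g[[i, j]])])
      list(def = d, alleles = alle)
    }
    if (rule == "J_ONLY") {
      cols[[length(cols) + 1L]] <- take("J", function(a) rep(TRUE, length(a)))
    } else if (rule == "L_ONLY") {
      cols[[length(cols) + 1L]] <- take("L", function(a) rep(TRUE, length(a)))
    } else if (rule == "NON_DISCRIMINATING") {
      cols[[length(cols) + 1L]] <- take("U", function(a) rep(TRUE, length(a)))
    } else { # SPLIT_BY_RANGE
      inJ <- function(a) inRange(a, def$j_min, def$j_max)
      inL <- function(a) inRange(a, def$l_min, def$l_max)
      cols[[length(cols) + 1L]] <- take("J", inJ)
      cols[[length(cols) + 1L]] <- take("L", inL)
      out <- take("U", function(a) !inJ(a) & !inL(a))
      nOut <- sum(lengths(out$alleles))
      if (nOut > 0) {
        unassigned <- unassigned + nOut
        cols[[length(cols) + 1L]] <- out
      }
    }
  }
  if (unassigned > 0)
    warning(unassigned,
            " allele(s) outside both diagnostic ranges left unpartitioned")
  newLoci <- do.call(rbind, lapply(cols, `[[`, "def"))
  rownames(newLoci) <- NULL
  ng <- matrix(vector("list", n * nrow(newLoci)), nrow = n)
  for (k in seq_along(cols))
    for (i in seq_len(n)) ng[[i, k]] <- cols[[k]]$alleles[[i]]
  rownames(ng) <- dataset@individuals$id
  colnames(ng) <- newLoci$name
  new("MsatDataset", genotypes = ng, loci = newLoci,
      individuals = dataset@individuals, sites = dataset@sites)
}

isoLoci <- function(dataset, haplome) {
  hap <- dataset@loci$haplome
  if (all(is.na(hap))) stop("dataset has not been split into isoloci")
  which(hap %in% haplome)
}

#' Number of haplome copies implied by a biotype
#'
#' @param biotype one of LL, LJ, LLJ, LLLJ.
#' @param haplome `"J"` or `"L"`.
#' @return integer copy number (vectorized over `biotype`).
#' @export
haplomePloidy <- function(biotype, haplome) {
  haplome <- match.arg(haplome, c("J", "L"))
  tab <- if (haplome == "L") c(LL = 2L, LJ = 1L, LLJ = 2L, LLLJ = 3L)
         else c(LL = 0L, LJ = 1L, LLJ = 1L, LLLJ = 1L)
  out <- tab[biotype]
  if (anyNA(out)) stop("cannot derive ploidy from biotype: ",
                       paste(unique(biotype[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Call biotypes from distinct allele counts at isoloci
#'
#' Copy number per haplome is the maximum over that haplome's isoloci of
#' the number of distinct alleles (with a floor of 1 when any allele of
#' the haplome is present at all): partial heterozygotes can only
#' under-report, never over-report, copy number.  The (L, J) copy pair
#' maps to a biotype as (2,0) LL, (1,1) LJ, (2,1) LLJ, (3,1) LLLJ; any
#' other combination (including individuals with no informative locus) is
#' left UNCALLED.  The tetraploid call therefore requires at least one
#' locus showing three distinct L alleles.
#'
#' @param dataset an isolocus [MsatDataset-class] (see [splitIsoloci()]).
#' @return the dataset with the `biotype` column filled.
#' @export
callBiotypes <- function(dataset) {
  jIdx <- isoLoci(dataset, "J")
  lIdx <- isoLoci(dataset, "L")
  g <- dataset@genotypes
  maxDistinct <- function(i, idx) {
    cnt <- lengths(g[i, idx, drop = TRUE])
    if (all(cnt == 0)) 0L else max(cnt)
  }
  bt <- vapply(seq_len(nInd(dataset)), function(i) {
    nL <- maxDistinct(i, lIdx)
    nJ <- maxDistinct(i, jIdx)
    key <- paste(nL, nJ)
    switch(key, "2 0" = "LL", "1 1" = "LJ", "2 1" = "LLJ", "3 1" = "LLLJ",
           "UNCALLED")
  }, character(1))
  dataset@individuals$biotype <- bt
  dataset
}

#' Modal multilocus genotype of a set of individuals
#'
#' Per locus, the most frequent genotype (as a set of distinct allele
#' sizes) among individuals with data; ties are broken in favor of the
#' lexicographically smallest allele-size vector.
#'
#' @param dataset an [MsatDataset-class].
#' @param ids individuals to use (default all).
#' @param loci locus names (default all).
#' @return named list locus -> integer allele vector (`integer(0)` when no
#'   individual has data at the locus).
#' @export
consensusGenotype <- function(dataset, ids = NULL, loci = NULL) {
  if (is.null(ids)) ids <- dataset@individuals$id
  if (is.null(loci)) loci <- dataset@loci$name
  if (length(ids) == 0) stop("consensus of an empty group")
  sub <- dataset[ids, loci]
  g <- sub@genotypes
  out <- lapply(seq_along(loci), function(j) {
    cells <- g[, j]
    cells <- cells[lengths(cells) > 0]
    if (length(cells) == 0) return(integer(0))
    keys <- vapply(cells, paste, character(1), collapse = "/")
    counts <- table(keys)
    best <- names(counts)[counts == max(counts)]
    # lexicographic tie-break on the allele-size vectors
    if (length(best) > 1) {
      vecs <- lapply(best, function(k)
        as.integer(strsplit(k, "/", fixed = TRUE)[[1]]))
      ord <- do.call(order, as.data.frame(t(vapply(vecs, function(v)
        c(v, rep(Inf, 1 + MAX_PLOIDY - length(v)))[seq_len(MAX_PLOIDY + 1)],
        numeric(MAX_PLOIDY + 1)))))
      best <- best[ord[1]]
    }
    as.integer(strsplit(best, "/", fixed = TRUE)[[1]])
  })
  names(out) <- loci
  out
}

#' Build a diagnostic rule table for group assignment
#'
#' The five genetic groups are defined on a handful of multimodal J-isoloci:
#' the consensus multilocus genotype corresponds to one group (the
#' consensus group), while each other group carries one or more divergent
#' diagnostic alleles at those loci.
#'
#' @param consensus named list locus -> allele vector at the diagnostic
#'   loci (the consensus genotype).
#' @param diagnostics data.frame with columns `group`, `locus`, `allele`.
#' @param consensus_group label of the group matching the consensus
#'   genotype everywhere (default "B").
#' @return a `DiagnosticRuleTable` (list with class attribute).
#' @export
makeRuleTable <- function(consensus, diagnostics, consensus_group = "B") {
  stopifnot(all(c("group", "locus", "allele") %in% names(diagnostics)))
  if (!all(diagnostics$locus %in% names(consensus)))
    stop("diagnostic locus absent from consensus: ",
         paste(setdiff(diagnostics$locus, names(consensus)), collapse = ", "))
  for (k in seq_len(nrow(diagnostics))) {
    if (diagnostics$allele[k] %in% consensus[[diagnostics$locus[k]]])
      stop("diagnostic allele equals the consensus allele at ",
           diagnostics$locus[k])
  }
  structure(list(consensus = consensus, diagnostics = diagnostics,
                 consensus_group = consensus_group),
            class = "DiagnosticRuleTable")
}

matchesAllele <- function(alleles, target, motif, tol) {
  any(abs(alleles - target) / motif <= tol)
}

#' Assign individuals to genetic groups via diagnostic J-alleles
#'
#' An individual matching the consensus genotype at every diagnostic locus
#' is assigned to the consensus group.  Otherwise every locus where it
#' deviates from the consensus must carry exactly one group's diagnostic
#' allele for the individual to be assigned to that group; deviations not
#' explained by a single group's diagnostics (including diagnostics of two
#' different groups) yield `X`.  Missing data at any diagnostic locus
#' yields `UNASSIGNED` with a warning.
#'
#' Because the diagnostic loci are multimodal -- allele clusters separated
#' by gaps of many mutation steps -- matching is done up to
#' `step_tolerance` single-repeat steps: an allele within that many steps
#' of the consensus (or diagnostic) allele counts as that allele.  The
#' default of 2 steps is well below half the smallest diagnostic gap
#' (8 steps), so clusters cannot be confused; `step_tolerance = 0` forces
#' exact matching.
#'
#' @param dataset isolocus [MsatDataset-class].
#' @param rule_table a [makeRuleTable()] result.
#' @param step_tolerance allele match tolerance in mutation steps.
#' @return dataset with the `group` column filled.
#' @export
assignGroups <- function(dataset, rule_table, step_tolerance = 2) {
  stopifnot(inherits(rule_table, "DiagnosticRuleTable"))
  cons <- rule_table$consensus
  diag <- rule_table$diagnostics
  dLoci <- names(cons)
  jn <- match(dLoci, dataset@loci$name)
  if (anyNA(jn)) stop("diagnostic locus not in dataset: ",
                      paste(dLoci[is.na(jn)], collapse = ", "))
  motif <- dataset@loci$motif[jn]
  g <- dataset@genotypes
  nWarn <- 0L
  grp <- vapply(seq_len(nInd(dataset)), function(i) {
    obs <- g[i, jn]
    if (any(lengths(obs) == 0)) {
      nWarn <<- nWarn + 1L
      return("UNASSIGNED")
    }
    consOK <- vapply(seq_along(dLoci), function(k) {
      all(vapply(obs[[k]], matchesAllele, logical(1),
                 alleles = cons[[dLoci[k]]], motif = motif[k],
                 tol = step_tolerance)) &&
      all(vapply(cons[[dLoci[k]]], function(ca)
        matchesAllele(obs[[k]], ca, motif[k], step_tolerance), logical(1)))
    }, logical(1))
    if (all(consOK)) return(rule_table$consensus_group)
    divergent <- dLoci[!consOK]
    hits <- vapply(unique(diag$group), function(gr) {
      dg <- diag[diag$group == gr, , drop = FALSE]
      # every divergent locus must be one of this group's diagnostic loci
      # and carry its diagnostic allele
      if (!all(divergent %in% dg$locus)) return(FALSE)
      all(vapply(seq_len(nrow(dg)), function(r) {
        k <- match(dg$locus[r], dLoci)
        matchesAllele(obs[[k]], dg$allele[r], motif[k], step_tolerance)
      }, logical(1)))
    }, logical(1))
    if (sum(hits) == 1) names(hits)[hits] else "X"
  }, character(1))
  if (nWarn > 0)
    warning(nWarn, " individual(s) with missing data at a diagnostic locus",
            " left UNASSIGNED")
  dataset@individuals$group <- grp
  dataset
}

#' Biotype proportions among called unisexuals
#'
#' Percentage of each unisexual biotype (LJ, LLJ, LLLJ) among all called
#' unisexual individuals.
#'
#' @param biotypes character vector of biotype calls (or an
#'   [MsatDataset-class]).
#' @return named numeric vector of percentages.
#' @export
biotypeProportions <- function(biotypes) {
  if (is(biotypes, "MsatDataset")) biotypes <- biotypes@individuals$biotype
  uni <- biotypes[biotypes %in% c("LJ", "LLJ", "LLLJ")]
  if (length(uni) == 0) stop("no called unisexual individuals")
  tab <- table(factor(uni, levels = c("LJ", "LLJ", "LLLJ")))
  stats::setNames(100 * as.numeric(tab) / length(uni), names(tab))
}
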