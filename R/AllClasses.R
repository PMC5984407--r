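#' @import methods
NULL

# Maximum ploidy observed in the L-J complex: tetraploid LLLJ.
MAX_PLOIDY <- 4L

BIOTYPES <- c("LL", "LJ", "LLJ", "LLLJ", "UNCALLED")
GROUPS   <- c("A", "B", "C", "D", "E", "X", "UNASSIGNED")
RULES    <- c("J_ONLY", "L_ONLY", "SPLIT_BY_RANGE", "NON_DISCRIMINATING")

#' MsatDataset: mixed-ploidy microsatellite genotypes
#'
#' Central container for co-dominant microsatellite genotypes of
#' mixed-ploidy individuals.  Each cell of the genotype matrix holds the
#' distinct allele sizes (integer bp, sorted ascending) observed for one
#' individual at one locus; allele multiplicity is deliberately not stored
#' because partial heterozygotes (e.g. a triploid typed AB which may be AAB
#' or ABB) leave it unresolved.  An empty integer vector encodes missing
#' data.
#'
#' The locus table carries, per locus, the repeat-motif length and the
#' species-diagnostic allele-size ranges used to split alleles into J
#' (\emph{A. jeffersonianum}) and L (\emph{A. laterale}) isoloci.  After
#' [splitIsoloci()] the columns are isoloci and the `haplome` column is one
#' of `"J"`, `"L"` or `"U"` (origin unresolved).
#'
#' @slot genotypes list-matrix (individuals x loci); each element an
#'   integer vector of distinct sorted allele sizes in bp, `integer(0)` for
#'   missing.
#' @slot loci data.frame with columns `name`, `motif` (bp per repeat unit),
#'   `j_min`, `j_max`, `l_min`, `l_max` (NA when the range is undefined),
#'   `rule` (one of J_ONLY, L_ONLY, SPLIT_BY_RANGE, NON_DISCRIMINATING) and
#'   `haplome` (NA before isolocus splitting).
#' @slot individuals data.frame with columns `id`, `site`,
#'   `mtdna_unisexual` (logical, NA when untyped), `biotype`, `group`.
#' @slot sites data.frame with columns `site`, `lat`, `lon`.
#' @export
setClass("MsatDataset",
         slots = c(genotypes   = "matrix",
                   loci        = "data.frame",
                   individuals = "data.frame",
                   sites       = "data.frame"))

setValidity("MsatDataset", function(object) {
  g <- object@genotypes
  ind <- object@individuals
  loc <- object@loci
  msgs <- character()
  if (!is.list(g) && length(g) > 0)
    msgs <- c(msgs, "genotype matrix must be a list-matrix")
  if (nrow(g) != nrow(ind))
    msgs <- c(msgs, "genotype rows must match individual table")
  if (ncol(g) != nrow(loc))
    msgs <- c(msgs, "genotype columns must match locus table")
  if (anyDuplicated(ind$id))
    msgs <- c(msgs, sprintf("duplicate individual id: %s",
                            ind$id[duplicated(ind$id)][1]))
  if (anyDuplicated(loc$name))
    msgs <- c(msgs, "duplicate locus names")
  if (any(loc$motif < 1))
    msgs <- c(msgs, "motif length must be >= 1 bp")
  bad <- !loc$rule %in% RULES
  if (any(bad))
    msgs <- c(msgs, sprintf("unknown locus rule: %s", loc$rule[bad][1]))
  # J and L diagnostic ranges must never overlap when both are defined
  both <- !is.na(loc$j_min) & !is.na(loc$l_min)
  if (any(both)) {
    ovl <- both & (loc$j_min <= loc$l_max) & (loc$l_min <= loc$j_max)
    if (any(ovl))
      msgs <- c(msgs, sprintf("J and L ranges overlap at locus %s",
                              loc$name[ovl][1]))
  }
  for (j in seq_len(ncol(g))) {
    for (i in seq_len(nrow(g))) {
      a <- g[[i, j]]
      if (length(a) == 0) next
      if (any(a < 0) || any(a != round(a)))
        return(sprintf("allele sizes must be nonnegative integers (%s, %s)",
                       ind$id[i], loc$name[j]))
      if (is.unsorted(a, strictly = TRUE))
        return(sprintf("alleles must be distinct and sorted (%s, %s)",
                       ind$id[i], loc$name[j]))
      if (loc$rule[j] != "NON_DISCRIMINATING" && length(a) > MAX_PLOIDY)
        return(sprintf(
          "more than %d distinct alleles at discriminating locus %s for %s",
          MAX_PLOIDY, loc$name[j], ind$id[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' AflpMatrix: binary AFLP band scores
#'
#' Presence/absence scores for dominant AFLP bands.  Band labels combine
#' the selective-primer combination and the fragment size.
#'
#' @slot presence binary integer matrix, individuals x bands, with
#'   individual ids as rownames and band labels as colnames.
#' @export
setClass("AflpMatrix", slots = c(presence = "matrix"))

setValidity("AflpMatrix", function(object) {
  m <- object@presence
  if (!is.numeric(m)) return("presence matrix must be numeric 0/1")
  if (!all(m %in% c(0, 1))) return("presence matrix entries must be 0 or 1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("presence matrix needs individual and band labels")
  if (anyDuplicated(rownames(m))) return("duplicate individual ids")
  TRUE
})

#' Construct an MsatDataset
#'
#' @param genotypes list-matrix (individuals x loci) of sorted distinct
#'   integer allele-size vectors; `integer(0)` marks missing data.
#' @param loci locus table (see [locusTable()]).
#' @param individuals data.frame with at least `id` and `site`.
#' @param sites optional site coordinate table (site, lat, lon).
#' @return a validated [MsatDataset-class].
#' @export
newMsatDataset <- function(genotypes, loci, individuals, sites = NULL) {
  if (is.null(sites)) {
    sites <- data.frame(site = unique(individuals$site),
                        lat = NA_real_, lon = NA_real_)
  }
  individuals$biotype <- if (is.null(individuals$biotype))
    "UNCALLED" else individuals$biotype
  individuals$group <- if (is.null(individuals$group))
    "UNASSIGNED" else individuals$group
  if (is.null(individuals$mtdna_unisexual))
    individuals$mtdna_unisexual <- NA
  rownames(genotypes) <- individuals$id
  colnames(genotypes) <- loci$name
  new("MsatDataset", genotypes = genotypes, loci = loci,
      individuals = individuals, sites = sites)
}

#' Build a locus table
#'
#' @param name locus names.
#' @param motif repeat-unit length in bp (recycled).
#' @param j_range,l_range two-column matrices (or NULL) of closed
#'   allele-size ranges assigned to the J and L haplomes; a row of NAs
#'   leaves the range undefined for that locus.
#' @param rule partitioning rule per locus; derived from the ranges when
#'   omitted.
#' @return data.frame suitable for the `loci` slot of [MsatDataset-class].
#' @export
locusTable <- function(name, motif, j_range = NULL, l_range = NULL,
                       rule = NULL) {
  n <- length(name)
  motif <- as.integer(rep_len(motif, n))
  pick <- function(r, col) {
    if (is.null(r)) rep(NA_real_, n) else r[, col]
  }
  out <- data.frame(name = as.character(name), motif = motif,
                    j_min = pick(j_range, 1), j_max = pick(j_range, 2),
                    l_min = pick(l_range, 1), l_max = pick(l_range, 2),
                    stringsAsFactors = FALSE)
  if (is.null(rule)) {
    rule <- ifelse(!is.na(out$j_min) & !is.na(out$l_min), "SPLIT_BY_RANGE",
            ifelse(!is.na(out$j_min), "J_ONLY",
            ifelse(!is.na(out$l_min), "L_ONLY", "NON_DISCRIMINATING")))
  }
  out$rule <- rule
  out$haplome <- NA_character_
  out
}

#' @describeIn MsatDataset-class number of individuals
#' @param object,x an `MsatDataset` or `AflpMatrix`.
#' @export
nInd <- function(object) nrow(object@genotypes)

#' @describeIn MsatDataset-class number of loci (columns of the genotype
#'   matrix; isoloci after splitting)
#' @export
nLoci <- function(object) ncol(object@genotypes)

#' @describeIn MsatDataset-class individual metadata (id, site, biotype,
#'   group, mtDNA flag)
#' @export
indTable <- function(object) object@individuals

#' @describeIn MsatDataset-class locus definition table
#' @export
lociTable <- function(object) object@loci

#' @describeIn MsatDataset-class site coordinate table
#' @export
siteTable <- function(object) object@sites

#' @describeIn MsatDataset-class genotype list-matrix
#' @export
genotypeMatrix <- function(object) object@genotypes

#' @describeIn AflpMatrix-class binary band matrix
#' @export
bandMatrix <- function(object) object@presence

setMethod("show", "MsatDataset", function(object) {
  loc <- object@loci
  hap <- if (all(is.na(loc$haplome))) "raw loci" else
    sprintf("isoloci (%s)", paste(sprintf("%s:%d", names(table(loc$haplome)),
                                          as.integer(table(loc$haplome))),
                                  collapse = ", "))
  cat(sprintf("MsatDataset: %d individuals, %d %s, %d sites\n",
              nInd(object), nLoci(object), hap, nrow(object@sites)))
  bt <- table(object@individuals$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), as.integer(bt)),
                           collapse = " "), "\n")
  gr <- table(object@individuals$group)
  cat("  groups:  ", paste(sprintf("%s=%d", names(gr), as.integer(gr)),
                           collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "AflpMatrix", function(object) {
  cat(sprintf("AflpMatrix: %d individuals x %d bands\n",
              nrow(object@presence), ncol(object@presence)))
  invisible(object)
})

#' Subset an MsatDataset by individuals and/or loci
#'
#' @param i individual ids, indices or logical vector.
#' @param j locus names, indices or logical vector.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "MsatDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@individuals$id)
  if (is.character(j)) j <- match(j, x@loci$name)
  if (anyNA(i)) stop("unknown individual id in subset")
  if (anyNA(j)) stop("unknown locus name in subset")
  ind <- x@individuals[i, , drop = FALSE]
  rownames(ind) <- NULL
  loc <- x@loci[j, , drop = FALSE]
  rownames(loc) <- NULL
  g <- x@genotypes[i, j, drop = FALSE]
  sites <- x@sites[x@sites$site %in% unique(ind$site), , drop = FALSE]
  rownames(sites) <- NULL
  new("MsatDataset", genotypes = g, loci = loc, individuals = ind,
      sites = sites)
})
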