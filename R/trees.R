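# Neighbor-joining with locus bootstrap, AFLP simple-match distances and
# extended majority-rule consensus.

checkSymmetricMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-8) stop("distance matrix diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`).  Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero with a
#' warning.
#'
#' @param m symmetric labeled distance matrix (>= 3 labels).
#' @return unrooted ape `phylo`.
#' @export
neighborJoining <- function(m) {
  checkSymmetricMatrix(m)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 labels")
  tree <- ape::nj(stats::as.dist(m))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Locus-bootstrap support for the Bruvo NJ tree
#'
#' Loci are resampled with replacement `n_reps` times; each pseudoreplicate
#' distance matrix (mean of the resampled per-locus Bruvo distances)
#' is rebuilt into an NJ tree.  Support for each internal node of the
#' full-data tree is the percentage of replicate trees containing the same
#' bipartition; nodes below `collapse_threshold` are collapsed into
#' polytomies.
#'
#' @param dataset isolocus [MsatDataset-class] with biotypes called.
#' @param haplome,model,freqs,freq_scope passed to [bruvoDistanceMatrix()].
#' @param n_reps number of bootstrap pseudoreplicates.
#' @param seed RNG seed for the locus resampling.
#' @param collapse_threshold support percentage below which nodes are
#'   collapsed (0 keeps the tree fully binary).
#' @return ape `phylo` with support percentages as `node.label`.
#' @export
bootstrapSupport <- function(dataset, haplome = "J", n_reps = 1000,
                             seed = NULL, collapse_threshold = 50,
                             model = c("add", "loss"), freqs = NULL,
                             freq_scope = "per-site") {
  perLocus <- bruvoDistanceMatrix(dataset, haplome = haplome, model = model,
                                  freqs = freqs, freq_scope = freq_scope,
                                  by_locus = TRUE)
  nLoc <- dim(perLocus)[3]
  if (nLoc < 2) stop("locus bootstrap needs at least 2 loci")
  full <- neighborJoining(meanLocusDistance(perLocus))
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    for (try in 1:100) {
      idx <- sample.int(nLoc, nLoc, replace = TRUE)
      m <- tryCatch(meanLocusDistance(perLocus[, , idx, drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(m)) break
    }
    if (is.null(m)) stop("could not resample loci leaving all pairs scored")
    reps[[r]] <- suppressWarnings(neighborJoining(m))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round(100 * counts / n_reps, 1)
  if (collapse_threshold > 0)
    full <- collapseBySupport(full, collapse_threshold)
  full
}

#' Collapse weakly supported nodes into polytomies
#'
#' Internal edges whose child node has support below `threshold` are
#' contracted.  The root node (trivial bipartition) is never collapsed.
#'
#' @param tree ape `phylo` with numeric `node.label` supports.
#' @param threshold support percentage.
#' @return ape `phylo`.
#' @export
collapseBySupport <- function(tree, threshold) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  repeat {
    childNodes <- tree$edge[, 2]
    internal <- which(childNodes > nTip & childNodes != root)
    weak <- internal[sup[childNodes[internal] - nTip] < threshold]
    if (length(weak) == 0) break
    e <- weak[1]
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    # reattach the child's descendants to its parent
    down <- tree$edge[, 1] == child
    tree$edge[down, 1] <- parent
    keepN <- setdiff(seq_len(tree$Nnode) + nTip, child)
    remap <- integer(max(keepN))
    remap[keepN] <- nTip + seq_along(keepN)
    tree$edge <- tree$edge[-e, , drop = FALSE]
    if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[-e]
    big <- tree$edge > nTip
    tree$edge[big] <- remap[tree$edge[big]]
    sup <- sup[-(child - nTip)]
    tree$Nnode <- tree$Nnode - 1L
  }
  tree$node.label <- sup
  tree
}

#' Simple-matching distance from a binary AFLP matrix
#'
#' `d(i, j)` is the proportion of bands at which the two individuals
#' differ (one minus the simple-matching coefficient).
#'
#' @param aflp an [AflpMatrix-class] or a binary matrix with rownames.
#' @return symmetric labeled distance matrix.
#' @export
simpleMatchDistance <- function(aflp) {
  m <- if (is(aflp, "AflpMatrix")) aflp@presence else aflp
  if (!all(m %in% c(0, 1))) stop("AFLP matrix must be binary")
  if (ncol(m) == 0) stop("AFLP matrix has no bands")
  d <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# canonical split encoding: the side of the bipartition not containing the
# first taxon, as a sorted character key over the canonical taxon order
treeSplits <- function(tree, taxa) {
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    memb <- match(tree$tip.label[cl], taxa)
    if (1L %in% memb) memb <- setdiff(seq_len(n), memb)
    if (length(memb) <= 1 || length(memb) >= n - 1) next  # trivial
    keys <- c(keys, paste(sort(memb), collapse = ","))
  }
  unique(keys)
}

splitsCompatible <- function(a, b) {
  # both sides exclude taxon 1: compatible iff nested or disjoint
  length(intersect(a, b)) == 0 || all(a %in% b) || all(b %in% a)
}

#' Majority-rule consensus tree (strict or extended)
#'
#' Bipartitions present in more than half of the input trees are retained;
#' under the extended rule the remaining bipartitions are then added
#' greedily in order of decreasing frequency (ties broken by the
#' lexicographically smallest bipartition encoding) whenever they are
#' compatible with the accepted set.  Node labels carry the bipartition
#' frequency as a percentage.
#'
#' @param trees list of ape `phylo` objects over the same leaf set.
#' @param mode `"extended"` (default) or `"strict"` majority rule.
#' @return ape `phylo` (topology only, with frequency node labels).
#' @export
majorityConsensus <- function(trees, mode = c("extended", "strict")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, taxa)) stop("trees have mismatched leaf sets")
  nT <- length(trees)
  counts <- new.env(parent = emptyenv())
  for (t in trees)
    for (k in treeSplits(t, taxa))
      counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / nT, numeric(1))
  ord <- order(-freq, keys)
  keys <- keys[ord]; freq <- freq[ord]
  asSet <- function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
  accepted <- list(); accFreq <- numeric(0)
  for (i in seq_along(keys)) {
    s <- asSet(keys[i])
    if (freq[i] > 0.5) {
      accepted[[length(accepted) + 1L]] <- s
      accFreq <- c(accFreq, freq[i])
    } else if (mode == "extended") {
      if (all(vapply(accepted, splitsCompatible, logical(1), b = s))) {
        accepted[[length(accepted) + 1L]] <- s
        accFreq <- c(accFreq, freq[i])
      }
    }
  }
  buildConsensusTree(taxa, accepted, round(100 * accFreq, 1))
}

# build a rooted newick from a laminar family of clusters (all excluding
# taxon 1), label internal nodes with supports, and read it back with ape
buildConsensusTree <- function(taxa, clusters, supports) {
  n <- length(taxa)
  sizes <- lengths(clusters)
  ord <- order(-sizes)
  render <- function(members, avail) {
    # avail: indices (into clusters) still unplaced, all subsets of members
    parts <- character(0)
    used <- integer(0)
    for (ci in avail) {
      if (ci %in% used) next
      sub <- avail[vapply(avail, function(cj)
        cj != ci && all(clusters[[cj]] %in% clusters[[ci]]), logical(1))]
      if (any(vapply(avail, function(cj)
        !cj %in% c(ci, sub) && all(clusters[[ci]] %in% clusters[[cj]]),
        logical(1)))) next  # not maximal here
      parts <- c(parts, paste0(render(clusters[[ci]], sub),
                               sprintf("%g", supports[ci])))
      used <- c(used, ci, sub)
    }
    covered <- unlist(clusters[avail[avail %in% used]])
    singles <- setdiff(members, covered)
    parts <- c(parts, taxa[singles])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(render(seq_len(n), seq_along(clusters)), ";")
  ape::read.tree(text = nwk)
}
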