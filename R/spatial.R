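# Spatial structure: Mantel tests, Mantel correlograms, Hellinger
# abundance distances, great-circle site distances.

upperTri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' row/column permutations of one matrix.  The one-tailed p-value uses the
#' +1 convention (the observed statistic is counted in both numerator and
#' denominator), so p is never zero.
#'
#' @param m1,m2 symmetric labeled distance matrices with identical labels
#'   in identical order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `r`, `r_squared` and `p`.
#' @export
mantelTest <- function(m1, m2, n_perm = 999, seed = NULL) {
  checkSymmetricMatrix(m1); checkSymmetricMatrix(m2)
  if (!identical(dim(m1), dim(m2)))
    stop("matrices must have the same dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("matrix labels must match in order")
  if (stats::sd(upperTri(m1)) == 0 || stats::sd(upperTri(m2)) == 0)
    stop("Mantel correlation undefined for a constant matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       permutations = n_perm)
  r <- unname(fit$statistic)
  list(r = r, r_squared = r^2, p = unname(fit$signif))
}

#' Mantel correlogram over geographic distance classes
#'
#' Equal-width distance classes over the observed geographic range; per
#' class a Mantel test of the genetic distances against the class
#' membership indicator, with progressive Holm correction across classes.
#'
#' @param m_gen genetic distance matrix.
#' @param m_geo geographic distance matrix in km (same labels/order), e.g.
#'   from [siteDistanceMatrix()] expanded to individuals.
#' @param n_classes number of distance classes.
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @return list with `classes` (data.frame: class index, upper break,
#'   midpoint, n pairs, r, p, p_corrected) and `break_points`.  Classes
#'   without pairs have NA statistics.
#' @export
mantelCorrelogram <- function(m_gen, m_geo, n_classes = 20, n_perm = 999,
                              seed = NULL) {
  checkSymmetricMatrix(m_gen); checkSymmetricMatrix(m_geo)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel.correlog(stats::as.dist(m_gen),
                                D.geo = stats::as.dist(m_geo),
                                n.class = n_classes, nperm = n_perm,
                                cutoff = FALSE, mult = "holm",
                                progressive = TRUE)
  res <- as.data.frame(fit$mantel.res)
  breaks <- fit$break.pts
  out <- data.frame(class = seq_len(nrow(res)),
                    upper_km = breaks[-1],
                    midpoint_km = res[["class.index"]],
                    n_pairs = res[["n.dist"]],
                    r = res[["Mantel.cor"]],
                    p = res[["Pr(Mantel)"]],
                    p_corrected = res[["Pr(corrected)"]])
  list(classes = out, break_points = breaks)
}

#' Hellinger distance between site abundance profiles
#'
#' Rows (sites) are converted to relative abundances, square-rooted, and
#' compared by Euclidean distance; distances are bounded by sqrt(2) and
#' invariant to scaling a row by a constant.
#'
#' @param abundance nonnegative site x group count matrix with rownames;
#'   every row sum must be positive.
#' @return symmetric labeled distance matrix.
#' @export
hellingerAbundanceDistance <- function(abundance) {
  m <- as.matrix(abundance)
  if (any(m < 0)) stop("abundances must be nonnegative")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("every site row must have a positive total")
  h <- sqrt(m / rs)
  d <- as.matrix(stats::dist(h))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Great-circle distances between sites, in km
#'
#' Haversine distances from the site coordinate table.
#'
#' @param sites data.frame with `site`, `lat`, `lon` (decimal degrees), or
#'   an [MsatDataset-class].
#' @return symmetric labeled matrix of distances in km.
#' @export
siteDistanceMatrix <- function(sites) {
  if (is(sites, "MsatDataset")) sites <- sites@sites
  if (anyNA(sites$lat) || anyNA(sites$lon))
    stop("site coordinates contain missing values")
  m <- geosphere::distm(cbind(sites$lon, sites$lat),
                        fun = geosphere::distHaversine) / 1000
  dimnames(m) <- list(sites$site, sites$site)
  m
}

#' Per-site genotype-group abundance table
#'
#' @param dataset [MsatDataset-class] with groups assigned.
#' @param groups group labels to tabulate (default: the assigned groups
#'   other than UNASSIGNED).
#' @return site x group count matrix.
#' @export
groupAbundanceTable <- function(dataset, groups = NULL) {
  ind <- dataset@individuals
  if (is.null(groups)) groups <- setdiff(unique(ind$group), "UNASSIGNED")
  tab <- table(ind$site, factor(ind$group, levels = groups))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
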