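# Fixtures are built in code; oracles are written independently of the
# package internals they check.

toyLoci <- function() {
  locusTable(
    name  = c("AmaD42", "AjeD13", "AjeD94"),
    motif = 4L,
    j_range = rbind(c(133, 193), c(190, 254), c(NA, NA)),
    l_range = rbind(c(209, 261), c(NA, NA), c(NA, NA)))
}

# two triploids, one diploid, one host diploid over the toy panel
toyDataset <- function() {
  g <- matrix(vector("list", 12), nrow = 4)
  g[[1, 1]] <- c(133L, 213L, 221L); g[[1, 2]] <- 210L; g[[1, 3]] <- 150L
  g[[2, 1]] <- c(137L, 213L, 221L); g[[2, 2]] <- 210L; g[[2, 3]] <- 154L
  g[[3, 1]] <- c(133L, 213L);       g[[3, 2]] <- 214L; g[[3, 3]] <- 150L
  g[[4, 1]] <- c(213L, 217L);       g[[4, 2]] <- integer(0)
  g[[4, 3]] <- c(150L, 158L)
  newMsatDataset(
    g, toyLoci(),
    data.frame(id = c("u1", "u2", "u3", "h1"),
               site = c("M01", "M01", "M02", "M01")),
    sites = data.frame(site = c("M01", "M02"),
                       lat = c(45.39, 45.43), lon = c(-73.98, -73.95)))
}

# --- independent Bruvo oracle: explicit enumeration of every assignment
# and every completion ---------------------------------------------------

permsRec <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permsRec(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracleStep <- function(a, b, motif) 1 - 2^(-round(abs(a - b) / motif))

oracleEqual <- function(x, y, motif) {
  best <- Inf
  for (p in permsRec(seq_along(y)))
    best <- min(best, mean(oracleStep(x, y[p], motif)))
  best
}

oracleBruvo <- function(g1, g2, motif, model = c("add", "loss")) {
  if (length(g1) == length(g2)) return(oracleEqual(g1, g2, motif))
  s <- if (length(g1) < length(g2)) g1 else g2
  l <- if (length(g1) < length(g2)) g2 else g1
  d <- length(l) - length(s)
  completionAverage <- function(pool) {
    grid <- do.call(expand.grid, rep(list(unique(pool)), d))
    mean(apply(grid, 1, function(v) oracleEqual(c(s, as.numeric(v)), l,
                                                motif)))
  }
  vals <- c(add = completionAverage(s), loss = completionAverage(l))
  mean(vals[model])
}

randomGenotype <- function(ploidy, motif = 4L, base = 100L, span = 6L) {
  sort(unique(base + motif * sample.int(span, ploidy, replace = TRUE)))
}

# exact rarefaction by enumerating every subsample (integer counts)
oracleRarefy <- function(counts, n) {
  pool <- rep(seq_along(counts), counts)
  mean(apply(utils::combn(length(pool), n), 2,
             function(ix) length(unique(pool[ix]))))
}

randomAdditiveTree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  ape::unroot(tr)
}
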