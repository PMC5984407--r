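# Forward-time kleptogenesis simulator.  Each site holds one deme per
# founded genetic group; generations are discrete and non-overlapping and
# every daughter's mother is drawn uniformly from the previous generation
# of her deme (Wright-Fisher resampling at constant deme size), so that
# within-site diversity coalesces while isolated sites diverge by
# mutation.  A daughter arises from one reproductive event:
#   clonal       - the maternal genome is copied unchanged;
#   replacement  - one uniformly chosen L haplome is replaced by a sperm
#                  gamete drawn from the site's sexual host pool;
#   elevation    - a host gamete is appended as an extra L haplome
#                  (capped at LLLJ: at 3 L haplomes the event is a no-op);
#   reduction    - one uniformly chosen L haplome is dropped (floored at
#                  LJ).
# Every haplome-locus then mutates by one repeat unit (direction 50/50)
# with probability mu, reflecting at the configured allele-size range
# bounds.  J haplomes are never exchanged: no A. jeffersonianum sperm
# donor occurs in the study area.  Host allele pools are stationary.

#' Build and validate a simulator configuration
#'
#' @param loci raw locus table (see [locusTable()]).
#' @param sites data.frame with `site`, `lat`, `lon`.
#' @param groups list of group definitions: each a list with `label`,
#'   `founder_J` (named allele vector over the J isoloci), `founder_L`
#'   (list of 1-3 named allele vectors over the L isoloci), `sites`
#'   (character vector of founding sites), and per-generation event
#'   probabilities `exchange_rate`, `elevation_rate`, `reduction_rate`.
#' @param host_pools named list site -> (L-isolocus -> named allele
#'   frequency vector); sites without a sexual host population are simply
#'   absent.
#' @param mu per-haplome per-locus single-step mutation probability.
#' @param generations number of generations simulated.
#' @param pop_size deme size (females per group per site).
#' @param n_sampled unisexual individuals sampled per site.
#' @param n_host_sampled LL host individuals sampled per site with a pool.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(loci, sites, groups, host_pools = list(),
                      mu = 1e-3, generations = 150, pop_size = 25,
                      n_sampled = 20, n_host_sampled = 10) {
  iso <- isolocusInfo(loci)
  for (g in groups) {
    stopifnot(!is.null(g$label), !is.null(g$founder_J),
              !is.null(g$founder_L), !is.null(g$sites))
    rates <- c(g$exchange_rate, g$elevation_rate, g$reduction_rate)
    if (any(rates < 0) || any(rates > 1) || sum(rates) > 1)
      stop("event rates of group ", g$label,
           " must be in [0,1] and sum to at most 1")
    if (!setequal(names(g$founder_J), iso$j$name))
      stop("founder J genotype of group ", g$label,
           " must cover the J isoloci")
    if (length(g$founder_L) < 1 || length(g$founder_L) > 3)
      stop("founder of group ", g$label, " must carry 1-3 L haplomes")
    for (h in g$founder_L)
      if (!setequal(names(h), iso$l$name))
        stop("founder L haplome of group ", g$label,
             " must cover the L isoloci")
    checkInRange <- function(vals, tab) {
      a <- vals[tab$name]
      bad <- a < tab$lo | a > tab$hi
      if (any(bad)) stop("founder allele out of range at ",
                         tab$name[bad][1], " for group ", g$label)
    }
    checkInRange(g$founder_J, iso$j)
    for (h in g$founder_L) checkInRange(h, iso$l)
    if (g$exchange_rate + g$elevation_rate > 0)
      for (s in g$sites)
        if (is.null(host_pools[[s]]))
          stop("group ", g$label, " needs a host pool at site ", s,
               " for exchange or elevation events")
  }
  for (s in names(host_pools)) {
    pool <- host_pools[[s]]
    if (!setequal(names(pool), iso$l$name))
      stop("host pool at ", s, " must cover the L isoloci")
    for (loc in names(pool)) {
      f <- pool[[loc]]
      if (abs(sum(f) - 1) > 1e-9)
        stop("host pool frequencies at ", s, "/", loc, " must sum to 1")
      if (any(f < 0)) stop("negative host pool frequency")
    }
  }
  structure(list(loci = loci, sites = sites, groups = groups,
                 host_pools = host_pools, mu = mu,
                 generations = generations, pop_size = pop_size,
                 n_sampled = n_sampled, n_host_sampled = n_host_sampled),
            class = "SimConfig")
}

# isolocus bookkeeping derived from the raw locus table: names, motifs
# and reflecting range bounds per haplome
isolocusInfo <- function(loci) {
  jRows <- loci$rule %in% c("J_ONLY", "SPLIT_BY_RANGE")
  lRows <- loci$rule %in% c("L_ONLY", "SPLIT_BY_RANGE")
  j <- data.frame(raw = loci$name[jRows],
                  name = paste0(loci$name[jRows], "-J"),
                  motif = loci$motif[jRows],
                  lo = loci$j_min[jRows], hi = loci$j_max[jRows])
  l <- data.frame(raw = loci$name[lRows],
                  name = paste0(loci$name[lRows], "-L"),
                  motif = loci$motif[lRows],
                  lo = loci$l_min[lRows], hi = loci$l_max[lRows])
  list(j = j, l = l)
}

mutateHaplome <- function(alleles, info, mu) {
  hit <- stats::runif(length(alleles)) < mu
  if (!any(hit)) return(list(alleles = alleles, n = 0L))
  step <- sample(c(-1, 1), sum(hit), replace = TRUE) * info$motif[hit]
  a <- alleles
  a[hit] <- a[hit] + step
  over <- a > info$hi; under <- a < info$lo
  a[over] <- 2 * info$hi[over] - a[over]
  a[under] <- 2 * info$lo[under] - a[under]
  list(alleles = a, n = sum(hit))
}

hostGamete <- function(pool, lInfo) {
  vapply(lInfo$name, function(loc) {
    f <- pool[[loc]]
    a <- as.integer(names(f))
    a[sample.int(length(a), 1, prob = f)]
  }, integer(1))
}

#' Simulate a kleptogenetic metapopulation
#'
#' Runs the forward-time model described above and returns the sampled
#' individuals as a raw-locus [MsatDataset-class] (ready for
#' [splitIsoloci()]) together with a ground-truth table.
#'
#' @param config a [simConfig()] object.
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return list with `dataset` (MsatDataset), `truth` (data.frame: id,
#'   site, true_group, true_biotype, n_exchange, n_elevation, n_reduction,
#'   n_mutation) and `config`.
#' @export
simulateKleptogenesis <- function(config, seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  iso <- isolocusInfo(config$loci)
  jN <- stats::setNames(seq_len(nrow(iso$j)), iso$j$name)
  demes <- list()
  for (g in config$groups) for (s in g$sites) {
    founder <- list(J = g$founder_J[iso$j$name],
                    L = lapply(g$founder_L, function(h) h[iso$l$name]),
                    nx = 0L, nel = 0L, nre = 0L, nmu = 0L)
    demes[[length(demes) + 1L]] <- list(
      site = s, group = g$label, rates = c(g$exchange_rate,
                                           g$elevation_rate,
                                           g$reduction_rate),
      pop = rep(list(founder), config$pop_size))
  }
  for (gen in seq_len(config$generations)) {
    for (d in seq_along(demes)) {
      deme <- demes[[d]]
      pool <- config$host_pools[[deme$site]]
      mothers <- sample.int(length(deme$pop), length(deme$pop),
                            replace = TRUE)
      newPop <- vector("list", length(deme$pop))
      u <- stats::runif(length(deme$pop))
      r <- deme$rates
      for (i in seq_along(newPop)) {
        kid <- deme$pop[[mothers[i]]]
        if (u[i] < r[1]) {                      # haplome replacement
          kid$L[[sample.int(length(kid$L), 1)]] <- hostGamete(pool, iso$l)
          kid$nx <- kid$nx + 1L
        } else if (u[i] < r[1] + r[2]) {        # ploidy elevation
          if (length(kid$L) < 3) {
            kid$L[[length(kid$L) + 1L]] <- hostGamete(pool, iso$l)
            kid$nel <- kid$nel + 1L
          }
        } else if (u[i] < r[1] + r[2] + r[3]) { # ploidy reduction
          if (length(kid$L) > 1) {
            kid$L[[sample.int(length(kid$L), 1)]] <- NULL
            kid$nre <- kid$nre + 1L
          }
        }
        mJ <- mutateHaplome(kid$J, iso$j, config$mu)
        kid$J <- mJ$alleles
        nmu <- mJ$n
        for (h in seq_along(kid$L)) {
          mL <- mutateHaplome(kid$L[[h]], iso$l, config$mu)
          kid$L[[h]] <- mL$alleles
          nmu <- nmu + mL$n
        }
        kid$nmu <- kid$nmu + nmu
        newPop[[i]] <- kid
      }
      demes[[d]]$pop <- newPop
    }
  }
  # sample unisexuals per site, pooled over that site's demes
  sampled <- list()
  for (s in unique(vapply(demes, `[[`, "", "site"))) {
    ds <- demes[vapply(demes, `[[`, "", "site") == s]
    all <- do.call(c, lapply(ds, function(d)
      lapply(d$pop, function(p) c(p, list(site = d$site, group = d$group)))))
    take <- sample.int(length(all), min(config$n_sampled, length(all)))
    sampled <- c(sampled, all[take])
  }
  # LL host individuals at sites with a pool
  hosts <- list()
  for (s in names(config$host_pools)) {
    if (config$n_host_sampled <= 0) next
    for (k in seq_len(config$n_host_sampled)) {
      hosts[[length(hosts) + 1L]] <- list(
        J = NULL, L = list(hostGamete(config$host_pools[[s]], iso$l),
                           hostGamete(config$host_pools[[s]], iso$l)),
        nx = NA_integer_, nel = NA_integer_, nre = NA_integer_,
        nmu = NA_integer_, site = s, group = "LL")
    }
  }
  all <- c(sampled, hosts)
  ids <- sprintf("ind%03d", seq_along(all))
  # assemble the raw-locus genotype matrix
  loci <- config$loci
  g <- matrix(vector("list", length(all) * nrow(loci)), nrow = length(all))
  for (i in seq_along(all)) {
    p <- all[[i]]
    for (j in seq_len(nrow(loci))) {
      nm <- loci$name[j]
      a <- integer(0)
      if (loci$rule[j] %in% c("J_ONLY", "SPLIT_BY_RANGE") && !is.null(p$J))
        a <- c(a, p$J[[jN[paste0(nm, "-J")]]])
      if (loci$rule[j] %in% c("L_ONLY", "SPLIT_BY_RANGE"))
        a <- c(a, vapply(p$L, `[[`, numeric(1), paste0(nm, "-L")))
      g[[i, j]] <- sort(unique(as.integer(a)))
    }
  }
  ind <- data.frame(id = ids,
                    site = vapply(all, `[[`, "", "site"),
                    mtdna_unisexual = vapply(all, function(p)
                      !identical(p$group, "LL"), logical(1)))
  ds <- newMsatDataset(g, loci, ind, config$sites)
  truth <- data.frame(
    id = ids, site = ind$site,
    true_group = vapply(all, `[[`, "", "group"),
    true_biotype = vapply(all, function(p) {
      if (identical(p$group, "LL")) "LL"
      else c("LJ", "LLJ", "LLLJ")[length(p$L)]
    }, character(1)),
    n_exchange = vapply(all, `[[`, NA_integer_, "nx"),
    n_elevation = vapply(all, `[[`, NA_integer_, "nel"),
    n_reduction = vapply(all, `[[`, NA_integer_, "nre"),
    n_mutation = vapply(all, `[[`, NA_integer_, "nmu"))
  list(dataset = ds, truth = truth, config = config)
}

#' Derive a synthetic dominant-band matrix from genotypes
#'
#' Converts a genotype table into an AFLP-like binary matrix by scoring
#' one band per observed (locus, allele size) combination: the band is
#' present when the individual carries that allele.  This preserves the
#' clustering structure of the co-dominant data in a dominant encoding
#' (band labels mimic primer-combination/size labels).
#'
#' @param dataset an [MsatDataset-class].
#' @return an [AflpMatrix-class].
#' @export
aflpFromDataset <- function(dataset) {
  g <- dataset@genotypes
  bands <- list()
  for (j in seq_len(ncol(g))) {
    sizes <- sort(unique(unlist(g[, j])))
    for (a in sizes)
      bands[[length(bands) + 1L]] <- c(j, a)
  }
  m <- matrix(0L, nrow(g), length(bands),
              dimnames = list(dataset@individuals$id,
                              vapply(bands, function(b)
                                sprintf("%s_%d", dataset@loci$name[b[1]],
                                        b[2]), character(1))))
  for (k in seq_along(bands))
    m[, k] <- vapply(seq_len(nrow(g)), function(i)
      as.integer(bands[[k]][2] %in% g[[i, bands[[k]][1]]]), integer(1))
  new("AflpMatrix", presence = m)
}
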