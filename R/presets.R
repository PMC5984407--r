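# Simulator presets.  The locus panel, allele sizes, event rates and host
# pool compositions are invented, but engineered to carry the qualitative
# structure of the empirical system: eight J isoloci and four L isoloci
# with tetranucleotide motifs, four multimodal J loci whose allele
# clusters sit >= 8 mutation steps apart and define five genetic groups,
# and sexual host pools whose L alleles include a highly divergent class
# (~9 steps from the main cluster) at frequency ~0.29.

#' Preset building blocks
#'
#' The locus panel, consensus J genotype, diagnostic alleles, founder L
#' haplomes and sexual host pool used by the simulator presets; exported
#' so custom [simConfig()] objects can be assembled from the same parts.
#'
#' @return `presetLoci()`: a locus table; `presetConsensusJ()`: named
#'   allele vector over the J isoloci; `presetDiagnostics()`: data.frame
#'   of group-diagnostic alleles; `presetFounderL(shift)`: list of two L
#'   haplomes (allele sizes shifted by `shift` bp); `presetHostPool()`:
#'   per-L-isolocus allele frequency tables.
#' @export
presetLoci <- function() {
  locusTable(
    name  = c("AjeD13", "AjeD294", "AjeD378", "AjeD346",
              "AmaD42", "AjeD23", "AjeD84", "AjeD422"),
    motif = 4L,
    j_range = rbind(c(190, 254), c(130, 194), c(200, 264), c(140, 204),
                    c(133, 229), c(165, 229), c(120, 184), c(150, 214)),
    l_range = rbind(c(NA, NA), c(NA, NA), c(NA, NA), c(NA, NA),
                    c(241, 305), c(241, 305), c(196, 260), c(226, 290)))
}

#' @rdname presetLoci
#' @export
presetConsensusJ <- function() {
  c("AjeD13-J" = 210L, "AjeD294-J" = 150L, "AjeD378-J" = 228L,
    "AjeD346-J" = 160L, "AmaD42-J" = 177L, "AjeD23-J" = 185L,
    "AjeD84-J" = 140L, "AjeD422-J" = 170L)
}

#' @rdname presetLoci
#' @export
presetDiagnostics <- function() {
  data.frame(group  = c("A", "C", "C", "D", "E"),
             locus  = c("AmaD42-J", "AjeD13-J", "AjeD23-J", "AjeD378-J",
                        "AmaD42-J"),
             allele = c(137L, 250L, 225L, 260L, 217L))
}

#' Diagnostic rule table matching the simulator presets
#'
#' Consensus J genotype at the four multimodal loci plus each group's
#' divergent diagnostic allele(s); group B is the consensus group.
#'
#' @return a [makeRuleTable()] result.
#' @export
presetRuleTable <- function() {
  cons <- presetConsensusJ()
  dLoci <- c("AmaD42-J", "AjeD13-J", "AjeD23-J", "AjeD378-J")
  makeRuleTable(as.list(cons[dLoci]), presetDiagnostics(),
                consensus_group = "B")
}

presetFounderJ <- function(group) {
  j <- presetConsensusJ()
  d <- presetDiagnostics()
  mine <- d[d$group == group, , drop = FALSE]
  j[mine$locus] <- mine$allele
  j
}

#' @rdname presetLoci
#' @param shift bp offset applied to the founder L alleles.
#' @export
presetFounderL <- function(shift = 0L) {
  base1 <- c("AmaD42-L" = 253L, "AjeD23-L" = 253L,
             "AjeD84-L" = 208L, "AjeD422-L" = 238L)
  base2 <- c("AmaD42-L" = 261L, "AjeD23-L" = 261L,
             "AjeD84-L" = 216L, "AjeD422-L" = 246L)
  list(base1 + shift, base2 + shift)
}

#' @rdname presetLoci
#' @export
presetHostPool <- function() {
  list(
    "AmaD42-L"  = c("249" = 0.18, "253" = 0.20, "257" = 0.18,
                    "261" = 0.12, "265" = 0.03, "297" = 0.29),
    "AjeD23-L"  = c("245" = 0.15, "253" = 0.18, "257" = 0.18,
                    "261" = 0.15, "265" = 0.05, "301" = 0.29),
    "AjeD84-L"  = c("200" = 0.25, "208" = 0.20, "212" = 0.20,
                    "216" = 0.20, "224" = 0.15),
    "AjeD422-L" = c("230" = 0.20, "238" = 0.25, "242" = 0.20,
                    "246" = 0.20, "254" = 0.15))
}

presetSites <- function(labels) {
  coords <- data.frame(
    site = c("S01", "S02", "S03", "S04"),
    lat  = c(45.428, 45.499, 45.518, 45.678),
    lon  = c(-73.946, -73.777, -73.740, -73.511))
  coords[coords$site %in% labels, , drop = FALSE]
}

group_ <- function(label, founder_L, sites, ex = 0, el = 0, re = 0) {
  list(label = label, founder_J = presetFounderJ(label),
       founder_L = founder_L, sites = sites,
       exchange_rate = ex, elevation_rate = el, reduction_rate = re)
}

#' Simulator presets
#'
#' Four named study conditions:
#' \describe{
#'   \item{clonal_only}{one triploid group (A) at four isolated sites, all
#'     event rates zero: diversity arises from mutation alone, so
#'     among-site variation should exceed within-site variation and no
#'     divergent host allele can ever appear.}
#'   \item{exchange_only}{one triploid group (B) at four sites with sexual
#'     host pools and a 10\% per-generation haplome-replacement rate (plus
#'     2\% elevation and 1\% reduction, elevation being the more common
#'     event in the complex): host alleles, including the divergent
#'     class, flow into the L haplomes.}
#'   \item{mixed_sympatry}{a clonal group (A) sympatric with two
#'     exchanging groups (B, E) and sampled LL hosts at two sites -- the
#'     configuration that discriminates the clonal from the exchanging
#'     signature within shared sites.}
#'   \item{all_diploid}{a diploid group (D) at two host-free sites, rates
#'     zero: only LJ biotypes can occur.}
#' }
#' Event rates are not empirical estimates; they are order-of-magnitude
#' values producing the qualitative contrast between the clonal and the
#' exchanging regimes.
#'
#' @param name preset name.
#' @param generations,pop_size,n_sampled,n_host_sampled,mu overrides of
#'   the preset defaults (see [simConfig()]).
#' @return a [simConfig()] object.
#' @export
kleptoPreset <- function(name = c("clonal_only", "exchange_only",
                                  "mixed_sympatry", "all_diploid"),
                         generations = 400, pop_size = 40, n_sampled = 15,
                         n_host_sampled = 10, mu = 5e-4) {
  name <- match.arg(name)
  loci <- presetLoci()
  pool <- presetHostPool()
  cfg <- switch(name,
    clonal_only = simConfig(
      loci, presetSites(c("S01", "S02", "S03", "S04")),
      groups = list(group_("A", presetFounderL(),
                           c("S01", "S02", "S03", "S04"))),
      host_pools = list(),
      n_host_sampled = 0),
    exchange_only = simConfig(
      loci, presetSites(c("S01", "S02", "S03", "S04")),
      groups = list(group_("B", presetFounderL(),
                           c("S01", "S02", "S03", "S04"),
                           ex = 0.1, el = 0.02, re = 0.01)),
      host_pools = list(S01 = pool, S02 = pool, S03 = pool, S04 = pool)),
    mixed_sympatry = simConfig(
      loci, presetSites(c("S01", "S02")),
      groups = list(
        group_("A", presetFounderL(), c("S01", "S02")),
        group_("B", presetFounderL(), c("S01", "S02"),
               ex = 0.1, el = 0.02, re = 0.01),
        group_("E", presetFounderL(4L), c("S01", "S02"),
               ex = 0.1, el = 0.02, re = 0.01)),
      host_pools = list(S01 = pool, S02 = pool)),
    all_diploid = simConfig(
      loci, presetSites(c("S03", "S04")),
      groups = list(group_("D", presetFounderL()[1], c("S03", "S04"))),
      host_pools = list(),
      n_host_sampled = 0))
  cfg$mu <- mu
  cfg$generations <- generations
  cfg$pop_size <- pop_size
  cfg$n_sampled <- n_sampled
  if (name %in% c("exchange_only", "mixed_sympatry"))
    cfg$n_host_sampled <- n_host_sampled
  cfg
}
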