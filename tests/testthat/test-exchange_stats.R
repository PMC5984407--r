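test_that("mutation steps are rounded repeat-unit differences", {
  expect_equal(mutationSteps(133, 137, 4), 1L)
  expect_equal(mutationSteps(108, 144, 4), 9L)
  expect_equal(mutationSteps(150, 150, 4), 0L)
})

test_that("divergent-allele detection flags alleles outside the main
           cluster", {
  motifs <- c(L1 = 4, L2 = 4, L3 = 4)
  res <- detectDivergentAlleles(list(L1 = c(100, 104, 108, 144)), motifs,
                                gap_threshold = 8)
  expect_equal(res$L1$allele, 144)
  expect_equal(res$L1$gap, 9L)
  # alleles all within two steps: nothing flagged
  res <- detectDivergentAlleles(list(L2 = c(100, 104, 108)), motifs)
  expect_equal(nrow(res$L2), 0)
  # a pair far from a larger cluster: both flagged
  res <- detectDivergentAlleles(list(L3 = c(201, 205, 209, 241, 253)),
                                motifs)
  expect_equal(res$L3$allele, c(241, 253))
  expect_equal(res$L3$gap[1], 8L)
  # two equal-size clusters need manual designation
  expect_error(detectDivergentAlleles(list(L1 = c(100, 104, 148, 152)),
                                      motifs),
               "equal-size")
})

test_that("carrier frequency counts haplome copy slots", {
  loci <- locusTable("AmaD42", 4L, j_range = rbind(c(133, 193)),
                     l_range = rbind(c(209, 261)))
  mk <- function(cells, biotypes) {
    g <- matrix(vector("list", length(cells)), ncol = 1)
    for (i in seq_along(cells)) g[[i, 1]] <- cells[[i]]
    ds <- newMsatDataset(g, loci,
                         data.frame(id = paste0("u", seq_along(cells)),
                                    site = "s"))
    ds@loci$haplome <- "L"; ds@loci$name <- "AmaD42-L"
    colnames(ds@genotypes) <- "AmaD42-L"
    ds@individuals$biotype <- biotypes
    ds
  }
  # 1 divergent copy among 4 slots (two LL diploids)
  ds <- mk(list(c(213L, 257L), c(213L, 217L)), c("LL", "LL"))
  expect_equal(carrierFrequency(ds, 257L, "AmaD42-L"), 25)
  # no carriers
  expect_equal(carrierFrequency(ds, 261L, "AmaD42-L"), 0)
  # every slot divergent
  ds <- mk(list(257L), "LL")
  expect_equal(carrierFrequency(ds, 257L, "AmaD42-L"), 100)
  # individuals denominator counts carriers, not copies
  ds <- mk(list(c(213L, 257L), c(213L, 217L)), c("LL", "LL"))
  expect_equal(carrierFrequency(ds, 257L, "AmaD42-L",
                                denominator = "individuals"), 50)
  # no data at the locus
  ds <- mk(list(integer(0)), "LL")
  expect_true(is.na(carrierFrequency(ds, 257L, "AmaD42-L")))
})

test_that("non-sampling probability matches the closed form and is
           monotone", {
  expect_equal(probNoCarrier(0, 25), 1)
  expect_equal(probNoCarrier(0.5, 0), 1)
  ps <- seq(0, 1, by = 0.1)
  expect_true(all(diff(probNoCarrier(ps, 10)) <= 0))
  ns <- 0:40
  expect_true(all(diff(probNoCarrier(0.3, ns)) <= 0))
})

test_that("haplome counts and weighted ploidy follow the biotype table", {
  grp <- c("LLJ", "LLJ", "LLJ", "LJ")
  expect_equal(weightedHaplomeCount(grp, "L"), 7L)
  expect_equal(weightedHaplomeCount(grp, "J"), 4L)
  expect_equal(weightedPloidyLevel(grp, "L"), 1.75)
  expect_equal(weightedPloidyLevel(grp, "J"), 1)
  expect_equal(weightedPloidyLevel(rep("LL", 3), "L"), 2)
  expect_equal(weightedHaplomeCount(character(0), "L"), 0L)
  expect_error(weightedPloidyLevel(character(0), "L"), "empty")
  expect_warning(weightedHaplomeCount(c("LLJ", "UNCALLED"), "L"),
                 "UNCALLED")
})

test_that("rarefied allele counts match exact subsample enumeration", {
  expect_equal(rarefiedAlleleCount(c(A = 3, B = 1), 2), 1.5)
  expect_equal(rarefiedAlleleCount(c(A = 3, B = 1), 4), 2)  # full sample
  expect_equal(rarefiedAlleleCount(c(A = 9), 3), 1)         # monomorphic
  expect_error(rarefiedAlleleCount(c(A = 3), 0), "positive")
  expect_error(rarefiedAlleleCount(c(A = 3), 5), "exceeds")
  set.seed(12)
  for (rep in 1:25) {
    k <- sample(1:4, 1)
    counts <- sample(1:4, k, replace = TRUE)
    while (sum(counts) > 12) counts <- counts - 1
    counts <- counts[counts > 0]
    n <- sample(seq_len(sum(counts)), 1)
    expect_equal(rarefiedAlleleCount(counts, n), oracleRarefy(counts, n),
                 tolerance = 1e-12)
  }
})

test_that("alternative alleles measure non-clonal excess richness", {
  loci <- locusTable("J1", 4L, j_range = rbind(c(100, 160)))
  mk <- function(cells) {
    g <- matrix(vector("list", length(cells)), ncol = 1)
    for (i in seq_along(cells)) g[[i, 1]] <- cells[[i]]
    ds <- newMsatDataset(g, loci,
                         data.frame(id = paste0("u", seq_along(cells)),
                                    site = "s"))
    ds@loci$haplome <- "J"; ds@individuals$biotype <- "LJ"
    ds
  }
  # perfect clones: zero alternative alleles at any rarefaction size
  ds <- mk(list(104L, 104L, 104L, 104L))
  expect_equal(alternativeAlleles(ds, indTable(ds)$id, "J"), 0)
  # four haploid copies {A,A,A,B}, consensus A: rarefied(2) - 1
  ds <- mk(list(104L, 104L, 104L, 108L))
  expect_equal(alternativeAlleles(ds, indTable(ds)$id, "J", n_rarefy = 2),
               rarefiedAlleleCount(c(3, 1), 2) - 1)
})

test_that("exchange lineages exceed their clonal J baseline in
           alternative alleles", {
  sim <- simulateKleptogenesis(kleptoPreset("exchange_only",
                                            generations = 80,
                                            pop_size = 15, n_sampled = 10),
                               seed = 29)
  iso <- suppressWarnings(
    assignGroups(callBiotypes(splitIsoloci(sim$dataset)),
                 presetRuleTable()))
  uni <- iso[indTable(iso)$biotype %in% c("LJ", "LLJ", "LLLJ"), ]
  rep <- suppressWarnings(alternativeAlleleReport(uni, min_size = 5))
  altL <- mean(rep$alt_alleles[rep$haplome == "L"])
  altJ <- mean(rep$alt_alleles[rep$haplome == "J"])
  expect_gt(altL, altJ)
  expect_true(all(rep$haplome_count >= rep$n_individuals))
})

test_that("dispersion partition separates within- and among-site
           variation", {
  # two sites of exact clones separated by d > 0: all variation among
  pts <- rbind(matrix(0, 4, 2), matrix(1, 4, 2))
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("u", 1:8), paste0("u", 1:8))
  groups <- rep("G", 8)
  sites <- rep(c("s1", "s2"), each = 4)
  dp <- dispersionPartition(m, groups, sites)
  expect_equal(dp$partition$intra, 0, tolerance = 1e-9)
  expect_equal(dp$partition$pct_inter, 100, tolerance = 1e-6)
  # identical members: everything zero
  m0 <- matrix(0, 8, 8, dimnames = dimnames(m))
  dp0 <- dispersionPartition(m0, groups, sites)
  expect_equal(dp0$partition$total, 0)
  # a single site: all variation within
  set.seed(4)
  pts <- matrix(rnorm(16), 8, 2)
  m1 <- as.matrix(dist(pts)); dimnames(m1) <- dimnames(m)
  dp1 <- dispersionPartition(m1, groups, rep("s1", 8))
  expect_equal(dp1$partition$pct_intra, 100, tolerance = 1e-9)
  expect_equal(dp1$partition$inter, 0, tolerance = 1e-12)
  # percentages always sum to 100
  expect_equal(dp$partition$pct_inter + dp$partition$pct_intra, 100)
})

test_that("dispersion comparison produces sensible Tukey letter codes", {
  set.seed(21)
  # three groups, the middle one overlapping both extremes: a / ab / b
  y <- c(rnorm(20, 0, 0.25), rnorm(20, 0.15, 0.25), rnorm(20, 0.3, 0.25))
  g <- rep(c("g1", "g2", "g3"), each = 20)
  cd <- compareDispersions(y, g)
  expect_equal(unname(cd$letters[c("g1", "g3")]), c("a", "b"))
  expect_setequal(strsplit(cd$letters[["g2"]], "")[[1]], c("a", "b"))
  # identical groups share a single letter
  cd0 <- compareDispersions(rep(c(1, 2), 20), rep(c("g1", "g2"), each = 20))
  expect_true(all(cd0$letters == "a") || cd0$p > 0.05)
  # zero variance everywhere is reported as undefined
  cdz <- compareDispersions(rep(1, 8), rep(c("g1", "g2"), each = 4))
  expect_true(is.na(cdz$F))
})
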