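test_that("allele step distance follows 1 - 2^(-steps)", {
  expect_equal(alleleStepDistance(133, 133, 4), 0)
  expect_equal(alleleStepDistance(133, 137, 4), 0.5)
  expect_equal(alleleStepDistance(100, 108, 4), 0.75)
  expect_warning(d <- alleleStepDistance(100, 103, 4), "rounded")
  expect_equal(d, 0.5)
  expect_error(alleleStepDistance(-4, 100, 4), "nonnegative")
})

test_that("genotype distance reproduces the add/loss worked examples", {
  # equal ploidy: best assignment among the two permutations
  expect_equal(bruvoGenotypeDistance(c(100, 104), c(100, 108), 4), 0.25)
  # identity at any ploidy
  expect_equal(bruvoGenotypeDistance(c(100, 104, 108), c(100, 104, 108), 4),
               0)
  # unequal ploidy: add completes from the smaller, loss from the larger
  expect_equal(bruvoGenotypeDistance(100, c(100, 108), 4, model = "add"),
               0.375)
  expect_equal(bruvoGenotypeDistance(100, c(100, 108), 4, model = "loss"),
               0.1875)
  expect_equal(bruvoGenotypeDistance(100, c(100, 108), 4), 0.28125)
  # missing data propagates as NA
  expect_true(is.na(bruvoGenotypeDistance(integer(0), c(100, 104), 4)))
})

test_that("genotype distance equals the exhaustive enumeration oracle", {
  set.seed(42)
  for (rep in 1:300) {
    p1 <- sample(1:4, 1); p2 <- sample(1:4, 1)
    g1 <- randomGenotype(p1); g2 <- randomGenotype(p2)
    g1 <- c(g1, g1[sample.int(length(g1), p1 - length(g1), replace = TRUE)])
    g2 <- c(g2, g2[sample.int(length(g2), p2 - length(g2), replace = TRUE)])
    for (model in list("add", "loss", c("add", "loss"))) {
      expect_equal(bruvoGenotypeDistance(g1, g2, 4, model),
                   oracleBruvo(g1, g2, 4, model),
                   tolerance = 1e-12,
                   info = paste(paste(g1, collapse = ","), "|",
                                paste(g2, collapse = ","), "|",
                                paste(model, collapse = "+")))
    }
  }
})

test_that("distance is monotone in the step difference and model-invariant
           at equal ploidy", {
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    g1 <- 100 + 4 * sample.int(5, k, replace = TRUE)
    g2 <- g1
    # push one allele of g2 progressively further away
    base <- bruvoGenotypeDistance(sort(g1), sort(g2), 4)
    prev <- base
    for (steps in 1:4) {
      g2m <- g2
      g2m[k] <- max(g2) + 4 * steps * 4  # move beyond every other allele
      d <- bruvoGenotypeDistance(sort(g1), sort(g2m), 4)
      expect_gte(d + 1e-12, prev)
      prev <- d
    }
    # add, loss and combined coincide when ploidies are equal
    expect_equal(bruvoGenotypeDistance(sort(g1), sort(g2), 4, "add"),
                 bruvoGenotypeDistance(sort(g1), sort(g2), 4, "loss"))
  }
})

test_that("allele frequency estimation splits unresolved copies uniformly", {
  loci <- locusTable("AmaD42", 4L, j_range = rbind(c(133, 193)),
                     l_range = rbind(c(209, 261)))
  mk <- function(cells, biotypes) {
    g <- matrix(vector("list", length(cells)), ncol = 1)
    for (i in seq_along(cells)) g[[i, 1]] <- cells[[i]]
    ind <- data.frame(id = paste0("u", seq_along(cells)), site = "s")
    ds <- newMsatDataset(g, loci, ind)
    ds@individuals$biotype <- biotypes
    ds@loci$haplome <- "L"
    ds@loci$name <- "AmaD42-L"
    colnames(ds@genotypes) <- "AmaD42-L"
    ds
  }
  # two diploids AA and AB
  ds <- mk(list(213L, c(213L, 217L)), c("LL", "LL"))
  f <- estimateAlleleFrequencies(ds, scope = "global")$tables$global[[1]]
  expect_equal(unname(f[c("213", "217")]), c(0.75, 0.25))
  # one triploid observed {A,B}: the third copy splits 0.5/0.5
  ds <- mk(list(c(213L, 217L)), "LLLJ")
  f <- estimateAlleleFrequencies(ds, scope = "global")$tables$global[[1]]
  expect_equal(unname(f), c(0.5, 0.5))
})

test_that("weighted partial-heterozygote distance matches hand enumeration", {
  # unambiguous genotypes reduce to the plain distance
  expect_equal(
    weightedPartialHetDistance(c(100, 104), c(100, 108), 2, 2, 4),
    bruvoGenotypeDistance(c(100, 104), c(100, 108), 4))
  # triploid observed {A,B}: completions AAB and ABB; equal frequencies
  # give the simple mean of the two completed distances
  other <- c(100, 104, 112)
  dAAB <- bruvoGenotypeDistance(c(100, 100, 108), other, 4)
  dABB <- bruvoGenotypeDistance(c(100, 108, 108), other, 4)
  f <- c("100" = 0.5, "108" = 0.5)
  expect_equal(
    weightedPartialHetDistance(c(100, 108), other, 3, 3, 4, f1 = f),
    mean(c(dAAB, dABB)))
  # degenerate frequencies concentrate all weight on one completion
  f1 <- c("100" = 1, "108" = 1e-12)
  expect_equal(
    weightedPartialHetDistance(c(100, 108), other, 3, 3, 4, f1 = f1),
    dAAB, tolerance = 1e-6)
  # an allele absent from the table gets the minimum frequency, warning
  expect_warning(
    weightedPartialHetDistance(c(100, 108), other, 3, 3, 4,
                               f1 = c("100" = 1)),
    "minimum")
})

test_that("pairwise matrices average per-locus distances over shared loci", {
  loci <- locusTable(c("L1", "L2"), 4L,
                     j_range = rbind(c(100, 160), c(200, 260)))
  mk <- function(cells) {
    g <- matrix(vector("list", 2 * length(cells)), ncol = 2)
    for (i in seq_along(cells)) {
      g[[i, 1]] <- cells[[i]][[1]]; g[[i, 2]] <- cells[[i]][[2]]
    }
    ds <- newMsatDataset(g, loci,
                         data.frame(id = paste0("u", seq_along(cells)),
                                    site = "s"))
    ds@loci$haplome <- "J"
    ds@individuals$biotype <- "LJ"
    ds
  }
  # identical individuals: zero matrix
  ds <- mk(list(list(104L, 204L), list(104L, 204L)))
  m <- bruvoDistanceMatrix(ds, haplome = "J")
  expect_equal(max(abs(m)), 0)
  # one step at one of two loci: (0 + 0.5) / 2
  ds <- mk(list(list(104L, 204L), list(104L, 208L)))
  expect_equal(bruvoDistanceMatrix(ds, haplome = "J")[1, 2], 0.25)
  # a missing locus drops out of the mean
  ds <- mk(list(list(104L, 204L), list(108L, integer(0))))
  expect_equal(bruvoDistanceMatrix(ds, haplome = "J")[1, 2], 0.5)
  # no shared locus is an error
  ds <- mk(list(list(104L, integer(0)), list(integer(0), 204L)))
  expect_error(bruvoDistanceMatrix(ds, haplome = "J"), "share no")
})

test_that("distance matrices are symmetric, bounded and zero-diagonal", {
  sim <- simulateKleptogenesis(kleptoPreset("mixed_sympatry",
                                            generations = 40,
                                            pop_size = 10, n_sampled = 8),
                               seed = 3)
  iso <- callBiotypes(splitIsoloci(sim$dataset))
  iso <- iso[indTable(iso)$biotype %in% c("LJ", "LLJ", "LLLJ"), ]
  for (h in c("J", "L", "LJ")) {
    m <- bruvoDistanceMatrix(iso, haplome = h)
    expect_equal(m, t(m))
    expect_equal(max(abs(diag(m))), 0)
    expect_true(all(m >= 0 & m <= 1))
  }
})
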