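test_that("isolocus splitting assigns alleles by range and conserves them", {
  ds <- toyDataset()
  iso <- splitIsoloci(ds)
  loc <- lociTable(iso)
  # allele 133 falls in the AmaD42 J range, 213/221 in the L range
  g <- genotypeMatrix(iso)
  expect_equal(g[[1, which(loc$name == "AmaD42-J")]], 133L)
  expect_equal(g[[1, which(loc$name == "AmaD42-L")]], c(213L, 221L))
  # J_ONLY rule sends every allele to the J isolocus
  expect_equal(loc$haplome[loc$name == "AjeD13-J"], "J")
  expect_equal(g[[1, which(loc$name == "AjeD13-J")]], 210L)
  # non-discriminating locus carried over as U
  expect_equal(loc$haplome[loc$name == "AjeD94"], "U")
})

test_that("alleles outside both ranges go to an unpartitioned column", {
  ds <- toyDataset()
  g <- genotypeMatrix(ds)
  g[[1, 1]] <- c(133L, 201L, 213L)   # 201 between the J and L ranges
  ds2 <- newMsatDataset(g, lociTable(ds), indTable(ds), siteTable(ds))
  expect_warning(iso <- splitIsoloci(ds2), "unpartitioned")
  loc <- lociTable(iso)
  expect_true("AmaD42-U" %in% loc$name)
  expect_equal(genotypeMatrix(iso)[[1, which(loc$name == "AmaD42-U")]], 201L)
})

test_that("partition conserves every allele of every individual", {
  sim <- simulateKleptogenesis(kleptoPreset("mixed_sympatry",
                                            generations = 30,
                                            pop_size = 10, n_sampled = 10),
                               seed = 91)
  ds <- sim$dataset
  iso <- splitIsoloci(ds)
  for (i in seq_len(nInd(ds))) {
    before <- sort(unname(unlist(genotypeMatrix(ds)[i, ])))
    after <- sort(unname(unlist(genotypeMatrix(iso)[i, ])))
    expect_identical(after, before)
  }
})

test_that("biotype calling follows the distinct-allele-count rule", {
  iso <- callBiotypes(splitIsoloci(toyDataset()))
  bt <- indTable(iso)$biotype
  expect_equal(bt, c("LLJ", "LLJ", "LJ", "LL"))
  # three distinct J alleles cannot arise from any biotype in the complex
  ds <- toyDataset()
  g <- genotypeMatrix(ds)
  g[[3, 2]] <- c(210L, 214L, 218L)   # AjeD13 (J only)
  ds2 <- newMsatDataset(g, lociTable(ds), indTable(ds), siteTable(ds))
  bt2 <- indTable(callBiotypes(splitIsoloci(ds2)))$biotype
  expect_equal(bt2[3], "UNCALLED")
})

test_that("biotype calling recovers the simulator truth on clonal presets", {
  for (preset in c("clonal_only", "all_diploid")) {
    sim <- simulateKleptogenesis(kleptoPreset(preset, generations = 60,
                                              pop_size = 12,
                                              n_sampled = 10), seed = 17)
    iso <- callBiotypes(splitIsoloci(sim$dataset))
    expect_identical(indTable(iso)$biotype, sim$truth$true_biotype)
  }
  # with random host gametes a partial heterozygote can be genuinely
  # information-free; calling may then only ever under-report ploidy
  sim <- simulateKleptogenesis(kleptoPreset("exchange_only",
                                            generations = 60,
                                            pop_size = 12, n_sampled = 15),
                               seed = 17)
  iso <- callBiotypes(splitIsoloci(sim$dataset))
  called <- indTable(iso)$biotype
  truth <- sim$truth$true_biotype
  ok <- called == truth
  ladder <- c(LJ = 1, LLJ = 2, LLLJ = 3)
  for (i in which(!ok & truth != "LL"))
    expect_lt(ladder[called[i]], ladder[truth[i]])
})

test_that("group assignment follows consensus and diagnostic alleles", {
  rt <- presetRuleTable()
  sim <- simulateKleptogenesis(kleptoPreset("mixed_sympatry",
                                            generations = 0,
                                            pop_size = 6, n_sampled = 12),
                               seed = 5)
  iso <- callBiotypes(splitIsoloci(sim$dataset))
  iso <- suppressWarnings(assignGroups(iso, rt))
  ind <- indTable(iso)
  uni <- ind$biotype != "LL"
  expect_identical(ind$group[uni],
                   sim$truth$true_group[match(ind$id, sim$truth$id)][uni])
  # hosts have no J data at the diagnostic loci
  expect_true(all(ind$group[!uni] == "UNASSIGNED"))
})

test_that("conflicting diagnostics yield X and missing data UNASSIGNED", {
  rt <- presetRuleTable()
  loci <- presetLoci <- lociTable(splitIsoloci(
    simulateKleptogenesis(kleptoPreset("all_diploid", generations = 0,
                                       pop_size = 2, n_sampled = 2),
                          seed = 1)$dataset))
  cons <- rt$consensus
  dLoci <- names(cons)
  mk <- function(alleles) {
    g <- matrix(vector("list", length(loci$name)), nrow = 1)
    for (k in seq_along(loci$name)) g[[1, k]] <- integer(0)
    for (loc in names(alleles))
      g[[1, which(loci$name == loc)]] <- alleles[[loc]]
    newMsatDataset(g, loci, data.frame(id = "x", site = "s"))
  }
  # diagnostics of two different groups (A and D) present -> X
  both <- cons
  both[["AmaD42-J"]] <- 137L   # A diagnostic
  both[["AjeD378-J"]] <- 260L  # D diagnostic
  ds <- mk(both)
  expect_equal(indTable(assignGroups(ds, rt))$group, "X")
  # missing data at one diagnostic locus -> UNASSIGNED with warning
  miss <- cons
  miss[["AmaD42-J"]] <- integer(0)
  expect_warning(out <- assignGroups(mk(miss), rt), "UNASSIGNED")
  expect_equal(indTable(out)$group, "UNASSIGNED")
  # exact consensus -> consensus group B
  expect_equal(indTable(assignGroups(mk(cons), rt))$group, "B")
})

test_that("consensus genotype is the modal one with lexicographic ties", {
  loci <- locusTable("L1", 4L, j_range = rbind(c(100, 160)))
  mk <- function(...) {
    cells <- list(...)
    g <- matrix(vector("list", length(cells)), ncol = 1)
    for (i in seq_along(cells)) g[[i, 1]] <- cells[[i]]
    newMsatDataset(g, loci,
                   data.frame(id = paste0("u", seq_along(cells)),
                              site = "s"))
  }
  # majority wins
  ds <- mk(c(100L, 104L), c(100L, 104L), c(100L, 104L), 108L)
  expect_equal(consensusGenotype(ds)[["L1"]], c(100L, 104L))
  # 2-2 tie: lexicographically smaller allele vector
  ds <- mk(c(100L, 104L), c(100L, 104L), c(100L, 108L), c(100L, 108L))
  expect_equal(consensusGenotype(ds)[["L1"]], c(100L, 104L))
  # single individual is its own consensus
  ds <- mk(c(112L, 116L))
  expect_equal(consensusGenotype(ds)[["L1"]], c(112L, 116L))
})

test_that("biotype proportions are percentages among called unisexuals", {
  bts <- c(rep("LLJ", 3), "LJ", "LL", "UNCALLED")
  p <- biotypeProportions(bts)
  expect_equal(unname(p[c("LJ", "LLJ", "LLLJ")]), c(25, 75, 0))
})
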