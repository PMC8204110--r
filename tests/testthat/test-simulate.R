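test_that("noise-free planted modules occupy exactly their carrier genomes", {
  cfg <- SimConfig(genomesPerLineage = 10, nBackgroundFamilies = 0,
                   plantedModules = list(plantedModule(25, "Pacearchaeota")),
                   flipNoise = 0, decoyRate = 0, seed = 42)
  sim <- simulateDataset(cfg)
  expect_equal(nrow(sim$truth$modules), 1L)
  expect_equal(sim$truth$modules$n_carriers, 10L)
  carriers <- sim$truth$carriers$genome_id
  expect_setequal(carriers,
                  sim$genomes$genome_id[sim$genomes$phylum == "Pacearchaeota"])
  pm <- buildPresenceMatrix(sim$hits, sim$genomes)
  P <- presence(pm)
  fams <- sim$truth$families$family_id
  expect_equal(nrow(P), 25L)
  for (f in fams) {
    expect_setequal(colnames(P)[P[f, ]], carriers)
  }
})

test_that("no planted modules yields an empty truth table", {
  cfg <- SimConfig(genomesPerLineage = 5, nBackgroundFamilies = 100,
                   backgroundProb = 0.5, plantedModules = list(),
                   flipNoise = 0, seed = 9)
  sim <- simulateDataset(cfg)
  expect_equal(nrow(sim$truth$modules), 0L)
  expect_equal(nrow(sim$truth$carriers), 0L)
  expect_true(all(is.na(sim$truth$families$module_id)))
})

test_that("same seed reproduces byte-identical tables, different seed differs", {
  cfg1 <- SimConfig(genomesPerLineage = 6, nBackgroundFamilies = 80, seed = 1)
  cfg1b <- SimConfig(genomesPerLineage = 6, nBackgroundFamilies = 80, seed = 1)
  cfg2 <- SimConfig(genomesPerLineage = 6, nBackgroundFamilies = 80, seed = 2)
  s1 <- simulateDataset(cfg1)
  s1b <- simulateDataset(cfg1b)
  s2 <- simulateDataset(cfg2)
  expect_identical(s1$hits, s1b$hits)
  expect_identical(s1$bacterialHits, s1b$bacterialHits)
  expect_false(identical(s1$hits, s2$hits))
  expect_identical(dim(s1$genomes), dim(s2$genomes))
  expect_identical(s1$truth$families$family_id, s2$truth$families$family_id)
})

test_that("planted modules below 20 families are rejected by the size rule", {
  expect_error(
    SimConfig(plantedModules = list(plantedModule(19, "Pacearchaeota"))),
    "at least 20")
})

test_that("probabilities and counts outside their domains are rejected", {
  expect_error(SimConfig(flipNoise = 1.2), "\\[0, 1\\]")
  expect_error(SimConfig(genomesPerLineage = 0), ">= 1")
  expect_error(
    SimConfig(plantedModules = list(plantedModule(20, "NotALineage"))),
    "NotALineage")
})

test_that("present-cell E-values fall below threshold and decoys above it", {
  cfg <- SimConfig(genomesPerLineage = 6, nBackgroundFamilies = 50,
                   plantedModules = list(), flipNoise = 0,
                   decoyRate = 0.1, seed = 4)
  sim <- simulateDataset(cfg)
  pm <- buildPresenceMatrix(sim$hits, sim$genomes, keepEmpty = TRUE)
  P <- presence(pm)
  pass <- sim$hits$evalue <= 0.001
  # every passing hit corresponds to a present cell; decoys never do
  expect_true(all(P[cbind(sim$hits$family_id[pass], sim$hits$genome_id[pass])]))
  expect_false(any(P[cbind(sim$hits$family_id[!pass],
                           sim$hits$genome_id[!pass])]))
  expect_true(all(sim$hits$evalue[!pass] > 0.001 & sim$hits$evalue[!pass] <= 10))
})

test_that("background prevalence converges to the configured probability", {
  cfg <- SimConfig(genomesPerLineage = 150, nBackgroundFamilies = 60,
                   backgroundProb = 0.3, plantedModules = list(),
                   flipNoise = 0, decoyRate = 0, seed = 77)
  sim <- simulateDataset(cfg)
  pm <- buildPresenceMatrix(sim$hits, sim$genomes, keepEmpty = TRUE)
  prev <- rowMeans(presence(pm))
  n <- ncol(presence(pm))
  se <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(prev - 0.3) <= 3 * se + 1 / n))
})

test_that("flip noise perturbs cells at the configured rate", {
  base <- SimConfig(genomesPerLineage = 40, nBackgroundFamilies = 100,
                    plantedModules = list(plantedModule(30, "Nanoarchaeota")),
                    flipNoise = 0, decoyRate = 0, seed = 12)
  noisy <- SimConfig(genomesPerLineage = 40, nBackgroundFamilies = 100,
                     plantedModules = list(plantedModule(30, "Nanoarchaeota")),
                     flipNoise = 0.05, decoyRate = 0, seed = 12)
  P0 <- presence(buildPresenceMatrix(simulateDataset(base)$hits,
                                     simulateDataset(base)$genomes,
                                     keepEmpty = TRUE))
  P1 <- presence(buildPresenceMatrix(simulateDataset(noisy)$hits,
                                     simulateDataset(noisy)$genomes,
                                     keepEmpty = TRUE))
  rate <- mean(P0[rownames(P1), colnames(P1)] != P1)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(P1)))
})

test_that("planted QC failures are constructed as described", {
  cfg <- SimConfig(genomesPerLineage = 10, nBackgroundFamilies = 0,
                   plantedModules = list(), flipNoise = 0, seed = 31,
                   qcPlanted = c(low_completeness = 2L, high_duplication = 2L,
                                 low_alignment = 2L, split_scaffold = 2L,
                                 ani_pairs = 2L))
  qc <- simulateQCInputs(cfg)
  truth <- qc$truth$genomes
  scgMat <- as.matrix(qc$scg[, -1])
  rownames(scgMat) <- qc$scg$genome_id

  lowC <- truth$genome_id[truth$planted_fail_completeness]
  expect_length(lowC, 2L)
  expect_true(all(rowSums(scgMat[lowC, , drop = FALSE] >= 1) <= 22))
  highD <- truth$genome_id[truth$planted_fail_duplication]
  expect_true(all(rowSums(scgMat[highD, , drop = FALSE] >= 2) >= 4))

  # planted alignment failures have >50% gap columns in the emitted FASTA;
  # count non-gap characters directly in the sequences
  aln <- qc$alignment
  lowA <- truth$genome_id[truth$planted_fail_alignment]
  for (g in truth$genome_id) {
    chars <- strsplit(as.character(aln[[g]]), "")[[1]]
    frac <- mean(!chars %in% c("-", "."))
    if (g %in% lowA) expect_lt(frac, 0.5) else expect_gte(frac, 0.5)
  }

  # planted ANI pairs sit above 95, every other pair below
  pairs <- qc$truth$aniPairs
  expect_equal(nrow(pairs), 2L)
  key <- paste(qc$ani$genome_a, qc$ani$genome_b)
  pkey <- paste(pairs$genome_a, pairs$genome_b)
  expect_true(all(qc$ani$ani[key %in% pkey] > 95))
  expect_true(all(qc$ani$ani[!key %in% pkey] < 95))

  # split-scaffold plants use two scaffolds, everyone else one
  nScf <- tapply(qc$rpScaffolds$scaffold_id, qc$rpScaffolds$genome_id,
                 function(x) length(unique(x)))
  split <- truth$genome_id[truth$planted_fail_scaffold]
  expect_true(all(nScf[split] == 2L))
  expect_true(all(nScf[setdiff(truth$genome_id, split)] == 1L))
})

test_that("simulated inputs round-trip through their on-disk formats", {
  cfg <- SimConfig(genomesPerLineage = 5, nBackgroundFamilies = 30, seed = 8)
  sim <- simulateDataset(cfg)
  qc <- simulateQCInputs(cfg)
  dir <- withr::local_tempdir()
  paths <- writeSimulatedInputs(sim, qc, dir)
  expect_true(all(file.exists(paths)))
  hits2 <- read.delim(paths[["hits"]])
  expect_equal(nrow(hits2), nrow(sim$hits))
  aln2 <- Biostrings::readAAStringSet(paths[["alignment"]])
  expect_equal(length(aln2), nrow(sim$genomes))
  expect_equal(length(unique(Biostrings::width(aln2))), 1L)
})
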