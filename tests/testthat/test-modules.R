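# hand-built fixture realizing the median-genome worked example:
# per-family genome counts {3, 2, 4, 3} and carriage g1:4 g2:3 g3:3 g4:1 g5:1
taxFixture <- function() {
  P <- matrix(FALSE, 4, 5, dimnames = list(paste0("f", 1:4), paste0("g", 1:5)))
  P["f1", c("g1", "g2", "g3")] <- TRUE
  P["f2", c("g1", "g5")] <- TRUE
  P["f3", c("g1", "g2", "g3", "g4")] <- TRUE
  P["f4", c("g1", "g2", "g3")] <- TRUE
  genomes <- data.frame(
    genome_id = paste0("g", 1:5),
    phylum = c("Pacearchaeota", "Pacearchaeota", "Woesearchaeota",
               "Euryarchaeota", "Euryarchaeota"),
    is_dpann = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    domain = "archaea")
  PresenceMatrix(P, genomes = genomes)
}

moduleSetFor <- function(pm, fams = rownames(presence(pm))) {
  extractModules(setNames(rep(1L, length(fams)), fams), minSize = 1)
}

test_that("dendrogram cut separates clean blocks and isolates singletons", {
  # three blocks with within-block distance 0, between-block distance 1
  m <- rbind(a1 = c(1, 1, 0, 0, 0, 0), a2 = c(1, 1, 0, 0, 0, 0),
             b1 = c(0, 0, 1, 1, 0, 0), b2 = c(0, 0, 1, 1, 0, 0),
             c1 = c(0, 0, 0, 0, 1, 1))
  colnames(m) <- paste0("g", 1:6)
  cl <- clusterFamilies(jaccardDistance(m), cutoff = 0.95)
  expect_equal(length(unique(cl$clusters)), 3L)
  expect_equal(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_false(cl$clusters[["a1"]] == cl$clusters[["b1"]])

  # all pairwise distances 1: complete-linkage merge heights all exceed 0.95
  d1 <- matrix(1, 4, 4, dimnames = list(paste0("f", 1:4), paste0("f", 1:4)))
  diag(d1) <- 0
  expect_equal(length(unique(clusterFamilies(d1)$clusters)), 4L)

  # all distances 0: a single cluster
  d0 <- matrix(0, 4, 4, dimnames = list(paste0("f", 1:4), paste0("f", 1:4)))
  expect_equal(length(unique(clusterFamilies(d0)$clusters)), 1L)
})

test_that("non-square or asymmetric distance input is rejected", {
  expect_error(clusterFamilies(matrix(0, 2, 3)), "square")
  d <- matrix(c(0, 0.2, 0.4, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(clusterFamilies(d), "symmetric")
})

test_that("clustering is invariant to input row order", {
  withr::local_seed(88)
  P <- randomPresence(30, 15, 0.3)
  d <- jaccardDistance(P)
  cl1 <- clusterFamilies(d)
  perm <- sample(nrow(d))
  cl2 <- clusterFamilies(d[perm, perm])
  sets1 <- sort(sapply(split(names(cl1$clusters), cl1$clusters),
                       function(x) paste(sort(x), collapse = ",")))
  sets2 <- sort(sapply(split(names(cl2$clusters), cl2$clusters),
                       function(x) paste(sort(x), collapse = ",")))
  expect_equal(unname(sets1), unname(sets2))
})

test_that("module extraction applies the >=20-family rule with stable numbering", {
  clusters <- setNames(rep(1:3, times = c(25, 19, 40)),
                       sprintf("fam%03d", 1:84))
  ms <- extractModules(clusters, minSize = 20)
  expect_equal(length(ms), 2L)
  tab <- moduleTable(ms)
  expect_equal(tab$module_id, c("M001", "M002"))
  expect_equal(tab$size, c(40L, 25L))       # descending size
  expect_equal(length(moduleResiduals(ms)), 1L)
  expect_equal(length(moduleResiduals(ms)$R001), 19L)

  none <- extractModules(setNames(1:10, paste0("f", 1:10)), minSize = 20)
  expect_equal(length(none), 0L)
  expect_equal(length(moduleResiduals(none)), 10L)

  # family sets of distinct modules are disjoint (partition property)
  expect_equal(anyDuplicated(unlist(moduleFamilies(ms))), 0L)
})

test_that("median-genome taxonomy follows the verbatim rule on the worked example", {
  pm <- taxFixture()
  ms <- assignModuleTaxonomy(moduleSetFor(pm), pm)
  tab <- moduleTable(ms)
  expect_equal(tab$m, 3L)                             # median of {3,2,4,3}
  expect_equal(retainedGenomes(ms)[[1]], c("g1", "g2", "g3"))
  expect_equal(tab$taxon_distribution, "Pacearchaeota:2;Woesearchaeota:1")
  expect_true(is.na(tab$assigned_single_lineage))     # not unanimous
  expect_equal(tab$dominant_lineage, "Pacearchaeota")
})

test_that("degenerate and even-count medians behave as specified", {
  # all families in exactly the same 5 genomes of one phylum
  P <- matrix(FALSE, 3, 6, dimnames = list(paste0("f", 1:3), paste0("g", 1:6)))
  P[, 1:5] <- TRUE
  genomes <- data.frame(genome_id = paste0("g", 1:6), phylum = "Pacearchaeota",
                        is_dpann = TRUE, domain = "archaea")
  pm <- PresenceMatrix(P, genomes = genomes)
  ms <- assignModuleTaxonomy(moduleSetFor(pm), pm)
  expect_equal(moduleTable(ms)$m, 5L)
  expect_equal(moduleTable(ms)$assigned_single_lineage, "Pacearchaeota")

  # integer median needs no rounding; fractional median rounds half-up
  expect_equal(fammod:::medianHalfUp(c(2, 2)), 2L)
  expect_equal(fammod:::medianHalfUp(c(2, 3)), 3L)
  expect_equal(fammod:::medianHalfUp(c(3, 2, 4, 3)), 3L)
})

test_that("modules with families absent from the matrix are rejected", {
  pm <- taxFixture()
  ms <- extractModules(setNames(1L, "fX"), minSize = 1)
  expect_error(assignModuleTaxonomy(ms, pm), "fX")
})

test_that("taxonomy matches a brute-force transcription on random instances", {
  withr::local_seed(909)
  for (rep in 1:40) {
    nf <- sample(3:12, 1); ng <- sample(4:15, 1)
    P <- randomPresence(nf, ng, runif(1, 0.2, 0.8))
    phyla <- setNames(sample(c("A", "B", "C"), ng, replace = TRUE),
                      colnames(P))
    genomes <- data.frame(genome_id = colnames(P), phylum = unname(phyla),
                          is_dpann = TRUE, domain = "archaea")
    pm <- PresenceMatrix(P, genomes = genomes)
    ms <- assignModuleTaxonomy(moduleSetFor(pm), pm)
    exp <- oracleTaxonomy(rownames(P), P, phyla)
    tab <- moduleTable(ms)
    expect_equal(tab$m, exp$m)
    expect_equal(sort(retainedGenomes(ms)[[1]]), exp$retained)
    expect_equal(tab$assigned_single_lineage, exp$single)
  }
})

test_that("occurrence and enrichment compare mean per-family prevalences", {
  # famA in 2/4 DPANN and 1/4 others; famB in 4/4 DPANN and 1/4 others
  P <- matrix(FALSE, 2, 8,
              dimnames = list(c("famA", "famB"),
                              c(paste0("d", 1:4), paste0("n", 1:4))))
  P["famA", c("d1", "d2", "n1")] <- TRUE
  P["famB", c("d1", "d2", "d3", "d4", "n1")] <- TRUE
  genomes <- data.frame(genome_id = colnames(P),
                        phylum = rep(c("Pacearchaeota", "Euryarchaeota"),
                                     each = 4),
                        is_dpann = rep(c(TRUE, FALSE), each = 4),
                        domain = "archaea")
  pm <- PresenceMatrix(P, genomes = genomes)
  ms <- classifyModuleOccurrence(moduleSetFor(pm), pm)
  tab <- moduleTable(ms)
  expect_equal(tab$dpann_prevalence, 0.75)
  expect_equal(tab$nondpann_prevalence, 0.25)
  expect_true(tab$enriched)
  expect_true(tab$occurs_in_dpann)

  # a module absent from all DPANN genomes does not occur there
  P2 <- P; P2[, 1:4] <- FALSE
  pm2 <- PresenceMatrix(P2, genomes = genomes)
  ms2 <- classifyModuleOccurrence(moduleSetFor(pm2), pm2)
  expect_false(moduleTable(ms2)$occurs_in_dpann)
  expect_false(moduleTable(ms2)$enriched)
})

test_that("prevalence is flagged undefined without both genome groups", {
  P <- matrix(TRUE, 1, 2, dimnames = list("famA", c("g1", "g2")))
  genomes <- data.frame(genome_id = c("g1", "g2"), phylum = "Pacearchaeota",
                        is_dpann = TRUE, domain = "archaea")
  pm <- PresenceMatrix(P, genomes = genomes)
  expect_warning(ms <- classifyModuleOccurrence(moduleSetFor(pm), pm),
                 "undefined")
  expect_false(moduleTable(ms)$prevalence_defined)
  expect_true(is.na(moduleTable(ms)$dpann_prevalence))
})

test_that("genome clustering merges identical genomes and splits disjoint blocks", {
  P <- matrix(FALSE, 4, 5,
              dimnames = list(paste0("f", 1:4), paste0("g", 1:5)))
  P[1:2, c("g1", "g2")] <- TRUE        # block 1: g1 == g2
  P[3:4, c("g3", "g4", "g5")] <- TRUE  # block 2
  pm <- PresenceMatrix(P)
  gc <- clusterGenomes(pm)
  hc <- gc$tree
  merged <- cutree(hc, h = 0)
  expect_equal(merged[["g1"]], merged[["g2"]])       # identical: height 0
  top <- cutree(hc, k = 2)
  expect_equal(length(unique(top[c("g1", "g2")])), 1L)
  expect_equal(length(unique(top[c("g3", "g4", "g5")])), 1L)
  expect_false(top[["g1"]] == top[["g3"]])

  # Newick export parses and carries all leaves
  phy <- ape::read.tree(text = gc$newick)
  expect_setequal(phy$tip.label, colnames(P))
  # ordered table has the leaf order
  expect_equal(colnames(gc$matrix), hc$labels[hc$order])

  expect_error(clusterGenomes(pm[, 1]), "at least 2")
})

test_that("planted modules are recovered end-to-end at 5% flip noise", {
  cfg <- SimConfig(genomesPerLineage = 25, nBackgroundFamilies = 300,
                   plantedModules = list(
                     plantedModule(25, "Pacearchaeota"),
                     plantedModule(30, "Woesearchaeota"),
                     plantedModule(20, "Euryarchaeota")),
                   flipNoise = 0.05, seed = 61)
  sim <- simulateDataset(cfg)
  pm <- buildPresenceMatrix(sim$hits, sim$genomes)
  ms <- detectModules(pm)
  det <- moduleFamilies(ms)
  truthF <- sim$truth$families
  planted <- split(truthF$family_id[!is.na(truthF$module_id)],
                   truthF$module_id[!is.na(truthF$module_id)])
  for (p in planted) {
    ov <- vapply(det, function(d)
      length(intersect(p, d)) / length(union(p, d)), numeric(1))
    expect_gte(max(ov), 0.8)
  }
  # detected modules partition their families
  expect_equal(anyDuplicated(unlist(det)), 0L)
})
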