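# Brute-force re-implementations of the verbatim rules, written as literal
# loops so they stay independent of the package's vectorized code paths.
# Used both by unit tests and by the rule-equivalence acceptance checks.

# Median-genome taxonomy rule, transcribed literally:
# "For each module, the median number of genomes per family (m) was
#  calculated. The genomes were ranked by the number of families they carry.
#  The m genomes that carry the most of families were retained; their phyla
#  distribution defines the taxonomic assignment of the module."
oracleTaxonomy <- function(fams, P, phylum) {
  counts <- integer(length(fams))
  for (i in seq_along(fams)) {
    counts[i] <- sum(P[fams[i], ])
  }
  med <- stats::median(counts)
  m <- as.integer(floor(med + 0.5))          # half-up when fractional
  genomes <- colnames(P)
  carriage <- integer(length(genomes))
  for (j in seq_along(genomes)) {
    carriage[j] <- sum(P[fams, genomes[j]])
  }
  ord <- order(-carriage, genomes, method = "radix")
  retained <- genomes[ord][seq_len(m)]
  dist <- table(phylum[retained])
  single <- if (m > 0 && length(unique(phylum[retained])) == 1L) {
    unique(phylum[retained])
  } else NA_character_
  list(m = m, retained = sort(retained), dist = dist, single = single)
}

# Breadth rule, transcribed literally: per-phylum percentage of
# representative genomes with an above-threshold hit; then, for families
# with at least one hit, the percentage of phyla where at least `frac` of
# genomes are hit (inclusive).
oracleBreadth <- function(hits, meta, families, threshold = 0.001,
                          frac = 1 / 3) {
  phyla <- sort(unique(meta$phylum), method = "radix")
  out <- data.frame(family_id = sort(families, method = "radix"),
                    has_bacterial_hit = FALSE,
                    n_phyla_passing = 0L, breadth_pct = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    f <- out$family_id[r]
    anyHit <- FALSE
    nPass <- 0L
    for (p in phyla) {
      gen <- meta$genome_id[meta$phylum == p]
      nHit <- 0L
      for (g in gen) {
        ok <- any(hits$family_id == f & hits$genome_id == g &
                    hits$evalue <= threshold)
        if (ok) nHit <- nHit + 1L
      }
      if (nHit > 0L) anyHit <- TRUE
      # inclusive "at least one third": compare on the count scale to avoid
      # any floating-point subtlety in the oracle itself
      if (nHit >= frac * length(gen) - 1e-12) nPass <- nPass + 1L
    }
    out$has_bacterial_hit[r] <- anyHit
    if (anyHit) {
      out$n_phyla_passing[r] <- nPass
      out$breadth_pct[r] <- 100 * nPass / length(phyla)
    }
  }
  out
}

# Dereplication rule: single-linkage components at ANI >= threshold
# (transitive closure by repeated boolean matrix multiplication), then
# "the most complete and less contaminated genome per cluster".
oracleDereplicate <- function(aniMat, meta, threshold = 95) {
  ids <- sort(meta$genome_id, method = "radix")
  A <- aniMat[ids, ids] >= threshold
  diag(A) <- TRUE
  R <- A
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  seen <- character(0)
  clusters <- list()
  for (g in ids) {
    if (g %in% seen) next
    members <- ids[R[g, ]]
    clusters[[length(clusters) + 1L]] <- sort(members, method = "radix")
    seen <- c(seen, members)
  }
  reps <- vapply(clusters, function(members) {
    sub <- meta[match(members, meta$genome_id), ]
    sub <- sub[order(-sub$completeness, sub$contamination, sub$genome_id,
                     method = "radix"), ]
    sub$genome_id[1L]
  }, character(1))
  list(clusters = clusters, representatives = sort(reps, method = "radix"))
}

# Random small instances ----------------------------------------------------

randomPresence <- function(nFam, nGen, p = 0.4) {
  m <- matrix(stats::runif(nFam * nGen) < p, nFam, nGen,
              dimnames = list(sprintf("f%02d", seq_len(nFam)),
                              sprintf("g%02d", seq_len(nGen))))
  m
}

randomANIMeta <- function(nGen, pEdge = 0.15) {
  ids <- sprintf("g%02d", seq_len(nGen))
  m <- matrix(stats::runif(nGen * nGen, 70, 94), nGen, nGen,
              dimnames = list(ids, ids))
  hi <- which(upper.tri(m) & matrix(stats::runif(nGen * nGen) < pEdge,
                                    nGen, nGen))
  m[hi] <- stats::runif(length(hi), 95, 99.9)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 100
  meta <- data.frame(genome_id = ids,
                     completeness = round(stats::runif(nGen, 50, 100), 1),
                     contamination = round(stats::runif(nGen, 0, 15), 1),
                     stringsAsFactors = FALSE)
  list(ani = m, meta = meta)
}

randomBacterialPanel <- function(nPhyla, genomesPerPhylum, nFam,
                                 pHit = 0.25, pDecoy = 0.1) {
  phyla <- sprintf("phy%02d", seq_len(nPhyla))
  meta <- data.frame(
    genome_id = unlist(lapply(phyla, function(p)
      sprintf("%s_g%d", p, seq_len(genomesPerPhylum)))),
    phylum = rep(phyla, each = genomesPerPhylum),
    stringsAsFactors = FALSE)
  fams <- sprintf("fam%02d", seq_len(nFam))
  grid <- expand.grid(family_id = fams, genome_id = meta$genome_id,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < pHit
  hits <- grid[keep, ]
  hits$evalue <- 10^stats::runif(nrow(hits), -20, -4)
  nDecoy <- ceiling(pDecoy * nrow(hits))
  if (nDecoy > 0) {
    dec <- grid[sample(nrow(grid), nDecoy), ]
    dec$evalue <- 10^stats::runif(nDecoy, -2.9, 0.9)
    hits <- rbind(hits, dec)
  }
  list(hits = hits, meta = meta, families = fams)
}

# Small planted fixture shared by exactness tests: three DPANN-only modules
# of 25 families, occupancy 1, no noise, no background.
exactFixtureConfig <- function(seed = 5) {
  SimConfig(
    lineages = defaultLineages(),
    genomesPerLineage = 12,
    nBackgroundFamilies = 0,
    plantedModules = list(
      plantedModule(25, "Pacearchaeota"),
      plantedModule(25, "Woesearchaeota"),
      plantedModule(25, "Micrarchaeota")),
    flipNoise = 0,
    seed = seed)
}
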