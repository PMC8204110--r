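## Synthetic data with planted structure.
##
## Everything downstream (QC cascade, presence matrix, module detection,
## breadth) can be checked against the ground truth these generators return.
## One pseudo-random stream per output artifact, all derived from the single
## master seed, so adding an artifact never perturbs another.

.AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
         "T","V","W","Y")

.simStreams <- function(seed) {
  withr::with_seed(seed, sample.int(2147483646L, 12L))
}

.genomeIDs <- function(config) {
  lin <- config@lineages$name
  n <- config@genomesPerLineage
  ids <- unlist(lapply(lin, function(l) sprintf("%s_g%03d", l, seq_len(n))))
  meta <- data.frame(
    genome_id = ids,
    domain = rep(config@lineages$domain, each = n),
    phylum = rep(lin, each = n),
    is_dpann = rep(config@lineages$is_dpann, each = n),
    stringsAsFactors = FALSE)
  meta[lexOrder(meta$genome_id), , drop = FALSE]
}

## Carrier sets: modules that list the same carrier lineage take successive
## non-overlapping genome blocks of that lineage (wrapping around if the
## summed occupancies exceed 1). Planted modules with heavily overlapping
## carrier sets would be indistinguishable at any dendrogram cutoff, so a
## ground-truth generator must plant distinguishable blocks.
.carrierSets <- function(config, meta) {
  cursors <- stats::setNames(rep(0L, nrow(config@lineages)),
                             config@lineages$name)
  byLin <- split(meta$genome_id, meta$phylum)
  lapply(config@plantedModules, function(pm) {
    carr <- character()
    for (ln in pm$lineages) {
      pool <- lexSort(byLin[[ln]])
      L <- length(pool)
      k <- max(1L, as.integer(ceiling(pm$occupancy * L)))
      idx <- ((cursors[[ln]] + seq_len(k) - 1L) %% L) + 1L
      cursors[[ln]] <<- cursors[[ln]] + k
      carr <- c(carr, pool[idx])
    }
    lexSort(unique(carr))
  })
}

.drawEvalues <- function(n) 10^stats::runif(n, -30, -4)
.drawDecoyEvalues <- function(n) 10^stats::runif(n, log10(0.0011), 1)

.hitsFromMatrix <- function(P, evalueStream, decoyStream, decoyRate) {
  pres <- which(P, arr.ind = TRUE)
  hits <- data.frame(
    family_id = rownames(P)[pres[, 1L]],
    subfamily_id = NA_character_,
    genome_id = colnames(P)[pres[, 2L]],
    evalue = numeric(nrow(pres)),
    stringsAsFactors = FALSE)
  hits$evalue <- withr::with_seed(evalueStream, .drawEvalues(nrow(hits)))
  if (decoyRate > 0) {
    abs_idx <- which(!P, arr.ind = TRUE)
    dec <- withr::with_seed(decoyStream, {
      keep <- stats::runif(nrow(abs_idx)) < decoyRate
      data.frame(
        family_id = rownames(P)[abs_idx[keep, 1L]],
        subfamily_id = NA_character_,
        genome_id = colnames(P)[abs_idx[keep, 2L]],
        evalue = .drawDecoyEvalues(sum(keep)),
        stringsAsFactors = FALSE)
    })
    hits <- rbind(hits, dec)
  }
  hits[lexOrder(hits$family_id, hits$genome_id, hits$evalue), , drop = FALSE]
}

#' Simulate a genome collection with planted family modules
#'
#' Generates genome metadata, archaeal homology hit records, a bacterial
#' genome panel with hit records, and the ground-truth tables describing the
#' planted structure. Planted module families share one carrier-genome set
#' before noise; background families get independent Bernoulli presence;
#' every presence/absence cell is then toggled independently with probability
#' \code{flipNoise}. Present cells emit hit records with E-values log-uniform
#' in [1e-30, 1e-4]; a fraction \code{decoyRate} of absent cells emit decoy
#' records with E-values in (0.001, 10] to exercise threshold filtering.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return list with elements \code{genomes} (metadata table), \code{hits}
#'   (archaeal hit records), \code{bacterialMeta}, \code{bacterialHits}, and
#'   \code{truth}, itself a list of \code{modules} (planted module table),
#'   \code{families} (family to module map, bacterial-like flag),
#'   \code{carriers} (module to carrier-genome map).
#' @examples
#' cfg <- SimConfig(genomesPerLineage = 8, nBackgroundFamilies = 30,
#'                  plantedModules = list(plantedModule(20, "Pacearchaeota")),
#'                  flipNoise = 0, seed = 7)
#' sim <- simulateDataset(cfg)
#' head(sim$hits)
#' @export
simulateDataset <- function(config) {
  validObject(config)
  streams <- .simStreams(config@seed)
  meta <- .genomeIDs(config)
  nG <- nrow(meta)

  nMod <- length(config@plantedModules)
  modIDs <- sprintf("P%02d", seq_len(nMod))
  modSizes <- vapply(config@plantedModules, `[[`, integer(1), "size")
  famMod <- if (nMod) {
    unlist(lapply(seq_len(nMod), function(j)
      sprintf("fam_%s_%03d", modIDs[j], seq_len(modSizes[j]))))
  } else character()
  famBg <- if (config@nBackgroundFamilies > 0L) {
    sprintf("fam_bg%04d", seq_len(config@nBackgroundFamilies))
  } else character()
  fams <- c(famMod, famBg)

  carriers <- .carrierSets(config, meta)

  P <- matrix(FALSE, nrow = length(fams), ncol = nG,
              dimnames = list(fams, meta$genome_id))
  k <- 0L
  for (j in seq_len(nMod)) {
    P[k + seq_len(modSizes[j]), carriers[[j]]] <- TRUE
    k <- k + modSizes[j]
  }
  if (length(famBg)) {
    P[famBg, ] <- withr::with_seed(streams[1L], {
      pf <- if (length(config@backgroundProb) == 2L) {
        stats::runif(length(famBg), config@backgroundProb[1L],
                     config@backgroundProb[2L])
      } else rep(config@backgroundProb, length(famBg))
      matrix(stats::runif(length(famBg) * nG) < pf, nrow = length(famBg))
    })
  }
  if (config@flipNoise > 0) {
    flips <- withr::with_seed(streams[2L],
      matrix(stats::runif(length(P)) < config@flipNoise, nrow = nrow(P)))
    P <- xor(P, flips)
  }

  hits <- .hitsFromMatrix(P, streams[3L], streams[4L], config@decoyRate)

  bactLike <- withr::with_seed(streams[5L],
    stats::runif(length(fams)) < config@bacterialLikeFrac)
  names(bactLike) <- fams

  bphyla <- sprintf("BacPhylum%02d", seq_len(config@nBacterialPhyla))
  bactMeta <- data.frame(
    genome_id = unlist(lapply(bphyla, function(p)
      sprintf("%s_g%02d", p, seq_len(config@genomesPerPhylum)))),
    domain = "bacteria",
    phylum = rep(bphyla, each = config@genomesPerPhylum),
    stringsAsFactors = FALSE)
  probs <- ifelse(bactLike, config@hitProbBacterialLike, config@hitProbOther)
  B <- withr::with_seed(streams[6L],
    matrix(stats::runif(length(fams) * nrow(bactMeta)) < probs,
           nrow = length(fams),
           dimnames = list(fams, bactMeta$genome_id)))
  bpres <- which(B, arr.ind = TRUE)
  bactHits <- data.frame(
    family_id = rownames(B)[bpres[, 1L]],
    subfamily_id = NA_character_,
    genome_id = colnames(B)[bpres[, 2L]],
    evalue = withr::with_seed(streams[11L], .drawEvalues(nrow(bpres))),
    stringsAsFactors = FALSE)
  bactHits <- bactHits[lexOrder(bactHits$family_id, bactHits$genome_id), ,
                       drop = FALSE]

  truthModules <- data.frame(
    module_id = modIDs,
    size = modSizes,
    carrier_lineages = vapply(config@plantedModules, function(pm)
      paste(pm$lineages, collapse = ","), character(1)),
    occupancy = vapply(config@plantedModules, `[[`, numeric(1), "occupancy"),
    n_carriers = vapply(carriers, length, integer(1)),
    single_lineage = vapply(config@plantedModules, function(pm)
      length(pm$lineages) == 1L, logical(1)),
    stringsAsFactors = FALSE)
  truthFamilies <- data.frame(
    family_id = fams,
    module_id = c(rep(modIDs, modSizes), rep(NA_character_, length(famBg))),
    bacterial_like = unname(bactLike),
    stringsAsFactors = FALSE)
  truthCarriers <- if (nMod) {
    data.frame(
      module_id = rep(modIDs, vapply(carriers, length, integer(1))),
      genome_id = unlist(carriers),
      stringsAsFactors = FALSE)
  } else {
    data.frame(module_id = character(), genome_id = character(),
               stringsAsFactors = FALSE)
  }

  list(genomes = meta, hits = hits, bacterialMeta = bactMeta,
       bacterialHits = bactHits,
       truth = list(modules = truthModules, families = truthFamilies,
                    carriers = truthCarriers))
}

#' Simulate quality-control inputs with planted failures
#'
#' Generates, for the same genome set as \code{\link{simulateDataset}}, a
#' 38-single-copy-gene count table, a long-form pairwise ANI table, an
#' aligned amino-acid FASTA of the concatenated 14 ribosomal proteins, and a
#' ribosomal-protein-to-scaffold table. A configurable number of genomes is
#' planted to fail each rule of the filter cascade (low SCG completeness,
#' high SCG duplication, <50 percent alignment columns, ribosomal proteins
#' split over two scaffolds) and pairs of genomes are planted as
#' ANI-redundant; all plants are returned as truth.
#'
#' @param config a \code{\linkS4class{SimConfig}}; the \code{qcPlanted} slot
#'   sets how many genomes are planted to fail each rule.
#' @return list with \code{scg} (genome_id + 38 copy-number columns),
#'   \code{ani} (genome_a, genome_b, ani; one row per unordered pair),
#'   \code{alignment} (\code{Biostrings::AAStringSet}, equal widths),
#'   \code{rpScaffolds} (genome_id, protein_name, scaffold_id), and
#'   \code{truth} with per-genome planted-failure flags plus the planted
#'   \code{aniPairs}.
#' @export
simulateQCInputs <- function(config) {
  validObject(config)
  streams <- .simStreams(config@seed)
  meta <- .genomeIDs(config)
  ids <- meta$genome_id
  nG <- length(ids)
  qp <- config@qcPlanted
  nPlant <- sum(qp[c("low_completeness", "high_duplication", "low_alignment",
                     "split_scaffold")]) + 2L * qp[["ani_pairs"]]
  if (nPlant > nG) {
    stop("more planted QC failures (", nPlant, ") than genomes (", nG, ")")
  }
  planted <- withr::with_seed(streams[7L], sample(ids, nPlant))
  take <- function(n) {
    out <- planted[seq_len(n)]
    planted <<- planted[-seq_len(n)]
    out
  }
  gLowC <- take(qp[["low_completeness"]])
  gHighD <- take(qp[["high_duplication"]])
  gLowA <- take(qp[["low_alignment"]])
  gSplit <- take(qp[["split_scaffold"]])
  gANI <- take(2L * qp[["ani_pairs"]])

  scg <- withr::with_seed(streams[8L], {
    m <- matrix(0L, nrow = nG, ncol = 38L,
                dimnames = list(ids, sprintf("scg%02d", 1:38)))
    for (g in ids) {
      nPres <- if (g %in% gLowC) sample(15:20, 1L) else sample(30:38, 1L)
      pres <- sample(38L, nPres)
      m[g, pres] <- 1L
      nDup <- if (g %in% gHighD) sample(4:7, 1L) else sample(0:2, 1L)
      nDup <- min(nDup, nPres)
      if (nDup > 0L) m[g, sample(pres, nDup)] <- 2L
    }
    m
  })
  scgTable <- data.frame(genome_id = ids, scg, stringsAsFactors = FALSE,
                         row.names = NULL, check.names = FALSE)

  alnWidth <- 400L
  alignment <- withr::with_seed(streams[9L], {
    rows <- vapply(ids, function(g) {
      nGap <- if (g %in% gLowA) sample(220:280, 1L) else sample(8:80, 1L)
      chars <- sample(.AA, alnWidth, replace = TRUE)
      chars[sample(alnWidth, nGap)] <- "-"
      paste(chars, collapse = "")
    }, character(1))
    Biostrings::AAStringSet(rows)
  })

  rpNames <- c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15",
               "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS17", "rpS19")
  rpScaffolds <- do.call(rbind, lapply(ids, function(g) {
    scf <- rep(paste0(g, "_scf1"), 14L)
    if (g %in% gSplit) scf[8:14] <- paste0(g, "_scf2")
    data.frame(genome_id = g, protein_name = rpNames, scaffold_id = scf,
               stringsAsFactors = FALSE)
  }))

  pairIdx <- which(upper.tri(matrix(0, nG, nG)), arr.ind = TRUE)
  aniPairsPlanted <- if (length(gANI)) {
    data.frame(genome_a = pmin(gANI[c(TRUE, FALSE)], gANI[c(FALSE, TRUE)]),
               genome_b = pmax(gANI[c(TRUE, FALSE)], gANI[c(FALSE, TRUE)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(genome_a = character(), genome_b = character(),
               stringsAsFactors = FALSE)
  }
  ani <- withr::with_seed(streams[10L], {
    df <- data.frame(genome_a = ids[pairIdx[, 1L]],
                     genome_b = ids[pairIdx[, 2L]],
                     ani = stats::runif(nrow(pairIdx), 70, 85),
                     stringsAsFactors = FALSE)
    key <- paste(pmin(df$genome_a, df$genome_b),
                 pmax(df$genome_a, df$genome_b))
    pkey <- paste(aniPairsPlanted$genome_a, aniPairsPlanted$genome_b)
    df$ani[key %in% pkey] <- stats::runif(sum(key %in% pkey), 96, 99)
    df
  })
  ani <- ani[lexOrder(ani$genome_a, ani$genome_b), , drop = FALSE]

  truth <- data.frame(
    genome_id = ids,
    planted_fail_completeness = ids %in% gLowC,
    planted_fail_duplication = ids %in% gHighD,
    planted_fail_alignment = ids %in% gLowA,
    planted_fail_scaffold = ids %in% gSplit,
    planted_ani_redundant = ids %in% gANI,
    stringsAsFactors = FALSE)

  list(scg = scgTable, ani = ani, alignment = alignment,
       rpScaffolds = rpScaffolds,
       truth = list(genomes = truth, aniPairs = aniPairsPlanted))
}

#' Write simulated inputs to a directory in the pipeline's on-disk formats
#'
#' Tables are written as tab-separated files with headers, the alignment as
#' aligned FASTA, truth tables alongside (prefixed \code{truth_}).
#'
#' @param dataset result of \code{\link{simulateDataset}}.
#' @param qc result of \code{\link{simulateQCInputs}} (optional).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulatedInputs <- function(dataset, qc = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    meta = writeTSVAtomic(dataset$genomes, p("meta.tsv")),
    hits = writeTSVAtomic(dataset$hits, p("hits.tsv")),
    bacterial_meta = writeTSVAtomic(dataset$bacterialMeta, p("bacterial_meta.tsv")),
    bacterial_hits = writeTSVAtomic(dataset$bacterialHits, p("bacterial_hits.tsv")),
    truth_modules = writeTSVAtomic(dataset$truth$modules, p("truth_modules.tsv")),
    truth_families = writeTSVAtomic(dataset$truth$families, p("truth_families.tsv")),
    truth_carriers = writeTSVAtomic(dataset$truth$carriers, p("truth_carriers.tsv")))
  if (!is.null(qc)) {
    Biostrings::writeXStringSet(qc$alignment, p("alignment.fasta"))
    paths <- c(paths,
      scg = writeTSVAtomic(qc$scg, p("scg.tsv")),
      ani = writeTSVAtomic(qc$ani, p("ani.tsv")),
      alignment = p("alignment.fasta"),
      rp_scaffolds = writeTSVAtomic(qc$rpScaffolds, p("rp_scaffolds.tsv")),
      truth_qc = writeTSVAtomic(qc$truth$genomes, p("truth_qc.tsv")),
      truth_ani_pairs = writeTSVAtomic(qc$truth$aniPairs, p("truth_ani_pairs.tsv")))
  }
  invisible(paths)
}
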