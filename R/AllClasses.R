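#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration for the synthetic dataset generator
#'
#' Describes a simulated genome collection with planted modules of
#' co-occurring protein families, background families with independent
#' Bernoulli presence, symmetric flip noise, a bacterial genome panel for the
#' breadth screen, and planted quality-control failures.
#'
#' @slot lineages data.frame with columns \code{name}, \code{is_dpann},
#'   \code{domain}; one row per archaeal lineage.
#' @slot genomesPerLineage integer, genomes simulated per lineage.
#' @slot nBackgroundFamilies integer, number of unplanted families.
#' @slot backgroundProb numeric of length 1 or 2; per-family presence
#'   probability for background families (length 2 = uniform range).
#' @slot plantedModules list of planted modules, each created by
#'   \code{\link{plantedModule}}.
#' @slot flipNoise numeric in [0,1]; independent probability of toggling any
#'   presence/absence cell.
#' @slot nBacterialPhyla,genomesPerPhylum integer, bacterial panel dimensions.
#' @slot bacterialLikeFrac numeric, fraction of families flagged
#'   bacterial-like (high incidence across bacterial phyla).
#' @slot hitProbBacterialLike,hitProbOther numeric, per-genome hit
#'   probability in the bacterial panel for the two family classes.
#' @slot decoyRate numeric, fraction of absent cells that still emit a hit
#'   record with E-value above the reporting threshold (exercises threshold
#'   filtering downstream).
#' @slot qcPlanted named integer vector with elements
#'   \code{low_completeness}, \code{high_duplication}, \code{low_alignment},
#'   \code{split_scaffold}, \code{ani_pairs}: how many genomes (or genome
#'   pairs) are planted to fail each quality-control rule.
#' @slot seed integer master seed; one derived stream per output artifact.
#' @seealso \code{\link{SimConfig}}, \code{\link{simulateDataset}},
#'   \code{\link{simulateQCInputs}}
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    lineages = "data.frame",
    genomesPerLineage = "integer",
    nBackgroundFamilies = "integer",
    backgroundProb = "numeric",
    plantedModules = "list",
    flipNoise = "numeric",
    nBacterialPhyla = "integer",
    genomesPerPhylum = "integer",
    bacterialLikeFrac = "numeric",
    hitProbBacterialLike = "numeric",
    hitProbOther = "numeric",
    decoyRate = "numeric",
    qcPlanted = "integer",
    seed = "integer"
  )
)

.validSimConfig <- function(object) {
  msg <- character()
  lin <- object@lineages
  if (!all(c("name", "is_dpann", "domain") %in% colnames(lin)) ||
      nrow(lin) < 1L) {
    msg <- c(msg, "lineages must have >=1 row and columns name, is_dpann, domain")
  } else if (anyDuplicated(lin$name)) {
    msg <- c(msg, "lineage names must be unique")
  }
  probs <- c(object@backgroundProb, object@flipNoise, object@bacterialLikeFrac,
             object@hitProbBacterialLike, object@hitProbOther, object@decoyRate)
  if (any(probs < 0 | probs > 1)) {
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  }
  if (!(length(object@backgroundProb) %in% 1:2)) {
    msg <- c(msg, "backgroundProb must have length 1 (scalar) or 2 (range)")
  }
  if (object@genomesPerLineage < 1L || object@nBacterialPhyla < 1L ||
      object@genomesPerPhylum < 1L) {
    msg <- c(msg, "genome and phylum counts must be >= 1")
  }
  if (object@nBackgroundFamilies < 0L) {
    msg <- c(msg, "nBackgroundFamilies must be >= 0")
  }
  for (pm in object@plantedModules) {
    if (!is.list(pm) || !all(c("size", "lineages", "occupancy") %in% names(pm))) {
      msg <- c(msg, "each planted module needs fields size, lineages, occupancy")
      next
    }
    if (pm$size < 20L) {
      msg <- c(msg, sprintf(
        "planted module size %d rejected: modules are blocks of at least 20 co-occurring families",
        pm$size))
    }
    if (pm$occupancy < 0 || pm$occupancy > 1) {
      msg <- c(msg, "carrier occupancy must lie in [0, 1]")
    }
    if (!all(pm$lineages %in% lin$name)) {
      msg <- c(msg, paste0("unknown carrier lineage(s): ",
                           paste(setdiff(pm$lineages, lin$name), collapse = ", ")))
    }
  }
  need <- c("low_completeness", "high_duplication", "low_alignment",
            "split_scaffold", "ani_pairs")
  if (!all(need %in% names(object@qcPlanted)) || any(object@qcPlanted < 0L)) {
    msg <- c(msg, paste0("qcPlanted must be a non-negative integer vector with names ",
                         paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("SimConfig", .validSimConfig)

#' Describe one planted module
#'
#' @param size number of families in the module (>= 20).
#' @param lineages character vector of carrier lineage names.
#' @param occupancy fraction of each carrier lineage's genomes that carry the
#'   module.
#' @return a list usable in the \code{plantedModules} slot of
#'   \code{\link{SimConfig}}.
#' @export
plantedModule <- function(size, lineages, occupancy = 1) {
  list(size = as.integer(size), lineages = as.character(lineages),
       occupancy = as.numeric(occupancy))
}

#' Construct a synthetic-data configuration
#'
#' Defaults describe the package's reference benchmark: 6 archaeal lineages
#' (4 DPANN, 2 non-DPANN) of 50 genomes each, 1,500 background families,
#' 12 planted modules with sizes from 20 to 60 (two per lineage, each
#' occupying half the lineage), flip noise 0.05, and an 8-phylum bacterial
#' panel of 6 genomes per phylum.
#'
#' @param lineages data.frame(name, is_dpann, domain).
#' @param genomesPerLineage,nBackgroundFamilies,nBacterialPhyla,genomesPerPhylum
#'   integer counts.
#' @param backgroundProb scalar presence probability for background families,
#'   or a length-2 range sampled uniformly per family.
#' @param plantedModules list of \code{\link{plantedModule}} entries.
#' @param flipNoise independent per-cell toggle probability in [0,1].
#' @param bacterialLikeFrac fraction of families with high bacterial incidence.
#' @param hitProbBacterialLike,hitProbOther per-genome bacterial hit
#'   probabilities for the two family classes.
#' @param decoyRate fraction of absent cells emitting an above-threshold hit.
#' @param qcPlanted named integer vector of planted QC-failure counts.
#' @param seed integer master seed.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- SimConfig(genomesPerLineage = 10, nBackgroundFamilies = 50,
#'                  plantedModules = list(plantedModule(20, "Pacearchaeota")),
#'                  seed = 1)
#' @export
SimConfig <- function(lineages = defaultLineages(),
                      genomesPerLineage = 50L,
                      nBackgroundFamilies = 1500L,
                      backgroundProb = 0.1,
                      plantedModules = defaultPlantedModules(lineages),
                      flipNoise = 0.05,
                      nBacterialPhyla = 8L,
                      genomesPerPhylum = 6L,
                      bacterialLikeFrac = 0.1,
                      hitProbBacterialLike = 0.6,
                      hitProbOther = 0.02,
                      decoyRate = 0.01,
                      qcPlanted = c(low_completeness = 2L, high_duplication = 2L,
                                    low_alignment = 2L, split_scaffold = 2L,
                                    ani_pairs = 2L),
                      seed = 1L) {
  new("SimConfig",
      lineages = as.data.frame(lineages, stringsAsFactors = FALSE),
      genomesPerLineage = as.integer(genomesPerLineage),
      nBackgroundFamilies = as.integer(nBackgroundFamilies),
      backgroundProb = as.numeric(backgroundProb),
      plantedModules = plantedModules,
      flipNoise = as.numeric(flipNoise),
      nBacterialPhyla = as.integer(nBacterialPhyla),
      genomesPerPhylum = as.integer(genomesPerPhylum),
      bacterialLikeFrac = as.numeric(bacterialLikeFrac),
      hitProbBacterialLike = as.numeric(hitProbBacterialLike),
      hitProbOther = as.numeric(hitProbOther),
      decoyRate = as.numeric(decoyRate),
      qcPlanted = vapply(qcPlanted, as.integer, integer(1)),
      seed = as.integer(seed))
}

#' Default archaeal lineage panel (4 DPANN, 2 non-DPANN)
#' @return data.frame(name, is_dpann, domain)
#' @export
defaultLineages <- function() {
  data.frame(
    name = c("Pacearchaeota", "Woesearchaeota", "Micrarchaeota",
             "Nanoarchaeota", "Euryarchaeota", "Crenarchaeota"),
    is_dpann = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    domain = "archaea",
    stringsAsFactors = FALSE)
}

#' Default planted modules: two per lineage, sizes spanning 20 to 60, each
#' occupying half of its carrier lineage (successive modules in a lineage get
#' non-overlapping genome blocks, so every planted module is recoverable).
#' @param lineages lineage table as in \code{\link{defaultLineages}}.
#' @return list of \code{\link{plantedModule}} entries.
#' @export
defaultPlantedModules <- function(lineages = defaultLineages()) {
  sizes <- as.integer(round(seq(20, 60, length.out = 2L * nrow(lineages))))
  mapply(function(sz, lin) plantedModule(sz, lin, occupancy = 0.5),
         sizes, rep(lineages$name, each = 2L), SIMPLIFY = FALSE)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      nrow(object@lineages), "lineages x", object@genomesPerLineage,
      "genomes;", length(object@plantedModules), "planted modules;",
      object@nBackgroundFamilies, "background families; flip noise",
      object@flipNoise, "; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## PresenceMatrix
## ---------------------------------------------------------------------------

#' Family-by-genome presence/absence matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay, \code{presence},
#' is a logical matrix with protein families as rows and genomes as columns.
#' Genome metadata (domain, phylum, DPANN flag) lives in \code{colData}; the
#' E-value threshold used to call presence is recorded in
#' \code{metadata(x)$evalue_threshold}.
#'
#' @seealso \code{\link{buildPresenceMatrix}}, \code{\link{jaccardDistance}}
#' @exportClass PresenceMatrix
setClass("PresenceMatrix", contains = "SummarizedExperiment")

.validPresenceMatrix <- function(object) {
  msg <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (!identical(anames, "presence")) {
    msg <- c(msg, "PresenceMatrix must have exactly one assay named 'presence'")
  } else {
    m <- SummarizedExperiment::assay(object, "presence")
    if (!is.logical(m)) msg <- c(msg, "presence assay must be logical")
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m)))) {
      msg <- c(msg, "presence assay needs family row names and genome column names")
    } else {
      if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate family ids")
      if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate genome ids")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("PresenceMatrix", .validPresenceMatrix)

#' Construct a PresenceMatrix from a logical matrix
#'
#' @param presence logical matrix (families x genomes) with dimnames.
#' @param genomes optional data.frame of genome metadata with a
#'   \code{genome_id} column; matched to the matrix columns.
#' @param threshold E-value threshold recorded as provenance.
#' @return a \code{\linkS4class{PresenceMatrix}}.
#' @export
PresenceMatrix <- function(presence, genomes = NULL, threshold = NA_real_) {
  storage.mode(presence) <- "logical"
  cd <- S4Vectors::DataFrame(row.names = colnames(presence))
  if (!is.null(genomes)) {
    stopIfMissingCols(genomes, "genome_id", "genome metadata")
    idx <- match(colnames(presence), genomes$genome_id)
    if (anyNA(idx)) {
      stop("genomes absent from metadata: ",
           paste(colnames(presence)[is.na(idx)], collapse = ", "))
    }
    cd <- S4Vectors::DataFrame(genomes[idx, setdiff(colnames(genomes), "genome_id"),
                                       drop = FALSE],
                               row.names = colnames(presence))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = presence), colData = cd)
  S4Vectors::metadata(se)$evalue_threshold <- threshold
  new("PresenceMatrix", se)
}

setMethod("show", "PresenceMatrix", function(object) {
  m <- SummarizedExperiment::assay(object, "presence")
  cat("PresenceMatrix:", nrow(m), "families x", ncol(m), "genomes;",
      sum(m), "present cells; E-value threshold",
      S4Vectors::metadata(object)$evalue_threshold, "\n")
})

## ---------------------------------------------------------------------------
## ModuleSet
## ---------------------------------------------------------------------------

#' A set of detected modules of co-occurring protein families
#'
#' Produced by \code{\link{detectModules}} (or step-wise by
#' \code{\link{clusterFamilies}} then \code{\link{extractModules}}).
#' Module family sets are disjoint by construction (a dendrogram cut is a
#' partition); clusters below the minimum size are kept in
#' \code{moduleResiduals}.
#'
#' @slot families named list of character vectors (family ids per module).
#' @slot table data.frame of per-module statistics (size, median-rule genome
#'   count m, retained genomes, taxon distribution, assigned lineage,
#'   prevalences, occurrence and enrichment flags).
#' @slot residuals named list of clusters smaller than the minimum size.
#' @slot retained named list of retained (top-carrying) genomes per module.
#' @slot tree the family dendrogram (\code{hclust}) or NULL.
#' @slot params list of the parameters used (linkage, cutoff, minSize, ...).
#' @exportClass ModuleSet
setClass("ModuleSet",
  representation(families = "list", table = "data.frame", residuals = "list",
                 retained = "list", tree = "ANY", params = "list"))

.validModuleSet <- function(object) {
  fams <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(fams)) {
    return("module family sets must be disjoint")
  }
  if (nrow(object@table) != length(object@families)) {
    return("table must have one row per module")
  }
  TRUE
}

setValidity("ModuleSet", .validModuleSet)

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet:", length(object@families), "modules (",
      length(unlist(object@families)), "families );",
      length(object@residuals), "residual clusters\n")
  if (nrow(object@table)) {
    print(utils::head(object@table, 5))
    if (nrow(object@table) > 5) cat("...\n")
  }
})

setMethod("length", "ModuleSet", function(x) length(x@families))
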