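## Configured, logged, reproducible pipeline: qc -> matrix -> modules ->
## breadth, with per-stage TSV outputs and a run manifest. The analysis path
## is fully deterministic; randomness is confined to the simulators.

#' Pipeline configuration
#'
#' Paths of all input tables plus every threshold of the analysis. The
#' config round-trips losslessly through a flat \code{key: value} text file
#' (\code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}).
#'
#' @slot inputs named character vector of input paths (\code{meta},
#'   \code{hits}, \code{scg}, \code{ani}, \code{alignment},
#'   \code{rp_scaffolds}; optional \code{subfamily_map},
#'   \code{bacterial_hits}, \code{bacterial_meta} may be empty strings).
#' @slot outdir output directory.
#' @slot evalue E-value cutoff (default 0.001).
#' @slot cutoff dendrogram cut height (default 0.95).
#' @slot minModuleSize minimum families per module (default 20).
#' @slot linkage linkage method for the family dendrogram.
#' @slot aniThreshold dereplication ANI percent (default 95).
#' @slot minCompleteness,maxContamination results-filter percents (70, 10).
#' @slot minAlnCoverage minimum ribosomal-protein alignment coverage (0.5).
#' @slot breadthFraction minimum per-phylum hit fraction for breadth (1/3).
#' @slot seed integer (recorded for provenance; the analysis itself is
#'   deterministic).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(inputs = "character", outdir = "character",
                 evalue = "numeric", cutoff = "numeric",
                 minModuleSize = "integer", linkage = "character",
                 aniThreshold = "numeric", minCompleteness = "numeric",
                 maxContamination = "numeric", minAlnCoverage = "numeric",
                 breadthFraction = "numeric", seed = "integer"))

.validPipelineConfig <- function(object) {
  msg <- character()
  need <- c("meta", "hits", "scg", "ani", "alignment", "rp_scaffolds")
  if (!all(need %in% names(object@inputs))) {
    msg <- c(msg, paste0("inputs must name ", paste(need, collapse = ", ")))
  }
  if (object@evalue <= 0) msg <- c(msg, "evalue must be positive")
  if (object@cutoff < 0 || object@cutoff > 1) {
    msg <- c(msg, "cutoff must lie in [0, 1] (Jaccard scale)")
  }
  if (object@minModuleSize < 1L) msg <- c(msg, "minModuleSize must be >= 1")
  if (!object@linkage %in% c("complete", "average")) {
    msg <- c(msg, "linkage must be 'complete' or 'average'")
  }
  if (object@aniThreshold < 0 || object@aniThreshold > 100) {
    msg <- c(msg, "aniThreshold must lie in [0, 100]")
  }
  if (object@minAlnCoverage < 0 || object@minAlnCoverage > 1) {
    msg <- c(msg, "minAlnCoverage must lie in [0, 1]")
  }
  if (object@breadthFraction < 0 || object@breadthFraction > 1) {
    msg <- c(msg, "breadthFraction must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
}

setValidity("PipelineConfig", .validPipelineConfig)

#' Construct a pipeline configuration
#' @param inputs named character vector of input paths; see
#'   \code{\linkS4class{PipelineConfig}}.
#' @param outdir output directory.
#' @param evalue,cutoff,minModuleSize,linkage,aniThreshold,minCompleteness
#'   thresholds; defaults as documented in the class.
#' @param maxContamination,minAlnCoverage,breadthFraction,seed more of same.
#' @return a validated \code{PipelineConfig}.
#' @export
pipelineConfig <- function(inputs, outdir, evalue = 0.001, cutoff = 0.95,
                           minModuleSize = 20L, linkage = "complete",
                           aniThreshold = 95, minCompleteness = 70,
                           maxContamination = 10, minAlnCoverage = 0.5,
                           breadthFraction = 1 / 3, seed = 1L) {
  new("PipelineConfig", inputs = inputs, outdir = outdir,
      evalue = as.numeric(evalue), cutoff = as.numeric(cutoff),
      minModuleSize = as.integer(minModuleSize), linkage = linkage,
      aniThreshold = as.numeric(aniThreshold),
      minCompleteness = as.numeric(minCompleteness),
      maxContamination = as.numeric(maxContamination),
      minAlnCoverage = as.numeric(minAlnCoverage),
      breadthFraction = as.numeric(breadthFraction), seed = as.integer(seed))
}

.configLines <- function(cfg) {
  num <- function(x) sprintf("%.17g", x)
  c(sprintf("input.%s: %s", names(cfg@inputs), cfg@inputs),
    paste0("outdir: ", cfg@outdir),
    paste0("evalue: ", num(cfg@evalue)),
    paste0("cutoff: ", num(cfg@cutoff)),
    paste0("min_module_size: ", cfg@minModuleSize),
    paste0("linkage: ", cfg@linkage),
    paste0("ani_threshold: ", num(cfg@aniThreshold)),
    paste0("min_completeness: ", num(cfg@minCompleteness)),
    paste0("max_contamination: ", num(cfg@maxContamination)),
    paste0("min_aln_coverage: ", num(cfg@minAlnCoverage)),
    paste0("breadth_fraction: ", num(cfg@breadthFraction)),
    paste0("seed: ", cfg@seed))
}

#' Write a pipeline configuration as a flat key: value file
#' @param cfg a \code{\linkS4class{PipelineConfig}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  writeLines(.configLines(cfg), path)
  invisible(path)
}

#' Read a pipeline configuration written by \code{\link{writePipelineConfig}}
#' @param path config file path.
#' @return a \code{\linkS4class{PipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(":", lines, fixed = TRUE), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  isInput <- startsWith(keys, "input.")
  inputs <- stats::setNames(vals[isInput], sub("^input\\.", "", keys[isInput]))
  pipelineConfig(
    inputs = inputs,
    outdir = get("outdir", "."),
    evalue = as.numeric(get("evalue", "0.001")),
    cutoff = as.numeric(get("cutoff", "0.95")),
    minModuleSize = as.integer(get("min_module_size", "20")),
    linkage = get("linkage", "complete"),
    aniThreshold = as.numeric(get("ani_threshold", "95")),
    minCompleteness = as.numeric(get("min_completeness", "70")),
    maxContamination = as.numeric(get("max_contamination", "10")),
    minAlnCoverage = as.numeric(get("min_aln_coverage", "0.5")),
    breadthFraction = as.numeric(get("breadth_fraction",
                                     sprintf("%.17g", 1 / 3))),
    seed = as.integer(get("seed", "1")))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(paste0("  ", .configLines(object)), sep = "\n")
})

#' Summarize a module set the way a comparative survey reports it
#'
#' Three headline statistics: modules occurring in at least one DPANN genome
#' (with their total family count), modules more common in DPANN than in
#' non-DPANN archaea (with family count), and enriched modules taxonomically
#' assigned to a single DPANN lineage.
#'
#' @param ms a fully annotated \code{\linkS4class{ModuleSet}} (after
#'   \code{\link{detectModules}}).
#' @return one-row data.frame: \code{modules_in_dpann},
#'   \code{families_in_dpann}, \code{modules_enriched},
#'   \code{families_enriched}, \code{modules_single_dpann_lineage}.
#' @export
summarizeModules <- function(ms) {
  tab <- moduleTable(ms)
  if (!nrow(tab)) {
    return(data.frame(modules_in_dpann = 0L, families_in_dpann = 0L,
                      modules_enriched = 0L, families_enriched = 0L,
                      modules_single_dpann_lineage = 0L))
  }
  occ <- tab$occurs_in_dpann %in% TRUE
  enr <- tab$enriched %in% TRUE
  sing <- enr & tab$assigned_dpann_lineage %in% TRUE
  data.frame(
    modules_in_dpann = sum(occ),
    families_in_dpann = sum(tab$size[occ]),
    modules_enriched = sum(enr),
    families_enriched = sum(tab$size[enr]),
    modules_single_dpann_lineage = sum(sing))
}

.readGenomeMeta <- function(path) {
  meta <- readTSV(path)
  stopIfMissingCols(meta, "genome_id", "genome metadata")
  if ("is_dpann" %in% colnames(meta)) {
    meta$is_dpann <- as.logical(meta$is_dpann)
  }
  meta
}

#' Run the full pipeline: QC, presence matrix, modules, breadth
#'
#' Executes the stages in order, writing per-stage TSVs, the genome
#' dendrogram (Newick), a module summary and a run manifest into the
#' configured output directory. All outputs are written atomically
#' (temporary \code{.partial} file, then rename); the manifest records the
#' config hash, input checksums and per-stage counts, and contains no
#' timestamps or absolute paths, so identical inputs give byte-identical
#' outputs. Stage errors propagate with the stage name.
#'
#' @param cfg a \code{\linkS4class{PipelineConfig}}.
#' @param verbose emit progress to stderr.
#' @return invisibly, a list with the QC report, the
#'   \code{\linkS4class{PresenceMatrix}}, the
#'   \code{\linkS4class{ModuleSet}}, the module summary, the breadth report
#'   (or NULL) and the manifest data.frame.
#' @export
runPipeline <- function(cfg, verbose = TRUE) {
  validObject(cfg)
  say <- function(...) if (verbose) logMsg("INFO", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  inp <- cfg@inputs
  required <- c("meta", "hits", "scg", "ani", "alignment", "rp_scaffolds")
  for (k in required) {
    if (!file.exists(inp[[k]])) {
      stop("stage 'inputs' failed: missing input file '", k, "': ", inp[[k]])
    }
  }
  dir.create(cfg@outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg@outdir, f)

  say("stage qc: filter cascade and dereplication")
  meta <- .readGenomeMeta(inp[["meta"]])
  qcReport <- stage("qc", {
    scg <- readTSV(inp[["scg"]])
    ani <- readTSV(inp[["ani"]])
    rp <- readTSV(inp[["rp_scaffolds"]])
    runGenomeQC(scg, ani, inp[["alignment"]], rp,
                aniThreshold = cfg@aniThreshold,
                minCompleteness = cfg@minCompleteness,
                maxContamination = cfg@maxContamination,
                minAlnCoverage = cfg@minAlnCoverage)
  })
  writeTSVAtomic(qcReport, out("qc_report.tsv"))
  survivors <- qcReport$genome_id[qcReport$final_pass]
  say("qc: ", nrow(qcReport), " genomes in, ", length(survivors), " surviving")

  say("stage matrix: presence/absence construction")
  pm <- stage("matrix", {
    hits <- readTSV(inp[["hits"]])
    subMap <- if (!is.na(inp["subfamily_map"]) &&
                  nzchar(inp["subfamily_map"])) {
      readTSV(inp[["subfamily_map"]])
    } else NULL
    keep <- meta[meta$genome_id %in% survivors, , drop = FALSE]
    hits <- hits[hits$genome_id %in% survivors, , drop = FALSE]
    buildPresenceMatrix(hits, keep, threshold = cfg@evalue,
                        subfamilyMap = subMap)
  })
  writePresenceMatrix(pm, out("presence_matrix.tsv"))
  say("matrix: ", nrow(pm), " families x ", ncol(pm), " genomes")

  say("stage modules: clustering, extraction, taxonomy, enrichment")
  ms <- stage("modules", {
    detectModules(pm, linkage = cfg@linkage, cutoff = cfg@cutoff,
                  minSize = cfg@minModuleSize)
  })
  writeTSVAtomic(moduleTable(ms), out("modules.tsv"))
  writeTSVAtomic(familyModuleMap(ms), out("family_modules.tsv"))
  resid <- moduleResiduals(ms)
  writeTSVAtomic(
    data.frame(cluster_id = rep(names(resid),
                                vapply(resid, length, integer(1))),
               family_id = unlist(resid, use.names = FALSE),
               stringsAsFactors = FALSE),
    out("residual_clusters.tsv"))
  summary <- summarizeModules(ms)
  writeTSVAtomic(summary, out("summary.tsv"))
  gclust <- NULL
  if (ncol(pm) >= 2L) {
    gclust <- stage("modules", clusterGenomes(pm, linkage = cfg@linkage))
    writeLines(gclust$newick, out("genome_dendrogram.nwk.partial"))
    file.rename(out("genome_dendrogram.nwk.partial"),
                out("genome_dendrogram.nwk"))
    om <- gclust$matrix
    writeTSVAtomic(data.frame(family_id = rownames(om), om * 1L,
                              check.names = FALSE),
                   out("ordered_matrix.tsv"))
  }
  say("modules: ", length(ms), " modules, ",
      length(moduleResiduals(ms)), " residual clusters")

  breadthTab <- NULL
  if (!is.na(inp["bacterial_hits"]) && nzchar(inp["bacterial_hits"])) {
    say("stage breadth: cross-domain incidence")
    breadthTab <- stage("breadth", {
      bhits <- readTSV(inp[["bacterial_hits"]])
      bmeta <- readTSV(inp[["bacterial_meta"]])
      inc <- perPhylumIncidence(bhits, bmeta, threshold = cfg@evalue,
                                families = familyIDs(pm))
      prof <- computeBreadth(inc, minFraction = cfg@breadthFraction)
      sizes <- stats::setNames(rowSums(presence(pm)), familyIDs(pm))
      breadthReport(prof, sizes)
    })
    writeTSVAtomic(breadthTab, out("breadth.tsv"))
    say("breadth: ", sum(breadthTab$has_bacterial_hit),
        " families with a bacterial hit")
  }

  manifest <- stage("manifest", {
    inFiles <- inp[nzchar(inp) & !is.na(inp)]
    sums <- tools::md5sum(inFiles)
    counts <- c(
      genomes_in = nrow(qcReport),
      genomes_final = length(survivors),
      ani_clusters = length(unique(qcReport$cluster_id)),
      families = nrow(pm),
      modules = length(ms),
      residual_clusters = length(moduleResiduals(ms)),
      modules_in_dpann = summary$modules_in_dpann,
      families_in_dpann = summary$families_in_dpann,
      modules_enriched = summary$modules_enriched,
      families_enriched = summary$families_enriched,
      modules_single_dpann_lineage = summary$modules_single_dpann_lineage,
      families_with_bacterial_hit = if (is.null(breadthTab)) 0L else
        sum(breadthTab$has_bacterial_hit))
    df <- rbind(
      ## hash the analysis parameters only: where results land (outdir) and
      ## where inputs live (paths) do not affect the computation, and the
      ## input *contents* are checksummed separately below
      data.frame(key = "config_md5",
                 value = md5String(paste(
                   grep("^(input\\.|outdir)", .configLines(cfg),
                        value = TRUE, invert = TRUE), collapse = "\n")),
                 stringsAsFactors = FALSE),
      data.frame(key = paste0("md5.", names(inFiles)),
                 value = unname(sums), stringsAsFactors = FALSE),
      data.frame(key = paste0("count.", names(counts)),
                 value = as.character(counts), stringsAsFactors = FALSE))
    df[lexOrder(df$key), , drop = FALSE]
  })
  writeTSVAtomic(manifest, out("manifest.tsv"))
  say("done")

  invisible(list(qc = qcReport, matrix = pm, modules = ms,
                 summary = summary, breadth = breadthTab,
                 manifest = manifest))
}
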