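## Genome quality control: single-copy-gene completeness/contamination, the
## draft-quality rule, the results-level percent filters, ribosomal-protein
## alignment coverage, and ANI-threshold dereplication.

#' Estimate completeness and contamination from 38 single-copy genes
#'
#' Completeness is the percentage of the 38 marker genes present at least
#' once; contamination is the percentage of extra (duplicated) copies
#' relative to the marker set.
#'
#' @param scg data.frame with a \code{genome_id} column followed by exactly
#'   38 non-negative integer copy-number columns, or a genome-by-38 numeric
#'   matrix with genome row names.
#' @return data.frame with columns \code{genome_id}, \code{n_scgs_present}
#'   (copy >= 1), \code{n_scgs_duplicated} (copy >= 2), \code{completeness}
#'   (= 100 * n_scgs_present / 38) and \code{contamination}
#'   (= 100 * (total copies - n_scgs_present) / 38).
#' @examples
#' m <- matrix(1, 1, 38, dimnames = list("g1", sprintf("scg%02d", 1:38)))
#' estimateCompleteness(m)  # completeness 100, contamination 0
#' @export
estimateCompleteness <- function(scg) {
  if (is.data.frame(scg)) {
    stopIfMissingCols(scg, "genome_id", "SCG table")
    ids <- scg$genome_id
    m <- as.matrix(scg[, setdiff(colnames(scg), "genome_id"), drop = FALSE])
  } else {
    m <- as.matrix(scg)
    ids <- rownames(m)
  }
  if (ncol(m) != 38L) {
    stop("SCG table must have exactly 38 marker columns, found ", ncol(m))
  }
  if (!is.numeric(m) || any(m < 0)) {
    stop("SCG copy numbers must be non-negative numbers")
  }
  nPresent <- rowSums(m >= 1)
  nDup <- rowSums(m >= 2)
  data.frame(
    genome_id = ids,
    n_scgs_present = as.integer(nPresent),
    n_scgs_duplicated = as.integer(nDup),
    completeness = 100 * nPresent / 38,
    contamination = 100 * (rowSums(m) - nPresent) / 38,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Draft-quality genome filter
#'
#' A genome passes if it has more than 22 of the 38 single-copy genes and
#' fewer than 4 duplicated copies; both bounds are strict.
#'
#' @param meta data.frame with columns \code{genome_id},
#'   \code{n_scgs_present}, \code{n_scgs_duplicated} (as produced by
#'   \code{\link{estimateCompleteness}}).
#' @return data.frame(genome_id, pass, reason); \code{reason} names the
#'   violated rule(s), comma-separated, empty when passing.
#' @export
draftQualityFilter <- function(meta) {
  stopIfMissingCols(meta, c("genome_id", "n_scgs_present", "n_scgs_duplicated"),
                    "genome metadata")
  okCount <- meta$n_scgs_present > 22L
  okDup <- meta$n_scgs_duplicated < 4L
  reason <- mapply(function(a, b) {
    paste(c(if (!a) "scg-count<=22", if (!b) "scg-duplicates>=4"),
          collapse = ",")
  }, okCount, okDup)
  data.frame(genome_id = meta$genome_id, pass = okCount & okDup,
             reason = as.character(reason),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Results-level genome filter
#'
#' A genome fails if completeness < 70 percent, contamination > 10 percent,
#' its row in the concatenated ribosomal-protein alignment covers < 50
#' percent of the columns, or its 14 ribosomal proteins are not co-encoded
#' on a single scaffold. All triggered reasons are listed.
#'
#' @param meta data.frame with \code{genome_id}, \code{completeness},
#'   \code{contamination}.
#' @param alnCoverage numeric vector in [0,1], named by genome id (or in
#'   \code{meta} order).
#' @param rpSingleScaffold logical vector, named by genome id (or in
#'   \code{meta} order).
#' @param minCompleteness,maxContamination,minAlnCoverage thresholds.
#' @return data.frame(genome_id, pass, reasons).
#' @export
resultsFilter <- function(meta, alnCoverage, rpSingleScaffold,
                          minCompleteness = 70, maxContamination = 10,
                          minAlnCoverage = 0.5) {
  stopIfMissingCols(meta, c("genome_id", "completeness", "contamination"),
                    "genome metadata")
  alignByName <- function(x, what) {
    if (!is.null(names(x))) {
      idx <- match(meta$genome_id, names(x))
      if (anyNA(idx)) stop(what, " missing for genome(s): ",
                           paste(meta$genome_id[is.na(idx)], collapse = ", "))
      x[idx]
    } else {
      if (length(x) != nrow(meta)) stop(what, " has wrong length")
      x
    }
  }
  cov <- alignByName(alnCoverage, "alignment coverage")
  single <- alignByName(rpSingleScaffold, "single-scaffold flag")
  if (any(cov < 0 | cov > 1)) stop("alignment coverage must lie in [0, 1]")
  fails <- cbind(
    completeness = meta$completeness < minCompleteness,
    contamination = meta$contamination > maxContamination,
    `alignment-coverage` = cov < minAlnCoverage,
    `rp-scaffold` = !single)
  reasons <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  data.frame(genome_id = meta$genome_id, pass = rowSums(fails) == 0,
             reasons = as.character(reasons),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of non-gap columns in an aligned FASTA row
#'
#' @param alignment a \code{Biostrings::AAStringSet} (or path to an aligned
#'   FASTA file); all rows must have equal width. Gap characters are
#'   \code{-} and \code{.}.
#' @param genomeID optional single genome id; when given, returns its scalar
#'   coverage (error if absent), otherwise the named vector for all rows.
#' @return numeric in [0, 1]: non-gap characters / alignment length.
#' @export
alignmentColumnCoverage <- function(alignment, genomeID = NULL) {
  if (is.character(alignment)) {
    alignment <- Biostrings::readAAStringSet(alignment)
  }
  w <- Biostrings::width(alignment)
  if (length(unique(w)) > 1L) {
    stop("ragged alignment: row widths differ (",
         paste(unique(w), collapse = ", "), ")")
  }
  gaps <- rowSums(Biostrings::letterFrequency(alignment, c("-", ".")))
  cov <- stats::setNames(1 - gaps / w, names(alignment))
  if (!is.null(genomeID)) {
    if (!genomeID %in% names(cov)) {
      stop("genome not found in alignment: ", genomeID)
    }
    return(unname(cov[genomeID]))
  }
  cov
}

.aniToMatrix <- function(ani, ids) {
  if (is.matrix(ani)) {
    if (nrow(ani) != ncol(ani) ||
        !isTRUE(all.equal(ani, t(ani), tolerance = 1e-8,
                          check.attributes = FALSE))) {
      stop("ANI matrix must be square and symmetric")
    }
    if (is.null(rownames(ani))) stop("ANI matrix needs genome id dimnames")
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    common <- intersect(ids, rownames(ani))
    m[common, common] <- ani[common, common]
    diag(m) <- 100
    return(m)
  }
  stopIfMissingCols(ani, c("genome_a", "genome_b", "ani"), "ANI table")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  keep <- ani$genome_a %in% ids & ani$genome_b %in% ids
  a <- ani$genome_a[keep]; b <- ani$genome_b[keep]; v <- ani$ani[keep]
  m[cbind(a, b)] <- v
  m[cbind(b, a)] <- v
  diag(m) <- 100
  m
}

#' Dereplicate genomes by single-linkage ANI clustering
#'
#' Clusters are the connected components of the graph whose edges link
#' genome pairs with ANI at or above the threshold (species-level
#' dereplication at the conventional 95 percent). The representative of each
#' cluster is the most complete genome, ties broken by lowest contamination,
#' then lexicographically smallest genome id.
#'
#' @param ani symmetric ANI matrix (percent) with genome dimnames, or a
#'   long-form data.frame(genome_a, genome_b, ani); pairs absent from a
#'   long-form table are treated as below threshold.
#' @param meta data.frame with \code{genome_id}, \code{completeness},
#'   \code{contamination} for every genome to cluster.
#' @param threshold ANI threshold in percent, inclusive; default 95.
#' @return data.frame(genome_id, cluster_id, is_representative); cluster ids
#'   are \code{cluster_0001, ...} ordered by each cluster's lexicographically
#'   smallest member.
#' @examples
#' meta <- data.frame(genome_id = c("a", "b", "c"),
#'                    completeness = c(80, 90, 75), contamination = 0)
#' ani <- data.frame(genome_a = "a", genome_b = "b", ani = 97)
#' dereplicate(ani, meta)  # {a,b} represented by b; c alone
#' @export
dereplicate <- function(ani, meta, threshold = 95) {
  stopIfMissingCols(meta, c("genome_id", "completeness", "contamination"),
                    "genome metadata")
  ids <- lexSort(meta$genome_id)
  m <- .aniToMatrix(ani, ids)
  adj <- m >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership[ids]
  ## stable cluster ids: order components by smallest member id
  first <- vapply(split(ids, comp), function(x) lexSort(x)[1L], character(1))
  compRank <- match(as.character(comp), names(first)[lexOrder(first)])
  clusterID <- sprintf("cluster_%04d", compRank)
  idx <- match(ids, meta$genome_id)
  df <- data.frame(genome_id = ids, cluster_id = clusterID,
                   completeness = meta$completeness[idx],
                   contamination = meta$contamination[idx],
                   stringsAsFactors = FALSE)
  df <- df[lexOrder(df$cluster_id, -df$completeness, df$contamination,
                    df$genome_id), , drop = FALSE]
  df$is_representative <- !duplicated(df$cluster_id)
  df <- df[lexOrder(df$genome_id), c("genome_id", "cluster_id",
                                     "is_representative")]
  rownames(df) <- NULL
  df
}

#' Run the full genome quality-control cascade
#'
#' Applies, for every genome: SCG-based completeness and contamination, the
#' draft-quality rule (>22 SCGs, <4 duplicated), the results-level filters
#' (completeness >= 70, contamination <= 10, ribosomal-protein alignment
#' coverage >= 0.5, single-scaffold requirement), and ANI dereplication with
#' representative selection. Rules are independent, so the surviving set
#' does not depend on the order in which they are applied; a genome survives
#' if it passes every rule and is its cluster's representative.
#'
#' @param scg SCG copy-number table (see \code{\link{estimateCompleteness}}).
#' @param ani ANI table or matrix (see \code{\link{dereplicate}}).
#' @param alignment aligned FASTA (\code{AAStringSet} or path); genomes
#'   absent from the alignment get coverage 0.
#' @param rpScaffolds data.frame(genome_id, protein_name, scaffold_id);
#'   genomes absent from the table fail the single-scaffold rule.
#' @param aniThreshold,minCompleteness,maxContamination,minAlnCoverage
#'   thresholds of the cascade.
#' @return the QC report: one row per genome with all metrics, each rule's
#'   outcome, cluster id, representative flag and the \code{final_pass}
#'   column marking the surviving analysis set.
#' @export
runGenomeQC <- function(scg, ani, alignment, rpScaffolds,
                        aniThreshold = 95, minCompleteness = 70,
                        maxContamination = 10, minAlnCoverage = 0.5) {
  meta <- estimateCompleteness(scg)
  meta <- meta[lexOrder(meta$genome_id), , drop = FALSE]
  draft <- draftQualityFilter(meta)

  cov <- alignmentColumnCoverage(alignment)
  covAll <- stats::setNames(rep(0, nrow(meta)), meta$genome_id)
  common <- intersect(names(cov), meta$genome_id)
  covAll[common] <- cov[common]

  stopIfMissingCols(rpScaffolds, c("genome_id", "scaffold_id"),
                    "ribosomal-protein scaffold table")
  nScf <- vapply(split(rpScaffolds$scaffold_id, rpScaffolds$genome_id),
                 function(x) length(unique(x)), integer(1))
  single <- stats::setNames(rep(FALSE, nrow(meta)), meta$genome_id)
  common <- intersect(names(nScf), meta$genome_id)
  single[common] <- nScf[common] == 1L

  res <- resultsFilter(meta, covAll, single, minCompleteness,
                       maxContamination, minAlnCoverage)
  derep <- dereplicate(ani, meta, threshold = aniThreshold)

  report <- data.frame(
    meta,
    draft_pass = draft$pass,
    draft_reason = draft$reason,
    aln_coverage = unname(covAll),
    rp_single_scaffold = unname(single),
    results_pass = res$pass,
    results_reasons = res$reasons,
    cluster_id = derep$cluster_id[match(meta$genome_id, derep$genome_id)],
    is_representative = derep$is_representative[match(meta$genome_id,
                                                      derep$genome_id)],
    stringsAsFactors = FALSE, row.names = NULL)
  report$final_pass <- report$draft_pass & report$results_pass &
    report$is_representative
  report
}
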