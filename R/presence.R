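## Presence/absence matrix construction from homology hit tables, and the
## Jaccard distance on presence profiles.

#' Build a family-by-genome presence/absence matrix from hit records
#'
#' A cell (family, genome) is marked present if at least one hit for the
#' family — directly or via a mapped subfamily — in that genome has E-value
#' at or below the threshold (the conventional reporting cutoff of 0.001).
#' Presence is binary: copy number is discarded. Genomes with no passing hit
#' are kept as all-absent columns so genome-side clustering reflects them.
#'
#' @param hits data.frame with columns \code{family_id} (or
#'   \code{subfamily_id} resolved through \code{subfamilyMap}),
#'   \code{genome_id}, \code{evalue} (> 0). A \code{subfamily_id} column may
#'   be NA for direct family-level hits.
#' @param genomes genome metadata data.frame with \code{genome_id} (and
#'   optionally \code{domain}, \code{phylum}, \code{is_dpann}); defines the
#'   matrix columns.
#' @param threshold E-value cutoff, inclusive; default 0.001.
#' @param subfamilyMap optional data.frame(subfamily_id, family_id); hits
#'   whose subfamily is missing from the map raise an error listing the
#'   offenders. Subfamily hits aggregate to families by union.
#' @param keepEmpty keep families whose hits all fail the threshold as
#'   all-absent rows (default FALSE: such rows are dropped).
#' @param unknownGenomes what to do with hits in genomes absent from
#'   \code{genomes}: \code{"error"} (default) or \code{"drop"} with warning.
#' @return a \code{\linkS4class{PresenceMatrix}} with lexicographically
#'   sorted row and column labels and the threshold recorded as provenance.
#' @examples
#' hits <- data.frame(family_id = "famA", genome_id = "g1", evalue = 1e-10)
#' genomes <- data.frame(genome_id = c("g1", "g2"))
#' presence(buildPresenceMatrix(hits, genomes))
#' @export
buildPresenceMatrix <- function(hits, genomes, threshold = 0.001,
                                subfamilyMap = NULL, keepEmpty = FALSE,
                                unknownGenomes = c("error", "drop")) {
  unknownGenomes <- match.arg(unknownGenomes)
  stopIfMissingCols(hits, c("genome_id", "evalue"), "hit table")
  stopIfMissingCols(genomes, "genome_id", "genome metadata")
  if (anyDuplicated(genomes$genome_id)) stop("duplicate genome ids in metadata")
  if (any(hits$evalue <= 0)) stop("E-values must be positive")

  fam <- if ("family_id" %in% colnames(hits)) hits$family_id else
    rep(NA_character_, nrow(hits))
  if (!is.null(subfamilyMap)) {
    stopIfMissingCols(subfamilyMap, c("subfamily_id", "family_id"),
                      "subfamily map")
    hasSub <- "subfamily_id" %in% colnames(hits) & !is.na(hits$subfamily_id)
    if (any(hasSub)) {
      idx <- match(hits$subfamily_id[hasSub], subfamilyMap$subfamily_id)
      if (anyNA(idx)) {
        bad <- unique(hits$subfamily_id[hasSub][is.na(idx)])
        stop("subfamilies missing from the map: ",
             paste(lexSort(bad), collapse = ", "))
      }
      fam[hasSub] <- subfamilyMap$family_id[idx]
    }
  }
  if (anyNA(fam)) stop("hits without family_id and without a mapped subfamily")

  unknown <- !(hits$genome_id %in% genomes$genome_id)
  if (any(unknown)) {
    offenders <- lexSort(unique(hits$genome_id[unknown]))
    if (unknownGenomes == "error") {
      stop("hits reference genomes absent from the metadata: ",
           paste(offenders, collapse = ", "))
    }
    warning("dropping hits in ", length(offenders),
            " genome(s) absent from the metadata")
    hits <- hits[!unknown, , drop = FALSE]
    fam <- fam[!unknown]
  }

  pass <- hits$evalue <= threshold
  famIDs <- lexSort(unique(if (keepEmpty) fam else fam[pass]))
  genIDs <- lexSort(unique(genomes$genome_id))
  P <- matrix(FALSE, length(famIDs), length(genIDs),
              dimnames = list(famIDs, genIDs))
  if (any(pass)) {
    P[cbind(fam[pass], hits$genome_id[pass])] <- TRUE
  }
  PresenceMatrix(P, genomes = genomes, threshold = threshold)
}

#' Jaccard distance between presence profiles
#'
#' For two profiles with presence sets P(x), P(y),
#' d(x, y) = 1 - |intersection| / |union|; by convention d = 0 when both
#' sets are empty (identical profiles). The result is symmetric with zero
#' diagonal and values in [0, 1].
#'
#' @param x a \code{\linkS4class{PresenceMatrix}} or a logical/0-1 matrix
#'   (families as rows, genomes as columns).
#' @param axis compute distances between \code{"families"} (rows) or
#'   \code{"genomes"} (columns).
#' @return symmetric numeric matrix with dimnames along the chosen axis.
#' @export
setGeneric("jaccardDistance",
           function(x, axis = c("families", "genomes"))
             standardGeneric("jaccardDistance"))

#' @rdname jaccardDistance
setMethod("jaccardDistance", "PresenceMatrix", function(x, axis) {
  jaccardDistance(presence(x), axis = axis)
})

#' @rdname jaccardDistance
setMethod("jaccardDistance", "matrix", function(x, axis) {
  axis <- match.arg(axis, c("families", "genomes"))
  M <- x * 1
  if (axis == "genomes") M <- t(M)
  if (nrow(M) == 0L) stop("matrix is empty along the chosen axis")
  A <- tcrossprod(M)                     # pairwise intersections
  s <- rowSums(M)
  U <- outer(s, s, "+") - A              # pairwise unions
  D <- 1 - A / U
  D[U == 0] <- 0                         # both profiles empty: identical
  diag(D) <- 0
  D
})

#' Write a presence matrix as a 0/1 TSV with header row and column
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
writePresenceMatrix <- function(pm, path) {
  m <- presence(pm)
  df <- data.frame(family_id = rownames(m), m * 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTSVAtomic(df, path)
}

#' Read a presence matrix written by \code{\link{writePresenceMatrix}}
#' @param path TSV path (first column \code{family_id}, then one 0/1 column
#'   per genome).
#' @param genomes optional genome metadata to attach.
#' @param threshold threshold to record as provenance.
#' @return a \code{\linkS4class{PresenceMatrix}}.
#' @export
readPresenceMatrix <- function(path, genomes = NULL, threshold = NA_real_) {
  df <- readTSV(path)
  stopIfMissingCols(df, "family_id", "presence matrix file")
  m <- as.matrix(df[, setdiff(colnames(df), "family_id"), drop = FALSE]) > 0
  rownames(m) <- df$family_id
  PresenceMatrix(m, genomes = genomes, threshold = threshold)
}
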