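## Cross-domain "breadth": for each archaeal protein family, the incidence
## of homology hits across bacterial phyla. Families hit in a large share of
## bacterial phyla are candidate inter-domain transfers (or core machinery
## common to both domains).

#' Per-family, per-phylum hit incidence across a bacterial genome panel
#'
#' For each (family, phylum) pair: the percentage of the phylum's
#' representative genomes with at least one hit to the family at or below
#' the E-value threshold. Duplicate hit records are harmless (union
#' semantics); subfamily hits aggregate to families by union.
#'
#' @param hits bacterial hit records: data.frame(family_id, genome_id,
#'   evalue), optionally \code{subfamily_id}.
#' @param bacterialMeta data.frame(genome_id, phylum) assigning every
#'   bacterial genome to a phylum; the genomes listed here are the
#'   representative set (the denominator).
#' @param threshold E-value cutoff, inclusive; default 0.001.
#' @param subfamilyMap optional data.frame(subfamily_id, family_id).
#' @param families optional character vector of family ids to report
#'   (families without hits get all-zero rows); defaults to the families
#'   present in \code{hits}.
#' @param minPhylumGenomes drop phyla represented by fewer genomes than
#'   this (with a warning); default 1 (no exclusion).
#' @return numeric matrix of percentages, families as rows, phyla as
#'   columns, both lexicographically sorted.
#' @examples
#' hits <- data.frame(family_id = "famA", genome_id = c("b1", "b2"),
#'                    evalue = 1e-6)
#' meta <- data.frame(genome_id = paste0("b", 1:6), phylum = "Firmicutes")
#' perPhylumIncidence(hits, meta)  # 2 of 6 genomes: 33.33
#' @export
perPhylumIncidence <- function(hits, bacterialMeta, threshold = 0.001,
                               subfamilyMap = NULL, families = NULL,
                               minPhylumGenomes = 1) {
  stopIfMissingCols(bacterialMeta, c("genome_id", "phylum"),
                    "bacterial metadata")
  if (anyDuplicated(bacterialMeta$genome_id)) {
    stop("duplicate genome ids in bacterial metadata")
  }
  stopIfMissingCols(hits, c("genome_id", "evalue"), "bacterial hit table")
  fam <- if ("family_id" %in% colnames(hits)) hits$family_id else
    rep(NA_character_, nrow(hits))
  if (!is.null(subfamilyMap)) {
    hasSub <- "subfamily_id" %in% colnames(hits) & !is.na(hits$subfamily_id)
    if (any(hasSub)) {
      idx <- match(hits$subfamily_id[hasSub], subfamilyMap$subfamily_id)
      if (anyNA(idx)) {
        stop("subfamilies missing from the map: ",
             paste(lexSort(unique(hits$subfamily_id[hasSub][is.na(idx)])),
                   collapse = ", "))
      }
      fam[hasSub] <- subfamilyMap$family_id[idx]
    }
  }
  unknown <- !(hits$genome_id %in% bacterialMeta$genome_id)
  if (any(unknown)) {
    warning("dropping ", sum(unknown),
            " hit(s) in genomes absent from the bacterial metadata")
    hits <- hits[!unknown, , drop = FALSE]
    fam <- fam[!unknown]
  }

  phylumSize <- table(bacterialMeta$phylum)
  small <- names(phylumSize)[phylumSize < minPhylumGenomes]
  if (length(small)) {
    warning("excluding phyla with fewer than ", minPhylumGenomes,
            " genomes: ", paste(small, collapse = ", "))
    phylumSize <- phylumSize[!names(phylumSize) %in% small]
  }
  phyla <- lexSort(names(phylumSize))
  famIDs <- lexSort(unique(c(families, fam[hits$evalue <= threshold])))

  inc <- matrix(0, length(famIDs), length(phyla),
                dimnames = list(famIDs, phyla))
  pass <- hits$evalue <= threshold
  if (any(pass)) {
    gphy <- bacterialMeta$phylum[match(hits$genome_id[pass],
                                       bacterialMeta$genome_id)]
    u <- unique(data.frame(family = fam[pass], genome = hits$genome_id[pass],
                           phylum = gphy, stringsAsFactors = FALSE))
    u <- u[u$phylum %in% phyla & u$family %in% famIDs, , drop = FALSE]
    if (nrow(u)) {
      cnt <- table(factor(u$family, levels = famIDs),
                   factor(u$phylum, levels = phyla))
      inc <- 100 * sweep(unclass(cnt), 2L,
                         as.numeric(phylumSize[phyla]), "/")
    }
  }
  inc
}

#' Compute the breadth statistic from per-phylum incidence
#'
#' A phylum counts toward a family's breadth when at least one third (by
#' default) of its representative genomes have an above-threshold hit; the
#' comparison is inclusive, so a phylum at exactly the fraction counts.
#' Breadth is the percentage of surveyed phyla that pass. Families with no
#' bacterial hit at all have no defined breadth (NA) and
#' \code{has_bacterial_hit} FALSE.
#'
#' @param incidence matrix from \code{\link{perPhylumIncidence}} (families x
#'   phyla, percentages).
#' @param minFraction minimum fraction of a phylum's genomes with a hit;
#'   default 1/3.
#' @return data.frame(family_id, has_bacterial_hit, n_phyla_passing,
#'   breadth_pct), one row per family.
#' @examples
#' inc <- rbind(famA = c(100 / 3, 0, 50))
#' colnames(inc) <- paste0("phy", 1:3)
#' computeBreadth(inc)  # 2 of 3 phyla pass: breadth 66.67
#' @export
computeBreadth <- function(incidence, minFraction = 1 / 3) {
  if (!is.matrix(incidence) || is.null(rownames(incidence))) {
    stop("incidence must be a matrix with family row names")
  }
  if (ncol(incidence) < 1L) stop("incidence must cover at least one phylum")
  hasHit <- rowSums(incidence) > 0
  ## inclusive at the boundary; small epsilon guards the floating-point
  ## representation of e.g. 100 * 2/6 vs 100 * 1/3
  passing <- incidence >= (100 * minFraction - 1e-9)
  nPass <- as.integer(rowSums(passing))
  breadth <- 100 * nPass / ncol(incidence)
  nPass[!hasHit] <- 0L
  breadth[!hasHit] <- NA_real_
  data.frame(family_id = rownames(incidence),
             has_bacterial_hit = unname(hasHit),
             n_phyla_passing = unname(nPass),
             breadth_pct = unname(breadth),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked breadth report
#'
#' Joins breadth profiles with family sizes and optional functional
#' categories, sorted by decreasing breadth, then decreasing size, then
#' family id — the table behind a breadth-versus-family-size scatter.
#'
#' @param profiles data.frame from \code{\link{computeBreadth}}.
#' @param familySizes named numeric vector (or data.frame(family_id, size))
#'   of family sizes (member proteins or member genomes; report which).
#' @param annotations optional named character vector (or
#'   data.frame(family_id, category)) of functional categories; unannotated
#'   families get \code{"unknown"}.
#' @return data.frame(family_id, size, has_bacterial_hit, n_phyla_passing,
#'   breadth_pct, category), ranked.
#' @export
breadthReport <- function(profiles, familySizes, annotations = NULL) {
  if (is.data.frame(familySizes)) {
    stopIfMissingCols(familySizes, c("family_id", "size"), "family sizes")
    familySizes <- stats::setNames(familySizes$size, familySizes$family_id)
  }
  if (is.data.frame(annotations)) {
    stopIfMissingCols(annotations, c("family_id", "category"), "annotations")
    annotations <- stats::setNames(annotations$category, annotations$family_id)
  }
  out <- profiles
  out$size <- unname(familySizes[out$family_id])
  out$category <- if (is.null(annotations)) "unknown" else {
    cat <- unname(annotations[out$family_id])
    ifelse(is.na(cat), "unknown", cat)
  }
  br <- ifelse(is.na(out$breadth_pct), -Inf, out$breadth_pct)
  sz <- ifelse(is.na(out$size), -Inf, out$size)
  out <- out[lexOrder(-br, -sz, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("family_id", "size", "has_bacterial_hit", "n_phyla_passing",
          "breadth_pct", "category")]
}
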