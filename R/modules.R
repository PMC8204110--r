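## Module detection: agglomerative clustering of family presence profiles,
## extraction of >=20-family modules, taxonomic assignment by the
## median-genome rule, and DPANN occurrence/enrichment classification.

.checkDistMatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance must be a square matrix or dist object")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  if (is.null(rownames(d))) {
    stop("distance matrix needs labels")
  }
  d
}

#' Cluster families by cutting a hierarchical-clustering dendrogram
#'
#' Agglomerative clustering of the family Jaccard distances; flat clusters
#' are formed by cutting the dendrogram at the given cophenetic distance
#' (merges at exactly the cutoff stay together). Labels are sorted
#' lexicographically before clustering so the result does not depend on
#' input row order.
#'
#' @param d symmetric distance matrix (or \code{dist}) with family labels.
#' @param linkage \code{"complete"} (default, matching the genome-side
#'   clustering) or \code{"average"}.
#' @param cutoff dendrogram cut height; default 0.95 on the Jaccard scale.
#' @return list with \code{clusters} (named integer vector of cluster
#'   memberships) and \code{tree} (the \code{hclust}, or NULL for a single
#'   family).
#' @examples
#' m <- rbind(f1 = c(1, 1, 0, 0), f2 = c(1, 1, 0, 0), f3 = c(0, 0, 1, 1))
#' colnames(m) <- paste0("g", 1:4)
#' clusterFamilies(jaccardDistance(m))$clusters  # f1,f2 together; f3 apart
#' @export
clusterFamilies <- function(d, linkage = c("complete", "average"),
                            cutoff = 0.95) {
  linkage <- match.arg(linkage)
  d <- .checkDistMatrix(d)
  ord <- lexOrder(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  if (nrow(d) == 1L) {
    return(list(clusters = stats::setNames(1L, rownames(d)), tree = NULL))
  }
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  clusters <- stats::cutree(tree, h = cutoff)
  list(clusters = clusters, tree = tree)
}

#' Extract modules (clusters of at least \code{minSize} families)
#'
#' Clusters meeting the size rule become modules, numbered deterministically
#' by descending size, ties broken by the lexicographically smallest member;
#' smaller clusters are kept as residuals.
#'
#' @param clustering result of \code{\link{clusterFamilies}} (or a named
#'   cluster-membership vector).
#' @param minSize minimum families per module; default 20.
#' @return a \code{\linkS4class{ModuleSet}} skeleton (ids and sizes only;
#'   see \code{\link{assignModuleTaxonomy}} and
#'   \code{\link{classifyModuleOccurrence}} for the remaining fields).
#' @export
extractModules <- function(clustering, minSize = 20) {
  clusters <- if (is.list(clustering)) clustering$clusters else clustering
  tree <- if (is.list(clustering)) clustering$tree else NULL
  sets <- lapply(split(names(clusters), clusters), lexSort)
  sizes <- vapply(sets, length, integer(1))
  firstMember <- vapply(sets, `[`, character(1), 1L)
  ord <- lexOrder(-sizes, firstMember)
  sets <- sets[ord]
  sizes <- sizes[ord]
  isMod <- sizes >= minSize
  modules <- sets[isMod]
  names(modules) <- sprintf("M%03d", seq_along(modules))
  residuals <- sets[!isMod]
  names(residuals) <- sprintf("R%03d", seq_along(residuals))
  tab <- data.frame(module_id = names(modules),
                    size = as.integer(sizes[isMod]),
                    stringsAsFactors = FALSE, row.names = NULL)
  new("ModuleSet", families = modules, table = tab, residuals = residuals,
      retained = list(), tree = tree,
      params = list(minSize = as.integer(minSize)))
}

#' Assign each module a taxonomic distribution by the median-genome rule
#'
#' For each module, the median number of genomes per family (m) is computed
#' (rounded half-up when fractional). Genomes are ranked by the number of
#' module families they carry (ties broken by lexicographic genome id) and
#' the top m genomes are retained; the phylum distribution of the retained
#' genomes is the module's taxonomic assignment. A single lineage is
#' assigned when at least \code{singleLineageFraction} of the retained
#' genomes share one phylum (default 1: strict unanimity).
#'
#' @param ms a \code{\linkS4class{ModuleSet}}.
#' @param pm the \code{\linkS4class{PresenceMatrix}} (its \code{colData}
#'   must carry \code{phylum}).
#' @param singleLineageFraction fraction of retained genomes that must share
#'   a phylum for a single-lineage assignment; default 1.
#' @return the \code{ModuleSet} with columns \code{m},
#'   \code{taxon_distribution} (\code{phylum:count} pairs, semicolon
#'   separated, decreasing count then name), \code{dominant_lineage},
#'   \code{assigned_single_lineage} (NA when the criterion is not met) added
#'   to its table, and retained genomes stored per module.
#' @export
assignModuleTaxonomy <- function(ms, pm, singleLineageFraction = 1) {
  stopifnot(is(ms, "ModuleSet"), is(pm, "PresenceMatrix"))
  cd <- SummarizedExperiment::colData(pm)
  if (!"phylum" %in% colnames(cd)) {
    stop("presence matrix colData must carry a 'phylum' column")
  }
  P <- presence(pm)
  phylum <- stats::setNames(as.character(cd$phylum), rownames(cd))
  tab <- ms@table
  retained <- vector("list", length(ms@families))
  names(retained) <- names(ms@families)
  mCol <- integer(nrow(tab))
  distCol <- character(nrow(tab))
  domCol <- character(nrow(tab))
  singCol <- character(nrow(tab))
  for (i in seq_along(ms@families)) {
    fams <- ms@families[[i]]
    miss <- setdiff(fams, rownames(P))
    if (length(miss)) {
      stop("module ", names(ms@families)[i],
           " has families absent from the matrix: ",
           paste(miss, collapse = ", "))
    }
    sub <- P[fams, , drop = FALSE]
    counts <- rowSums(sub)                      # genomes per family
    m <- medianHalfUp(counts)
    carriage <- colSums(sub)                    # module families per genome
    ord <- lexOrder(-carriage, colnames(sub))
    top <- colnames(sub)[ord][seq_len(m)]
    retained[[i]] <- top
    cnt <- table(phylum[top])
    ## deterministic tie-break among equal counts: phylum name
    dist <- if (length(cnt)) {
      v <- as.integer(cnt)
      nm <- names(cnt)
      stats::setNames(v, nm)[lexOrder(-v, nm)]
    } else integer(0)
    mCol[i] <- m
    distCol[i] <- paste(sprintf("%s:%d", names(dist), dist),
                        collapse = ";")
    domCol[i] <- if (length(dist)) names(dist)[1L] else NA_character_
    singCol[i] <- if (m > 0L && length(dist) &&
                      dist[1L] / m >= singleLineageFraction) {
      names(dist)[1L]
    } else NA_character_
  }
  tab$m <- mCol
  tab$taxon_distribution <- distCol
  tab$dominant_lineage <- domCol
  tab$assigned_single_lineage <- singCol
  tab$retained_genomes <- vapply(retained, paste, character(1), collapse = ";")
  ms@table <- tab
  ms@retained <- retained
  validObject(ms)
  ms
}

#' Classify module occurrence and enrichment in a flagged lineage group
#'
#' A module occurs in the DPANN if at least one DPANN genome carries at
#' least one of its families. The DPANN prevalence of a module is the mean,
#' over its families, of the fraction of DPANN genomes carrying the family;
#' the non-DPANN prevalence is computed analogously over the remaining
#' archaeal genomes. A module is enriched when its DPANN prevalence exceeds
#' its non-DPANN prevalence.
#'
#' @param ms a \code{\linkS4class{ModuleSet}}.
#' @param pm the \code{\linkS4class{PresenceMatrix}}; \code{colData} must
#'   carry \code{is_dpann} (and optionally \code{domain}; non-archaeal
#'   columns are ignored).
#' @return the \code{ModuleSet} with columns \code{occurs_in_dpann},
#'   \code{dpann_prevalence}, \code{nondpann_prevalence}, \code{enriched},
#'   \code{prevalence_defined} (FALSE when either group is empty, in which
#'   case the prevalences are NA) and \code{assigned_dpann_lineage} (single
#'   assigned lineage that is a DPANN phylum) added to its table.
#' @export
classifyModuleOccurrence <- function(ms, pm) {
  stopifnot(is(ms, "ModuleSet"), is(pm, "PresenceMatrix"))
  cd <- SummarizedExperiment::colData(pm)
  if (!"is_dpann" %in% colnames(cd)) {
    stop("presence matrix colData must carry an 'is_dpann' column")
  }
  arch <- if ("domain" %in% colnames(cd)) cd$domain == "archaea" else
    rep(TRUE, nrow(cd))
  dp <- arch & cd$is_dpann
  non <- arch & !cd$is_dpann
  P <- presence(pm)
  defined <- sum(dp) > 0L && sum(non) > 0L
  dpannPhyla <- unique(as.character(cd$phylum[dp]))
  tab <- ms@table
  occ <- logical(nrow(tab)); dprev <- nprev <- rep(NA_real_, nrow(tab))
  for (i in seq_along(ms@families)) {
    sub <- P[ms@families[[i]], , drop = FALSE]
    occ[i] <- sum(dp) > 0L && any(sub[, dp, drop = FALSE])
    if (defined) {
      dprev[i] <- mean(rowMeans(sub[, dp, drop = FALSE]))
      nprev[i] <- mean(rowMeans(sub[, non, drop = FALSE]))
    }
  }
  if (!defined && nrow(tab)) {
    warning("zero DPANN or zero non-DPANN genomes: prevalences undefined")
  }
  tab$occurs_in_dpann <- occ
  tab$dpann_prevalence <- dprev
  tab$nondpann_prevalence <- nprev
  tab$enriched <- defined & dprev > nprev
  tab$prevalence_defined <- defined
  tab$assigned_dpann_lineage <- if ("assigned_single_lineage" %in% colnames(tab)) {
    !is.na(tab$assigned_single_lineage) &
      tab$assigned_single_lineage %in% dpannPhyla
  } else rep(NA, nrow(tab))
  ms@table <- tab
  ms
}

#' Detect, assign and classify modules in one step
#'
#' Runs the family-side Jaccard distance, hierarchical clustering with the
#' dendrogram cutoff, module extraction, median-genome taxonomic assignment
#' and DPANN occurrence/enrichment classification. Families with all-absent
#' profiles are uninformative and excluded from clustering by default.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} whose \code{colData}
#'   carries \code{phylum} and \code{is_dpann}.
#' @param linkage,cutoff see \code{\link{clusterFamilies}}.
#' @param minSize minimum module size; default 20.
#' @param dropEmpty drop all-absent family rows before clustering.
#' @param singleLineageFraction see \code{\link{assignModuleTaxonomy}}.
#' @return a fully annotated \code{\linkS4class{ModuleSet}}.
#' @export
detectModules <- function(pm, linkage = "complete", cutoff = 0.95,
                          minSize = 20, dropEmpty = TRUE,
                          singleLineageFraction = 1) {
  P <- presence(pm)
  if (dropEmpty) {
    keep <- rowSums(P) > 0L
    pm <- pm[keep, ]
  }
  d <- jaccardDistance(pm, axis = "families")
  cl <- clusterFamilies(d, linkage = linkage, cutoff = cutoff)
  ms <- extractModules(cl, minSize = minSize)
  ms@params <- c(ms@params, list(linkage = linkage, cutoff = cutoff,
                                 singleLineageFraction = singleLineageFraction))
  ms <- assignModuleTaxonomy(ms, pm,
                             singleLineageFraction = singleLineageFraction)
  classifyModuleOccurrence(ms, pm)
}

#' Family-to-module assignment table
#' @param ms a \code{\linkS4class{ModuleSet}}.
#' @return data.frame(family_id, module_id), modules only.
#' @export
familyModuleMap <- function(ms) {
  fams <- ms@families
  data.frame(
    family_id = unlist(fams, use.names = FALSE),
    module_id = rep(names(fams), vapply(fams, length, integer(1))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-side clustering of presence profiles
#'
#' Complete-linkage hierarchical clustering of genomes on the Jaccard
#' distance between their family presence profiles (the clustering behind a
#' presence/absence heatmap), with a Newick export of the dendrogram and a
#' leaf-ordered 0/1 table.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} with at least 2 genomes.
#' @param linkage linkage method; default \code{"complete"}.
#' @return list with \code{tree} (\code{hclust}), \code{newick} (character
#'   scalar) and \code{matrix} (the presence matrix with genome columns in
#'   deterministic leaf order).
#' @export
clusterGenomes <- function(pm, linkage = "complete") {
  P <- presence(pm)
  if (ncol(P) < 2L) {
    stop("genome clustering needs at least 2 genomes")
  }
  d <- jaccardDistance(pm, axis = "genomes")
  ord <- lexOrder(rownames(d))
  tree <- stats::hclust(stats::as.dist(d[ord, ord]), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(tree))
  list(tree = tree, newick = newick,
       matrix = P[, tree$labels[tree$order], drop = FALSE])
}
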