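#' Build the similarity graph
#'
#' Nodes are all query and subject IDs appearing in the (already filtered)
#' hit table; an undirected edge connects two sequences if at least one
#' surviving hit exists in either direction.  Self-loops and parallel edges
#' are collapsed.
#'
#' @param hits filtered tabular-6 data.frame (see \code{\link{filterHits}}).
#' @return an \link[igraph]{igraph} graph.
#' @export
buildGraph <- function(hits) {
  nodes <- unique(c(hits$query_id, hits$subject_id))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(hits)) {
    edges <- hits[hits$query_id != hits$subject_id, c("query_id", "subject_id")]
    g <- igraph::add_edges(g, t(as.matrix(edges)))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Connected components of a similarity graph
#'
#' @param graph an \link[igraph]{igraph} graph.
#' @return list of character vectors (sorted node names), one per component;
#'   two nodes share a component iff a path connects them.
#' @export
graphComponents <- function(graph) {
  comp <- igraph::components(graph)
  if (comp$no == 0L) return(list())
  unname(lapply(split(names(comp$membership), comp$membership), sort))
}

#' Retention filter for OCG candidates
#'
#' A component is retained iff it has at least \code{minOcgSize} members in
#' total and its coexpressed members come from at least
#' \code{minCoexpSpecies} distinct species.
#'
#' @param components list of character vectors of sequence IDs.
#' @param speciesOf named character vector, species per sequence ID.
#' @param isCoexp named logical vector, coexpression flag per sequence ID.
#' @param params a \linkS4class{PipelineParams}.
#' @return the retained subset of \code{components}.
#' @export
filterOcgs <- function(components, speciesOf, isCoexp,
                       params = pipelineParams()) {
  keep <- vapply(components, function(m) {
    length(m) >= params@minOcgSize &&
      length(unique(speciesOf[m[which(isCoexp[m])]])) >= params@minCoexpSpecies
  }, logical(1))
  components[keep]
}

#' Rank retained components into labelled OCGs
#'
#' Components are ordered by coexpression ratio (coexpressed members over
#' total members) descending, then by total size descending, then by the
#' lexicographically smallest member ID.  Labels "0000", "0001", ... are
#' assigned in that order (width grows beyond four digits if ever needed).
#'
#' @inheritParams filterOcgs
#' @param bestR named numeric vector, best Spearman coefficient per
#'   coexpressed sequence (NA otherwise).
#' @return an \linkS4class{OCGSet}.
#' @export
rankOcgs <- function(components, speciesOf, isCoexp, bestR = NULL) {
  if (is.null(bestR)) bestR <- setNames(rep(NA_real_, 0), character())
  if (!length(components))
    return(new("OCGSet",
               members = data.frame(label = character(), seq_id = character(),
                                    species_id = character(),
                                    is_coexp = logical(), best_r = numeric(),
                                    stringsAsFactors = FALSE),
               summary = data.frame(label = character(), n_total = integer(),
                                    n_coexp = integer(),
                                    n_species_coexp = integer(),
                                    ratio = numeric(),
                                    stringsAsFactors = FALSE)))
  nTotal <- lengths(components)
  nCoexp <- vapply(components, function(m) length(which(isCoexp[m])), integer(1))
  nSpecies <- vapply(components, function(m)
    length(unique(speciesOf[m[which(isCoexp[m])]])), integer(1))
  ratio <- nCoexp / nTotal
  firstId <- vapply(components, function(m) sort(m)[1], character(1))
  ord <- order(-ratio, -nTotal, firstId)
  w <- max(4L, nchar(length(components) - 1L))
  labels <- formatC(seq_along(ord) - 1L, width = w, flag = "0")
  members <- do.call(rbind, lapply(seq_along(ord), function(k) {
    m <- sort(components[[ord[k]]])
    data.frame(label = labels[k], seq_id = m,
               species_id = unname(speciesOf[m]),
               is_coexp = unname(isCoexp[m]),
               best_r = unname(bestR[m]),
               stringsAsFactors = FALSE)
  }))
  rownames(members) <- NULL
  summary <- data.frame(label = labels,
                        n_total = nTotal[ord],
                        n_coexp = nCoexp[ord],
                        n_species_coexp = nSpecies[ord],
                        ratio = ratio[ord],
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  new("OCGSet", members = members, summary = summary)
}

#' Display name of an OCG member
#'
#' Coexpressed members carry the \code{_coexp} suffix in FASTA files,
#' alignments, trees and annotation sidecars.
#'
#' @param seqId sequence ID(s).
#' @param isCoexp logical flag(s).
#' @return character vector of display names.
#' @export
ocgDisplayName <- function(seqId, isCoexp) {
  ifelse(rep_len(isCoexp, length(seqId)), paste0(seqId, "_coexp"), seqId)
}

#' Write one peptide FASTA per OCG
#'
#' Files are named \code{<label>.fasta}; coexpressed members carry the
#' \code{_coexp} suffix, all other headers are unmodified.
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param seqs \link[Biostrings]{AAStringSet} covering all members (plain
#'   IDs).
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, one per OCG.
#' @export
writeOcgFastas <- function(ocgs, seqs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(ocgSummary(ocgs)$label, function(lab) {
    m <- ocgMembers(ocgs, lab)
    miss <- setdiff(m$seq_id, names(seqs))
    if (length(miss))
      stopf("OCG %s member(s) without sequence: %s", lab,
            paste(miss, collapse = ", "))
    x <- seqs[m$seq_id]
    names(x) <- ocgDisplayName(m$seq_id, m$is_coexp)
    path <- file.path(dir, paste0(lab, ".fasta"))
    writeXStringSet(x, path)
    path
  }, character(1))
}

#' Write the OCG summary table
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeOcgSummary <- function(ocgs, path) {
  write.table(ocgSummary(ocgs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
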