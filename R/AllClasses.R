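#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet translate subseq pairwiseAlignment
#'   pattern subject nmatch nmismatch pid width score start end
#' @importFrom stats cor pt setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' Pipeline parameter container
#'
#' Holds every tunable threshold of the coexpression / orthology / phylogeny
#' pipeline together with the seed used for all random draws.  Defaults follow
#' the conventional settings for bait-based candidate gene discovery across
#' species:
#'
#' \describe{
#'   \item{rCutoff}{minimum Spearman coefficient for a coexpression hit
#'     (default 0.7).}
#'   \item{pCutoff}{maximum p-value for a coexpression hit (default 0.05).}
#'   \item{numCut}{maximum number of candidate genes kept per species
#'     (default 100).}
#'   \item{minExpCutoff}{minimum cumulative TPM of a candidate over all
#'     samples (default 30).}
#'   \item{evalueCutoff}{maximum e-value of a similarity hit (default 1e-5,
#'     inclusive).}
#'   \item{scoreCutoff}{bit score a hit must strictly exceed (default 100).}
#'   \item{lenCutoff}{alignment length a hit must strictly exceed
#'     (default 100 columns).}
#'   \item{simCutoff}{percent identity a hit must strictly exceed
#'     (default 80).}
#'   \item{occupancy}{minimum percent of non-gap characters for an alignment
#'     column to be kept (default 10).}
#'   \item{seqsClusterAnno}{percent of each OCG sampled for functional
#'     annotation (default 50; values below 10 are raised to 10).}
#'   \item{minOcgSize}{minimum number of sequences in a retained OCG
#'     (default 10).}
#'   \item{minCoexpSpecies}{minimum number of species contributing
#'     coexpressed members to a retained OCG (default 3).}
#'   \item{seed}{integer seed for all random draws (default 1).}
#' }
#'
#' @slot rCutoff,pCutoff,numCut,minExpCutoff,evalueCutoff,scoreCutoff,lenCutoff,simCutoff,occupancy,seqsClusterAnno,minOcgSize,minCoexpSpecies,seed numeric scalars, see Description.
#' @export
setClass("PipelineParams", representation(
  rCutoff = "numeric",
  pCutoff = "numeric",
  numCut = "numeric",
  minExpCutoff = "numeric",
  evalueCutoff = "numeric",
  scoreCutoff = "numeric",
  lenCutoff = "numeric",
  simCutoff = "numeric",
  occupancy = "numeric",
  seqsClusterAnno = "numeric",
  minOcgSize = "numeric",
  minCoexpSpecies = "numeric",
  seed = "integer"
))

setValidity("PipelineParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in slotNames(object))
    if (!one(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(msg)) return(msg)
  if (object@rCutoff < 0 || object@rCutoff > 1) msg <- c(msg, "rCutoff must be in [0, 1]")
  if (object@pCutoff <= 0 || object@pCutoff > 1) msg <- c(msg, "pCutoff must be in (0, 1]")
  if (object@numCut < 1) msg <- c(msg, "numCut must be >= 1")
  if (object@seqsClusterAnno < 10) msg <- c(msg, "seqsClusterAnno must be >= 10 after clamping")
  if (object@occupancy < 0 || object@occupancy > 100) msg <- c(msg, "occupancy must be in [0, 100]")
  if (object@evalueCutoff < 0) msg <- c(msg, "evalueCutoff must be >= 0")
  if (object@minOcgSize < 1 || object@minCoexpSpecies < 1) msg <- c(msg, "minOcgSize and minCoexpSpecies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a PipelineParams object
#'
#' @param rCutoff,pCutoff,numCut,minExpCutoff,evalueCutoff,scoreCutoff,lenCutoff,simCutoff,occupancy,seqsClusterAnno,minOcgSize,minCoexpSpecies,seed see \linkS4class{PipelineParams}.
#' @return A validated \linkS4class{PipelineParams} object.  A
#'   \code{seqsClusterAnno} below 10 is raised to 10 with a warning.
#' @examples
#' pipelineParams()
#' pipelineParams(rCutoff = 0.8, numCut = 50)
#' @export
pipelineParams <- function(rCutoff = 0.7, pCutoff = 0.05, numCut = 100,
                           minExpCutoff = 30, evalueCutoff = 1e-5,
                           scoreCutoff = 100, lenCutoff = 100, simCutoff = 80,
                           occupancy = 10, seqsClusterAnno = 50,
                           minOcgSize = 10, minCoexpSpecies = 3, seed = 1L) {
  if (seqsClusterAnno < 10) {
    warning("seqsClusterAnno below 10% is not allowed; using 10")
    seqsClusterAnno <- 10
  }
  new("PipelineParams",
      rCutoff = as.numeric(rCutoff), pCutoff = as.numeric(pCutoff),
      numCut = as.numeric(numCut), minExpCutoff = as.numeric(minExpCutoff),
      evalueCutoff = as.numeric(evalueCutoff), scoreCutoff = as.numeric(scoreCutoff),
      lenCutoff = as.numeric(lenCutoff), simCutoff = as.numeric(simCutoff),
      occupancy = as.numeric(occupancy), seqsClusterAnno = as.numeric(seqsClusterAnno),
      minOcgSize = as.numeric(minOcgSize), minCoexpSpecies = as.numeric(minCoexpSpecies),
      seed = as.integer(seed))
}

setMethod("show", "PipelineParams", function(object) {
  cat("PipelineParams\n")
  for (s in slotNames(object))
    cat(sprintf("  %-16s %g\n", s, slot(object, s)))
})

#' Per-species input data
#'
#' Bundles one species' TPM expression matrix (genes x samples), its coding
#' sequences and its bait gene IDs.  Gene IDs are expected to be cleaned
#' (see \code{\link{cleanGeneId}}) and to match between the matrix and the
#' CDS set; every bait must be present in both.
#'
#' @slot speciesId single character label.
#' @slot tpm numeric matrix, genes in rows, samples in columns.
#' @slot cds \link[Biostrings]{DNAStringSet} of coding sequences.
#' @slot baits character vector of bait gene IDs.
#' @export
setClass("SpeciesData", representation(
  speciesId = "character",
  tpm = "matrix",
  cds = "DNAStringSet",
  baits = "character"
))

setValidity("SpeciesData", function(object) {
  msg <- character()
  if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
    msg <- c(msg, "speciesId must be a single non-empty string")
  g <- rownames(object@tpm)
  s <- colnames(object@tpm)
  if (is.null(g) || is.null(s)) msg <- c(msg, "tpm must have gene rownames and sample colnames")
  if (!is.null(g) && anyDuplicated(g)) msg <- c(msg, "duplicate gene IDs in tpm")
  if (!is.null(s) && anyDuplicated(s)) msg <- c(msg, "duplicate sample IDs in tpm")
  if (!all(is.finite(object@tpm)) || any(object@tpm < 0))
    msg <- c(msg, "tpm values must be finite and >= 0")
  if (anyDuplicated(names(object@cds))) msg <- c(msg, "duplicate sequence IDs in cds")
  missTpm <- setdiff(object@baits, g)
  missCds <- setdiff(object@baits, names(object@cds))
  if (length(missTpm))
    msg <- c(msg, sprintf("bait(s) %s of species '%s' absent from count table",
                          paste(missTpm, collapse = ", "), object@speciesId))
  if (length(missCds))
    msg <- c(msg, sprintf("bait(s) %s of species '%s' absent from CDS file",
                          paste(missCds, collapse = ", "), object@speciesId))
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesData object
#'
#' @param speciesId species label.
#' @param tpm numeric matrix of TPM values (genes x samples).
#' @param cds \link[Biostrings]{DNAStringSet} of coding sequences.
#' @param baits character vector of bait IDs.
#' @return A validated \linkS4class{SpeciesData} object.
#' @export
speciesData <- function(speciesId, tpm, cds, baits) {
  new("SpeciesData", speciesId = speciesId, tpm = tpm,
      cds = cds, baits = as.character(baits))
}

setMethod("show", "SpeciesData", function(object) {
  cat(sprintf("SpeciesData '%s': %d genes x %d samples, %d CDS, %d bait(s)\n",
              object@speciesId, nrow(object@tpm), ncol(object@tpm),
              length(object@cds), length(object@baits)))
})

#' Species-level coexpression candidate set
#'
#' Result of \code{\link{coexpressionScan}}: one row per retained gene with
#' the bait it correlates best with, plus the baits themselves (tagged with
#' \code{r_s = 1} against themselves).
#'
#' @slot speciesId character label.
#' @slot hits data.frame with columns \code{gene_id}, \code{bait_id},
#'   \code{r_s}, \code{p_value}, \code{cumulative_tpm}, \code{is_bait}.
#' @slot baitIds character vector of the species' baits.
#' @slot nConstantSkipped number of genes skipped because their expression
#'   was constant across samples (Spearman undefined).
#' @export
setClass("CandidateSet", representation(
  speciesId = "character",
  hits = "data.frame",
  baitIds = "character",
  nConstantSkipped = "integer"
))

setValidity("CandidateSet", function(object) {
  need <- c("gene_id", "bait_id", "r_s", "p_value", "cumulative_tpm", "is_bait")
  if (!all(need %in% names(object@hits)))
    return(sprintf("hits must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@hits$gene_id)) return("duplicate gene_id in hits")
  if (any(abs(object@hits$r_s) > 1 + 1e-12)) return("|r_s| must be <= 1")
  TRUE
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet '%s': %d gene(s) (%d bait(s); %d constant gene(s) skipped)\n",
              object@speciesId, nrow(object@hits), length(object@baitIds),
              object@nConstantSkipped))
})

#' Set of Orthologous Coexpressed Groups (OCGs)
#'
#' Connected components of the filtered cross-species similarity graph that
#' survived the retention rules, ranked by coexpression ratio and labelled
#' "0000", "0001", ...
#'
#' @slot members data.frame with columns \code{label}, \code{seq_id},
#'   \code{species_id}, \code{is_coexp}, \code{best_r} (NA for members that
#'   entered via similarity search only).
#' @slot summary data.frame with one row per OCG: \code{label},
#'   \code{n_total}, \code{n_coexp}, \code{n_species_coexp}, \code{ratio}.
#' @export
setClass("OCGSet", representation(
  members = "data.frame",
  summary = "data.frame"
))

setValidity("OCGSet", function(object) {
  msg <- character()
  if (!all(c("label", "seq_id", "species_id", "is_coexp", "best_r") %in% names(object@members)))
    msg <- c(msg, "members lacks required columns")
  if (!all(c("label", "n_total", "n_coexp", "n_species_coexp", "ratio") %in% names(object@summary)))
    msg <- c(msg, "summary lacks required columns")
  if (length(msg)) return(msg)
  if (anyDuplicated(object@summary$label)) msg <- c(msg, "duplicate OCG labels")
  if (nrow(object@summary) &&
      (any(object@summary$ratio <= 0) || any(object@summary$ratio > 1)))
    msg <- c(msg, "ratio must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OCGSet", function(object) {
  cat(sprintf("OCGSet: %d OCG(s), %d member sequence(s)\n",
              nrow(object@summary), nrow(object@members)))
  if (nrow(object@summary)) {
    print(utils::head(object@summary, 5))
    if (nrow(object@summary) > 5) cat("  ...\n")
  }
})

#' @describeIn OCGSet-class number of OCGs in the set.
#' @param x,object an \code{OCGSet}.
#' @export
setMethod("length", "OCGSet", function(x) nrow(x@summary))

#' OCG summary table accessor
#' @param x an \linkS4class{OCGSet}.
#' @return data.frame with one row per OCG.
#' @export
ocgSummary <- function(x) x@summary

#' OCG member table accessor
#' @param x an \linkS4class{OCGSet}.
#' @param label optional OCG label to subset to.
#' @return data.frame of members.
#' @export
ocgMembers <- function(x, label = NULL) {
  m <- x@members
  if (!is.null(label)) m <- m[m$label %in% label, , drop = FALSE]
  m
}

#' Species ID accessor
#' @param x a \linkS4class{SpeciesData} or \linkS4class{CandidateSet}.
#' @export
speciesId <- function(x) x@speciesId

#' Candidate hit table accessor
#' @param x a \linkS4class{CandidateSet}.
#' @return data.frame of retained genes and their best-bait correlations.
#' @export
candidateHits <- function(x) x@hits
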