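#' Annotation subsample size
#'
#' Number of sequences drawn from an OCG for functional annotation: the
#' requested percentage of the OCG (values below 10\% are raised to 10\%),
#' rounded up, but never fewer than five sequences, and never more than the
#' OCG holds.
#'
#' @param nTotal number of sequences in the OCG.
#' @param pct requested percentage (default 50).
#' @return integer sample size.
#' @examples
#' subsampleSize(100, 50)  # 50
#' subsampleSize(20, 5)    # raised to 10%, then to the 5-sequence floor: 5
#' subsampleSize(4, 50)    # capped at 4
#' @export
subsampleSize <- function(nTotal, pct = 50) {
  stopifnot(nTotal >= 1, pct >= 0)
  effPct <- max(pct, 10)
  size <- max(ceiling(effPct / 100 * nTotal), 5)
  as.integer(min(size, nTotal))
}

#' Random member subsample of an OCG
#'
#' Uniform sampling without replacement, reproducible for a fixed seed.
#'
#' @param ids character vector of member IDs.
#' @param size sample size (\code{<= length(ids)}).
#' @param seed integer seed.
#' @return character vector of sampled IDs.
#' @export
subsampleMembers <- function(ids, size, seed) {
  stopifnot(size <= length(ids))
  if (size == length(ids)) return(ids)
  withSeed(seed, sample(ids, size))
}

#' Functionally annotate one OCG
#'
#' Each sampled sequence is searched against the reference peptide set; its
#' best hit is the reference with the maximal bit score (ties: smallest
#' reference ID).  The OCG annotation is the modal best-hit reference (ties:
#' lexicographically smallest); the reliability score is the fraction of
#' sampled sequences voting for it.  Sequences with no hit vote for the
#' sentinel \code{"unannotated"}, so reliability reflects annotation
#' coverage honestly.
#'
#' @param sampled \link[Biostrings]{AAStringSet} of sampled members.
#' @param reference \link[Biostrings]{AAStringSet} of reference peptides.
#' @param annoTable optional named character vector mapping reference IDs to
#'   descriptions (see \code{\link{readAnnotationTable}}).
#' @param engine a search engine (see \code{\link{searchEngine}}).
#' @return list with \code{ref_id}, \code{text}, \code{reliability},
#'   \code{n_sampled}, \code{votes} (named integer vector).
#' @export
annotateOcg <- function(sampled, reference, annoTable = NULL,
                        engine = searchEngine("builtin")) {
  if (!length(sampled)) stopf("empty annotation sample")
  if (!length(reference)) stopf("empty reference set")
  hits <- runSearch(engine, sampled, reference)
  votes <- vapply(names(sampled), function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    if (!nrow(h)) return("unannotated")
    h$subject_id[order(-h$bitscore, h$subject_id)][1]
  }, character(1))
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  win <- sort(winners)[1]
  text <- if (win == "unannotated") "" else
    if (!is.null(annoTable) && win %in% names(annoTable)) unname(annoTable[[win]]) else ""
  list(ref_id = win, text = text,
       reliability = as.numeric(max(tab)) / length(sampled),
       n_sampled = length(sampled),
       votes = c(table(votes)))
}

#' Annotate every OCG of a set
#'
#' Applies \code{\link{subsampleSize}}, \code{\link{subsampleMembers}} and
#' \code{\link{annotateOcg}} per OCG.  The per-OCG sampling seed is derived
#' deterministically from \code{params@seed} and the OCG rank so results are
#' reproducible and independent of evaluation order.
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param seqs \link[Biostrings]{AAStringSet} of member peptides (plain IDs).
#' @param reference reference peptides, or NULL to skip annotation.
#' @param annoTable optional named character vector of descriptions.
#' @param engine a search engine.
#' @param params a \linkS4class{PipelineParams}.
#' @return data.frame with one row per OCG: \code{label}, \code{n_total},
#'   \code{n_coexp}, \code{ratio}, \code{n_sampled},
#'   \code{annotation_ref_id}, \code{annotation_text}, \code{reliability};
#'   annotation columns are empty when \code{reference} is NULL.
#' @export
annotateOcgs <- function(ocgs, seqs, reference = NULL, annoTable = NULL,
                         engine = searchEngine("builtin"),
                         params = pipelineParams()) {
  sm <- ocgSummary(ocgs)
  out <- data.frame(label = sm$label, n_total = sm$n_total,
                    n_coexp = sm$n_coexp, ratio = sm$ratio,
                    n_sampled = NA_integer_,
                    annotation_ref_id = "", annotation_text = "",
                    reliability = NA_real_, stringsAsFactors = FALSE)
  if (is.null(reference)) return(out)
  for (k in seq_len(nrow(sm))) {
    m <- ocgMembers(ocgs, sm$label[k])
    size <- subsampleSize(nrow(m), params@seqsClusterAnno)
    picked <- subsampleMembers(sort(m$seq_id), size, params@seed + k)
    ann <- annotateOcg(seqs[picked], reference, annoTable, engine)
    out$n_sampled[k] <- ann$n_sampled
    out$annotation_ref_id[k] <- ann$ref_id
    out$annotation_text[k] <- ann$text
    out$reliability[k] <- ann$reliability
  }
  out
}

#' Write the functional annotation table
#'
#' Tab-separated, one row per OCG in rank order: label, sequence counts,
#' coexpression ratio, winning annotation and its reliability score.  The
#' table is written (with empty annotation columns) even when annotation was
#' disabled.
#'
#' @param annotations data.frame from \code{\link{annotateOcgs}}.
#' @param path output path (conventionally \code{functional_annotation.txt}).
#' @return \code{path}, invisibly.
#' @export
writeFunctionalAnnotation <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
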