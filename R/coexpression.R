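#' Spearman rank correlation with two-sided p-value
#'
#' Computes the Spearman coefficient on average (tie-corrected) ranks and the
#' two-sided p-value from the t approximation
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom.  For
#' \eqn{|r| = 1} the p-value is 0.  If either vector is constant the
#' coefficient is undefined and both values are returned as \code{NA}
#' (callers skip such genes rather than erroring).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return named numeric vector \code{c(r, p)}.
#' @examples
#' spearmanTest(1:5, c(2, 1, 4, 3, 5))  # r = 0.8
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(c(r = NA_real_, p = NA_real_))
  r <- stats::cor(rx, ry)
  c(r = r, p = spearmanPValue(r, n))
}

# Two-sided p-value of a Spearman coefficient via the t approximation.
spearmanPValue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                     lower.tail = FALSE))
  unname(p)
}

#' Cumulative expression of a gene
#'
#' Sum of TPM values over all samples; used as the minimum-expression filter
#' of the coexpression scan.
#'
#' @param species a \linkS4class{SpeciesData} object (or a bare TPM matrix).
#' @param geneId gene identifier.
#' @return non-negative numeric scalar.
#' @export
cumulativeExpression <- function(species, geneId) {
  tpm <- if (is(species, "SpeciesData")) species@tpm else species
  if (!geneId %in% rownames(tpm))
    stopf("gene '%s' not present in expression matrix", geneId)
  sum(tpm[geneId, ])
}

#' Coexpression scan of one species against its baits
#'
#' Correlates every gene with every bait by Spearman rank correlation and
#' retains a gene iff (a) its coefficient against at least one bait reaches
#' \code{rCutoff}, (b) the p-value for that bait is at most \code{pCutoff},
#' and (c) its cumulative TPM over all samples reaches \code{minExpCutoff}.
#' Surviving genes are ranked by their best coefficient over all baits
#' (ties: lexicographic gene ID) and truncated to \code{numCut}.  The baits
#' themselves are then appended as members with \code{r_s = 1} against
#' themselves, regardless of the filters.  All thresholds are inclusive.
#'
#' Genes with constant expression have undefined rank correlation and are
#' skipped; their count is recorded in the result.
#'
#' @param species a \linkS4class{SpeciesData} object.
#' @param params a \linkS4class{PipelineParams} object.
#' @param adjustP apply Benjamini-Hochberg correction per bait before the
#'   p-value filter.  Off by default: the p-value used is the plain two-sided
#'   test p-value per (gene, bait) pair.
#' @return a \linkS4class{CandidateSet}.
#' @export
coexpressionScan <- function(species, params = pipelineParams(), adjustP = FALSE) {
  stopifnot(is(species, "SpeciesData"), is(params, "PipelineParams"))
  tpm <- species@tpm
  baits <- species@baits
  if (ncol(tpm) < 3L)
    stopf("species '%s' has %d sample(s); need at least 3", species@speciesId, ncol(tpm))
  miss <- setdiff(baits, rownames(tpm))
  if (length(miss))
    stopf("bait(s) %s absent from count table of species '%s'",
          paste(miss, collapse = ", "), species@speciesId)

  n <- ncol(tpm)
  ranks <- t(apply(tpm, 1L, rank))          # genes x samples
  sds <- apply(ranks, 1L, stats::sd)
  constant <- sds == 0
  genes <- setdiff(rownames(tpm)[!constant], baits)
  nSkipped <- sum(constant & !rownames(tpm) %in% baits)

  hits <- data.frame(gene_id = character(), bait_id = character(),
                     r_s = numeric(), p_value = numeric(),
                     cumulative_tpm = numeric(), is_bait = logical(),
                     stringsAsFactors = FALSE)
  useBaits <- baits[!constant[baits]]
  if (length(genes) && length(useBaits)) {
    rmat <- stats::cor(t(ranks[genes, , drop = FALSE]),
                       t(ranks[useBaits, , drop = FALSE]))   # genes x baits
    pmat <- matrix(spearmanPValue(rmat, n), nrow = nrow(rmat),
                   dimnames = dimnames(rmat))
    if (adjustP) pmat <- apply(pmat, 2L, stats::p.adjust, method = "BH")
    pass <- rmat >= params@rCutoff & pmat <= params@pCutoff
    cum <- rowSums(tpm[genes, , drop = FALSE])
    cand <- lapply(which(rowSums(pass) > 0 & cum >= params@minExpCutoff),
                   function(i) {
      ok <- which(pass[i, ])
      best <- ok[order(-rmat[i, ok], useBaits[ok])][1]
      data.frame(gene_id = genes[i], bait_id = useBaits[best],
                 r_s = rmat[i, best], p_value = pmat[i, best],
                 cumulative_tpm = cum[i], is_bait = FALSE,
                 stringsAsFactors = FALSE)
    })
    if (length(cand)) {
      hits <- do.call(rbind, cand)
      hits <- hits[order(-hits$r_s, hits$gene_id), , drop = FALSE]
      if (nrow(hits) > params@numCut)
        hits <- hits[seq_len(params@numCut), , drop = FALSE]
    }
  }
  baitRows <- data.frame(gene_id = baits, bait_id = baits, r_s = 1.0,
                         p_value = 0.0,
                         cumulative_tpm = rowSums(tpm[baits, , drop = FALSE]),
                         is_bait = TRUE, stringsAsFactors = FALSE)
  hits <- rbind(hits, baitRows)
  rownames(hits) <- NULL
  new("CandidateSet", speciesId = species@speciesId, hits = hits,
      baitIds = baits, nConstantSkipped = as.integer(nSkipped))
}

#' Write a per-species candidate table
#'
#' @param candidates a \linkS4class{CandidateSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(candidates, path) {
  write.table(candidates@hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
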