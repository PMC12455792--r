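#' Parse a pipeline config file
#'
#' The config file lists one dataset (species) per row as four comma-separated
#' fields without a header: species ID, path to the TPM count table (TSV),
#' path to the CDS multi-FASTA, path to the bait ID file (one ID per line).
#'
#' @param path path to the config file.
#' @return data.frame with columns \code{species_id}, \code{tpm_path},
#'   \code{cds_path}, \code{bait_path}; one row per non-empty config row,
#'   order preserved.
#' @examples
#' cfg <- tempfile()
#' writeLines("SpA,/tmp/a.tsv,/tmp/a.fasta,/tmp/a.baits.txt", cfg)
#' parseConfig(cfg)
#' @export
parseConfig <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stopf("config file '%s' is empty", path)
  rows <- lapply(keep, function(i) {
    f <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(f) != 4L)
      stopf("config row %d has %d comma-separated field(s), expected 4", i, length(f))
    f
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("species_id", "tpm_path", "cds_path", "bait_path")
  if (anyDuplicated(df$species_id))
    stopf("duplicate species ID(s) in config: %s",
          paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "))
  empty <- !nzchar(df$species_id) | !nzchar(df$tpm_path) |
    !nzchar(df$cds_path) | !nzchar(df$bait_path)
  if (any(empty)) stopf("config row %d has an empty field", keep[which(empty)[1]])
  rownames(df) <- NULL
  df
}

#' Write a pipeline config file
#'
#' Inverse of \code{\link{parseConfig}}.
#'
#' @param entries data.frame as returned by \code{\link{parseConfig}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(entries, path) {
  writeLines(paste(entries$species_id, entries$tpm_path,
                   entries$cds_path, entries$bait_path, sep = ","), path)
  invisible(path)
}

#' Clean a gene identifier
#'
#' Replaces every character outside \code{[A-Za-z0-9._-]} with an underscore
#' so IDs are safe for FASTA headers, Newick labels and file names.  The
#' transformation is deterministic, idempotent and length-preserving.
#'
#' @param rawId character vector of identifiers.
#' @return cleaned character vector of the same length.
#' @examples
#' cleanGeneId("AT1G56650.1")
#' cleanGeneId("gene|001;v2")
#' @export
cleanGeneId <- function(rawId) {
  if (!length(rawId) || any(is.na(rawId)) || any(!nzchar(rawId)))
    stopf("gene IDs must be non-empty")
  gsub("[^A-Za-z0-9._-]", "_", rawId)
}

#' Reduce isoforms to one representative per gene
#'
#' Keeps, for every gene, the transcript with the longest coding sequence;
#' ties are broken by the lexicographically smallest sequence ID.
#'
#' @param cds \link[Biostrings]{DNAStringSet} of transcript CDS.
#' @param geneOf named character vector mapping every sequence ID to its gene
#'   label.
#' @return \code{DNAStringSet} with exactly one record per gene label, in the
#'   input order of the retained records.
#' @examples
#' library(Biostrings)
#' cds <- DNAStringSet(c(G.1 = "ATGAAA", G.2 = "ATG"))
#' reduceIsoforms(cds, c(G.1 = "G", G.2 = "G"))
#' @export
reduceIsoforms <- function(cds, geneOf) {
  ids <- names(cds)
  miss <- setdiff(ids, names(geneOf))
  if (length(miss))
    stopf("sequence ID(s) missing from gene mapping: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  genes <- unname(geneOf[ids])
  len <- width(cds)
  keep <- unlist(lapply(split(seq_along(ids), genes), function(idx) {
    best <- idx[len[idx] == max(len[idx])]
    best[order(ids[best])][1]
  }), use.names = FALSE)
  cds[sort(keep)]
}

#' Sample quality filter for RNA-seq count data
#'
#' A sample is retained iff its total read count is at least one million and
#' the 100 transcripts with the highest counts jointly account for at least
#' 20\% of its reads.  This is an optional preprocessing step applied before
#' TPM tables enter the pipeline.
#'
#' @param totalReads named numeric vector, total reads per sample.
#' @param transcriptCounts numeric matrix of per-transcript read counts,
#'   transcripts in rows, samples in columns; column names must cover the
#'   same samples as \code{totalReads}.
#' @param minReads,topN,minTopFraction filter constants (defaults 1e6, 100,
#'   0.20).
#' @return character vector of retained sample names, in input order.
#' @export
qcFilterSamples <- function(totalReads, transcriptCounts,
                            minReads = 1e6, topN = 100, minTopFraction = 0.20) {
  samples <- names(totalReads)
  if (is.null(samples) || is.null(colnames(transcriptCounts)))
    stopf("both inputs must carry sample names")
  miss <- union(setdiff(samples, colnames(transcriptCounts)),
                setdiff(colnames(transcriptCounts), samples))
  if (length(miss))
    stopf("sample(s) missing from one of the inputs: %s", paste(miss, collapse = ", "))
  keep <- vapply(samples, function(s) {
    if (totalReads[[s]] < minReads) return(FALSE)
    cnt <- sort(transcriptCounts[, s], decreasing = TRUE)
    top <- sum(cnt[seq_len(min(topN, length(cnt)))])
    top / totalReads[[s]] >= minTopFraction
  }, logical(1))
  samples[keep]
}

#' Read a TPM count table
#'
#' Expects a tab-separated table with gene IDs in the first column and a
#' header row of sample names.  Gene IDs are cleaned via
#' \code{\link{cleanGeneId}}.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stopf("count table '%s' does not exist", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2L) stopf("count table '%s' has no sample columns", path)
  ids <- cleanGeneId(as.character(df[[1]]))
  if (anyDuplicated(ids))
    stopf("duplicate gene ID(s) in count table '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stopf("non-numeric expression value(s) in column(s) %s of '%s'",
          paste(names(vals)[bad], collapse = ", "), path)
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read a CDS FASTA file
#'
#' Sequence IDs are taken as the first whitespace-delimited token of each
#' header and cleaned via \code{\link{cleanGeneId}}.
#'
#' @param path path to the FASTA file.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file '%s' does not exist", path)
  x <- readDNAStringSet(path)
  names(x) <- cleanGeneId(sub("\\s.*$", "", names(x)))
  if (anyDuplicated(names(x)))
    stopf("duplicate sequence ID(s) in '%s'", path)
  x
}

#' Read a bait ID file
#'
#' One sequence ID per line; blank lines are ignored; IDs are cleaned.
#'
#' @param path path to the text file.
#' @return character vector of bait IDs.
#' @export
readBaits <- function(path) {
  if (!file.exists(path)) stopf("bait file '%s' does not exist", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stopf("bait file '%s' contains no IDs", path)
  cleanGeneId(ids)
}

#' Read a two-column functional annotation table
#'
#' Tab-separated; first column reference sequence IDs, second column the
#' functional description.
#'
#' @param path path to the TSV file.
#' @return named character vector mapping reference ID to description.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stopf("annotation table '%s' does not exist", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "", col.names = c("id", "fn"),
                   fill = FALSE)
  setNames(as.character(df$fn), cleanGeneId(as.character(df$id)))
}

#' Load one species' data as described by a config entry
#'
#' Reads the count table, CDS FASTA and bait list and validates that every
#' bait is present in both the count table and the CDS set (a missing bait is
#' a hard error naming the ID and species).
#'
#' @param entry one-row data.frame (a row of \code{\link{parseConfig}} output).
#' @return a \linkS4class{SpeciesData} object.
#' @export
loadSpeciesData <- function(entry) {
  tpm <- readCountTable(entry$tpm_path)
  cds <- readCdsFasta(entry$cds_path)
  baits <- readBaits(entry$bait_path)
  speciesData(entry$species_id, tpm, cds, baits)
}
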