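#' Translate coding sequences to peptides
#'
#' Frame +1, standard genetic code.  A trailing remainder of 1-2 nt is
#' ignored, a trailing stop codon is stripped, and internal stop codons are
#' rendered as \code{X} with a warning (one per offending sequence set).
#' Ambiguous codons also translate to \code{X}.
#'
#' @param cds \link[Biostrings]{DNAStringSet} (or single character string).
#' @return \link[Biostrings]{AAStringSet} of the same length and names.
#' @examples
#' translateCds(Biostrings::DNAStringSet(c(g = "ATGGCTTAA")))  # "MA"
#' @export
translateCds <- function(cds) {
  if (is.character(cds)) cds <- DNAStringSet(cds)
  if (any(width(cds) < 3L))
    stopf("coding sequence(s) shorter than 3 nt: %s",
          paste(utils::head(names(cds)[width(cds) < 3L], 5), collapse = ", "))
  trimmed <- subseq(cds, 1L, 3L * (width(cds) %/% 3L))
  aa <- as.character(suppressWarnings(
    translate(trimmed, if.fuzzy.codon = "solve", no.init.codon = TRUE)))
  aa <- sub("\\*$", "", aa)
  internal <- grepl("*", aa, fixed = TRUE)
  if (any(internal))
    warnf("internal stop codon(s) translated as 'X' in: %s",
          paste(utils::head(names(cds)[internal], 5), collapse = ", "))
  aa <- gsub("*", "X", aa, fixed = TRUE)
  out <- AAStringSet(aa)
  names(out) <- names(cds)
  out
}

# Karlin-Altschul gapped constants for BLOSUM62, gap open 11 / extend 1.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Built-in exact local-alignment search engine
#'
#' Smith-Waterman local alignment of every query against every subject with
#' BLOSUM62, gap open 11 / extension 1.  Scores are converted to bit scores
#' via the standard gapped Karlin-Altschul constants
#' (\eqn{\lambda = 0.267}, \eqn{K = 0.041}) and e-values as
#' \eqn{m \cdot n \cdot 2^{-bits}} with \eqn{m} the query length and \eqn{n}
#' the total residue count of the subject set.  Percent identity, alignment
#' length, mismatches, gap openings and 1-based coordinates are measured on
#' the traceback.  Pairs with raw score 0 are omitted.  The constants are
#' approximate: bit scores and e-values are comparable between runs of this
#' engine, not to an external aligner's.
#'
#' @param queries,subjects \link[Biostrings]{AAStringSet}s.
#' @return data.frame in tabular-6 column order (\code{query_id},
#'   \code{subject_id}, \code{pident}, \code{aln_length}, \code{mismatches},
#'   \code{gap_opens}, \code{q_start}, \code{q_end}, \code{s_start},
#'   \code{s_end}, \code{evalue}, \code{bitscore}).
#' @export
builtinSearch <- function(queries, subjects) {
  if (!length(queries) || !length(subjects))
    stopf("queries and subjects must be non-empty")
  empty <- width(queries) == 0L
  if (any(empty)) {
    warnf("skipping empty query sequence(s): %s",
          paste(names(queries)[empty], collapse = ", "))
    queries <- queries[!empty]
  }
  emptyS <- width(subjects) == 0L
  if (any(emptyS)) {
    warnf("skipping empty subject sequence(s): %s",
          paste(names(subjects)[emptyS], collapse = ", "))
    subjects <- subjects[!emptyS]
  }
  dbLen <- sum(width(subjects))
  res <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    pa <- pairwiseAlignment(pattern = subjects, subject = queries[[i]],
                            type = "local", substitutionMatrix = "BLOSUM62",
                            gapOpening = 11, gapExtension = 1)
    s <- score(pa)
    keep <- which(s > 0)
    if (!length(keep)) next
    alnP <- as.character(pattern(pa))[keep]      # subject rows
    alnS <- as.character(subject(pa))[keep]      # query rows
    alnLen <- nchar(alnP)
    matches <- nmatch(pa)[keep]
    mism <- nmismatch(pa)[keep]
    gapOpens <- countGapRuns(alnP) + countGapRuns(alnS)
    bits <- (.KA_LAMBDA * s[keep] - log(.KA_K)) / log(2)
    evalue <- width(queries)[i] * dbLen * 2^(-bits)
    res[[i]] <- data.frame(
      query_id = names(queries)[i],
      subject_id = names(subjects)[keep],
      pident = 100 * matches / alnLen,
      aln_length = alnLen,
      mismatches = mism,
      gap_opens = gapOpens,
      q_start = start(subject(pa))[keep],
      q_end = end(subject(pa))[keep],
      s_start = start(pattern(pa))[keep],
      s_end = end(pattern(pa))[keep],
      evalue = evalue,
      bitscore = bits,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- emptyHitTable()
  rownames(out) <- NULL
  out
}

emptyHitTable <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Protein search engine constructor
#'
#' A search engine maps a query and a subject peptide set to a table of
#' similarity hits in tabular-6 form, deterministically for fixed inputs.
#' \code{"builtin"} (the default everywhere) is the exact Smith-Waterman
#' engine of \code{\link{builtinSearch}} and needs no external binary.
#' \code{"diamond"} and \code{"blastp"} shell out to DIAMOND or NCBI BLAST+
#' with default sensitivity, writing the inputs to a temporary directory and
#' parsing the tabular-6 output.
#'
#' @param name one of \code{"builtin"}, \code{"diamond"}, \code{"blastp"}.
#' @param path path to the external binary (defaults to the name on
#'   \code{PATH}).
#' @return an object of class \code{SearchEngine}.
#' @export
searchEngine <- function(name = c("builtin", "diamond", "blastp"), path = NULL) {
  name <- match.arg(name)
  fun <- switch(name,
    builtin = builtinSearch,
    diamond = function(q, s) externalSearch(q, s, "diamond", path),
    blastp = function(q, s) externalSearch(q, s, "blastp", path))
  structure(list(name = name, fun = fun), class = "SearchEngine")
}

#' Run a search engine
#' @param engine a \code{SearchEngine} (see \code{\link{searchEngine}}).
#' @param queries,subjects \link[Biostrings]{AAStringSet}s.
#' @return tabular-6 data.frame of hits.
#' @export
runSearch <- function(engine, queries, subjects) {
  stopifnot(inherits(engine, "SearchEngine"))
  engine$fun(queries, subjects)
}

# Shell out to diamond blastp or NCBI blastp; both emit tabular-6.
externalSearch <- function(queries, subjects, tool, path = NULL) {
  bin <- if (is.null(path)) Sys.which(tool) else path
  if (!nzchar(bin) || !file.exists(bin))
    stopf("'%s' binary not found; install it or use the builtin engine", tool)
  dir <- tempfile("simsearch")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  qf <- file.path(dir, "query.fasta")
  sf <- file.path(dir, "db.fasta")
  out <- file.path(dir, "hits.tsv")
  writeXStringSet(queries, qf)
  writeXStringSet(subjects, sf)
  if (tool == "diamond") {
    db <- file.path(dir, "db")
    system2(bin, c("makedb", "--in", sf, "-d", db), stdout = FALSE, stderr = FALSE)
    system2(bin, c("blastp", "-q", qf, "-d", db, "-o", out, "--outfmt", "6"),
            stdout = FALSE, stderr = FALSE)
  } else {
    mk <- Sys.which("makeblastdb")
    if (!nzchar(mk)) stopf("'makeblastdb' not found on PATH")
    system2(mk, c("-in", sf, "-dbtype", "prot"), stdout = FALSE, stderr = FALSE)
    system2(bin, c("-query", qf, "-db", sf, "-outfmt", "6", "-out", out),
            stdout = FALSE, stderr = FALSE)
  }
  if (!file.exists(out)) stopf("%s produced no output", tool)
  parseTabular6(out)
}

#' Parse a tabular-6 similarity file
#'
#' Standard 12-column BLAST/DIAMOND tabular output (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore).  IDs are
#' cleaned via \code{\link{cleanGeneId}}.
#'
#' @param path path to the file.
#' @return data.frame of hits (see \code{\link{builtinSearch}} for columns);
#'   empty file gives an empty table.
#' @export
parseTabular6 <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyHitTable())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stopf("line %d of '%s' has %d column(s), expected 12",
          which(nf != 12L)[1], path, nf[nf != 12L][1])
  m <- do.call(rbind, fields)
  data.frame(query_id = cleanGeneId(m[, 1]), subject_id = cleanGeneId(m[, 2]),
             pident = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
             mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
             q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
             s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             stringsAsFactors = FALSE)
}

#' Write hits in tabular-6 form
#' @param hits data.frame of hits.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTabular6 <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Filter similarity hits
#'
#' A hit is retained iff its e-value does not exceed \code{evalueCutoff}
#' (inclusive), its bit score is strictly greater than \code{scoreCutoff},
#' its alignment length strictly exceeds \code{lenCutoff}, its percent
#' identity strictly exceeds \code{simCutoff}, and it is not a self-hit.
#' Order is preserved; applying the filter twice equals applying it once.
#'
#' @param hits data.frame of hits.
#' @param params a \linkS4class{PipelineParams}.
#' @return filtered data.frame.
#' @export
filterHits <- function(hits, params = pipelineParams()) {
  keep <- hits$evalue <= params@evalueCutoff &
    hits$bitscore > params@scoreCutoff &
    hits$aln_length > params@lenCutoff &
    hits$pident > params@simCutoff &
    hits$query_id != hits$subject_id
  hits[keep, , drop = FALSE]
}

#' Collect candidate genes and their cross-species orthologs
#'
#' Every coexpression candidate (including baits) of every species is used as
#' a query against every species' proteome; hits surviving
#' \code{\link{filterHits}} contribute their subject sequences.  The result
#' is the combined peptide collection: all candidates plus all matched
#' subjects, deduplicated, with per-sequence species and coexpression
#' metadata.  Candidates with an untranslatable CDS are dropped with a
#' warning.
#'
#' @param candidateSets list of \linkS4class{CandidateSet}, one per species.
#' @param speciesList list of \linkS4class{SpeciesData} in matching order.
#' @param engine a search engine (see \code{\link{searchEngine}}).
#' @param params a \linkS4class{PipelineParams}.
#' @return list with elements \code{seqs} (\code{AAStringSet}),
#'   \code{species} (named character), \code{isCoexp} (named logical),
#'   \code{bestR} (named numeric, NA for non-candidates).
#' @export
collectCandidateOrthologs <- function(candidateSets, speciesList,
                                      engine = searchEngine("builtin"),
                                      params = pipelineParams()) {
  ids <- vapply(speciesList, speciesId, character(1))
  names(speciesList) <- ids
  names(candidateSets) <- vapply(candidateSets, speciesId, character(1))
  if (!setequal(names(candidateSets), ids))
    stopf("candidate sets and species data do not cover the same species")

  proteomes <- lapply(speciesList, function(sp) {
    ok <- width(sp@cds) >= 3L
    if (!all(ok))
      warnf("species '%s': dropping %d sequence(s) shorter than one codon",
            sp@speciesId, sum(!ok))
    translateCds(sp@cds[ok])
  })

  queries <- AAStringSet()
  meta <- list()
  for (sid in ids) {
    hits <- candidateSets[[sid]]@hits
    have <- hits$gene_id %in% names(proteomes[[sid]])
    if (!all(have))
      warnf("species '%s': candidate(s) without translatable CDS dropped: %s",
            sid, paste(hits$gene_id[!have], collapse = ", "))
    hits <- hits[have, , drop = FALSE]
    q <- proteomes[[sid]][hits$gene_id]
    queries <- c(queries, q)
    meta[[sid]] <- data.frame(seq_id = hits$gene_id, species_id = sid,
                              best_r = hits$r_s, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)

  subjectsFound <- character()
  subjectSpecies <- character()
  if (length(queries)) {
    for (sid in ids) {
      hits <- filterHits(runSearch(engine, queries, proteomes[[sid]]), params)
      subj <- unique(hits$subject_id)
      new <- setdiff(subj, subjectsFound)
      subjectsFound <- c(subjectsFound, new)
      subjectSpecies <- c(subjectSpecies, rep(sid, length(new)))
    }
  }

  allIds <- unique(c(meta$seq_id, subjectsFound))
  species <- setNames(subjectSpecies, subjectsFound)
  species[meta$seq_id] <- meta$species_id
  isCoexp <- setNames(rep(FALSE, length(allIds)), allIds)
  isCoexp[meta$seq_id] <- TRUE
  bestR <- setNames(rep(NA_real_, length(allIds)), allIds)
  bestR[meta$seq_id] <- meta$best_r

  seqs <- AAStringSet()
  for (sid in ids) {
    take <- allIds[species[allIds] == sid]
    seqs <- c(seqs, proteomes[[sid]][intersect(names(proteomes[[sid]]), take)])
  }
  list(seqs = seqs, species = species[names(seqs)],
       isCoexp = isCoexp[names(seqs)], bestR = bestR[names(seqs)])
}

#' Write the combined candidate collection as FASTA
#'
#' Coexpression candidates carry the \code{_coexp} suffix in their headers;
#' similarity-search orthologs keep their plain IDs.
#'
#' @param collection result of \code{\link{collectCandidateOrthologs}}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeCollectionFasta <- function(collection, path) {
  seqs <- collection$seqs
  names(seqs) <- ifelse(collection$isCoexp, paste0(names(seqs), "_coexp"),
                        names(seqs))
  writeXStringSet(seqs, path)
  invisible(path)
}
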