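#' Global multiple alignment of an OCG
#'
#' \code{method = "builtin"} uses a center-star progressive alignment: the
#' center is the sequence maximizing the summed pairwise global alignment
#' score (BLOSUM62, gap open 11 / extension 1) against all others; every
#' other sequence is aligned to the center pairwise and the pairwise
#' alignments are merged on the center's coordinates ("once a gap, always a
#' gap").  Degapping any output row recovers the input sequence exactly.
#' \code{"mafft"} and \code{"muscle"} shell out to the external aligners
#' with their default parameters.
#'
#' @param seqs \link[Biostrings]{AAStringSet}, at least 2 sequences.
#' @param method one of \code{"builtin"}, \code{"mafft"}, \code{"muscle"}.
#' @param mafft,muscle path to the respective binary when not on \code{PATH}.
#' @return \link[Biostrings]{AAStringSet} of equal-width gapped rows, input
#'   names and order preserved.
#' @export
alignOcg <- function(seqs, method = c("builtin", "mafft", "muscle"),
                     mafft = NULL, muscle = NULL) {
  method <- match.arg(method)
  if (length(seqs) < 2L) stopf("alignment requires at least 2 sequences")
  switch(method,
         builtin = centerStarAlign(seqs),
         mafft = mafftAlign(seqs, mafft),
         muscle = muscleAlign(seqs, muscle))
}

centerStarAlign <- function(seqs) {
  n <- length(seqs)
  if (n == 2L) {
    pa <- pairwiseAlignment(seqs[1], seqs[[2]], type = "global",
                            substitutionMatrix = "BLOSUM62",
                            gapOpening = 11, gapExtension = 1)
    out <- AAStringSet(c(as.character(pattern(pa)), as.character(subject(pa))))
    names(out) <- names(seqs)
    return(out)
  }
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    s <- pairwiseAlignment(seqs[(i + 1L):n], seqs[[i]], type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 11, gapExtension = 1,
                           scoreOnly = TRUE)
    scores[i, (i + 1L):n] <- s
    scores[(i + 1L):n, i] <- s
  }
  center <- which.max(rowSums(scores))
  others <- setdiff(seq_len(n), center)
  L <- width(seqs)[center]
  pa <- pairwiseAlignment(seqs[others], seqs[[center]], type = "global",
                          substitutionMatrix = "BLOSUM62",
                          gapOpening = 11, gapExtension = 1)
  cAln <- strsplit(as.character(subject(pa)), "", fixed = TRUE)  # center rows
  oAln <- strsplit(as.character(pattern(pa)), "", fixed = TRUE)  # other rows
  # gap profile: gaps in the center row before residue j+1 (slot j+1 of L+1)
  profiles <- lapply(cAln, function(cc) {
    g <- integer(L + 1L)
    pos <- 0L
    for (ch in cc) {
      if (ch == "-") g[pos + 1L] <- g[pos + 1L] + 1L else pos <- pos + 1L
    }
    g
  })
  G <- Reduce(pmax, profiles)
  centerChars <- strsplit(as.character(seqs[[center]]), "", fixed = TRUE)[[1]]
  buildRow <- function(chars, profile) {
    # chars: the row aligned to the center's pairwise coordinates
    res <- character(0)
    pos <- 0L    # center residues consumed
    i <- 1L
    for (j in 0:L) {
      take <- profile[j + 1L]
      seg <- if (take > 0L) chars[i:(i + take - 1L)] else character(0)
      i <- i + take
      res <- c(res, seg, rep("-", G[j + 1L] - take))
      if (j < L) {
        res <- c(res, chars[i])
        i <- i + 1L
      }
    }
    paste(res, collapse = "")
  }
  rows <- character(n)
  rows[center] <- buildRow(centerChars,
                           integer(L + 1L))  # center has no own gaps
  for (k in seq_along(others))
    rows[others[k]] <- buildRow(oAln[[k]], profiles[[k]])
  out <- AAStringSet(rows)
  names(out) <- names(seqs)
  out
}

mafftAlign <- function(seqs, path = NULL) {
  bin <- if (is.null(path)) Sys.which("mafft") else path
  if (!nzchar(bin) || !file.exists(bin))
    stopf("MAFFT binary not found; provide it via the 'mafft' argument (--mafft)")
  dir <- tempfile("mafft"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inp <- file.path(dir, "in.fasta"); out <- file.path(dir, "out.fasta")
  writeXStringSet(seqs, inp)
  system2(bin, c("--quiet", inp), stdout = out, stderr = FALSE)
  aln <- readAAStringSet(out)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln[names(seqs)]
}

muscleAlign <- function(seqs, path = NULL) {
  bin <- if (is.null(path)) Sys.which("muscle") else path
  if (!nzchar(bin) || !file.exists(bin))
    stopf("MUSCLE binary not found; provide it via the 'muscle' argument (--muscle)")
  dir <- tempfile("muscle"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inp <- file.path(dir, "in.fasta"); out <- file.path(dir, "out.fasta")
  writeXStringSet(seqs, inp)
  system2(bin, c("-in", inp, "-out", out), stdout = FALSE, stderr = FALSE)
  aln <- readAAStringSet(out)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln[names(seqs)]
}

#' Trim alignment columns by occupancy
#'
#' Keeps exactly the columns whose fraction of non-gap characters is at
#' least \code{occupancyPct / 100} (inclusive boundary).  Row order is
#' preserved and the operation is idempotent.
#'
#' @param aln \link[Biostrings]{AAStringSet} of equal-width gapped rows.
#' @param occupancyPct percent occupancy cutoff (default 10).
#' @return trimmed \code{AAStringSet}.
#' @export
occupancyTrim <- function(aln, occupancyPct = 10) {
  if (length(unique(width(aln))) != 1L)
    stopf("alignment rows have unequal width")
  m <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  occ <- colMeans(m != "-")
  keep <- occ >= occupancyPct / 100
  if (!any(keep))
    stopf("occupancy trimming removed every column; lower the occupancy cutoff")
  out <- AAStringSet(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""))
  names(out) <- names(aln)
  out
}

#' Pairwise p-distances of an alignment
#'
#' Mismatches over shared non-gap columns per pair.  A pair with zero shared
#' columns receives 1.1 times the maximum observed distance, with a warning.
#'
#' @param aln \link[Biostrings]{AAStringSet} of equal-width gapped rows.
#' @return symmetric numeric distance matrix.
#' @export
pDistance <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  n <- nrow(m)
  ng <- m != "-"
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ng[i, ] & ng[j, ]
    if (!any(shared)) {
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- sum(m[i, shared] != m[j, shared]) / sum(shared)
    }
  }
  if (anyNA(d)) {
    warnf("sequence pair(s) share no aligned columns; distance set to 1.1 x maximum")
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- if (is.finite(mx) && mx > 0) 1.1 * mx else 1
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining; negative branch lengths arising from the NJ
#' algebra are clamped to zero and the tree is returned unrooted.  On an
#' additive distance matrix this recovers the generating topology.
#'
#' @param d symmetric numeric distance matrix with taxon dimnames.
#' @return an unrooted \code{phylo} object.
#' @export
njFromDistance <- function(d) {
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::unroot(tree)
}

#' Infer a per-OCG gene tree
#'
#' \code{method = "nj"} (the default) computes p-distances on the trimmed
#' alignment and runs standard neighbor-joining; negative branch lengths
#' arising from the NJ algebra are clamped to zero and the tree is returned
#' unrooted.  \code{"fasttree"} shells out to FastTree with \code{-wag
#' -nosupport}; \code{"raxml-ng"} uses the model \code{LG+G8+F};
#' \code{"iqtree"} runs with its model-selection defaults.
#'
#' @param aln \link[Biostrings]{AAStringSet} of at least 3 aligned rows.
#' @param method tree engine.
#' @param binary optional path to the external binary.
#' @return an \link[ape]{ape} \code{phylo} object (unrooted, leaf labels =
#'   row names).
#' @export
inferTree <- function(aln, method = c("nj", "fasttree", "raxml-ng", "iqtree"),
                      binary = NULL) {
  method <- match.arg(method)
  if (length(aln) < 3L) stopf("tree inference requires at least 3 sequences")
  if (method == "nj") return(njFromDistance(pDistance(aln)))
  dir <- tempfile("tree"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inp <- file.path(dir, "aln.fasta")
  writeXStringSet(aln, inp)
  if (method == "fasttree") {
    bin <- if (is.null(binary)) Sys.which("fasttree") else binary
    if (!nzchar(bin) || !file.exists(bin)) stopf("FastTree binary not found")
    nwk <- system2(bin, c("-wag", "-nosupport", inp), stdout = TRUE,
                   stderr = FALSE)
    return(ape::unroot(parseNewick(text = paste(nwk, collapse = ""))))
  }
  if (method == "raxml-ng") {
    bin <- if (is.null(binary)) Sys.which("raxml-ng") else binary
    if (!nzchar(bin) || !file.exists(bin)) stopf("raxml-ng binary not found")
    system2(bin, c("--msa", inp, "--model", "LG+G8+F", "--prefix",
                   file.path(dir, "rx"), "--threads", "1"),
            stdout = FALSE, stderr = FALSE)
    best <- file.path(dir, "rx.raxml.bestTree")
    if (!file.exists(best)) stopf("raxml-ng produced no tree")
    return(ape::unroot(parseNewick(best)))
  }
  bin <- if (is.null(binary)) Sys.which("iqtree") else binary
  if (!nzchar(bin) || !file.exists(bin)) stopf("IQ-TREE binary not found")
  system2(bin, c("-s", inp, "-nt", "1"), stdout = FALSE, stderr = FALSE)
  tf <- paste0(inp, ".treefile")
  if (!file.exists(tf)) stopf("IQ-TREE produced no tree")
  ape::unroot(parseNewick(tf))
}

#' Write a tree in Newick format
#'
#' @param tree an \link[ape]{ape} \code{phylo} object.
#' @param path output path (conventionally \code{<label>.tree}).
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Parse a Newick tree
#'
#' Validates parenthesis balance before parsing (reporting the character
#' position of the first imbalance) and preserves leaf labels, including the
#' \code{_coexp} suffix, verbatim.
#'
#' @param path path to a Newick file (or NULL when \code{text} is given).
#' @param text Newick string.
#' @return an \link[ape]{ape} \code{phylo} object.
#' @export
parseNewick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stopf("tree file '%s' does not exist", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stopf("malformed Newick: unmatched ')' at position %d", which(depth < 0)[1])
  if (length(depth) && depth[length(depth)] != 0)
    stopf("malformed Newick: %d unclosed '(' at end of input", depth[length(depth)])
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stopf("malformed Newick: could not be parsed")
  tree
}
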