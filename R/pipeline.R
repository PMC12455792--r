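#' Result of a full pipeline run
#'
#' @slot candidates list of \linkS4class{CandidateSet}, one per species.
#' @slot collection combined candidate/ortholog collection (see
#'   \code{\link{collectCandidateOrthologs}}).
#' @slot ocgs an \linkS4class{OCGSet}.
#' @slot annotations data.frame of per-OCG functional annotations.
#' @slot trees named list of \code{phylo} trees, one per OCG label.
#' @slot params the \linkS4class{PipelineParams} used.
#' @slot outDir output directory.
#' @export
setClass("PipelineRun", representation(
  candidates = "list",
  collection = "list",
  ocgs = "OCGSet",
  annotations = "data.frame",
  trees = "list",
  params = "PipelineParams",
  outDir = "character"
))

setMethod("show", "PipelineRun", function(object) {
  cat(sprintf("PipelineRun: %d species, %d OCG(s), output in '%s'\n",
              length(object@candidates), length(object@ocgs), object@outDir))
})

#' Run the full candidate-gene discovery pipeline
#'
#' Executes all stages in order: per-species Spearman coexpression scan
#' against the baits; cross-species protein similarity search to collect
#' orthologs of the candidates; all-vs-all search over the combined
#' collection; graph clustering into Orthologous Coexpressed Groups (OCGs)
#' with the retention rules; ranking by coexpression ratio; optional
#' majority-vote functional annotation against a reference peptide set;
#' per-OCG global alignment, occupancy trimming and gene-tree inference; and
#' the report files (run documentation with MD5 digests, species histogram,
#' per-OCG FASTA / alignment / tree / iTOL annotation files).
#'
#' @param config path to a config file (see \code{\link{parseConfig}}), or
#'   NULL when \code{speciesList} is given directly.
#' @param speciesList list of \linkS4class{SpeciesData} (alternative to
#'   \code{config}).
#' @param params a \linkS4class{PipelineParams}.
#' @param outDir output directory (created if needed).
#' @param engine search engine (see \code{\link{searchEngine}}).
#' @param alnMethod alignment method for \code{\link{alignOcg}}.
#' @param treeMethod tree method for \code{\link{inferTree}}.
#' @param reference optional reference peptide FASTA path or
#'   \code{AAStringSet} for functional annotation.
#' @param annoTable optional annotation table path or named character vector.
#' @param mafft,muscle optional paths to the external aligner binaries.
#' @param adjustP apply Benjamini-Hochberg correction in the coexpression
#'   scan (off by default).
#' @return a \linkS4class{PipelineRun}.
#' @export
runPipeline <- function(config = NULL, speciesList = NULL,
                        params = pipelineParams(), outDir = tempfile("ocgrun"),
                        engine = searchEngine("builtin"),
                        alnMethod = "builtin", treeMethod = "nj",
                        reference = NULL, annoTable = NULL,
                        mafft = NULL, muscle = NULL, adjustP = FALSE) {
  inputFiles <- character(0)
  if (is.null(speciesList)) {
    if (is.null(config)) stopf("provide either a config path or a speciesList")
    entries <- parseConfig(config)
    inputFiles <- c(config, entries$tpm_path, entries$cds_path,
                    entries$bait_path)
    speciesList <- lapply(seq_len(nrow(entries)), function(i)
      loadSpeciesData(entries[i, , drop = FALSE]))
  }
  if (is.character(reference)) {
    inputFiles <- c(inputFiles, reference)
    ref <- readAAStringSet(reference)
    names(ref) <- cleanGeneId(sub("\\s.*$", "", names(ref)))
    reference <- ref
  }
  if (is.character(annoTable) && length(annoTable) == 1L &&
      is.null(names(annoTable))) {
    inputFiles <- c(inputFiles, annoTable)
    annoTable <- readAnnotationTable(annoTable)
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  # Step 1: per-species coexpression scan
  candidates <- lapply(speciesList, coexpressionScan, params = params,
                       adjustP = adjustP)
  for (cs in candidates)
    writeCandidateTable(cs, file.path(outDir,
                                      paste0(speciesId(cs), ".candidates.tsv")))

  # Step 2: cross-species ortholog collection
  collection <- collectCandidateOrthologs(candidates, speciesList, engine,
                                          params)
  writeCollectionFasta(collection, file.path(outDir, "collection.fasta"))

  # Step 3: all-vs-all similarity graph and OCG extraction
  hits <- filterHits(runSearch(engine, collection$seqs, collection$seqs),
                     params)
  comps <- graphComponents(buildGraph(hits))
  kept <- filterOcgs(comps, collection$species, collection$isCoexp, params)
  ocgs <- rankOcgs(kept, collection$species, collection$isCoexp,
                   collection$bestR)
  writeOcgSummary(ocgs, file.path(outDir, "ocg_summary.tsv"))
  writeOcgFastas(ocgs, collection$seqs, outDir)

  # Step 4: functional annotation (optional; table written regardless)
  annotations <- annotateOcgs(ocgs, collection$seqs, reference, annoTable,
                              engine, params)
  writeFunctionalAnnotation(annotations,
                            file.path(outDir, "functional_annotation.txt"))

  # Steps 5-6: per-OCG alignment, occupancy trimming, tree
  trees <- list()
  for (lab in ocgSummary(ocgs)$label) {
    m <- ocgMembers(ocgs, lab)
    seqs <- collection$seqs[m$seq_id]
    names(seqs) <- ocgDisplayName(m$seq_id, m$is_coexp)
    aln <- alignOcg(seqs, method = alnMethod, mafft = mafft, muscle = muscle)
    writeXStringSet(aln, file.path(outDir, paste0(lab, ".aln.fasta")))
    trimmed <- occupancyTrim(aln, params@occupancy)
    writeXStringSet(trimmed, file.path(outDir,
                                       paste0(lab, ".aln.trimmed.fasta")))
    tree <- inferTree(trimmed, method = treeMethod)
    writeNewick(tree, file.path(outDir, paste0(lab, ".tree")))
    trees[[lab]] <- tree
    writeItolCoexpAnnotation(ocgs, lab,
                             file.path(outDir,
                                       paste0(lab, ".iTOL_coexp_annotation.txt")))
    writeItolGradientLabels(ocgs, lab,
                            file.path(outDir,
                                      paste0(lab, ".iTOL_gradient_labels.txt")),
                            rCutoff = params@rCutoff)
  }

  # Step 7: reports
  sampleCounts <- vapply(speciesList, function(sp) ncol(sp@tpm), integer(1))
  names(sampleCounts) <- vapply(speciesList, speciesId, character(1))
  speciesHistogram(candidates, sampleCounts,
                   htmlPath = file.path(outDir, "species_count_histogram.html"),
                   tsvPath = file.path(outDir, "species_count_histogram.tsv"))
  writeDocu(file.path(outDir, "docu.txt"), params, inputFiles,
            tools = c(engine = engine$name, alignment = alnMethod,
                      tree = treeMethod))
  new("PipelineRun", candidates = candidates, collection = collection,
      ocgs = ocgs, annotations = annotations, trees = trees,
      params = params, outDir = outDir)
}

#' Compare retained OCGs against a planted family truth table
#'
#' Maps every retained OCG to the families of its members and scores
#' precision (retained OCGs whose members all belong to one planted pathway
#' family) and recall (planted pathway families spanning at least
#' \code{minCoexpSpecies} species that are recovered as exactly one retained
#' OCG).
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param truth truth data.frame from \code{\link{generateFamilies}}.
#' @param pathwayFamilies indices of planted module families.
#' @return list with \code{precision}, \code{recall}, \code{ocgFamily}
#'   (named integer: dominant family per OCG, NA if mixed).
#' @export
scoreAgainstTruth <- function(ocgs, truth, pathwayFamilies) {
  sm <- ocgSummary(ocgs)
  fams <- setNames(truth$family, truth$seq_id)
  ocgFamily <- setNames(rep(NA_integer_, nrow(sm)), sm$label)
  pure <- logical(nrow(sm))
  for (k in seq_len(nrow(sm))) {
    f <- unique(fams[ocgMembers(ocgs, sm$label[k])$seq_id])
    if (length(f) == 1L && !is.na(f)) {
      ocgFamily[k] <- f
      pure[k] <- f %in% pathwayFamilies
    }
  }
  recovered <- vapply(pathwayFamilies, function(f)
    sum(ocgFamily == f, na.rm = TRUE) == 1L, logical(1))
  list(precision = if (nrow(sm)) mean(pure) else NA_real_,
       recall = mean(recovered),
       ocgFamily = ocgFamily)
}
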