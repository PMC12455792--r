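test_that("translateCds follows frame +1 with stop and remainder handling", {
  out <- translateCds(DNAStringSet(c(a = "ATG", b = "ATGGCTTAA")))
  expect_equal(as.character(out), c(a = "M", b = "MA"))
  expect_warning(out2 <- translateCds(DNAStringSet(c(c = "ATGTAAGCT"))),
                 "internal stop")
  expect_equal(as.character(out2), c(c = "MXA"))
  # trailing 1-2 nt remainder ignored
  expect_equal(as.character(translateCds(DNAStringSet(c(d = "ATGGCTTA")))),
               c(d = "MA"))
  expect_error(translateCds(DNAStringSet(c(e = "AT"))), "shorter than 3")
})

test_that("filterHits enforces the four thresholds with the stated strictness", {
  p <- pipelineParams()
  expect_equal(nrow(filterHits(hitRow(bitscore = 100), p)), 0L)   # strict >
  expect_equal(nrow(filterHits(hitRow(bitscore = 100.5), p)), 1L)
  expect_equal(nrow(filterHits(hitRow(pident = 80), p)), 0L)      # strict >
  expect_equal(nrow(filterHits(hitRow(aln_length = 100L), p)), 0L) # strict >
  expect_equal(nrow(filterHits(hitRow(evalue = 1e-5), p)), 1L)    # inclusive
  expect_equal(nrow(filterHits(hitRow(evalue = 1.1e-5), p)), 0L)
  expect_equal(nrow(filterHits(hitRow(query_id = "A", subject_id = "A"), p)), 0L)

  # pure subset operation, idempotent
  set.seed(8)
  hits <- do.call(rbind, lapply(1:50, function(i)
    hitRow(query_id = sample(LETTERS, 1), subject_id = sample(LETTERS, 1),
           pident = runif(1, 60, 100), aln_length = sample(50:300, 1),
           evalue = 10^runif(1, -40, -3), bitscore = runif(1, 50, 400))))
  f1 <- filterHits(hits)
  expect_true(all(rownames(f1) %in% rownames(hits)))
  expect_equal(filterHits(f1), f1)
})

test_that("parseTabular6 maps fields, handles empty files and rejects bad lines", {
  path <- tempfile()
  writeLines("A\tB\t95.5\t120\t5\t1\t1\t120\t3\t122\t1e-30\t250", path)
  h <- parseTabular6(path)
  expect_equal(h$pident, 95.5)
  expect_equal(h$bitscore, 250)
  expect_equal(h$s_start, 3L)

  writeLines(character(0), path)
  expect_equal(nrow(parseTabular6(path)), 0L)

  writeLines("A\tB\t95.5\t120\t5\t1\t1\t120\t3\t122\t1e-30", path)
  expect_error(parseTabular6(path), "line 1.*11 column")

  # round-trip
  set.seed(10)
  hits <- do.call(rbind, lapply(1:10, function(i)
    hitRow(query_id = sprintf("q%d", i), subject_id = sprintf("s%d", i),
           pident = round(runif(1, 50, 100), 2),
           evalue = signif(10^runif(1, -30, -3), 6),
           bitscore = round(runif(1, 80, 300), 1))))
  writeTabular6(hits, path)
  back <- parseTabular6(path)
  expect_equal(back, hits, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("builtinSearch reports a perfect self-alignment and symmetric scores", {
  set.seed(12)
  a <- randomPeptide(200)
  b <- randomPeptide(180)
  aa <- AAStringSet(c(x = a, y = b))
  hits <- builtinSearch(aa, aa)
  self <- hits[hits$query_id == "x" & hits$subject_id == "x", ]
  expect_equal(self$pident, 100.0)
  expect_equal(self$aln_length, 200L)
  expect_equal(self$q_start, 1L)
  expect_equal(self$q_end, 200L)
  xy <- hits[hits$query_id == "x" & hits$subject_id == "y", ]
  yx <- hits[hits$query_id == "y" & hits$subject_id == "x", ]
  if (nrow(xy) && nrow(yx))
    expect_equal(xy$bitscore, yx$bitscore)  # symmetric substitution matrix
  # diagonal pair present for every sequence before self-hit removal
  expect_true(all(names(aa) %in% hits$query_id[hits$query_id == hits$subject_id]))
})

test_that("unrelated random sequences never survive the default filters", {
  set.seed(13)
  for (i in 1:10) {
    aa <- AAStringSet(c(u = randomPeptide(100), v = randomPeptide(100)))
    surv <- filterHits(builtinSearch(aa[1], aa[2]))
    expect_equal(nrow(surv), 0L)
  }
})

test_that("planted families produce only within-family edges after filtering", {
  for (rep in 1:15) {
    pf <- plantedFamilies(nFam = 2, size = 3, nCodons = 150, seed = rep)
    hits <- filterHits(builtinSearch(pf$pep, pf$pep))
    if (nrow(hits)) {
      crossFam <- pf$family[hits$query_id] != pf$family[hits$subject_id]
      expect_equal(sum(crossFam), 0L)
    }
    # and every within-family pair is recovered
    expect_equal(nrow(hits), 2 * 2 * choose(3, 2))
  }
})

test_that("collectCandidateOrthologs gathers candidates plus filtered subjects, deduplicated", {
  spec <- syntheticSpec(nSpecies = 3, nFamilies = 3, pathwayFamilies = 1:2,
                        copiesPerSpecies = 1, nSamples = 20,
                        cdsLengthRange = c(450, 600), nBackgroundGenes = 2,
                        seed = 21)
  ds <- syntheticDataset(spec)
  cands <- lapply(ds$speciesList, coexpressionScan)
  coll <- collectCandidateOrthologs(cands, ds$speciesList)
  candidateIds <- unlist(lapply(cands, function(cs) candidateHits(cs)$gene_id))
  expect_true(all(candidateIds %in% names(coll$seqs)))
  expect_false(anyDuplicated(names(coll$seqs)) > 0)
  expect_true(all(coll$isCoexp[candidateIds]))
  # orthologs of the pathway families from non-candidate species are present
  fam1 <- ds$truth$seq_id[which(ds$truth$family == 1)]
  expect_true(all(fam1 %in% names(coll$seqs)))
  # the _coexp suffix appears only on candidates in the written FASTA
  path <- tempfile()
  writeCollectionFasta(coll, path)
  hdr <- names(readAAStringSet(path))
  expect_setequal(sub("_coexp$", "", hdr), names(coll$seqs))
  expect_equal(sum(grepl("_coexp$", hdr)), sum(coll$isCoexp))
})
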