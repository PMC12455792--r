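test_that("subsampleSize applies the percentage, the 10% floor and the 5-sequence minimum", {
  expect_equal(subsampleSize(100, 50), 50L)
  expect_equal(subsampleSize(20, 5), 5L)     # pct raised to 10 -> 2 -> floor 5
  expect_equal(subsampleSize(4, 50), 4L)     # capped at the population
  expect_equal(subsampleSize(100, 10), 10L)
  expect_equal(subsampleSize(11, 50), 6L)    # ceil(5.5)

  # monotone in both arguments, never exceeding nTotal nor below min(5, n)
  for (n in c(1, 3, 5, 8, 13, 40, 101)) {
    prev <- 0L
    for (pct in c(0, 5, 10, 25, 50, 75, 100)) {
      s <- subsampleSize(n, pct)
      expect_gte(s, prev)
      expect_lte(s, n)
      expect_gte(s, min(5L, n))
      prev <- s
    }
  }
  for (pct in c(10, 50)) {
    prev <- 0L
    for (n in c(1, 4, 9, 20, 50, 200)) {
      s <- subsampleSize(n, pct)
      expect_gte(s, prev)
      prev <- s
    }
  }
})

test_that("subsampleMembers is seed-reproducible and roughly uniform", {
  ids <- sprintf("m%02d", 1:10)
  expect_identical(subsampleMembers(ids, 10, 1), ids)
  a <- subsampleMembers(ids, 5, 99)
  b <- subsampleMembers(ids, 5, 99)
  expect_identical(a, b)
  expect_length(unique(a), 5L)

  counts <- setNames(numeric(10), ids)
  nDraw <- 2000
  for (s in seq_len(nDraw))
    counts[subsampleMembers(ids, 5, s)] <- counts[subsampleMembers(ids, 5, s)] + 1
  freq <- counts / nDraw
  sigma <- sqrt(0.5 * 0.5 / nDraw)
  expect_true(all(abs(freq - 0.5) < 3 * sigma + 0.02))
})

test_that("annotateOcg picks the modal best hit with lexicographic ties and honest reliability", {
  # reference-derived members: every member best-hits its own ancestor
  pf <- plantedFamilies(nFam = 2, size = 4, nCodons = 150, seed = 5)
  fam1 <- pf$pep[pf$family[names(pf$pep)] == 1]
  fam2 <- pf$pep[pf$family[names(pf$pep)] == 2]
  ref <- AAStringSet(c(REF_A = as.character(fam1[[1]]),
                       REF_B = as.character(fam2[[1]])))
  ann <- annotateOcg(fam1, ref)
  expect_equal(ann$ref_id, "REF_A")
  expect_equal(ann$reliability, 1.0)

  # mixed votes 3:1 give reliability 0.75
  mixed <- c(fam1[1:1], fam2[1:3])
  ann2 <- annotateOcg(mixed, ref)
  expect_equal(ann2$ref_id, "REF_B")
  expect_equal(ann2$reliability, 0.75)

  # tie 2:2 resolved to the lexicographically smaller reference
  tie <- c(fam1[1:2], fam2[1:2])
  expect_equal(annotateOcg(tie, ref)$ref_id, "REF_A")

  # sequences without any hit vote for the sentinel
  nullEngine <- structure(list(name = "null",
                               fun = function(q, s) hitRow()[0, ]),
                          class = "SearchEngine")
  ann3 <- annotateOcg(fam1[1:2], ref, engine = nullEngine)
  expect_equal(ann3$ref_id, "unannotated")
  expect_equal(ann3$text, "")
  expect_equal(ann3$reliability, 1.0)

  expect_error(annotateOcg(AAStringSet(), ref), "empty")
})

test_that("annotateOcgs covers every OCG and the written table preserves rank order", {
  pf <- plantedFamilies(nFam = 2, size = 5, nCodons = 150, seed = 8)
  fam <- pf$family[names(pf$pep)]
  species <- setNames(sub("_.*", "", names(pf$pep)), names(pf$pep))
  coexp <- setNames(fam == 1, names(pf$pep))       # family 1 fully coexpressed
  coexp[names(fam)[fam == 2][1]] <- TRUE           # one stray coexp in family 2
  ocgs <- rankOcgs(split(names(pf$pep), fam), species, coexp)
  ref <- AAStringSet(c(REF_A = as.character(pf$pep[[names(fam)[fam == 1][1]]]),
                       REF_B = as.character(pf$pep[[names(fam)[fam == 2][1]]])))
  anno <- annotateOcgs(ocgs, pf$pep, ref,
                       annoTable = c(REF_A = "enzyme A", REF_B = "enzyme B"),
                       params = pipelineParams(minOcgSize = 5))
  expect_equal(anno$label, ocgSummary(ocgs)$label)
  expect_equal(anno$n_sampled, c(5L, 5L))
  expect_true(all(anno$reliability == 1.0))
  # the coexpressed family ranks first and is annotated with its ancestor
  expect_equal(anno$annotation_ref_id[anno$ratio == 1.0], "REF_A")
  expect_equal(anno$annotation_text, c("enzyme A", "enzyme B")[
    match(anno$annotation_ref_id, c("REF_A", "REF_B"))])

  path <- tempfile()
  writeFunctionalAnnotation(anno, path)
  back <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(back$label, as.integer(anno$label))  # "0000" reads as 0
  expect_equal(back$reliability, anno$reliability)

  # annotation disabled: table still written with empty annotation columns
  annoOff <- annotateOcgs(ocgs, pf$pep, reference = NULL)
  expect_equal(nrow(annoOff), 2L)
  expect_true(all(annoOff$annotation_ref_id == ""))
  writeFunctionalAnnotation(annoOff, path)
  expect_equal(length(readLines(path)), 3L)
})
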