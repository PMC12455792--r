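test_that("builtin alignment conserves sequences and handles a single indel", {
  aa <- AAStringSet(c(a = "MKVLHEQWYRADT", b = "MKVLHEQWYRADT"))
  aln <- alignOcg(aa)
  expect_equal(width(aln), c(13L, 13L))
  expect_equal(as.character(aln[[1]]), as.character(aln[[2]]))

  # three sequences differing by one deletion: exactly one gap column
  tri <- AAStringSet(c(a = "MKVLHEQWYRADTKKNG", b = "MKVLHEQWYRADTKKNG",
                       c = "MKVLHEQYRADTKKNG"))
  alnT <- alignOcg(tri)
  expect_equal(length(unique(width(alnT))), 1L)
  expect_equal(sum(grepl("-", as.character(alnT))), 1L)
  expect_equal(unique(width(alnT)), 17L)

  # degapping any row recovers the input, for a larger random family
  pf <- plantedFamilies(nFam = 1, size = 6, nCodons = 120, seed = 3)
  alnF <- alignOcg(pf$pep)
  expect_equal(length(unique(width(alnF))), 1L)
  for (nm in names(pf$pep))
    expect_equal(gsub("-", "", as.character(alnF[[nm]])),
                 as.character(pf$pep[[nm]]))

  expect_error(alignOcg(aa[1]), "at least 2")
})

test_that("external aligner adapters run when present and name their flag when absent", {
  pf <- plantedFamilies(nFam = 1, size = 4, nCodons = 100, seed = 9)
  aln <- alignOcg(pf$pep, method = "mafft")
  expect_setequal(names(aln), names(pf$pep))
  expect_equal(length(unique(width(aln))), 1L)
  for (nm in names(pf$pep))
    expect_equal(gsub("-", "", as.character(aln[[nm]])),
                 as.character(pf$pep[[nm]]))
  expect_error(alignOcg(pf$pep, method = "muscle",
                        muscle = "/nonexistent/muscle"), "muscle")
})

test_that("occupancyTrim keeps columns at or above the cutoff, idempotently", {
  rows <- c(sprintf("r%02d", 1:10))
  aln <- AAStringSet(setNames(c("MA-K", rep("M-AK", 9)), rows))
  # col2 occupancy 10% (exactly at default cutoff) kept; col3 90% kept
  trimmed <- occupancyTrim(aln, 10)
  expect_equal(unique(width(trimmed)), 4L)
  # at 20% the 10%-occupancy column goes
  trimmed20 <- occupancyTrim(aln, 20)
  expect_equal(unique(width(trimmed20)), 3L)
  expect_equal(as.character(trimmed20[[1]]), "M-K")  # col 2 dropped
  # idempotence and residue conservation
  expect_equal(as.character(occupancyTrim(trimmed20, 20)),
               as.character(trimmed20))
  gapfree <- AAStringSet(c(a = "MKV", b = "MKL"))
  expect_equal(as.character(occupancyTrim(gapfree, 10)),
               as.character(gapfree))
  allgap <- AAStringSet(c(a = "M-", b = "M-"))
  expect_error(occupancyTrim(allgap, 150), "lower the occupancy")
})

test_that("pDistance counts mismatches over shared columns and flags disjoint pairs", {
  aln <- AAStringSet(c(a = "MKVL", b = "MKIL", c = "MKVL"))
  d <- pDistance(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  disjoint <- AAStringSet(c(a = "MK--", b = "--VL", c = "MKVD"))
  expect_warning(d2 <- pDistance(disjoint), "no aligned columns")
  expect_equal(d2["a", "b"], 1.1 * max(d2["a", "c"], d2["b", "c"]))
})

test_that("neighbor joining recovers the planted split of an additive matrix", {
  # 4-taxon additive matrix with ((A,B),(C,D)) structure
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:1):1);")
  d <- cophenetic(tr)
  nj <- njFromDistance(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
  # branch lengths of the additive matrix are reproduced
  expect_equal(sum(nj$edge.length), sum(tr$edge.length), tolerance = 1e-9)

  # 3 taxa: the unique topology with three-point branch lengths
  d3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njFromDistance(d3)
  expect_equal(ape::Ntip(t3), 3L)
  expect_equal(sum(t3$edge.length), 0.6, tolerance = 1e-9)  # (a+b+c)/2
})

test_that("tree inference runs on alignments and FastTree adapter matches leaves", {
  pf <- plantedFamilies(nFam = 1, size = 5, nCodons = 120, seed = 4)
  aln <- alignOcg(pf$pep)
  tree <- inferTree(aln)
  expect_setequal(tree$tip.label, names(pf$pep))
  expect_true(all(tree$edge.length >= 0))
  expect_error(inferTree(aln[1:2]), "at least 3")

  ft <- inferTree(aln, method = "fasttree")
  expect_setequal(ft$tip.label, names(pf$pep))
})

test_that("Newick writing and parsing round-trip, preserving _coexp labels", {
  txt <- "(A:1,B:1,(C_coexp:1,D:1):1);"
  tree <- parseNewick(text = txt)
  expect_equal(ape::Ntip(tree), 4L)
  expect_true("C_coexp" %in% tree$tip.label)
  path <- tempfile(fileext = ".tree")
  writeNewick(tree, path)
  back <- parseNewick(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::dist.topo(back, tree), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tree$edge.length),
               tolerance = 1e-9)

  expect_error(parseNewick(text = "((A:1,B:1);"), "unclosed")
  expect_error(parseNewick(text = "(A:1,B:1));"), "position")
})
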