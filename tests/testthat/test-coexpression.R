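test_that("spearmanTest matches hand-derived examples and is symmetric", {
  expect_equal(spearmanTest(1:5, (1:5)^3)[["r"]], 1.0)
  expect_equal(spearmanTest(1:6, rev((1:6)^2))[["r"]], -1.0)
  # d^2 = (1,1,1,1,0): r = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearmanTest(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))[["r"]], 0.8)
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(spearmanTest(x, y), spearmanTest(y, x))
  expect_true(is.na(spearmanTest(rep(1, 10), rnorm(10))[["r"]]))
})

test_that("spearmanTest agrees with a rank-then-Pearson oracle, with and without ties", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) {  # inject ties
      x <- round(x, 1)
      y <- round(y, 1)
    }
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    st <- spearmanTest(x, y)
    expect_equal(st[["r"]], pearsonManual(rank(x), rank(y)), tolerance = 1e-12)
    if (!any(duplicated(x)) && !any(duplicated(y))) {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      expect_equal(st[["p"]], ct$p.value, tolerance = 1e-12)
    }
  }
})

test_that("coexpressionScan applies all four candidate filters", {
  n <- 25
  bait <- as.numeric(1:n)
  # genes with exact Spearman values against the bait via constructed d^2
  d2for <- function(r) round((1 - r) * n * (n^2 - 1) / 6)
  tpm <- rbind(bait1 = bait,
               hi = as.numeric(permWithD2(n, d2for(0.9))),
               lowr = as.numeric(permWithD2(n, d2for(0.3))),
               lowexp = as.numeric(permWithD2(n, d2for(0.9))) * (29 / 325))
  colnames(tpm) <- sprintf("S%02d", 1:n)
  sp <- speciesData("SpA", tpm,
                    DNAStringSet(setNames(rep("ATGGCT", 4), rownames(tpm))),
                    "bait1")
  hits <- candidateHits(coexpressionScan(sp))
  expect_setequal(hits$gene_id, c("hi", "bait1"))       # lowr fails (a), lowexp fails (c)
  expect_equal(hits$r_s[hits$gene_id == "hi"], 0.9)
  expect_equal(hits$cumulative_tpm[hits$gene_id == "hi"], sum(tpm["hi", ]))
  expect_true(all(hits$r_s[hits$is_bait] == 1.0))

  # cumulative expression exactly at the cutoff is retained (inclusive)
  tpm2 <- rbind(bait1 = bait,
                edge = as.numeric(permWithD2(n, d2for(0.9))) * (30 / 325))
  colnames(tpm2) <- colnames(tpm)
  sp2 <- speciesData("SpA", tpm2,
                     DNAStringSet(setNames(rep("ATGGCT", 2), rownames(tpm2))),
                     "bait1")
  expect_true("edge" %in% candidateHits(coexpressionScan(sp2))$gene_id)
})

test_that("coexpressionScan truncates to numcut by best_r with deterministic ties", {
  set.seed(9)
  n <- 30
  traj <- 10^runif(n, 0, 2)
  genes <- t(vapply(1:150, function(i) traj * exp(rnorm(n, 0, 0.05)),
                    numeric(n)))
  rownames(genes) <- sprintf("g%03d", 1:150)
  tpm <- rbind(bait1 = traj, genes)
  colnames(tpm) <- sprintf("S%02d", 1:n)
  sp <- speciesData("SpA", tpm,
                    DNAStringSet(setNames(rep("ATGGCT", nrow(tpm)),
                                          rownames(tpm))), "bait1")
  cs <- coexpressionScan(sp)
  hits <- candidateHits(cs)
  expect_equal(nrow(hits), 100 + 1)                  # numcut genes + the bait
  nonbait <- hits[!hits$is_bait, ]
  expect_equal(nonbait$r_s, sort(nonbait$r_s, decreasing = TRUE))

  # invariance to sample-column and gene-row permutation
  perm <- sample(n)
  spP <- speciesData("SpA", tpm[sample(nrow(tpm)), perm],
                     DNAStringSet(setNames(rep("ATGGCT", nrow(tpm)),
                                           rownames(tpm))), "bait1")
  hitsP <- candidateHits(coexpressionScan(spP))
  expect_setequal(hitsP$gene_id, hits$gene_id)
  expect_equal(hitsP[order(hitsP$gene_id), c("r_s", "p_value")],
               hits[order(hits$gene_id), c("r_s", "p_value")],
               ignore_attr = TRUE)
})

test_that("coexpressionScan errors on missing baits or too few samples", {
  sp <- tinySpecies()
  spBad <- speciesData("SpA", sp@tpm[, 1:2], sp@cds, "bait1")
  expect_error(coexpressionScan(spBad), "at least 3")
  tpm <- sp@tpm
  expect_error(speciesData("SpA", tpm, sp@cds, "nope"), "nope")
})

test_that("constant-expression genes are skipped, not errors", {
  sp <- tinySpecies()
  tpm <- rbind(sp@tpm, flat = rep(5, ncol(sp@tpm)))
  cds <- c(sp@cds, DNAStringSet(c(flat = "ATGGCT")))
  sp2 <- speciesData("SpA", tpm, cds, "bait1")
  cs <- coexpressionScan(sp2)
  expect_equal(cs@nConstantSkipped, 1L)
  expect_false("flat" %in% candidateHits(cs)$gene_id)
})

test_that("cumulativeExpression equals an independent loop sum", {
  sp <- tinySpecies()
  expect_equal(cumulativeExpression(sp, "g1"), sum(sp@tpm["g1", ]))
  set.seed(4)
  v <- runif(20, 0, 50)
  m <- matrix(v, 1, dimnames = list("g", sprintf("S%d", 1:20)))
  acc <- 0
  for (j in 1:20) acc <- acc + m["g", j]
  expect_equal(cumulativeExpression(m, "g"), acc)
  expect_equal(cumulativeExpression(rbind(m * 0), "g"), 0)
  expect_error(cumulativeExpression(m, "zz"), "not present")
})
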