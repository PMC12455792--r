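# Shared fixture builders; everything is generated in code at test time.

suppressPackageStartupMessages({
  library(Biostrings)
})

# A minimal hit-table row with all filters passing unless overridden.
hitRow <- function(query_id = "A", subject_id = "B", pident = 95,
                   aln_length = 150L, mismatches = 5L, gap_opens = 0L,
                   q_start = 1L, q_end = 150L, s_start = 1L, s_end = 150L,
                   evalue = 1e-30, bitscore = 250) {
  data.frame(query_id = query_id, subject_id = subject_id, pident = pident,
             aln_length = aln_length, mismatches = mismatches,
             gap_opens = gap_opens, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

# Random peptide of length n (20 standard amino acids).
randomPeptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Tiny two-species SpeciesData fixture whose genes g1..g3 track the bait.
tinySpecies <- function(sid = "SpA", nSamples = 12, seed = 7) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    traj <- 10^runif(nSamples, 0, 2)
    tpm <- rbind(
      bait1 = traj,
      g1 = traj * exp(rnorm(nSamples, 0, 0.1)),
      g2 = traj^1.2 * exp(rnorm(nSamples, 0, 0.1)),
      g3 = exp(rnorm(nSamples, 2, 1)))
    colnames(tpm) <- sprintf("S%02d", seq_len(nSamples))
    cds <- DNAStringSet(vapply(rownames(tpm), function(i)
      paste0("ATG", paste(sample(c("GCT", "GAA", "TGG", "CAT"), 120,
                                 replace = TRUE), collapse = "")),
      character(1)))
    speciesData(sid, tpm, cds, "bait1")
  })
}

# Brute-force transitive-closure components oracle over an edge list.
closureComponents <- function(nodes, edges) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(nodes, nodes)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- TRUE
    adj[edges[k, 2], edges[k, 1]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(lapply(seq_len(n), function(i) sort(nodes[adj[i, ]])))
  comps[order(vapply(comps, `[`, "", 1))]
}

# Pearson correlation computed from the definitional sums (no stats::cor).
pearsonManual <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Build a permutation of 1..n whose sum of squared rank differences against
# the identity is exactly `target`, by composing disjoint swaps of span k
# (each contributing 2 k^2).  Used to construct exact Spearman values.
permWithD2 <- function(n, target) {
  stopifnot(target %% 2 == 0)
  y <- seq_len(n)
  free <- rep(TRUE, n)
  rem <- target
  while (rem > 0) {
    placed <- FALSE
    for (k in min(n - 1, floor(sqrt(rem / 2))):1) {
      for (i in seq_len(n - k)) {
        if (free[i] && free[i + k]) {
          tmp <- y[i]; y[i] <- y[i + k]; y[i + k] <- tmp
          free[c(i, i + k)] <- FALSE
          rem <- rem - 2 * k^2
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("cannot realize target d2 with disjoint swaps")
  }
  y
}

# Small planted-family peptide fixture: `nFam` families of `size` members,
# mutated from a family ancestor; returns AAStringSet plus family map.
plantedFamilies <- function(nFam = 2, size = 3, nCodons = 160, seed = 1) {
  set.seed(seed)
  spec <- syntheticSpec(nSpecies = size, nFamilies = nFam,
                        pathwayFamilies = 1, copiesPerSpecies = 1,
                        nSamples = 5, cdsLengthRange = c(3 * nCodons, 3 * nCodons),
                        nBackgroundGenes = 0, seed = sample.int(1e6, 1))
  fam <- generateFamilies(spec)
  cds <- do.call(c, unname(fam$cds))
  list(pep = translateCds(cds),
       family = setNames(fam$truth$family, fam$truth$seq_id))
}
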