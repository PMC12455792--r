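#' Specification of a synthetic multi-species dataset
#'
#' Describes a fully synthetic benchmark dataset: several species, each with
#' a gene set partitioned into orthologous families (detectable by protein
#' similarity), a subset of families forming a coexpressed module that tracks
#' a latent pathway activity together with the bait, and uncorrelated
#' background genes with log-scale expression noise.
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 5 species, 12 families present in every species with 2 paralogous
#' copies each, families 1-4 forming the pathway module (copy 1 coexpressed,
#' copy 2 background), 50 RNA-seq samples per species, ancestral CDS of
#' 600-1200 nt, a target within-family pairwise peptide identity of 90\%,
#' and log-normal expression noise with sd 0.25.
#'
#' @param nSpecies number of species.
#' @param nFamilies number of orthologous gene families.
#' @param pathwayFamilies indices of the families forming the coexpressed
#'   module.
#' @param copiesPerSpecies paralogous copies of each family per species.
#' @param nSamples RNA-seq samples per species.
#' @param cdsLengthRange ancestral CDS length range in nt (rounded to whole
#'   codons).
#' @param withinIdentity target within-family pairwise peptide identity
#'   (percent); between-family identity is that of unrelated random
#'   sequences (well below 40\%).
#' @param noiseSd standard deviation of the log-scale expression noise on
#'   module genes.
#' @param nBackgroundGenes additional family-less background genes per
#'   species.
#' @param seed integer seed; fixed seed gives a byte-identical dataset.
#' @return a \code{SyntheticSpec} list.
#' @export
syntheticSpec <- function(nSpecies = 5, nFamilies = 12, pathwayFamilies = 1:4,
                          copiesPerSpecies = 2, nSamples = 50,
                          cdsLengthRange = c(600, 1200), withinIdentity = 90,
                          noiseSd = 0.25, nBackgroundGenes = 10, seed = 1L) {
  stopifnot(nSpecies >= 1, nFamilies >= 1, nSamples >= 3,
            all(pathwayFamilies %in% seq_len(nFamilies)),
            withinIdentity > 40 + 30,  # within must exceed between by >= 40
            cdsLengthRange[1] >= 300, cdsLengthRange[2] <= 1500)
  structure(list(nSpecies = nSpecies, nFamilies = nFamilies,
                 pathwayFamilies = pathwayFamilies,
                 copiesPerSpecies = copiesPerSpecies, nSamples = nSamples,
                 cdsLengthRange = cdsLengthRange,
                 withinIdentity = withinIdentity, noiseSd = noiseSd,
                 nBackgroundGenes = nBackgroundGenes, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.CODONS <- {
  b <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# sample() misbehaves on length-1 vectors; draw from an integer range safely.
sampleRange <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

# One random CDS of `nCodons` codons, ATG first, no internal stops.
randomCds <- function(nCodons) {
  paste0("ATG", paste(sample(.CODONS, nCodons - 1L, replace = TRUE),
                      collapse = ""))
}

# Substitute a fraction q of codons by a random different non-stop codon.
mutateCds <- function(cds, q) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  hit <- which(stats::runif(length(codons)) < q)
  hit <- hit[hit > 1L]                 # keep the start codon
  for (i in hit) codons[i] <- sample(setdiff(.CODONS, codons[i]), 1L)
  paste(codons, collapse = "")
}

#' Generate the gene families of a synthetic dataset
#'
#' Each family derives from one random ancestral CDS (length within the
#' spec's range, whole codons, no internal stops) which is mutated
#' independently per species and paralogous copy by codon substitution.  The
#' per-lineage substitution rate is \code{(1 - withinIdentity/100) * 0.4},
#' chosen so the realized pairwise peptide identity within a family sits at
#' or slightly above the target and comfortably above the 80\% similarity
#' filter.  Family-less background genes are added per species.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{cds} (per-species named list of
#'   \code{DNAStringSet}), \code{truth} (data.frame seq_id, species_id,
#'   family, copy, is_pathway), \code{ancestors} (\code{DNAStringSet}, one
#'   per family).
#' @export
generateFamilies <- function(spec) {
  withSeed(spec$seed, {
    sids <- sprintf("Species%02d", seq_len(spec$nSpecies))
    q <- (1 - spec$withinIdentity / 100) * 0.4
    ncRange <- floor(spec$cdsLengthRange / 3)
    anc <- vapply(seq_len(spec$nFamilies), function(f)
      randomCds(sampleRange(ncRange[1], ncRange[2])), character(1))
    cds <- setNames(vector("list", length(sids)), sids)
    truth <- list()
    for (sid in sids) {
      seqs <- character(0)
      for (f in seq_len(spec$nFamilies)) {
        for (cp in seq_len(spec$copiesPerSpecies)) {
          id <- sprintf("%s_f%02d_c%d", sid, f, cp)
          seqs[id] <- mutateCds(anc[f], q)
          truth[[length(truth) + 1L]] <- data.frame(
            seq_id = id, species_id = sid, family = f, copy = cp,
            is_pathway = f %in% spec$pathwayFamilies && cp == 1L,
            stringsAsFactors = FALSE)
        }
      }
      for (b in seq_len(spec$nBackgroundGenes)) {
        id <- sprintf("%s_bg%02d", sid, b)
        seqs[id] <- randomCds(sampleRange(ncRange[1], ncRange[2]))
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = id, species_id = sid, family = NA_integer_, copy = NA_integer_,
          is_pathway = FALSE, stringsAsFactors = FALSE)
      }
      cds[[sid]] <- DNAStringSet(seqs)
    }
    ancestors <- DNAStringSet(setNames(anc, sprintf("REF_f%02d",
                                                    seq_len(spec$nFamilies))))
    list(cds = cds, truth = do.call(rbind, truth), ancestors = ancestors)
  })
}

#' Generate expression matrices and bait lists
#'
#' Each species receives one latent pathway-activity trajectory spanning two
#' orders of magnitude of TPM.  Pathway-module genes are monotone power
#' transforms of the trajectory multiplied by log-normal noise — monotone
#' transforms leave ranks untouched, so the target Spearman correlation is
#' controlled directly by the noise level.  All other genes are independent
#' log-normal background.  The copy-1 gene of the first pathway family is
#' designated the species' bait.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param families result of \code{\link{generateFamilies}}.
#' @return list with \code{tpm} (per-species matrix) and \code{baits}
#'   (per-species character vector).
#' @export
generateExpression <- function(spec, families) {
  withSeed(spec$seed + 1L, {
    sids <- names(families$cds)
    samples <- sprintf("S%02d", seq_len(spec$nSamples))
    tpm <- setNames(vector("list", length(sids)), sids)
    baits <- setNames(vector("list", length(sids)), sids)
    for (sid in sids) {
      genes <- names(families$cds[[sid]])
      info <- families$truth[match(genes, families$truth$seq_id), ]
      traj <- 10^stats::runif(spec$nSamples, 0, 2)
      m <- matrix(0, length(genes), spec$nSamples,
                  dimnames = list(genes, samples))
      for (i in seq_along(genes)) {
        if (isTRUE(info$is_pathway[i])) {
          b <- stats::runif(1, 0.8, 1.25)
          base <- traj^b
          base <- base / max(base) * stats::runif(1, 50, 200)
          m[i, ] <- base * exp(stats::rnorm(spec$nSamples, 0, spec$noiseSd))
        } else {
          m[i, ] <- exp(stats::rnorm(spec$nSamples, stats::runif(1, 0, 3), 1))
        }
      }
      tpm[[sid]] <- round(m, 4)
      baits[[sid]] <- sprintf("%s_f%02d_c1", sid, spec$pathwayFamilies[1])
    }
    list(tpm = tpm, baits = baits)
  })
}

#' Build a synthetic dataset in memory
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{speciesList} (list of \linkS4class{SpeciesData}),
#'   \code{reference} (\code{AAStringSet} of ancestral peptides),
#'   \code{annoTable} (named character), \code{truth} (data.frame).
#' @export
syntheticDataset <- function(spec = syntheticSpec()) {
  fam <- generateFamilies(spec)
  expr <- generateExpression(spec, fam)
  speciesList <- lapply(names(fam$cds), function(sid)
    speciesData(sid, expr$tpm[[sid]], fam$cds[[sid]], expr$baits[[sid]]))
  reference <- translateCds(fam$ancestors)
  annoTable <- setNames(sprintf("pathway enzyme family %02d",
                                seq_len(spec$nFamilies)),
                        names(fam$ancestors))
  list(speciesList = speciesList, reference = reference,
       annoTable = annoTable, truth = fam$truth, spec = spec)
}

#' Emit a synthetic dataset to disk
#'
#' Writes a complete, valid pipeline input: the config file, per-species TPM
#' tables (TSV), CDS FASTA files and bait lists, plus the reference peptide
#' FASTA, the annotation table, and truth tables (family and pathway
#' membership) for assertions.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param outDir output directory (created if needed).
#' @return list with \code{configPath}, \code{referencePath},
#'   \code{annoPath}, \code{truthPath} and the in-memory \code{dataset}.
#' @export
emitDataset <- function(spec = syntheticSpec(), outDir) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outDir)) stopf("cannot create output directory '%s'", outDir)
  }
  ds <- syntheticDataset(spec)
  rows <- character(0)
  for (sp in ds$speciesList) {
    sid <- speciesId(sp)
    tpmPath <- file.path(outDir, paste0(sid, ".tpm.tsv"))
    cdsPath <- file.path(outDir, paste0(sid, ".cds.fasta"))
    baitPath <- file.path(outDir, paste0(sid, ".baits.txt"))
    df <- data.frame(gene_id = rownames(sp@tpm), sp@tpm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, tpmPath, sep = "\t", quote = FALSE, row.names = FALSE)
    writeXStringSet(sp@cds, cdsPath)
    writeLines(sp@baits, baitPath)
    rows <- c(rows, paste(sid, tpmPath, cdsPath, baitPath, sep = ","))
  }
  configPath <- file.path(outDir, "config.csv")
  writeLines(rows, configPath)
  referencePath <- file.path(outDir, "reference.pep.fasta")
  writeXStringSet(ds$reference, referencePath)
  annoPath <- file.path(outDir, "reference.anno.tsv")
  writeLines(sprintf("%s\t%s", names(ds$annoTable), unname(ds$annoTable)),
             annoPath)
  truthPath <- file.path(outDir, "truth_families.tsv")
  write.table(ds$truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(configPath = configPath, referencePath = referencePath,
       annoPath = annoPath, truthPath = truthPath, dataset = ds)
}
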