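#' MD5 digest of a file
#'
#' Standard MD5 of the raw bytes, as recorded in the run documentation for
#' every input file.
#'
#' @param path file path(s).
#' @return character vector of 32-character lowercase hex digests.
#' @export
computeMd5 <- function(path) {
  bad <- !file.exists(path)
  if (any(bad)) stopf("cannot read file(s): %s", paste(path[bad], collapse = ", "))
  unname(tools::md5sum(path))
}

#' Write the run documentation file
#'
#' Records the package version, every pipeline parameter, the engines /
#' external tools used, the seed, and the MD5 digest of every input file, so
#' a run can be reproduced exactly.
#'
#' @param path output path (conventionally \code{docu.txt}).
#' @param params a \linkS4class{PipelineParams}.
#' @param inputFiles character vector of input file paths.
#' @param tools named character vector of tool/engine versions.
#' @return \code{path}, invisibly.
#' @export
writeDocu <- function(path, params, inputFiles = character(),
                      tools = character()) {
  lines <- c(
    sprintf("tool_version\t%s", as.character(packageVersion("OCGfinder"))),
    vapply(slotNames(params), function(s)
      sprintf("param\t%s\t%.10g", s, slot(params, s)), character(1)))
  if (length(tools))
    lines <- c(lines, sprintf("tool\t%s\t%s", names(tools), unname(tools)))
  if (length(inputFiles))
    lines <- c(lines, sprintf("input\t%s\t%s", inputFiles,
                              computeMd5(inputFiles)))
  writeLines(lines, path)
  invisible(path)
}

#' Parse a run documentation file back into parameters
#'
#' @param path path to a \code{docu.txt} written by \code{\link{writeDocu}}.
#' @return list with \code{params} (\linkS4class{PipelineParams}),
#'   \code{inputs} (named character vector path -> md5) and \code{tools}.
#' @export
readDocu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  pv <- f[vapply(f, `[`, "", 1) == "param"]
  vals <- setNames(as.numeric(vapply(pv, `[`, "", 3)),
                   vapply(pv, `[`, "", 2))
  p <- pipelineParams()
  for (nm in names(vals)) slot(p, nm) <- if (nm == "seed") as.integer(vals[[nm]]) else vals[[nm]]
  validObject(p)
  iv <- f[vapply(f, `[`, "", 1) == "input"]
  tv <- f[vapply(f, `[`, "", 1) == "tool"]
  list(params = p,
       inputs = setNames(vapply(iv, `[`, "", 3), vapply(iv, `[`, "", 2)),
       tools = setNames(vapply(tv, `[`, "", 3), vapply(tv, `[`, "", 2)))
}

#' Species histogram of samples and coexpressed sequences
#'
#' Reports, per species, the number of RNA-seq samples and the number of
#' coexpressed sequences retained by the scan (species with zero candidates
#' are reported with 0, not omitted — an underrepresented species is a
#' finding, not a gap).  The TSV carries the exact numbers; the HTML file is
#' a presentation-only inline-SVG bar chart of the same two series.
#'
#' @param candidateSets list of \linkS4class{CandidateSet}.
#' @param sampleCounts named integer vector, samples per species.
#' @param htmlPath,tsvPath output paths.
#' @return data.frame with columns \code{species_id}, \code{n_samples},
#'   \code{n_coexp}, invisibly.
#' @export
speciesHistogram <- function(candidateSets, sampleCounts,
                             htmlPath = NULL, tsvPath = NULL) {
  ids <- names(sampleCounts)
  nCoexp <- setNames(integer(length(ids)), ids)
  for (cs in candidateSets) nCoexp[speciesId(cs)] <- nrow(cs@hits)
  df <- data.frame(species_id = ids, n_samples = as.integer(sampleCounts),
                   n_coexp = as.integer(nCoexp), stringsAsFactors = FALSE)
  if (!is.null(tsvPath))
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(htmlPath)) {
    barH <- 18L
    rowH <- 2L * barH + 14L
    mx <- max(df$n_samples, df$n_coexp, 1L)
    svgRows <- unlist(lapply(seq_len(nrow(df)), function(i) {
      y <- (i - 1L) * rowH
      c(sprintf('<text x="0" y="%d" font-size="12">%s</text>', y + 12L,
                df$species_id[i]),
        sprintf('<rect class="bar-samples" x="150" y="%d" width="%.1f" height="%d" fill="#4c78a8"/>',
                y, 400 * df$n_samples[i] / mx, barH - 4L),
        sprintf('<rect class="bar-coexp" x="150" y="%d" width="%.1f" height="%d" fill="#f58518"/>',
                y + barH, 400 * df$n_coexp[i] / mx, barH - 4L))
    }))
    html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
              "<title>Species counts</title></head><body>",
              "<h1>Samples (blue) and coexpressed sequences (orange) per species</h1>",
              sprintf('<svg width="600" height="%d">', nrow(df) * rowH + 10L),
              svgRows, "</svg></body></html>")
    writeLines(html, htmlPath)
  }
  invisible(df)
}

#' iTOL binary-dataset file marking coexpressed leaves
#'
#' Emits a \code{DATASET_BINARY} file whose DATA block lists exactly the
#' \code{_coexp}-suffixed leaves of one OCG, so they can be highlighted on
#' the corresponding tree in iTOL.
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param label OCG label.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeItolCoexpAnnotation <- function(ocgs, label, path) {
  m <- ocgMembers(ocgs, label)
  lines <- c("DATASET_BINARY", "SEPARATOR COMMA",
             sprintf("DATASET_LABEL,coexp members OCG %s", label),
             "COLOR,#f58518", "FIELD_SHAPES,2", "FIELD_LABELS,coexp",
             "DATA",
             sprintf("%s,1", ocgDisplayName(m$seq_id[m$is_coexp], TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' iTOL gradient-dataset file of best correlation coefficients
#'
#' Emits a \code{DATASET_GRADIENT} file assigning every coexpressed member
#' its best Spearman coefficient; the colour scale is anchored at
#' \code{[rCutoff, 1]} (so a bait, with coefficient 1, maps to the maximum
#' colour).  Members that entered via similarity search receive no entry.
#'
#' @param ocgs an \linkS4class{OCGSet}.
#' @param label OCG label.
#' @param path output path.
#' @param rCutoff lower anchor of the colour scale (default 0.7).
#' @return \code{path}, invisibly.
#' @export
writeItolGradientLabels <- function(ocgs, label, path, rCutoff = 0.7) {
  m <- ocgMembers(ocgs, label)
  m <- m[m$is_coexp & !is.na(m$best_r), , drop = FALSE]
  lines <- c("DATASET_GRADIENT", "SEPARATOR COMMA",
             sprintf("DATASET_LABEL,best r_s OCG %s", label),
             "COLOR,#4c78a8",
             "COLOR_MIN,#ffffff", "COLOR_MAX,#08306b",
             sprintf("USER_MIN_VALUE,%g", rCutoff),
             "USER_MAX_VALUE,1",
             "DATA",
             sprintf("%s,%.6g", ocgDisplayName(m$seq_id, TRUE), m$best_r))
  writeLines(lines, path)
  invisible(path)
}
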