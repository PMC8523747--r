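#' Write a probe annotation to disk
#'
#' Emits `manifest.tsv` (1-based probe positions, Illumina convention),
#' `tss.tsv`, and one `chromhmm_<cell type>.bed` per cell type.  BED
#' files are 0-based half-open; the internal segments are 1-based
#' inclusive, so `start` is decremented on the way out.
#'
#' @param annotation A `probe_annotation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             tss = file.path(dir, "tss.tsv"))
  write_tsv(annotation$probes, paths["manifest"])
  write_tsv(annotation$tss, paths["tss"])
  for (ct in annotation$cell_types) {
    seg <- annotation$segments[[ct]]
    bed <- data.frame(chrom = seg$chrom,
                      start = format(seg$start - 1, scientific = FALSE,
                                     trim = TRUE),
                      end = format(seg$end, scientific = FALSE,
                                   trim = TRUE),
                      name = seg$state)
    p <- file.path(dir, paste0("chromhmm_", ct, ".bed"))
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[paste0("bed_", ct)] <- p
  }
  invisible(paths)
}

#' Write a simulated cohort to disk
#'
#' Emits `beta.tsv` (probes x samples, probe ids in the first column),
#' `metadata.tsv`, `truth.tsv` and `variant_calls.tsv` (one row per
#' carrier, MAF 0, not twin-concordant).
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- sim$cohort
  paths <- c(beta = file.path(dir, "beta.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             variants = file.path(dir, "variant_calls.tsv"))
  write_matrix_tsv(cohort$beta, paths["beta"], id_col = "probe_id")
  write_tsv(cohort$samples, paths["metadata"])
  write_tsv(sim$truth, paths["truth"])
  genes <- grep("^vaf_", names(cohort$samples), value = TRUE)
  calls <- do.call(rbind, lapply(genes, function(v) {
    g <- sub("^vaf_", "", v)
    carriers <- cohort$samples[[g]]
    data.frame(sample_id = cohort$samples$sample_id[carriers],
               gene = g, vaf = cohort$samples[[v]][carriers],
               maf = 0, twin_concordant = FALSE)
  }))
  write_tsv(calls, paths["variants"])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a probes-x-samples matrix from TSV
#'
#' @param path TSV path with ids in the first column.
#' @return Numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read chromatin-state segmentations from a BED file
#'
#' Uses rtracklayer, so the 0-based half-open BED coordinates arrive as
#' 1-based inclusive ranges; the `name` column carries the state label.
#'
#' @param path BED path.
#' @return A `GRanges` with a `state` metadata column.
#' @export
read_chromhmm_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr)$state <- S4Vectors::mcols(gr)$name
  gr
}

#' Write a PWM set in MEME minimal format
#'
#' @param pwm_set A list of PWMs as produced by [make_pwm_set()].
#' @param path Output path.
#' @export
write_meme <- function(pwm_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwm_set[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", names(bg), bg), collapse = " "),
               ""), con)
  for (pwm in pwm_set) {
    m <- pwm$matrix
    writeLines(sprintf("MOTIF %s", pwm$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m)), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal-format PWM file
#'
#' The background frequency line is optional and defaults to uniform.
#' Motif family labels are recovered from the id suffix `"_<FAMILY>"`
#' when present.
#'
#' @param path MEME-format path.
#' @return Named list of PWMs (`id`, `family`, `matrix`, `background`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  motif_at <- grep("^MOTIF", lines)
  pwms <- lapply(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[i:length(lines)])[1] + i - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- t(m)
    rownames(mat) <- c("A", "C", "G", "T")
    fam <- if (grepl("_", id)) sub(".*_", "", id) else NA_character_
    list(id = id, family = fam, matrix = mat, background = bg)
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  pwms
}
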