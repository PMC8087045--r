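# Readers and writers for the standard interchange formats: transcript-space
# GFF3 + FASTA, footprint TSV/SAM, offset and truth tables.

#' Write a transcriptome as FASTA + transcript-space GFF3
#'
#' Sequences are written in the DNA alphabet (U -> T), as is conventional
#' for FASTA/GFF3; [load_transcriptome()] converts back. The GFF3 carries
#' `mRNA`, `five_prime_UTR`, `CDS` and `three_prime_UTR` features in
#' transcript coordinates (seqid = transcript id, 1-based).
#'
#' @param models Model tibble.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(models, fasta, gff3) {
  dna <- Biostrings::DNAStringSet(chartr("U", "T", models$seq))
  names(dna) <- models$id
  Biostrings::writeXStringSet(dna, fasta)

  rows <- purrr::pmap(models, function(id, seq, utr5_len, cds_len, utr3_len,
                                       utr3_annotated, ...) {
    tx_len <- nchar(seq)
    feats <- list(c("mRNA", 1L, tx_len))
    if (utr5_len > 0) feats <- c(feats, list(c("five_prime_UTR", 1L, utr5_len)))
    feats <- c(feats, list(c("CDS", utr5_len + 1L, utr5_len + cds_len)))
    if (utr3_annotated && utr3_len > 0) {
      feats <- c(feats, list(c("three_prime_UTR", utr5_len + cds_len + 1L,
                               tx_len)))
    }
    purrr::map_chr(feats, function(f) {
      paste(id, "readthroughr", f[1], f[2], f[3], ".", "+", ".",
            paste0("ID=", id, ":", f[1], ";Parent=", id), sep = "\t")
    })
  })
  writeLines(c("##gff-version 3", unlist(rows)), gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read / write footprint records as TSV
#'
#' Plain tabular footprint format: `transcript_id`, `five_prime` (0-based
#' 5'-end position on the transcript), `length` (nt).
#'
#' @param footprints Footprint tibble.
#' @param path File path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_footprints_tsv <- function(footprints, path) {
  readr::write_tsv(footprints %>%
                     select("transcript_id", "five_prime", "length"), path)
  invisible(path)
}

#' @rdname write_footprints_tsv
#' @export
read_footprints_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    five_prime = readr::col_integer(),
    length = readr::col_integer()
  ))
}

#' Read / write footprints as SAM alignments to the transcriptome
#'
#' The SAM writer emits unpaired forward-strand records with the read start
#' as the 5' end in transcript coordinates and the read sequence taken from
#' the transcript. The reader accepts SAM or BAM and extracts
#' (`transcript_id`, `five_prime`, `length`).
#'
#' @param footprints Footprint tibble.
#' @param models Model tibble (for header lengths and read sequences).
#' @param path File path (`.sam` for the writer; `.sam` or `.bam` for the
#'   reader).
#' @return The footprint tibble (reader) or the path, invisibly (writer).
#' @export
write_footprints_sam <- function(footprints, models, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", models$id, "\tLN:", nchar(models$seq)))
  idx <- match(footprints$transcript_id, models$id)
  if (anyNA(idx)) abort("footprints reference transcripts absent from models")
  seqs <- chartr("U", "T",
                 substr(models$seq[idx], footprints$five_prime + 1L,
                        footprints$five_prime + footprints$length))
  # reads overhanging the transcript 3' end are N-padded so SEQ matches CIGAR
  pad <- footprints$length - nchar(seqs)
  seqs[pad > 0] <- paste0(seqs[pad > 0], strrep("N", pad[pad > 0]))
  recs <- paste(sprintf("r%06d", seq_len(nrow(footprints))), 0L,
                footprints$transcript_id, footprints$five_prime + 1L, 255L,
                paste0(footprints$length, "M"), "*", 0L, 0L, seqs, "*",
                sep = "\t")
  writeLines(c(header, recs), path)
  invisible(path)
}

#' @rdname write_footprints_sam
#' @export
read_footprints_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth"))
  )[[1]]
  tibble(transcript_id = as.character(res$rname),
         five_prime = res$pos - 1L,
         length = res$qwidth)
}

#' Read / write a P-site offset table
#'
#' TSV with columns `length` (read length, nt) and `offset` (P-site offset
#' from the 5' end, nt; `0 <= offset < length`).
#'
#' @param offsets Offset tibble.
#' @param path File path.
#' @return The tibble (reader) or the path, invisibly (writer).
#' @export
write_offset_table <- function(offsets, path) {
  validate_offset_table(offsets)
  readr::write_tsv(offsets, path)
  invisible(path)
}

#' @rdname write_offset_table
#' @export
read_offset_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    length = readr::col_integer(), offset = readr::col_integer()
  ))
  validate_offset_table(out)
  out
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits FASTA + GFF3 (transcriptome), footprints TSV, truth TSV, offset
#' TSV and RNA-seq abundance TSV under one directory, with a small manifest
#' recording the seed.
#'
#' @param models,truth,footprints Generator outputs.
#' @param config The [synthetic_config()] used.
#' @param seed The seed used.
#' @param dir Output directory (created if needed).
#' @param rnaseq Optional abundance tibble from [simulate_rnaseq()].
#' @return Invisibly, the directory.
#' @export
write_synthetic_dataset <- function(models, truth, footprints, config, seed,
                                    dir, rnaseq = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcriptome(models, file.path(dir, "transcriptome.fa"),
                      file.path(dir, "transcriptome.gff3"))
  write_footprints_tsv(footprints, file.path(dir, "footprints.tsv"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  write_offset_table(config$offsets, file.path(dir, "offsets.tsv"))
  if (!is.null(rnaseq)) {
    readr::write_tsv(rnaseq, file.path(dir, "abundance.tsv"))
  }
  writeLines(c(paste0("seed\t", seed),
               paste0("n_genes\t", config$n_genes)),
             file.path(dir, "MANIFEST.tsv"))
  invisible(dir)
}
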