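# Transcript-coordinate models and analysis-region geometry.
#
# All coordinates are 0-based, half-open intervals in transcript space.
# Sequences are stored as RNA (A/C/G/U). The annotated CDS includes its stop
# codon; the "adjusted" convention used throughout the analysis moves the stop
# codon to the 3'-UTR side (cds_adj = CDS minus stop, utr3_adj = stop + 3'-UTR).

#' Load a transcriptome into transcript-coordinate models
#'
#' Parses a transcript-space GFF3 (seqid = transcript id, with `CDS` and
#' optional `five_prime_UTR`/`three_prime_UTR` features) together with a FASTA
#' of transcript sequences into one model row per protein-coding transcript.
#' Transcripts without annotated UTRs receive default UTR lengths taken from
#' the flanking sequence present in the FASTA record and are flagged
#' `utr3_annotated = FALSE`; an optional UTR-length table overrides lengths
#' and marks transcripts as experimentally annotated.
#'
#' Records violating the model invariants (CDS length not a multiple of 3 or
#' shorter than 6 nt, CDS not ending in a stop codon, non-ACGU characters)
#' are rejected with a per-record report attached as
#' `attr(models, "rejected")`, not silently dropped. A CDS annotation whose
#' transcript is missing from the FASTA is a fatal error naming the record.
#'
#' @param gff3 Path to a GFF3 file with transcript-space features.
#' @param fasta Path to a FASTA file of transcript sequences (DNA or RNA
#'   alphabet; T is converted to U).
#' @param utr_table Optional data frame or TSV path with columns
#'   `transcript_id`, `utr5_len`, `utr3_len`.
#' @param utr5_default,utr3_default Default UTR lengths (nt) imputed for
#'   transcripts lacking UTR annotation (defaults 97 and 173, the 75th
#'   percentile lengths of experimentally mapped yeast UTRs).
#' @return A tibble with columns `id`, `seq`, `utr5_len`, `cds_len`,
#'   `utr3_len`, `utr3_annotated`, carrying the rejection report as the
#'   `"rejected"` attribute.
#' @export
load_transcriptome <- function(gff3, fasta, utr_table = NULL,
                               utr5_default = 97, utr3_default = 173) {
  gr <- rtracklayer::import(gff3)
  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seq_chr <- chartr("Tt", "Uu", toupper(as.character(seqs)))

  feat <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  cds <- feat %>%
    filter(.data$type == "CDS") %>%
    group_by(.data$seqid) %>%
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              cds_span = sum(.data$end - .data$start + 1L), .groups = "drop")
  if (any(cds$cds_span != cds$cds_end - cds$cds_start + 1L)) {
    bad <- cds$seqid[cds$cds_span != cds$cds_end - cds$cds_start + 1L]
    abort(paste0("non-contiguous CDS in transcript coordinates for: ",
                 paste(bad, collapse = ", ")))
  }
  missing_seq <- setdiff(cds$seqid, names(seq_chr))
  if (length(missing_seq) > 0) {
    abort(paste0("CDS annotation references sequences absent from FASTA: ",
                 paste(missing_seq, collapse = ", ")))
  }
  has_utr3 <- feat %>% filter(.data$type == "three_prime_UTR") %>%
    pull(.data$seqid) %>% unique()
  has_utr5 <- feat %>% filter(.data$type == "five_prime_UTR") %>%
    pull(.data$seqid) %>% unique()

  if (!is.null(utr_table)) {
    if (is.character(utr_table)) {
      utr_table <- readr::read_tsv(utr_table, show_col_types = FALSE)
    }
    stopifnot(all(c("transcript_id", "utr5_len", "utr3_len") %in%
                    names(utr_table)))
  }

  rejected <- tibble(id = character(), reason = character())
  rows <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    id <- cds$seqid[i]
    full <- seq_chr[[id]]
    full_len <- nchar(full)
    cds_lo <- cds$cds_start[i] - 1L   # 0-based
    cds_hi <- cds$cds_end[i]          # half-open
    cds_len <- cds_hi - cds_lo

    ann5 <- id %in% has_utr5
    ann3 <- id %in% has_utr3
    u5 <- cds_lo
    u3 <- full_len - cds_hi
    if (!is.null(utr_table) && id %in% utr_table$transcript_id) {
      r <- utr_table[match(id, utr_table$transcript_id), ]
      u5 <- min(as.integer(r$utr5_len), cds_lo)
      u3 <- min(as.integer(r$utr3_len), full_len - cds_hi)
      ann3 <- TRUE
    } else {
      if (!ann5) u5 <- min(utr5_default, cds_lo)
      if (!ann3) u3 <- min(utr3_default, full_len - cds_hi)
    }
    seq_i <- substr(full, cds_lo - u5 + 1L, cds_hi + u3)

    reason <- NULL
    if (cds_len %% 3L != 0L) {
      reason <- "CDS length not divisible by 3"
    } else if (cds_len < 6L) {
      reason <- "CDS shorter than 6 nt"
    } else if (!(substr(seq_i, u5 + cds_len - 2L, u5 + cds_len) %in%
                   STOP_CODONS)) {
      reason <- "CDS does not end in a stop codon"
    } else if (grepl("[^ACGU]", seq_i)) {
      reason <- "sequence contains non-ACGU characters"
    }
    if (!is.null(reason)) {
      rejected <- bind_rows(rejected, tibble(id = id, reason = reason))
      next
    }
    rows[[i]] <- tibble(
      id = id, seq = seq_i,
      utr5_len = as.integer(u5), cds_len = as.integer(cds_len),
      utr3_len = as.integer(u3), utr3_annotated = ann3
    )
  }
  models <- bind_rows(rows)
  if (nrow(rejected) > 0) {
    inform(paste0(nrow(rejected), " transcript(s) rejected at load; ",
                  "see attr(models, \"rejected\")"))
  }
  attr(models, "rejected") <- rejected
  models
}

#' Validate transcript models against their invariants
#'
#' @param models A model tibble as returned by [load_transcriptome()].
#' @return Invisibly `TRUE`; aborts with the offending ids otherwise.
#' @export
validate_models <- function(models) {
  stop_codon <- substr(models$seq,
                       models$utr5_len + models$cds_len - 2L,
                       models$utr5_len + models$cds_len)
  ok <- models$utr5_len + models$cds_len + models$utr3_len ==
    nchar(models$seq) &
    models$cds_len %% 3L == 0L & models$cds_len >= 6L &
    stop_codon %in% STOP_CODONS
  if (!all(ok)) {
    abort(paste0("invalid transcript models: ",
                 paste(models$id[!ok], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Build the filtered reference gene set
#'
#' Retains transcripts with experimentally annotated 3'-UTRs and without
#' same-strand overlap of more than `max_overlap` nucleotides with another
#' gene (read assignment being ambiguous there). An overlap of exactly
#' `max_overlap` is retained ("more than" read strictly).
#'
#' @param models Model tibble.
#' @param overlap_pairs Optional data frame with columns `id_a`, `id_b`,
#'   `overlap_nt`, `same_strand`, precomputed from genomic coordinates.
#' @param max_overlap Maximum tolerated same-strand overlap in nt (default 18).
#' @return Character vector of retained transcript ids (possibly empty).
#' @export
build_reference_set <- function(models, overlap_pairs = NULL,
                                max_overlap = 18) {
  ids <- models$id[models$utr3_annotated]
  if (!is.null(overlap_pairs) && nrow(overlap_pairs) > 0) {
    bad <- overlap_pairs %>%
      filter(.data$same_strand, .data$overlap_nt > max_overlap)
    ids <- setdiff(ids, unique(c(bad$id_a, bad$id_b)))
  }
  sort(ids)
}

#' Locate the readthrough extension within each 3'-UTR
#'
#' The extension runs from the first nucleotide after the canonical stop codon
#' through the last nucleotide of the first downstream stop codon that is in
#' frame 0 with the CDS (inclusive by default; `include_downstream_stop =
#' FALSE` ends it just before). When no in-frame stop exists within the
#' 3'-UTR, the extension covers the whole post-stop 3'-UTR and
#' `has_downstream_stop = FALSE`.
#'
#' @param models Model tibble.
#' @param include_downstream_stop Include the downstream stop codon's 3 nt in
#'   the extension (default `TRUE`).
#' @return A region-map tibble with 0-based half-open intervals: `cds_adj_*`
#'   (CDS minus stop), `utr3_adj_*` (stop + 3'-UTR), `ext_*`, `distal_*`,
#'   plus `has_downstream_stop` and `utr3_empty` flags.
#' @export
locate_extensions <- function(models, include_downstream_stop = TRUE) {
  scan_one <- function(seq, utr5, cds_len, utr3) {
    post <- utr5 + cds_len  # 0-based first nt after canonical stop
    if (utr3 <= 0L) return(c(ext_len = 0L, has_stop = 0L))
    n_codons <- utr3 %/% 3L
    if (n_codons > 0L) {
      for (k in seq_len(n_codons)) {
        cod <- substr(seq, post + 3L * (k - 1L) + 1L, post + 3L * k)
        if (cod %in% STOP_CODONS) {
          len <- if (include_downstream_stop) 3L * k else 3L * (k - 1L)
          return(c(ext_len = len, has_stop = 1L))
        }
      }
    }
    c(ext_len = utr3, has_stop = 0L)
  }
  res <- purrr::pmap(
    list(models$seq, models$utr5_len, models$cds_len, models$utr3_len),
    function(s, u5, cl, u3) scan_one(s, u5, cl, u3)
  )
  ext_len <- purrr::map_int(res, ~ as.integer(.x[["ext_len"]]))
  has_stop <- purrr::map_lgl(res, ~ .x[["has_stop"]] == 1)
  tibble(
    id = models$id,
    utr5_len = models$utr5_len,
    cds_len = models$cds_len,
    utr3_len = models$utr3_len,
    tx_len = nchar(models$seq),
    cds_adj_lo = models$utr5_len,
    cds_adj_hi = models$utr5_len + models$cds_len - 3L,
    utr3_adj_lo = models$utr5_len + models$cds_len - 3L,
    utr3_adj_hi = nchar(models$seq),
    ext_lo = models$utr5_len + models$cds_len,
    ext_hi = models$utr5_len + models$cds_len + ext_len,
    distal_lo = models$utr5_len + models$cds_len + ext_len,
    distal_hi = nchar(models$seq),
    has_downstream_stop = has_stop,
    utr3_empty = models$utr3_len == 0L
  )
}

#' Label transcript positions by analysis region
#'
#' Deterministically maps 0-based transcript positions to one of `utr5`,
#' `cds`, `extension`, `distal_utr3`. Under the default convention the three
#' nucleotides of the canonical stop codon belong to the 3'-UTR side and are
#' reported as part of the extension flank; `stop_in_utr3 = FALSE` restores
#' the standard CDS-includes-stop convention.
#'
#' @param regionmaps Region-map tibble from [locate_extensions()].
#' @param transcript_id Character vector of transcript ids (recycled).
#' @param psite Integer vector of 0-based P-site positions.
#' @param stop_in_utr3 Assign canonical stop codon positions to the 3'-UTR
#'   side (default `TRUE`).
#' @return Character vector of region labels.
#' @export
region_of <- function(regionmaps, transcript_id, psite, stop_in_utr3 = TRUE) {
  idx <- match(transcript_id, regionmaps$id)
  if (anyNA(idx)) {
    abort(paste0("unknown transcript id(s): ",
                 paste(unique(transcript_id[is.na(idx)]), collapse = ", ")))
  }
  if (any(psite < 0L | psite >= regionmaps$tx_len[idx])) {
    abort("P-site position outside transcript bounds")
  }
  cds_hi <- if (stop_in_utr3) regionmaps$cds_adj_hi[idx] else
    regionmaps$cds_adj_hi[idx] + 3L
  ext_lo <- if (stop_in_utr3) regionmaps$utr3_adj_lo[idx] else
    regionmaps$ext_lo[idx]
  lab <- rep("distal_utr3", length(psite))
  lab[psite < regionmaps$ext_hi[idx]] <- "extension"
  lab[psite < cds_hi] <- "cds"
  lab[psite < regionmaps$utr5_len[idx]] <- "utr5"
  # between cds_adj_hi and ext_lo only arises when stop_in_utr3 = FALSE has
  # already widened cds; with the default convention ext covers the stop flank
  lab[psite >= cds_hi & psite < ext_lo] <- "extension"
  lab
}
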