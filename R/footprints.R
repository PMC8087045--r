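# P-site assignment, reading frames, metagene profiles, region/frame counts.

#' Filter footprints by read length
#'
#' Keeps ribosome-protected fragments whose lengths fall in the allowed set
#' (default 20-23 and 27-32 nt, the length classes retained for analysis;
#' 24-26 nt reads are excluded).
#'
#' @param footprints Tibble with at least a `length` column.
#' @param allowed Integer vector of allowed read lengths.
#' @return The filtered tibble; the number of dropped reads is reported and
#'   stored as `attr(, "n_dropped")`.
#' @export
filter_footprint_lengths <- function(footprints,
                                     allowed = c(20:23, 27:32)) {
  keep <- footprints$length %in% allowed
  out <- footprints[keep, , drop = FALSE]
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(paste0(n_drop, " footprint(s) dropped by length filter"))
  }
  attr(out, "n_dropped") <- n_drop
  out
}

#' Assign P-site positions from a read-length offset table
#'
#' The P-site position of each footprint is its 5' end plus a per-length
#' offset taken from an externally estimated offset table (offsets are
#' consumed, never estimated here). When `models` is supplied, reads whose
#' P-site falls outside the transcript (possible with imputed UTRs) are
#' dropped and counted in a QC log.
#'
#' @param footprints Tibble with `transcript_id`, `five_prime` (0-based) and
#'   `length` columns.
#' @param offsets Tibble with `length` and `offset` columns
#'   (`0 <= offset < length`).
#' @param models Optional model tibble used to drop out-of-range P-sites.
#' @return Tibble with a `psite` column added (and out-of-range reads removed
#'   when `models` is given; count in `attr(, "n_out_of_range")`).
#' @export
assign_psites <- function(footprints, offsets, models = NULL) {
  validate_offset_table(offsets)
  miss <- setdiff(unique(footprints$length), offsets$length)
  if (length(miss) > 0) {
    abort(paste0("read length(s) missing from offset table: ",
                 paste(sort(miss), collapse = ", ")))
  }
  out <- footprints %>%
    mutate(psite = .data$five_prime +
             offsets$offset[match(.data$length, offsets$length)])
  if (!is.null(models)) {
    tx_len <- nchar(models$seq)[match(out$transcript_id, models$id)]
    if (anyNA(tx_len)) {
      abort("footprints reference transcripts absent from models")
    }
    ok <- out$psite >= 0L & out$psite < tx_len
    n_out <- sum(!ok)
    if (n_out > 0) {
      inform(paste0(n_out, " footprint(s) with out-of-transcript P-sites ",
                    "dropped"))
    }
    out <- out[ok, , drop = FALSE]
    attr(out, "n_out_of_range") <- n_out
  }
  out
}

validate_offset_table <- function(offsets) {
  stopifnot(all(c("length", "offset") %in% names(offsets)))
  if (any(offsets$offset < 0 | offsets$offset >= offsets$length)) {
    abort("offset table violates 0 <= offset < read length")
  }
  invisible(TRUE)
}

#' Reading frame of P-site positions relative to the CDS
#'
#' Frame is `(psite - utr5_len) mod 3` with floored modulo, so frame 0 in the
#' 3'-UTR means in-frame with the CDS (readthrough is by definition in-frame).
#'
#' @param models Model tibble.
#' @param transcript_id Character vector of transcript ids.
#' @param psite Integer vector of 0-based P-site positions.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
frame_of <- function(models, transcript_id, psite) {
  idx <- match(transcript_id, models$id)
  if (anyNA(idx)) {
    abort("unknown transcript id(s) in frame_of()")
  }
  tx_len <- nchar(models$seq)[idx]
  if (any(psite < 0L | psite >= tx_len)) {
    abort("P-site position outside transcript bounds")
  }
  as.integer((psite - models$utr5_len[idx]) %% 3L)
}

#' Add reading-frame annotation to footprints
#'
#' @param footprints Tibble with `transcript_id` and `psite` columns.
#' @param models Model tibble.
#' @return The tibble with an integer `frame` column.
#' @export
add_frames <- function(footprints, models) {
  footprints %>%
    mutate(frame = frame_of(models, .data$transcript_id, .data$psite))
}

#' Metagene profile of P-sites around the start or stop codon
#'
#' Pools P-site positions of all footprints across the supplied gene set,
#' expressed relative to the first nucleotide of the start or canonical stop
#' codon, and normalizes by the total number of footprints in the window
#' (pool-then-normalize; no per-gene normalization).
#'
#' @param footprints Tibble with `transcript_id` and `psite`.
#' @param models Model tibble (restrict to the reference set before calling
#'   if desired).
#' @param anchor `"start"` or `"stop"`.
#' @param window Length-2 integer vector of relative positions, inclusive.
#'   Defaults to `c(-20, 40)` around the start and `c(-40, 80)` around the
#'   stop codon.
#' @return A tibble of class `rt_metagene` with columns `position`, `n`,
#'   `fraction`.
#' @export
metagene_profile <- function(footprints, models,
                             anchor = c("start", "stop"), window = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window)) {
    window <- if (anchor == "start") c(-20L, 40L) else c(-40L, 80L)
  }
  idx <- match(footprints$transcript_id, models$id)
  keep <- !is.na(idx)
  fp <- footprints[keep, , drop = FALSE]
  idx <- idx[keep]
  anchor_pos <- if (anchor == "start") models$utr5_len[idx] else
    models$utr5_len[idx] + models$cds_len[idx] - 3L
  rel <- fp$psite - anchor_pos
  rel <- rel[rel >= window[1] & rel <= window[2]]
  grid <- seq.int(window[1], window[2])
  n <- tabulate(match(rel, grid), nbins = length(grid))
  total <- sum(n)
  if (total == 0) {
    warn("no footprints fall in the metagene window; all-zero profile")
    frac <- rep(0, length(grid))
  } else {
    frac <- n / total
  }
  out <- tibble(position = grid, n = n, fraction = frac)
  class(out) <- c("rt_metagene", class(out))
  attr(out, "anchor") <- anchor
  attr(out, "window") <- window
  out
}

#' Count footprints by gene, region and reading frame
#'
#' Tallies frame-annotated P-sites by analysis region per gene, plus an
#' edge-trimmed CDS count (`cds_trimmed`) that additionally excludes P-sites
#' in the first `cds_exclude[1]` and last `cds_exclude[2]` nucleotides of the
#' annotated CDS (defaults 15 and 33 nt, compensating for ribosome queuing at
#' start and stop codons). Genes whose CDS is shorter than
#' `sum(cds_exclude) + 3` nt get `NA` trimmed counts and are flagged.
#'
#' @param footprints Frame-annotated footprint tibble (`transcript_id`,
#'   `psite`, `frame`).
#' @param models Model tibble.
#' @param regionmaps Region-map tibble from [locate_extensions()].
#' @param cds_exclude Length-2 integer vector: nucleotides excluded from the
#'   CDS 5' and 3' edges for the trimmed counts.
#' @param stop_in_utr3 Region-labeling convention switch (see [region_of()]).
#' @return A long tibble `id x region x frame` with a complete grid over the
#'   genes in `models` (regions `utr5`, `cds`, `extension`, `distal_utr3`,
#'   `cds_trimmed`). The total number of in-range footprints is stored as
#'   `attr(, "library_total")`; flagged short-CDS genes as
#'   `attr(, "short_cds")`.
#' @export
count_region_frames <- function(footprints, models, regionmaps,
                                cds_exclude = c(15L, 33L),
                                stop_in_utr3 = TRUE) {
  stopifnot("frame" %in% names(footprints))
  fp <- footprints %>% filter(.data$transcript_id %in% models$id)
  fp <- fp %>%
    mutate(region = region_of(regionmaps, .data$transcript_id, .data$psite,
                              stop_in_utr3 = stop_in_utr3))
  regions <- c("utr5", "cds", "extension", "distal_utr3")
  base <- fp %>%
    count(.data$transcript_id, .data$region, .data$frame) %>%
    rename(id = "transcript_id")

  # trimmed CDS counts on the annotated CDS (stop codon included in the zone)
  idx <- match(fp$transcript_id, models$id)
  cds_lo <- models$utr5_len[idx]
  cds_hi <- cds_lo + models$cds_len[idx]
  in_trim <- fp$psite >= cds_lo + cds_exclude[1] &
    fp$psite < cds_hi - cds_exclude[2] & fp$region == "cds"
  trimmed <- fp[in_trim, , drop = FALSE] %>%
    count(.data$transcript_id, .data$frame) %>%
    rename(id = "transcript_id") %>%
    mutate(region = "cds_trimmed")

  grid <- tidyr::expand_grid(
    id = models$id, region = c(regions, "cds_trimmed"), frame = 0:2
  )
  counts <- grid %>%
    left_join(bind_rows(base, trimmed), by = c("id", "region", "frame")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))

  short <- models$id[models$cds_len < sum(cds_exclude) + 3L]
  if (length(short) > 0) {
    counts$n[counts$id %in% short & counts$region == "cds_trimmed"] <- NA
  }
  attr(counts, "library_total") <- nrow(fp)
  attr(counts, "short_cds") <- short
  attr(counts, "cds_exclude") <- cds_exclude
  counts
}

#' Per-frame read fractions for a region
#'
#' @param counts Region-frame count tibble from [count_region_frames()].
#' @param region Region label to summarise (`NULL` for all regions).
#' @param by_gene Compute per-gene fractions instead of pooling over genes.
#' @return Tibble with `region`, `frame`, `n`, `fraction` (plus `id` when
#'   `by_gene`). Fractions are `NA` (flagged) where a region's total is zero.
#' @export
frame_fractions <- function(counts, region = NULL, by_gene = FALSE) {
  x <- counts %>% filter(.data$region != "cds_trimmed")
  if (!is.null(region)) {
    reg <- region
    x <- x %>% filter(.data$region %in% reg)
  }
  keys <- if (by_gene) c("id", "region") else "region"
  x %>%
    group_by(across(all_of(keys)), .data$frame) %>%
    summarise(n = sum(.data$n), .groups = "drop_last") %>%
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n)
           else NA_real_) %>%
    ungroup()
}
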