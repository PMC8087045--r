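# The adjusted readthrough-efficiency statistic, expression filters,
# High/Low grouping, and PTC readthrough ratios.

#' Reads per kilobase of region per million mapped reads
#'
#' @param count Read count(s).
#' @param region_len Region length(s) in nt (must be positive).
#' @param library_total Total mapped reads in the library (must be positive).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, region_len, library_total) {
  if (any(region_len <= 0)) abort("region_len must be positive")
  if (any(library_total <= 0)) abort("library_total must be positive")
  count / (region_len / 1e3) / (library_total / 1e6)
}

#' Compute the adjusted readthrough efficiency per gene
#'
#' The statistic is the log2 ratio of frame-0 ribosome density (footprint
#' count per nt) in the adjusted 3'-UTR (canonical stop codon + annotated
#' 3'-UTR) to frame-0 density in the edge-trimmed CDS:
#' `log2((n_f0_utr3 / utr3_len_adj) / (n_f0_cds_trimmed / cds_trimmed_len))`.
#' Only frame-0 P-sites enter either term; CDS counts exclude the first 15
#' and last 33 nt edge zones (already applied in `counts`), while the 3'-UTR
#' term applies no exclusion at the downstream stop because many extension
#' regions are shorter than the exclusion zone — readthrough can therefore be
#' somewhat overestimated where ribosomes pile up at the downstream stop.
#'
#' Genes with zero trimmed-CDS frame-0 counts get `NA` (undefined); genes
#' with zero 3'-UTR frame-0 counts get `-Inf` (excluded from ranked
#' analyses). No pseudocounts are used.
#'
#' @param counts Region-frame count tibble from [count_region_frames()].
#' @param models Model tibble.
#' @param regionmaps Region-map tibble.
#' @param numerator `"utr3"` (default: whole adjusted 3'-UTR) or
#'   `"extension"` (extension region only).
#' @param include_stop_in_len Count the canonical stop's 3 nt in the 3'-UTR
#'   density denominator (default `TRUE`, consistent with the adjusted
#'   transcriptome convention).
#' @return A tibble with per-gene counts, lengths, `log2_re`, `rpkm_cds`,
#'   `rpkm_utr3`, and placeholder `passes_filter`/`group` columns.
#' @export
readthrough_efficiency <- function(counts, models, regionmaps,
                                   numerator = c("utr3", "extension"),
                                   include_stop_in_len = TRUE) {
  numerator <- match.arg(numerator)
  library_total <- attr(counts, "library_total") %||%
    sum(counts$n[counts$region != "cds_trimmed"], na.rm = TRUE)
  cds_exclude <- attr(counts, "cds_exclude") %||% c(15L, 33L)

  wide <- counts %>%
    group_by(.data$id, .data$region) %>%
    summarise(n_all = sum(.data$n),
              n_f0 = sum(.data$n[.data$frame == 0L]),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "region",
                       values_from = c("n_all", "n_f0"),
                       values_fill = list(n_all = 0L, n_f0 = 0L))
  rm_idx <- match(wide$id, regionmaps$id)
  m_idx <- match(wide$id, models$id)
  cds_len <- models$cds_len[m_idx]
  utr3_len <- models$utr3_len[m_idx]
  ext_len <- regionmaps$ext_hi[rm_idx] - regionmaps$ext_lo[rm_idx]

  n_f0_utr3 <- if (numerator == "utr3") {
    wide$n_f0_extension + wide$n_f0_distal_utr3
  } else {
    # extension-only numerator still includes reads on the canonical stop
    # flank, which region_of() labels as extension
    wide$n_f0_extension
  }
  utr3_len_adj <- if (numerator == "utr3") {
    utr3_len + if (include_stop_in_len) 3L else 0L
  } else {
    ext_len + if (include_stop_in_len) 3L else 0L
  }
  cds_trimmed_len <- cds_len - sum(cds_exclude)
  n_f0_cds_trimmed <- wide$n_f0_cds_trimmed

  density_utr3 <- n_f0_utr3 / utr3_len_adj
  density_cds <- n_f0_cds_trimmed / cds_trimmed_len
  log2_re <- ifelse(
    is.na(n_f0_cds_trimmed) | n_f0_cds_trimmed == 0 | cds_trimmed_len <= 0,
    NA_real_,
    ifelse(n_f0_utr3 == 0, -Inf, log2(density_utr3 / density_cds))
  )

  tibble(
    id = wide$id,
    n_f0_cds_trimmed = n_f0_cds_trimmed,
    n_f0_utr3 = n_f0_utr3,
    cds_trimmed_len = cds_trimmed_len,
    utr3_len_adj = utr3_len_adj,
    log2_re = log2_re,
    rpkm_cds = rpkm(wide$n_all_cds, pmax(cds_len - 3L, 1L), library_total),
    rpkm_utr3 = rpkm(wide$n_all_extension + wide$n_all_distal_utr3,
                     pmax(utr3_len + 3L, 1L), library_total),
    passes_filter = NA,
    group = NA_character_
  )
}

#' Apply the expression-level filters
#'
#' The default conjunctive rule discards genes with *both* CDS RPKM below
#' `min_rpkm_cds` *and* 3'-UTR RPKM below `min_rpkm_utr3`; the disjunctive
#' variant discards genes failing either threshold.
#'
#' @param estimates Tibble from [readthrough_efficiency()].
#' @param min_rpkm_cds,min_rpkm_utr3 RPKM thresholds (defaults 5 and 0.5).
#' @param rule `"conjunctive"` (default) or `"disjunctive"`.
#' @return The tibble with `passes_filter` set.
#' @export
apply_expression_filters <- function(estimates, min_rpkm_cds = 5,
                                     min_rpkm_utr3 = 0.5,
                                     rule = c("conjunctive", "disjunctive")) {
  rule <- match.arg(rule)
  low_cds <- estimates$rpkm_cds < min_rpkm_cds
  low_utr3 <- estimates$rpkm_utr3 < min_rpkm_utr3
  estimates$passes_filter <- if (rule == "conjunctive") {
    !(low_cds & low_utr3)
  } else {
    !(low_cds | low_utr3)
  }
  estimates
}

#' Assign High / Low / Mid readthrough groups
#'
#' Ranks filtered genes with finite `log2_re` and labels the top `fraction`
#' as `High` and the bottom `fraction` as `Low` (the rest `Mid`; genes not
#' passing the filters or without a finite estimate stay `NA`). Group sizes
#' are `floor(n * fraction)`. Ties are broken by gene id so the grouping is
#' order-independent.
#'
#' @param estimates Tibble with `log2_re` and `passes_filter` columns.
#' @param fraction Tail fraction per group (default 0.15).
#' @return The tibble with `group` set.
#' @export
classify_high_low <- function(estimates, fraction = 0.15) {
  eligible <- which(estimates$passes_filter %in% TRUE &
                      is.finite(estimates$log2_re))
  n <- length(eligible)
  if (n < ceiling(2 / fraction)) {
    abort(paste0("too few filtered finite estimates (", n,
                 ") to form High/Low groups"))
  }
  vals <- estimates$log2_re[eligible]
  if (length(unique(vals)) == 1L) {
    abort("all readthrough estimates identical; quantile groups undefined")
  }
  k <- floor(n * fraction)
  ord <- eligible[order(vals, estimates$id[eligible])]
  estimates$group[eligible] <- "Mid"
  estimates$group[head(ord, k)] <- "Low"
  estimates$group[utils::tail(ord, k)] <- "High"
  estimates
}

#' Readthrough of a premature termination codon
#'
#' Ratio of frame-0 P-site counts strictly downstream of the PTC (past its
#' codon, through the end of the annotated CDS) to those strictly upstream
#' (from the CDS start). The ratio cancels mRNA-abundance differences between
#' samples.
#'
#' @param footprints Frame-annotated footprints for one sample.
#' @param models Model tibble.
#' @param ptc_table Tibble with `id` and `ptc_pos` (0-based transcript
#'   position of the PTC's first nucleotide; must be in frame 0 within the
#'   CDS).
#' @return Tibble `id`, `ptc_pos`, `n_f0_down`, `n_f0_up`, `ratio` (`NA` and
#'   flagged when no upstream counts exist).
#' @export
ptc_readthrough <- function(footprints, models, ptc_table) {
  purrr::pmap(ptc_table, function(id, ptc_pos, ...) {
    m <- models[models$id == id, ]
    if (nrow(m) != 1L) abort(paste0("unknown gene: ", id))
    cds_lo <- m$utr5_len
    cds_hi <- m$utr5_len + m$cds_len
    if (ptc_pos < cds_lo || ptc_pos + 3L > cds_hi ||
        (ptc_pos - cds_lo) %% 3L != 0L) {
      abort(paste0("ptc_pos not an in-frame CDS codon start for ", id))
    }
    fp <- footprints[footprints$transcript_id == id &
                       footprints$frame == 0L, ]
    up <- sum(fp$psite >= cds_lo & fp$psite < ptc_pos)
    down <- sum(fp$psite >= ptc_pos + 3L & fp$psite < cds_hi)
    tibble(id = id, ptc_pos = ptc_pos, n_f0_down = down, n_f0_up = up,
           ratio = if (up > 0) down / up else NA_real_)
  }) %>% bind_rows()
}
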