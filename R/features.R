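# The per-gene X-variable set: stop-codon context nucleotides, nascent
# peptide exit-tunnel properties, 3'-UTR descriptors, codon optimality, and
# randomized negative controls.
#
# Position numbering follows the mRNA-channel convention: the stop codon is
# nt +1..+3 in the A site, nt +4 is the first nucleotide after it, and nt -1
# is the last nucleotide of the penultimate (P-site) codon.

#' Default residue property tables
#'
#' Charge: + = K, R, H; - = D, E; 0 = the rest. Polarity and the four-class
#' hydrophobicity grouping follow the Kyte-Doolittle scale binned at 2.8, 1.0
#' and -3.4 (very hydrophobic F/I/V/L, hydrophobic A/M/C, neutral
#' G/T/S/W/Y/P/H, hydrophilic R/K/N/D/Q/E). Aromatic residues are F, W, Y.
#' All tables cover the 20 residues exactly once and can be overridden.
#'
#' @return Tibble with columns `aa`, `charge`, `polarity`, `aromatic`,
#'   `hydrophobicity`.
#' @export
residue_properties <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  charge <- ifelse(aa %in% c("K", "R", "H"), "pos",
                   ifelse(aa %in% c("D", "E"), "neg", "neutral"))
  polarity <- ifelse(aa %in% c("S", "T", "C", "Y", "N", "Q", "D", "E",
                               "K", "R", "H"), "polar", "nonpolar")
  aromatic <- ifelse(aa %in% c("F", "W", "Y"), "aromatic", "nonaromatic")
  hydro <- dplyr::case_when(
    aa %in% c("F", "I", "V", "L") ~ "very_hydrophobic",
    aa %in% c("A", "M", "C") ~ "hydrophobic",
    aa %in% c("G", "T", "S", "W", "Y", "P", "H") ~ "neutral",
    TRUE ~ "hydrophilic"
  )
  tibble(aa = aa, charge = charge, polarity = polarity,
         aromatic = aromatic, hydrophobicity = hydro)
}

translate_codons <- function(codons) {
  aa <- GENETIC_CODE_RNA[codons]
  if (anyNA(aa)) abort("unknown codon(s) in translation")
  unname(aa)
}

#' Extract stop-codon context nucleotides and flanking codons
#'
#' Reads the stop codon identity, nt -15..-1 (CDS side), nt +4..+9 (3'-UTR
#' side), the first in-frame downstream stop codon identity, and the P-/E-site
#' codons and amino acids directly from each transcript sequence. Genes whose
#' 3'-UTR extends fewer than 6 nt past the stop get `NA` for the missing +k
#' positions; genes with fewer than 18 nt of CDS upstream of the stop get
#' `NA` for missing -k positions. Both are flagged in `context_complete`.
#'
#' @param models Model tibble.
#' @param regionmaps Region-map tibble from [locate_extensions()].
#' @return One row per gene with columns `stop_codon`, `nt_m15`..`nt_m1`,
#'   `nt_p4`..`nt_p9`, `first_utr3_stop`, `p_site_codon`, `e_site_codon`,
#'   `p_site_aa`, `e_site_aa`, `utr3_len`, `context_complete`.
#' @export
extract_sequence_context <- function(models, regionmaps) {
  stop_lo <- models$utr5_len + models$cds_len - 3L  # 0-based
  seq <- models$seq
  char_at <- function(pos0) {
    # pos0: 0-based position; NA where out of range
    ok <- pos0 >= 0L & pos0 < nchar(seq)
    out <- rep(NA_character_, length(pos0))
    out[ok] <- substr(seq[ok], pos0[ok] + 1L, pos0[ok] + 1L)
    out
  }
  ctx <- tibble(id = models$id)
  for (k in 15:1) {
    v <- char_at(stop_lo - k)
    v[models$cds_len - 3L < k] <- NA_character_  # -k must lie within the CDS
    ctx[[paste0("nt_m", k)]] <- v
  }
  ctx$stop_codon <- substr(seq, stop_lo + 1L, stop_lo + 3L)
  for (k in 4:9) {
    ctx[[paste0("nt_p", k)]] <- char_at(stop_lo + k - 1L)
  }
  # only positions within the transcript's 3'-UTR count; flag short 3'-UTRs
  short3 <- models$utr3_len < 6L
  for (k in 4:9) {
    col <- paste0("nt_p", k)
    ctx[[col]][models$utr3_len < k - 3L] <- NA_character_
  }
  rm_idx <- match(models$id, regionmaps$id)
  ctx$first_utr3_stop <- ifelse(
    regionmaps$has_downstream_stop[rm_idx],
    substr(seq, regionmaps$ext_hi[rm_idx] - 2L, regionmaps$ext_hi[rm_idx]),
    "none"
  )
  p_cod <- substr(seq, stop_lo - 2L, stop_lo)
  e_cod <- substr(seq, stop_lo - 5L, stop_lo - 3L)
  enough_p <- models$cds_len >= 9L
  enough_e <- models$cds_len >= 12L
  ctx$p_site_codon <- ifelse(enough_p, p_cod, NA_character_)
  ctx$e_site_codon <- ifelse(enough_e, e_cod, NA_character_)
  ctx$p_site_aa <- ifelse(enough_p, GENETIC_CODE_RNA[p_cod], NA_character_)
  ctx$e_site_aa <- ifelse(enough_e, GENETIC_CODE_RNA[e_cod], NA_character_)
  ctx$utr3_len <- models$utr3_len
  ctx$context_complete <- !short3 & models$cds_len >= 18L + 3L
  ctx %>% relocate("id", "stop_codon")
}

#' Translate the C-terminal residues of each CDS
#'
#' Residue "aa 1" is the last residue before the stop codon (the P-site
#' residue when the stop occupies the A site); indexing increases toward the
#' N-terminus. Genes with fewer than `n_codons` sense codons return the full
#' (shorter) string and are flagged.
#'
#' @param models Model tibble.
#' @param n_codons Number of C-terminal residues to return (default 30,
#'   covering the ribosome exit tunnel).
#' @return Tibble `id`, `c_term` (residue string, aa 1 first), `n_aa`,
#'   `truncated`.
#' @export
translate_c_terminus <- function(models, n_codons = 30L) {
  res <- purrr::pmap(
    list(models$id, models$seq, models$utr5_len, models$cds_len),
    function(id, seq, u5, cl) {
      n_sense <- cl %/% 3L - 1L
      take <- min(n_codons, n_sense)
      stop_lo <- u5 + cl - 3L
      starts <- stop_lo - 3L * seq_len(take)  # aa1, aa2, ... (0-based)
      codons <- substr(rep(seq, take), starts + 1L, starts + 3L)
      if (any(codons %in% STOP_CODONS)) {
        abort(paste0("in-frame internal stop codon in CDS of ", id))
      }
      tibble(id = id,
             c_term = paste(translate_codons(codons), collapse = ""),
             n_aa = take, truncated = take < n_codons)
    }
  )
  bind_rows(res)
}

#' Residue-class fractions for an exit-tunnel window
#'
#' Counts of each charge / polarity / aromaticity / hydrophobicity class
#' divided by the window length; each class group sums to 1 over a non-empty
#' window. Empty windows return `NA` fractions.
#'
#' @param window Character vector of residue strings (one window per gene).
#' @param tables Residue property tables (default [residue_properties()]).
#' @return Tibble of per-window class fractions.
#' @export
tunnel_property_fractions <- function(window, tables = residue_properties()) {
  classes <- list(
    charge = c("pos", "neutral", "neg"),
    polarity = c("polar", "nonpolar"),
    aromatic = c("aromatic"),
    hydrophobicity = c("hydrophilic", "neutral", "hydrophobic",
                       "very_hydrophobic")
  )
  out <- purrr::map(window, function(w) {
    if (is.na(w) || nchar(w) == 0L) {
      vals <- unlist(unname(purrr::imap(classes, function(lv, p)
        setNames(rep(NA_real_, length(lv)), paste0(p, "_", lv)))))
      return(as_tibble(as.list(vals)))
    }
    aa <- strsplit(w, "")[[1]]
    idx <- match(aa, tables$aa)
    if (anyNA(idx)) abort("unknown residue in tunnel window")
    vals <- unlist(unname(purrr::imap(classes, function(lv, p) {
      col <- tables[[p]][idx]
      setNames(purrr::map_dbl(lv, ~ mean(col == .x)), paste0(p, "_", lv))
    })))
    as_tibble(as.list(vals))
  })
  bind_rows(out)
}

TUNNEL_REGIONS <- list(upper = 3:9, constriction = 10:12,
                       central = 13:19, lower = 20:30)

tunnel_window <- function(c_term, positions) {
  purrr::map_chr(c_term, function(s) {
    pos <- positions[positions <= nchar(s)]
    if (length(pos) == 0L) return(NA_character_)
    paste(strsplit(s, "")[[1]][pos], collapse = "")
  })
}

#' Attach externally predicted features
#'
#' Copies per-gene 3'-UTR structure values (lowest minimum free energy of a
#' 150-nt scanning window and distance of the structure from the stop codon)
#' and lower-tunnel helix fractions from externally produced tables. These
#' are always consumed as inputs, never computed here. Genes absent from a
#' table get `NA`.
#'
#' @param features Feature tibble keyed by `id`.
#' @param struct_table Data frame or TSV path with `id`, `mfe` (kcal/mol,
#'   <= 0), `struct_distance` (nt), or `NULL`.
#' @param helix_table Data frame or TSV path with `id`, `helix_fraction`
#'   in `[0, 1]`, or `NULL`.
#' @return The feature tibble with `mfe`, `struct_distance`,
#'   `helix_fraction` columns.
#' @export
attach_external_features <- function(features, struct_table = NULL,
                                     helix_table = NULL) {
  read_tbl <- function(x) {
    if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else x
  }
  struct_table <- read_tbl(struct_table)
  helix_table <- read_tbl(helix_table)
  if (!is.null(struct_table)) {
    stopifnot(all(c("id", "mfe", "struct_distance") %in% names(struct_table)))
    if (any(struct_table$mfe > 0, na.rm = TRUE)) {
      abort("mfe values must be <= 0 kcal/mol")
    }
    features$mfe <- struct_table$mfe[match(features$id, struct_table$id)]
    features$struct_distance <-
      struct_table$struct_distance[match(features$id, struct_table$id)]
  } else {
    features$mfe <- NA_real_
    features$struct_distance <- NA_real_
  }
  if (!is.null(helix_table)) {
    stopifnot(all(c("id", "helix_fraction") %in% names(helix_table)))
    if (any(helix_table$helix_fraction < 0 | helix_table$helix_fraction > 1,
            na.rm = TRUE)) {
      abort("helix_fraction values must lie in [0, 1]")
    }
    features$helix_fraction <-
      helix_table$helix_fraction[match(features$id, helix_table$id)]
  } else {
    features$helix_fraction <- NA_real_
  }
  n_absent <- sum(is.na(features$mfe)) + sum(is.na(features$helix_fraction))
  if (n_absent > 0 && (!is.null(struct_table) || !is.null(helix_table))) {
    inform(paste0(n_absent, " external feature value(s) missing; set to NA"))
  }
  features
}

#' Add randomized negative-control features
#'
#' Assigns each gene one uniform integer in 1..100 (`random_number`) and one
#' uniform category from A/C/G/U (`random_factor`). Because the assignment is
#' random, neither variable can carry signal; they calibrate the importance
#' baseline of the forest models. Reproducible under `seed`.
#'
#' @param features Feature tibble keyed by `id`.
#' @param seed Integer seed.
#' @return The tibble with `random_number` and `random_factor` columns.
#' @export
add_negative_controls <- function(features, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(features)
  features$random_number <- sample.int(100L, n, replace = TRUE)
  features$random_factor <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  features
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Per-gene codon optimality from a tAI table
#'
#' Geometric mean of per-codon tRNA adaptation index over the CDS sense
#' codons (stop excluded). [codon_tai()] exposes the per-codon lookup, e.g.
#' for annotating P-site codons.
#'
#' @param models Model tibble.
#' @param tai_table Data frame or TSV path with columns `codon` (RNA
#'   alphabet) and `tai` in `[0, 1]` covering the 61 sense codons.
#' @return Tibble `id`, `tai`.
#' @export
gene_tai <- function(models, tai_table) {
  if (is.character(tai_table)) {
    tai_table <- readr::read_tsv(tai_table, show_col_types = FALSE)
  }
  tab <- setNames(tai_table$tai, tai_table$codon)
  res <- purrr::pmap_dbl(
    list(models$seq, models$utr5_len, models$cds_len),
    function(seq, u5, cl) {
      starts <- u5 + 3L * (seq_len(cl %/% 3L - 1L) - 1L)
      codons <- substr(rep(seq, length(starts)), starts + 1L, starts + 3L)
      vals <- tab[codons]
      if (anyNA(vals)) abort("codon absent from tAI table")
      exp(mean(log(vals)))
    }
  )
  tibble(id = models$id, tai = res)
}

#' @rdname gene_tai
#' @param codons Character vector of RNA codons.
#' @export
codon_tai <- function(codons, tai_table) {
  if (is.character(tai_table) && length(tai_table) == 1L &&
      file.exists(tai_table)) {
    tai_table <- readr::read_tsv(tai_table, show_col_types = FALSE)
  }
  vals <- tai_table$tai[match(codons, tai_table$codon)]
  if (anyNA(vals)) abort("codon absent from tAI table")
  vals
}

#' Assemble the per-gene feature matrix
#'
#' Combines sequence context, exit-tunnel residue-class fractions for the
#' four tunnel regions (upper aa 3-9, constriction aa 10-12, central aa
#' 13-19, lower aa 20-30), 3'-UTR descriptors, external predictions, and the
#' randomized negative controls into one wide tibble. Feature extraction is a
#' pure function of (models, tables, seed). The feature schema (name, type,
#' group) is attached as `attr(, "schema")` and via [feature_schema()].
#'
#' @param models Model tibble.
#' @param regionmaps Region-map tibble.
#' @param seed Seed for the negative controls.
#' @param struct_table,helix_table Optional external feature tables (see
#'   [attach_external_features()]).
#' @param tables Residue property tables.
#' @return Wide feature tibble, one row per gene.
#' @export
build_feature_matrix <- function(models, regionmaps, seed,
                                 struct_table = NULL, helix_table = NULL,
                                 tables = residue_properties()) {
  ctx <- extract_sequence_context(models, regionmaps)
  cterm <- translate_c_terminus(models)
  fm <- ctx %>% left_join(cterm %>% select("id", "c_term"), by = "id")
  for (reg in names(TUNNEL_REGIONS)) {
    win <- tunnel_window(fm$c_term, TUNNEL_REGIONS[[reg]])
    fr <- tunnel_property_fractions(win, tables)
    names(fr) <- paste0(reg, "_", names(fr))
    fm <- bind_cols(fm, fr)
  }
  fm <- fm %>% select(-"c_term")
  fm <- attach_external_features(fm, struct_table, helix_table)
  fm <- add_negative_controls(fm, seed)
  cat_cols <- c("stop_codon", paste0("nt_m", 15:1), paste0("nt_p", 4:9),
                "first_utr3_stop", "p_site_aa", "e_site_aa", "random_factor")
  num_cols <- setdiff(names(fm), c("id", "context_complete", "p_site_codon",
                                   "e_site_codon", cat_cols))
  schema <- tibble(
    feature = c(cat_cols, num_cols),
    type = c(rep("categorical", length(cat_cols)),
             rep("numeric", length(num_cols)))
  )
  attr(fm, "schema") <- schema
  fm
}

#' @rdname build_feature_matrix
#' @param features A feature tibble from [build_feature_matrix()].
#' @export
feature_schema <- function(features) {
  attr(features, "schema")
}
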