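# Fixture builders and independent brute-force oracles used across tests.

# Build a single transcript model from explicit region sequences.
toy_model <- function(id = "tx1", utr5 = "ACGU", cds = "AUGGCUUAA",
                      utr3 = "CAAAAA", utr3_annotated = TRUE) {
  tibble::tibble(
    id = id, seq = paste0(utr5, cds, utr3),
    utr5_len = nchar(utr5), cds_len = nchar(cds), utr3_len = nchar(utr3),
    utr3_annotated = utr3_annotated
  )
}

# Footprint tibble straight from P-site positions (offset-0 reads).
toy_footprints <- function(id, psite, length = 28L) {
  tibble::tibble(transcript_id = id, five_prime = as.integer(psite),
                 length = as.integer(length), psite = as.integer(psite))
}

zero_offsets <- tibble::tibble(length = c(20:23, 27:32), offset = 0L)

# Independent codon-by-codon scan for the extension length (nt), counting
# the first downstream in-frame stop codon as part of the extension.
oracle_ext_len <- function(utr3_seq) {
  stops <- c("UAA", "UAG", "UGA")
  i <- 1L
  while (i + 2L <= nchar(utr3_seq)) {
    if (substr(utr3_seq, i, i + 2L) %in% stops) return(i + 2L)
    i <- i + 3L
  }
  nchar(utr3_seq)
}

# Independent per-nucleotide region labeler (stop codon on the 3'-UTR side,
# canonical-stop flank and extension both labeled "extension").
oracle_region_labels <- function(model) {
  u5 <- model$utr5_len
  cl <- model$cds_len
  tx_len <- nchar(model$seq)
  utr3_seq <- substr(model$seq, u5 + cl + 1L, tx_len)
  ext_end <- u5 + cl + oracle_ext_len(utr3_seq)  # 0-based half-open
  vapply(seq_len(tx_len) - 1L, function(pos) {
    if (pos < u5) "utr5"
    else if (pos < u5 + cl - 3L) "cds"
    else if (pos < u5 + cl) "extension"       # canonical stop flank
    else if (pos < ext_end) "extension"
    else "distal_utr3"
  }, character(1))
}

# Random valid transcript model (independent of the package generator).
random_toy_model <- function(id, seed) {
  set.seed(seed)
  nt <- c("A", "C", "G", "U")
  rand <- function(n) paste(sample(nt, n, replace = TRUE), collapse = "")
  sense <- setdiff(
    as.vector(outer(outer(nt, nt, paste0), nt, paste0)),
    c("UAA", "UAG", "UGA")
  )
  n_cod <- sample(10:25, 1)
  cds <- paste0("AUG",
                paste(sample(sense, n_cod, replace = TRUE), collapse = ""),
                sample(c("UAA", "UAG", "UGA"), 1))
  toy_model(id = id, utr5 = rand(sample(5:40, 1)), cds = cds,
            utr3 = rand(sample(10:90, 1)))
}
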