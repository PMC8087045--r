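# Shared constants: RNA-alphabet codon tables.

STOP_CODONS <- c("UAA", "UAG", "UGA")

GENETIC_CODE_RNA <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), chartr("T", "U", names(gc)))
})

SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "U")
  all <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(all, STOP_CODONS)
})
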