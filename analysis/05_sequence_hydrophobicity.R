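#!/usr/bin/env Rscript
# Sequence-level analyses: the Eisenberg hydrophobicity index of the
# residue-63 cavity, and pairwise global-alignment identity. The cross-species
# identity comparison needs the full-length UniProt sequences (Q14116 human,
# P97636 rat, Q9TU73 bovine, Q9XSQ7 horse, P70380 mouse) and therefore a
# one-time download; offline, the identity machinery is demonstrated on
# bundled synthetic demo sequences instead.

source(file.path("analysis", "00_common.R"))

cavity <- il18_cavity63()
idx <- hydrophobicity_index(cavity$residue)
cat(sprintf("Residue-63 cavity (%d residues): hydrophobicity index %.2f\n",
            nrow(cavity), idx))
cat("  hydrophobic:", paste(cavity$residue[cavity$group == "hydrophobic"],
                            collapse = ", "), "\n")
cat("  hydrophilic:", paste(cavity$residue[cavity$group == "hydrophilic"],
                            collapse = ", "), "\n")
cav_out <- cavity
cav_out$eisenberg <- vapply(cavity$residue, hydrophobicity_index, numeric(1))
write_tsv(cav_out, file.path(results_dir, "cavity63_hydrophobicity.tsv"))

accessions <- c("Q14116", "P97636", "Q9TU73", "Q9XSQ7", "P70380")
fa <- file.path("scratch", "il18_uniprot.fasta")
fetched <- tryCatch({
  if (!file.exists(fa)) fetch_uniprot_fasta(accessions, fa)
  TRUE
}, error = function(e) FALSE, warning = function(w) FALSE)

if (isTRUE(fetched) && file.exists(fa)) {
  seqs <- read_fasta(fa)
  named <- stats::setNames(seqs$seq,
                           vapply(accessions, function(a) {
                             seqs$id[grepl(a, seqs$id)][1]
                           }, ""))
  m <- identity_matrix(named)
  write_tsv(cbind(id = rownames(m), as.data.frame(m)),
            file.path(results_dir, "identity_matrix_uniprot.tsv"))
  cat("Cross-species identity matrix written (UniProt full sequences).\n")
  print(round(m, 1))
} else {
  cat("UniProt not reachable; demonstrating identity on synthetic demo",
      "sequences.\n")
  demo <- c(
    demo_ref = "MKVLITTSAEWQRNDFGHYACDEKLMPVIWTSAE",
    demo_var = "MKVLITTSAEWQRNDFGHYACREKLMPVIWTSAE",  # one substitution
    demo_del = "MKVLITTSAEWQRNDFGHYACDEKLMPVIW"       # truncated
  )
  m <- identity_matrix(demo)
  write_tsv(cbind(id = rownames(m), as.data.frame(m)),
            file.path(results_dir, "identity_matrix_demo.tsv"))
  print(m)
}
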