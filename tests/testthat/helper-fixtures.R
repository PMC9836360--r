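# Hand-built synthetic GenBank fixture.  The 70 nt genome is assembled
# from segments chosen so every CDS location form has a hand-computable
# spliced sequence (literals asserted in the tests).
#   1..3    AAA
#   4..12   ATGGCAGCA      CDS atp8, forward
#   13..19  TTTTTTT
#   20..28  TGCTGCCAT      CDS cob, complement -> ATGGCAGCA
#   29..30  CC
#   31..36  ATGGCA         CDS nad1 exon 1
#   37..39  GGG
#   40..45  GCATAA         CDS nad1 exon 2 -> join = ATGGCAGCATAA
#   46..49  TTTT
#   50..55  TTACCA         CDS cox1 part 1 \ complement(join) ->
#   56..59  GGGG                            /   ATGGCATGGTAA
#   60..65  TGCCAT         CDS cox1 part 2
#   66..70  AAAAA          rRNA
fixture_genome_seq <- function() {
  paste0("AAA", "ATGGCAGCA", "TTTTTTT", "TGCTGCCAT", "CC", "ATGGCA",
         "GGG", "GCATAA", "TTTT", "TTACCA", "GGGG", "TGCCAT", "AAAAA")
}

write_genbank_fixture <- function(path = tempfile(fileext = ".gb")) {
  q <- function(x) paste0(strrep(" ", 21), x)
  f <- function(key, loc) sprintf("     %-16s%s", key, loc)
  seq70 <- tolower(fixture_genome_seq())
  lines <- c(
    "LOCUS       SYNMITO01                 70 bp    DNA     circular",
    "DEFINITION  Synthetic mitogenome fixture (hand-built, not a real genome).",
    "FEATURES             Location/Qualifiers",
    f("source", "1..70"),
    f("CDS", "4..12"),
    q("/gene=\"atp8\""),
    f("CDS", "complement(20..28)"),
    q("/gene=\"cob\""),
    f("CDS", "join(31..36,"),
    q("40..45)"),
    q("/gene=\"nad1\""),
    f("CDS", "complement(join(50..55,60..65))"),
    q("/gene=\"cox1\""),
    f("tRNA", "3..5"),
    q("/product=\"tRNA-Ala\""),
    q("/anticodon=\"(pos:3..5,aa:Ala,seq:ugc)\""),
    f("tRNA", "6..8"),
    q("/product=\"tRNA-Ala\""),
    q("/anticodon=\"(pos:6..8,aa:Ala,seq:ugc)\""),
    f("tRNA", "9..11"),
    q("/product=\"tRNA-Ile\""),
    q("/note=\"anticodon: GAU\""),
    f("tRNA", "13..15"),
    q("/product=\"tRNA-Ser\""),
    f("rRNA", "66..70"),
    q("/product=\"rnl\""),
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(seq70, seq(1, 60, 10),
                                         pmin(seq(10, 69, 10), 60)),
                               collapse = " ")),
    sprintf("%9d %s", 61, substring(seq70, 61, 70)),
    "//")
  writeLines(lines, path)
  path
}

write_fasta_fixture <- function(entries, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(mapply(function(h, s) c(paste0(">", h), s),
                           names(entries), entries, SIMPLIFY = FALSE)),
             path)
  path
}

# tRNA count TSV fixture
write_trna_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# expand a genes-by-64 counts matrix into a DNA CDS FASTA
counts_to_fasta <- function(m, path = tempfile(fileext = ".fa")) {
  entries <- stats::setNames(vapply(seq_len(nrow(m)), function(i) {
    cods <- rep(colnames(m), m[i, ])
    chartr("U", "T", paste(cods, collapse = ""))
  }, character(1)), rownames(m))
  write_fasta_fixture(entries, path)
}

# tRNAome -> tRNA count TSV
trnaome_to_tsv <- function(trn, path = tempfile(fileext = ".tsv")) {
  write_trna_fixture(data.frame(anticodon = names(trn$copy_numbers),
                                amino_acid = "Xxx",
                                copy_number = unname(trn$copy_numbers)),
                     path)
}

# full-coverage Watson-Crick tRNAome: one exact anticodon per sense codon
wc_trnaome <- function(code, copies = 1L) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  acs <- vapply(code$sense_codons, function(cod) {
    b <- strsplit(cod, "")[[1]]
    paste0(comp[[b[3]]], comp[[b[2]]], comp[[b[1]]])
  }, character(1))
  trnaome(stats::setNames(rep(copies, length(acs)), acs),
          genome_id = "wc", organelle = "mito")
}
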