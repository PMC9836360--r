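test_that("registered genetic codes have the documented structure", {
  std <- genetic_code("standard")
  expect_identical(std$codon_to_aa[["UGA"]], "*")
  expect_length(std$sense_codons, 61L)
  expect_equal(std$enc_max, 61)
  expect_setequal(std$families$Ile, c("AUU", "AUC", "AUA"))
  expect_identical(names(which(lengths(std$families) == 3L)), "Ile")

  mito <- genetic_code("mold_mito")
  expect_identical(mito$codon_to_aa[["UGA"]], "W")
  expect_identical(mito$codon_to_aa[["AUA"]], "I")
  expect_length(mito$sense_codons, 62L)
  expect_equal(mito$enc_max, 62)
  expect_setequal(mito$families$Trp, c("UGA", "UGG"))

  # numeric aliases resolve to the same tables
  expect_identical(genetic_code("1")$codon_to_aa, std$codon_to_aa)
  expect_identical(genetic_code("4")$codon_to_aa, mito$codon_to_aa)
  expect_error(genetic_code("no_such_code"), "unknown genetic code")
})

test_that("custom code table files round-trip; incomplete tables error", {
  std <- genetic_code("standard")
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(names(std$codon_to_aa), std$codon_to_aa, sep = "\t"), path)
  custom <- genetic_code(path)
  expect_identical(custom$codon_to_aa, std$codon_to_aa)
  expect_equal(custom$enc_max, 61)

  writeLines(paste(names(std$codon_to_aa)[1:63], std$codon_to_aa[1:63],
                   sep = "\t"), path)
  expect_error(genetic_code(path), "64 codons")
})

test_that("family partition covers every sense codon exactly once", {
  for (code_id in c("standard", "mold_mito")) {
    code <- genetic_code(code_id)
    for (split in c(TRUE, FALSE)) {
      fams <- codon_families(code, family_policy(split_sixfold = split,
                                                 exclude_nondegenerate = FALSE))
      flat <- unlist(fams, use.names = FALSE)
      expect_identical(sort(flat), sort(code$sense_codons))
      expect_false(anyDuplicated(flat) > 0)
    }
    # split policy: sixfold families become 4 + 2
    split_fams <- codon_families(code, family_policy())
    expect_setequal(split_fams$Ser4, c("UCU", "UCC", "UCA", "UCG"))
    expect_setequal(split_fams$Ser2, c("AGU", "AGC"))
    expect_setequal(split_fams$Leu2, c("UUA", "UUG"))
    expect_setequal(split_fams$Arg2, c("AGA", "AGG"))
  }
})

test_that("count_codons handles trimming, QC and errors as documented", {
  code <- genetic_code("standard")
  cc <- count_codons("ATGGCAGCA", code)
  expect_equal(cc$n_codons, 3L)
  expect_equal(unname(cc$counts[c("AUG", "GCA")]), c(1L, 2L))
  expect_equal(sum(cc$counts), cc$n_codons)

  trimmed <- count_codons("ATGGCATGA", code)
  expect_equal(trimmed$n_codons, 2L)
  expect_equal(unname(trimmed$counts["UGA"]), 0L)

  skipped <- count_codons("ATGNNNGCA", code)
  expect_equal(skipped$n_codons, 2L)
  expect_equal(skipped$n_skipped, 1L)

  expect_error(count_codons("ATGGCAG", code), "divisible by 3")
  expect_error(count_codons("ATGTGAGCA", code, gene_id = "bad"),
               "internal stop.*bad")
  # RNA input and lowercase are accepted
  expect_identical(count_codons("augGCAgca", code)$counts, cc$counts)
  # UGA is sense under the mold mito code: no trimming, no error
  mito <- genetic_code("mold_mito")
  expect_equal(count_codons("ATGTGAGCA", mito)$n_codons, 3L)
})

test_that("counting matches the naive oracle and splits over concatenation", {
  code <- genetic_code("standard")
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    cods <- sample(code$sense_codons, n, replace = TRUE)
    s <- chartr("U", "T", paste(cods, collapse = ""))
    got <- count_codons(s, code)
    expect_identical(got$counts, oracle_count(s, code$stop_codons))
    expect_equal(got$n_codons, sum(got$counts))
    # concatenation equals pooling of the halves
    k <- 3 * (n %/% 2)
    s1 <- substr(s, 1, k); s2 <- substr(s, k + 1, nchar(s))
    pooled <- pool_counts(list(count_codons(s1, code),
                               count_codons(s2, code)))
    expect_identical(pooled$counts, got$counts)
  }
})

test_that("pool_counts sums counts and enforces shared genome and code", {
  code <- genetic_code("standard")
  a <- count_codons("GCAGCA", code, gene_id = "a", genome_id = "G1")
  b <- count_codons("GCAGCT", code, gene_id = "b", genome_id = "G1")
  pooled <- pool_counts(list(a, b))
  expect_equal(unname(pooled$counts[c("GCA", "GCU")]), c(3L, 1L))
  expect_equal(pooled$n_codons, 4L)
  expect_identical(pool_counts(list(a))$counts, a$counts)
  expect_error(pool_counts(list()), "empty")
  c_other <- count_codons("GCAGCA", code, gene_id = "c", genome_id = "G2")
  expect_error(pool_counts(list(a, c_other)), "mixed genomes")
  d_code <- count_codons("GCAGCA", genetic_code("mold_mito"), gene_id = "d",
                         genome_id = "G1")
  expect_error(pool_counts(list(a, d_code)), "mixed codes")
})
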