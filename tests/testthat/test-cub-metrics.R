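code_std <- genetic_code("standard")
code_mito <- genetic_code("mold_mito")

test_that("RSCU reproduces the printed worked-example values", {
  # fourfold Thr family used once, by ACC only
  r <- rscu(counts_from(c(ACC = 1, GCA = 2)), code_std)
  expect_equal(r$values[["ACC"]], 4)
  expect_equal(r$values[["ACU"]], 0)
  # Pro used three times, CCG once: 1 / (3/4)
  r2 <- rscu(counts_from(c(CCG = 1, CCU = 2)), code_std)
  expect_equal(r2$values[["CCG"]], 4 / 3, tolerance = 1e-12)
  expect_equal(round(r2$values[["CCG"]], 2), 1.33)
  # split sixfold: UCC alone in the Ser fourfold sub-family scores 4
  r3 <- rscu(counts_from(c(UCC = 2)), code_std, family_policy())
  expect_equal(r3$values[["UCC"]], 4)
  # unsplit: same counts in the full sixfold family score 6
  r4 <- rscu(counts_from(c(UCC = 2)), code_std,
             family_policy(split_sixfold = FALSE))
  expect_equal(r4$values[["UCC"]], 6)
  # uniform usage in a family gives 1 everywhere
  r5 <- rscu(counts_from(c(GCU = 1, GCC = 1, GCA = 1, GCG = 1)), code_std)
  expect_equal(unname(r5$values[c("GCU", "GCC", "GCA", "GCG")]), rep(1, 4))
})

test_that("RSCU family sums equal family size and scale-invariance holds", {
  set.seed(11)
  fams <- codon_families(code_std, family_policy())
  for (i in 1:40) {
    cc <- random_counts(code_std, n_codons = sample(c(30, 100, 300), 1))
    r <- rscu(cc, code_std)
    for (fam in fams) {
      if (sum(cc$counts[fam]) > 0)
        expect_equal(sum(r$values[fam]), length(fam), tolerance = 1e-9)
      else expect_true(all(is.na(r$values[fam])))
    }
    # scaling all counts leaves RSCU unchanged
    scaled <- counts_from(cc$counts[cc$counts > 0] * 7L)
    expect_equal(rscu(scaled, code_std)$values, r$values, tolerance = 1e-12)
    # oracle equivalence
    expect_equal(r$values, oracle_rscu(cc$counts, fams), tolerance = 1e-12)
  }
})

test_that("stop codons and nondegenerate families obey the policy", {
  cc <- counts_from(c(AUG = 5, UGG = 5, GCA = 5))
  r <- rscu(cc, code_std)
  expect_false(any(c("AUG", "UGG", "UAA", "UGA") %in% names(r$values)))
  r_keep <- rscu(cc, code_std, family_policy(exclude_nondegenerate = FALSE))
  expect_equal(r_keep$values[["AUG"]], 1)
})

test_that("gc_content matches hand-computed fractions", {
  expect_equal(gc_content(counts_from(c(GCA = 2)))[["gc3s"]], 0)
  expect_equal(gc_content(counts_from(c(GCC = 1, GCG = 1)))[["gc3s"]], 1)
  expect_equal(gc_content(counts_from(c(GCC = 1, GCA = 1)))[["gc3s"]], 0.5)
  expect_equal(gc_content(counts_from(c(GCA = 2)))[["gc"]], 4 / 6)
  # Met/Trp third positions count for gc3 but not gc3s
  g <- gc_content(counts_from(c(AUG = 1, GCA = 1)))
  expect_equal(g[["gc3"]], 0.5)
  expect_equal(g[["gc3s"]], 0)
})

test_that("ENc hits both analytic limits", {
  counts <- stats::setNames(integer(64), all_codons())
  for (f in code_std$families) counts[f[1]] <- 10L
  one_per_family <- counts_from(counts[counts > 0])
  expect_equal(enc(one_per_family, code_std)$enc, 20, tolerance = 1e-12)
  expect_equal(enc_from_homozygosity(
    c("2" = 1 / 2, "3" = 1 / 3, "4" = 1 / 4, "6" = 1 / 6), code_std), 61,
    tolerance = 1e-12)
  expect_equal(enc_from_homozygosity(
    c("2" = 1 / 2, "3" = 1 / 3, "4" = 1 / 4, "6" = 1 / 6), code_mito), 62,
    tolerance = 1e-12)
  expect_error(enc_from_homozygosity(c("2" = 0.5), code_std), "every")
})

test_that("ENc matches the brute-force oracle on random genes", {
  set.seed(23)
  for (i in 1:60) {
    code <- if (i %% 2) code_std else code_mito
    cc <- random_counts(code, n_codons = sample(c(25, 60, 150, 400), 1))
    got <- enc(cc, code)
    expect_equal(got$enc, oracle_enc(cc$counts, code), tolerance = 1e-9)
    expect_lte(got$enc, code$enc_max)
    expect_gte(got$enc, 1)
  }
})

test_that("ENc self-concatenation difference shrinks with gene length", {
  set.seed(5)
  delta <- function(n) {
    cc <- random_counts(code_std, n_codons = n)
    doubled <- counts_from(cc$counts[cc$counts > 0] * 2L)
    abs(enc(doubled, code_std)$enc - enc(cc, code_std)$enc)
  }
  d <- vapply(c(60, 600, 6000), function(n) mean(replicate(20, delta(n))),
              numeric(1))
  expect_true(all(diff(d) < 0))   # shrinks with length
  expect_lt(d[3], 0.5)            # and approaches the exact large-n limit
})

test_that("the neutral curve has its documented shape and values", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0.5), 60.5)
  s <- seq(0, 1, by = 0.005)
  expect_true(all(expected_enc(s) <= 61))
  expect_equal(s[which.max(expected_enc(s))], 0.5)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
})

test_that("neutral_fit computes R2 against the curve, incl. hand-checked negative case", {
  # points exactly on the curve
  gc3 <- c(0.1, 0.3, 0.5, 0.7)
  on_curve <- data.frame(enc = expected_enc(gc3), gc3 = gc3)
  expect_equal(neutral_fit(on_curve)$r2, 1)
  # anti-correlated points, R2 worked out by hand:
  # gc3 0,0,.5,.5 -> expected 31,31,60.5,60.5; enc 60,62,30,32 (mean 46)
  # SS_tot = 904; SS_res = 841+961+930.25+812.25 = 3544.5
  anti <- data.frame(enc = c(60, 62, 30, 32), gc3 = c(0, 0, 0.5, 0.5))
  expect_equal(neutral_fit(anti)$r2, 1 - 3544.5 / 904, tolerance = 1e-12)
  # degenerate: all enc identical -> SS_tot = 0 -> NA with reason
  flat <- data.frame(enc = rep(40, 4), gc3 = gc3)
  nf <- neutral_fit(flat)
  expect_true(is.na(nf$r2))
  expect_match(nf$reason, "SS_tot")
  expect_error(neutral_fit(on_curve[1:2, ]), "at least 3")
})

test_that("enc_deviation follows its definition and sign convention", {
  expect_equal(enc_deviation(40, 40), 0)
  expect_equal(enc_deviation(20, 40), 0.5)
  expect_lt(enc_deviation(50, 40), 0)
  expect_error(enc_deviation(30, -1), "> 0")
  cc <- random_counts(code_std, 300)
  p <- enc(cc, code_std)
  expect_equal(enc_deviation(p), (p$enc_expected - p$enc) / p$enc_expected)
  expect_equal(p$deviation, enc_deviation(p))
})

test_that("enc_table agrees with the scalar path gene by gene", {
  set.seed(31)
  genes <- lapply(1:12, function(i)
    random_counts(code_mito, sample(c(40, 120, 300), 1),
                  gene_id = paste0("g", i)))
  tab <- enc_table(counts_matrix(genes), code_mito)
  for (i in seq_along(genes)) {
    p <- enc(genes[[i]], code_mito)
    expect_equal(tab$enc[i], p$enc, tolerance = 1e-12)
    expect_equal(tab$gc3[i], p$gc3, tolerance = 1e-12)
    expect_equal(tab$deviation[i], p$deviation, tolerance = 1e-12)
  }
})
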