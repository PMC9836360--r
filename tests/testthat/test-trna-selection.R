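code_std <- genetic_code("standard")
code_mito <- genetic_code("mold_mito")

test_that("wi is 1 everywhere for a uniform Watson-Crick tRNAome", {
  # under a WC-only s-vector (no wobble classes), one exact tRNA per codon
  # at equal copy number gives wi = 1 for every sense codon
  wi <- compute_wi(wc_trnaome(code_std), c(WC = 0), code_std)
  expect_equal(unname(wi$values), rep(1, 61), tolerance = 1e-12)
  expect_length(wi$zero_replaced, 0L)
  # with the default wobble classes the same tRNAome gains wobble
  # contributions, so wi is still positive everywhere but not flat
  wi_def <- compute_wi(wc_trnaome(code_std), default_s_vector(), code_std)
  expect_length(wi_def$zero_replaced, 0L)
  expect_equal(max(wi_def$values), 1)
  expect_gt(stats::sd(wi_def$values), 0)
})

test_that("wi is invariant to scaling copy numbers and max-normalised", {
  set.seed(41)
  for (i in 1:20) {
    acs <- unique(replicate(12, paste(sample(c("A", "C", "G", "U"), 3,
                                             replace = TRUE), collapse = "")))
    cn <- stats::setNames(sample(1:4, length(acs), replace = TRUE), acs)
    w1 <- compute_wi(trnaome(cn), code = code_std)
    w2 <- compute_wi(trnaome(cn * 5L), code = code_std)
    expect_equal(w1$values, w2$values, tolerance = 1e-12)
    expect_equal(max(w1$values), 1)
    expect_true(all(w1$values > 0))
  }
})

test_that("wi hand-checks on a single-anticodon tRNAome", {
  # one UGC(Ala) tRNA, copies 2: W(GCA) = (1-0)*2 = 2, W(GCG) = (1-0.68)*2
  wi <- compute_wi(trnaome(c(UGC = 2L)), default_s_vector(), code_std)
  expect_equal(wi$values[["GCA"]], 1)
  expect_equal(wi$values[["GCG"]], 0.32, tolerance = 1e-12)
  # every other codon had W = 0 and was replaced by the geometric mean
  expect_equal(sort(setdiff(code_std$sense_codons, c("GCA", "GCG"))),
               sort(wi$zero_replaced))
  gm <- exp(mean(log(c(1, 0.32))))
  expect_equal(unname(wi$values[wi$zero_replaced][1]), gm, tolerance = 1e-12)
  # missing a whole family: all Pro codons flagged
  expect_true(all(c("CCU", "CCC", "CCA", "CCG") %in% wi$zero_replaced))
})

test_that("tai is the count-weighted geometric mean of wi", {
  wi <- compute_wi(wc_trnaome(code_std), c(WC = 0), code_std)
  cc <- counts_from(c(GCA = 3, UUU = 2))
  expect_equal(tai(cc, wi)$tai, 1)
  # two codons, wi 1 and 0.25, one use each -> sqrt(0.25) = 0.5
  wi2 <- wi
  wi2$values[["UUU"]] <- 0.25
  expect_equal(tai(counts_from(c(GCA = 1, UUU = 1)), wi2)$tai, 0.5)
  # concatenation = length-weighted geometric mean of the parts
  a <- counts_from(c(GCA = 2, UUU = 1), gene_id = "a")
  b <- counts_from(c(GCC = 1, UUC = 2), gene_id = "b")
  wi2$values[["GCC"]] <- 0.5; wi2$values[["UUC"]] <- 0.8
  t_ab <- tai(pool_counts(list(a, b)), wi2)$tai
  expect_equal(t_ab,
               (tai(a, wi2)$tai^3 * tai(b, wi2)$tai^3)^(1 / 6),
               tolerance = 1e-12)
  expect_error(tai(counts_from(c(GCA = 0)), wi), "no usable codons")
})

test_that("s_statistic recovers exact and null correlations", {
  tai_v <- seq(0.2, 0.9, length.out = 20)
  expect_equal(s_statistic(tai_v, 2 * tai_v + 1), 1)
  expect_equal(s_statistic(tai_v, -tai_v), -1)
  set.seed(53)
  s_null <- s_statistic(runif(200), runif(200))
  expect_lt(abs(s_null), 0.2)
  expect_warning(s0 <- s_statistic(rep(0.5, 10), runif(10)), "constant")
  expect_true(is.na(s0))
  expect_error(s_statistic(1:2, 1:2), "at least 3")
  # spearman flavour is rank-based
  expect_equal(s_statistic(tai_v, exp(tai_v), method = "spearman"), 1)
})

test_that("permutation_s_test is seed-deterministic with documented fields", {
  sc <- scenario("selected")
  m <- simulate_genes(sc$spec, sc$wi, as = "matrix")
  et <- enc_table(m, code_mito)
  r1 <- permutation_s_test(m, et$deviation, sc$wi, n_perm = 50, seed = 7)
  r2 <- permutation_s_test(m, et$deviation, sc$wi, n_perm = 50, seed = 7)
  expect_identical(r1, r2)
  r3 <- permutation_s_test(m, et$deviation, sc$wi, n_perm = 50, seed = 8)
  expect_false(identical(r1$perm_values, r3$perm_values))
  expect_length(r1$perm_values, 50L)
  expect_gte(r1$empirical_p, 1 / 51)
  expect_identical(r1$significant, r1$empirical_p <= 0.05)
  expect_error(permutation_s_test(m, et$deviation, sc$wi, n_perm = 0),
               "n_perm")
})

test_that("the S-test has power under strong selection", {
  sc <- scenario("selected")
  sig <- vapply(1:10, function(i) {
    sp <- sc$spec; sp$seed <- 600L + i
    m <- simulate_genes(sp, sc$wi, as = "matrix")
    et <- enc_table(m, code_mito)
    permutation_s_test(m, et$deviation, sc$wi, n_perm = 100,
                       seed = 700L + i)$significant
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("optimize_s_vector improves its objective and recovers a perturbed s", {
  sc <- scenario("selected")
  truth <- default_s_vector()
  truth[["U:G"]] <- 0.2    # perturbed wobble constraint to recover
  wi_true <- compute_wi(sc$trnaome, truth, code_mito)
  sp <- synthetic_spec(n_genes = 500L, gene_length = 300L, gc3_target = 0.35,
                       beta = 2, expression = "lognormal",
                       code_id = "mold_mito", seed = 97L)
  m <- simulate_genes(sp, wi_true, as = "matrix")
  et <- enc_table(m, code_mito)
  # default objective (the S correlation) never decreases from its start
  fit_s <- optimize_s_vector(m, et$deviation, sc$trnaome, code_mito,
                             seed = 5L)
  base_obj <- s_statistic(
    mitocub:::tai_vector(m, compute_wi(sc$trnaome, default_s_vector(),
                                       code_mito)$values),
    et$deviation)
  expect_gte(fit_s$objective, base_obj)
  expect_true(all(diff(fit_s$trace$objective) >= 0))
  # the usage-contrast objective recovers the generating constraint
  fit <- optimize_s_vector(m, et$deviation, sc$trnaome, code_mito,
                           objective = "usage_contrast", seed = 5L)
  expect_lt(abs(fit$s[["U:G"]] - truth[["U:G"]]), 0.15)
  # seed-reproducible trace
  fit2 <- optimize_s_vector(m, et$deviation, sc$trnaome, code_mito,
                            objective = "usage_contrast", seed = 5L)
  expect_identical(fit$trace, fit2$trace)
})
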