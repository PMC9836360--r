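code_std <- genetic_code("standard")

make_rscu_set <- function(counts_list) {
  lapply(counts_list, rscu, code = code_std, policy = family_policy())
}

test_that("build_rscu_matrix applies the fill policy and column set", {
  g1 <- counts_from(c(GCA = 2, GCC = 2, CCG = 1), gene_id = "g1")
  g2 <- counts_from(c(GCA = 4, UUU = 1), gene_id = "g2")
  m <- build_rscu_matrix(make_rscu_set(list(g1, g2)))
  expect_false(any(c("AUG", "UGG", "UAA") %in% colnames(m)))
  # g2 has no Pro observations: filled with 0
  expect_equal(unname(m["g2", "CCG"]), 0)
  expect_equal(unname(m["g1", "CCG"]), 4)
  expect_false(anyNA(m))
  identical_rows <- build_rscu_matrix(make_rscu_set(list(g1, g1)))
  expect_equal(identical_rows[1, ], identical_rows[2, ])
  expect_error(build_rscu_matrix(list()), "empty")
})

test_that("CA of a fixed 3x4 table matches the dense eigendecomposition oracle", {
  m <- matrix(c(10, 2, 3, 5,
                1, 12, 4, 2,
                3, 4, 9, 8), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:4)))
  ca <- correspondence_analysis(m)
  expect_equal(unname(ca$eigenvalues), oracle_ca_eigen(m), tolerance = 1e-10)
  # total inertia identity: sum of eigenvalues = chi^2 / N
  chi2 <- suppressWarnings(stats::chisq.test(m)$statistic)
  expect_equal(ca$total_inertia, unname(chi2) / sum(m), tolerance = 1e-10)
  expect_equal(sum(ca$pct_inertia), 100)
  # contributions sum to 1 per dimension
  expect_equal(unname(colSums(ca$row_contrib)), rep(1, ncol(ca$row_contrib)))
  expect_equal(unname(colSums(ca$col_contrib)), rep(1, ncol(ca$col_contrib)))
})

test_that("CA identities hold on random tables; weighted centroids at origin", {
  set.seed(17)
  for (i in 1:25) {
    m <- matrix(rpois(8 * 12, lambda = 5), nrow = 8)
    m <- m + 1L   # no zero rows/columns
    ca <- correspondence_analysis(m)
    expect_equal(unname(ca$eigenvalues), oracle_ca_eigen(m), tolerance = 1e-9)
    expect_equal(max(abs(colSums(ca$row_mass * ca$row_coords))), 0,
                 tolerance = 1e-9)
    expect_equal(max(abs(colSums(ca$col_mass * ca$col_coords))), 0,
                 tolerance = 1e-9)
  }
})

test_that("CA handles degenerate inputs as documented", {
  ident <- matrix(rep(c(3, 1, 2, 4), each = 3), nrow = 3,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  ca <- correspondence_analysis(ident)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_length(ca$eigenvalues, 0)
  withzero <- cbind(ident, z = 0)
  expect_identical(correspondence_analysis(withzero)$dropped_columns, "z")
  expect_error(correspondence_analysis(matrix(1, 1, 3)), "at least 2 rows")
  expect_error(correspondence_analysis(matrix(c(-1, 2, 2, 2), 2)),
               "non-negative")
  expect_error(correspondence_analysis(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("CA separates a simulated two-class gene set on dimension 1", {
  sc <- scenario("two_class")
  m <- simulate_genes(sc$spec, as = "matrix")
  rv <- lapply(seq_len(nrow(m)), function(i)
    rscu(counts_from(m[i, ][m[i, ] > 0], code_id = "mold_mito",
                     gene_id = rownames(m)[i]),
         genetic_code("mold_mito")))
  ca <- correspondence_analysis(build_rscu_matrix(rv))
  cls <- sc$spec$gc3_target > 0.5
  signs <- ca$row_coords[, 1] > 0
  acc <- max(mean(signs == cls), mean(signs == !cls))
  expect_gt(acc, 0.95)
})

test_that("hierarchical clustering is deterministic and order-invariant", {
  set.seed(3)
  base <- matrix(rnorm(5 * 10), nrow = 5,
                 dimnames = list(c("gA", "gB", "gC", "gD", "gE"), NULL))
  base["gB", ] <- base["gA", ] + 0.01   # gA,gB near each other
  dend <- hierarchical_cluster(base)
  expect_s3_class(dend, "cub_dendrogram")
  # first merge joins the closest pair gA,gB
  first <- sort(rownames(base)[-dend$hclust$merge[1, ]])
  expect_identical(first, c("gA", "gB"))
  # permuting input rows leaves the tree unchanged
  perm <- base[sample(rownames(base)), ]
  expect_identical(hierarchical_cluster(perm)$newick, dend$newick)
  # identical profiles merge at height 0
  twin <- rbind(x = base[1, ], y = base[1, ])
  expect_equal(hierarchical_cluster(twin)$hclust$height[1], 0)
  expect_error(hierarchical_cluster(base[1, , drop = FALSE]), "at least 2")
  dup <- base; rownames(dup) <- c("g", "g", "gC", "gD", "gE")
  expect_error(hierarchical_cluster(dup), "duplicate")
})

test_that("newick output round-trips through ape with matching leaves", {
  set.seed(9)
  m <- matrix(rnorm(4 * 6), nrow = 4,
              dimnames = list(paste0("sp", 1:4), NULL))
  for (linkage in c("average", "complete", "ward")) {
    dend <- hierarchical_cluster(m, linkage = linkage)
    phy <- ape::read.tree(text = dend$newick)
    expect_setequal(phy$tip.label, paste0("sp", 1:4))
    expect_true(all(diff(dend$hclust$height) >= 0))  # monotone heights
  }
})
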