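#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon *j* in a synonymous family of size *k* with family total
#' *N* is `X_j / (N / k)`: the observed count divided by the count expected
#' if all synonymous codons were used equally.  A value of 1 means no bias;
#' *k* means exclusive use of one codon in a *k*-codon family.  Codons of
#' families with no observations are `NA`.  Stop codons, and (under the
#' default policy) single-codon families, are excluded; sixfold families
#' are split into fourfold + twofold sub-families by default.
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()]; defaults to the code the counts were
#'   made with.
#' @param policy A [family_policy()].
#' @return An `rscu_vector` object: `values` is a named numeric vector over
#'   the retained codons, plus `owner_id`, `family_policy`, `code_id`.
#' @examples
#' code <- genetic_code("standard")
#' cc <- count_codons("ACCGCAGCAGCC", code)   # Thr x1 (ACC), Ala x3
#' r <- rscu(cc, code)
#' r$values[["ACC"]]   # 4: sole used codon of a fourfold family
#' @export
rscu <- function(counts, code = genetic_code(counts$code_id),
                 policy = family_policy()) {
  stopifnot(inherits(counts, "codon_counts"))
  fams <- codon_families(code, policy)
  vals <- rep(NA_real_, 64L)
  names(vals) <- all_codons()
  keep <- character(0)
  for (cod in fams) {
    keep <- c(keep, cod)
    n <- sum(counts$counts[cod])
    vals[cod] <- if (n > 0L) counts$counts[cod] / (n / length(cod)) else NA_real_
  }
  structure(list(owner_id = counts$gene_id,
                 values = vals[sort(keep)],
                 family_policy = policy,
                 code_id = code$code_id),
            class = "rscu_vector")
}

#' @export
print.rscu_vector <- function(x, ...) {
  cat("RSCU vector for", x$owner_id, "(code", x$code_id, ")\n")
  v <- x$values[!is.na(x$values)]
  print(round(v[order(-v)][seq_len(min(8L, length(v)))], 3))
  invisible(x)
}

#' GC content and third-position GC content of a gene
#'
#' `gc` is the G+C fraction over all codon positions of the counted
#' codons.  `gc3` is the G+C fraction at third positions of all counted
#' codons; `gc3s` restricts to codons of degenerate (size >= 2, unsplit)
#' families — the synonymous-sites convention used by the neutral ENc-GC3
#' model, which excludes Met, Trp (standard code) and stop codons.
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(gc, gc3, gc3s)`; entries are `NA` when
#'   no eligible codons exist.
#' @export
gc_content <- function(counts, code = genetic_code(counts$code_id)) {
  stopifnot(inherits(counts, "codon_counts"))
  cods <- all_codons()
  x <- counts$counts
  n <- sum(x)
  if (n == 0L) return(c(gc = NA_real_, gc3 = NA_real_, gc3s = NA_real_))
  gc_per_codon <- vapply(strsplit(cods, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  third_gc <- substr(cods, 3L, 3L) %in% c("G", "C")
  gc <- sum(x * gc_per_codon) / (3 * n)
  gc3 <- sum(x[third_gc]) / n
  syn <- unlist(code$families[lengths(code$families) > 1L], use.names = FALSE)
  ns <- sum(x[syn])
  gc3s <- if (ns > 0L) sum(x[syn][substr(syn, 3L, 3L) %in% c("G", "C")]) / ns
          else NA_real_
  c(gc = gc, gc3 = gc3, gc3s = gc3s)
}

#' Wright's effective number of codons (ENc)
#'
#' Summarises the nonuniformity of synonymous codon usage in a gene.
#' Values range from 20 (extreme bias: one codon per amino acid, standard
#' code) to the code-specific maximum (61 for the standard code, 62 for
#' the mold mitochondrial code).
#'
#' Per unsplit family with `n >= 2` observed codons, the homozygosity
#' estimate is `F = (n * sum(p^2) - 1) / (n - 1)` where `p` are the within-
#' family codon proportions.  Families with `n < 2` or `F <= 0` are
#' excluded from their degeneracy class mean `F_k`.  A class with no valid
#' family borrows the mean of the nearest available classes (e.g. the
#' threefold class borrows the average of the two- and fourfold class
#' means) and is recorded in `imputed_classes`; with no information at all
#' it falls back to the uniform value `1/k`.  Then
#' `ENc = m_1 + sum_k m_k / F_k` over the code's degenerate classes, where
#' `m_k` is the number of families in class `k` and `m_1` the number of
#' single-codon families.  The returned `enc` is capped to
#' `[1, enc_max]`; `enc_raw` is uncapped.
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return An `enc_point` object: `gene_id`, `enc`, `enc_raw`, `gc3`
#'   (the GC3s convention), `gc3_all`, `enc_expected` (neutral expectation
#'   at `gc3`), `deviation`, `class_fs`, `imputed_classes`,
#'   `low_confidence`.
#' @seealso [expected_enc()], [neutral_fit()]
#' @export
enc <- function(counts, code = genetic_code(counts$code_id)) {
  stopifnot(inherits(counts, "codon_counts"))
  m <- matrix(counts$counts, nrow = 1L,
              dimnames = list(counts$gene_id, names(counts$counts)))
  tab <- enc_table(m, code)
  gcs <- gc_content(counts, code)
  structure(list(gene_id = counts$gene_id,
                 enc = tab$enc, enc_raw = tab$enc_raw,
                 gc3 = gcs[["gc3s"]], gc3_all = gcs[["gc3"]],
                 enc_expected = if (is.na(gcs[["gc3s"]])) NA_real_
                                else expected_enc(gcs[["gc3s"]]),
                 deviation = NA_real_,
                 class_fs = attr(tab, "class_fs")[1L, ],
                 imputed_classes = strsplit(tab$imputed_classes, ",")[[1L]],
                 low_confidence = tab$low_confidence),
            class = "enc_point") |> .fill_deviation()
}

.fill_deviation <- function(p) {
  if (!is.na(p$enc) && !is.na(p$enc_expected) && p$enc_expected > 0)
    p$deviation <- (p$enc_expected - p$enc) / p$enc_expected
  p
}

#' @export
print.enc_point <- function(x, ...) {
  cat(sprintf("ENc point for %s: ENc = %.3f (raw %.3f), GC3s = %.3f, expected %.3f, deviation %.3f\n",
              x$gene_id, x$enc, x$enc_raw, x$gc3, x$enc_expected, x$deviation))
  if (length(x$imputed_classes) && nzchar(x$imputed_classes[1L]))
    cat("  imputed classes:", paste(x$imputed_classes, collapse = ", "),
        if (x$low_confidence) "(low confidence)", "\n")
  invisible(x)
}

#' Vectorised ENc over a genes-by-64 counts matrix
#'
#' Matrix backend of [enc()]: computes ENc, GC3s, the neutral expectation
#' and the ENc deviation for every row at once.  This is the fast path the
#' simulation and pipeline code uses.
#'
#' @param m Integer matrix, genes in rows, the 64 codons as columns (see
#'   [counts_matrix()]).
#' @param code A [genetic_code()].
#' @return A data.frame with one row per gene: `gene_id`, `enc`, `enc_raw`,
#'   `gc3`, `gc3_all`, `enc_expected`, `deviation`, per-class `F_k`
#'   columns, `imputed_classes`, `low_confidence`.
#' @export
enc_table <- function(m, code) {
  stopifnot(is.matrix(m), ncol(m) == 64L, inherits(code, "genetic_code"))
  if (is.null(colnames(m))) colnames(m) <- all_codons()
  fams <- code$families
  sizes <- lengths(fams)
  deg_sizes <- sort(unique(sizes[sizes > 1L]))
  n_single <- sum(sizes == 1L)
  G <- nrow(m)
  # per-family homozygosity
  fam_F <- matrix(NA_real_, G, length(fams), dimnames = list(NULL, names(fams)))
  fam_n <- matrix(0L, G, length(fams))
  for (j in seq_along(fams)) {
    sub <- m[, fams[[j]], drop = FALSE]
    n <- rowSums(sub)
    fam_n[, j] <- n
    sump2 <- rowSums((sub / pmax(n, 1L))^2)
    F <- (n * sump2 - 1) / (n - 1)
    F[n < 2L] <- NA_real_
    F[!is.na(F) & F <= 0] <- NA_real_
    fam_F[, j] <- F
  }
  class_fs <- matrix(NA_real_, G, length(deg_sizes),
                     dimnames = list(NULL, paste0("F", deg_sizes)))
  for (i in seq_along(deg_sizes)) {
    k <- deg_sizes[i]
    sel <- which(sizes == k)
    class_fs[, i] <- rowMeans(fam_F[, sel, drop = FALSE], na.rm = TRUE)
  }
  class_fs[is.nan(class_fs)] <- NA_real_
  # impute missing classes from nearest available neighbours
  imputed <- matrix(FALSE, G, length(deg_sizes))
  filled <- class_fs
  for (i in seq_along(deg_sizes)) {
    miss <- which(is.na(class_fs[, i]))
    if (!length(miss)) next
    imputed[miss, i] <- TRUE
    lower <- if (i > 1L) class_fs[miss, i - 1L] else NA_real_
    upper <- if (i < length(deg_sizes)) class_fs[miss, i + 1L] else NA_real_
    est <- rowMeans(cbind(lower, upper), na.rm = TRUE)
    est[is.nan(est)] <- NA_real_
    # second ring, then uniform fallback
    if (anyNA(est)) {
      for (j in which(is.na(est))) {
        avail <- which(!is.na(class_fs[miss[j], ]))
        est[j] <- if (length(avail))
          class_fs[miss[j], avail[which.min(abs(avail - i))]]
        else 1 / deg_sizes[i]
      }
    }
    filled[miss, i] <- est
  }
  m_k <- vapply(deg_sizes, function(k) sum(sizes == k), numeric(1))
  enc_raw <- n_single + rowSums(sweep(1 / filled, 2L, m_k, `*`))
  any_obs <- rowSums(fam_n >= 2L) > 0L
  enc_raw[!any_obs] <- NA_real_
  enc_capped <- pmin(pmax(enc_raw, 1), code$enc_max)
  # GC content columns
  cods <- colnames(m)
  gc_per_codon <- vapply(strsplit(cods, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  syn <- unlist(fams[sizes > 1L], use.names = FALSE)
  syn_gc3 <- syn[substr(syn, 3L, 3L) %in% c("G", "C")]
  tot <- rowSums(m)
  gc3_all <- rowSums(m[, substr(cods, 3L, 3L) %in% c("G", "C"), drop = FALSE]) /
    pmax(tot, 1L)
  ns <- rowSums(m[, syn, drop = FALSE])
  gc3s <- rowSums(m[, syn_gc3, drop = FALSE]) / pmax(ns, 1L)
  gc3s[ns == 0L] <- NA_real_
  gc3_all[tot == 0L] <- NA_real_
  expected <- ifelse(is.na(gc3s), NA_real_, expected_enc(pmin(pmax(gc3s, 0), 1)))
  out <- data.frame(gene_id = rownames(m) %||% as.character(seq_len(G)),
                    enc = enc_capped, enc_raw = enc_raw,
                    gc3 = gc3s, gc3_all = gc3_all,
                    enc_expected = expected,
                    deviation = (expected - enc_capped) / expected,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(class_fs))
  out$imputed_classes <- apply(imputed, 1L, function(z)
    paste(deg_sizes[z], collapse = ","))
  out$low_confidence <- rowSums(imputed) > 2L
  attr(out, "class_fs") <- class_fs
  out
}

#' ENc from fixed class homozygosities
#'
#' The analytic class-sum path of Wright's formula:
#' `ENc = m_1 + sum_k m_k / F_k` with the mean homozygosity of each
#' degeneracy class supplied directly.  With every `F_k` at its uniform
#' value `1/k` this returns the code's no-bias maximum (61 for the
#' standard code); with every `F_k = 1` it returns the number of families
#' (20 for the standard code).
#'
#' @param fbar Named numeric vector of class mean homozygosities; names
#'   are the class sizes (e.g. `c("2" = 0.5, "3" = 1/3, "4" = 0.25,
#'   "6" = 1/6)`).  Must cover every degenerate class of the code.
#' @param code A [genetic_code()].
#' @return ENc value (uncapped).
#' @examples
#' enc_from_homozygosity(c("2" = 1/2, "3" = 1/3, "4" = 1/4, "6" = 1/6),
#'                       genetic_code("standard"))  # 61
#' @export
enc_from_homozygosity <- function(fbar, code) {
  stopifnot(inherits(code, "genetic_code"), is.numeric(fbar),
            !is.null(names(fbar)))
  sizes <- lengths(code$families)
  deg <- sort(unique(sizes[sizes > 1L]))
  if (!all(as.character(deg) %in% names(fbar)))
    stop("fbar must name every degenerate class: ",
         paste(deg, collapse = ", "))
  if (any(fbar <= 0 | fbar > 1)) stop("homozygosities must lie in (0, 1]")
  m_k <- vapply(deg, function(k) sum(sizes == k), numeric(1))
  sum(sizes == 1L) + sum(m_k / fbar[as.character(deg)])
}

#' Expected ENc under neutral mutational bias
#'
#' The neutral ENc-GC3 curve: `g(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`,
#' the ENc expected if codon usage were shaped by third-position
#' composition alone.
#'
#' @param gc3 Numeric vector of third-position GC fractions in `[0, 1]`.
#' @return Expected ENc values.
#' @examples
#' expected_enc(c(0, 0.5, 1))  # 31, 60.5, 32
#' @export
expected_enc <- function(gc3) {
  stopifnot(is.numeric(gc3))
  if (any(!is.na(gc3) & (gc3 < 0 | gc3 > 1)))
    stop("gc3 must lie in [0, 1]")
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Fit of observed ENc values to the neutral expectation
#'
#' Measures how well a set of (GC3, ENc) gene points track the neutral
#' curve: `R^2 = 1 - sum((enc - g(gc3))^2) / sum((enc - mean(enc))^2)`.
#' The comparison is against the curve itself, not a refitted regression,
#' so `R^2` may be negative when the cloud deviates strongly.
#'
#' @param points A data.frame with columns `enc` and `gc3` (e.g. from
#'   [enc_table()]), or a list of `enc_point` objects.
#' @return A `neutral_fit` object: `r2`, `n_genes`, `residuals`
#'   (expected - observed, per gene).
#' @export
neutral_fit <- function(points) {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "enc_point"))) {
    points <- data.frame(enc = vapply(points, `[[`, numeric(1), "enc"),
                         gc3 = vapply(points, `[[`, numeric(1), "gc3"))
  }
  stopifnot(is.data.frame(points), all(c("enc", "gc3") %in% names(points)))
  ok <- stats::complete.cases(points[, c("enc", "gc3")])
  pts <- points[ok, ]
  if (nrow(pts) < 3L) stop("need at least 3 genes with valid ENc and GC3")
  expd <- expected_enc(pts$gc3)
  ss_tot <- sum((pts$enc - mean(pts$enc))^2)
  resid <- expd - pts$enc
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(resid^2) / ss_tot
  structure(list(r2 = r2, n_genes = nrow(pts), residuals = resid,
                 reason = if (ss_tot == 0) "all observed ENc identical (SS_tot = 0)"
                          else NULL),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Neutral ENc-GC3 fit over %d genes: R^2 = %s\n", x$n_genes,
              if (is.na(x$r2)) paste0("NA (", x$reason, ")")
              else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' ENc deviation from the neutral expectation
#'
#' The selection proxy used by the S-test: `(expected - observed) /
#' expected`.  Zero means the gene sits on the neutral curve; positive
#' values mean more codon usage bias than mutational bias alone predicts.
#'
#' @param point An `enc_point`, or a numeric vector of observed ENc values
#'   (then `expected` must be supplied).
#' @param expected Expected ENc values (recycled).
#' @return Numeric deviation(s).
#' @export
enc_deviation <- function(point, expected = NULL) {
  if (inherits(point, "enc_point")) {
    if (is.na(point$enc)) stop("ENc is missing for gene ", point$gene_id)
    return((point$enc_expected - point$enc) / point$enc_expected)
  }
  stopifnot(is.numeric(point), is.numeric(expected))
  if (any(!is.na(expected) & expected <= 0)) stop("expected ENc must be > 0")
  (expected - point) / expected
}
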