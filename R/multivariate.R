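#' Assemble an RSCU matrix for multivariate analysis
#'
#' Stacks per-gene (or per-genome) RSCU vectors into a rows-by-codons
#' matrix suitable for [correspondence_analysis()] or
#' [hierarchical_cluster()].  `NA` values (families with no observations)
#' are replaced according to `fill` — by default 0, recorded in the
#' matrix's `"fill"` attribute.
#'
#' @param rscu_vectors Non-empty list of `rscu_vector` objects sharing a
#'   code and family policy.
#' @param fill Value substituted for `NA` cells (default 0).
#' @return Numeric matrix, rows named by owner ids, columns the retained
#'   codons in alphabetical order.
#' @export
build_rscu_matrix <- function(rscu_vectors, fill = 0) {
  if (!length(rscu_vectors)) stop("empty list of RSCU vectors")
  stopifnot(all(vapply(rscu_vectors, inherits, logical(1), "rscu_vector")))
  codes <- unique(vapply(rscu_vectors, `[[`, character(1), "code_id"))
  if (length(codes) != 1L)
    stop("RSCU vectors computed under mixed codes: ",
         paste(codes, collapse = ", "))
  cols <- names(rscu_vectors[[1L]]$values)
  m <- do.call(rbind, lapply(rscu_vectors, function(r) {
    if (!identical(names(r$values), cols))
      stop("RSCU vectors computed under different family policies")
    r$values
  }))
  rownames(m) <- vapply(rscu_vectors, `[[`, character(1), "owner_id")
  m[is.na(m)] <- fill
  attr(m, "fill") <- fill
  attr(m, "code_id") <- codes
  m
}

#' Correspondence analysis of a codon usage table
#'
#' Standard correspondence analysis, the multivariate method of choice for
#' RSCU tables (whose columns are interdependent within synonymous
#' families and hence unsuited to PCA).  With correspondence matrix
#' `P = X / n`, row/column masses `r`, `c`, the standardised residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` are decomposed by SVD; principal
#' coordinates are the scaled singular vectors, eigenvalues the squared
#' singular values, and the total inertia equals `chi^2 / n` of the table.
#'
#' All-zero columns are dropped (and reported); all-zero rows are an
#' error.  Axis signs are fixed deterministically by forcing the column
#' with the largest absolute coordinate positive on each dimension.
#'
#' @param m Non-negative numeric matrix (genes x codons).
#' @param n_dims Number of dimensions to retain (default all).
#' @return A `ca_result`: `row_coords`, `col_coords` (principal
#'   coordinates), `eigenvalues`, `pct_inertia`, `row_contrib`,
#'   `col_contrib` (per-dimension contribution fractions),
#'   `total_inertia`, `dropped_columns`.
#' @export
correspondence_analysis <- function(m, n_dims = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("correspondence analysis requires non-negative entries")
  if (nrow(m) < 2L) stop("need at least 2 rows")
  zero_col <- colSums(m) == 0
  dropped <- colnames(m)[zero_col] %||% which(zero_col)
  m <- m[, !zero_col, drop = FALSE]
  if (any(rowSums(m) == 0)) stop("all-zero rows are not allowed: ",
                                 paste(rownames(m)[rowSums(m) == 0],
                                       collapse = ", "))
  n <- sum(m)
  if (n == 0) stop("grand total of the table is 0")
  P <- m / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  if (!is.null(n_dims)) keep <- keep[seq_len(min(n_dims, length(keep)))]
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # principal coordinates
  F_row <- sweep(U, 1L, sqrt(r), `/`) %*% diag(d, nrow = length(d))
  G_col <- sweep(V, 1L, sqrt(cm), `/`) %*% diag(d, nrow = length(d))
  # deterministic axis signs: largest-|coordinate| column positive
  for (j in seq_along(d)) {
    i_max <- which.max(abs(G_col[, j]))
    if (G_col[i_max, j] < 0) {
      G_col[, j] <- -G_col[, j]
      F_row[, j] <- -F_row[, j]
    }
  }
  eig <- d^2
  total <- sum(sv$d^2)
  row_contrib <- sweep(r * F_row^2, 2L, eig, `/`)
  col_contrib <- sweep(cm * G_col^2, 2L, eig, `/`)
  dn <- sprintf("Dim%d", seq_along(d))
  dimnames(F_row) <- list(rownames(m), dn)
  dimnames(G_col) <- list(colnames(m), dn)
  dimnames(row_contrib) <- dimnames(F_row)
  dimnames(col_contrib) <- dimnames(G_col)
  structure(list(row_coords = F_row, col_coords = G_col,
                 eigenvalues = stats::setNames(eig, dn),
                 pct_inertia = stats::setNames(100 * eig / total, dn),
                 row_contrib = row_contrib, col_contrib = col_contrib,
                 total_inertia = total, row_mass = r, col_mass = cm,
                 dropped_columns = as.character(dropped)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns\n")
  k <- min(5L, length(x$eigenvalues))
  cat("  total inertia:", format(x$total_inertia, digits = 5), "\n")
  cat("  % inertia:",
      paste(sprintf("%s %.1f%%", names(x$pct_inertia)[1:k],
                    x$pct_inertia[1:k]), collapse = ", "), "\n")
  if (length(x$dropped_columns))
    cat("  dropped all-zero columns:",
        paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of genome RSCU profiles
#'
#' Clusters genome-level RSCU profiles and returns the dendrogram with a
#' Newick serialisation (branch lengths derived from merge heights).
#' Defaults are Euclidean distance with average linkage (UPGMA).  Rows are
#' sorted by id before clustering so the result is invariant to input
#' order; equal-distance ties then resolve lexicographically.
#'
#' @param profiles Matrix from [build_rscu_matrix()] (genomes x codons) or
#'   a list of `rscu_vector` objects.
#' @param distance `"euclidean"`, `"manhattan"`, or `"correlation"`
#'   (1 - Pearson correlation).
#' @param linkage `"average"`, `"complete"`, or `"ward"` (ward.D2).
#' @return A `cub_dendrogram`: `hclust` (the stats::hclust tree),
#'   `newick`, `leaves`, `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(profiles,
                                 distance = c("euclidean", "manhattan",
                                              "correlation"),
                                 linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.list(profiles) && !is.matrix(profiles))
    profiles <- build_rscu_matrix(profiles)
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < 2L) stop("need at least 2 profiles to cluster")
  if (anyNA(profiles)) stop("profiles contain NA cells; fill them first")
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  if (anyDuplicated(ids)) stop("duplicate genome ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  profiles <- profiles[order(ids), , drop = FALSE]
  d <- switch(distance,
              euclidean = stats::dist(profiles, method = "euclidean"),
              manhattan = stats::dist(profiles, method = "manhattan"),
              correlation = stats::as.dist(1 - stats::cor(t(profiles))))
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 newick = ape::write.tree(phy),
                 leaves = sort(ids),
                 distance = distance, linkage = linkage),
            class = "cub_dendrogram")
}

#' @export
print.cub_dendrogram <- function(x, ...) {
  cat("RSCU dendrogram (", x$distance, "distance,", x$linkage, "linkage )\n")
  cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  cat("  newick:", x$newick, "\n")
  invisible(x)
}
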