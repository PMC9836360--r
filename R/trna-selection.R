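#' Construct a tRNAome
#'
#' Anticodon gene copy numbers (tGCN) for one genome, the input of
#' [compute_wi()] and [decodability()].
#'
#' @param copy_numbers Named positive integer vector (names = RNA
#'   anticodons, 5'->3', position 34 first), or a data.frame with columns
#'   `anticodon` and `copy_number` (e.g. from [read_trna_counts()]; rows
#'   with `NA` anticodons are dropped with a warning).
#' @param genome_id,organelle Metadata.
#' @return A `trnaome` object.
#' @export
trnaome <- function(copy_numbers, genome_id = "genome",
                    organelle = c("mito", "nuclear")) {
  organelle <- match.arg(organelle)
  if (is.data.frame(copy_numbers)) {
    if (anyNA(copy_numbers$anticodon)) {
      warning("dropping ", sum(is.na(copy_numbers$anticodon)),
              " tRNA row(s) with unknown anticodon")
      copy_numbers <- copy_numbers[!is.na(copy_numbers$anticodon), ]
    }
    cn <- tapply(copy_numbers$copy_number, copy_numbers$anticodon, sum)
    copy_numbers <- stats::setNames(as.integer(cn), names(cn))
  }
  stopifnot(is.numeric(copy_numbers), !is.null(names(copy_numbers)))
  names(copy_numbers) <- toupper(chartr("Tt", "Uu", names(copy_numbers)))
  bad <- !grepl("^[ACGU]{3}$", names(copy_numbers))
  if (any(bad)) stop("invalid anticodons: ",
                     paste(names(copy_numbers)[bad], collapse = ", "))
  if (any(copy_numbers < 1)) stop("copy numbers must be >= 1")
  if (sum(copy_numbers) < 1) stop("empty tRNAome")
  structure(list(genome_id = genome_id, organelle = organelle,
                 copy_numbers = copy_numbers[order(names(copy_numbers))]),
            class = "trnaome")
}

#' @export
print.trnaome <- function(x, ...) {
  cat("tRNAome of", x$genome_id, "(", x$organelle, "):",
      length(x$copy_numbers), "anticodons,",
      sum(x$copy_numbers), "gene copies\n")
  print(x$copy_numbers)
  invisible(x)
}

#' Default wobble-constraint vector (s-vector)
#'
#' Selective constraints `s` in `[0, 1]` per codon:anticodon pairing class
#' at the wobble position (anticodon base 34 against codon base 3).
#' Watson-Crick pairings carry no constraint (`s = 0`); wobble pairings are
#' penalised.  The default values are the widely used defaults of the
#' reference tRNA-adaptation-index implementation; they are editable and
#' can be round-tripped through [write_table()] / [read_s_vector()].
#'
#' Classes: `WC` (all Watson-Crick 34:3 pairs, including A34:U3), `G:U`
#' (G34 reading U-ending codons), `U:G` (U34 reading G-ending codons),
#' `I:C` and `I:A` (A34 treated as inosine reading C- and A-ending
#' codons).
#'
#' @return Named numeric vector (an s-vector).
#' @export
default_s_vector <- function() {
  c("WC" = 0, "G:U" = 0.41, "I:C" = 0.28, "I:A" = 0.9999, "U:G" = 0.68)
}

#' Read an s-vector from a two-column TSV (class, s)
#' @param path TSV with columns `class` and `s`.
#' @return Named numeric vector.
#' @export
read_s_vector <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("class", "s") %in% names(tab)))
  s <- stats::setNames(tab$s, tab$class)
  .validate_s(s)
  s
}

.validate_s <- function(s) {
  stopifnot(is.numeric(s), !is.null(names(s)))
  if (any(s < 0 | s > 1)) stop("s-vector values must lie in [0, 1]")
  if (!"WC" %in% names(s)) stop("s-vector must define the WC class")
  invisible(s)
}

# Pairing classes recognised at the wobble position: for each anticodon
# base 34, which codon third bases it reads and under which class.
.PAIRING_34 <- list(
  G = c(C = "WC", U = "G:U"),
  C = c(G = "WC"),
  U = c(A = "WC", G = "U:G"),
  A = c(U = "WC", C = "I:C", A = "I:A")  # A34 treated as inosine
)

#' Relative adaptiveness (wi) of every sense codon
#'
#' For each sense codon `c`, the absolute adaptiveness is
#' `W_c = sum over pairing tRNAs of (1 - s_pairing) * tGCN`, where the sum
#' runs over all anticodons whose bases 35-36 Watson-Crick pair the codon
#' bases 2-1 and whose base 34 reads the codon's third base under a
#' recognised pairing class.  `wi = W / max(W)`.  Codons with `W = 0`
#' (undecodable by the tRNAome under these pairing classes) are replaced
#' by the geometric mean of the nonzero `wi` and listed in
#' `zero_replaced`.  Doubling all copy numbers leaves `wi` unchanged.
#'
#' @param trnaome A [trnaome()].
#' @param s An s-vector (see [default_s_vector()]).
#' @param code A [genetic_code()].
#' @return A `wi_vector`: `values` (named over sense codons, max 1),
#'   `zero_replaced`, `s`, `code_id`.
#' @export
compute_wi <- function(trnaome, s = default_s_vector(),
                       code = genetic_code("standard")) {
  stopifnot(inherits(trnaome, "trnaome"), inherits(code, "genetic_code"))
  .validate_s(s)
  sense <- code$sense_codons
  W <- stats::setNames(numeric(length(sense)), sense)
  for (ac in names(trnaome$copy_numbers)) {
    n <- trnaome$copy_numbers[[ac]]
    b34 <- substr(ac, 1L, 1L)
    stem <- revcomp(substr(ac, 2L, 3L))  # codon bases 1-2
    reads <- .PAIRING_34[[b34]]
    for (b3 in names(reads)) {
      cls <- reads[[b3]]
      if (!cls %in% names(s)) next
      cod <- paste0(stem, b3)
      if (cod %in% sense) W[cod] <- W[cod] + (1 - s[[cls]]) * n
    }
  }
  if (max(W) == 0) stop("tRNAome decodes no sense codon at all")
  wi <- W / max(W)
  zero <- names(wi)[wi == 0]
  if (length(zero)) wi[zero] <- exp(mean(log(wi[wi > 0])))
  structure(list(values = wi, zero_replaced = zero, s = s,
                 code_id = code$code_id, genome_id = trnaome$genome_id),
            class = "wi_vector")
}

#' @export
print.wi_vector <- function(x, ...) {
  cat("Relative adaptiveness (wi) for", x$genome_id,
      "under code", x$code_id, "\n")
  cat("  range:", sprintf("%.4f..%.4f;", min(x$values), max(x$values)),
      length(x$zero_replaced), "codon(s) zero-replaced\n")
  invisible(x)
}

#' tRNA adaptation index of a gene
#'
#' Geometric mean of the `wi` values over a gene's codons:
#' `tAI = exp( sum_c n_c log wi_c / sum_c n_c )`, stop codons excluded.
#' Equals 1 iff every used codon has `wi = 1`.
#'
#' @param counts A `codon_counts` object.
#' @param wi A `wi_vector`.
#' @return A `tai_result`: `gene_id`, `tai` in `(0, 1]`.
#' @export
tai <- function(counts, wi) {
  stopifnot(inherits(counts, "codon_counts"), inherits(wi, "wi_vector"))
  n <- counts$counts[names(wi$values)]
  tot <- sum(n)
  if (tot == 0L) stop("no usable codons in gene ", counts$gene_id)
  structure(list(gene_id = counts$gene_id,
                 tai = exp(sum(n * log(wi$values)) / tot)),
            class = "tai_result")
}

#' @export
print.tai_result <- function(x, ...) {
  cat(sprintf("tAI(%s) = %.4f\n", x$gene_id, x$tai))
  invisible(x)
}

# fast path: tAI for every row of a genes-by-64 counts matrix
tai_vector <- function(m, wi_values) {
  sense <- names(wi_values)
  sub <- m[, sense, drop = FALSE]
  tot <- rowSums(sub)
  if (any(tot == 0)) stop("genes with no usable codons: ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  exp(as.vector(sub %*% log(wi_values)) / tot)
}

#' The S statistic: correlation between tAI and ENc deviation
#'
#' Correlation between per-gene tRNA adaptation (tAI) and the per-gene ENc
#' deviation from the neutral expectation, `(expected - observed) /
#' expected`: the share of codon-usage variance attributable to
#' translational selection.  Pearson by default; Spearman optionally.
#'
#' @param tai_values Numeric vector of per-gene tAI values.
#' @param deviations Numeric vector of per-gene ENc deviations.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation (`NA` with a warning if either input is
#'   constant).
#' @export
s_statistic <- function(tai_values, deviations,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(tai_values, deviations)
  x <- tai_values[ok]; y <- deviations[ok]
  if (length(x) < 3L) stop("need at least 3 gene points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant tAI or deviation: S undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' Permutation S-test for translational selection
#'
#' Computes the observed S value for a gene set and its permutation null:
#' in each replicate the multiset of `wi` values is randomly reassigned to
#' the sense codons, per-gene tAI values recomputed, and S recalculated.
#' The empirical p-value uses the add-one correction
#' `p = (1 + #[perm >= obs]) / (n_perm + 1)` and is therefore never 0; the
#' observed S is declared significant when it falls in the top 5% of the
#' permutation distribution, i.e. `empirical_p <= 0.05` (at `n_perm = 100`
#' this means at most 4 permuted values reach the observed S; the exact
#' type-I rate under exchangeability is 5/101).
#'
#' @param gene_counts List of `codon_counts` or a genes-by-64 counts
#'   matrix.
#' @param deviations Per-gene ENc deviations, aligned with the genes (e.g.
#'   the `deviation` column of [enc_table()]).
#' @param wi A `wi_vector`.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation RNG.
#' @param method Correlation flavour, see [s_statistic()].
#' @return An `stest_result`: `genome_id`, `s_value`, `perm_values`,
#'   `empirical_p`, `significant`, `n_perm`, `seed`, `correlation_type`.
#' @export
permutation_s_test <- function(gene_counts, deviations, wi, n_perm = 100L,
                               seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  m <- if (is.matrix(gene_counts)) gene_counts else counts_matrix(gene_counts)
  stopifnot(length(deviations) == nrow(m))
  genome_id <- if (is.matrix(gene_counts)) "geneset"
               else gene_counts[[1L]]$genome_id
  wv <- wi$values
  obs <- s_statistic(tai_vector(m, wv), deviations, method = method)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pv <- stats::setNames(sample(wv), names(wv))
      s_statistic(tai_vector(m, pv), deviations, method = method)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  structure(list(genome_id = genome_id,
                 s_value = obs,
                 correlation_type = method,
                 n_perm = as.integer(n_perm),
                 perm_values = perm,
                 empirical_p = p,
                 significant = !is.na(obs) && p <= 0.05,
                 seed = as.integer(seed)),
            class = "stest_result")
}

#' @export
print.stest_result <- function(x, ...) {
  cat(sprintf("S-test for %s: S = %.4f (%s), p = %.4f over %d permutations -> %s\n",
              x$genome_id, x$s_value, x$correlation_type, x$empirical_p,
              x$n_perm,
              if (x$significant) "significant (top 5%)" else "not significant"))
  invisible(x)
}

#' Optimise the wobble-constraint vector against a gene set
#'
#' Species-specific tuning of the s-vector (the stAI idea): coordinate
#' hill climbing over the non-Watson-Crick constraint classes, maximising
#' a scalar objective.  Accepted steps never decrease the objective; the
#' climb and its trace are fully determined by the seed.
#'
#' Two objectives are built in:
#' \describe{
#'   \item{`"s_correlation"` (default)}{the S statistic itself, the
#'     correlation between tAI and ENc deviation.  Useful for maximising
#'     the selection signal, but note it rewards *stronger* wobble
#'     constraints than the ones generating the data, because inflating
#'     the within-family wi contrast inflates the tAI spread — it is not a
#'     consistent estimator of the generating constraints.}
#'   \item{`"usage_contrast"`}{correlation, over codons, between the
#'     family-centred wi values and the family-centred log usage contrast
#'     of high- versus low-deviation genes.  Family-centring cancels
#'     mutational bias, so this objective recovers the generating
#'     constraints from synthetic data.}
#' }
#' A `function(s_vector) -> scalar` may be supplied instead.
#'
#' @param gene_counts List of `codon_counts` or a counts matrix.
#' @param deviations Per-gene ENc deviations.
#' @param trnaome A [trnaome()].
#' @param code A [genetic_code()].
#' @param s_init Starting s-vector.
#' @param bounds Two-element numeric, box constraints for every class
#'   (default `c(0, 1)`).
#' @param objective `"s_correlation"`, `"usage_contrast"`, or a function.
#' @param seed Integer seed (coordinate visiting order is randomised).
#' @return List: `s` (optimised vector), `objective` (its value), `trace`
#'   (data.frame of accepted steps).
#' @export
optimize_s_vector <- function(gene_counts, deviations, trnaome,
                              code = genetic_code("standard"),
                              s_init = default_s_vector(),
                              bounds = c(0, 1),
                              objective = c("s_correlation",
                                            "usage_contrast"),
                              seed = 1L) {
  m <- if (is.matrix(gene_counts)) gene_counts else counts_matrix(gene_counts)
  if (!is.function(objective)) {
    objective <- switch(match.arg(objective),
      s_correlation = function(s) {
        wi <- compute_wi(trnaome, s, code)
        s_statistic(tai_vector(m, wi$values), deviations)
      },
      usage_contrast = .usage_contrast_objective(m, deviations, trnaome,
                                                 code))
  }
  free <- setdiff(names(s_init), "WC")
  cur <- s_init
  f_cur <- objective(cur)
  if (is.na(f_cur)) stop("objective undefined at the initial s-vector")
  trace <- data.frame(step = 0L, class = "init", value = NA_real_,
                      objective = f_cur)
  with_seed(seed, {
    for (step_size in c(0.2, 0.1, 0.05, 0.02)) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (cl in sample(free)) {
          for (cand in c(cur[[cl]] + step_size, cur[[cl]] - step_size)) {
            if (cand < bounds[1L] || cand > bounds[2L]) next
            trial <- cur
            trial[[cl]] <- cand
            f_trial <- objective(trial)
            if (!is.na(f_trial) && f_trial > f_cur) {
              cur <- trial
              f_cur <- f_trial
              trace <- rbind(trace, data.frame(step = nrow(trace),
                                               class = cl, value = cand,
                                               objective = f_cur))
              improved <- TRUE
            }
          }
        }
      }
    }
  })
  list(s = cur, objective = f_cur, trace = trace)
}

# Usage-contrast objective: family-centred log-usage difference between
# high- and low-deviation genes, correlated with family-centred wi.
# Mutational bias is a per-codon additive term in log usage that is
# identical in both groups, so the contrast isolates the selection tilt.
.usage_contrast_objective <- function(m, deviations, trnaome, code) {
  fams <- code$families[lengths(code$families) > 1L]
  hi <- deviations >= stats::median(deviations, na.rm = TRUE)
  u_hi <- colSums(m[hi, , drop = FALSE])
  u_lo <- colSums(m[!hi, , drop = FALSE])
  delta <- log(u_hi + 0.5) - log(u_lo + 0.5)    # add-half smoothing
  cdelta <- unlist(lapply(fams, function(f) delta[f] - mean(delta[f])))
  function(s) {
    wiv <- compute_wi(trnaome, s, code)$values
    cwi <- unlist(lapply(fams, function(f) wiv[f] - mean(wiv[f])))
    stats::cor(cdelta, cwi)
  }
}

# Evaluate an expression under a temporary RNG state; restores the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
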