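#' Count codons in a coding sequence
#'
#' Tallies sense-codon usage of an in-frame coding sequence.  Input may be
#' DNA or RNA, any case; it is transcribed to uppercase RNA internally.  A
#' single trailing stop codon (under the given code) is silently trimmed;
#' an internal stop codon is a hard error (it signals a frame or annotation
#' problem).  Codons containing a non-ACGU character are skipped and
#' counted in `n_skipped`.
#'
#' @param seq Coding nucleotide string, length divisible by 3.
#' @param code A [genetic_code()].
#' @param gene_id,genome_id Identifiers carried into the result.
#' @param organelle `"mito"` or `"nuclear"` (metadata only).
#' @return A `codon_counts` object: `counts` is a named integer vector over
#'   all 64 codons (stop codons always 0), `n_codons` the number of sense
#'   codons counted, `n_skipped` the number of ambiguous codons dropped.
#' @examples
#' cc <- count_codons("ATGGCAGCA", genetic_code("standard"))
#' cc$n_codons                 # 3
#' cc$counts[c("AUG", "GCA")]  # 1, 2
#' @export
count_codons <- function(seq, code, gene_id = "gene", genome_id = "genome",
                         organelle = c("mito", "nuclear")) {
  stopifnot(is.character(seq), length(seq) == 1L, inherits(code, "genetic_code"))
  organelle <- match.arg(organelle)
  rna <- toupper(chartr("Tt", "Uu", seq))
  if (nchar(rna) %% 3L != 0L)
    stop("sequence length of '", gene_id, "' (", nchar(rna),
         ") is not divisible by 3")
  n <- nchar(rna) %/% 3L
  if (n == 0L) stop("empty sequence for '", gene_id, "'")
  cods <- substring(rna, seq(1L, by = 3L, length.out = n),
                    seq(3L, by = 3L, length.out = n))
  ok <- !is.na(match(cods, all_codons()))
  # trim one trailing stop codon if present
  if (ok[n] && cods[n] %in% code$stop_codons) {
    cods <- cods[-n]
    ok <- ok[-n]
  }
  internal_stop <- which(ok & cods %in% code$stop_codons)
  if (length(internal_stop))
    stop("internal stop codon (", cods[internal_stop[1L]], ") at codon ",
         internal_stop[1L], " in gene '", gene_id, "'")
  counts <- integer(64L)
  names(counts) <- all_codons()
  tab <- table(cods[ok])
  counts[names(tab)] <- as.integer(tab)
  new_codon_counts(counts, gene_id = gene_id, genome_id = genome_id,
                   organelle = organelle, code_id = code$code_id,
                   n_skipped = sum(!ok))
}

new_codon_counts <- function(counts, gene_id, genome_id, organelle,
                             code_id, n_skipped = 0L) {
  stopifnot(length(counts) == 64L, all(counts >= 0))
  structure(list(gene_id = gene_id, genome_id = genome_id,
                 organelle = organelle, code_id = code_id,
                 counts = counts, n_codons = sum(counts),
                 n_skipped = as.integer(n_skipped)),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts for", x$gene_id, "(genome", x$genome_id,
      "|", x$organelle, "| code", x$code_id, ")\n")
  cat(" ", x$n_codons, "sense codons,", x$n_skipped, "skipped\n")
  used <- x$counts[x$counts > 0]
  print(used[order(-used)][seq_len(min(10L, length(used)))])
  invisible(x)
}

#' Pool codon counts across genes of one genome
#'
#' Element-wise sum of per-gene counts, producing a genome-level
#' `codon_counts` (the input of genome-level RSCU profiles).  All inputs
#' must share `genome_id` and genetic code.
#'
#' @param gene_counts Non-empty list of `codon_counts`.
#' @param gene_id Identifier of the pooled result (default
#'   `"<genome_id>:pooled"`).
#' @return A `codon_counts` object.
#' @export
pool_counts <- function(gene_counts, gene_id = NULL) {
  if (!length(gene_counts)) stop("cannot pool an empty list of counts")
  stopifnot(all(vapply(gene_counts, inherits, logical(1), "codon_counts")))
  genomes <- unique(vapply(gene_counts, `[[`, character(1), "genome_id"))
  codes <- unique(vapply(gene_counts, `[[`, character(1), "code_id"))
  if (length(genomes) != 1L) stop("cannot pool counts from mixed genomes: ",
                                  paste(genomes, collapse = ", "))
  if (length(codes) != 1L) stop("cannot pool counts under mixed codes: ",
                                paste(codes, collapse = ", "))
  counts <- Reduce(`+`, lapply(gene_counts, `[[`, "counts"))
  new_codon_counts(counts,
                   gene_id = gene_id %||% paste0(genomes, ":pooled"),
                   genome_id = genomes,
                   organelle = gene_counts[[1L]]$organelle,
                   code_id = codes,
                   n_skipped = sum(vapply(gene_counts, `[[`, integer(1),
                                          "n_skipped")))
}

#' Stack codon counts into a genes-by-64 matrix
#'
#' @param gene_counts List of `codon_counts`.
#' @return Integer matrix with one row per gene (rownames = gene ids) and
#'   the 64 codons as columns.
#' @export
counts_matrix <- function(gene_counts) {
  stopifnot(length(gene_counts) > 0L)
  m <- do.call(rbind, lapply(gene_counts, `[[`, "counts"))
  rownames(m) <- vapply(gene_counts, `[[`, character(1), "gene_id")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
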