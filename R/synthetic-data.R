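#' Specification of a synthetic gene set
#'
#' Describes the stated generative world of the simulator: genes whose
#' amino-acid sequence is uniform over the degenerate synonymous families
#' and whose synonymous codon choice mixes a mutational bias (third-
#' position GC target) with an exponential tilt towards high-`wi` codons
#' of strength `beta`.  `beta = 0` is exactly the pure mutational model.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in codons.
#' @param gc3_target Third-position GC probability in `[0, 1]`; scalar or
#'   one value per gene (mutational bias pi).
#' @param beta Translational selection strength, `>= 0`.
#' @param expression Per-gene positive weights multiplying `beta`:
#'   a numeric vector, `"constant"` (all 1), or `"lognormal"` (drawn
#'   log-normal meanlog 0, sdlog 1 from the spec seed — a conventional
#'   stand-in for an expression distribution).
#' @param code_id Genetic code id (see [genetic_code()]).
#' @param seed Integer seed; identical specs produce identical gene sets.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 200L, gene_length = 300L,
                           gc3_target = 0.5, beta = 0,
                           expression = "constant",
                           code_id = "mold_mito", seed = 1L) {
  stopifnot(n_genes >= 1L, gene_length >= 1L, beta >= 0,
            all(gc3_target >= 0 & gc3_target <= 1))
  if (is.character(expression))
    expression <- match.arg(expression, c("constant", "lognormal"))
  else stopifnot(is.numeric(expression), all(expression > 0))
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 gc3_target = rep_len(gc3_target, n_genes),
                 beta = beta, expression = expression,
                 code_id = code_id, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic spec: %d genes x %d codons, code %s, beta %g, seed %d\n",
              x$n_genes, x$gene_length, x$code_id, x$beta, x$seed))
  cat(sprintf("  gc3 target: %s | expression: %s\n",
              paste(format(range(x$gc3_target)), collapse = ".."),
              if (is.character(x$expression)) x$expression
              else "numeric (user)"))
  invisible(x)
}

#' Simulate a tRNAome of controlled decoding coverage
#'
#' `"full"`: for every synonymous family, enough anticodons (G34 for
#' pyrimidine-ending codons, U34 for purine-ending) that all sense codons
#' are decodable under crick wobble rules.  `"sparse"`: exactly one
#' anticodon per amino acid — the versatility-maximising one for its
#' largest sub-family — emulating a minimal mitochondrial tRNAome and
#' leaving some codons undecodable.  Copy numbers are 1 plus a seeded
#' Poisson jitter, so tGCN varies without changing coverage.
#'
#' @param code A [genetic_code()].
#' @param coverage `"full"` or `"sparse"`.
#' @param seed Integer seed.
#' @param genome_id,organelle Metadata for the result.
#' @return A [trnaome()].
#' @export
simulate_trnaome <- function(code = genetic_code("mold_mito"),
                             coverage = c("full", "sparse"), seed = 1L,
                             genome_id = "synthetic", organelle = "mito") {
  coverage <- match.arg(coverage)
  stopifnot(inherits(code, "genetic_code"))
  acs <- character(0)
  for (nm in names(code$families)) {
    cod <- code$families[[nm]]
    stems <- split(cod, substr(cod, 1L, 2L))
    fam_acs <- character(0)
    for (stem in names(stems)) {
      endings <- substr(stems[[stem]], 3L, 3L)
      picks <- character(0)
      if (any(endings %in% c("C", "U"))) picks <- c(picks, "G")
      if (any(endings %in% c("A", "G"))) picks <- c(picks, "U")
      # anticodon = revcomp(stem + complement(base34)); base34 prepended
      fam_acs <- c(fam_acs, paste0(picks, revcomp(stem)))
    }
    if (coverage == "sparse") {
      # one anticodon per amino acid: prefer the largest stem group, and
      # within it the U34 (purine-reading) anticodon when present
      sizes <- lengths(stems)
      big <- names(stems)[which.max(sizes)]
      endings <- substr(stems[[big]], 3L, 3L)
      cover_u <- sum(endings %in% c("A", "G"))  # U34 reads A and G
      cover_g <- sum(endings %in% c("C", "U"))  # G34 reads C and U
      pick34 <- if (cover_u >= cover_g) "U" else "G"
      fam_acs <- paste0(pick34, revcomp(big))
    }
    acs <- c(acs, fam_acs)
  }
  acs <- sort(unique(acs))
  cn <- with_seed(seed, 1L + stats::rpois(length(acs), 0.5))
  trnaome(stats::setNames(cn, acs), genome_id = genome_id,
          organelle = organelle)
}

#' Simulate codon counts for a gene set
#'
#' Per gene, `gene_length` amino acids are drawn uniformly over the
#' degenerate (size >= 2) families; the synonymous codon within a family
#' is drawn with probability proportional to
#' `m(c) * exp(beta * g * wi_c)`, where the mutational weight `m(c)` puts
#' probability `gc3_target/2` on each of G and C and `(1-gc3_target)/2`
#' on each of A and U at the third position (positions 1-2 uniform across
#' the family's stems), and `g` is the gene's expression weight.  With
#' `beta = 0` this is exactly the mutational null.
#'
#' @param spec A [synthetic_spec()].
#' @param wi A `wi_vector` over the spec's code (required when
#'   `beta > 0`); see [compute_wi()].
#' @param as Return a list of `codon_counts` (default) or the bare
#'   genes-by-64 counts matrix (fast path).
#' @param genome_id Genome id stamped on the genes.
#' @return List of `codon_counts`, or an integer matrix when
#'   `as = "matrix"`; either way the realised per-gene expression weights
#'   are attached as attribute `"expression"`.
#' @export
simulate_genes <- function(spec, wi = NULL,
                           as = c("codon_counts", "matrix"),
                           genome_id = "synthetic") {
  as <- match.arg(as)
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code(spec$code_id)
  fams <- code$families[lengths(code$families) > 1L]
  n_fam <- length(fams)
  cods <- all_codons()
  if (spec$beta > 0 && is.null(wi))
    stop("a wi_vector is required when beta > 0")
  wiv <- stats::setNames(numeric(64L), cods)
  if (!is.null(wi)) wiv[names(wi$values)] <- wi$values
  fam_index <- lapply(fams, function(cod) match(cod, cods))
  third <- substr(cods, 3L, 3L)
  G <- spec$n_genes
  m <- with_seed(spec$seed, {
    g <- if (is.character(spec$expression)) {
      if (spec$expression == "lognormal") stats::rlnorm(G, 0, 1)
      else rep(1, G)
    } else rep_len(spec$expression, G)
    # per-gene codon probability vector over all 64 codons
    tilt <- spec$beta * g                 # per gene
    pi_gc <- spec$gc3_target              # per gene
    key <- paste(signif(tilt, 12), signif(pi_gc, 12))
    out <- matrix(0L, G, 64L, dimnames = list(sprintf("g%04d", seq_len(G)),
                                              cods))
    for (grp in split(seq_len(G), key)) {
      i1 <- grp[1L]
      p3 <- ifelse(third %in% c("G", "C"), pi_gc[i1] / 2, (1 - pi_gc[i1]) / 2)
      q <- numeric(64L)
      for (fi in seq_len(n_fam)) {
        idx <- fam_index[[fi]]
        w <- p3[idx] * exp(tilt[i1] * wiv[idx])
        q[idx] <- (w / sum(w)) / n_fam
      }
      draws <- stats::rmultinom(length(grp), spec$gene_length, q)
      out[grp, ] <- t(draws)
    }
    attr(out, "expression") <- g
    out
  })
  if (as == "matrix") return(m)
  genes <- lapply(seq_len(G), function(i)
    new_codon_counts(m[i, ], gene_id = rownames(m)[i], genome_id = genome_id,
                     organelle = "mito", code_id = code$code_id))
  attr(genes, "expression") <- attr(m, "expression")
  genes
}

#' Packaged simulation scenarios
#'
#' Named fixtures with documented seeds:
#' \describe{
#'   \item{neutral}{200 genes, `beta = 0`, genome-wide GC3 target 0.35 —
#'     pure mutational bias, shared by all genes of the genome (mutational
#'     bias is a genome-level property; per-gene GC3 spreads are available
#'     directly through [synthetic_spec()] for neutrality-plot fixtures).}
#'   \item{selected}{200 genes, `beta = 2`, log-normal expression weights,
#'     GC3 target 0.35 — translational selection on top of AT bias.}
#'   \item{two_class}{100 genes at GC3 0.25 plus 100 at 0.75 — the
#'     correspondence-analysis separation fixture.}
#' }
#'
#' @param name Scenario name.
#' @param seed Base seed (default 101); the tRNAome uses `seed + 1`.
#' @return List: `spec` (a [synthetic_spec()]), `trnaome` (a sparse
#'   mitochondrial-style [trnaome()]), `wi` (its [compute_wi()] vector),
#'   `code`.
#' @export
scenario <- function(name = c("neutral", "selected", "two_class"),
                     seed = 101L) {
  name <- match.arg(name)
  code <- genetic_code("mold_mito")
  spec <- switch(name,
    neutral = synthetic_spec(n_genes = 200L, gene_length = 300L,
                             gc3_target = 0.35, beta = 0,
                             code_id = "mold_mito", seed = seed),
    selected = synthetic_spec(n_genes = 200L, gene_length = 300L,
                              gc3_target = 0.35, beta = 2,
                              expression = "lognormal",
                              code_id = "mold_mito", seed = seed),
    two_class = synthetic_spec(n_genes = 200L, gene_length = 300L,
                               gc3_target = rep(c(0.25, 0.75), each = 100L),
                               beta = 0, code_id = "mold_mito", seed = seed))
  trn <- simulate_trnaome(code, "sparse", seed = seed + 1L)
  list(spec = spec, trnaome = trn, wi = compute_wi(trn, code = code),
       code = code)
}
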