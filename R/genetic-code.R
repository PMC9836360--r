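# Bases and codons are RNA, uppercase, throughout the package.
RNA_BASES <- c("U", "C", "A", "G")

#' The 64 RNA codons in canonical (U, C, A, G nested) order
#'
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  as.vector(vapply(RNA_BASES, function(b1)
    vapply(RNA_BASES, function(b2)
      paste0(b1, b2, RNA_BASES), character(4)), character(16)))
}

# NCBI-style amino-acid strings over the canonical codon order.
# Single-letter amino acids; "*" marks stop codons.
.CODE_STRINGS <- list(
  standard  = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  mold_mito = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
)
# Aliases: NCBI translation table numbers.
.CODE_ALIASES <- c("1" = "standard", "4" = "mold_mito")

.AA3 <- c(F = "Phe", L = "Leu", S = "Ser", Y = "Tyr", C = "Cys", W = "Trp",
          P = "Pro", H = "His", Q = "Gln", R = "Arg", I = "Ile", M = "Met",
          T = "Thr", N = "Asn", K = "Lys", V = "Val", A = "Ala", D = "Asp",
          E = "Glu", G = "Gly", "*" = "STOP")

#' Build a genetic code table
#'
#' Constructs a `genetic_code` object holding the codon-to-amino-acid map,
#' the synonymous family partition, Wright's degeneracy classes, and the
#' theoretical maximum of the effective number of codons for the code.
#'
#' Two codes are registered: `"standard"` (NCBI translation table 1, alias
#' `"1"`) and `"mold_mito"` (NCBI translation table 4, alias `"4"`), the
#' mold mitochondrial code in which UGA encodes tryptophan and AUA remains
#' isoleucine.  A path to a plain-text table (lines of `CODON<TAB>AA`,
#' RNA codons, one-letter amino acids, `*` for stop) may be given instead
#' to register a custom code.
#'
#' @param code_id `"standard"`, `"mold_mito"`, `"1"`, `"4"`, or a path to a
#'   custom code table file.
#' @return A `genetic_code` object with elements `code_id`, `codon_to_aa`
#'   (named character vector over all 64 codons), `stop_codons`,
#'   `sense_codons`, `families` (unsplit synonymous families, a named list
#'   of codon vectors), `degeneracy_classes` (families grouped by size),
#'   and `enc_max`.
#' @examples
#' code <- genetic_code("standard")
#' code$enc_max                      # 61
#' genetic_code("mold_mito")$codon_to_aa[["UGA"]]  # "W"
#' @export
genetic_code <- function(code_id = "standard") {
  stopifnot(is.character(code_id), length(code_id) == 1L)
  if (code_id %in% names(.CODE_ALIASES)) code_id <- .CODE_ALIASES[[code_id]]
  codons <- all_codons()
  if (code_id %in% names(.CODE_STRINGS)) {
    aa <- strsplit(.CODE_STRINGS[[code_id]], "")[[1]]
    names(aa) <- codons
  } else if (file.exists(code_id)) {
    tab <- utils::read.table(code_id, sep = "\t", header = FALSE,
                             col.names = c("codon", "aa"),
                             colClasses = "character")
    tab$codon <- toupper(chartr("Tt", "Uu", tab$codon))
    if (!setequal(tab$codon, codons) || nrow(tab) != 64L)
      stop("custom code table must cover exactly the 64 codons once each")
    aa <- stats::setNames(tab$aa, tab$codon)[codons]
    code_id <- paste0("custom:", basename(code_id))
  } else {
    stop("unknown genetic code id: ", code_id)
  }
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  fams <- split(sense, aa[sense])
  names(fams) <- .aa_name(names(fams))
  fams <- fams[order(names(fams))]
  sizes <- lengths(fams)
  classes <- split(names(fams), sizes)
  # ENc upper bound: every class mean homozygosity at its uniform value 1/k.
  enc_max <- sum(as.integer(names(classes)) * lengths(classes))
  structure(list(code_id = code_id,
                 codon_to_aa = aa,
                 stop_codons = stops,
                 sense_codons = sense,
                 families = fams,
                 degeneracy_classes = classes,
                 enc_max = enc_max),
            class = "genetic_code")
}

.aa_name <- function(aa1) {
  out <- .AA3[aa1]
  out[is.na(out)] <- aa1[is.na(out)]
  unname(out)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$code_id, "\n")
  cat(" ", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons (",
      paste(x$stop_codons, collapse = ", "), ")\n")
  cat("  degeneracy classes:",
      paste(sprintf("%s-fold x%d", names(x$degeneracy_classes),
                    lengths(x$degeneracy_classes)), collapse = ", "), "\n")
  cat("  ENc maximum:", x$enc_max, "\n")
  invisible(x)
}

#' Family policy for RSCU computation
#'
#' Records how synonymous families are formed when computing RSCU vectors:
#' whether sixfold families (Leu, Ser, Arg under the standard code) are
#' split into their fourfold and twofold sub-families, and whether
#' nondegenerate (single-codon) families are excluded.  ENc always uses the
#' unsplit Wright classes regardless of this policy.
#'
#' @param split_sixfold Split sixfold families into fourfold + twofold
#'   sub-families (default `TRUE`).
#' @param exclude_nondegenerate Drop single-codon families from RSCU
#'   vectors (default `TRUE`).
#' @return A `family_policy` object.
#' @export
family_policy <- function(split_sixfold = TRUE, exclude_nondegenerate = TRUE) {
  structure(list(split_sixfold = isTRUE(split_sixfold),
                 exclude_nondegenerate = isTRUE(exclude_nondegenerate)),
            class = "family_policy")
}

#' @export
print.family_policy <- function(x, ...) {
  cat("Family policy: split_sixfold =", x$split_sixfold,
      "| exclude_nondegenerate =", x$exclude_nondegenerate, "\n")
  invisible(x)
}

#' Synonymous families under a family policy
#'
#' @param code A `genetic_code`.
#' @param policy A [family_policy()].
#' @return Named list of codon vectors; sub-families of a split sixfold
#'   family are suffixed with their size (e.g. `Ser4`, `Ser2`).
#' @examples
#' fams <- codon_families(genetic_code("standard"), family_policy())
#' fams$Ser4  # UCU UCC UCA UCG
#' @export
codon_families <- function(code, policy = family_policy()) {
  stopifnot(inherits(code, "genetic_code"), inherits(policy, "family_policy"))
  fams <- code$families
  if (policy$split_sixfold) {
    out <- list()
    for (nm in names(fams)) {
      cod <- fams[[nm]]
      if (length(cod) == 6L) {
        stems <- substr(cod, 1L, 2L)
        for (grp in split(cod, stems)) {
          out[[paste0(nm, length(grp))]] <- grp
        }
      } else {
        out[[nm]] <- cod
      }
    }
    fams <- out
  }
  if (policy$exclude_nondegenerate) fams <- fams[lengths(fams) > 1L]
  fams[order(names(fams))]
}

# Reverse complement of an RNA string (vectorised over characters).
revcomp <- function(x) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1))
}
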