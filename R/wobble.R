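#' Wobble pairing rules
#'
#' Which codon third bases each anticodon base 34 can read.  Three modes:
#' \describe{
#'   \item{strict}{Watson-Crick only: G34:C, C34:G, U34:A, A34:U.}
#'   \item{crick}{classic wobble: G34 reads \{C, U\}; U34 reads \{A, G\};
#'     C34 reads \{G\}; A34 reads \{U\}.}
#'   \item{extended}{crick plus inosine: A34 is treated as I34 and reads
#'     \{U, C, A\} (when `assume_inosine`, the default for this mode).}
#' }
#' Every mode contains all Watson-Crick pairings, and
#' `extended >= crick >= strict` in decoding capacity.
#'
#' @param mode `"strict"`, `"crick"` (default), or `"extended"`.
#' @param assume_inosine Read A34 as inosine in extended mode.
#' @return A `wobble_rules` object: `mode`, `pairings` (list base34 ->
#'   codon third bases), `assume_inosine`.
#' @export
wobble_rules <- function(mode = c("crick", "strict", "extended"),
                         assume_inosine = (mode == "extended")) {
  mode <- match.arg(mode)
  pairings <- switch(mode,
    strict = list(G = "C", C = "G", U = "A", A = "U"),
    crick = list(G = c("C", "U"), C = "G", U = c("A", "G"), A = "U"),
    extended = list(G = c("C", "U"), C = "G", U = c("A", "G"),
                    A = if (isTRUE(assume_inosine)) c("U", "C", "A") else "U"))
  structure(list(mode = mode, pairings = pairings,
                 assume_inosine = isTRUE(assume_inosine)),
            class = "wobble_rules")
}

#' @export
print.wobble_rules <- function(x, ...) {
  cat("Wobble rules:", x$mode,
      if (x$assume_inosine) "(A34 read as inosine)", "\n")
  for (b in names(x$pairings))
    cat(" ", b, "34 reads codon 3rd base:",
        paste(x$pairings[[b]], collapse = ", "), "\n")
  invisible(x)
}

#' Codons decodable by one anticodon
#'
#' Anticodons are written 5'->3', so position 34 (the wobble base) is the
#' first character and pairs the codon's third base; anticodon positions
#' 35 and 36 Watson-Crick pair codon positions 2 and 1 (antiparallel
#' reverse-complement convention).
#'
#' @param anticodon RNA 3-mer.
#' @param rules A [wobble_rules()].
#' @return Character vector of codons.
#' @examples
#' anticodon_to_codons("CAU", wobble_rules("strict"))  # AUG
#' anticodon_to_codons("UGC", wobble_rules("crick"))   # GCA GCG
#' @export
anticodon_to_codons <- function(anticodon, rules = wobble_rules()) {
  stopifnot(inherits(rules, "wobble_rules"))
  anticodon <- toupper(chartr("Tt", "Uu", anticodon))
  if (!grepl("^[ACGU]{3}$", anticodon))
    stop("invalid anticodon: ", anticodon)
  stem <- revcomp(substr(anticodon, 2L, 3L))  # codon positions 1-2
  thirds <- rules$pairings[[substr(anticodon, 1L, 1L)]]
  paste0(stem, thirds)
}

#' Decoding capacity of a tRNAome
#'
#' Which sense codons the tRNAome can read under the given wobble rules:
#' the union of [anticodon_to_codons()] over all anticodons, intersected
#' with the code's sense codons.  The complement is the undecodable set.
#'
#' @param trnaome A [trnaome()].
#' @param code A [genetic_code()].
#' @param rules A [wobble_rules()].
#' @return A `decodability_report`: `decodable` (named logical over sense
#'   codons), `undecodable_set`, `supporting` (list codon -> anticodons),
#'   `rules_used`, `genome_id`.
#' @export
decodability <- function(trnaome, code = genetic_code("standard"),
                         rules = wobble_rules()) {
  stopifnot(inherits(trnaome, "trnaome"), inherits(code, "genetic_code"))
  sense <- code$sense_codons
  supporting <- stats::setNames(vector("list", length(sense)), sense)
  for (ac in names(trnaome$copy_numbers)) {
    for (cod in anticodon_to_codons(ac, rules)) {
      if (cod %in% sense)
        supporting[[cod]] <- c(supporting[[cod]], ac)
    }
  }
  decodable <- lengths(supporting) > 0L
  structure(list(genome_id = trnaome$genome_id,
                 decodable = decodable,
                 undecodable_set = sense[!decodable],
                 supporting = supporting,
                 rules_used = rules),
            class = "decodability_report")
}

#' @export
print.decodability_report <- function(x, ...) {
  cat("Decodability of", x$genome_id, "under", x$rules_used$mode, "rules:\n")
  cat(" ", sum(x$decodable), "of", length(x$decodable),
      "sense codons decodable\n")
  if (length(x$undecodable_set))
    cat("  undecodable:", paste(x$undecodable_set, collapse = ", "), "\n")
  invisible(x)
}

#' Wobble-versatility check of a tRNAome
#'
#' For each synonymous family with at least one tRNA, asks whether the
#' observed anticodon wobble base (position 34) maximises the number of
#' family codons the anticodon can read under crick wobble rules — the
#' wobble versatility hypothesis — as opposed to, say, Watson-Crick
#' matching the most used codon.  For a twofold pyrimidine-ending family
#' (NNY) the maximising base is G34 (reads U and C); for NNR it is U34;
#' for a fourfold family U34 (reads A and G, the crick maximum of 2).
#'
#' @param trnaome A [trnaome()].
#' @param code A [genetic_code()].
#' @return data.frame with one row per family that has tRNAs:
#'   `family`, `anticodons`, `observed_wobble_base`,
#'   `versatility_maximizing`, `note`.
#' @export
versatility_check <- function(trnaome, code = genetic_code("standard")) {
  stopifnot(inherits(trnaome, "trnaome"), inherits(code, "genetic_code"))
  rules <- wobble_rules("crick")
  fams <- code$families
  rows <- list()
  for (nm in names(fams)) {
    cod <- fams[[nm]]
    # anticodons whose Watson-Crick codon lies in this family
    acs <- names(trnaome$copy_numbers)[
      revcomp(names(trnaome$copy_numbers)) %in% cod]
    if (!length(acs)) next
    verdicts <- logical(length(acs))
    notes <- character(0)
    for (i in seq_along(acs)) {
      ac <- acs[i]
      stem <- revcomp(substr(ac, 2L, 3L))
      endings <- substr(cod[substr(cod, 1L, 2L) == stem], 3L, 3L)
      cover <- vapply(RNA_BASES, function(b)
        length(intersect(rules$pairings[[b]], endings)), numeric(1))
      obs <- substr(ac, 1L, 1L)
      verdicts[i] <- cover[[obs]] == max(cover)
      if (!verdicts[i])
        notes <- c(notes, sprintf("%s: %s34 reads %d of %d family codons (max %d)",
                                  ac, obs, cover[[obs]], length(endings),
                                  max(cover)))
    }
    rows[[nm]] <- data.frame(
      family = nm,
      anticodons = paste(acs, collapse = ","),
      observed_wobble_base = paste(substr(acs, 1L, 1L), collapse = ","),
      versatility_maximizing = all(verdicts),
      note = if (length(notes)) paste(notes, collapse = "; ") else "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
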