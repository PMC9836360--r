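#' Read coding sequences from a FASTA file
#'
#' One `gene_record` per entry; the header token before the first
#' whitespace becomes the gene id.  Sequences are uppercased.  Duplicate
#' ids receive a deterministic numeric suffix (`_2`, `_3`, ...) with a
#' warning.
#'
#' @param path FASTA file of nucleotide CDS.
#' @param genome_id Genome identifier attached to every record.
#' @param organelle `"mito"` or `"nuclear"` (from run configuration, never
#'   inferred from headers).
#' @return List of `gene_record` objects (`gene_id`, `genome_id`,
#'   `organelle`, `sequence`, `source`).
#' @export
read_cds_fasta <- function(path, genome_id = "genome",
                           organelle = c("mito", "nuclear")) {
  organelle <- match.arg(organelle)
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("no FASTA entries in ", path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  ids <- sub("\\s.*$", "", names(dna))
  bad <- grepl("[^ACGTUMRWSYKVHDBN]", seqs)
  if (any(bad))
    stop("non-IUPAC nucleotide characters in entries: ",
         paste(ids[bad], collapse = ", "))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate FASTA ids renamed with numeric suffixes: ",
            paste(dup, collapse = ", "))
    ids <- .dedup_ids(ids)
  }
  mapply(function(id, s) gene_record(id, genome_id, organelle, s, "fasta"),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

gene_record <- function(gene_id, genome_id, organelle, sequence, source) {
  stopifnot(nzchar(sequence))
  structure(list(gene_id = gene_id, genome_id = genome_id,
                 organelle = organelle, sequence = sequence, source = source),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("Gene %s (%s, %s, %d nt, from %s)\n", x$gene_id, x$genome_id,
              x$organelle, nchar(x$sequence), x$source))
  invisible(x)
}

#' Write gene records to a FASTA file
#'
#' @param records List of `gene_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r)
    c(paste0(">", r$gene_id), r$sequence)))
  writeLines(lines, path)
  invisible(path)
}

# ---- GenBank flat files -----------------------------------------------
# No maintained R parser for GenBank flat files is available, so a minimal
# reader is implemented here: LOCUS, FEATURES (location + qualifiers, with
# join()/complement() handling), ORIGIN.  Coordinates are 1-based
# inclusive on the forward strand, per the format definition.

#' Extract CDS, tRNA features and summary statistics from a GenBank file
#'
#' Parses a GenBank flat file and returns (a) one `gene_record` per CDS,
#' honouring `join()` locations (exons concatenated in annotation order)
#' and `complement()` strands; (b) tRNA features aggregated by anticodon
#' into copy-number rows; (c) a genome summary (length, GC fraction,
#' feature counts).  tRNA anticodons are taken from the `/anticodon`
#' qualifier or, failing that, a `(pos:...)`-free 3-mer in `/note`; a tRNA
#' without either is counted but flagged with an `NA` anticodon rather
#' than guessed from the product name.
#'
#' @param path GenBank flat file.
#' @param genome_id Genome identifier (default: the LOCUS name).
#' @param organelle `"mito"` or `"nuclear"`.
#' @return List with elements `genes` (list of `gene_record`), `trna`
#'   (data.frame `anticodon`, `amino_acid`, `copy_number`), and `summary`
#'   (list: `genome_id`, `length`, `gc`, `n_cds`, `n_trna`, `n_rrna`,
#'   `flagged_cds`).
#' @export
read_genbank <- function(path, genome_id = NULL,
                         organelle = c("mito", "nuclear")) {
  organelle <- match.arg(organelle)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  name <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L]
          else "genbank_record"
  if (is.null(genome_id)) genome_id <- name
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN sequence block: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
    starts <- grep("^ {5}\\S", block)
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1L])
      rest <- trimws(sub("^ {5}\\S+\\s*", "", chunk[1L]))
      body <- trimws(chunk[-1L])
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", body)
      loc_extra <- if (length(qual_at)) body[seq_len(qual_at[1L] - 1L)] else body
      loc <- paste0(rest, paste(loc_extra, collapse = ""))
      quals <- if (length(qual_at)) .parse_qualifiers(body[qual_at[1L]:length(body)])
               else list()
      features[[length(features) + 1L]] <-
        list(key = key, location = loc, qualifiers = quals)
    }
  }
  keys <- vapply(features, `[[`, character(1), "key")
  genes <- list()
  flagged <- character(0)
  cds_feats <- features[keys == "CDS"]
  raw_ids <- vapply(seq_along(cds_feats), function(i) {
    q <- cds_feats[[i]]$qualifiers
    gsub("\\s+", "_",
         q$gene %||% q$locus_tag %||% q$product %||% paste0("cds_", i))
  }, character(1))
  uniq_ids <- .dedup_ids(raw_ids)
  for (fi in seq_along(cds_feats)) {
    f <- cds_feats[[fi]]
    id <- uniq_ids[fi]
    s <- tryCatch(.extract_location(genome_seq, f$location),
                  error = function(e) {
                    warning("CDS '", id, "': ", conditionMessage(e))
                    NULL
                  })
    if (is.null(s)) next
    if (nchar(s) %% 3L != 0L) {
      warning("CDS '", id, "' length ", nchar(s), " not divisible by 3; flagged")
      flagged <- c(flagged, id)
    }
    genes[[length(genes) + 1L]] <-
      gene_record(id, genome_id, organelle, s, "genbank")
  }
  trna_feats <- features[keys == "tRNA"]
  anti <- character(0); aas <- character(0)
  for (f in trna_feats) {
    ac <- .trna_anticodon(f$qualifiers)
    prod <- f$qualifiers$product %||% ""
    aa <- if (grepl("^tRNA-", prod)) sub("^tRNA-([A-Za-z]{3}).*$", "\\1", prod)
          else NA_character_
    anti <- c(anti, ac)
    aas <- c(aas, aa)
  }
  trna <- if (length(anti)) {
    key <- paste(ifelse(is.na(anti), "unknown", anti),
                 ifelse(is.na(aas), "unknown", aas), sep = "|")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "|", fixed = TRUE)
    data.frame(anticodon = vapply(parts, function(p)
                 if (p[1L] == "unknown") NA_character_ else p[1L], character(1)),
               amino_acid = vapply(parts, function(p)
                 if (p[2L] == "unknown") NA_character_ else p[2L], character(1)),
               copy_number = agg$Freq, stringsAsFactors = FALSE)
  } else {
    data.frame(anticodon = character(0), amino_acid = character(0),
               copy_number = integer(0))
  }
  gc <- mean(strsplit(genome_seq, "")[[1L]] %in% c("G", "C"))
  list(genes = genes, trna = trna,
       summary = list(genome_id = genome_id, length = nchar(genome_seq),
                      gc = gc, n_cds = length(cds_feats),
                      n_trna = length(trna_feats),
                      n_rrna = sum(keys == "rRNA"),
                      flagged_cds = flagged))
}

# occurrence-numbered suffixes for duplicate ids: x, x_2, x_3, ...
.dedup_ids <- function(ids) {
  occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ifelse(occ == 1L, ids, paste0(ids, "_", occ))
}

.parse_qualifiers <- function(lines) {
  # fold continuation lines into their qualifier
  idx <- cumsum(grepl("^/", lines))
  folded <- vapply(split(lines, idx), paste, character(1), collapse = " ")
  out <- list()
  for (q in folded) {
    m <- regmatches(q, regexec("^/([A-Za-z_]+)(=(.*))?$", q))[[1L]]
    if (length(m) < 2L) next
    val <- if (length(m) >= 4L && nzchar(m[4L])) gsub('^"|"$', "", m[4L]) else TRUE
    out[[m[2L]]] <- val
  }
  out
}

.trna_anticodon <- function(quals) {
  for (field in c("anticodon", "note")) {
    v <- quals[[field]]
    if (is.null(v) || isTRUE(v)) next
    # formats: (pos:1..3,aa:Ala,seq:ugc)  or  "anticodon: UGC" in /note
    m <- regmatches(v, regexec("seq\\s*:\\s*([ACGTUacgtu]{3})", v))[[1L]]
    if (length(m) == 2L) return(toupper(chartr("Tt", "Uu", m[2L])))
    m <- regmatches(v, regexec("anticodon\\s*:?\\s*([ACGTUacgtu]{3})\\b", v))[[1L]]
    if (length(m) == 2L) return(toupper(chartr("Tt", "Uu", m[2L])))
  }
  NA_character_
}

# Extract a (possibly join()ed / complement()ed) GenBank location from a
# DNA string.  Coordinates 1-based inclusive.
.extract_location <- function(genome_seq, loc) {
  loc <- gsub("[<>\\s]", "", loc)
  .walk <- function(expr) {
    if (grepl("^complement\\(", expr)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", expr)
      return(.revcomp_dna(.walk(inner)))
    }
    if (grepl("^(join|order)\\(", expr)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", expr)
      parts <- .split_top(inner)
      return(paste(vapply(parts, .walk, character(1)), collapse = ""))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", expr)) {
      ab <- as.integer(strsplit(expr, "\\.\\.")[[1L]])
      if (ab[2L] > nchar(genome_seq) || ab[1L] < 1L || ab[1L] > ab[2L])
        stop("location ", expr, " outside sequence of length ",
             nchar(genome_seq))
      return(substr(genome_seq, ab[1L], ab[2L]))
    }
    if (grepl("^[0-9]+$", expr)) {
      p <- as.integer(expr)
      if (p < 1L || p > nchar(genome_seq)) stop("position ", p, " out of range")
      return(substr(genome_seq, p, p))
    }
    stop("unsupported location syntax: ", expr)
  }
  .walk(loc)
}

# split a comma-separated location list at parenthesis depth 0
.split_top <- function(x) {
  chars <- strsplit(x, "")[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cut <- which(chars == "," & depth == 0L)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

.revcomp_dna <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

#' Read a tabular tRNA count file
#'
#' Expects a TSV with header columns `anticodon`, `amino_acid`,
#' `copy_number` (the tGCN input of the tRNA adaptation machinery).
#' Anticodons are normalised to uppercase RNA.
#'
#' @param path TSV file.
#' @return data.frame with validated columns.
#' @export
read_trna_counts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("anticodon", "amino_acid", "copy_number")
  if (!all(need %in% names(tab)))
    stop("tRNA count table must have columns: ", paste(need, collapse = ", "))
  tab$anticodon <- toupper(chartr("Tt", "Uu", tab$anticodon))
  bad <- !grepl("^[ACGU]{3}$", tab$anticodon)
  if (any(bad)) stop("invalid anticodons: ",
                     paste(tab$anticodon[bad], collapse = ", "))
  if (any(tab$copy_number < 1)) stop("copy numbers must be >= 1")
  tab[need]
}

#' Write a result table as TSV or JSON
#'
#' Deterministic column order (as given), floating-point values at 6
#' significant digits, UTF-8 output.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  out <- rows
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  if (format == "tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
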