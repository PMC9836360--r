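# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain loops, no shared helpers beyond base R.

# naive codon counter: walk the string three bases at a time
oracle_count <- function(seq, stop_codons) {
  s <- toupper(chartr("Tt", "Uu", seq))
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  n <- length(cods)
  if (cods[n] %in% stop_codons) cods <- cods[-n]
  cods <- cods[grepl("^[ACGU]{3}$", cods)]
  out <- integer(64)
  names(out) <- mitocub::all_codons()
  for (c in cods) out[c] <- out[c] + 1L
  out
}

# naive RSCU over a family list
oracle_rscu <- function(counts, families) {
  out <- c()
  for (fam in families) {
    N <- sum(counts[fam])
    k <- length(fam)
    v <- if (N == 0) rep(NA_real_, k) else counts[fam] / (N / k)
    out <- c(out, stats::setNames(v, fam))
  }
  out[order(names(out))]
}

# naive Wright ENc: per-family homozygosity, class means, class sums.
# Imputation mirrors the documented rule (nearest available classes).
oracle_enc <- function(counts, code) {
  fams <- code$families
  sizes <- lengths(fams)
  deg <- sort(unique(sizes[sizes > 1]))
  Fhat <- list()
  for (nm in names(fams)) {
    cod <- fams[[nm]]
    n <- sum(counts[cod])
    if (n < 2) next
    p <- counts[cod] / n
    F <- (n * sum(p^2) - 1) / (n - 1)
    if (F > 0) Fhat[[nm]] <- F
  }
  fbar <- sapply(deg, function(k) {
    vals <- unlist(Fhat[names(fams)[sizes == k]])
    if (length(vals)) mean(vals) else NA_real_
  })
  names(fbar) <- deg
  orig <- fbar   # imputation always reads the unimputed class means
  for (i in seq_along(deg)) {
    if (!is.na(orig[i])) next
    lower <- if (i > 1) orig[i - 1] else NA
    upper <- if (i < length(deg)) orig[i + 1] else NA
    est <- mean(c(lower, upper), na.rm = TRUE)
    if (is.nan(est)) {
      avail <- which(!is.na(orig))
      est <- if (length(avail)) orig[avail[which.min(abs(avail - i))]]
             else 1 / deg[i]
    }
    fbar[i] <- est
  }
  m_k <- sapply(deg, function(k) sum(sizes == k))
  raw <- sum(sizes == 1) + sum(m_k / fbar)
  min(max(raw, 1), code$enc_max)
}

# dense eigendecomposition oracle for correspondence analysis
oracle_ca_eigen <- function(m) {
  n <- sum(m)
  P <- m / n
  r <- rowSums(P); cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)$values
  sort(ev[ev > 1e-12], decreasing = TRUE)
}

# exhaustive decodability scan over all 64 codons
oracle_decodable <- function(anticodons, sense, pairings) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  ok <- character(0)
  for (cod in sense) {
    b <- strsplit(cod, "")[[1]]
    for (ac in anticodons) {
      a <- strsplit(ac, "")[[1]]
      if (comp[[a[3]]] == b[1] && comp[[a[2]]] == b[2] &&
          b[3] %in% pairings[[a[1]]]) {
        ok <- c(ok, cod)
        break
      }
    }
  }
  sort(setdiff(sense, ok))
}

# random codon_counts over a code's sense codons
random_counts <- function(code, n_codons = 300, gene_id = "rand") {
  cods <- sample(code$sense_codons, n_codons, replace = TRUE)
  counts <- integer(64)
  names(counts) <- mitocub::all_codons()
  tab <- table(cods)
  counts[names(tab)] <- as.integer(tab)
  mitocub:::new_codon_counts(counts, gene_id, "oracle_genome", "mito",
                             code$code_id)
}

counts_from <- function(x, code_id = "standard", gene_id = "g",
                        genome_id = "genome") {
  counts <- stats::setNames(integer(64), mitocub::all_codons())
  counts[names(x)] <- as.integer(x)
  mitocub:::new_codon_counts(counts, gene_id, genome_id, "mito", code_id)
}
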