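#' Declarative run configuration
#'
#' One object describing a full analysis run: the genomes (id, organelle,
#' CDS FASTA or GenBank path, tRNA count source), the genetic code per
#' organelle, family policy, clustering and wobble options, S-test
#' settings, and the output directory.  All randomness in the run flows
#' from the single `seed`.
#'
#' @param genomes data.frame with columns `id`, `organelle`
#'   (`mito`/`nuclear`), and at least one of `cds` (FASTA path) /
#'   `genbank` (GenBank path); optional `trna` (tRNA count TSV path;
#'   GenBank-derived counts are used when absent).
#' @param mito_code,nuclear_code Genetic code ids per organelle.
#' @param split_sixfold,exclude_nondegenerate Family policy flags, see
#'   [family_policy()].
#' @param distance,linkage Clustering options, see
#'   [hierarchical_cluster()].
#' @param wobble_mode Decodability rule mode, see [wobble_rules()].
#' @param n_perm,correlation S-test options.
#' @param seed Integer seed.
#' @param out_dir Output directory for [run_report()].
#' @return A `run_config` object.
#' @export
run_config <- function(genomes, mito_code = "mold_mito",
                       nuclear_code = "standard",
                       split_sixfold = TRUE, exclude_nondegenerate = TRUE,
                       distance = "euclidean", linkage = "average",
                       wobble_mode = "crick", n_perm = 100L,
                       correlation = "pearson", seed = 1L,
                       out_dir = "mitocub_results") {
  structure(list(genomes = genomes, mito_code = mito_code,
                 nuclear_code = nuclear_code,
                 split_sixfold = split_sixfold,
                 exclude_nondegenerate = exclude_nondegenerate,
                 distance = distance, linkage = linkage,
                 wobble_mode = wobble_mode, n_perm = as.integer(n_perm),
                 correlation = correlation, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns problems instead of raising them; an empty character vector
#' means the configuration is runnable.  Entries are prefixed `error:` or
#' `warning:` (warnings do not block [run_report()]).
#'
#' @param config A [run_config()].
#' @return Character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  g <- config$genomes
  if (!is.data.frame(g) || !nrow(g))
    return("error: genomes must be a non-empty data.frame")
  if (!all(c("id", "organelle") %in% names(g)))
    problems <- c(problems, "error: genomes needs columns 'id' and 'organelle'")
  else {
    if (anyDuplicated(g$id))
      problems <- c(problems, paste0("error: duplicate genome ids: ",
                                     paste(unique(g$id[duplicated(g$id)]),
                                           collapse = ", ")))
    if (!all(g$organelle %in% c("mito", "nuclear")))
      problems <- c(problems, "error: organelle must be 'mito' or 'nuclear'")
    if (any(g$organelle == "mito") && config$mito_code == "standard")
      problems <- c(problems,
                    "warning: mitochondrial genomes under the standard code")
    has_cds <- !is.na(.col_or_na(g, "cds"))
    has_gb <- !is.na(.col_or_na(g, "genbank"))
    if (!all(has_cds | has_gb))
      problems <- c(problems,
                    "error: every genome needs a 'cds' or 'genbank' path")
    paths <- c(.col_or_na(g, "cds"), .col_or_na(g, "genbank"),
               .col_or_na(g, "trna"))
    for (p in paths[!is.na(paths)]) {
      if (!file.exists(p))
        problems <- c(problems, paste0("error: missing input file: ", p))
    }
    no_trna <- !has_gb & is.na(.col_or_na(g, "trna"))
    if (any(no_trna))
      problems <- c(problems, paste0(
        "error: no tRNA source (trna TSV or GenBank) for the S-test in: ",
        paste(g$id[no_trna], collapse = ", ")))
  }
  if (config$n_perm < 1L)
    problems <- c(problems, "error: n_perm must be >= 1")
  if (!config$wobble_mode %in% c("strict", "crick", "extended"))
    problems <- c(problems, "error: unknown wobble mode")
  problems
}

#' Run the full codon-usage-bias report for a set of genomes
#'
#' Per genome: reads the CDS (FASTA or GenBank) and tRNA counts, counts
#' codons, computes gene-level RSCU / ENc / GC3 tables, the genome-level
#' RSCU profile, the neutral-fit R-squared, the wi and tAI tables, the
#' permutation S-test, and the wobble decodability report.  Across
#' genomes: the gene-level correspondence analysis and the genome-profile
#' dendrogram.  Every table is written under `config$out_dir` along with
#' a JSON manifest recording the seed and a hash of the configuration;
#' identical config + inputs yield identical output.
#'
#' @param config A [run_config()]; must validate without `error:` entries.
#' @return The report bundle (named list of results), invisibly; tables on
#'   disk under `config$out_dir`.
#' @export
run_report <- function(config) {
  problems <- validate_config(config)
  errors <- grep("^error:", problems, value = TRUE)
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  policy <- family_policy(config$split_sixfold, config$exclude_nondegenerate)
  rules <- wobble_rules(config$wobble_mode)
  bundle <- list(genomes = list())
  all_gene_rscu <- list()
  genome_profiles <- list()
  for (i in seq_len(nrow(config$genomes))) {
    row <- config$genomes[i, ]
    stage <- function(what) paste0(what, " [genome ", row$id, "]")
    code <- genetic_code(
      if (row$organelle == "mito") config$mito_code else config$nuclear_code)
    gb <- NULL
    gb_path <- .col_or_na(row, "genbank")
    genes <- if (!is.na(gb_path)) {
      gb <- read_genbank(gb_path, genome_id = row$id,
                         organelle = row$organelle)
      gb$genes
    } else {
      read_cds_fasta(row$cds, genome_id = row$id, organelle = row$organelle)
    }
    if (!length(genes)) stop("no genes in ", stage("read"))
    counts <- lapply(genes, function(rec)
      tryCatch(count_codons(rec$sequence, code, gene_id = rec$gene_id,
                            genome_id = row$id, organelle = row$organelle),
               error = function(e)
                 stop(stage("count_codons"), ": ", conditionMessage(e),
                      call. = FALSE)))
    trna_path <- .col_or_na(row, "trna")
    trna_tab <- if (!is.na(trna_path)) read_trna_counts(trna_path) else gb$trna
    trn <- trnaome(trna_tab, genome_id = row$id, organelle = row$organelle)
    m <- counts_matrix(counts)
    etab <- enc_table(m, code)
    gene_rscu <- lapply(counts, rscu, code = code, policy = policy)
    pooled <- rscu(pool_counts(counts), code = code, policy = policy)
    nf <- tryCatch(neutral_fit(etab), error = function(e) NULL)
    wi <- compute_wi(trn, code = code)
    tai_vals <- tai_vector(m, wi$values)
    stest <- permutation_s_test(m, etab$deviation, wi,
                                n_perm = config$n_perm, seed = config$seed,
                                method = config$correlation)
    stest$genome_id <- row$id
    deco <- decodability(trn, code, rules)
    # per-genome tables
    etab$tai <- tai_vals
    write_table(etab[setdiff(names(etab), "class_fs")],
                file.path(config$out_dir, paste0(row$id, "_genes.tsv")))
    write_table(data.frame(codon = names(wi$values), wi = wi$values),
                file.path(config$out_dir, paste0(row$id, "_wi.tsv")))
    write_table(data.frame(codon = names(deco$decodable),
                           decodable = deco$decodable),
                file.path(config$out_dir, paste0(row$id, "_decodability.tsv")))
    write_table(data.frame(perm = seq_along(stest$perm_values),
                           s = stest$perm_values),
                file.path(config$out_dir, paste0(row$id, "_stest_perm.tsv")))
    bundle$genomes[[row$id]] <- list(
      enc = etab, rscu = gene_rscu, pooled_rscu = pooled,
      neutral_fit = nf, wi = wi, tai = tai_vals, stest = stest,
      decodability = deco, summary = gb$summary)
    all_gene_rscu <- c(all_gene_rscu, gene_rscu)
    pooled$owner_id <- row$id
    genome_profiles[[row$id]] <- pooled
  }
  # cross-genome multivariate stage
  rm_gene <- build_rscu_matrix(all_gene_rscu)
  rownames(rm_gene) <- make.unique(rownames(rm_gene), sep = "@")
  bundle$ca <- correspondence_analysis(rm_gene)
  write_table(data.frame(gene = rownames(bundle$ca$row_coords),
                         bundle$ca$row_coords, check.names = FALSE),
              file.path(config$out_dir, "ca_row_coords.tsv"))
  write_table(data.frame(codon = rownames(bundle$ca$col_coords),
                         bundle$ca$col_coords, check.names = FALSE),
              file.path(config$out_dir, "ca_col_coords.tsv"))
  write_table(data.frame(dim = names(bundle$ca$eigenvalues),
                         eigenvalue = bundle$ca$eigenvalues,
                         pct_inertia = bundle$ca$pct_inertia),
              file.path(config$out_dir, "ca_eigenvalues.tsv"))
  if (length(genome_profiles) >= 2L) {
    bundle$dendrogram <- hierarchical_cluster(
      build_rscu_matrix(genome_profiles),
      distance = config$distance, linkage = config$linkage)
    writeLines(bundle$dendrogram$newick,
               file.path(config$out_dir, "genome_rscu_dendrogram.nwk"))
  }
  manifest <- list(package = "mitocub",
                   version = as.character(utils::packageVersion("mitocub")),
                   seed = config$seed,
                   n_perm = config$n_perm,
                   wobble_mode = config$wobble_mode,
                   distance = config$distance, linkage = config$linkage,
                   genomes = config$genomes$id,
                   config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}

# column as character vector, NA-filled when the column is absent
.col_or_na <- function(df, name) {
  if (name %in% names(df)) as.character(df[[name]])
  else rep(NA_character_, nrow(df))
}

#' Deterministic hash of a run configuration
#'
#' MD5 of the canonical JSON serialisation; embedded in every manifest so
#' reruns are verifiable.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
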