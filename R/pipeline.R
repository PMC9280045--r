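# Orchestration: run the full characterization over a set of input files
# and verify the shipped transcribed-table fixtures against the published
# classification counts.

.read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the characterization pipeline
#'
#' Executes the stages whose inputs are present in the configuration, in
#' dependency order: codon usage (CDS FASTA, optional reference frequency
#' TSVs), protein physicochemistry (protein FASTA), phylogeny (aligned
#' FASTA, optional anchors TSV with columns `anchor_id`, `clade`),
#' annotation (GFF3 + genome FASTA + motif TSV), and expression (matrix
#' TSV and/or Ct TSV). Each stage writes its result tables to
#' `output_dir`; a stage error is recorded and its dependents skipped.
#'
#' @param config A named list or path to a YAML file. Recognized entries:
#'   `cds`, `ref_freqs` (named list label -> TSV with columns `codon`,
#'   `freq`), `proteins`, `alignment`, `anchors`, `genome`, `gff`,
#'   `motifs`, `expression_matrix`, `ct_table`, `references`,
#'   `calibrator`, `output_dir`, `seed`, and threshold overrides
#'   `hf_percent`, `hf_mult`, `ratio_lo`, `ratio_hi`, `long_gene_bp`,
#'   `promoter_len`, `bootstrap_reps`.
#' @return A run report: list with `stages` (data frame of status per
#'   stage), `outputs`, `thresholds`, `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- list(hf_percent = config$hf_percent %||% 60,
                     hf_mult = config$hf_mult %||% 1.5,
                     ratio_lo = config$ratio_lo %||% 0.5,
                     ratio_hi = config$ratio_hi %||% 2.0,
                     long_gene_bp = config$long_gene_bp %||% 3000,
                     promoter_len = config$promoter_len %||% 2000,
                     bootstrap_reps = config$bootstrap_reps %||% 1000)
  seed <- config$seed %||% 1L
  stages <- data.frame(stage = character(), status = character(),
                       message = character(), stringsAsFactors = FALSE)
  outputs <- character()
  note <- function(stage, status, message = "") {
    stages[nrow(stages) + 1L, ] <<- list(stage, status, message)
  }
  run_stage <- function(stage, enabled, fun) {
    if (!enabled) { note(stage, "skipped", "inputs not configured"); return() }
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) conditionMessage(e))
    if (identical(res, "ok")) note(stage, "ok") else
      note(stage, "error", res)
  }

  run_stage("codon_usage", !is.null(config$cds), function() {
    cds <- read_fasta(config$cds, "dna")
    counts <- count_codons(cds, label = "cds_set")
    usage <- compute_usage(counts, hf_percent = thresholds$hf_percent,
                           hf_mult = thresholds$hf_mult)
    outputs <<- c(outputs, .write_tsv(usage, file.path(out_dir, "usage.tsv")))
    if (!is.null(config$ref_freqs)) {
      freq <- codon_frequency(counts)
      for (lbl in names(config$ref_freqs)) {
        rf <- .read_tsv(config$ref_freqs[[lbl]])
        ref <- stats::setNames(rf$freq, rf$codon)
        rt <- ratio_compare(freq, ref, lbl, thresholds$ratio_lo,
                            thresholds$ratio_hi)
        outputs <<- c(outputs, .write_tsv(
          rt, file.path(out_dir, paste0("ratios_", lbl, ".tsv"))))
      }
    }
  })

  run_stage("protparam", !is.null(config$proteins), function() {
    prot <- read_fasta(config$proteins, "protein")
    outputs <<- c(outputs, .write_tsv(phys_chem_profiles(prot),
                                      file.path(out_dir, "protparam.tsv")))
  })

  run_stage("phylogeny", !is.null(config$alignment), function() {
    aln <- read_fasta(config$alignment, "protein-aligned")
    tree <- bootstrap_support(aln, n_reps = thresholds$bootstrap_reps,
                              seed = seed)
    path <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, path)
    outputs <<- c(outputs, path)
    if (!is.null(config$anchors)) {
      anc <- .read_tsv(config$anchors)
      D <- pairwise_distance(aln)
      cl <- assign_clades(D, stats::setNames(anc$clade, anc$anchor_id))
      outputs <<- c(outputs, .write_tsv(cl, file.path(out_dir, "clades.tsv")))
    }
  })

  run_stage("annotation", !is.null(config$gff), function() {
    models <- read_gff3(config$gff)
    outputs <<- c(outputs,
                  .write_tsv(structure_stats_table(models,
                                                   thresholds$long_gene_bp),
                             file.path(out_dir, "structure.tsv")))
    if (!is.null(config$genome) && !is.null(config$motifs)) {
      genome <- read_fasta(config$genome, "dna")
      motifs <- .read_tsv(config$motifs)
      proms <- lapply(models, function(m)
        extract_promoter(genome, m, thresholds$promoter_len))
      hits <- scan_promoters(proms, motifs)
      outputs <<- c(outputs, .write_tsv(hits, file.path(out_dir, "hits.tsv")))
      summ <- summarize_elements(hits, motifs,
                                 gene_ids = names(models))
      bycat <- cbind(gene_id = rownames(summ$by_category), summ$by_category)
      outputs <<- c(outputs, .write_tsv(bycat,
                                        file.path(out_dir,
                                                  "element_summary.tsv")))
    }
  })

  run_stage("expression", !is.null(config$expression_matrix) ||
              !is.null(config$ct_table), function() {
    if (!is.null(config$expression_matrix)) {
      m <- as.matrix(.read_tsv(config$expression_matrix)[, -1, drop = FALSE])
      rownames(m) <- .read_tsv(config$expression_matrix)[[1]]
      z <- transform_matrix(m, "row_z")
      outputs <<- c(outputs, .write_tsv(cbind(gene_id = rownames(z),
                                              as.data.frame(z)),
                                        file.path(out_dir, "heat.tsv")))
    }
    if (!is.null(config$ct_table)) {
      ct <- .read_tsv(config$ct_table)
      folds <- relative_expression(ct, config$references, config$calibrator)
      outputs <<- c(outputs, .write_tsv(folds,
                                        file.path(out_dir, "folds.tsv")))
    }
  })

  report <- list(stages = stages, outputs = outputs,
                 thresholds = thresholds, seed = seed)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the transcribed published codon-usage tables
#'
#' Reads the shipped fixture TSVs: the per-species RSCU/RFSC table (with an
#' `anomalous` flag on cells whose printed RSCU and RFSC columns are
#' internally inconsistent) and the codon-frequency ratio table against the
#' four reference genomes.
#'
#' @param fixture_dir Directory with `table1_rscu_rfsc.tsv` and
#'   `table2_ratios.tsv`; defaults to the copies installed with the
#'   package.
#' @return A list `usage` (long data frame), `ratios` (long data frame).
#' @export
load_fixture_tables <- function(fixture_dir = system.file("extdata",
                                                          package = "woxkit")) {
  p1 <- file.path(fixture_dir, "table1_rscu_rfsc.tsv")
  p2 <- file.path(fixture_dir, "table2_ratios.tsv")
  if (!file.exists(p1) || !file.exists(p2))
    stop("fixture tables not found under ", fixture_dir)
  usage <- .read_tsv(p1)
  ratios <- .read_tsv(p2)
  if (!identical(sort(unique(usage$codon)),
                 sort(synonymous_families()$codon)) ||
      nrow(usage) != 256L || nrow(ratios) != 1024L)
    stop("fixture tables are corrupted (unexpected shape)")
  list(usage = usage, ratios = ratios)
}

#' Verify the transcribed tables against the published counts
#'
#' Recomputes, from the shipped fixtures and this package's classification
#' rules, the cross-species bias partition, the consensus high-frequency
#' codon set, the divergent-codon counts of the four highlighted
#' species/host comparisons, and the clade percentage summary, and compares
#' them with the counts the source tables report.
#'
#' @param fixture_dir Fixture directory (see [load_fixture_tables()]).
#' @return A data frame `check`, `expected`, `observed`, `pass`.
#' @export
verify_fixtures <- function(fixture_dir = system.file("extdata",
                                                      package = "woxkit")) {
  fx <- load_fixture_tables(fixture_dir)
  species <- c("HbWOX", "JcWOX", "MeWOX", "RcWOX")
  tables <- lapply(species, function(sp) {
    sub <- fx$usage[fx$usage$species == sp, ]
    usage_table_from_values(sub$codon, sub$rscu, sub$rfsc, label = sp)
  })
  names(tables) <- species
  checks <- list()
  add <- function(check, expected, observed) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, expected = expected, observed = observed,
      pass = identical(expected, observed), stringsAsFactors = FALSE)
  }
  bp <- bias_partition(tables)
  add("bias_partition", "19/23/2/20", paste(bp, collapse = "/"))
  cons <- consensus_high_frequency(tables)
  add("high_frequency_consensus", "GCA,GAU,CCA,AGA",
      paste(cons[order(match(cons, c("GCA", "GAU", "CCA", "AGA")))],
            collapse = ","))
  pairs <- list(c("JcWOX", "At", 6L), c("HbWOX", "Pt", 6L),
                c("MeWOX", "Nt", 5L), c("RcWOX", "Pt", 5L))
  for (p in pairs) {
    sub <- fx$ratios[fx$ratios$set == p[1] & fx$ratios$ref == p[2], ]
    ndiv <- sum(classify_ratio(sub$ratio) == "divergent")
    add(paste0("divergent_", p[1], "_vs_", p[2]), p[3], as.character(ndiv))
  }
  pct <- clade_proportions(c(modern = 38L, intermediate = 12L, ancient = 9L))
  add("clade_proportions", "64.4/20.3/15.3",
      paste(sprintf("%.1f", pct[c("modern", "intermediate", "ancient")]),
            collapse = "/"))
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
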