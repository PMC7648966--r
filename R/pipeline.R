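# End-to-end orchestration: callcirc -> annotate -> rtclass -> quantify ->
# de -> sponge, from one config, with a run manifest and deterministic
# outputs. Also the one-command fixture demo with truth-based evaluation.

#' Read a pipeline config (YAML)
#'
#' @param path YAML file; see [pipeline_config()] for the fields.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Assemble and validate a pipeline configuration
#'
#' @param genome,gtf,sample_sheet required input paths.
#' @param reads named list/vector of per-sample FASTQ paths (names =
#'   sample ids).
#' @param out_dir output directory.
#' @param mirna_panel,mirna_targets,gene_counts optional input paths
#'   (sponge screen and gene track are skipped when absent).
#' @param k,mm,min_reads,min_samples,flank,min_identity,min_length,fc,alpha,min_sites,top_sites,n_random
#'   stage parameters (documented defaults follow the published rules).
#' @param seed seed for the stochastic steps (random host-correlation
#'   draws).
#' @return validated config list.
#' @export
pipeline_config <- function(genome, gtf, sample_sheet, reads, out_dir,
                            mirna_panel = NULL, mirna_targets = NULL,
                            gene_counts = NULL, k = 20L, mm = 0L,
                            min_reads = 2L, min_samples = 4L, flank = 50L,
                            min_identity = 0.8, min_length = 25L, fc = 2,
                            alpha = 0.05, min_sites = 5L, top_sites = 10L,
                            n_random = 50L, seed = 1L) {
  cfg <- list(genome = genome, gtf = gtf, sample_sheet = sample_sheet,
              reads = as.list(reads), out_dir = out_dir,
              mirna_panel = mirna_panel, mirna_targets = mirna_targets,
              gene_counts = gene_counts, k = as.integer(k),
              mm = as.integer(mm), min_reads = as.integer(min_reads),
              min_samples = as.integer(min_samples),
              flank = as.integer(flank), min_identity = min_identity,
              min_length = as.integer(min_length), fc = fc, alpha = alpha,
              min_sites = as.integer(min_sites),
              top_sites = as.integer(top_sites),
              n_random = as.integer(n_random), seed = as.integer(seed))
  for (f in c("genome", "gtf", "sample_sheet")) {
    if (is.null(cfg[[f]])) stopf("config field '%s' is required", f)
    if (!file.exists(cfg[[f]])) stopf("config field '%s': no such file: %s",
                                      f, cfg[[f]])
  }
  if (!length(cfg$reads)) stopf("config field 'reads' is required")
  if (is.null(names(cfg$reads)) || any(names(cfg$reads) == ""))
    stopf("config field 'reads' must be named by sample id")
  for (p in unlist(cfg$reads))
    if (!file.exists(p)) stopf("config field 'reads': no such file: %s", p)
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return invisibly, a list of all stage results plus `manifest`; stage
#'   tables are also written as TSV under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message(sprintf("[circheart] %s", sprintf(...)))

  msg("loading genome and annotation")
  genome <- genome_bundle(read_fasta(cfg$genome), read_gtf(cfg$gtf))
  groups <- read_sample_sheet(cfg$sample_sheet)
  if (length(unique(groups)) != 2L) stopf("exactly two groups required")

  msg("stage callcirc: %d sample(s), k=%d mm=%d", length(cfg$reads), cfg$k,
      cfg$mm)
  cc <- call_circrnas(genome, cfg$reads, k = cfg$k, mm = cfg$mm,
                      min_reads = cfg$min_reads)
  junctions <- cc$junctions
  write_junction_bed(junctions, file.path(cfg$out_dir, "junctions.bed"))
  write_tsv(cbind(junctions$table, junctions$support),
            file.path(cfg$out_dir, "junction_support.tsv"))

  msg("stage annotate: %d junction(s)", nrow(junctions$table))
  records <- annotate_junctions(junctions, genome)
  write_tsv(records[, setdiff(names(records), "spliced_seq")],
            file.path(cfg$out_dir, "circ_records.tsv"))
  write_fasta(setNames(records$spliced_seq, records$name),
              file.path(cfg$out_dir, "circ_sequences.fa"))

  msg("stage rtclass: %d two-gene record(s)",
      sum(records$origin == "two-gene"))
  rt <- screen_rt(records, genome, w = cfg$flank,
                  min_identity = cfg$min_identity,
                  min_length = cfg$min_length)
  write_tsv(rt, file.path(cfg$out_dir, "rt_calls.tsv"))

  msg("stage quantify")
  samples <- names(cfg$reads)
  sup <- junctions$support
  dimnames(sup) <- list(records$name, colnames(sup))
  cm <- count_matrix(sup, setNames(cc$mapped_totals[samples], samples),
                     groups)
  expr <- srpbm_table(cm)
  write_tsv(data.frame(name = rownames(expr), expr, check.names = FALSE),
            file.path(cfg$out_dir, "circ_srpbm.tsv"))
  tier <- tier_filter(cm, min_reads = cfg$min_reads,
                      min_samples = cfg$min_samples)
  presence <- presence_profile(cm, min_reads = cfg$min_reads)
  write_tsv(presence$histogram, file.path(cfg$out_dir,
                                          "presence_histogram.tsv"))
  write_tsv(data.frame(name = names(tier$keep),
                       high_confidence = unname(tier$keep)),
            file.path(cfg$out_dir, "tier_flags.tsv"))

  gene_cm <- NULL; gene_de <- NULL; corr <- NULL
  if (!is.null(cfg$gene_counts)) {
    gene_cm <- read_count_matrix(cfg$gene_counts)
    gene_expr <- fpkm_table(gene_cm, vapply(genome$genes, gene_exon_length,
                                            numeric(1)))
    hc <- records$name[tier$keep & !is.na(records$host1) &
                         records$origin != "two-gene"]
    pairs <- data.frame(circ = hc,
                        host = records$host1[match(hc, records$name)],
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$host %in% rownames(gene_expr), , drop = FALSE]
    if (nrow(pairs) >= 3L) {
      corr <- host_correlation(expr[, colnames(gene_expr), drop = FALSE],
                               gene_expr, pairs, n_random = cfg$n_random,
                               seed = cfg$seed)
      write_tsv(corr$host, file.path(cfg$out_dir, "host_correlation.tsv"))
    }
    msg("stage de (genes): %d feature(s)", nrow(gene_cm$counts))
    gene_de <- de_genes(gene_cm, fc_threshold = cfg$fc, alpha = cfg$alpha)
    write_tsv(gene_de[order(gene_de$pvalue), ],
              file.path(cfg$out_dir, "gene_de.tsv"))
  }

  msg("stage de (circRNAs): %d high-confidence feature(s)",
      nrow(tier$matrix$counts))
  circ_de <- de_circ(tier$matrix, fc_threshold = cfg$fc, alpha = cfg$alpha)
  write_tsv(circ_de[order(circ_de$pvalue), ],
            file.path(cfg$out_dir, "circ_de.tsv"))

  sponge <- NULL; network <- NULL; sites <- NULL
  if (!is.null(cfg$mirna_panel)) {
    panel <- read_mirna_panel(cfg$mirna_panel)
    hc_names <- names(tier$keep)[tier$keep]
    seqs <- setNames(records$spliced_seq, records$name)[hc_names]
    msg("stage sponge: %d circRNA(s) x %d miRNA(s)", length(seqs),
        nrow(panel))
    sites <- sponge_site_table(seqs, panel)
    write_tsv(sites, file.path(cfg$out_dir, "sponge_sites.tsv"))
    sponge <- sponge_candidates(sites, min_sites = cfg$min_sites,
                                top_sites = cfg$top_sites)
    write_tsv(sponge$candidates, file.path(cfg$out_dir,
                                           "sponge_candidates.tsv"))
    if (!is.null(cfg$mirna_targets)) {
      targets <- read.delim(cfg$mirna_targets, stringsAsFactors = FALSE)
      network <- build_network(sponge$candidates, targets,
                               gene_de = gene_de, panel = panel,
                               circ_de = circ_de)
      write_tsv(network$edges, file.path(cfg$out_dir, "network_edges.tsv"))
    }
  }

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("reads"))],
    samples = samples, seed = cfg$seed,
    stage_counts = list(
      junctions = nrow(junctions$table),
      records = nrow(records),
      two_gene = sum(records$origin == "two-gene"),
      true_rt = sum(rt$call == "true_rt"),
      homology_artifact = sum(rt$call == "homology_artifact"),
      high_confidence = sum(tier$keep),
      de_circ_up = sum(circ_de$direction == "up"),
      de_circ_down = sum(circ_de$direction == "down"),
      sponge_candidates = if (is.null(sponge)) NA_integer_
                          else length(sponge$candidate_ids),
      network_edges = if (is.null(network)) NA_integer_
                      else nrow(network$edges)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, junctions = junctions,
                 mapped_totals = cc$mapped_totals, log = cc$log,
                 records = records, rt = rt, counts = cm, srpbm = expr,
                 tier = tier, presence = presence, corr = corr,
                 circ_de = circ_de, gene_cm = gene_cm, gene_de = gene_de,
                 sites = sites, sponge = sponge, network = network,
                 manifest = manifest))
}

## ------------------------------------------------------------ evaluation ----

#' Compare called junctions with the planted truth
#'
#' @param junctions called [bsj_set()].
#' @param truth_circ truth table of planted circles (`chrom`, `start`,
#'   `end`, `strand` columns).
#' @return list with `recall`, `precision`, `n_truth`, `n_called`,
#'   `missed` and `spurious` key vectors.
#' @export
evaluate_junctions <- function(junctions, truth_circ) {
  tk <- junction_key(truth_circ)
  ck <- junction_key(junctions$table)
  list(recall = if (length(tk)) mean(tk %in% ck) else NA_real_,
       precision = if (length(ck)) mean(ck %in% tk) else NA_real_,
       n_truth = length(tk), n_called = length(ck),
       missed = setdiff(tk, ck), spurious = setdiff(ck, tk))
}

#' Compare read-through calls with the planted truth
#'
#' @param rt [screen_rt()] table.
#' @param truth_circ truth table with `rt_status`.
#' @return list with `accuracy`, `n`, `n_correct`, and the merged table.
#' @export
evaluate_rt <- function(rt, truth_circ) {
  truth_circ$key <- junction_key(truth_circ)
  rt$key <- junction_key(rt)
  merged <- merge(rt[, c("key", "call")],
                  truth_circ[truth_circ$rt_status != "n/a",
                             c("key", "rt_status")], by = "key")
  list(accuracy = if (nrow(merged)) mean(merged$call == merged$rt_status)
                  else NA_real_,
       n = nrow(merged), n_correct = sum(merged$call == merged$rt_status),
       table = merged)
}

#' Compare pipeline seed-site counts with the planted truth
#'
#' @param sites [sponge_site_table()] output (circ ids are record names).
#' @param truth_sites truth site table (`truth_id`, `mirna_id`, counts).
#' @param records annotated records (to map names to junction keys).
#' @param truth_circ truth circle table (to map truth ids to keys).
#' @return list with `agreement` (fraction of truth pairs whose counted
#'   total matches exactly) and the merged table.
#' @export
evaluate_sites <- function(sites, truth_sites, records, truth_circ) {
  truth_circ$key <- junction_key(truth_circ)
  records$key <- junction_key(records)
  truth_sites$key <- truth_circ$key[match(truth_sites$truth_id,
                                          truth_circ$truth_id)]
  truth_sites$name <- records$name[match(truth_sites$key, records$key)]
  merged <- merge(truth_sites,
                  sites[, c("circ_id", "mirna_id", "n_sites")],
                  by.x = c("name", "mirna_id"),
                  by.y = c("circ_id", "mirna_id"))
  merged$truth_total <- merged$n_8mer + merged$n_7mer_m8 + merged$n_7mer_a1
  list(agreement = if (nrow(merged))
         mean(merged$n_sites == merged$truth_total) else NA_real_,
       n = nrow(merged), table = merged)
}

#' One-command fixture demo
#'
#' Generates the default synthetic fixture under `dir`, runs the full
#' pipeline on it, and evaluates junction recall/precision, read-through
#' classification accuracy, seed-site agreement and planted fold-change
#' recovery against the truth tables.
#'
#' @param seed fixture seed.
#' @param dir working directory (default: a fresh temporary directory).
#' @param quiet suppress progress messages?
#' @return list with `fixture`, `pipeline` and `summary` (named numeric
#'   vector of the evaluation metrics).
#' @export
demo_run <- function(seed = 1L, dir = tempfile("circheart_demo_"),
                     quiet = FALSE) {
  run <- function(expr) if (quiet) suppressMessages(expr) else expr
  fx <- simulate_fixture(sim_config(seed = seed), file.path(dir, "fixture"))
  cfg <- pipeline_config(
    genome = fx$paths$genome, gtf = fx$paths$gtf,
    sample_sheet = fx$paths$samples,
    reads = as.list(fx$paths$reads), out_dir = file.path(dir, "out"),
    mirna_panel = fx$paths$mirna, mirna_targets = fx$paths$targets,
    gene_counts = fx$paths$gene_counts, seed = seed)
  res <- run(run_pipeline(cfg))

  ev_j <- evaluate_junctions(res$junctions, fx$truth$circ)
  ev_rt <- evaluate_rt(res$rt, fx$truth$circ)
  ev_s <- evaluate_sites(res$sites, fx$sites, res$records, fx$truth$circ)
  # planted fold-change recovery on the read-level fixture (descriptive)
  truth <- fx$truth$circ
  truth$key <- junction_key(truth)
  rec_key <- setNames(res$records$name, junction_key(res$records))
  de <- res$circ_de
  planted <- truth[truth$fc != 1, ]
  want <- ifelse(planted$fc > 1, "up", "down")
  got <- de$direction[match(rec_key[planted$key], de$feature_id)]
  de_recovery <- mean(got == want, na.rm = TRUE)

  summary <- c(junction_recall = ev_j$recall,
               junction_precision = ev_j$precision,
               rt_accuracy = ev_rt$accuracy,
               site_agreement = ev_s$agreement,
               de_direction_recovery = de_recovery,
               host_correlation_wilcox_p =
                 if (is.null(res$corr)) NA_real_ else res$corr$wilcox_p)
  if (!quiet) {
    message("[circheart] demo summary:")
    for (nm in names(summary))
      message(sprintf("  %-28s %s", nm, format(summary[[nm]], digits = 4)))
  }
  invisible(list(fixture = fx, pipeline = res, summary = summary))
}
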