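#' Run the full mapping pipeline
#'
#' Orchestrates simulate -> qc -> scan -> prioritize -> conserve ->
#' verify as one configured run. Stages hand data to each other through
#' plain files (TSV/VCF/FASTA) in `out_dir`, so every stage is
#' independently inspectable and re-runnable; a consolidated report is
#' written as JSON and TSV.
#'
#' @param config `NULL`, a list, or the path of a YAML file. Recognised
#'   blocks: `sim` (passed to [sim_config()]), `qc` (`threshold`,
#'   `max_conflict_rate`), `scan` (`window_size`, `step`,
#'   `missing_policy`), `prioritize` (`control_mode`,
#'   `missing_controls`), `conserve` (`threshold`), `stages` (named
#'   logical toggles) and `regions_file` (external regions TSV used when
#'   the scan stage is toggled off).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; overrides `config$sim$seed`.
#' @return Object of class `run_report` (invisibly): per-stage
#'   parameters, outputs, counts and elapsed seconds.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("autozyg_run"),
                         seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stages <- c(list(simulate = TRUE, qc = TRUE, scan = TRUE,
                   prioritize = TRUE, conserve = TRUE, verify = TRUE),
              config$stages)
  stages <- stages[!duplicated(names(stages))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  report <- list(seed = seed, out_dir = out_dir, stages = list())
  note <- function(stage, params, outputs, counts, elapsed) {
    report$stages[[stage]] <<- list(params = params, outputs = outputs,
                                    counts = counts,
                                    elapsed_s = round(elapsed, 3))
  }

  if (isTRUE(stages$simulate)) {
    t0 <- proc.time()[3]
    scfg <- do.call(sim_config, c(list(seed = seed), config$sim))
    bundle <- simulate_dataset(scfg)
    write_pedigree_tsv(bundle$ped, p("pedigree.tsv"))
    write_genotypes_tsv(bundle$genotypes, p("genotypes.tsv"))
    write_ped_map(bundle$genotypes, bundle$ped, p("genotypes"))
    write_vcf(bundle$variants$case, p("case.vcf"))
    write_vcf(bundle$variants$controls, p("controls.vcf"))
    write_vcf(variant_table(bundle$variants$panel), p("panel.vcf"))
    write_genome_fasta(bundle$genome, p("genome.fa"))
    write_gene_models_tsv(bundle$gene_models, p("genes.tsv"))
    write_alignment_fasta(bundle$alignment, p("alignment.fa"))
    # targeted-genotyping emulation: per-individual genotypes at the two
    # seeded variant positions, from the truth labels
    tg <- data.frame(
      sample_id = bundle$ped$id,
      gt_v1 = causal_copy_counts(bundle$truth, bundle$truth$causal_cols[1],
                                 bundle$truth$carrier_hap_row),
      gt_v2 = causal_copy_counts(bundle$truth, bundle$truth$causal_cols[2],
                                 bundle$truth$carrier_hap_row),
      phenotype = ifelse(bundle$ped$role == "case", "affected",
                         "unaffected"))
    utils::write.table(tg, p("targeted_genotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg_out <- scfg
    class(cfg_out) <- NULL
    cfg_out$allele_freq <- NULL
    yaml::write_yaml(cfg_out, p("config.yaml"))
    note("simulate", list(seed = seed),
         c("pedigree.tsv", "genotypes.tsv", "case.vcf", "controls.vcf",
           "panel.vcf", "genome.fa", "genes.tsv", "alignment.fa",
           "targeted_genotypes.tsv", "config.yaml"),
         list(individuals = nrow(bundle$ped),
              markers = ncol(bundle$genotypes$calls),
              case_variants = nrow(bundle$variants$case$variants)),
         proc.time()[3] - t0)
  }

  ped <- read_pedigree_tsv(p("pedigree.tsv"))
  if (isTRUE(stages$qc)) {
    t0 <- proc.time()[3]
    gm <- read_genotypes_tsv(p("genotypes.tsv"))
    qc_par <- c(list(gm = gm, ped = ped), config$qc)
    qc <- do.call(run_genotype_qc, qc_par)
    write_genotypes_tsv(qc$genotypes, p("genotypes_qc.tsv"))
    utils::write.table(qc$summary, p("qc_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("qc", config$qc, c("genotypes_qc.tsv", "qc_summary.tsv"),
         list(input = qc$n_input, retained = qc$n_retained),
         proc.time()[3] - t0)
  }

  if (isTRUE(stages$scan)) {
    t0 <- proc.time()[3]
    gm <- read_genotypes_tsv(p("genotypes_qc.tsv"))
    scan_par <- c(list(gm = gm, roles = pedigree_roles(ped)), config$scan)
    regions <- do.call(scan_autozygosity, scan_par)
    write_regions_tsv(regions, p("regions.tsv"))
    write_regions_bed(regions, p("regions.bed"))
    note("scan", config$scan, c("regions.tsv", "regions.bed"),
         list(regions = nrow(regions),
              largest_mb = if (nrow(regions)) max(regions$length_mb) else 0),
         proc.time()[3] - t0)
  } else if (!is.null(config$regions_file)) {
    file.copy(config$regions_file, p("regions.tsv"), overwrite = TRUE)
  }

  if (isTRUE(stages$prioritize)) {
    t0 <- proc.time()[3]
    case <- read_vcf(p("case.vcf"))
    controls <- read_vcf(p("controls.vcf"))
    panel <- read_panel_vcf(p("panel.vcf"))
    regions <- read_regions_tsv(p("regions.tsv"))
    models <- read_gene_models_tsv(p("genes.tsv"))
    genome <- read_genome_fasta(p("genome.fa"))
    pr_par <- c(list(case = case, controls = controls, panel = panel,
                     regions = regions, gene_models = models,
                     genome = genome), config$prioritize)
    pri <- do.call(prioritize_variants, pr_par)
    utils::write.table(pri$candidates, p("candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pri$trace, p("filter_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("prioritize", config$prioritize,
         c("candidates.tsv", "filter_trace.tsv"),
         stats::setNames(as.list(pri$counts$n), pri$counts$stage),
         proc.time()[3] - t0)
  }

  if (isTRUE(stages$conserve)) {
    t0 <- proc.time()[3]
    aln <- read_alignment_fasta(p("alignment.fa"))
    cand <- utils::read.table(p("candidates.tsv"), sep = "\t",
                              header = TRUE,
                              colClasses = c(chr = "character"))
    pos <- as.integer(gsub("[^0-9]", "", cand$protein_change))
    pos <- pos[!is.na(pos)]
    thr <- if (!is.null(config$conserve$threshold))
      config$conserve$threshold else 0.9
    cons <- if (length(pos))
      conservation_profile(aln, names(aln)[1], pos, threshold = thr)
    else NULL
    if (!is.null(cons))
      utils::write.table(cons, p("conservation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    note("conserve", list(threshold = thr), "conservation.tsv",
         list(positions = length(pos),
              conserved = if (is.null(cons)) 0 else sum(cons$conserved)),
         proc.time()[3] - t0)
  }

  if (isTRUE(stages$verify)) {
    t0 <- proc.time()[3]
    tg <- utils::read.table(p("targeted_genotypes.tsv"), sep = "\t",
                            header = TRUE,
                            colClasses = c(sample_id = "character"))
    g1 <- stats::setNames(tg$gt_v1, tg$sample_id)
    g2 <- stats::setNames(tg$gt_v2, tg$sample_id)
    phe <- stats::setNames(tg$phenotype, tg$sample_id)
    conc1 <- genotype_concordance(g1, phe)
    conc2 <- genotype_concordance(g2, phe)
    r2 <- ld_r2(g1, g2)
    cand <- utils::read.table(p("candidates.tsv"), sep = "\t",
                              header = TRUE,
                              colClasses = c(chr = "character"))
    sep_bp <- if (nrow(cand) >= 2L) diff(range(cand$pos)) else NA
    cm <- if (!is.na(sep_bp)) bp_to_cM(sep_bp) else NA
    gam <- if (!is.na(cm) && cm > 0) gametes_per_recombination(cm) else NA
    # in-silico RFLP at the first candidate: the alternative allele
    # destroys or creates an MspI pattern difference
    genome <- read_genome_fasta(p("genome.fa"))
    digest <- list()
    if (nrow(cand)) {
      amp_start <- cand$pos[1] - 60L
      amp_end <- cand$pos[1] + 60L
      amp_ref <- genome_fetch(genome, cand$chr[1], amp_start, amp_end)
      amp_alt <- amp_ref
      substr(amp_alt, cand$pos[1] - amp_start + 1L,
             cand$pos[1] - amp_start + 1L) <- cand$alt[1]
      digest <- list(
        ref = insilico_digest(amp_ref, "C^CGG", "ref"),
        alt = insilico_digest(amp_alt, "C^CGG", "alt"))
    }
    ver <- data.frame(
      metric = c("concordant_v1", "concordant_v2", "ld_r2",
                 "separation_bp", "separation_cM",
                 "gametes_per_recombination"),
      value = c(conc1$concordant, conc2$concordant, r2, sep_bp, cm, gam))
    utils::write.table(ver, p("verify.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("verify", list(),
         "verify.tsv",
         list(concordant = conc1$concordant && conc2$concordant,
              ld_r2 = r2, separation_bp = sep_bp,
              gametes_per_recombination = gam,
              ref_fragments = length(digest$ref$fragment_lengths),
              alt_fragments = length(digest$alt$fragment_lengths)),
         proc.time()[3] - t0)
  }

  class(report) <- "run_report"
  jsonlite::write_json(report_payload(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rep_tsv <- do.call(rbind, lapply(names(report$stages), function(s) {
    data.frame(stage = s,
               counts = paste(names(report$stages[[s]]$counts),
                              unlist(report$stages[[s]]$counts),
                              sep = "=", collapse = "; "))
  }))
  utils::write.table(rep_tsv, p("report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}

# report content with timings stripped (the determinism contract covers
# everything else)
report_payload <- function(report) {
  report$stages <- lapply(report$stages, function(s) {
    s$elapsed_s <- NULL
    s
  })
  unclass(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ") ->", x$out_dir, "\n")
  for (s in names(x$stages)) {
    cnt <- x$stages[[s]]$counts
    cat(sprintf("  %-10s %s\n", s,
                paste(names(cnt), unlist(cnt), sep = "=", collapse = ", ")))
  }
  invisible(x)
}
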