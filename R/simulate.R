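#' Genotype matrix container
#'
#' Samples x biallelic markers, coded as copies of the alternative allele
#' (0/1/2, `NA` = missing), tied to a marker map.
#'
#' @param calls integer matrix (samples x markers) with dimnames.
#' @param map data frame with at least `marker_id`, `chr`, `bp`,
#'   `ref`, `alt`; `chr`/`bp` may be `NA` (unknown position) — QC removes
#'   those. Row order must match the columns of `calls`.
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have sample rownames and marker colnames")
  if (!identical(colnames(calls), as.character(map$marker_id)))
    stop("map rows must match calls columns")
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype codes must be in {0, 1, 2, NA}")
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "markers; call rate",
      sprintf("%.3f", mean(!is.na(x$calls))), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Emit an array-style genotype matrix from gene-dropped truth
#'
#' Genotypes are the haplotype sums at marker loci, perturbed by an
#' independent symmetric single-step miscall per call (hets miscalled to
#' either homozygote with equal probability, homozygotes to the het) and by
#' independent per-call missingness. A designated marker subset receives an
#' elevated error rate, emulating assays prone to paternity conflicts.
#'
#' @param truth a `sim_truth` from [gene_drop()]/[seed_causal_allele()].
#' @param config a [sim_config()].
#' @param seed integer seed (default derived from `config$seed`).
#' @return A [geno_matrix()]; the elevated-error marker indices are in
#'   `attr(, "error_markers")`.
#' @export
emit_array_genotypes <- function(truth, config, seed = config$seed + 1L) {
  set.seed(seed)
  mk <- which(truth$loci$type == "marker")
  n <- nrow(truth$ped)
  G <- truth$H[2L * seq_len(n) - 1L, mk, drop = FALSE] +
    truth$H[2L * seq_len(n), mk, drop = FALSE]
  rownames(G) <- truth$ped$id
  colnames(G) <- truth$loci$id[mk]
  m <- length(mk)

  conflict_idx <- integer(0)
  if (config$conflict_markers > 0L && config$conflict_error_rate > 0)
    conflict_idx <- sort(sample.int(m, min(config$conflict_markers, m)))

  if (config$genotype_error_rate > 0) {
    err <- matrix(stats::runif(n * m), n, m) < config$genotype_error_rate
    if (any(err)) {
      g <- G[err]
      flip <- stats::runif(length(g)) < 0.5
      G[err] <- ifelse(g == 1L, ifelse(flip, 0L, 2L), 1L)
    }
  }
  # conflict-prone assays: calls replaced by a random genotype, which is
  # what produces opposing-homozygote paternity conflicts at QC
  if (length(conflict_idx)) {
    blk <- G[, conflict_idx, drop = FALSE]
    hit <- matrix(stats::runif(length(blk)), nrow(blk)) <
      config$conflict_error_rate
    blk[hit] <- sample(0:2, sum(hit), replace = TRUE)
    G[, conflict_idx] <- blk
  }
  if (config$missing_rate > 0) {
    G[matrix(stats::runif(n * m), n, m) < config$missing_rate] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  map <- data.frame(marker_id = truth$loci$id[mk], chr = truth$loci$chr[mk],
                    bp = truth$loci$bp[mk], cM = truth$loci$cM[mk],
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  gm <- geno_matrix(G, map)
  attr(gm, "error_markers") <- conflict_idx
  gm
}

#' Variant table (minimal VCF-like container)
#'
#' @param variants data frame with `chr`, `pos`, `ref`, `alt` (SNVs:
#'   single bases).
#' @param gt integer matrix (variants x samples) of alternative-allele
#'   copies, `NA` = missing; `NULL` for a site-only table.
#' @return Object of class `variant_table`.
#' @export
variant_table <- function(variants, gt = NULL) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("chr", "pos", "ref", "alt") %in% names(variants)))
  if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
  if (any(variants$pos < 1)) stop("pos must be >= 1")
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    if (nrow(gt) != nrow(variants)) stop("gt rows must match variants")
    if (is.null(colnames(gt))) stop("gt must have sample colnames")
  }
  structure(list(variants = variants, gt = gt), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x$variants), "variants")
  if (!is.null(x$gt)) cat(" x", ncol(x$gt), "samples")
  cat("\n")
  invisible(x)
}

variant_key <- function(df) paste(df$chr, df$pos, df$ref, df$alt, sep = ":")

# n distinct sorted integer positions in [lo, hi] without materializing
# the full range
sample_positions <- function(n, lo, hi) {
  pos <- integer(0)
  while (length(pos) < n) {
    pos <- unique(c(pos, as.integer(floor(
      stats::runif(2L * n, lo, hi + 1)))))
  }
  sort(utils::head(pos, n))
}

#' Emit WGS-like variant tables for a sequenced case, controls and a panel
#'
#' The case table holds shared background variants plus exactly two linked
#' private missense variants (separated by the configured offset) inside
#' the autozygous segment, homozygous-alternative in the case, together
#' with a few private variants outside the mapped chromosome (exercising
#' the region filter). The two seeded variants are absent from the control
#' and panel tables; every background variant is present in the panel with
#' at least one allele copy.
#'
#' @param truth a seeded `sim_truth` (from [seed_causal_allele()]).
#' @param config a [sim_config()].
#' @param case_id sequenced case (default: first `case` in the pedigree).
#' @param control_ids sequenced controls (default: five unrelated
#'   non-carrier individuals).
#' @param seed integer seed.
#' @return list(case, controls, panel): two [variant_table()]s and a panel
#'   data frame (`chr`, `pos`, `ref`, `alt`, `ac`, `an`).
#' @export
emit_variant_tables <- function(truth, config,
                                case_id = NULL, control_ids = NULL,
                                seed = config$seed + 2L) {
  set.seed(seed)
  ped <- truth$ped
  if (is.null(truth$causal_cols))
    stop("truth has no seeded causal allele; run seed_causal_allele() first")
  if (is.null(case_id)) case_id <- ped$id[ped$role == "case"][1]
  if (is.null(control_ids)) {
    noncar <- names(truth$causal_copies)[truth$causal_copies == 0]
    control_ids <- utils::head(
      intersect(ped$id[ped$role == "control"], noncar), 5L)
  }

  reg <- synthetic_gene_region(config, seed = config$seed + 3L)
  seeded <- reg$variants  # two missense (+ optional synonymous decoy)

  bases <- c("A", "C", "G", "T")
  nb <- config$n_background_variants
  gene_span <- c(reg$model$exons$start[1] - 200L,
                 max(reg$model$exons$end) + 200L)
  pos <- sample_positions(nb * 2L, config$span_bp[1], config$span_bp[2])
  pos <- pos[pos < gene_span[1] | pos > gene_span[2]]
  pos <- utils::head(pos, nb)
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  q <- stats::runif(length(pos), 0.05, 0.5)
  bg <- data.frame(chr = config$chr, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  case_bg_gt <- stats::rbinom(length(pos), 2L, q)
  ctrl_gt <- matrix(stats::rbinom(length(pos) * length(control_ids), 2L, q),
                    ncol = length(control_ids),
                    dimnames = list(NULL, control_ids))
  an <- 2L * config$panel_size
  panel_ac <- if (config$panel_size > 0L)
    pmax(1L, stats::rbinom(length(pos), an, q)) else integer(0)

  # private variants outside the mapped chromosome
  noff <- config$n_offchr_private
  off <- if (noff > 0L) data.frame(
    chr = "5", pos = sample_positions(noff, 1, 5e7),
    ref = sample(bases, noff, replace = TRUE), stringsAsFactors = FALSE
  ) else NULL
  if (!is.null(off))
    off$alt <- vapply(off$ref, function(b) sample(setdiff(bases, b), 1L),
                      character(1))

  # genotypes of the two seeded variants come from the truth labels
  seed_gt_case <- vapply(seq_len(nrow(seeded)), function(i) {
    col <- which(truth$loci$chr == seeded$chr[i] &
                   truth$loci$bp == seeded$pos[i])
    if (length(col) == 1L)
      causal_copy_counts(truth, col, truth$carrier_hap_row)[[case_id]]
    else 2L  # decoy variant: seeded hom-alt by construction
  }, integer(1))

  keep_bg <- case_bg_gt > 0L
  case_df <- rbind(bg[keep_bg, , drop = FALSE], off, seeded)
  case_gt <- matrix(c(case_bg_gt[keep_bg],
                      rep(2L, if (is.null(off)) 0L else nrow(off)),
                      seed_gt_case),
                    ncol = 1L, dimnames = list(NULL, case_id))
  ord <- order(case_df$chr, case_df$pos)
  case_tab <- variant_table(case_df[ord, , drop = FALSE],
                            case_gt[ord, , drop = FALSE])

  ctrl_tab <- variant_table(bg, ctrl_gt)
  panel <- if (config$panel_size > 0L)
    data.frame(bg, ac = panel_ac, an = an)
  else data.frame(chr = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), ac = integer(0), an = integer(0))
  list(case = case_tab, controls = ctrl_tab, panel = panel,
       case_id = case_id, control_ids = control_ids)
}

#' Synthetic candidate-gene region: transcript model, reference sequence
#' and the seeded coding variants
#'
#' Builds a two-exon plus-strand transcript anchored at the configured
#' causal position so that the first seeded variant falls in codon 45
#' (CGG -> CAG, p.R45Q, destroying an MspI site) and the linked variant in
#' codon 444
#' (ACC -> ATC, p.T444I), embedded in random reference sequence. With
#' `include_synonymous_decoy` a third private variant in codon 445
#' (GCT -> GCC, synonymous) is added.
#'
#' @param config a [sim_config()]; requires
#'   `linked_variant_offset_bp > 1200`.
#' @param seed integer seed for the random flanking sequence.
#' @return list(model, genome, variants, protein).
#' @export
synthetic_gene_region <- function(config, seed = config$seed + 3L) {
  set.seed(seed)
  p1 <- config$causal_bp
  p2 <- config$causal_bp + config$linked_variant_offset_bp
  if (config$linked_variant_offset_bp <= 1200L)
    stop("linked_variant_offset_bp must exceed the first exon span (1200 bp)")
  e1s <- p1 - 133L; e1e <- p1 + 1194L          # CDS bases 1..1328
  e2s <- p2 - 2L;  e2e <- e2s + 3546L          # CDS bases 1329..4875
  gstart <- e1s - 2000L
  gend <- e2e + 2000L
  seqc <- sample(c("A", "C", "G", "T"), gend - gstart + 1L, replace = TRUE)
  put <- function(s, pos, codon) {
    s[(pos - gstart + 1L):(pos - gstart + 3L)] <- strsplit(codon, "")[[1]]
    s
  }
  # codon 45 CGG (Arg) preceded by C: the reference carries an MspI site
  # (CCGG) that the G>A allele (CAG, Gln) destroys — RFLP-discriminable
  seqc[p1 - 2L - gstart + 1L] <- "C"
  seqc <- put(seqc, p1 - 1L, "CGG")   # codon 45
  seqc <- put(seqc, p2 - 1L, "ACC")   # codon 444
  seqc <- put(seqc, p2 + 2L, "GCT")   # codon 445
  genome <- genome_seq(stats::setNames(list(paste(seqc, collapse = "")),
                                       config$causal_chr),
                       stats::setNames(as.integer(gstart), config$causal_chr))
  model <- gene_model("TX1", config$causal_chr, "+",
                      data.frame(start = c(e1s, e2s), end = c(e1e, e2e)),
                      e1s, e2e)
  variants <- data.frame(chr = config$causal_chr,
                         pos = c(p1, p2),
                         ref = c("G", "C"), alt = c("A", "T"),
                         stringsAsFactors = FALSE)
  if (config$include_synonymous_decoy)
    variants <- rbind(variants,
                      data.frame(chr = config$causal_chr, pos = p2 + 4L,
                                 ref = "T", alt = "C",
                                 stringsAsFactors = FALSE))
  cds <- genome_fetch(genome, config$causal_chr, e1s, e1e)
  cds <- paste0(cds, genome_fetch(genome, config$causal_chr, e2s, e2e))
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  list(model = model, genome = genome, variants = variants,
       protein = protein)
}

#' Simulate a multi-species protein alignment with controlled conservation
#'
#' Emulates an ortholog alignment: each non-reference sequence substitutes
#' residues independently, at a low rate in conserved columns and a high
#' rate in designated variable columns.
#'
#' @param ref_protein reference protein string (1-letter codes).
#' @param n_species number of non-reference sequences (default 12).
#' @param conserved_positions residue positions (1-based, reference
#'   coordinates) held nearly invariant (substitution rate 0.01).
#' @param variable_positions positions substituted at rate 0.7.
#' @param base_rate substitution rate elsewhere (default 0.15).
#' @param ref_id name of the reference sequence.
#' @param seed integer seed.
#' @return Named character vector of aligned sequences (gapless), reference
#'   first.
#' @export
simulate_protein_alignment <- function(ref_protein, n_species = 12L,
                                       conserved_positions = integer(0),
                                       variable_positions = integer(0),
                                       base_rate = 0.15,
                                       ref_id = "Bos_taurus", seed = 1L) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- strsplit(ref_protein, "")[[1]]
  L <- length(ref)
  rate <- rep(base_rate, L)
  rate[conserved_positions] <- 0.01
  rate[variable_positions] <- 0.7
  out <- vapply(seq_len(n_species), function(i) {
    s <- ref
    hit <- stats::runif(L) < rate
    s[hit] <- vapply(s[hit], function(a)
      sample(setdiff(aas, a), 1L), character(1))
    paste(s, collapse = "")
  }, character(1))
  stats::setNames(c(ref_protein, out),
                  c(ref_id, sprintf("species%02d", seq_len(n_species))))
}

#' Generate a complete synthetic study bundle
#'
#' Runs the full generator: default pedigree, marker map, gene dropping,
#' causal-allele seeding, array genotypes (with QC flaws: low call rate via
#' missingness, elevated-error markers, unpositioned and duplicate-position
#' markers), WGS-like variant tables, candidate-gene region with reference
#' sequence, and a multi-species protein alignment in which the first
#' candidate residue is conserved and the second is not.
#'
#' @param config a [sim_config()].
#' @param ped optional pedigree (default [build_default_pedigree()]).
#' @return Object of class `sim_bundle`.
#' @export
simulate_dataset <- function(config = sim_config(), ped = NULL) {
  if (is.null(ped)) ped <- build_default_pedigree()
  set.seed(config$seed)
  bp <- sample_positions(config$n_markers, config$span_bp[1],
                         config$span_bp[2])
  map <- genetic_map(config$chr, bp, rate_cM_per_Mb = config$rate_cM_per_Mb)
  freqs <- config$allele_freq
  if (is.null(freqs)) freqs <- stats::runif(config$n_markers, 0.1, 0.9)
  extras <- data.frame(chr = config$causal_chr,
                       bp = c(config$causal_bp,
                              config$causal_bp +
                                config$linked_variant_offset_bp))
  truth0 <- gene_drop(ped, map, freqs, seed = config$seed,
                      extra_positions = extras)
  truth <- seed_causal_allele(truth0, ped, config)
  gm <- emit_array_genotypes(truth, config)

  # map flaws for the QC module: unknown and duplicated positions
  set.seed(config$seed + 4L)
  m <- nrow(gm$map)
  flawed <- sample.int(m, min(m, config$n_unpositioned +
                                config$n_duplicate_pos))
  unpos <- utils::head(flawed, config$n_unpositioned)
  dups <- utils::tail(flawed, min(config$n_duplicate_pos,
                                  length(flawed) - length(unpos)))
  gm$map$chr[unpos] <- NA
  gm$map$bp[unpos] <- NA
  for (d in dups[dups > 1L]) gm$map$bp[d] <- gm$map$bp[d - 1L]

  vt <- emit_variant_tables(truth, config)
  reg <- synthetic_gene_region(config)
  aln <- simulate_protein_alignment(reg$protein,
                                    conserved_positions = 45L,
                                    variable_positions = 444L,
                                    seed = config$seed + 5L)
  structure(list(config = config, ped = ped, map = map, truth = truth,
                 genotypes = gm, variants = vt, genome = reg$genome,
                 gene_models = list(reg$model), protein = reg$protein,
                 alignment = aln, roles = pedigree_roles(ped),
                 case_id = vt$case_id, control_ids = vt$control_ids),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic study bundle (seed", x$config$seed, ")\n")
  print(x$ped)
  print(x$genotypes)
  cat("Case VCF:", nrow(x$variants$case$variants), "variants; panel:",
      nrow(x$variants$panel), "sites x", x$config$panel_size, "animals\n")
  invisible(x)
}
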