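toy_variants <- function(pos, chr = "1", gt_case = 2L) {
  n <- length(pos)
  variant_table(data.frame(chr = chr, pos = pos, ref = "A", alt = "G",
                           stringsAsFactors = FALSE),
                matrix(rep_len(gt_case, n), ncol = 1,
                       dimnames = list(NULL, "case")))
}

test_that("region filter bounds are 1-based inclusive", {
  regions <- data.frame(chr = "1", start_bp = 100L, end_bp = 200L)
  tab <- toy_variants(c(99L, 100L, 150L, 200L, 201L))
  res <- filter_in_regions(tab, regions)
  expect_identical(res$table$variants$pos, c(100L, 150L, 200L))
  # empty region list drops everything
  empty <- regions[0, ]
  expect_identical(nrow(filter_in_regions(tab, empty)$table$variants), 0L)
})

test_that("private-homozygous filter enumerates control genotypes correctly", {
  tab <- variant_table(
    data.frame(chr = "1", pos = 1:4 * 10L, ref = "A", alt = "G"),
    cbind(case = c(2L, 1L, 2L, 2L)))
  controls <- variant_table(
    data.frame(chr = "1", pos = c(30L, 40L), ref = "A", alt = "G"),
    cbind(k1 = c(1L, 0L), k2 = c(0L, NA)))
  res <- filter_private_homozygous(tab, "case", controls)
  # pos 10: hom, unseen in controls -> kept; pos 20: case het -> dropped;
  # pos 30: control k1 carries -> dropped; pos 40: controls 0/missing
  # (not masking by default) -> kept
  expect_identical(res$table$variants$pos, c(10L, 40L))
  strict <- filter_private_homozygous(tab, "case", controls,
                                      missing_controls = "strict")
  expect_identical(strict$table$variants$pos, 10L)
  presence <- filter_private_homozygous(tab, "case", controls,
                                        control_mode = "allele_presence")
  expect_identical(presence$table$variants$pos, 10L)
  expect_error(filter_private_homozygous(tab, "nobody", controls),
               "absent")
})

test_that("panel absence is absolute", {
  tab <- toy_variants(c(10L, 20L, 30L))
  panel <- data.frame(chr = "1", pos = c(20L, 30L), ref = "A", alt = "G",
                      ac = c(3L, 0L))
  res <- filter_absent_in_panel(tab, panel)
  # ac > 0 masks; an ac = 0 panel row does not
  expect_identical(res$table$variants$pos, c(10L, 30L))
  # empty panel keeps everything
  none <- filter_absent_in_panel(tab, panel[0, ])
  expect_identical(nrow(none$table$variants), 3L)
})

test_that("hand-built genes annotate to the expected protein changes", {
  # + strand, single exon, codon 45 = CGA (Arg); G>A at its middle -> CAA
  flank <- paste(rep("A", 10), collapse = "")
  codons <- c(rep("GCT", 44), "CGA", rep("GCT", 5))
  seqc <- paste0(flank, paste(codons, collapse = ""), flank)
  genome <- genome_seq(list(`1` = seqc))
  model <- gene_model("t1", "1", "+", data.frame(start = 11, end = 160),
                      11, 160)
  pos_mid45 <- 10 + 44 * 3 + 2
  ann <- annotate_consequence("1", pos_mid45, "G", "A", model, genome)
  expect_identical(ann$consequence, "missense")
  expect_identical(ann$protein_change$notation, "R45Q")
  # synonymous third-position change GCT -> GCC
  ann2 <- annotate_consequence("1", 13, "T", "C", model, genome)
  expect_identical(ann2$consequence, "synonymous")
  expect_null(ann2$protein_change)
  # stop gained: CGA -> TGA
  ann3 <- annotate_consequence("1", pos_mid45 - 1, "C", "T", model, genome)
  expect_identical(ann3$consequence, "stop_gained")
  # intronic and intergenic
  model2 <- gene_model("t2", "1", "+",
                       data.frame(start = c(11, 101), end = c(70, 160)),
                       11, 160)
  expect_identical(
    annotate_consequence("1", 80, substr(seqc, 80, 80),
                         setdiff(c("A", "C"), substr(seqc, 80, 80))[1],
                         model2, genome)$consequence, "intronic")
  expect_identical(
    annotate_consequence("1", 5, "A", "C", model, genome)$consequence,
    "intergenic")
  # guards: reference mismatch and non-SNV
  expect_error(annotate_consequence("1", pos_mid45, "C", "A", model,
                                    genome), "mismatch")
  expect_error(annotate_consequence("1", pos_mid45, "GG", "A", model,
                                    genome), "SNV")
})

test_that("minus-strand annotation is the reverse-complement mirror", {
  # build the mirrored contig explicitly and expect identical calls
  for (seed in 1:10) {
    b <- random_gene_bundle(seed, max_exons = 3)
    snv <- random_cds_snv(b)
    ann <- annotate_consequence(b$model$chr, snv$pos, snv$ref, snv$alt,
                                b$model, b$genome)
    L <- nchar(b$genome$seq[[b$model$chr]])
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    genome2 <- genome_seq(setNames(list(rc(b$genome$seq[[b$model$chr]])),
                                   b$model$chr))
    flip <- function(p) L - p + 1L
    model2 <- gene_model(b$model$transcript_id, b$model$chr,
                         if (b$model$strand == "+") "-" else "+",
                         data.frame(start = flip(b$model$exons$end),
                                    end = flip(b$model$exons$start)),
                         flip(b$model$cds_end), flip(b$model$cds_start))
    ann2 <- annotate_consequence(b$model$chr, flip(snv$pos), rc(snv$ref),
                                 rc(snv$alt), model2, genome2)
    expect_identical(ann2$consequence, ann$consequence)
    if (!is.null(ann$protein_change))
      expect_identical(ann2$protein_change$notation,
                       ann$protein_change$notation)
  }
})

test_that("annotation agrees with full-CDS re-translation on random genes", {
  for (seed in 1:200) {
    b <- random_gene_bundle(seed)
    snv <- random_cds_snv(b)
    ann <- annotate_consequence(b$model$chr, snv$pos, snv$ref, snv$alt,
                                b$model, b$genome)
    want <- oracle_consequence(b$model, b$genome, snv$pos, snv$alt)
    expect_identical(ann$consequence, want$consequence,
                     label = paste("seed", seed))
    if (!is.null(ann$protein_change)) {
      expect_identical(ann$protein_change$aa_pos, want$aa_pos)
      expect_identical(ann$protein_change$ref_aa, want$ref_aa)
      expect_identical(ann$protein_change$alt_aa, want$alt_aa)
    }
  }
})

test_that("filter stages are intersective: order never changes the result", {
  b <- simulate_dataset(sim_config(seed = 12))
  regions <- data.frame(chr = "20", start_bp = 30e6, end_bp = 45e6)
  tab <- b$variants$case
  f_region <- function(t) filter_in_regions(t, regions)$table
  f_priv <- function(t)
    filter_private_homozygous(t, b$case_id, b$variants$controls)$table
  f_panel <- function(t) filter_absent_in_panel(t, b$variants$panel)$table
  orders <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  keys <- lapply(orders, function(o) {
    t <- tab
    for (f in list(f_region, f_priv, f_panel)[o]) t <- f(t)
    sort(paste(t$variants$chr, t$variants$pos))
  })
  expect_identical(keys[[1]], keys[[2]])
  expect_identical(keys[[1]], keys[[3]])
})

test_that("removing a masking control variant can only grow the survivors", {
  b <- simulate_dataset(sim_config(seed = 14))
  regions <- data.frame(chr = "20", start_bp = b$config$span_bp[1],
                        end_bp = b$config$span_bp[2])
  full <- prioritize_variants(b$variants$case, b$variants$controls,
                              b$variants$panel, regions, b$gene_models,
                              b$genome)
  ctrl <- b$variants$controls
  drop <- sample(nrow(ctrl$variants), 5)
  fewer <- variant_table(ctrl$variants[-drop, ], ctrl$gt[-drop, ])
  less <- prioritize_variants(b$variants$case, fewer, b$variants$panel,
                              regions, b$gene_models, b$genome)
  expect_gte(nrow(less$candidates), nrow(full$candidates))
})

test_that("the trace shows all-pass survivors and one first-fail per drop", {
  b <- simulate_dataset(sim_config(seed = 15))
  regions <- data.frame(chr = "20", start_bp = b$config$span_bp[1],
                        end_bp = b$config$span_bp[2])
  pri <- prioritize_variants(b$variants$case, b$variants$controls,
                             b$variants$panel, regions, b$gene_models,
                             b$genome)
  surv <- paste(pri$candidates$chr, pri$candidates$pos,
                pri$candidates$ref, pri$candidates$alt, sep = ":")
  for (k in unique(pri$trace$key)) {
    rows <- pri$trace[pri$trace$key == k, ]
    if (k %in% surv) {
      expect_true(all(rows$pass))
    } else {
      expect_identical(sum(!rows$pass), 1L)  # dropped at its first failure
    }
  }
})
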