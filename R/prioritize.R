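#' Candidate-variant prioritization
#'
#' Reduces a sequenced case's variant table to candidate causal mutations
#' for a recessive trait: inside the mapped candidate regions, homozygous
#' for the alternative allele in the case, absent from sequenced controls
#' and from a population panel, and protein-changing according to the
#' built-in consequence annotator.
#'
#' @name variant_prioritization
NULL

new_trace <- function(tab) {
  data.frame(key = variant_key(tab$variants), stage = NA_character_,
             pass = TRUE, reason = "", stringsAsFactors = FALSE)
}

trace_stage <- function(tab, keep, stage, reason) {
  n <- nrow(tab$variants)
  data.frame(key = variant_key(tab$variants),
             stage = rep_len(stage, n), pass = keep,
             reason = ifelse(keep, "", rep_len(reason, n)),
             stringsAsFactors = FALSE)
}

subset_table <- function(tab, keep) {
  variant_table(tab$variants[keep, , drop = FALSE],
                if (is.null(tab$gt)) NULL else tab$gt[keep, , drop = FALSE])
}

#' Keep variants inside candidate regions
#'
#' Bounds are 1-based inclusive on both sides.
#'
#' @param tab a [variant_table()].
#' @param regions data frame with `chr`, `start_bp`, `end_bp` (e.g. an
#'   `autozyg_regions` object).
#' @return list(table, trace).
#' @export
filter_in_regions <- function(tab, regions) {
  v <- tab$variants
  keep <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (v$chr == regions$chr[i] &
                      v$pos >= regions$start_bp[i] &
                      v$pos <= regions$end_bp[i])
  }
  list(table = subset_table(tab, keep),
       trace = trace_stage(tab, keep, "region", "outside candidate regions"))
}

#' Keep variants homozygous-alternative in the case and absent in controls
#'
#' @param tab a [variant_table()] with the case genotype column.
#' @param case_id sequenced case sample.
#' @param controls a [variant_table()] of the sequenced controls (or
#'   `NULL` for none).
#' @param control_mode `"genotype"` (default): a control masks a variant
#'   when its genotype there carries the alternative allele;
#'   `"allele_presence"`: any control record at the site with the same
#'   alternative allele masks it, regardless of genotype.
#' @param missing_controls `"not_masking"` (default): a missing control
#'   genotype leaves the variant private; `"strict"`: it masks.
#' @return list(table, trace).
#' @export
filter_private_homozygous <- function(tab, case_id, controls = NULL,
                                      control_mode = c("genotype",
                                                       "allele_presence"),
                                      missing_controls = c("not_masking",
                                                           "strict")) {
  control_mode <- match.arg(control_mode)
  missing_controls <- match.arg(missing_controls)
  if (is.null(tab$gt) || !case_id %in% colnames(tab$gt))
    stop("case genotype '", case_id, "' absent from variant table")
  g_case <- tab$gt[, case_id]
  hom <- !is.na(g_case) & g_case == 2L
  masked <- rep(FALSE, nrow(tab$variants))
  if (!is.null(controls) && nrow(controls$variants)) {
    idx <- match(variant_key(tab$variants), variant_key(controls$variants))
    hit <- !is.na(idx)
    if (control_mode == "allele_presence") {
      masked <- hit
    } else {
      gt <- controls$gt[idx[hit], , drop = FALSE]
      carries <- rowSums(gt > 0L, na.rm = TRUE) > 0L
      if (missing_controls == "strict")
        carries <- carries | rowSums(is.na(gt)) > 0L
      masked[hit] <- carries
    }
  }
  keep <- hom & !masked
  reason <- ifelse(!hom, "case not homozygous-alternative",
                   "allele observed in a control")
  list(table = subset_table(tab, keep),
       trace = trace_stage(tab, keep, "private_homozygous", reason))
}

#' Keep variants absent from the population panel
#'
#' "Absent" is absolute: any observed copy of the alternative allele in
#' the panel removes the variant.
#'
#' @param tab a [variant_table()].
#' @param panel data frame (`chr`, `pos`, `ref`, `alt`, `ac`) of panel
#'   allele counts, or a [variant_table()] with panel genotypes.
#' @return list(table, trace).
#' @export
filter_absent_in_panel <- function(tab, panel) {
  if (inherits(panel, "variant_table")) {
    ac <- rowSums(panel$gt, na.rm = TRUE)
    panel <- data.frame(panel$variants, ac = ac)
  }
  if (nrow(panel)) {
    idx <- match(variant_key(tab$variants), variant_key(panel))
    present <- !is.na(idx) & panel$ac[pmax(idx, 1L)] > 0L
  } else present <- rep(FALSE, nrow(tab$variants))
  keep <- !present
  list(table = subset_table(tab, keep),
       trace = trace_stage(tab, keep, "panel", "allele present in panel"))
}

#' Annotate the coding consequence of an SNV
#'
#' Locates the variant in the spliced CDS of a transcript model
#' (strand-aware; minus-strand transcripts are reverse-complemented),
#' translates the reference and alternative codons with the standard
#' nuclear genetic code, and classifies the change. Positions inside the
#' transcript span but outside the CDS are reported `intronic`; positions
#' outside the span are `intergenic`. A mismatch between the variant's
#' reference allele and the genome base is a hard error — it indicates a
#' coordinate bug, not data noise.
#'
#' @param chr,pos,ref,alt the SNV (single-base ref/alt).
#' @param model a [gene_model()].
#' @param genome a [genome_seq()].
#' @return list(consequence, protein_change) where `protein_change` is
#'   `NULL` for non-protein-altering classes and otherwise a list with
#'   `ref_aa`, `aa_pos`, `alt_aa` and `notation` (e.g. `"R45Q"`).
#' @export
annotate_consequence <- function(chr, pos, ref, alt, model, genome) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("only SNVs are supported (got ", ref, ">", alt, ")")
  if (chr != model$chr ||
      pos < model$exons$start[1] || pos > max(model$exons$end))
    return(list(consequence = "intergenic", protein_change = NULL))
  cpos <- cds_genomic_positions(model)
  i <- match(pos, cpos)
  if (is.na(i))
    return(list(consequence = "intronic", protein_change = NULL))
  gref <- genome_fetch(genome, chr, pos, pos)
  if (gref != toupper(ref))
    stop("reference mismatch at ", chr, ":", pos, " (variant ", ref,
         ", genome ", gref, ")")
  L <- length(cpos)
  cds_i <- if (model$strand == "+") i else L - i + 1L
  codon_idx <- (cds_i - 1L) %/% 3L + 1L
  offsets <- ((codon_idx - 1L) * 3L + 1L):(codon_idx * 3L)
  gpos <- if (model$strand == "+") cpos[offsets] else rev(cpos)[offsets]
  fetch1 <- function(p) genome_fetch(genome, chr, p, p)
  bases <- vapply(gpos, fetch1, character(1))
  if (model$strand == "-")
    bases <- vapply(bases, reverse_complement, character(1))
  ref_codon <- paste(bases, collapse = "")
  within <- which(gpos == pos)
  alt_base <- if (model$strand == "+") toupper(alt)
  else reverse_complement(alt)
  alt_bases <- bases
  alt_bases[within] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- if (ref_aa == alt_aa) "synonymous"
  else if (alt_aa == "*") "stop_gained"
  else if (ref_aa == "*") "stop_lost"
  else "missense"
  pc <- NULL
  if (cls %in% c("missense", "stop_gained", "stop_lost"))
    pc <- list(ref_aa = ref_aa, aa_pos = codon_idx, alt_aa = alt_aa,
               notation = paste0(ref_aa, codon_idx, alt_aa))
  list(consequence = cls, protein_change = pc)
}

#' Full prioritization of a case variant table
#'
#' Applies the four filters in order — candidate region, private
#' homozygous, panel absence, protein-changing — and returns the
#' survivors with annotations, the per-stage counts and the full filter
#' trace. The filters are intersective, so the final set does not depend
#' on their order.
#'
#' @param case a [variant_table()] with the case genotypes.
#' @param controls a [variant_table()] of sequenced controls (or `NULL`).
#' @param panel panel allele counts (see [filter_absent_in_panel()]).
#' @param regions candidate regions (see [filter_in_regions()]).
#' @param gene_models list of [gene_model()]s.
#' @param genome a [genome_seq()].
#' @param case_id case sample id (default: the only genotype column).
#' @param protein_classes consequence classes counted as protein-changing.
#' @param ... passed to [filter_private_homozygous()].
#' @return Object of class `prioritization`: list(candidates, counts,
#'   trace). `candidates` is a data frame of the surviving variants with
#'   `consequence` and `protein_change` notation columns.
#' @export
prioritize_variants <- function(case, controls, panel, regions,
                                gene_models, genome, case_id = NULL,
                                protein_classes = c("missense",
                                                    "stop_gained",
                                                    "stop_lost"), ...) {
  if (is.null(case_id)) case_id <- colnames(case$gt)[1]
  traces <- list()
  s1 <- filter_in_regions(case, regions)
  traces[[1]] <- s1$trace
  s2 <- filter_private_homozygous(s1$table, case_id, controls, ...)
  traces[[2]] <- s2$trace
  s3 <- filter_absent_in_panel(s2$table, panel)
  traces[[3]] <- s3$trace

  v <- s3$table$variants
  ann <- lapply(seq_len(nrow(v)), function(i) {
    best <- list(consequence = "intergenic", protein_change = NULL)
    rank <- c(intergenic = 0, intronic = 1, synonymous = 2, missense = 3,
              stop_lost = 4, stop_gained = 5)
    for (gmod in gene_models) {
      a <- annotate_consequence(v$chr[i], v$pos[i], v$ref[i], v$alt[i],
                                gmod, genome)
      if (rank[[a$consequence]] > rank[[best$consequence]]) best <- a
    }
    best
  })
  consequence <- vapply(ann, function(a) a$consequence, character(1))
  keep <- consequence %in% protein_classes
  traces[[4]] <- trace_stage(s3$table, keep, "protein_changing",
                             "not protein-changing")
  final <- subset_table(s3$table, keep)
  cand <- final$variants
  cand$consequence <- consequence[keep]
  cand$protein_change <- vapply(ann[keep], function(a)
    if (is.null(a$protein_change)) NA_character_
    else a$protein_change$notation, character(1))
  cand$case_gt <- final$gt[, case_id]
  trace <- do.call(rbind, traces)
  counts <- data.frame(
    stage = c("input", "region", "private_homozygous", "panel",
              "protein_changing"),
    n = c(nrow(case$variants), nrow(s1$table$variants),
          nrow(s2$table$variants), nrow(s3$table$variants), nrow(cand)))
  structure(list(candidates = cand, counts = counts, trace = trace,
                 case_id = case_id),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat("Variant prioritization (case", x$case_id, ")\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$candidates)) {
    cat("Candidates:\n")
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.prioritization <- function(object, ...) {
  cat(nrow(object$candidates), "candidate variant(s):",
      paste(sprintf("%s:%d %s>%s (%s %s)", object$candidates$chr,
                    object$candidates$pos, object$candidates$ref,
                    object$candidates$alt, object$candidates$consequence,
                    object$candidates$protein_change), collapse = "; "),
      "\n")
  invisible(object)
}
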