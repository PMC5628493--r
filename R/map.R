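#' Genetic marker map
#'
#' An ordered marker map with physical (bp, 1-based) and genetic (cM)
#' positions. When `cM` is not supplied it is derived from the physical
#' position at a constant rate, the standard cattle-scale approximation of
#' 1 cM per Mb.
#'
#' @param chr chromosome label per marker.
#' @param bp 1-based physical position, strictly increasing within a
#'   chromosome.
#' @param cM genetic position; defaults to `bp / 1e6 * rate_cM_per_Mb`.
#' @param rate_cM_per_Mb recombination rate used for auto-derived cM
#'   (default 1.0).
#' @param marker_id optional marker identifiers.
#' @return An object of class `genetic_map` (a data frame with columns
#'   `marker_id`, `chr`, `bp`, `cM`).
#' @export
genetic_map <- function(chr, bp, cM = NULL, rate_cM_per_Mb = 1.0,
                        marker_id = NULL) {
  if (length(bp) == 0L) stop("empty map")
  if (is.null(cM)) cM <- bp / 1e6 * rate_cM_per_Mb
  if (is.null(marker_id)) marker_id <- sprintf("M%05d", seq_along(bp))
  df <- data.frame(marker_id = as.character(marker_id),
                   chr = as.character(chr), bp = as.integer(bp),
                   cM = as.numeric(cM), stringsAsFactors = FALSE)
  for (ch in unique(df$chr)) {
    b <- df$bp[df$chr == ch]
    m <- df$cM[df$chr == ch]
    if (any(diff(b) <= 0))
      stop("bp not strictly increasing on chromosome ", ch)
    if (any(diff(m) < 0))
      stop("cM decreasing on chromosome ", ch)
  }
  attr(df, "rate_cM_per_Mb") <- rate_cM_per_Mb
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study conditions: a ~50K-density marker set on one 72-Mb chromosome
#' (about 17 markers/Mb), a recessive causal allele at 39,829,806 bp with a
#' linked private variant 34,342 bp away, >95% call rates with rare
#' single-step genotyping errors, a designated marker subset with elevated
#' error rate (emulating paternity-conflict-prone assays), a handful of
#' markers with unknown or duplicated map positions, and a 1682-animal
#' reference-allele-only population panel.
#'
#' @param seed integer master seed; all generator outputs are reproducible
#'   functions of it.
#' @param n_markers number of array markers (default 1200).
#' @param chr chromosome label (default "20").
#' @param span_bp length-2 physical span of the marker set.
#' @param allele_freq either a vector of per-marker founder alternative
#'   allele frequencies or `NULL`, in which case frequencies are drawn
#'   Uniform(0.1, 0.9) to mimic array ascertainment toward common SNPs.
#' @param causal_chr,causal_bp position of the seeded recessive allele.
#' @param linked_variant_offset_bp separation of the second seeded private
#'   variant (default 34342).
#' @param missing_rate per-call missingness probability (default 0.02).
#' @param genotype_error_rate per-call symmetric single-step miscall
#'   probability (default 0.001).
#' @param conflict_markers number of markers with elevated error rate used
#'   to exercise the paternity-conflict QC rule (default 8).
#' @param conflict_error_rate probability that a call at a conflict-prone
#'   marker is replaced by a random genotype (default 0.8).
#' @param n_unpositioned markers whose map position is blanked (default 5).
#' @param n_duplicate_pos markers given a duplicated position (default 2,
#'   i.e. one ambiguous pair).
#' @param panel_size number of animals in the population panel
#'   (default 1682).
#' @param n_background_variants shared background variants in the WGS-like
#'   tables (default 150).
#' @param n_offchr_private private case variants placed outside the mapped
#'   chromosome, exercising the region filter (default 10).
#' @param include_synonymous_decoy also seed a synonymous private
#'   homozygous variant inside the region (default FALSE), exercising the
#'   protein-changing filter stage.
#' @param rate_cM_per_Mb genetic map rate (default 1.0).
#' @param carrier_founder id of the founder whose haplotype receives the
#'   causal allele; `NULL` selects automatically (a non-control founder
#'   ancestral to all cases and obligate carriers).
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_markers = 1200L,
                       chr = "20",
                       span_bp = c(1e6, 72e6),
                       allele_freq = NULL,
                       causal_chr = "20",
                       causal_bp = 39829806L,
                       linked_variant_offset_bp = 34342L,
                       missing_rate = 0.02,
                       genotype_error_rate = 0.001,
                       conflict_markers = 8L,
                       conflict_error_rate = 0.8,
                       n_unpositioned = 5L,
                       n_duplicate_pos = 2L,
                       panel_size = 1682L,
                       n_background_variants = 150L,
                       n_offchr_private = 10L,
                       include_synonymous_decoy = FALSE,
                       rate_cM_per_Mb = 1.0,
                       carrier_founder = NULL) {
  cfg <- list(seed = as.integer(seed), n_markers = as.integer(n_markers),
              chr = as.character(chr), span_bp = as.numeric(span_bp),
              allele_freq = allele_freq,
              causal_chr = as.character(causal_chr),
              causal_bp = as.integer(causal_bp),
              linked_variant_offset_bp = as.integer(linked_variant_offset_bp),
              missing_rate = missing_rate,
              genotype_error_rate = genotype_error_rate,
              conflict_markers = as.integer(conflict_markers),
              conflict_error_rate = conflict_error_rate,
              n_unpositioned = as.integer(n_unpositioned),
              n_duplicate_pos = as.integer(n_duplicate_pos),
              panel_size = as.integer(panel_size),
              n_background_variants = as.integer(n_background_variants),
              n_offchr_private = as.integer(n_offchr_private),
              include_synonymous_decoy = isTRUE(include_synonymous_decoy),
              rate_cM_per_Mb = rate_cM_per_Mb,
              carrier_founder = carrier_founder)
  rates <- c(cfg$missing_rate, cfg$genotype_error_rate, cfg$conflict_error_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (cfg$causal_bp < cfg$span_bp[1] || cfg$causal_bp > cfg$span_bp[2])
    stop("causal_bp outside marker span")
  if (cfg$n_markers < 2L) stop("n_markers must be >= 2")
  class(cfg) <- "sim_config"
  cfg
}
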