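#' Assay-level verification utilities
#'
#' In-silico PCR-RFLP fragment prediction, recessive genotype-phenotype
#' concordance, composite linkage-disequilibrium r-squared, and
#' physical-to-genetic distance arithmetic.
#'
#' @name assay_stats
NULL

#' In-silico restriction digest of an amplicon
#'
#' Scans the amplicon for every (possibly overlapping) occurrence of the
#' recognition sequence and cuts at the marked offset — an idealized
#' complete digestion. An allele that destroys the site (e.g. CCGG ->
#' CTGG for MspI) therefore yields a different fragment pattern, which is
#' how RFLP genotyping distinguishes alleles.
#'
#' @param sequence amplicon DNA string (alphabet A/C/G/T/N).
#' @param site recognition sequence with a single `^` marking the cut
#'   position, e.g. `"C^CGG"` for MspI.
#' @param allele_label optional label carried into the result.
#' @return list(allele_label, fragment_lengths): fragment lengths sorted
#'   ascending, always summing to the amplicon length.
#' @examples
#' insilico_digest("AACCGGTT", "C^CGG")  # fragments 3 and 5
#' @export
insilico_digest <- function(sequence, site = "C^CGG",
                            allele_label = NA_character_) {
  sequence <- toupper(sequence)
  if (!nchar(sequence)) stop("empty sequence")
  if (!grepl("^[ACGTN]+$", sequence))
    stop("sequence alphabet must be A/C/G/T/N")
  if (lengths(regmatches(site, gregexpr("\\^", site))) != 1L)
    stop("site must contain exactly one '^'")
  cut_offset <- regexpr("\\^", site) - 1L
  recog <- gsub("\\^", "", site)
  hits <- gregexpr(paste0("(?=", recog, ")"), sequence, perl = TRUE)[[1]]
  n <- nchar(sequence)
  cuts <- integer(0)
  if (hits[1] != -1L) {
    cuts <- as.integer(hits) + cut_offset - 1L  # cut after this base
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  }
  frags <- diff(c(0L, cuts, n))
  list(allele_label = allele_label, fragment_lengths = sort(frags))
}

#' Genotype-phenotype concordance under a recessive model
#'
#' Concordant iff every affected individual is homozygous for the
#' alternative allele (genotype 2) and no unaffected individual is.
#' Missing genotypes are excluded from the table and from the call.
#'
#' @param genotypes named vector (sample -> 0/1/2/NA).
#' @param phenotypes named vector (sample -> "affected"/"unaffected").
#' @param model only `"recessive"` is implemented.
#' @return Object of class `concordance`: list(model, contingency,
#'   concordant, discordant_samples).
#' @export
genotype_concordance <- function(genotypes, phenotypes,
                                 model = "recessive") {
  model <- match.arg(model)
  ids <- intersect(names(genotypes), names(phenotypes))
  g <- genotypes[ids]
  p <- phenotypes[ids]
  if (!any(p == "affected")) stop("at least one affected sample required")
  ok <- !is.na(g)
  if (!any(ok)) stop("all genotypes missing")
  g <- g[ok]; p <- p[ok]
  tab <- table(genotype = factor(g, levels = 0:2),
               phenotype = factor(p, levels = c("affected", "unaffected")))
  disc <- names(g)[(p == "affected" & g != 2L) |
                     (p == "unaffected" & g == 2L)]
  structure(list(model = model, contingency = tab,
                 concordant = length(disc) == 0L,
                 discordant_samples = disc),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Recessive-model concordance:",
      if (x$concordant) "CONCORDANT" else "discordant", "\n")
  print(x$contingency)
  if (length(x$discordant_samples))
    cat("Discordant:", paste(x$discordant_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Composite linkage-disequilibrium r-squared of two loci
#'
#' Squared Pearson correlation of genotype dosages — the phase-free
#' composite r-squared, distinct from haplotype r-squared (phase is
#' unknown in targeted genotyping data).
#'
#' @param g1,g2 genotype dosage vectors (0/1/2, `NA` allowed); pairs with
#'   a missing value are removed.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2L) stop("fewer than 2 complete genotype pairs")
  v1 <- stats::var(g1)
  v2 <- stats::var(g2)
  if (v1 == 0 || v2 == 0)
    stop("r-squared undefined for a constant genotype vector")
  # cov/var share the same summation, so identical vectors give exactly 1
  r2 <- stats::cov(g1, g2)^2 / (v1 * v2)
  min(r2, 1)
}

#' Physical to genetic distance
#'
#' @param distance_bp physical distance in bp (>= 0).
#' @param rate_cM_per_Mb recombination rate (default 1 cM/Mb).
#' @param digits rounding of the returned cM value (default 3).
#' @return Genetic distance in cM.
#' @examples
#' bp_to_cM(34000)  # 0.034
#' @export
bp_to_cM <- function(distance_bp, rate_cM_per_Mb = 1.0, digits = 3L) {
  if (any(distance_bp < 0)) stop("negative distance")
  round(distance_bp / 1e6 * rate_cM_per_Mb, digits)
}

#' Expected gametes per recombination event
#'
#' Uses the small-distance approximation (recombination fraction =
#' cM/100) with no mapping-function correction.
#'
#' @param distance_cM genetic distance in cM, in (0, 50].
#' @return `round(100 / distance_cM)` gametes.
#' @examples
#' gametes_per_recombination(0.034)  # 2941
#' @export
gametes_per_recombination <- function(distance_cM) {
  if (any(distance_cM <= 0)) stop("distance must be positive")
  if (any(distance_cM > 50)) stop("distance above 50 cM (free recombination)")
  round(100 / distance_cM)
}
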