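#' Sliding-window autozygosity scan for a recessive trait
#'
#' Slides a fixed-size window (default 40 SNPs) across each chromosome of
#' a QC-filtered genotype matrix and keeps windows whose case haplotype is
#' consistent with recessive inheritance: all cases homozygous for the same
#' allele at every window SNP, every obligate carrier compatible with
#' exactly one copy (carrier but not homozygous), and no control
#' homozygous for the case haplotype. Overlapping or bookended consistent
#' windows are merged into maximal runs reported as candidate regions.
#'
#' Criteria are evaluated on unphased genotypes: "homozygous for the case
#' haplotype" and "not homozygous for it" are phase-free statements, and
#' "heterozygous" for an obligate carrier maps to carrier-compatible but
#' not homozygous; the scan therefore needs no phasing step.
#'
#' @param gm a [geno_matrix()] (markers position-sorted within
#'   chromosome; unpositioned markers must be removed first, see
#'   [run_genotype_qc()]).
#' @param roles named character vector (sample -> role) or a [pedigree()];
#'   at least one `case` required. Samples with role `unknown` (or absent
#'   from `roles`) are ignored.
#' @param window_size window size in SNPs (default 40).
#' @param step step in SNPs between window starts (default 1).
#' @param missing_policy how a missing call is treated when classifying:
#'   `"compatible"` (default; a missing call is consistent with any class,
#'   i.e. ignored), `"incompatible"` (counts as a mismatch) or
#'   `"fail_window"` (any missing call among scored samples voids the
#'   window).
#' @return Object of class `autozyg_regions`: a data frame with one row
#'   per candidate region (`chr`, `start_bp`, `end_bp`, `length_mb`,
#'   `n_snps`), sorted by chromosome and start. Start/end are the
#'   positions of the outermost SNPs (1-based inclusive).
#' @export
scan_autozygosity <- function(gm, roles, window_size = 40L, step = 1L,
                              missing_policy = c("compatible",
                                                 "incompatible",
                                                 "fail_window")) {
  missing_policy <- match.arg(missing_policy)
  if (window_size < 2L) stop("window_size must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  if (inherits(roles, "pedigree")) roles <- pedigree_roles(roles)
  roles <- roles[names(roles) %in% rownames(gm$calls)]
  case_ids <- names(roles)[roles == "case"]
  carrier_ids <- names(roles)[roles == "obligate_carrier"]
  control_ids <- names(roles)[roles == "control"]
  if (!length(case_ids)) stop("roles must assign at least one case")
  map <- gm$map
  if (any(is.na(map$chr) | is.na(map$bp)))
    stop("genotype matrix contains unpositioned markers; run QC first")

  regions <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    idx <- idx[order(map$bp[idx])]
    m <- length(idx)
    if (m < window_size) {
      message("chromosome ", ch, " has fewer than ", window_size,
              " markers; skipped")
      next
    }
    cons <- consistent_windows(gm$calls[, idx, drop = FALSE], case_ids,
                               carrier_ids, control_ids, window_size,
                               step, missing_policy)
    if (!length(cons)) next
    runs <- merge_window_runs(cons, window_size)
    bp <- map$bp[idx]
    for (r in runs) {
      first <- r[1]; last <- r[2]
      regions[[length(regions) + 1L]] <- data.frame(
        chr = ch, start_bp = bp[first], end_bp = bp[last],
        length_mb = region_length_mb(bp[first], bp[last]),
        n_snps = last - first + 1L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(regions)) do.call(rbind, regions)
  else data.frame(chr = character(0), start_bp = integer(0),
                  end_bp = integer(0), length_mb = numeric(0),
                  n_snps = integer(0))
  chr_num <- suppressWarnings(as.numeric(out$chr))
  out <- out[order(!is.na(chr_num), chr_num, out$chr, out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("autozyg_regions", "data.frame"),
            window_size = window_size, step = step,
            missing_policy = missing_policy)
}

# window start indices whose windows satisfy all three criteria, for one
# chromosome's genotype block (samples x markers, position-sorted)
consistent_windows <- function(G, case_ids, carrier_ids, control_ids,
                               w, step, policy) {
  m <- ncol(G)
  caseG <- G[case_ids, , drop = FALSE]
  n0 <- colSums(caseG == 0L, na.rm = TRUE)
  n2 <- colSums(caseG == 2L, na.rm = TRUE)
  anyhet <- colSums(caseG == 1L, na.rm = TRUE) > 0L
  nmiss_case <- colSums(is.na(caseG))
  viol <- anyhet | (n0 > 0L & n2 > 0L)
  if (policy != "compatible") viol <- viol | (nmiss_case > 0L)
  allele <- ifelse(n2 > 0L, 2L, ifelse(n0 > 0L, 0L, NA_integer_))
  allele[viol] <- NA_integer_
  defined <- !viol & !is.na(allele)

  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(w + 1L):(m + 1L)] - cs[1:(m - w + 1L)]
  }
  starts <- seq.int(1L, m - w + 1L, by = step)
  ok <- wsum(viol)[starts] == 0

  score <- function(ids, is_control) {
    res <- rep(TRUE, length(starts))
    for (s in ids) {
      g <- G[s, ]
      miss <- is.na(g)
      hom <- !is.na(allele) & !miss & g == allele
      incl <- !is.na(allele) & !miss &
        ((allele == 2L & g >= 1L) | (allele == 0L & g <= 1L))
      inf <- as.integer(defined & !miss)
      if (policy == "compatible") {
        hom[miss | !defined] <- TRUE
        incl[miss | !defined] <- TRUE
      } else {
        # missing counts as an informative mismatch; undefined-allele
        # markers stay uninformative and non-blocking
        hom[miss & defined] <- FALSE
        incl[miss & defined] <- FALSE
        hom[!defined] <- TRUE
        incl[!defined] <- TRUE
        inf[miss & defined] <- 1L
      }
      all_hom <- wsum(!hom)[starts] == 0
      all_incl <- wsum(!incl)[starts] == 0
      n_inf <- wsum(inf)[starts]
      if (is_control) {
        res <- res & !(all_hom & n_inf > 0)
      } else {
        res <- res & (n_inf == 0 | (all_incl & !all_hom))
      }
      if (policy == "fail_window")
        res <- res & (wsum(miss)[starts] == 0)
    }
    res
  }
  ok <- ok & score(carrier_ids, FALSE) & score(control_ids, TRUE)
  if (policy == "fail_window") {
    miss_case <- wsum(nmiss_case > 0L)[starts] == 0
    ok <- ok & miss_case
  }
  starts[ok]
}

# merge overlapping/bookended consistent windows (given start indices) into
# maximal runs; returns list of c(first_marker, last_marker)
merge_window_runs <- function(starts, w) {
  starts <- sort(starts)
  runs <- list()
  cur_first <- starts[1]
  cur_last_start <- starts[1]
  for (s in starts[-1]) {
    if (s <= cur_last_start + w) {
      cur_last_start <- s
    } else {
      runs[[length(runs) + 1L]] <- c(cur_first, cur_last_start + w - 1L)
      cur_first <- s
      cur_last_start <- s
    }
  }
  runs[[length(runs) + 1L]] <- c(cur_first, cur_last_start + w - 1L)
  runs
}

#' Region length in Mb, as tabulated
#'
#' @param start_bp,end_bp outermost SNP positions (1-based inclusive).
#' @return `round((end_bp - start_bp) / 1e6, 2)`.
#' @examples
#' region_length_mb(24179723, 71793734)  # 47.61
#' @export
region_length_mb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("negative span")
  round((end_bp - start_bp) / 1e6, 2)
}

#' @export
print.autozyg_regions <- function(x, ...) {
  cat("Candidate autozygous regions (window",
      attr(x, "window_size"), "SNPs ):", nrow(x), "\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
summary.autozyg_regions <- function(object, ...) {
  cat(nrow(object), "candidate regions;")
  if (nrow(object))
    cat(" largest", max(object$length_mb), "Mb on chromosome",
        object$chr[which.max(object$length_mb)])
  cat("\n")
  invisible(object)
}

#' Infer the shared homozygous case haplotype of one window
#'
#' @param gm a [geno_matrix()].
#' @param window integer vector of marker column indices (one
#'   chromosome, position-sorted).
#' @param case_ids case sample ids.
#' @param missing_policy see [scan_autozygosity()].
#' @return Integer vector of shared homozygous genotype codes (0 or 2;
#'   `NA` where every case is missing under the `compatible` policy), or
#'   `NULL` when no consistent case haplotype exists.
#' @export
infer_case_window_haplotype <- function(gm, window, case_ids,
                                        missing_policy = "compatible") {
  if (length(unique(gm$map$chr[window])) > 1L)
    stop("window spans a chromosome boundary")
  caseG <- gm$calls[case_ids, window, drop = FALSE]
  out <- integer(length(window))
  for (j in seq_along(window)) {
    g <- caseG[, j]
    if (any(is.na(g)) && missing_policy != "compatible") return(NULL)
    g <- g[!is.na(g)]
    if (any(g == 1L)) return(NULL)
    u <- unique(g)
    if (length(u) > 1L) return(NULL)
    out[j] <- if (length(u)) u else NA_integer_
  }
  out
}

#' Classify a sample against a case window haplotype
#'
#' `homozygous_carrier` if the sample is homozygous for the haplotype
#' allele at every window SNP; `carrier` if it is not, but its genotype is
#' consistent with carrying at least one copy everywhere; otherwise
#' `non_carrier`.
#'
#' @param gm a [geno_matrix()].
#' @param sample_id sample to classify.
#' @param window marker column indices.
#' @param hap output of [infer_case_window_haplotype()].
#' @param missing_policy see [scan_autozygosity()].
#' @return `"homozygous_carrier"`, `"carrier"` or `"non_carrier"`.
#' @export
classify_window_sample <- function(gm, sample_id, window, hap,
                                   missing_policy = "compatible") {
  g <- gm$calls[sample_id, window]
  informative <- !is.na(hap)
  if (missing_policy == "compatible") {
    informative <- informative & !is.na(g)
    if (!any(informative)) return("carrier")
    g <- g[informative]; hap <- hap[informative]
    if (all(g == hap)) return("homozygous_carrier")
    if (all((hap == 2L & g >= 1L) | (hap == 0L & g <= 1L)))
      return("carrier")
    return("non_carrier")
  }
  g <- g[informative]; hap <- hap[informative]
  if (!length(g)) return("carrier")
  if (!any(is.na(g)) && all(g == hap)) return("homozygous_carrier")
  if (!any(is.na(g)) &&
      all((hap == 2L & g >= 1L) | (hap == 0L & g <= 1L)))
    return("carrier")
  "non_carrier"
}

#' Evaluate one window against the recessive consistency criteria
#'
#' @inheritParams infer_case_window_haplotype
#' @param roles named role vector or [pedigree()].
#' @return `TRUE` iff a shared homozygous case haplotype exists, every
#'   obligate carrier classifies as `carrier`, and no control classifies
#'   as `homozygous_carrier`.
#' @export
window_consistent <- function(gm, window, roles,
                              missing_policy = "compatible") {
  if (inherits(roles, "pedigree")) roles <- pedigree_roles(roles)
  roles <- roles[names(roles) %in% rownames(gm$calls)]
  case_ids <- names(roles)[roles == "case"]
  if (!length(case_ids)) stop("roles must assign at least one case")
  if (missing_policy == "fail_window") {
    scored <- names(roles)[roles %in% c("case", "obligate_carrier",
                                        "control")]
    if (anyNA(gm$calls[scored, window])) return(FALSE)
  }
  hap <- infer_case_window_haplotype(gm, window, case_ids, missing_policy)
  if (is.null(hap)) return(FALSE)
  for (s in names(roles)[roles == "obligate_carrier"]) {
    if (classify_window_sample(gm, s, window, hap, missing_policy) !=
        "carrier") return(FALSE)
  }
  for (s in names(roles)[roles == "control"]) {
    if (classify_window_sample(gm, s, window, hap, missing_policy) ==
        "homozygous_carrier") return(FALSE)
  }
  TRUE
}
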