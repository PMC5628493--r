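#' Marker quality control
#'
#' Three marker-exclusion rules applied before mapping, in the
#' conventional order:
#' \enumerate{
#'   \item call rate: markers successfully genotyped in less than a given
#'     fraction of samples (default 95%) are removed;
#'   \item Mendelian conflicts: markers showing opposing-homozygote
#'     parent/offspring conflicts in more than `max_conflict_rate` of
#'     tested pairs are removed;
#'   \item map position: markers with unknown or duplicated genomic
#'     positions are removed.
#' }
#' Samples are never removed.
#'
#' @name genotype_qc
NULL

new_qc_report <- function(rule, removed, stats, params, note = NULL) {
  structure(list(rule = rule, removed = removed, stats = stats,
                 params = params, note = note),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC rule:", x$rule, "- removed", length(x$removed), "markers")
  if (!is.null(x$note)) cat(" (", x$note, ")")
  cat("\n")
  invisible(x)
}

drop_markers <- function(gm, marker_ids) {
  keep <- !colnames(gm$calls) %in% marker_ids
  geno_matrix(gm$calls[, keep, drop = FALSE],
              gm$map[keep, , drop = FALSE])
}

#' Remove markers with low call rate
#'
#' @param gm a [geno_matrix()].
#' @param threshold minimum fraction of successfully genotyped samples a
#'   marker must reach to be retained; markers strictly below it are
#'   removed (default 0.95, i.e. "genotyped in less than 95%" fails).
#' @return list(genotypes, report).
#' @export
call_rate_filter <- function(gm, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(gm$calls) == 0L || ncol(gm$calls) == 0L) stop("empty matrix")
  rate <- colMeans(!is.na(gm$calls))
  removed <- colnames(gm$calls)[rate < threshold]
  rep <- new_qc_report("call_rate", removed,
                       data.frame(marker_id = colnames(gm$calls),
                                  call_rate = unname(rate)),
                       list(threshold = threshold))
  list(genotypes = drop_markers(gm, removed), report = rep)
}

#' Remove markers with frequent parent/offspring conflicts
#'
#' A conflict is an opposing-homozygote pair: parent 0 with child 2 or
#' parent 2 with child 0 — the only two of the nine parent/child genotype
#' combinations that are Mendelian-impossible at a biallelic marker. Pairs
#' where either call is missing are excluded from the denominator.
#'
#' @param gm a [geno_matrix()].
#' @param ped a [pedigree()]; only parents present in the matrix are
#'   tested.
#' @param max_conflict_rate markers whose conflict rate over tested pairs
#'   exceeds this are removed (default 0.10).
#' @return list(genotypes, report). When no parent/offspring pair is
#'   available the rule is skipped (reported in the `note`).
#' @export
mendelian_conflict_filter <- function(gm, ped, max_conflict_rate = 0.10) {
  samples <- rownames(gm$calls)
  pairs <- list()
  for (i in seq_len(nrow(ped))) {
    child <- ped$id[i]
    if (!child %in% samples) next
    for (p in c(ped$sire[i], ped$dam[i]))
      if (!is.na(p) && p %in% samples)
        pairs[[length(pairs) + 1L]] <- c(p, child)
  }
  if (!length(pairs)) {
    rep <- new_qc_report("mendelian_conflict", character(0), NULL,
                         list(max_conflict_rate = max_conflict_rate),
                         note = "no parent/offspring pairs; rule skipped")
    return(list(genotypes = gm, report = rep))
  }
  m <- ncol(gm$calls)
  conflicts <- tested <- numeric(m)
  for (pr in pairs) {
    gp <- gm$calls[pr[1], ]
    gc <- gm$calls[pr[2], ]
    ok <- !is.na(gp) & !is.na(gc)
    tested <- tested + ok
    conflicts <- conflicts +
      (ok & ((gp == 0L & gc == 2L) | (gp == 2L & gc == 0L)))
  }
  rate <- ifelse(tested > 0, conflicts / tested, 0)
  removed <- colnames(gm$calls)[rate > max_conflict_rate]
  rep <- new_qc_report("mendelian_conflict", removed,
                       data.frame(marker_id = colnames(gm$calls),
                                  conflicts = conflicts, tested = tested,
                                  conflict_rate = rate),
                       list(max_conflict_rate = max_conflict_rate,
                            n_pairs = length(pairs)))
  list(genotypes = drop_markers(gm, removed), report = rep)
}

#' Remove markers with unknown or ambiguous map positions
#'
#' Markers with missing chromosome or position are removed; markers
#' sharing a (chr, bp) position are all removed (ambiguity is mutual).
#'
#' @param gm a [geno_matrix()].
#' @return list(genotypes, report).
#' @export
position_filter <- function(gm) {
  map <- gm$map
  unknown <- is.na(map$chr) | is.na(map$bp)
  key <- paste(map$chr, map$bp)
  dup <- !unknown & (duplicated(key) | duplicated(key, fromLast = TRUE))
  removed <- map$marker_id[unknown | dup]
  rep <- new_qc_report("position", removed,
                       data.frame(marker_id = map$marker_id,
                                  unknown_position = unknown,
                                  duplicated_position = dup),
                       list())
  list(genotypes = drop_markers(gm, removed), report = rep)
}

#' Run the full marker QC chain
#'
#' Applies call-rate, Mendelian-conflict and position filters in order
#' and reports, for each rule, the markers it removed (attribution is by
#' first failing rule).
#'
#' @inheritParams call_rate_filter
#' @inheritParams mendelian_conflict_filter
#' @return list(genotypes, reports, summary) of class `qc_result`.
#' @export
run_genotype_qc <- function(gm, ped = NULL, threshold = 0.95,
                            max_conflict_rate = 0.10) {
  n0 <- ncol(gm$calls)
  s1 <- call_rate_filter(gm, threshold)
  s2 <- if (!is.null(ped))
    mendelian_conflict_filter(s1$genotypes, ped, max_conflict_rate)
  else list(genotypes = s1$genotypes,
            report = new_qc_report("mendelian_conflict", character(0), NULL,
                                   list(), note = "no pedigree; skipped"))
  s3 <- position_filter(s2$genotypes)
  reports <- list(call_rate = s1$report, mendelian_conflict = s2$report,
                  position = s3$report)
  removed <- vapply(reports, function(r) length(r$removed), integer(1))
  structure(list(genotypes = s3$genotypes, reports = reports,
                 summary = data.frame(rule = names(removed),
                                      removed = unname(removed)),
                 n_input = n0, n_retained = ncol(s3$genotypes$calls)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Marker QC:", x$n_input, "->", x$n_retained, "markers\n")
  for (r in x$reports) print(r)
  invisible(x)
}
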