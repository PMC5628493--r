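#' Per-residue conservation from a protein multiple alignment
#'
#' Quantifies how conserved a reference residue is across an ortholog
#' alignment, as the fraction of aligned non-gap residues identical to the
#' reference residue in that column (identity score), with Shannon column
#' entropy as secondary evidence. No substitution-matrix weighting is
#' applied: the question asked is identity-level conservation.
#'
#' @name conservation
NULL

check_alignment <- function(aln, ref_id) {
  if (is.null(names(aln)) || !ref_id %in% names(aln))
    stop("reference id '", ref_id, "' not in alignment")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have equal length")
  if (!grepl("[^-]", aln[[ref_id]]))
    stop("reference sequence is all gaps")
  invisible(aln)
}

#' Map a reference residue position to its alignment column
#'
#' @param aln named character vector of aligned sequences (gaps `-`).
#' @param ref_id name of the reference sequence.
#' @param ref_pos 1-based residue index in the ungapped reference.
#' @return Alignment column index holding that residue.
#' @export
ref_position_to_column <- function(aln, ref_id, ref_pos) {
  check_alignment(aln, ref_id)
  res <- strsplit(aln[[ref_id]], "")[[1]]
  nongap <- which(res != "-")
  if (ref_pos < 1L || ref_pos > length(nongap))
    stop("ref_pos ", ref_pos, " outside ungapped reference length ",
         length(nongap))
  nongap[ref_pos]
}

#' Conservation of the alignment column holding a reference residue
#'
#' @inheritParams ref_position_to_column
#' @param threshold identity score at or above which the residue is called
#'   conserved (default 0.9).
#' @param gap_policy `"exclude"` (default): gaps are dropped from both the
#'   numerator and the denominator; `"mismatch"`: gaps count as
#'   mismatching residues in the denominator.
#' @return A one-row data frame: `ref_position`, `column`, `ref_residue`,
#'   `identity_score`, `entropy` (bits), `conserved`, `n_residues`, and
#'   `flagged` (TRUE when all non-reference sequences are gapped so the
#'   score rests on the reference alone).
#' @export
column_conservation <- function(aln, ref_id, ref_pos, threshold = 0.9,
                                gap_policy = c("exclude", "mismatch")) {
  gap_policy <- match.arg(gap_policy)
  col <- ref_position_to_column(aln, ref_id, ref_pos)
  res <- vapply(aln, function(s) substr(s, col, col), character(1))
  ref_res <- res[[ref_id]]
  nongap <- res[res != "-"]
  denom <- if (gap_policy == "exclude") length(nongap) else length(res)
  identity <- sum(nongap == ref_res) / denom
  p <- table(nongap) / length(nongap)
  entropy <- -sum(p * log2(p))
  flagged <- length(nongap) == 1L && length(res) > 1L
  data.frame(ref_position = ref_pos, column = col, ref_residue = ref_res,
             identity_score = identity, entropy = entropy,
             conserved = identity >= threshold,
             n_residues = length(nongap), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Conservation profile over several reference positions
#'
#' @inheritParams column_conservation
#' @param positions vector of reference residue positions.
#' @return Data frame with one row per position (see
#'   [column_conservation()]).
#' @export
conservation_profile <- function(aln, ref_id, positions, threshold = 0.9,
                                 gap_policy = "exclude") {
  do.call(rbind, lapply(positions, function(p)
    column_conservation(aln, ref_id, p, threshold, gap_policy)))
}
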