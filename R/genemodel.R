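#' Transcript gene model
#'
#' Minimal exon/CDS transcript model for coding-consequence annotation.
#' Coordinates are genomic, 1-based inclusive; `exons` are non-overlapping
#' and sorted; the CDS bounds must fall inside the exon union and the
#' spliced CDS length must be divisible by 3.
#'
#' @param transcript_id identifier.
#' @param chr chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame (or 2-column matrix) with `start`, `end`.
#' @param cds_start,cds_end genomic CDS bounds (1-based inclusive;
#'   `cds_start < cds_end` regardless of strand).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(transcript_id, chr, strand, exons, cds_start,
                       cds_end) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  gm <- structure(list(transcript_id = transcript_id, chr = as.character(chr),
                       strand = strand, exons = exons,
                       cds_start = as.integer(cds_start),
                       cds_end = as.integer(cds_end)),
                  class = "gene_model")
  cpos <- cds_genomic_positions(gm)
  if (!length(cpos)) stop("CDS bounds outside exon union")
  if (!all(c(cds_start, cds_end) %in% cpos))
    stop("CDS bounds outside exon union")
  if (length(cpos) %% 3L != 0L)
    stop("spliced CDS length (", length(cpos), ") not divisible by 3")
  gm
}

# genomic positions of CDS bases in genomic (ascending) order
cds_genomic_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq.int(model$exons$start[i], model$exons$end[i])
  }))
  pos[pos >= model$cds_start & pos <= model$cds_end]
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model", x$transcript_id, "on", x$chr, "strand", x$strand,
      "\n  exons:", nrow(x$exons),
      " CDS:", x$cds_start, "-", x$cds_end,
      "(", length(cds_genomic_positions(x)) / 3, "codons )\n")
  invisible(x)
}

#' Genome sequence source
#'
#' Wraps one or more chromosome (sub)sequences with an offset, so a small
#' region of a large chromosome can serve as the reference without storing
#' the whole chromosome. `genome_fetch()` returns bases by genomic
#' coordinate.
#'
#' @param sequences named list/character vector of sequences (names =
#'   chromosomes).
#' @param offsets named integer vector: genomic coordinate of base 1 of
#'   each sequence (default 1 for all).
#' @return Object of class `genome_seq`.
#' @export
genome_seq <- function(sequences, offsets = NULL) {
  sequences <- as.list(sequences)
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by chromosome")
  if (is.null(offsets)) offsets <- stats::setNames(
    rep(1L, length(sequences)), names(sequences))
  structure(list(seq = lapply(sequences, toupper),
                 offset = offsets[names(sequences)]),
            class = "genome_seq")
}

#' @rdname genome_seq
#' @param genome a `genome_seq`.
#' @param chr chromosome.
#' @param start,end genomic coordinates (1-based inclusive).
#' @export
genome_fetch <- function(genome, chr, start, end) {
  if (!chr %in% names(genome$seq))
    stop("chromosome '", chr, "' not in genome source")
  off <- genome$offset[[chr]]
  s <- start - off + 1L
  e <- end - off + 1L
  if (s < 1L || e > nchar(genome$seq[[chr]]))
    stop("coordinates ", start, "-", end, " outside genome source for ", chr)
  substr(genome$seq[[chr]], s, e)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("untranslatable codon: ", codon)
  aa
}

#' Random toy gene with matching genome, for annotator validation
#'
#' Generates a random transcript model (1-5 exons, either strand) embedded
#' in a random sequence, used to validate the consequence annotator against
#' full-CDS re-translation.
#'
#' @param seed integer seed.
#' @param chr chromosome label.
#' @param max_exons maximum exon count.
#' @return list(model, genome, cds_positions).
#' @export
random_gene_bundle <- function(seed = 1L, chr = "T", max_exons = 5L) {
  set.seed(seed)
  n_ex <- sample.int(max_exons, 1L)
  cur <- sample.int(50L, 1L)
  starts <- ends <- integer(n_ex)
  for (i in seq_len(n_ex)) {
    starts[i] <- cur
    ends[i] <- cur + sample(30:120, 1L)
    cur <- ends[i] + sample(10:60, 1L)
  }
  pos <- unlist(lapply(seq_len(n_ex), function(i) starts[i]:ends[i]))
  # pick CDS bounds on exonic bases so the spliced length is a codon multiple
  repeat {
    bounds <- sort(sample(pos, 2L))
    inside <- pos[pos >= bounds[1] & pos <= bounds[2]]
    if (length(inside) >= 9L && length(inside) %% 3L == 0L) break
  }
  strand <- sample(c("+", "-"), 1L)
  model <- gene_model(paste0("toy", seed), chr, strand,
                      data.frame(start = starts, end = ends),
                      bounds[1], bounds[2])
  glen <- max(ends) + 20L
  seqc <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                collapse = "")
  genome <- genome_seq(stats::setNames(list(seqc), chr))
  list(model = model, genome = genome,
       cds_positions = cds_genomic_positions(model))
}
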