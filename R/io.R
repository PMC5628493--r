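#' File formats
#'
#' Readers/writers for the plain-text formats used between pipeline
#' stages: pedigree TSV, genotypes as wide TSV or PED/MAP pair, minimal
#' VCFv4.2 (GT-only; panel as site-list with INFO AC/AN), candidate
#' regions as 1-based TSV or 0-based half-open BED, genome/alignment
#' FASTA. VCF parsing is backed by vcfR.
#'
#' @name io
NULL

#' @rdname io
#' @param ped a [pedigree()].
#' @param path output file.
#' @export
write_pedigree_tsv <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_pedigree_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "")
  validate_pedigree(df)
}

#' @rdname io
#' @param gm a [geno_matrix()].
#' @export
write_genotypes_tsv <- function(gm, path) {
  df <- data.frame(sample_id = rownames(gm$calls), gm$calls,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  map_path <- paste0(path, ".map")
  utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(path, map_path))
}

#' @rdname io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  map <- utils::read.table(paste0(path, ".map"), sep = "\t", header = TRUE,
                           colClasses = c(marker_id = "character",
                                          chr = "character"))
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$sample_id
  geno_matrix(calls, map)
}

#' @rdname io
#' @param prefix output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @details PED/MAP follows the PLINK text convention: the MAP file has
#'   chromosome, marker id, cM and bp columns; the PED file has family,
#'   individual, sire, dam, sex (1=M/2=F), phenotype (2=affected,
#'   1=unaffected) and two allele columns per marker (`0 0` = missing).
#' @export
write_ped_map <- function(gm, ped, prefix) {
  map <- gm$map
  cM <- if ("cM" %in% names(map)) map$cM else 0
  utils::write.table(
    data.frame(chr = ifelse(is.na(map$chr), 0, map$chr),
               id = map$marker_id, cM = ifelse(is.na(map$bp), 0, cM),
               bp = ifelse(is.na(map$bp), 0, map$bp)),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- rownames(gm$calls)
  pi <- match(ids, ped$id)
  alleles <- matrix("0", nrow = length(ids), ncol = 2L * ncol(gm$calls))
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$alt[j], map$ref[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$alt[j], map$ref[j]))
    alleles[, 2L * j - 1L] <- a1
    alleles[, 2L * j] <- a2
  }
  lead <- data.frame(fid = "FAM1", iid = ids,
                     pat = ifelse(is.na(ped$sire[pi]), "0", ped$sire[pi]),
                     mat = ifelse(is.na(ped$dam[pi]), "0", ped$dam[pi]),
                     sex = ifelse(ped$sex[pi] == "M", 1L, 2L),
                     pheno = ifelse(ped$role[pi] == "case", 2L, 1L))
  utils::write.table(cbind(lead, alleles), paste0(prefix, ".ped"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' @rdname io
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chr", "marker_id", "cM", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  pedf <- utils::read.table(paste0(prefix, ".ped"), sep = " ",
                            colClasses = "character")
  m <- nrow(map)
  ids <- pedf[[2]]
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = m,
                  dimnames = list(ids, map$marker_id))
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    a1 <- pedf[[6L + 2L * j - 1L]]
    a2 <- pedf[[6L + 2L * j]]
    obs <- sort(unique(c(a1, a2)))
    obs <- obs[obs != "0"]
    ref[j] <- if (length(obs)) obs[1] else "A"
    alt[j] <- if (length(obs) > 1L) obs[2] else "N"
    g <- (a1 == alt[j]) + (a2 == alt[j])
    g[a1 == "0" | a2 == "0"] <- NA
    calls[, j] <- as.integer(g)
  }
  map$chr[map$chr == "0"] <- NA
  map$bp[map$bp == 0L] <- NA
  map$ref <- ref
  map$alt <- alt
  geno_matrix(calls, map[, c("marker_id", "chr", "bp", "cM", "ref", "alt")])
}

#' @rdname io
#' @param tab a [variant_table()].
#' @export
write_vcf <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  v <- tab$variants
  if (is.null(tab$gt)) {
    ac <- if ("ac" %in% names(v)) v$ac else 0L
    an <- if ("an" %in% names(v)) v$an else 0L
    writeLines(c("##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
                 "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total alleles\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%d;AN=%d",
                       v$chr, v$pos, v$ref, v$alt, ac, an), con)
  } else {
    samples <- colnames(tab$gt)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"), con)
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (i in seq_len(nrow(v))) {
      gt <- tab$gt[i, ]
      gts <- ifelse(is.na(gt), "./.", code[as.character(gt)])
      writeLines(paste(c(v$chr[i], v$pos[i], ".", v$ref[i], v$alt[i],
                         ".", ".", ".", "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname io
#' @details Multi-allelic VCF records are split into one biallelic record
#'   per alternative allele on input; genotypes then count copies of that
#'   allele.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- if (ncol(vcf@gt) > 1L) vcf@gt[, -1, drop = FALSE] else NULL
  rows <- list()
  gts <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chr = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      if (!is.null(gt_raw)) {
        g <- sub(":.*", "", gt_raw[i, ])
        cnt <- vapply(strsplit(g, "[/|]"), function(a) {
          if (any(a == ".")) return(NA_integer_)
          sum(a == as.character(k))
        }, integer(1))
        gts[[length(gts) + 1L]] <- cnt
      }
    }
  }
  variants <- do.call(rbind, rows)
  gt <- if (length(gts)) {
    mat <- do.call(rbind, gts)
    colnames(mat) <- colnames(gt_raw)
    mat
  } else NULL
  variant_table(variants, gt)
}

#' @rdname io
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chr = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ac = integer(0), an = integer(0)))
  if (ncol(vcf@gt) > 1L) {
    tab <- read_vcf(path)
    return(data.frame(tab$variants,
                      ac = rowSums(tab$gt, na.rm = TRUE),
                      an = rowSums(!is.na(tab$gt)) * 2L))
  }
  getinfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[0-9]+"), info))
    as.integer(sub(paste0(key, "="), "", m))
  }
  data.frame(chr = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT,
             ac = vapply(fix$INFO, getinfo, integer(1), key = "AC"),
             an = vapply(fix$INFO, getinfo, integer(1), key = "AN"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param regions an `autozyg_regions` data frame.
#' @export
write_regions_tsv <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_regions_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(chr = "character"))
}

#' @rdname io
#' @details BED output converts the 1-based inclusive region coordinates
#'   to BED's 0-based half-open convention: `chromStart = start_bp - 1`,
#'   `chromEnd = end_bp`.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chr, chromStart = regions$start_bp - 1L,
                   chromEnd = regions$end_bp)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param genome a [genome_seq()].
#' @details Genome FASTA headers carry the offset as `chr:offset` so a
#'   sub-chromosomal reference slice round-trips.
#' @export
write_genome_fasta <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(genome$seq)) {
    writeLines(paste0(">", ch, ":", genome$offset[[ch]]), con)
    s <- genome$seq[[ch]]
    starts <- seq.int(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  has_off <- grepl(":", nm)
  chr <- ifelse(has_off, sub(":.*", "", nm), nm)
  off <- ifelse(has_off, as.integer(sub(".*:", "", nm)), 1L)
  genome_seq(stats::setNames(as.list(as.character(ss)), chr),
             stats::setNames(as.integer(off), chr))
}

#' @rdname io
#' @param aln named character vector of aligned protein sequences.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln)) writeLines(c(paste0(">", nm), aln[[nm]]), con)
  invisible(path)
}

#' @rdname io
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname io
#' @param models list of [gene_model()]s.
#' @details Gene models are serialized as a GFF-like TSV: one exon row per
#'   line plus a CDS row carrying the CDS bounds.
#' @export
write_gene_models_tsv <- function(models, path) {
  rows <- lapply(models, function(m) {
    rbind(data.frame(transcript_id = m$transcript_id, chr = m$chr,
                     strand = m$strand, feature = "exon",
                     start = m$exons$start, end = m$exons$end),
          data.frame(transcript_id = m$transcript_id, chr = m$chr,
                     strand = m$strand, feature = "CDS",
                     start = m$cds_start, end = m$cds_end))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_gene_models_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(transcript_id = "character",
                                         chr = "character"))
  lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$feature == "exon", ]
    cds <- d[d$feature == "CDS", ]
    gene_model(d$transcript_id[1], d$chr[1], d$strand[1],
               ex[, c("start", "end")], cds$start, cds$end)
  })
}
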