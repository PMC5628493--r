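# Shared fixtures and independent oracles used across the test files.
# The oracles are deliberately naive re-implementations written straight
# from the selection criteria, kept independent of the package internals
# they check.

# quick genotype-matrix constructor
make_gm <- function(calls, chr = "1", bp = NULL, sample_ids = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(sample_ids)) rownames(calls) <- sample_ids
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  if (is.null(bp)) bp <- seq_len(ncol(calls)) * 1000L
  colnames(calls) <- sprintf("m%04d", seq_len(ncol(calls)))
  map <- data.frame(marker_id = colnames(calls),
                    chr = rep_len(chr, ncol(calls)), bp = bp,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno_matrix(calls, map)
}

# ---- exhaustive sliding-window oracle -------------------------------------

oracle_window_ok <- function(G, cols, roles, policy) {
  cases <- names(roles)[roles == "case"]
  carriers <- names(roles)[roles == "obligate_carrier"]
  controls <- names(roles)[roles == "control"]
  if (policy == "fail_window" &&
      anyNA(G[c(cases, carriers, controls), cols])) return(FALSE)
  hap <- rep(NA_integer_, length(cols))
  for (j in seq_along(cols)) {
    g <- G[cases, cols[j]]
    if (anyNA(g) && policy != "compatible") return(FALSE)
    gn <- g[!is.na(g)]
    if (any(gn == 1L)) return(FALSE)
    if (length(unique(gn)) > 1L) return(FALSE)
    if (length(gn)) hap[j] <- gn[1]
  }
  classify <- function(s) {
    g <- G[s, cols]
    keep <- !is.na(hap)
    if (policy == "compatible") keep <- keep & !is.na(g)
    g2 <- g[keep]; h2 <- hap[keep]
    if (!length(g2)) return("carrier")
    if (anyNA(g2)) return("non_carrier")  # incompatible policy
    if (all(g2 == h2)) return("homozygous_carrier")
    if (all(ifelse(h2 == 2L, g2 >= 1L, g2 <= 1L))) return("carrier")
    "non_carrier"
  }
  for (s in carriers) if (classify(s) != "carrier") return(FALSE)
  for (s in controls) if (classify(s) == "homozygous_carrier") return(FALSE)
  TRUE
}

oracle_regions <- function(gm, roles, w, step = 1L,
                           policy = "compatible") {
  G <- gm$calls
  map <- gm$map
  out <- NULL
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    idx <- idx[order(map$bp[idx])]
    m <- length(idx)
    if (m < w) next
    covered <- rep(FALSE, m)
    for (s in seq(1L, m - w + 1L, by = step)) {
      if (oracle_window_ok(G, idx[s:(s + w - 1L)], roles, policy))
        covered[s:(s + w - 1L)] <- TRUE
    }
    r <- rle(covered)
    e <- cumsum(r$lengths)
    b <- e - r$lengths + 1L
    for (k in which(r$values)) {
      out <- rbind(out, data.frame(
        chr = ch, start_bp = map$bp[idx][b[k]], end_bp = map$bp[idx][e[k]],
        n_snps = e[k] - b[k] + 1L, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(chr = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0))
  out[order(out$chr, out$start_bp), , drop = FALSE]
}

# random structured fixture: unconstrained genotypes plus planted shared
# homozygous case segments so both consistent and inconsistent windows occur
random_scan_fixture <- function(seed, n_snps = 120L, n_samples = 12L,
                                na_rate = 0.03) {
  set.seed(seed)
  roles <- c(rep("case", 2L), rep("obligate_carrier", 2L),
             rep("control", n_samples - 5L), "unknown")
  names(roles) <- sprintf("s%02d", seq_len(n_samples))
  q <- runif(n_snps, 0.1, 0.9)
  G <- t(replicate(n_samples, rbinom(n_snps, 2L, q)))
  rownames(G) <- names(roles)
  nseg <- sample(0:3, 1L)
  for (k in seq_len(nseg)) {
    len <- sample(5:40, 1L)
    a <- sample(n_snps - len, 1L)
    span <- a:(a + len - 1L)
    hap <- 2L * rbinom(len, 1L, 0.5)
    G[roles == "case", span] <- matrix(hap, nrow = 2L, ncol = len,
                                       byrow = TRUE)
    G[roles == "obligate_carrier", span] <- 1L
  }
  G[matrix(runif(length(G)), nrow(G)) < na_rate] <- NA_integer_
  list(gm = make_gm(G, chr = sample(c("1", "2"), 1L)), roles = roles)
}

# ---- full-CDS re-translation oracle for the annotator ---------------------

oracle_consequence <- function(model, genome, pos, alt) {
  seqc <- genome$seq[[model$chr]]
  off <- genome$offset[[model$chr]]
  cds_pos <- integer(0)
  for (i in seq_len(nrow(model$exons)))
    cds_pos <- c(cds_pos, model$exons$start[i]:model$exons$end[i])
  cds_pos <- cds_pos[cds_pos >= model$cds_start & cds_pos <= model$cds_end]
  base_at <- function(s, p) substr(s, p - off + 1L, p - off + 1L)
  ref_cds <- paste(vapply(cds_pos, base_at, character(1), s = seqc),
                   collapse = "")
  mut <- seqc
  substr(mut, pos - off + 1L, pos - off + 1L) <- alt
  alt_cds <- paste(vapply(cds_pos, base_at, character(1), s = mut),
                   collapse = "")
  if (model$strand == "-") {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    ref_cds <- rc(ref_cds)
    alt_cds <- rc(alt_cds)
  }
  tr <- function(x) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE)), "")[[1]]
  p_ref <- tr(ref_cds)
  p_alt <- tr(alt_cds)
  d <- which(p_ref != p_alt)
  if (!length(d)) return(list(consequence = "synonymous"))
  stopifnot(length(d) == 1L)
  cls <- if (p_alt[d] == "*") "stop_gained"
  else if (p_ref[d] == "*") "stop_lost"
  else "missense"
  list(consequence = cls, aa_pos = d, ref_aa = p_ref[d], alt_aa = p_alt[d])
}

# random coding SNV inside a toy gene bundle
random_cds_snv <- function(bundle) {
  pos <- sample(bundle$cds_positions, 1L)
  ref <- genome_fetch(bundle$genome, bundle$model$chr, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(pos = pos, ref = ref, alt = alt)
}

# error-free simulation configuration used by recovery-style checks
errorfree_config <- function(seed, ...) {
  sim_config(seed = seed, genotype_error_rate = 0, conflict_error_rate = 0,
             ...)
}

# truth-haplotype consistency condition for recovery checks: a run of at
# least `w` consecutive retained markers spanning the causal position on
# which all four case haplotypes are identical by descent from the carrier
# founder haplotype and every obligate carrier still carries it
truth_window_condition <- function(bundle, qc_gm, w = 40L) {
  truth <- bundle$truth
  ped <- bundle$ped
  hap_row <- truth$carrier_hap_row
  cols <- match(colnames(qc_gm$calls), truth$loci$id)
  cols <- cols[!is.na(cols)]
  cols <- cols[truth$loci$chr[cols] == bundle$config$causal_chr]
  cols <- cols[order(truth$loci$bp[cols])]
  if (length(cols) < w) return(FALSE)
  hap_rows_of <- function(id) {
    i <- match(id, ped$id)
    c(2L * i - 1L, 2L * i)
  }
  ok <- rep(TRUE, length(cols))
  for (a in ped$id[ped$role == "case"]) {
    r <- hap_rows_of(a)
    ok <- ok & truth$O[r[1], cols] == hap_row &
      truth$O[r[2], cols] == hap_row
  }
  for (k in ped$id[ped$role == "obligate_carrier"]) {
    r <- hap_rows_of(k)
    ok <- ok & (truth$O[r[1], cols] == hap_row |
                  truth$O[r[2], cols] == hap_row)
  }
  bp <- truth$loci$bp[cols]
  causal <- bundle$config$causal_bp
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    if (ends[j] - starts[j] + 1L >= w &&
        bp[starts[j]] <= causal && bp[ends[j]] >= causal) return(TRUE)
  }
  FALSE
}

# opposing-homozygote conflict count over all parent/offspring pairs
count_mendel_conflicts <- function(gm, ped) {
  n <- 0L
  for (i in seq_len(nrow(ped))) {
    child <- ped$id[i]
    if (!child %in% rownames(gm$calls)) next
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (is.na(p) || !p %in% rownames(gm$calls)) next
      gp <- gm$calls[p, ]; gc <- gm$calls[child, ]
      n <- n + sum((gp == 0L & gc == 2L) | (gp == 2L & gc == 0L),
                   na.rm = TRUE)
    }
  }
  n
}
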