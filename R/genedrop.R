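#' Draw crossover positions for one meiosis (Haldane model)
#'
#' Crossover count is Poisson with mean equal to the chromosome length in
#' Morgans; positions are uniform on the cM scale. No interference.
#'
#' @param length_cM chromosome genetic length in cM.
#' @return Sorted numeric vector of crossover positions (cM), possibly
#'   empty.
#' @export
draw_crossovers <- function(length_cM) {
  if (length_cM <= 0) return(numeric(0))
  n <- stats::rpois(1L, length_cM / 100)
  sort(stats::runif(n, 0, length_cM))
}

# Transmit one gamete: for each locus (cM positions, sorted), which of the
# parent's two haplotypes it is copied from (1 or 2).
meiosis_source <- function(cM) {
  xo <- draw_crossovers(max(cM) - min(cM))
  start <- sample(1:2, 1L)
  if (!length(xo)) return(rep.int(start, length(cM)))
  # number of crossovers to the left of each locus flips the source
  nleft <- findInterval(cM - min(cM), xo)
  src <- ifelse(nleft %% 2L == 0L, start, 3L - start)
  as.integer(src)
}

#' Drop founder haplotypes through a pedigree
#'
#' Forward simulation of allele transmission (gene dropping): founder
#' haplotypes are drawn marker-wise from founder allele frequencies, then
#' passed down through each meiosis under the Haldane model (crossover
#' count Poisson on the cM scale, positions uniform, no interference).
#' Besides alleles, each transmitted haplotype carries founder-of-origin
#' labels, giving exact identity-by-descent ground truth.
#'
#' @param ped a [pedigree()].
#' @param map a [genetic_map()] of array markers.
#' @param founder_freqs alternative-allele frequency per marker (length
#'   `nrow(map)`); founder haplotype alleles are Bernoulli draws from these.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param extra_positions optional data frame (`chr`, `bp`) of additional
#'   loci (e.g. causal sites) tracked alongside the markers; founders carry
#'   the reference allele there until [seed_causal_allele()] places the
#'   mutation.
#' @return An object of class `sim_truth`: a list with the pedigree, the
#'   locus table (`loci`: chr, bp, cM, type marker/extra), an allele matrix
#'   `H` (2 rows per individual x loci, 0/1 alternative-allele indicator)
#'   and an origin matrix `O` of the same shape holding founder haplotype
#'   row indices.
#' @export
gene_drop <- function(ped, map, founder_freqs, seed = 1L,
                      extra_positions = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!inherits(map, "genetic_map") || nrow(map) == 0L) stop("empty map")
  if (length(founder_freqs) != nrow(map))
    stop("founder_freqs length must equal number of markers")
  rate <- attr(map, "rate_cM_per_Mb")
  if (is.null(rate)) rate <- 1.0

  loci <- data.frame(chr = map$chr, bp = map$bp, cM = map$cM,
                     type = "marker", id = map$marker_id,
                     stringsAsFactors = FALSE)
  freqs <- as.numeric(founder_freqs)
  if (!is.null(extra_positions) && nrow(extra_positions)) {
    ex <- data.frame(chr = as.character(extra_positions$chr),
                     bp = as.integer(extra_positions$bp),
                     cM = extra_positions$bp / 1e6 * rate,
                     type = "extra",
                     id = sprintf("X%03d", seq_len(nrow(extra_positions))),
                     stringsAsFactors = FALSE)
    loci <- rbind(loci, ex)
    freqs <- c(freqs, rep(0, nrow(ex)))
  }
  ord <- order(loci$chr, loci$bp)
  loci <- loci[ord, , drop = FALSE]
  freqs <- freqs[ord]
  rownames(loci) <- NULL

  set.seed(seed)
  truth <- drop_transmissions(ped, loci, freqs, constraints = NULL)
  truth
}

# Core sampler shared by gene_drop() and seed_causal_allele(): samples
# founder haplotypes (or reuses `founder_H`), then transmits in topological
# order. `constraints` is NULL or a list(check = function(ind_idx, H, O) ...)
# used for local rejection (see seed_causal_allele).
drop_transmissions <- function(ped, loci, freqs, constraints = NULL,
                               founder_H = NULL, local_cap = 10000L) {
  n <- nrow(ped)
  L <- nrow(loci)
  H <- matrix(0L, nrow = 2L * n, ncol = L)
  O <- matrix(0L, nrow = 2L * n, ncol = L)
  rownames(H) <- rownames(O) <- paste0(rep(ped$id, each = 2L), ".", 1:2)
  hap_rows <- function(id) {
    i <- match(id, ped$id)
    c(2L * i - 1L, 2L * i)
  }
  chr_split <- split(seq_len(L), loci$chr)

  # founders
  fids <- founders(ped)
  for (f in fids) {
    r <- hap_rows(f)
    if (!is.null(founder_H)) {
      H[r, ] <- founder_H[r, ]
    } else {
      H[r[1], ] <- stats::rbinom(L, 1L, freqs)
      H[r[2], ] <- stats::rbinom(L, 1L, freqs)
    }
    O[r[1], ] <- r[1]
    O[r[2], ] <- r[2]
  }

  transmit <- function(parent_id) {
    pr <- hap_rows(parent_id)
    hap <- integer(L)
    org <- integer(L)
    for (idx in chr_split) {
      src <- meiosis_source(loci$cM[idx])
      take <- pr[src]
      hap[idx] <- H[cbind(take, idx)]
      org[idx] <- O[cbind(take, idx)]
    }
    list(hap = hap, org = org)
  }

  order_ids <- topo_order(ped)
  for (id in order_ids) {
    i <- match(id, ped$id)
    if (is.na(ped$sire[i])) next  # founder
    r <- hap_rows(id)
    tries <- 0L
    repeat {
      gs <- transmit(ped$sire[i])
      gd <- transmit(ped$dam[i])
      H[r[1], ] <- gs$hap; O[r[1], ] <- gs$org
      H[r[2], ] <- gd$hap; O[r[2], ] <- gd$org
      if (is.null(constraints) || constraints$check(i, H, O)) break
      tries <- tries + 1L
      if (tries >= local_cap)
        stop("constraint for individual '", id,
             "' not satisfied after ", local_cap, " transmission samples; ",
             "pedigree structure incompatible with required copy numbers")
    }
  }

  structure(list(ped = ped, loci = loci, founder_freqs = freqs,
                 H = H, O = O),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Gene-dropped haplotypes:", nrow(x$ped), "individuals x",
      nrow(x$loci), "loci (", sum(x$loci$type == "marker"), "markers )\n")
  if (!is.null(x$carrier_founder))
    cat("Causal allele seeded on founder", x$carrier_founder,
        "haplotype; copy counts:",
        paste(sprintf("%s=%d", names(x$causal_copies), x$causal_copies)[
          x$causal_copies > 0], collapse = ", "), "\n")
  invisible(x)
}

#' Causal copy counts at a locus, from founder-origin labels
#'
#' @param truth a `sim_truth`.
#' @param locus_col column index into `truth$loci`.
#' @param origin_row founder haplotype row carrying the causal allele.
#' @return Named integer vector (per individual) of causal copies (0/1/2).
#' @export
causal_copy_counts <- function(truth, locus_col, origin_row) {
  n <- nrow(truth$ped)
  o <- truth$O[, locus_col]
  counts <- (o[2 * seq_len(n) - 1L] == origin_row) +
    (o[2 * seq_len(n)] == origin_row)
  stats::setNames(as.integer(counts), truth$ped$id)
}

#' Seed a recessive causal allele on a founder haplotype
#'
#' Places the causal mutation on one haplotype of an ancestral carrier
#' founder, then re-samples transmissions by rejection until the pedigree
#' roles are honoured at the causal site and at the linked second site:
#' every `case` carries 2 copies, every `obligate_carrier` exactly 1, and
#' every `control` at most 1. Rejection is applied per individual in
#' topological order (each constrained individual's own two meioses are
#' re-drawn until its copy number is correct), preserving exchangeability
#' of the rest of the genome; founder haplotypes are kept fixed.
#'
#' @param truth output of [gene_drop()] run with the causal positions in
#'   `extra_positions`.
#' @param ped the pedigree (defaults to `truth$ped`).
#' @param config a [sim_config()]; supplies the causal position, the linked
#'   offset and optionally `carrier_founder`.
#' @return A new `sim_truth` with fields `carrier_founder`,
#'   `carrier_hap_row`, `causal_cols` and `causal_copies` added.
#' @export
seed_causal_allele <- function(truth, ped = truth$ped, config) {
  loci <- truth$loci
  pos1 <- config$causal_bp
  pos2 <- config$causal_bp + config$linked_variant_offset_bp
  c1 <- which(loci$chr == config$causal_chr & loci$bp == pos1)
  c2 <- which(loci$chr == config$causal_chr & loci$bp == pos2)
  if (length(c1) != 1L || length(c2) != 1L)
    stop("causal positions not present in truth loci; run gene_drop() with ",
         "extra_positions covering them")

  founder_id <- config$carrier_founder
  if (is.null(founder_id)) {
    need <- ped$id[ped$role %in% c("case", "obligate_carrier")]
    cand <- Filter(function(f) {
      all(vapply(need, function(x) f %in% ancestors(ped, x) || f == x,
                 logical(1)))
    }, founders(ped))
    cand <- cand[ped$role[match(cand, ped$id)] != "control"]
    if (!length(cand))
      stop("no non-control founder is ancestral to all cases and obligate ",
           "carriers; cannot place causal allele")
    founder_id <- cand[[1]]
  }
  fi <- match(founder_id, ped$id)
  if (is.na(fi) || !founder_id %in% founders(ped))
    stop("carrier founder '", founder_id, "' is not a pedigree founder")
  hap_row <- 2L * fi - 1L

  # feasibility: every constrained individual must have a parental path to
  # the carrier founder
  constrained <- ped$id[ped$role %in% c("case", "obligate_carrier")]
  for (x in setdiff(constrained, founder_id)) {
    if (!founder_id %in% ancestors(ped, x))
      stop("individual '", x, "' has role ", ped$role[match(x, ped$id)],
           " but no carrier path to founder '", founder_id, "'")
  }

  founder_H <- truth$H
  founder_H[hap_row, c(c1, c2)] <- 1L
  # other founder haplotypes stay reference at the causal sites (enforced
  # at gene_drop time via zero frequency on extra loci)

  required <- c(case = 2L, obligate_carrier = 1L)
  check <- function(i, H, O) {
    role <- ped$role[i]
    rows <- c(2L * i - 1L, 2L * i)
    cnt1 <- sum(O[rows, c1] == hap_row)
    cnt2 <- sum(O[rows, c2] == hap_row)
    if (role %in% names(required))
      return(cnt1 == required[[role]] && cnt2 == required[[role]])
    if (role == "control") return(cnt1 <= 1L && cnt2 <= 1L)
    TRUE
  }

  out <- drop_transmissions(ped, loci, truth$founder_freqs,
                            constraints = list(check = check),
                            founder_H = founder_H)
  out$carrier_founder <- founder_id
  out$carrier_hap_row <- hap_row
  out$causal_cols <- c(c1, c2)
  out$causal_copies <- causal_copy_counts(out, c1, hap_row)
  out
}
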