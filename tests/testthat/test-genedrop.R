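trio <- pedigree(c("f", "m", "o"), sire = c(NA, NA, "f"),
                 dam = c(NA, NA, "m"), sex = c("M", "F", "F"),
                 role = c("unknown", "unknown", "unknown"))

test_that("a zero-length map transmits intact parental haplotypes", {
  map <- genetic_map(chr = "1", bp = seq(1000, 10000, by = 1000),
                     cM = rep(0, 10))
  truth <- gene_drop(trio, map, founder_freqs = runif(10), seed = 11)
  for (h in 5:6) {  # offspring haplotype rows
    parent_rows <- if (h == 5) 1:2 else 3:4
    matches <- vapply(parent_rows, function(r)
      identical(truth$H[h, ], truth$H[r, ]) &&
        all(truth$O[h, ] == r), logical(1))
    expect_true(any(matches))
  }
})

test_that("fixed founder frequencies fix the genotypes", {
  map <- genetic_map(chr = "1", bp = c(1e6, 2e6, 3e6))
  truth <- gene_drop(trio, map, founder_freqs = c(1, 0, 1), seed = 2)
  expect_true(all(truth$H[, 1] == 1L))
  expect_true(all(truth$H[, 2] == 0L))
  expect_true(all(truth$H[, 3] == 1L))
})

test_that("crossover counts follow the Poisson mean of the map length", {
  set.seed(42)
  counts <- replicate(10000, length(draw_crossovers(100)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1.0), 3 * se)
})

test_that("gene dropping is reproducible for a fixed seed", {
  map <- genetic_map(chr = "1", bp = seq(1e6, 50e6, length.out = 100))
  f <- runif(100)
  t1 <- gene_drop(build_default_pedigree(5), map, f, seed = 99)
  t2 <- gene_drop(build_default_pedigree(5), map, f, seed = 99)
  expect_identical(t1$H, t2$H)
  expect_identical(t1$O, t2$O)
})

test_that("gene drop rejects an empty map", {
  expect_error(genetic_map(chr = character(0), bp = integer(0)), "empty")
})

test_that("seeded causal allele honours every role's copy number", {
  for (seed in c(3, 17, 51)) {
    cfg <- sim_config(seed = seed)
    b <- simulate_dataset(cfg)
    ped <- b$ped
    copies <- b$truth$causal_copies
    expect_true(all(copies[ped$id[ped$role == "case"]] == 2L))
    expect_true(all(copies[ped$id[ped$role == "obligate_carrier"]] == 1L))
    expect_true(all(copies[ped$id[ped$role == "control"]] <= 1L))
    # controls unrelated to the carrier founder carry nothing
    expect_identical(unname(copies["US1"]), 0L)
    # both case haplotypes at the causal site descend from the carrier
    # founder haplotype (autozygous by descent)
    for (a in ped$id[ped$role == "case"]) {
      i <- match(a, ped$id)
      expect_true(all(b$truth$O[c(2 * i - 1, 2 * i),
                                b$truth$causal_cols[1]] ==
                        b$truth$carrier_hap_row))
    }
  }
})

test_that("an impossible role configuration is rejected with a diagnostic", {
  # case whose parents have no path to the carrier founder
  ped <- pedigree(c("F1", "u1", "u2", "kid"),
                  sire = c(NA, NA, NA, "u1"), dam = c(NA, NA, NA, "u2"),
                  sex = c("M", "M", "F", "M"),
                  role = c("unknown", "unknown", "unknown", "case"))
  map <- genetic_map(chr = "20", bp = seq(1e6, 50e6, length.out = 50))
  cfg <- sim_config(seed = 1, n_markers = 50, carrier_founder = "F1")
  truth <- gene_drop(ped, map, runif(50), seed = 1,
                     extra_positions = data.frame(
                       chr = "20", bp = c(cfg$causal_bp,
                                          cfg$causal_bp + 34342)))
  expect_error(seed_causal_allele(truth, ped, cfg), "carrier path")
})

test_that("IBD segments around the causal site shrink with pedigree depth", {
  # chains of increasing meiosis count between founder and proband
  make_chain <- function(depth) {
    ids <- c("F0", paste0("W", 1:depth), paste0("G", 1:depth))
    gsires <- if (depth > 1) paste0("G", 1:(depth - 1)) else character(0)
    sire <- c(NA, rep(NA, depth), "F0", gsires)
    dam <- c(NA, rep(NA, depth), paste0("W", 1:depth))
    sex <- c("M", rep("F", depth), rep("M", depth))
    pedigree(ids, sire, dam, sex, "unknown")
  }
  map <- genetic_map(chr = "1", bp = seq(1e5, 100e6, length.out = 200))
  seg_len <- function(truth, probe_row) {
    o <- truth$O[probe_row, ]
    mid <- 100L  # probe around the map centre
    run <- o == o[mid]
    left <- mid
    while (left > 1L && run[left - 1L]) left <- left - 1L
    right <- mid
    while (right < length(run) && run[right + 1L]) right <- right + 1L
    truth$loci$bp[right] - truth$loci$bp[left]
  }
  mean_len <- sapply(c(1L, 3L, 6L), function(depth) {
    ped <- make_chain(depth)
    probe <- 2L * match(paste0("G", depth), ped$id) - 1L
    lens <- vapply(1:200, function(s) {
      truth <- gene_drop(ped, map, rep(0.5, 200), seed = 1000L * depth + s)
      seg_len(truth, probe)
    }, numeric(1))
    mean(lens, na.rm = TRUE)
  })
  expect_true(all(diff(mean_len) < 0))
})
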