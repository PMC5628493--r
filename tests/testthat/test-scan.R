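roles4 <- c(a1 = "case", a2 = "case", d1 = "obligate_carrier",
            c1 = "control")

test_that("region lengths in Mb match the tabulated convention", {
  expect_identical(region_length_mb(24179723, 71793734), 47.61)
  expect_identical(region_length_mb(83888935, 86613020), 2.72)
  expect_identical(region_length_mb(32671451, 45368987), 12.70)
  expect_identical(region_length_mb(25879452, 31426001), 5.55)
  expect_identical(region_length_mb(12330184, 16012903), 3.68)
  expect_identical(region_length_mb(24144679, 25776811), 1.63)
  expect_identical(region_length_mb(5, 5), 0)
  expect_error(region_length_mb(10, 5), "negative")
})

test_that("case window haplotype requires agreement of homozygous cases", {
  # both cases homozygous and identical -> the shared vector
  gm <- make_gm(rbind(a1 = c(2L, 0L, 2L), a2 = c(2L, 0L, 2L),
                      d1 = c(1L, 1L, 1L), c1 = c(0L, 0L, 0L)),
                sample_ids = names(roles4))
  expect_identical(infer_case_window_haplotype(gm, 1:3, c("a1", "a2")),
                   c(2L, 0L, 2L))
  # one case heterozygous at one SNP -> none
  gm$calls["a2", 2] <- 1L
  expect_null(infer_case_window_haplotype(gm, 1:3, c("a1", "a2")))
  # cases homozygous for different alleles -> none
  gm$calls["a2", 2] <- 2L
  expect_null(infer_case_window_haplotype(gm, 1:3, c("a1", "a2")))
})

test_that("two-case windows agree with the direct criterion, exhaustively", {
  # all 81 combinations of two case genotypes over a 2-SNP window
  combos <- expand.grid(g11 = 0:2, g12 = 0:2, g21 = 0:2, g22 = 0:2)
  for (i in seq_len(nrow(combos))) {
    g <- combos[i, ]
    gm <- make_gm(rbind(a1 = c(g$g11, g$g12), a2 = c(g$g21, g$g22)),
                  sample_ids = c("a1", "a2"))
    hap <- infer_case_window_haplotype(gm, 1:2, c("a1", "a2"))
    valid <- all(c(g$g11, g$g12, g$g21, g$g22) != 1) &&
      g$g11 == g$g21 && g$g12 == g$g22
    expect_identical(!is.null(hap), valid)
    if (valid) expect_identical(hap, c(g$g11, g$g12))
  }
})

test_that("sample classification follows the carrier definitions", {
  hap <- c(2L, 0L, 2L)
  gm0 <- make_gm(rbind(x = c(2L, 0L, 2L)), sample_ids = "x")
  expect_identical(classify_window_sample(gm0, "x", 1:3, hap),
                   "homozygous_carrier")
  gm1 <- make_gm(rbind(x = c(1L, 0L, 2L)), sample_ids = "x")
  expect_identical(classify_window_sample(gm1, "x", 1:3, hap), "carrier")
  # homozygous for the non-haplotype allele at one SNP -> non-carrier
  gm2 <- make_gm(rbind(x = c(0L, 0L, 2L)), sample_ids = "x")
  expect_identical(classify_window_sample(gm2, "x", 1:3, hap),
                   "non_carrier")
  # per-SNP enumeration against the definition
  for (h in c(0L, 2L)) for (g in 0:2) {
    gm <- make_gm(rbind(x = g), sample_ids = "x")
    got <- classify_window_sample(gm, "x", 1L, h)
    want <- if (g == h) "homozygous_carrier"
    else if ((h == 2L && g >= 1L) || (h == 0L && g <= 1L)) "carrier"
    else "non_carrier"
    expect_identical(got, want)
  }
})

test_that("window consistency combines the three role criteria", {
  gm <- make_gm(rbind(a1 = c(2L, 2L), a2 = c(2L, 2L), d1 = c(1L, 1L),
                      c1 = c(0L, 1L)), sample_ids = names(roles4))
  expect_true(window_consistent(gm, 1:2, roles4))
  # a control homozygous for the case haplotype voids the window
  gm$calls["c1", ] <- c(2L, 2L)
  expect_false(window_consistent(gm, 1:2, roles4))
  # an obligate carrier that cannot carry voids it too
  gm$calls["c1", ] <- c(0L, 1L)
  gm$calls["d1", ] <- c(0L, 0L)
  expect_false(window_consistent(gm, 1:2, roles4))
})

test_that("a fully consistent chromosome yields one saturated region", {
  n <- 60
  gm <- make_gm(rbind(a1 = rep(2L, n), a2 = rep(2L, n), d1 = rep(1L, n),
                      c1 = rep(1L, n)), sample_ids = names(roles4),
                bp = seq(1e6, 60e6, length.out = n))
  reg <- scan_autozygosity(gm, roles4, window_size = 40)
  expect_identical(nrow(reg), 1L)
  expect_identical(reg$n_snps, n)
  expect_identical(reg$start_bp, gm$map$bp[1])
  expect_identical(reg$end_bp, gm$map$bp[n])
})

test_that("scan equals exhaustive naive window evaluation on fixtures", {
  for (seed in 1:15) {
    fx <- random_scan_fixture(seed)
    w <- sample(c(6L, 10L, 25L), 1)
    st <- sample(c(1L, 2L, 3L), 1)
    pol <- sample(c("compatible", "incompatible", "fail_window"), 1)
    got <- scan_autozygosity(fx$gm, fx$roles, window_size = w, step = st,
                             missing_policy = pol)
    want <- oracle_regions(fx$gm, fx$roles, w, st, pol)
    got_df <- data.frame(got)[, c("chr", "start_bp", "end_bp", "n_snps")]
    rownames(got_df) <- rownames(want) <- NULL
    expect_identical(got_df, want,
                     label = sprintf("seed %d w=%d step=%d %s",
                                     seed, w, st, pol))
  }
})

test_that("adding a control can only shrink the consistent-window set", {
  for (seed in 21:28) {
    fx <- random_scan_fixture(seed, n_samples = 10)
    r1 <- scan_autozygosity(fx$gm, fx$roles, window_size = 10)
    set.seed(seed)
    extra <- rbind(fx$gm$calls,
                   zz = sample(c(0:2, NA), ncol(fx$gm$calls), TRUE))
    gm2 <- geno_matrix(extra, fx$gm$map)
    roles2 <- c(fx$roles, zz = "control")
    r2 <- scan_autozygosity(gm2, roles2, window_size = 10)
    # every surviving region is contained in one of the original regions
    if (nrow(r2)) for (i in seq_len(nrow(r2))) {
      inside <- any(r1$chr == r2$chr[i] & r1$start_bp <= r2$start_bp[i] &
                      r1$end_bp >= r2$end_bp[i])
      expect_true(inside)
    }
    expect_lte(sum(r2$n_snps), sum(r1$n_snps))
  }
})

test_that("scan output is invariant to sample order and marker labels", {
  fx <- random_scan_fixture(77)
  r1 <- scan_autozygosity(fx$gm, fx$roles, window_size = 10)
  perm <- sample(nrow(fx$gm$calls))
  gm2 <- fx$gm
  gm2$calls <- gm2$calls[perm, ]
  gm2$map$marker_id <- colnames(gm2$calls) <-
    sprintf("relabel%03d", seq_len(ncol(gm2$calls)))
  r2 <- scan_autozygosity(gm2, fx$roles, window_size = 10)
  expect_identical(data.frame(r1), data.frame(r2))
})

test_that("chromosomes shorter than the window are skipped with a notice", {
  gm <- make_gm(rbind(a1 = rep(2L, 10), a2 = rep(2L, 10),
                      d1 = rep(1L, 10), c1 = rep(0L, 10)),
                chr = c(rep("1", 8), "2", "2"),
                bp = c(1:8 * 1000L, 1000L, 2000L),
                sample_ids = names(roles4))
  expect_message(reg <- scan_autozygosity(gm, roles4, window_size = 5),
                 "fewer than")
  expect_true(all(reg$chr == "1"))
})

test_that("unpositioned markers are rejected before scanning", {
  fx <- random_scan_fixture(5)
  fx$gm$map$bp[3] <- NA
  expect_error(scan_autozygosity(fx$gm, fx$roles, window_size = 10),
               "unpositioned")
})
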