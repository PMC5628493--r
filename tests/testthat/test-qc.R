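test_that("call-rate rule removes markers strictly below the threshold", {
  # 20 samples: 18/20 = 90% (< 95%, removed), 19/20 = 95% exactly
  # (retained under the strict "less than" rule), fully observed retained
  calls <- matrix(1L, nrow = 20, ncol = 3)
  calls[1:2, 1] <- NA
  calls[1, 2] <- NA
  gm <- make_gm(calls)
  res <- call_rate_filter(gm, threshold = 0.95)
  expect_identical(res$report$removed, "m0001")
  expect_identical(colnames(res$genotypes$calls), c("m0002", "m0003"))
  # fully observed matrix: nothing removed
  res2 <- call_rate_filter(make_gm(matrix(0:2, 6, 4)), 0.95)
  expect_length(res2$report$removed, 0)
})

test_that("only opposing homozygotes count as Mendelian conflicts", {
  ped <- pedigree(c("p", "m", "o"), sire = c(NA, NA, "p"),
                  dam = c(NA, NA, "m"), sex = c("M", "F", "F"))
  # enumerate all 9 parent(p)/child(o) combinations, one marker each
  combos <- expand.grid(parent = 0:2, child = 0:2)
  calls <- rbind(p = combos$parent, m = rep(1L, 9), o = combos$child)
  gm <- make_gm(calls, sample_ids = c("p", "m", "o"))
  res <- mendelian_conflict_filter(gm, ped, max_conflict_rate = 0)
  conflicts <- res$report$stats$conflicts
  expected <- as.integer((combos$parent == 0 & combos$child == 2) |
                           (combos$parent == 2 & combos$child == 0))
  expect_identical(as.integer(conflicts), expected)
  # the dam is heterozygous everywhere: she can never conflict
  expect_true(all(res$report$stats$tested == 2))
})

test_that("missing parental calls are excluded from the denominator", {
  ped <- pedigree(c("p", "o"), sire = c(NA, "p"), dam = c(NA, NA),
                  sex = c("M", "M"))
  calls <- rbind(p = c(NA, 0L), o = c(2L, 2L))
  gm <- make_gm(calls, sample_ids = c("p", "o"))
  res <- mendelian_conflict_filter(gm, ped, max_conflict_rate = 0)
  expect_identical(res$report$stats$tested, c(0, 1))
  expect_identical(res$report$removed, "m0002")
})

test_that("error-free gene-dropped data passes the conflict rule", {
  b <- simulate_dataset(errorfree_config(31, n_markers = 300))
  res <- mendelian_conflict_filter(b$genotypes, b$ped,
                                   max_conflict_rate = 0)
  expect_length(res$report$removed, 0)
})

test_that("the conflict rule is skipped without parent/offspring pairs", {
  ped <- pedigree(c("x", "y"), sire = c(NA, NA), dam = c(NA, NA),
                  sex = c("M", "F"))
  gm <- make_gm(matrix(1L, 2, 3), sample_ids = c("x", "y"))
  res <- mendelian_conflict_filter(gm, ped)
  expect_match(res$report$note, "skipped")
  expect_identical(res$genotypes$calls, gm$calls)
})

test_that("position rule removes unknown and mutually-duplicated positions", {
  gm <- make_gm(matrix(1L, 4, 5))
  gm$map$bp[2] <- NA
  gm$map$bp[4] <- gm$map$bp[3]
  res <- position_filter(gm)
  expect_setequal(res$report$removed, c("m0002", "m0003", "m0004"))
  # clean map: nothing removed
  expect_length(position_filter(make_gm(matrix(1L, 4, 5)))$report$removed, 0)
})

test_that("filters commute when their failure sets are disjoint", {
  ped <- pedigree(c("p", "m", "o"), sire = c(NA, NA, "p"),
                  dam = c(NA, NA, "m"), sex = c("M", "F", "F"))
  for (seed in 1:5) {
    set.seed(seed)
    calls <- matrix(sample(c(0:2, NA), 3 * 40, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)),
                    nrow = 3, ncol = 40)
    rownames(calls) <- c("p", "m", "o")
    gm <- make_gm(calls, sample_ids = c("p", "m", "o"))
    gm$map$bp[sample(40, 3)] <- NA
    a <- position_filter(call_rate_filter(gm, 0.7)$genotypes)$genotypes
    b <- call_rate_filter(position_filter(gm)$genotypes, 0.7)$genotypes
    expect_identical(colnames(a$calls), colnames(b$calls))
  }
})

test_that("per-rule removals and survivors account for every marker", {
  b <- simulate_dataset(sim_config(seed = 9, n_markers = 400))
  qc <- run_genotype_qc(b$genotypes, b$ped)
  expect_identical(qc$n_input, sum(qc$summary$removed) + qc$n_retained)
})
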