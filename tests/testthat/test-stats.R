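test_that("paired t reproduces the hand-worked example and the null cases", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 2, degenerate = FALSE))
  # alternating differences: zero mean, nonzero variance -> t = 0, p = 1
  a <- c(2, 1, 2, 1, 2, 1)
  b <- c(1, 2, 1, 2, 1, 2)
  res <- paired_t(a, b)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # d = (1, 2, 3, 4): mean 2.5, sd ~1.2910, SE ~0.6455, t ~3.873, p ~0.0305
  res <- paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(res$t, 2.5 / (stats::sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$p, 0.030466, tolerance = 1e-4)
  expect_equal(res$df, 3)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t matches the textbook implementation to high precision", {
  set.seed(612)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    a <- stats::rnorm(n, 5, 2)
    b <- stats::rnorm(n, 5, 2)
    res <- paired_t(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$df, unname(ref$parameter))
  }
})

test_that("zero-variance nonzero-mean differences are flagged degenerate", {
  expect_warning(res <- paired_t(c(2, 2, 2), c(1, 1, 1)), "zero-variance")
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
})

test_that("BH step-up matches hand computation and p.adjust", {
  bh <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(bh$significant))
  expect_equal(bh$threshold, 0.04)  # 0.04 <= 4 * 0.05 / 4
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  expect_true(bh_adjust(0.04, alpha = 0.05)$significant)
  expect_false(bh_adjust(0.06, alpha = 0.05)$significant)
  # step-up can rescue p-values above the raw per-test line...
  bh2 <- bh_adjust(c(0.001, 0.002, 0.04), alpha = 0.05)
  expect_true(all(bh2$significant))
  # ...but never declares anything beyond the raw-alpha set
  set.seed(41)
  for (i in 1:10) {
    p <- stats::runif(50)^2
    bh <- bh_adjust(p, 0.05)
    expect_true(all(p[bh$significant] <= 0.05))
    # agreement with the standard adjusted-p implementation
    expect_identical(bh$significant,
                     stats::p.adjust(p, "BH") <= 0.05 & bh$threshold > 0)
  }
  empty <- bh_adjust(numeric(0))
  expect_length(empty$significant, 0)
  expect_equal(empty$threshold, 0)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Shapiro-Wilk screen flags degenerates and controls with BH", {
  # a perfectly linear 3-point sample has W ~ 1
  res <- normality_check(list(lin = c(1, 2, 3)))
  expect_gt(res$W[1], 0.999)
  expect_false(res$reject[1])
  res <- normality_check(list(const = rep(4, 10), ok = c(1, 2, 4, 3, 5)))
  expect_true(res$degenerate[1])
  expect_true(is.na(res$W[1]))
  expect_false(res$degenerate[2])
  # normal replicate sets across many regions: (almost) never rejected
  set.seed(2024)
  reps <- replicate(524, stats::rnorm(40, 100, 10), simplify = FALSE)
  res <- normality_check(reps)
  expect_lt(mean(res$reject), 0.02)
})

test_that("compare_all is exactly null for identity mutation with paired seeds", {
  m <- psd7_model()
  pairs <- list(
    run_region(fixture_region(region_id = "r1"), m,
               mutation_spec("shank1_pdz_gkap", 1.0), n_rep = 3,
               base_seed = 5, t_end = 2),
    run_region(fixture_region(AMPAR = 20, region_id = "r2"), m,
               mutation_spec("shank1_pdz_gkap", 1.0), n_rep = 3,
               base_seed = 500, t_end = 2))
  cmp <- compare_all(pairs)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))
  expect_false(any(cmp$degenerate))
  # focus complex: BH across regions, no discoveries under the null
  focus <- pairs[[1]]$keys[1]
  cmp2 <- compare_all(pairs, focus = focus)
  expect_false(any(cmp2$bh_significant[cmp2$key == focus]))
  expect_equal(attr(cmp2, "bh_threshold"), 0)
})

test_that("compare_all agrees with scalar paired_t cell by cell", {
  m <- psd7_model()
  pr <- run_region(fixture_region(), m, mutation_spec("shank1_pdz_gkap", 5.5),
                   n_rep = 6, base_seed = 21, t_end = 2)
  cmp <- compare_all(list(pr))
  for (j in sample(seq_along(pr$keys), 25)) {
    ref <- suppressWarnings(paired_t(pr$wt[, j], pr$mut[, j]))
    row <- cmp[cmp$key == pr$keys[j], ]
    expect_equal(row$t, ref$t, tolerance = 1e-12)
    expect_equal(row$p, ref$p, tolerance = 1e-12)
    expect_equal(row$degenerate, ref$degenerate)
  }
})

test_that("appearance report lists complexes present in one scenario only", {
  pr <- structure(list(
    region_id = "rX", region_type = "t", keys = c("kA", "kB", "kC"),
    wt = matrix(c(1, 1, 0, 0, 2, 2), 2, 3, dimnames = list(NULL, c("kA", "kB", "kC"))),
    mut = matrix(c(1, 1, 3, 3, 0, 0), 2, 3, dimnames = list(NULL, c("kA", "kB", "kC")))),
    class = "scenario_pair")
  rep <- appearance_report(list(pr))
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$key, c("kB", "kC"))
  expect_equal(rep$scenario[rep$key == "kB"], "mut")
  expect_equal(rep$scenario[rep$key == "kC"], "wt")
})
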