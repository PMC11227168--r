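test_that("initial states are unbound monomers and seed-deterministic", {
  m <- toy_ab_model()
  st <- sim_state(m, c(A = 3))
  expect_equal(sum(st$inst_species == 1), 3)
  expect_equal(nrow(st$bonds), 0)
  expect_true(all(is.na(st$slot_bond)))
  expect_equal(st$time, 0)
  empty <- sim_state(m, c(A = 0, B = 0))
  expect_length(empty$inst_species, 0)
  expect_error(sim_state(m, c(A = -1)), "non-negative")
  expect_error(sim_state(m, c(A = 1.5)), "non-negative")
  expect_error(sim_state(m, c(Z = 1)), "unknown species")
  r1 <- run_ssa(m, c(A = 4, B = 4), seed = 11, t_end = 2)
  r2 <- run_ssa(m, c(A = 4, B = 4), seed = 11, t_end = 2)
  expect_identical(r1$counts, r2$counts)
})

test_that("association propensity counts eligible free-site pairs", {
  m <- toy_ab_model(k_on = 1, k_off = 2)
  st <- sim_state(m, c(A = 2, B = 3), seed = 1)
  pr <- event_propensities(st)
  expect_equal(pr$propensity[pr$type == "assoc"], 2 * 3)
  expect_equal(pr$propensity[pr$type == "dissoc"], 0)
  # bind everything: 2 bonds, k_off = 2 -> dissociation propensity 4;
  # association 1 * (0 free A) = 0
  st <- sim_step(sim_step(st))
  pr <- event_propensities(st)
  expect_equal(nrow(st$bonds), 2)
  expect_equal(pr$propensity[pr$type == "assoc"], 0)
  expect_equal(pr$propensity[pr$type == "dissoc"], 2 * 2)
  # self-rule on one site class counts unordered pairs: C(2, 2) = 1
  hm <- homodimer_model()
  pr <- event_propensities(sim_state(hm, c(H = 2), seed = 1))
  expect_equal(pr$propensity[pr$type == "assoc"], 1)
  pr <- event_propensities(sim_state(hm, c(H = 4), seed = 1))
  expect_equal(pr$propensity[pr$type == "assoc"], choose(4, 2))
})

test_that("intra-complex pairs are excluded when ring closure is disallowed", {
  cm <- chain_model()
  st <- sim_state(cm, c(P = 2), seed = 3)
  # 2 heads x 2 tails minus 2 same-molecule pairs = 2 eligible pairs
  pr <- event_propensities(st)
  expect_equal(pr$propensity[pr$type == "assoc"], 2)
  st <- sim_step(st)  # now one P-P dimer: remaining head/tail on same complex
  expect_equal(nrow(st$bonds), 1)
  pr <- event_propensities(st)
  expect_equal(pr$propensity[pr$type == "assoc"], 0)
})

test_that("stepping a 1+1 dimer associates first, then can only dissociate", {
  m <- toy_ab_model()
  st <- sim_state(m, c(A = 1, B = 1), seed = 5)
  st1 <- sim_step(st)
  expect_equal(nrow(st1$bonds), 1)
  expect_gt(st1$time, 0)
  st2 <- sim_step(st1)  # the only possible event restores the original bonds
  expect_equal(nrow(st2$bonds), 0)
  expect_identical(is.na(st2$slot_bond), is.na(st$slot_bond))
  expect_identical(state_complex_keys(st2), state_complex_keys(st))
})

test_that("a rule-free model leaves every species as monomers, exactly", {
  m <- interaction_model(
    species = list(list(name = "A", sites = data.frame(name = "x",
                                                       multiplicity = 1L))),
    rules = data.frame(id = character(0), species_a = character(0),
                       site_a = character(0), species_b = character(0),
                       site_b = character(0), k_on = numeric(0),
                       k_off = numeric(0)))
  r <- run_ssa(m, c(A = 7), seed = 1, t_end = 1, n_samples = 10)
  expect_true(r$absorbed)
  expect_equal(unname(r$abundance["(A)"]), 7)
  expect_equal(length(r$keys), 1)
})

test_that("1+1 dimer occupancy converges to the stationary value 1/2", {
  m <- toy_ab_model(k_on = 1, k_off = 1)
  r <- run_ssa(m, c(A = 1, B = 1), seed = 42, t_end = 2000, n_samples = 400)
  expect_lt(abs(r$abundance[["(A[ab/x/y](B))"]] - 0.5), 0.1)
})

test_that("dimer bond counts match the exact birth-death stationary law", {
  # 10+10 dimerization: replicate means vs the closed-form chain mean
  ex <- exact_dimer_equilibrium(10, 10, 1, 1)
  m <- toy_ab_model()
  runs <- replicate_runs(m, c(A = 10, B = 10), n_rep = 12, base_seed = 700,
                         t_end = 60, n_samples = 100)
  means <- vapply(runs, function(r) r$abundance[["(A[ab/x/y](B))"]],
                  numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - ex$mean), 3 * se + 1e-12)
  # full stationary distribution: chi-square goodness of fit across seeds,
  # snapshots spaced far beyond the chain's relaxation time
  ex3 <- exact_dimer_equilibrium(3, 3, 1, 1)
  reject <- 0
  for (s in 1:20) {
    r <- run_ssa(m, c(A = 3, B = 3), seed = 9000 + s, t_end = 800,
                 burn_in_fraction = 0.25, n_samples = 150)
    k <- if ("(A[ab/x/y](B))" %in% r$keys)
      r$counts[, "(A[ab/x/y](B))"] else rep(0L, nrow(r$counts))
    obs <- tabulate(k + 1, nbins = 4)
    expected <- ex3$pi * length(k)
    # merge low-expectation bins upward
    while (length(expected) > 2 && min(expected) < 5) {
      i <- which.min(expected)
      j <- if (i == 1) 2 else i - 1
      expected[j] <- expected[j] + expected[i]
      obs[j] <- obs[j] + obs[i]
      expected <- expected[-i]; obs <- obs[-i]
    }
    stat <- sum((obs - expected)^2 / expected)
    if (stats::pchisq(stat, df = length(expected) - 1, lower.tail = FALSE) <
        0.01) reject <- reject + 1
  }
  expect_lte(reject, 1)
})

test_that("species counts are conserved in every snapshot", {
  m <- psd7_model()
  ab <- unlist(fixture_region()[1, species_names(m)])
  r <- run_ssa(m, ab, seed = 31, t_end = 3, n_samples = 50)
  comp <- t(vapply(r$keys, function(k) {
    cmp <- composition(k)
    out <- stats::setNames(numeric(7), species_names(m))
    out[names(cmp)] <- cmp
    out
  }, numeric(7)))
  totals <- r$counts %*% comp  # snapshots x species
  for (s in species_names(m))
    expect_true(all(totals[, s] == ab[[s]]))
})

test_that("no cyclic complex ever forms under the default acyclic dynamics", {
  m <- psd7_model()
  ab <- unlist(fixture_region(Shank1 = 60, Homer1 = 40)[1, species_names(m)])
  r <- run_ssa(m, ab, seed = 13, t_end = 3)
  # tree keys use the parenthesis form; ring/multi-edge keys use braces
  expect_false(any(startsWith(r$keys, "{")))
})

test_that("ring closure is possible when intra-complex binding is enabled", {
  cm <- chain_model()
  cm$allow_intra_complex_binding <- TRUE
  r <- run_ssa(cm, c(P = 6), seed = 2, t_end = 30, n_samples = 60)
  expect_true(any(startsWith(r$keys, "{")))
})

test_that("replicate_runs is deterministic and seeded per replicate", {
  m <- toy_ab_model()
  one <- replicate_runs(m, c(A = 5, B = 5), n_rep = 1, base_seed = 20,
                        t_end = 2)
  expect_length(one, 1)
  expect_identical(one[[1]]$counts,
                   run_ssa(m, c(A = 5, B = 5), seed = 21, t_end = 2)$counts)
  a <- replicate_runs(m, c(A = 5, B = 5), n_rep = 3, base_seed = 8, t_end = 2)
  b <- replicate_runs(m, c(A = 5, B = 5), n_rep = 3, base_seed = 8, t_end = 2)
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))
  expect_equal(vapply(a, `[[`, numeric(1), "seed"), 8 + 1:3)
})

test_that("run parameters are validated", {
  m <- toy_ab_model()
  expect_error(run_ssa(m, c(A = 1, B = 1), seed = 1, t_end = 0), "t_end")
  expect_error(run_ssa(m, c(A = 1, B = 1), seed = 1, burn_in_fraction = 1),
               "burn_in")
  expect_error(run_ssa(m, c(A = 1, B = 1), seed = 1, n_samples = 0),
               "n_samples")
  expect_error(replicate_runs(m, c(A = 1, B = 1), n_rep = 0), "n_rep")
})
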