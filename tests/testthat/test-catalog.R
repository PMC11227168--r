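psd95_star <- function(syngap_on_first) {
  # NMDAR-P1, AMPAR bridging P1 and P2, SynGAP on P1 (or P2): same
  # composition, different topology
  complex_graph(
    c("NMDAR", "PSD-95", "AMPAR", "PSD-95", "SynGAP"),
    data.frame(a = c(1, 3, 3, 5),
               b = c(2, 2, 4, if (syngap_on_first) 2 else 4),
               rule = c("nmdar_psd95", "ampar_psd95", "ampar_psd95",
                        "syngap_psd95"),
               site_a = c("ctail", "ttail", "ttail", "pbm"),
               site_b = c("pdz12", "pdz12", "pdz12", "pdz3")))
}

relabel <- function(g, perm) {
  e <- g$edges
  e$a <- match(e$a, perm)
  e$b <- match(e$b, perm)
  complex_graph(g$species[perm], e)
}

test_that("canonical keys are invariant under instance renumbering", {
  g <- psd95_star(TRUE)
  k <- canonical_key(g)
  set.seed(404)
  for (i in 1:10) {
    p <- sample(length(g$species))
    expect_identical(canonical_key(relabel(g, p)), k)
  }
  # monomers of the same species always share a key
  expect_identical(canonical_key(complex_graph("PSD-95")),
                   canonical_key(complex_graph("PSD-95")))
  # different species, same shape -> different keys
  k_nmdar <- canonical_key(complex_graph(
    c("NMDAR", "PSD-95"),
    data.frame(a = 1, b = 2, rule = "nmdar_psd95", site_a = "ctail",
               site_b = "pdz12")))
  k_ampar <- canonical_key(complex_graph(
    c("AMPAR", "PSD-95"),
    data.frame(a = 1, b = 2, rule = "ampar_psd95", site_a = "ttail",
               site_b = "pdz12")))
  expect_false(k_nmdar == k_ampar)
})

test_that("topology distinguishes complexes with identical composition", {
  g1 <- psd95_star(TRUE)
  g2 <- psd95_star(FALSE)
  k1 <- canonical_key(g1)
  k2 <- canonical_key(g2)
  expect_identical(composition(k1), composition(k2))
  expect_false(k1 == k2)
  # the brute-force oracle agrees that they are not isomorphic
  expect_false(oracle_isomorphic(g1, g2))
  # and agrees that relabelings are isomorphic with matching keys
  g1p <- relabel(g1, c(3, 5, 1, 2, 4))
  expect_true(oracle_isomorphic(g1, g1p))
  expect_identical(canonical_key(g1p), k1)
})

test_that("keys of ring and multi-edge complexes follow the oracle too", {
  # AMPAR doubly bound to one PSD-95 (multi-edge) vs a 4-ring
  double <- complex_graph(
    c("AMPAR", "PSD-95"),
    data.frame(a = c(1, 1), b = c(2, 2), rule = "ampar_psd95",
               site_a = "ttail", site_b = "pdz12"))
  ring <- complex_graph(
    c("AMPAR", "PSD-95", "AMPAR", "PSD-95"),
    data.frame(a = c(1, 3, 3, 1), b = c(2, 2, 4, 4), rule = "ampar_psd95",
               site_a = "ttail", site_b = "pdz12"))
  kd <- canonical_key(double)
  kr <- canonical_key(ring)
  expect_false(kd == kr)
  expect_identical(canonical_key(relabel(ring, c(2, 1, 4, 3))), kr)
  expect_identical(canonical_key(relabel(ring, c(3, 4, 1, 2))), kr)
  expect_true(oracle_isomorphic(ring, relabel(ring, c(3, 2, 1, 4))))
})

test_that("disconnected graphs are rejected", {
  g <- complex_graph(c("A", "B"))  # two nodes, no edge
  expect_error(canonical_key(g), "not connected")
})

test_that("composition parses keys from both encodings", {
  g <- psd95_star(TRUE)
  cmp <- composition(canonical_key(g))
  expect_identical(cmp, c(AMPAR = 1L, NMDAR = 1L, `PSD-95` = 2L, SynGAP = 1L))
  expect_identical(composition("(PSD-95)"), c(`PSD-95` = 1L))
  shank_dimer <- canonical_key(complex_graph(
    c("Shank1", "Shank1"),
    data.frame(a = 1, b = 2, rule = "shank1_sam_polymer",
               site_a = "sam_head", site_b = "sam_tail")))
  expect_identical(composition(shank_dimer), c(Shank1 = 2L))
  expect_equal(complex_size(shank_dimer), 2)
  expect_equal(composition_string(shank_dimer), "Shank1x2")
  ring <- canonical_key(complex_graph(
    c("Homer1", "Homer1"),
    data.frame(a = c(1, 1), b = c(2, 2), rule = c("homer_cc", "homer_cc"),
               site_a = c("cc_a", "cc_a"), site_b = c("cc_b", "cc_b"))))
  expect_identical(composition(ring), c(Homer1 = 2L))
  expect_error(composition("garbage"), "malformed")
})

test_that("key_has_rule detects bonds of a given rule", {
  g <- complex_graph(
    c("GKAP", "Shank1"),
    data.frame(a = 2, b = 1, rule = "shank1_pdz_gkap", site_a = "pdz",
               site_b = "cterm"))
  k <- canonical_key(g)
  expect_true(key_has_rule(k, "shank1_pdz_gkap"))
  expect_false(key_has_rule(k, "gkap_psd95"))
  expect_false(key_has_rule("(GKAP)", "shank1_pdz_gkap"))
})

test_that("catalogs assign stable first-encounter numeric ids", {
  cat <- complex_catalog()
  k1 <- canonical_key(complex_graph("PSD-95"))
  k2 <- canonical_key(complex_graph("AMPAR"))
  r1 <- register(cat, k1)
  expect_equal(r1$numeric_id, 1L)
  expect_equal(register(cat, k2)$numeric_id, 2L)
  expect_equal(register(cat, k1)$numeric_id, 1L)  # idempotent
  expect_equal(catalog_size(cat), 2L)
  tab <- catalog_table(cat)
  expect_equal(tab$numeric_id, 1:2)
  expect_equal(tab$composition, c("PSD-95", "AMPAR"))
  cat5 <- complex_catalog(base = 5L)
  expect_equal(register(cat5, k1)$numeric_id, 5L)
})
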