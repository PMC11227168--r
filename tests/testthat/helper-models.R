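# Small models and fixtures built in code for the tests.

toy_ab_model <- function(k_on = 1, k_off = 1) dimer_model(k_on, k_off)

# A single species with one self-associating site pair (head/tail chain).
chain_model <- function(k_on = 1, k_off = 1) {
  interaction_model(
    species = list(list(name = "P",
                        sites = data.frame(name = c("h", "t"),
                                           multiplicity = c(1L, 1L)))),
    rules = data.frame(id = "ht", species_a = "P", site_a = "h",
                       species_b = "P", site_b = "t",
                       k_on = k_on, k_off = k_off),
    name = "chain")
}

# Homodimer rule on a single site class (self-rule with identical sides).
homodimer_model <- function(k_on = 1, k_off = 1) {
  interaction_model(
    species = list(list(name = "H",
                        sites = data.frame(name = "s", multiplicity = 1L))),
    rules = data.frame(id = "ss", species_a = "H", site_a = "s",
                       species_b = "H", site_b = "s",
                       k_on = k_on, k_off = k_off),
    name = "homodimer")
}

# One small deterministic region row for pipeline tests.
fixture_region <- function(NMDAR = 5, AMPAR = 40, `PSD-95` = 80, SynGAP = 20,
                           GKAP = 40, Shank1 = 40, Homer1 = 10,
                           region_id = "regA", region_type = "typeA") {
  data.frame(region_id = region_id, region_type = region_type,
             NMDAR = NMDAR, AMPAR = AMPAR, `PSD-95` = `PSD-95`,
             SynGAP = SynGAP, GKAP = GKAP, Shank1 = Shank1, Homer1 = Homer1,
             check.names = FALSE)
}
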