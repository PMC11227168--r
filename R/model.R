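#' Interaction models: species, binding sites, and site-level binding rules
#'
#' An interaction model is the simulator's rulebook: a set of protein species,
#' each carrying named binding sites with a multiplicity (number of identical
#' copies of the site on one molecule), and a set of pairwise site-level
#' binding rules with mass-action on/off rates. Self-rules (both sides on the
#' same species) are permitted and are required for polymerizing scaffolds
#' such as Shank1 (SAM head-to-tail) and Homer1 (coiled-coil).
#'
#' @param species list of species, each `list(name=, sites=)` where `sites` is
#'   a data frame with columns `name` and `multiplicity`.
#' @param rules data frame with columns `id`, `species_a`, `site_a`,
#'   `species_b`, `site_b`, `k_on`, `k_off`.
#' @param allow_intra_complex_binding logical; if `FALSE` (default) binding
#'   between two sites already in the same complex (ring closure) is
#'   forbidden, so every complex is tree-shaped.
#' @param name optional model name.
#' @return an object of class `interaction_model`.
#' @export
interaction_model <- function(species, rules,
                              allow_intra_complex_binding = FALSE,
                              name = "model") {
  m <- structure(
    list(species = species, rules = rules,
         allow_intra_complex_binding = isTRUE(allow_intra_complex_binding),
         name = name),
    class = "interaction_model")
  validate_model(m)
  m
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf("<interaction_model '%s': %d species, %d rules, intra-complex binding %s>\n",
              x$name, length(x$species), nrow(x$rules),
              if (x$allow_intra_complex_binding) "allowed" else "disallowed"))
  invisible(x)
}

#' @rdname interaction_model
#' @param model an `interaction_model`.
#' @export
validate_model <- function(model) {
  sp_names <- vapply(model$species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names))
    stop("duplicate species name: ", sp_names[duplicated(sp_names)][1])
  for (s in model$species) {
    st <- s$sites
    if (!is.data.frame(st) || !all(c("name", "multiplicity") %in% names(st)))
      stop("species '", s$name, "': sites must have columns name, multiplicity")
    if (anyDuplicated(st$name))
      stop("species '", s$name, "': duplicate site name")
    if (any(st$multiplicity < 1) || any(st$multiplicity != round(st$multiplicity)))
      stop("species '", s$name, "': site multiplicity must be a positive integer")
  }
  r <- model$rules
  need <- c("id", "species_a", "site_a", "species_b", "site_b", "k_on", "k_off")
  if (!is.data.frame(r) || !all(need %in% names(r)))
    stop("rules must be a data frame with columns ", paste(need, collapse = ", "))
  if (anyDuplicated(r$id)) stop("duplicate rule id: ", r$id[duplicated(r$id)][1])
  site_ok <- function(spec, site) {
    i <- match(spec, sp_names)
    !is.na(i) && site %in% model$species[[i]]$sites$name
  }
  for (i in seq_len(nrow(r))) {
    if (!site_ok(r$species_a[i], r$site_a[i]))
      stop("rule '", r$id[i], "': unknown site ", r$species_a[i], ".", r$site_a[i])
    if (!site_ok(r$species_b[i], r$site_b[i]))
      stop("rule '", r$id[i], "': unknown site ", r$species_b[i], ".", r$site_b[i])
    if (!is.finite(r$k_on[i]) || r$k_on[i] <= 0)
      stop("rule '", r$id[i], "': k_on must be > 0")
    if (!is.finite(r$k_off[i]) || r$k_off[i] <= 0)
      stop("rule '", r$id[i], "': k_off must be > 0")
  }
  invisible(model)
}

#' Species names of a model
#' @param model an `interaction_model`.
#' @return character vector of species names, in model order.
#' @export
species_names <- function(model) {
  vapply(model$species, function(s) s$name, character(1))
}

#' Load an interaction model from a YAML/JSON config file
#'
#' The schema has keys `species[].name`, `species[].sites[].{name,multiplicity}`,
#' `rules[].{id,a:[species,site],b:[species,site],k_on,k_off}` and
#' `options.allow_intra_complex_binding`. See the shipped fixture
#' `system.file("extdata", "psd7_default.yaml", package = "psdsim")`.
#'
#' @param path path to a model config file.
#' @return a validated `interaction_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  for (key in c("species", "rules"))
    if (is.null(cfg[[key]])) stop("model file '", path, "': missing key '", key, "'")
  species <- lapply(cfg$species, function(s) {
    if (is.null(s$name)) stop("species entry without a name")
    sites <- do.call(rbind, lapply(s$sites, function(x) {
      if (is.null(x$name) || is.null(x$multiplicity))
        stop("species '", s$name, "': each site needs name and multiplicity")
      data.frame(name = as.character(x$name),
                 multiplicity = as.integer(x$multiplicity))
    }))
    list(name = as.character(s$name), sites = sites)
  })
  rules <- do.call(rbind, lapply(cfg$rules, function(r) {
    for (f in c("id", "a", "b", "k_on", "k_off"))
      if (is.null(r[[f]])) stop("rule entry missing field '", f, "'")
    if (length(r$a) != 2 || length(r$b) != 2)
      stop("rule '", r$id, "': sides must be [species, site] pairs")
    data.frame(id = as.character(r$id),
               species_a = as.character(r$a[[1]]), site_a = as.character(r$a[[2]]),
               species_b = as.character(r$b[[1]]), site_b = as.character(r$b[[2]]),
               k_on = as.numeric(r$k_on), k_off = as.numeric(r$k_off))
  }))
  interaction_model(species, rules,
                    allow_intra_complex_binding =
                      isTRUE(cfg$options$allow_intra_complex_binding),
                    name = if (!is.null(cfg$name)) cfg$name else
                      sub("\\.[^.]*$", "", basename(path)))
}

#' Write an interaction model to a YAML config file
#'
#' Round-trips with [load_model()]: `load_model(write_model(m, f))` recovers
#' `m`.
#'
#' @param model an `interaction_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cfg <- list(
    name = model$name,
    options = list(allow_intra_complex_binding = model$allow_intra_complex_binding),
    species = lapply(model$species, function(s) {
      list(name = s$name,
           sites = lapply(seq_len(nrow(s$sites)), function(i)
             list(name = s$sites$name[i],
                  multiplicity = as.integer(s$sites$multiplicity[i]))))
    }),
    rules = lapply(seq_len(nrow(model$rules)), function(i) {
      r <- model$rules[i, ]
      list(id = r$id, a = list(r$species_a, r$site_a),
           b = list(r$species_b, r$site_b),
           k_on = r$k_on, k_off = r$k_off)
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' The bundled seven-protein postsynaptic-density model
#'
#' Loads the `psd7_default` fixture: NMDAR, AMPAR, PSD-95, SynGAP, GKAP,
#' Shank1 and Homer1 with eight site-level binding rules. The rule
#' `shank1_pdz_gkap` (Shank1 PDZ domain binding the GKAP C-terminus) is the
#' target of the hypomorphic mutation scenario.
#'
#' @return an `interaction_model`.
#' @export
psd7_model <- function() {
  load_model(system.file("extdata", "psd7_default.yaml", package = "psdsim",
                         mustWork = TRUE))
}

#' Mutation specifications: off-rate perturbation of one binding rule
#'
#' A hypomorphic mutation weakening one interaction is modeled as a
#' multiplicative increase of that rule's dissociation rate, leaving the
#' binding (on) rate untouched; the dissociation constant Kd = k_off/k_on is
#' multiplied by the same factor. `off_rate_factor = 1` is the identity
#' (wild-type) mutation. The default factor 5.5 models the Shank1 R743H
#' hypomorph.
#'
#' @param target_rule rule id to perturb.
#' @param off_rate_factor positive multiplier applied to the rule's `k_off`.
#' @return an object of class `mutation_spec`.
#' @export
mutation_spec <- function(target_rule, off_rate_factor = 5.5) {
  if (!is.character(target_rule) || length(target_rule) != 1)
    stop("target_rule must be a single rule id")
  if (!is.finite(off_rate_factor) || off_rate_factor <= 0)
    stop("off_rate_factor must be > 0")
  structure(list(target_rule = target_rule,
                 off_rate_factor = off_rate_factor),
            class = "mutation_spec")
}

#' Apply a mutation to a model
#'
#' Returns a copy of `model` in which the target rule's `k_off` is multiplied
#' by the mutation's `off_rate_factor`; every other field, including all
#' `k_on` values, is unchanged. The input model is not modified.
#'
#' @param model an `interaction_model`.
#' @param mut a [mutation_spec()].
#' @return the perturbed `interaction_model`.
#' @export
apply_mutation <- function(model, mut) {
  stopifnot(inherits(model, "interaction_model"), inherits(mut, "mutation_spec"))
  i <- match(mut$target_rule, model$rules$id)
  if (is.na(i))
    stop("unknown rule id '", mut$target_rule, "' in model '", model$name, "'")
  model$rules$k_off[i] <- model$rules$k_off[i] * mut$off_rate_factor
  model
}

#' Dissociation constant of a binding rule
#'
#' @param rule one row of a model's `rules` data frame (or any list with
#'   `k_on` and `k_off`).
#' @return `k_off / k_on`.
#' @export
dissociation_constant <- function(rule) {
  if (is.null(rule$k_on) || is.null(rule$k_off))
    stop("rule must have k_on and k_off")
  rule$k_off / rule$k_on
}

# Integer-indexed form of a model consumed by the C++ engine.
# Classes are (species, site) pairs; indices are 0-based on the C++ side.
compile_model <- function(model) {
  sp <- species_names(model)
  cls_species <- integer(0); cls_site <- character(0)
  species_slots <- vector("list", length(sp))
  for (si in seq_along(model$species)) {
    st <- model$species[[si]]$sites
    rows <- matrix(0L, nrow = nrow(st), ncol = 2)
    for (k in seq_len(nrow(st))) {
      cls_species <- c(cls_species, si - 1L)
      cls_site <- c(cls_site, st$name[k])
      rows[k, ] <- c(length(cls_site) - 1L, as.integer(st$multiplicity[k]))
    }
    species_slots[[si]] <- rows
  }
  class_of <- function(spec, site) {
    i <- which(cls_species == match(spec, sp) - 1L & cls_site == site)
    i - 1L
  }
  r <- model$rules
  list(n_species = length(sp), species_names = sp,
       class_species = cls_species, class_site = cls_site,
       species_slots = species_slots,
       rule_a = vapply(seq_len(nrow(r)), function(i)
         class_of(r$species_a[i], r$site_a[i]), integer(1)),
       rule_b = vapply(seq_len(nrow(r)), function(i)
         class_of(r$species_b[i], r$site_b[i]), integer(1)),
       k_on = r$k_on, k_off = r$k_off, rule_ids = r$id,
       allow_intra = model$allow_intra_complex_binding)
}
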