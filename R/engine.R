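#' Run one stochastic simulation of complex formation
#'
#' Direct-method Gillespie simulation of association/dissociation events among
#' protein copies under a site-level interaction model. Association
#' propensity for a rule is `k_on` times the number of eligible free-site
#' pairs (pairs inside one complex excluded unless the model allows
#' intra-complex binding; unordered pairs for self-rules on one site class);
#' dissociation propensity is `k_off` times the number of existing bonds of
#' the rule. The simulation runs to `t_end` and records the complex
#' distribution at `n_samples` evenly spaced times in
#' `(burn_in_fraction * t_end, t_end]`; reported abundances are per-complex
#' means over those snapshots.
#'
#' @param model an [interaction_model()].
#' @param abundances named vector of non-negative integer copy numbers;
#'   species missing from the vector get zero copies.
#' @param seed integer seed; identical inputs give identical results.
#' @param t_end total simulated time (arbitrary units, > 0).
#' @param burn_in_fraction fraction of `t_end` discarded before sampling
#'   (in `[0, 1)`).
#' @param n_samples number of recorded snapshots (>= 1).
#' @return an object of class `psd_run` with elements `abundance` (named mean
#'   count per canonical complex key), `keys`, `counts` (integer snapshot
#'   matrix, `n_samples` rows), `seed`, `t_end`, `n_samples`, `n_events`,
#'   `absorbed`.
#' @export
run_ssa <- function(model, abundances, seed, t_end = 5,
                    burn_in_fraction = 0.5, n_samples = 100) {
  stopifnot(inherits(model, "interaction_model"))
  if (!(is.numeric(t_end) && length(t_end) == 1 && t_end > 0))
    stop("t_end must be a positive number")
  if (!(is.numeric(burn_in_fraction) && burn_in_fraction >= 0 &&
        burn_in_fraction < 1))
    stop("burn_in_fraction must be in [0, 1)")
  if (!(is.numeric(n_samples) && n_samples >= 1))
    stop("n_samples must be >= 1")
  counts <- normalize_abundances(model, abundances)
  cm <- compile_model(model)
  res <- cpp_run_ssa(cm, counts, t_end, burn_in_fraction,
                     as.integer(n_samples), as.numeric(seed))
  keys <- as.character(res$keys)
  m <- res$counts
  colnames(m) <- keys
  ab <- colMeans(m)
  structure(list(abundance = ab, keys = keys, counts = m,
                 seed = seed, t_end = t_end, n_samples = as.integer(n_samples),
                 n_events = res$n_events, absorbed = res$absorbed),
            class = "psd_run")
}

#' @export
print.psd_run <- function(x, ...) {
  cat(sprintf("<psd_run: %d complex types over %d snapshots, seed %s, %g events>\n",
              length(x$keys), x$n_samples, format(x$seed), x$n_events))
  invisible(x)
}

normalize_abundances <- function(model, abundances) {
  sp <- species_names(model)
  if (is.null(names(abundances)) && length(abundances) == length(sp))
    names(abundances) <- sp
  unknown <- setdiff(names(abundances), sp)
  if (length(unknown))
    stop("unknown species in abundances: ", paste(unknown, collapse = ", "))
  counts <- integer(length(sp))
  names(counts) <- sp
  counts[names(abundances)] <- abundances
  if (any(counts < 0) || any(counts != round(counts)))
    stop("copy counts must be non-negative integers")
  as.integer(counts)
}

#' Replicate simulations with consecutive seeds
#'
#' Replicate `i` uses seed `base_seed + i`, so a replicate set is fully
#' determined by `base_seed`. The default replicate count used throughout the
#' pipeline is 40.
#'
#' @inheritParams run_ssa
#' @param n_rep number of replicates (>= 1).
#' @param base_seed integer; replicate `i` runs with seed `base_seed + i`.
#' @param ... passed to [run_ssa()] (`t_end`, `burn_in_fraction`, `n_samples`).
#' @return list of `psd_run` objects, length `n_rep`.
#' @export
replicate_runs <- function(model, abundances, n_rep = 40, base_seed = 0, ...) {
  if (!(is.numeric(n_rep) && n_rep >= 1))
    stop("n_rep must be >= 1")
  lapply(seq_len(n_rep), function(i)
    run_ssa(model, abundances, seed = base_seed + i, ...))
}

#' Per-replicate abundance matrix
#'
#' Collects the mean abundances of a list of runs into an
#' `n_rep x n_complexes` matrix over the union of observed complex keys
#' (absent complexes are 0).
#'
#' @param runs list of `psd_run` objects.
#' @return numeric matrix, one row per replicate, columns named by key.
#' @export
replicate_matrix <- function(runs) {
  keys <- sort(unique(unlist(lapply(runs, function(r) r$keys))))
  m <- matrix(0, nrow = length(runs), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(runs)) m[i, runs[[i]]$keys] <- runs[[i]]$abundance
  m
}

# ---------------------------------------------------------------------------
# Reference implementation of the chain in plain R. One event at a time on an
# explicit state, driven by R's RNG; used for inspection and for validating
# the compiled engine on small systems. The fast path is run_ssa().
# ---------------------------------------------------------------------------

#' Initialize an explicit simulation state (reference implementation)
#'
#' All molecules start as unbound monomers at time 0. The state is a plain R
#' structure meant for small systems and step-by-step inspection; the
#' compiled [run_ssa()] path is used for production runs.
#'
#' @inheritParams run_ssa
#' @return an object of class `sim_state` holding slot occupancy, bonds and
#'   the current time. The RNG is R's own; call `set.seed(seed)` before
#'   stepping for reproducibility (done here when `seed` is given).
#' @export
sim_state <- function(model, abundances, seed = NULL) {
  stopifnot(inherits(model, "interaction_model"))
  counts <- normalize_abundances(model, abundances)
  sp <- species_names(model)
  inst_species <- rep(seq_along(sp), counts)
  slot_inst <- integer(0); slot_species <- integer(0); slot_site <- character(0)
  for (i in seq_along(inst_species)) {
    st <- model$species[[inst_species[i]]]$sites
    for (k in seq_len(nrow(st))) {
      nrep <- st$multiplicity[k]
      slot_inst <- c(slot_inst, rep(i, nrep))
      slot_species <- c(slot_species, rep(inst_species[i], nrep))
      slot_site <- c(slot_site, rep(st$name[k], nrep))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  structure(list(model = model, inst_species = inst_species,
                 slot_inst = slot_inst, slot_species = slot_species,
                 slot_site = slot_site,
                 slot_bond = rep(NA_integer_, length(slot_inst)),
                 bonds = data.frame(rule = character(0), slot_a = integer(0),
                                    slot_b = integer(0)),
                 time = 0),
            class = "sim_state")
}

state_components <- function(state) {
  n <- length(state$inst_species)
  comp <- seq_len(n)
  b <- state$bonds
  if (nrow(b)) {
    repeat {
      changed <- FALSE
      for (j in seq_len(nrow(b))) {
        i1 <- state$slot_inst[b$slot_a[j]]; i2 <- state$slot_inst[b$slot_b[j]]
        if (comp[i1] != comp[i2]) {
          comp[comp == max(comp[i1], comp[i2])] <- min(comp[i1], comp[i2])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  comp
}

#' Event propensities of a simulation state (reference implementation)
#'
#' @param state a [sim_state()].
#' @return data frame with columns `rule`, `type` (`"assoc"`/`"dissoc"`) and
#'   `propensity`.
#' @export
event_propensities <- function(state) {
  model <- state$model
  comp <- state_components(state)
  free <- is.na(state$slot_bond)
  out <- NULL
  for (j in seq_len(nrow(model$rules))) {
    r <- model$rules[j, ]
    fa <- which(free & state$slot_site == r$site_a &
                  species_names(model)[state$slot_species] == r$species_a)
    fb <- which(free & state$slot_site == r$site_b &
                  species_names(model)[state$slot_species] == r$species_b)
    same_class <- (r$species_a == r$species_b && r$site_a == r$site_b)
    if (same_class) {
      pairs <- expand.grid(a = fa, b = fb)
      pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
    } else {
      pairs <- expand.grid(a = fa, b = fb)
    }
    if (nrow(pairs) && !model$allow_intra_complex_binding) {
      keep <- comp[state$slot_inst[pairs$a]] != comp[state$slot_inst[pairs$b]]
      pairs <- pairs[keep, , drop = FALSE]
    }
    n_bonds <- sum(state$bonds$rule == r$id)
    out <- rbind(out,
                 data.frame(rule = r$id, type = "assoc",
                            propensity = r$k_on * nrow(pairs)),
                 data.frame(rule = r$id, type = "dissoc",
                            propensity = r$k_off * n_bonds))
  }
  out
}

#' Advance a simulation state by one Gillespie event (reference implementation)
#'
#' Advances time by an exponential waiting time with rate equal to the total
#' propensity and applies one event sampled proportionally to propensity.
#' With zero total propensity the state is absorbing: it is returned
#' unchanged with attribute `absorbed = TRUE`.
#'
#' @param state a [sim_state()].
#' @return the updated `sim_state`.
#' @export
sim_step <- function(state) {
  model <- state$model
  props <- event_propensities(state)
  A <- sum(props$propensity)
  if (A <= 0) {
    attr(state, "absorbed") <- TRUE
    return(state)
  }
  state$time <- state$time + stats::rexp(1, A)
  k <- sample.int(nrow(props), 1, prob = props$propensity)
  r <- model$rules[match(props$rule[k], model$rules$id), ]
  if (props$type[k] == "assoc") {
    comp <- state_components(state)
    free <- is.na(state$slot_bond)
    fa <- which(free & state$slot_site == r$site_a &
                  species_names(model)[state$slot_species] == r$species_a)
    fb <- which(free & state$slot_site == r$site_b &
                  species_names(model)[state$slot_species] == r$species_b)
    pairs <- expand.grid(a = fa, b = fb)
    if (r$species_a == r$species_b && r$site_a == r$site_b)
      pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
    if (!model$allow_intra_complex_binding)
      pairs <- pairs[comp[state$slot_inst[pairs$a]] !=
                       comp[state$slot_inst[pairs$b]], , drop = FALSE]
    sel <- pairs[sample.int(nrow(pairs), 1), ]
    bid <- nrow(state$bonds) + 1L
    state$bonds <- rbind(state$bonds,
                         data.frame(rule = r$id, slot_a = sel$a, slot_b = sel$b))
    state$slot_bond[c(sel$a, sel$b)] <- bid
  } else {
    cand <- which(state$bonds$rule == r$id)
    j <- cand[sample.int(length(cand), 1)]
    state$slot_bond[c(state$bonds$slot_a[j], state$bonds$slot_b[j])] <- NA_integer_
    state$bonds <- state$bonds[-j, , drop = FALSE]
    state$slot_bond[!is.na(state$slot_bond) & state$slot_bond > j] <-
      state$slot_bond[!is.na(state$slot_bond) & state$slot_bond > j] - 1L
  }
  state
}

#' Complex keys of the current state (reference implementation)
#'
#' @param state a [sim_state()].
#' @return character vector with one canonical key per complex (connected
#'   component), including monomers.
#' @export
state_complex_keys <- function(state) {
  comp <- state_components(state)
  model <- state$model
  sp <- species_names(model)
  vapply(sort(unique(comp)), function(cc) {
    mem <- which(comp == cc)
    loc <- match(seq_along(comp), mem)
    b <- state$bonds
    keep <- which(comp[state$slot_inst[b$slot_a]] == cc)
    rr <- model$rules[match(b$rule[keep], model$rules$id), , drop = FALSE]
    canonical_key(complex_graph(
      species = sp[state$inst_species[mem]],
      edges = data.frame(
        a = loc[state$slot_inst[b$slot_a[keep]]],
        b = loc[state$slot_inst[b$slot_b[keep]]],
        rule = b$rule[keep],
        site_a = state$slot_site[b$slot_a[keep]],
        site_b = state$slot_site[b$slot_b[keep]])))
  }, character(1))
}
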