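# Brute-force labeled-graph isomorphism oracle, independent of the package's
# canonicalization: a graph's oracle form is the minimum, over every
# species-preserving permutation of its nodes, of a flat encoding (species in
# sorted order plus the sorted multiset of permuted edge signatures). Two
# graphs are isomorphic iff their oracle forms are equal.

# all permutations of seq_len(n) as rows (n <= 7 here)
.perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  p <- get0(key, envir = .perm_cache)
  if (!is.null(p)) return(p)
  p <- if (n == 1) matrix(1L, 1, 1) else {
    sub <- all_perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      m <- sub
      m[m >= k] <- m[m >= k] + 1L
      cbind(rep(k, nrow(m)), m, deparse.level = 0)
    }))
  }
  assign(key, p, envir = .perm_cache)
  p
}

# permutations `perm` with g$species[i] placed at target slot perm[i], where
# target slots are grouped by sorted species (species-preserving only)
species_perms <- function(species) {
  ord <- order(species)                 # target slot t holds species[ord[t]]
  groups <- split(seq_along(species), species)
  placements <- list(integer(length(species)))
  for (g in groups) {
    # slots (in target numbering) that carry this species
    slots <- which(species[ord] == species[g[1]])
    pg <- all_perms(length(g))
    placements <- do.call(c, lapply(seq_len(nrow(pg)), function(r) {
      lapply(placements, function(base) {
        base[g] <- slots[pg[r, ]]
        base
      })
    }))
  }
  placements
}

edge_sigs <- function(edges, perm) {
  if (!nrow(edges)) return(character(0))
  a <- perm[edges$a]; b <- perm[edges$b]
  swap <- a > b | (a == b & edges$site_a > edges$site_b)
  sort(ifelse(swap,
              paste0(b, "-", a, ":", edges$rule, "/", edges$site_b, "/", edges$site_a),
              paste0(a, "-", b, ":", edges$rule, "/", edges$site_a, "/", edges$site_b)))
}

oracle_form <- function(g) {
  sp <- paste(sort(g$species), collapse = ",")
  best <- NULL
  for (perm in species_perms(g$species)) {
    enc <- paste(edge_sigs(g$edges, perm), collapse = ";")
    if (is.null(best) || enc < best) best <- enc
  }
  paste0(sp, "#", best)
}

oracle_isomorphic <- function(g1, g2) oracle_form(g1) == oracle_form(g2)

# -------------------------------------------------------------------------
# Exhaustive enumeration of connected bond graphs realizable under a model's
# rule set: trees grown by leaf attachment up to `max_tree_nodes`, plus every
# cyclic/multi-edge closure (adding rule-compatible edges between existing
# nodes, including self-loops) on graphs up to `max_cyclic_nodes`.
# Deduplicated up to isomorphism via the oracle form.
# -------------------------------------------------------------------------

model_site_caps <- function(model) {
  caps <- list()
  for (s in model$species)
    caps[[s$name]] <- stats::setNames(as.integer(s$sites$multiplicity),
                                      s$sites$name)
  caps
}

free_sites <- function(g, caps) {
  out <- NULL
  for (i in seq_along(g$species)) {
    cap <- caps[[g$species[i]]]
    used <- stats::setNames(integer(length(cap)), names(cap))
    e <- g$edges
    if (nrow(e)) {
      ia <- which(e$a == i); ib <- which(e$b == i)
      for (s in e$site_a[ia]) used[s] <- used[s] + 1L
      for (s in e$site_b[ib]) used[s] <- used[s] + 1L
    }
    left <- cap - used
    for (s in names(left)[left > 0])
      out <- rbind(out, data.frame(node = i, site = s, free = left[[s]]))
  }
  if (is.null(out)) data.frame(node = integer(0), site = character(0),
                               free = integer(0)) else out
}

add_edge <- function(g, a, b, rule, site_a, site_b) {
  g$edges <- rbind(g$edges, data.frame(a = a, b = b, rule = rule,
                                       site_a = site_a, site_b = site_b))
  g
}

attach_children <- function(g, model, caps) {
  fs <- free_sites(g, caps)
  out <- list()
  r <- model$rules
  for (j in seq_len(nrow(r))) {
    # new partner on side b, attached to a free a-side site
    hit <- fs[g$species[fs$node] == r$species_a[j] & fs$site == r$site_a[j], ]
    for (nd in hit$node) {
      g2 <- g
      g2$species <- c(g2$species, r$species_b[j])
      out[[length(out) + 1]] <- add_edge(g2, nd, length(g2$species),
                                         r$id[j], r$site_a[j], r$site_b[j])
    }
    # new partner on side a, attached to a free b-side site
    hit <- fs[g$species[fs$node] == r$species_b[j] & fs$site == r$site_b[j], ]
    for (nd in hit$node) {
      g2 <- g
      g2$species <- c(g2$species, r$species_a[j])
      out[[length(out) + 1]] <- add_edge(g2, length(g2$species), nd,
                                         r$id[j], r$site_a[j], r$site_b[j])
    }
  }
  out
}

close_edges <- function(g, model, caps) {
  fs <- free_sites(g, caps)
  out <- list()
  r <- model$rules
  for (j in seq_len(nrow(r))) {
    fa <- fs[g$species[fs$node] == r$species_a[j] & fs$site == r$site_a[j], ]
    fb <- fs[g$species[fs$node] == r$species_b[j] & fs$site == r$site_b[j], ]
    for (na in fa$node) for (nb in fb$node) {
      same_class <- r$species_a[j] == r$species_b[j] && r$site_a[j] == r$site_b[j]
      if (na == nb) {
        if (same_class && fa$free[fa$node == na] < 2) next  # one slot, no pair
        if (same_class && na > nb) next
      }
      if (same_class && na > nb) next  # unordered
      out[[length(out) + 1]] <- add_edge(g, na, nb, r$id[j],
                                         r$site_a[j], r$site_b[j])
    }
  }
  out
}

enumerate_fixture_graphs <- function(model, max_tree_nodes = 7,
                                     max_cyclic_nodes = 5) {
  caps <- model_site_caps(model)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  reps <- list()
  keep <- function(g) {
    f <- oracle_form(g)
    if (!is.null(get0(f, envir = seen))) return(NULL)
    assign(f, TRUE, envir = seen)
    reps[[length(reps) + 1]] <<- g
    g
  }
  frontier <- list()
  for (s in model$species) {
    g <- complex_graph(s$name)
    if (!is.null(keep(g))) frontier[[length(frontier) + 1]] <- g
  }
  # trees by leaf attachment
  n <- 1
  while (n < max_tree_nodes) {
    nxt <- list()
    for (g in frontier)
      for (child in attach_children(g, model, caps))
        if (!is.null(keep(child))) nxt[[length(nxt) + 1]] <- child
    frontier <- nxt
    n <- n + 1
  }
  # cyclic closure on everything small enough (repeat until no new graphs)
  pool <- Filter(function(g) length(g$species) <= max_cyclic_nodes, reps)
  while (length(pool)) {
    nxt <- list()
    for (g in pool)
      for (child in close_edges(g, model, caps))
        if (!is.null(keep(child))) nxt[[length(nxt) + 1]] <- child
    pool <- nxt
  }
  reps
}
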