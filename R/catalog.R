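#' Complex bond graphs and canonical keys
#'
#' A complex is a connected labeled multigraph: nodes are protein copies
#' labeled by species, edges are bonds labeled by the binding rule and the
#' site name on each endpoint. Two complexes are the same iff their labeled
#' bond graphs are isomorphic; identical copies of a site (e.g. the two
#' PDZ1/2 sites of PSD-95) are interchangeable, so edges carry site *names*,
#' never copy indices. [canonical_key()] returns a string that is identical
#' for two graphs exactly when they are isomorphic: trees (the only complexes
#' reachable under the default acyclic dynamics) use a centroid-rooted
#' canonical form; general graphs use color refinement with exhaustive
#' individualization.
#'
#' @param species character vector of node species labels.
#' @param edges data frame with columns `a`, `b` (1-based node indices),
#'   `rule`, `site_a`, `site_b`; zero rows for a monomer.
#' @return `complex_graph` returns an object of class `complex_graph`.
#' @export
complex_graph <- function(species, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0)
    edges <- data.frame(a = integer(0), b = integer(0), rule = character(0),
                        site_a = character(0), site_b = character(0))
  stopifnot(all(c("a", "b", "rule", "site_a", "site_b") %in% names(edges)))
  structure(list(species = as.character(species), edges = edges),
            class = "complex_graph")
}

#' @rdname complex_graph
#' @param graph a `complex_graph`.
#' @return `canonical_key` returns the canonical key string.
#' @export
canonical_key <- function(graph) {
  stopifnot(inherits(graph, "complex_graph"))
  e <- graph$edges
  cpp_canonical_key(graph$species,
                    cbind(as.integer(e$a), as.integer(e$b)),
                    as.character(e$rule), as.character(e$site_a),
                    as.character(e$site_b))
}

#' Species composition encoded in a canonical key
#'
#' @param key a canonical key string as produced by [canonical_key()] or the
#'   simulation engine.
#' @return named integer vector: species -> copy count (a multiset).
#' @export
composition <- function(key) {
  stopifnot(is.character(key), length(key) == 1)
  if (startsWith(key, "{")) {
    body <- sub("\\{([^#]*)#.*", "\\1", key)
    sp <- strsplit(body, ",", fixed = TRUE)[[1]]
  } else if (startsWith(key, "(")) {
    # species token follows each '(' and ends at '(', ')' or '['
    sp <- regmatches(key, gregexpr("\\(([^()\\[]+)", key))[[1]]
    sp <- sub("^\\(", "", sp)
  } else {
    stop("malformed complex key: ", substr(key, 1, 40))
  }
  if (!length(sp) || any(!nzchar(sp)))
    stop("malformed complex key: ", substr(key, 1, 40))
  out <- table(sp)
  stats::setNames(as.integer(out), names(out))
}

#' Number of proteins in a complex key
#' @inheritParams composition
#' @return integer protein count.
#' @export
complex_size <- function(key) sum(composition(key))

#' Human-readable composition string of a key (e.g. "AMPAR/PSD-95/SynGAP")
#' @inheritParams composition
#' @return single string; repeated species appear with a `xN` suffix.
#' @export
composition_string <- function(key) {
  cmp <- composition(key)
  paste(ifelse(cmp > 1, paste0(names(cmp), "x", cmp), names(cmp)),
        collapse = "/")
}

#' Does a complex key contain a bond formed by a given rule?
#' @inheritParams composition
#' @param rule_id binding rule id.
#' @return logical.
#' @export
key_has_rule <- function(key, rule_id) {
  grepl(paste0("[", rule_id, "/"), key, fixed = TRUE) ||
    grepl(paste0(":", rule_id, "/"), key, fixed = TRUE)
}

#' Complex catalogs: stable numeric ids for canonical keys
#'
#' A catalog maps canonical keys to consecutive numeric ids in first-encounter
#' order. Canonical keys are the stable identity of a complex; numeric ids
#' are run-local conveniences for reporting (their order depends on the order
#' in which complexes were first seen).
#'
#' @param base integer id given to the first registered key (default 1).
#' @return `complex_catalog` returns an empty catalog.
#' @details Canonical keys of large polymeric complexes can be arbitrarily
#'   long, so the catalog indexes them through 64-bit string hashes with
#'   collision buckets rather than using the keys as environment names.
#' @export
complex_catalog <- function(base = 1L) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  meta <- new.env(parent = emptyenv())
  assign("n", 0L, envir = meta)
  structure(list(env = env, base = as.integer(base), meta = meta),
            class = "complex_catalog")
}

#' @rdname complex_catalog
#' @param catalog a `complex_catalog`.
#' @param key canonical key string.
#' @return `register` returns the `ComplexRecord` for `key`: a list with
#'   `key`, `numeric_id`, `composition`, `size`. Registering a known key
#'   returns its existing record.
#' @export
register <- function(catalog, key) {
  stopifnot(inherits(catalog, "complex_catalog"))
  h <- cpp_hash_keys(key)
  bucket <- get0(h, envir = catalog$env, inherits = FALSE)
  if (!is.null(bucket))
    for (rec in bucket) if (rec$key == key) return(rec)
  n <- get("n", envir = catalog$meta)
  id <- catalog$base + n
  cmp <- composition(key)
  rec <- list(key = key, numeric_id = id, composition = cmp,
              size = sum(cmp))
  assign(h, c(bucket, list(rec)), envir = catalog$env)
  assign("n", n + 1L, envir = catalog$meta)
  rec
}

#' @rdname complex_catalog
#' @return `catalog_size` returns the number of distinct registered keys.
#' @export
catalog_size <- function(catalog) get("n", envir = catalog$meta)

#' @rdname complex_catalog
#' @return `catalog_table` returns a data frame (`numeric_id`, `key`,
#'   `composition`, `size`) sorted by id.
#' @export
catalog_table <- function(catalog) {
  hashes <- ls(catalog$env, all.names = TRUE)
  if (!length(hashes))
    return(data.frame(numeric_id = integer(0), key = character(0),
                      composition = character(0), size = integer(0)))
  recs <- do.call(c, lapply(hashes, function(h) get(h, envir = catalog$env)))
  df <- data.frame(
    numeric_id = vapply(recs, function(r) r$numeric_id, integer(1)),
    key = vapply(recs, function(r) r$key, character(1)),
    composition = vapply(recs, function(r)
      composition_string(r$key), character(1)),
    size = vapply(recs, function(r) as.integer(r$size), integer(1)))
  df[order(df$numeric_id), , drop = FALSE]
}
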