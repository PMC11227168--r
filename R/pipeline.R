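#' Read and write region abundance tables
#'
#' A region table is a flat TSV/CSV with header
#' `region_id, region_type, <one column per model protein>`; lines starting
#' with `#` are provenance comments. Values may be mRNA expression levels
#' (see [scale_mrna()]) or protein copy numbers.
#'
#' @param path file path.
#' @param proteins optional character vector of protein columns that must be
#'   present (e.g. `species_names(model)`).
#' @return data frame with `region_id`, `region_type` and protein columns.
#' @export
read_region_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("region table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("region_id", "region_type") %in% names(df)))
    stop("region table must have region_id and region_type columns: ", path)
  if (!is.null(proteins)) {
    miss <- setdiff(proteins, names(df))
    if (length(miss))
      stop("region table is missing protein columns: ",
           paste(miss, collapse = ", "))
  }
  vals <- df[, setdiff(names(df), c("region_id", "region_type")), drop = FALSE]
  if (any(vals < 0)) stop("region table contains negative values")
  df
}

#' @rdname read_region_table
#' @param df region table data frame.
#' @param header_lines optional character vector written as `#` comments.
#' @export
write_region_table <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale mRNA expression to protein copy numbers
#'
#' Expression values are converted to copy numbers by one global linear
#' factor anchored on PSD-95: `f = psd95_reference / mean(expression of
#' PSD-95 across regions)`. Every protein value is multiplied by `f` and
#' rounded to the nearest non-negative integer. A single global factor (not
#' per-region) preserves the between-region variation of PSD-95 itself.
#'
#' @param df region table with expression values.
#' @param psd95_reference target mean PSD-95 copy number (default 328.09, the
#'   across-region mean of the reference abundance statistics).
#' @param psd95_col name of the PSD-95 column.
#' @return region table with integer copy numbers.
#' @export
scale_mrna <- function(df, psd95_reference = 328.09, psd95_col = "PSD-95") {
  if (!psd95_col %in% names(df))
    stop("column '", psd95_col, "' not found in region table")
  m <- mean(df[[psd95_col]])
  if (!is.finite(m) || m <= 0)
    stop("PSD-95 column has non-positive mean; cannot scale")
  f <- psd95_reference / m
  cols <- setdiff(names(df), c("region_id", "region_type"))
  for (cn in cols) df[[cn]] <- pmax(0, round(df[[cn]] * f))
  df
}

#' Simulate one region under the wild-type and mutant scenarios
#'
#' Runs [replicate_runs()] twice: once with `model` and once with
#' `apply_mutation(model, mutation)`. With `paired_seeds = TRUE` (default),
#' replicate `i` of both scenarios uses the same seed (common random
#' numbers), so the paired difference isolates the effect of the rate
#' perturbation; with the identity mutation the two scenarios are then
#' bitwise identical.
#'
#' @param region one-row data frame (or list) with `region_id`, `region_type`
#'   and one copy-number entry per model protein.
#' @param model an [interaction_model()].
#' @param mutation a [mutation_spec()].
#' @param n_rep replicates per scenario (default 40).
#' @param base_seed integer; replicate `i` uses seed `base_seed + i`.
#' @param paired_seeds logical; if `FALSE` the mutant replicates use seeds
#'   `base_seed + n_rep + i` instead (independent streams).
#' @param ... passed to [run_ssa()].
#' @return object of class `scenario_pair`: `region_id`, `region_type`,
#'   `keys` (union over scenarios), `wt` and `mut` replicate-by-complex
#'   abundance matrices.
#' @export
run_region <- function(region, model, mutation, n_rep = 40, base_seed = 0,
                       paired_seeds = TRUE, ...) {
  sp <- species_names(model)
  ab <- unlist(region[sp])
  wt_runs <- replicate_runs(model, ab, n_rep = n_rep, base_seed = base_seed, ...)
  mut_model <- apply_mutation(model, mutation)
  mut_base <- if (paired_seeds) base_seed else base_seed + n_rep
  mut_runs <- replicate_runs(mut_model, ab, n_rep = n_rep,
                             base_seed = mut_base, ...)
  wt <- replicate_matrix(wt_runs)
  mut <- replicate_matrix(mut_runs)
  keys <- sort(unique(c(colnames(wt), colnames(mut))))
  pad <- function(m) {
    out <- matrix(0, nrow = nrow(m), ncol = length(keys),
                  dimnames = list(NULL, keys))
    out[, colnames(m)] <- m
    out
  }
  structure(list(region_id = as.character(region[["region_id"]]),
                 region_type = as.character(region[["region_type"]]),
                 keys = keys, wt = pad(wt), mut = pad(mut)),
            class = "scenario_pair")
}

#' Run the full experiment over a region table
#'
#' @param regions region table (copy numbers).
#' @param model an [interaction_model()].
#' @param mutation a [mutation_spec()].
#' @param n_rep replicates per scenario and region.
#' @param base_seed integer; region `r` (row order) uses replicate seeds
#'   `base_seed + (r - 1) * seed_stride + i`, independent of scheduling.
#' @param seed_stride seed offset between regions (default 10000; must exceed
#'   `2 * n_rep`).
#' @param progress logical; print one line per region.
#' @param ... passed to [run_ssa()].
#' @return list of `scenario_pair`, one per region.
#' @export
run_experiment <- function(regions, model, mutation, n_rep = 40,
                           base_seed = 0, seed_stride = 10000,
                           progress = FALSE, ...) {
  if (seed_stride <= 2 * n_rep) stop("seed_stride must exceed 2 * n_rep")
  lapply(seq_len(nrow(regions)), function(r) {
    if (progress)
      message("region ", r, "/", nrow(regions), ": ", regions$region_id[r])
    run_region(regions[r, , drop = FALSE], model, mutation, n_rep = n_rep,
               base_seed = base_seed + (r - 1) * seed_stride, ...)
  })
}

#' Assemble the region-by-complex abundance matrix
#'
#' One row per region, one column per complex key; the column set is the
#' union of the keys observed in any region under either scenario (absent
#' complexes are 0); cells are replicate means.
#'
#' @param pairs list of `scenario_pair` objects (see [run_region()]).
#' @param scenario `"wt"` or `"mut"`.
#' @return numeric matrix with region ids as row names and canonical keys as
#'   column names; attribute `scenario` records the scenario.
#' @export
assemble_matrix <- function(pairs, scenario = c("wt", "mut")) {
  scenario <- match.arg(scenario)
  if (!length(pairs)) stop("need at least one region")
  ids <- vapply(pairs, function(p) p$region_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate region_id: ", ids[duplicated(ids)][1])
  keys <- sort(unique(unlist(lapply(pairs, function(p) p$keys))))
  m <- matrix(0, nrow = length(pairs), ncol = length(keys),
              dimnames = list(ids, keys))
  for (i in seq_along(pairs)) {
    x <- colMeans(pairs[[i]][[scenario]])
    m[i, names(x)] <- x
  }
  attr(m, "scenario") <- scenario
  m
}

#' Per-species copy totals implied by an abundance row
#'
#' Lifts the engine's conservation law through averaging: for a vector of
#' complex abundances, returns the total copies of each species, i.e.
#' `sum over complexes of abundance * copies of the species in the complex`.
#'
#' @param abundance named numeric vector (complex key -> abundance).
#' @param proteins character vector of species to total.
#' @return named numeric vector of per-species totals.
#' @export
species_totals <- function(abundance, proteins) {
  out <- stats::setNames(numeric(length(proteins)), proteins)
  keys <- names(abundance)
  for (k in seq_along(abundance)) {
    cmp <- composition(keys[k])
    hit <- intersect(names(cmp), proteins)
    out[hit] <- out[hit] + abundance[k] * cmp[hit]
  }
  out
}

#' Write an abundance matrix (with catalog sidecar) to TSV
#'
#' @param m matrix from [assemble_matrix()].
#' @param path output TSV path (regions x complex numeric ids).
#' @param catalog a [complex_catalog()]; all matrix keys are registered so
#'   the sidecar maps numeric ids back to canonical keys.
#' @param header_lines provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, catalog, header_lines = character(0)) {
  ids <- vapply(colnames(m), function(k) register(catalog, k)$numeric_id,
                integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  df <- data.frame(region_id = rownames(m), check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  names(df) <- c("region_id", paste0("c", ids))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
write_catalog_tsv <- function(catalog, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(catalog_table(catalog), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
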