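#' Reference abundance statistics for the seven-protein model
#'
#' Per-protein minimum, maximum, mean and standard deviation of the input
#' copy numbers (derived from mRNA expression across brain regions) used as
#' the default profile for the synthetic region generator.
#'
#' @return data frame with columns `protein`, `min`, `max`, `mean`, `sd`.
#' @export
abundance_profile <- function() {
  data.frame(
    protein = c("NMDAR", "AMPAR", "PSD-95", "SynGAP", "GKAP", "Shank1",
                "Homer1"),
    min  = c(0,  1,   36,  11,  2,   1,   1),
    max  = c(95, 688, 1067, 359, 367, 388, 124),
    mean = c(16.84, 126.81, 328.09, 102.21, 82.62, 69.20, 21.98),
    sd   = c(17.87, 78.39, 159.21, 60.13, 65.50, 59.40, 17.20))
}

# mean and sd of a normal(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z <= 0) return(c(NA_real_, NA_real_))
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# parent (mu, sigma) whose [a, b]-truncation has the target mean and sd
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    if (any(!is.finite(mo))) return(1e6)
    ((mo[1] - target_mean) / target_sd)^2 + ((mo[2] - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate synthetic region abundance tables
#'
#' Draws per-protein copy numbers from a truncated normal on the profile's
#' `[min, max]` range, rounded to integers and clamped to the range. The
#' parent normal is moment-matched so that the *truncated* distribution has
#' the profile's mean and SD (a normal truncated at the profile parameters
#' directly would be biased upward for the low-abundance proteins).
#' Alternatively a moment-matched log-normal (`distribution = "lognormal"`)
#' captures the right-skew of real expression data. Regions are assigned
#' round-robin to `n_types` region types. Proteins are sampled independently;
#' between-protein correlation present in real data is not emulated.
#'
#' @param n_regions number of regions (default 524).
#' @param n_types number of region types (default 27).
#' @param profile data frame as returned by [abundance_profile()].
#' @param seed integer seed (R RNG); identical seeds give identical tables.
#' @param distribution `"truncnorm"` (default) or `"lognormal"`.
#' @return region table data frame (`region_id`, `region_type`, one column
#'   per protein).
#' @export
generate_regions <- function(n_regions = 524, n_types = 27,
                             profile = abundance_profile(), seed = 1,
                             distribution = c("truncnorm", "lognormal")) {
  distribution <- match.arg(distribution)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (any(profile$max < profile$min))
    stop("infeasible profile: max < min for ",
         profile$protein[profile$max < profile$min][1])
  if (any(profile$sd < 0)) stop("profile SD must be >= 0")
  set.seed(seed)
  out <- data.frame(
    region_id = sprintf("R%04d", seq_len(n_regions)),
    region_type = paste0("type",
                         ((seq_len(n_regions) - 1) %% n_types) + 1),
    check.names = FALSE)
  for (i in seq_len(nrow(profile))) {
    a <- profile$min[i]; b <- profile$max[i]
    m <- profile$mean[i]; s <- profile$sd[i]
    if (s == 0) {
      x <- rep(round(m), n_regions)
    } else if (distribution == "truncnorm") {
      par <- truncnorm_match(m, s, a, b)
      lo <- stats::pnorm(a, par["mu"], par["sigma"])
      hi <- stats::pnorm(b, par["mu"], par["sigma"])
      u <- stats::runif(n_regions, lo, hi)
      x <- round(stats::qnorm(u, par["mu"], par["sigma"]))
    } else {
      # log-normal with the target mean and sd, truncated to [a, b]
      sdlog2 <- log(1 + (s / m)^2)
      mulog <- log(m) - sdlog2 / 2
      sdlog <- sqrt(sdlog2)
      lo <- stats::plnorm(max(a, 0), mulog, sdlog)
      hi <- stats::plnorm(b, mulog, sdlog)
      u <- stats::runif(n_regions, lo, hi)
      x <- round(stats::qlnorm(u, mulog, sdlog))
    }
    out[[profile$protein[i]]] <- pmin(pmax(x, ceiling(a)), floor(b))
  }
  out
}

#' Exact stationary law of the reversible dimerization chain
#'
#' For `A + B <-> AB` with `n_A` and `n_B` copies, the bond count `k` is a
#' 1-D birth-death chain with birth rate `k_on * (n_A - k) * (n_B - k)` and
#' death rate `k_off * k`. Detailed balance gives
#' `pi(k) proportional to prod_{j<k} k_on (n_A - j)(n_B - j) / (k_off (j+1))`.
#' This closed form is the independent oracle used to validate the
#' simulation engine.
#'
#' @param n_A,n_B copy numbers (non-negative integers).
#' @param k_on,k_off positive rates.
#' @return list with `k` (0..min(n_A, n_B)), `pi` (stationary probabilities,
#'   summing to 1) and `mean` (stationary mean bond count).
#' @export
exact_dimer_equilibrium <- function(n_A, n_B, k_on = 1, k_off = 1) {
  stopifnot(n_A >= 0, n_B >= 0, k_on > 0, k_off > 0)
  kmax <- min(n_A, n_B)
  lp <- c(0, cumsum(vapply(seq_len(kmax), function(k) {
    j <- k - 1
    log(k_on) + log(n_A - j) + log(n_B - j) - log(k_off) - log(j + 1)
  }, numeric(1))))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  list(k = 0:kmax, pi = p, mean = sum((0:kmax) * p))
}

#' Toy dimer model A + B <-> AB
#'
#' Two monovalent species with one binding rule; its exact stationary law is
#' [exact_dimer_equilibrium()].
#'
#' @param k_on,k_off rates of the single rule `ab`.
#' @return an [interaction_model()].
#' @export
dimer_model <- function(k_on = 1, k_off = 1) {
  interaction_model(
    species = list(
      list(name = "A", sites = data.frame(name = "x", multiplicity = 1L)),
      list(name = "B", sites = data.frame(name = "y", multiplicity = 1L))),
    rules = data.frame(id = "ab", species_a = "A", site_a = "x",
                       species_b = "B", site_b = "y",
                       k_on = k_on, k_off = k_off),
    name = "dimer")
}

#' One-call harness for the seven-protein experiment
#'
#' Returns everything needed to reproduce the full pipeline at configurable
#' scale: the bundled `psd7_default` model, a synthetic region table with the
#' reference abundance statistics, and the hypomorphic mutation spec
#' (Shank1 PDZ : GKAP off-rate multiplied by 5.5).
#'
#' @param seed integer seed for the region table.
#' @param n_regions number of synthetic regions (default 30; use 524 for the
#'   full-scale setting).
#' @param n_types number of region types.
#' @param n_rep replicate count carried along for the pipeline (default 40).
#' @param off_rate_factor mutation off-rate multiplier (default 5.5).
#' @return list with `model`, `regions`, `mutation`, `n_rep`.
#' @export
make_psd7_experiment <- function(seed = 1, n_regions = 30, n_types = 27,
                                 n_rep = 40, off_rate_factor = 5.5) {
  list(model = psd7_model(),
       regions = generate_regions(n_regions = n_regions, n_types = n_types,
                                  seed = seed),
       mutation = mutation_spec("shank1_pdz_gkap", off_rate_factor),
       n_rep = n_rep)
}
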