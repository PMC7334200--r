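# Absolute per-site per-generation mutation rate estimation.

#' Per-site per-generation mutation rate
#'
#' The observed mutation count divided by the product of the number of
#' sites and the number of gametogeneses (two per trio).
#'
#' @param n_obs Observed mutation count.
#' @param n_site Number of sites.
#' @param n_gen Number of gametogeneses.
#' @return The rate `n_obs / (n_site * n_gen)`.
#' @export
mutation_rate <- function(n_obs, n_site, n_gen) {
  stop_if_not_scalar_count(n_obs, "n_obs")
  stop_if_not_scalar_count(n_site, "n_site")
  stop_if_not_scalar_count(n_gen, "n_gen")
  if (n_site == 0 || n_gen == 0) {
    stop("'n_site' and 'n_gen' must be positive")
  }
  as.numeric(n_obs) / (as.numeric(n_site) * as.numeric(n_gen))
}

#' Exonic and intronic mutation rates from stacked windows
#'
#' The exonic compartment is the set of central-exon window sites; the
#' intronic proxy is every remaining window site (including flanks that
#' contain neighboring exons). Sites and mutations are counted per window
#' occurrence, so a position shared by two overlapping windows counts
#' twice in both numerator and denominator.
#'
#' @param windows A `dnm_windows` object.
#' @param dnms DNM data.frame.
#' @param n_gen Number of gametogeneses (2 x trios).
#' @return data.frame with one row per compartment: n_obs, n_site, n_gen
#'   and the rate mu.
#' @export
window_mutation_rates <- function(windows, dnms, n_gen) {
  dnms <- validate_dnms(dnms)
  hits <- map_mutations_to_windows(windows, dnms)
  central <- windows$labels == 1L
  is_central <- central[cbind(hits$window, hits$offset)]
  n_site_e <- sum(central)
  n_site_i <- length(central) - n_site_e
  data.frame(
    compartment = c("exonic", "intronic"),
    n_obs = c(sum(is_central), sum(!is_central)),
    n_site = c(n_site_e, n_site_i),
    n_gen = n_gen,
    mu = c(mutation_rate(sum(is_central), n_site_e, n_gen),
           mutation_rate(sum(!is_central), n_site_i, n_gen)))
}
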