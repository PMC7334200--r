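# Context-model comparison by full-site log-likelihood and AIC.
#
# Every site of every window contributes: a mutated site contributes
# log P(observed alternate | context), an unmutated site contributes
# log(1 - sum of the three alternate probabilities). Sites lacking the
# widest compared context are excluded from all schemes so likelihoods
# are computed on a common sample. At a recurrent site one mutation is
# chosen at random under a recorded seed.

#' Assemble per-site observed states over all windows
#'
#' @param windows A `dnm_windows` object.
#' @param dnms DNM data.frame.
#' @param seed Seed for the random choice of one mutation at recurrent
#'   sites.
#' @return Object of class `site_state_data`: the windows, a data.frame of
#'   mutated window sites (window, offset, alt), the total site count and
#'   the seed.
#' @export
site_state_data <- function(windows, dnms, seed = 1L) {
  dnms <- validate_dnms(dnms)
  hits <- map_mutations_to_windows(windows, dnms)
  hits$alt <- dnms$alt[hits$row]
  key <- paste(hits$window, hits$offset)
  if (anyDuplicated(key)) {
    hits <- withr::with_seed(seed, {
      hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
      hits[!duplicated(paste(hits$window, hits$offset)), , drop = FALSE]
    })
  }
  structure(list(windows = windows,
                 mutated = hits[order(hits$window, hits$offset),
                                c("window", "offset", "alt")],
                 total_sites = nrow(windows$windows) * windows$width,
                 seed = seed),
            class = "site_state_data")
}

#' Full-site log-likelihood of a context model
#'
#' @param data A `site_state_data` object.
#' @param model A `context_model`.
#' @param genome Named `DNAStringSet`.
#' @param valid Optional logical matrix (windows x width) of sites to
#'   include; defaults to sites with readable context at the model's own
#'   width.
#' @return Log-likelihood (scalar). The number of observed mutations with
#'   zero modeled probability (each contributing -Inf) is attached as
#'   `attr(, "n_zero_prob")`.
#' @export
site_loglikelihood <- function(data, model, genome, valid = NULL) {
  windows <- data$windows
  win <- windows$windows
  S <- nrow(win); L <- windows$width
  code_list <- genome_codes(genome, model$k_eff)
  fvec <- rowSums(model$prob)
  if (any(fvec > 1 + 1e-12)) {
    stop("invalid model: total mutation probability exceeds 1 for some context")
  }
  ll <- 0
  n_zero <- 0L
  mut <- data$mutated
  mut_split <- split(seq_len(nrow(mut)),
                     factor(mut$window, levels = seq_len(S)))
  for (s in seq_len(S)) {
    pos <- win$start[s]:win$end[s]
    codes <- code_list[[win$chrom[s]]][pos]
    f <- fvec[codes + 1]
    ok <- !is.na(f)
    if (!is.null(valid)) ok <- ok & valid[s, ]
    log_unmut <- log1p(-f)
    ms <- mut[mut_split[[s]], , drop = FALSE]
    contrib <- sum(log_unmut[ok])
    if (nrow(ms) > 0) {
      o <- ms$offset
      use <- ok[o]
      contrib <- contrib - sum(log_unmut[o[use]])
      pmut <- model$prob[cbind(codes[o[use]] + 1,
                               match(ms$alt[use], BASES))]
      n_zero <- n_zero + sum(pmut == 0)
      contrib <- contrib + sum(log(pmut))
    }
    ll <- ll + contrib
  }
  attr(ll, "n_zero_prob") <- n_zero
  ll
}

#' Akaike information criterion
#'
#' @param loglik Log-likelihood.
#' @param n_params Number of free parameters.
#' @return `2 * n_params - 2 * loglik`.
#' @export
aic <- function(loglik, n_params) {
  2 * n_params - 2 * loglik
}

#' Compare context schemes on a common site set
#'
#' Estimates each scheme's model from the training mutations, evaluates
#' the full-site log-likelihood over all window sites (excluding, for
#' every scheme alike, sites lacking the widest scheme's context), and
#' computes AIC and the exonic-excess permutation test per scheme. An
#' observed mutation with zero modeled probability makes the comparison
#' fail unless `prob_floor` is set.
#'
#' @param windows A `dnm_windows` object.
#' @param dnms DNM data.frame; used both as training mutations and as the
#'   observed states (in-sample, as in the source analysis).
#' @param genome Named `DNAStringSet`.
#' @param schemes List of [context_scheme()] objects.
#' @param n_perm Permutations for the excess test (default 1000).
#' @param seed Seed for recurrent-site resolution and permutations.
#' @param prob_floor Optional pseudo-probability substituted for zero
#'   modeled probabilities of observed mutations (default off).
#' @return data.frame of class `model_comparison`: one row per scheme with
#'   excess_pct, sd_pct, p_value, loglik, n_params, aic and a `best` flag
#'   on the minimum-AIC scheme.
#' @export
compare_models <- function(windows, dnms, genome, schemes,
                           n_perm = 1000L, seed = 1L, prob_floor = NULL) {
  stopifnot(length(schemes) >= 1)
  dnms <- validate_dnms(dnms)
  k_max <- max(vapply(schemes, function(s) {
    if (s$kind == "cpg") 3L else s$k
  }, 0L))
  # common valid-site mask: context readable at the widest scheme
  win <- windows$windows
  S <- nrow(win); L <- windows$width
  code_list <- genome_codes(genome, k_max)
  valid <- matrix(TRUE, S, L)
  for (s in seq_len(S)) {
    codes <- code_list[[win$chrom[s]]][win$start[s]:win$end[s]]
    valid[s, ] <- !is.na(codes)
  }
  data <- site_state_data(windows, dnms, seed = seed)
  rows <- lapply(schemes, function(sch) {
    model <- estimate_context_model(dnms, genome, sch)
    if (!is.null(prob_floor)) {
      model$prob[model$prob == 0] <- prob_floor
    }
    ll <- site_loglikelihood(data, model, genome, valid = valid)
    if (attr(ll, "n_zero_prob") > 0) {
      stop(attr(ll, "n_zero_prob"), " observed mutation(s) with zero ",
           "modeled probability under scheme ", format(sch),
           "; set 'prob_floor' to proceed")
    }
    ex <- exonic_excess_test(windows, dnms, genome, model, n_perm = n_perm,
                             seed = seed)
    data.frame(model = format(sch), excess_pct = ex$excess_pct,
               sd_pct = ex$sd_pct, p_value = ex$p_value,
               loglik = as.numeric(ll), n_params = parameter_count(sch),
               aic = aic(as.numeric(ll), parameter_count(sch)))
  })
  out <- do.call(rbind, rows)
  out$best <- out$aic == min(out$aic)
  class(out) <- c("model_comparison", "data.frame")
  out
}
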