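# Observed and expected mutation profiles over stacked internal-exon-
# centered windows, and the permutation test of exonic excess.
#
# For each window, per-site mutation frequencies f_l (sum of the three
# alternate probabilities under a context model) are rescaled to sum to 1
# across the window. The window's observed mutation total n_s is then
# redistributed over its sites in proportion to the rescaled frequencies,
# so expected counts are conserved per window by construction. The excess
# statistic counts mutations at central-exon sites and compares them to
# the mean over permutations in which each window's n_s mutations are
# redrawn multinomially over its sites. Only the central-exon total of
# each permutation enters the statistic, and the multinomial marginal of
# a category subset is binomial, so permutations draw the exonic count
# directly as Binomial(n_s, p_exonic) per window -- an exact, faster
# equivalent of redrawing all sites.

# Per-window site frequencies under a model, optionally restricting
# central-exon site frequencies to alternates with a given coding
# consequence. Returns matrices f and fresc (S x L).
window_site_freq <- function(windows, genome, model, stratify = NULL,
                             models = NULL) {
  fchrom <- site_mutation_freq(genome, model)
  win <- windows$windows
  S <- nrow(win); L <- windows$width
  f <- matrix(0, nrow = S, ncol = L)
  for (s in seq_len(S)) {
    f[s, ] <- fchrom[[win$chrom[s]]][win$start[s]:win$end[s]]
  }
  if (!is.null(stratify)) {
    stratify <- match.arg(stratify, c("synonymous", "nonsynonymous"))
    if (is.null(models)) stop("'models' is required for stratification")
    code_list <- genome_codes(genome, model$k_eff)
    sam_cache <- new.env()
    for (s in seq_len(S)) {
      cen <- which(windows$labels[s, ] == 1L)
      if (length(cen) == 0) next
      g <- win$gene_id[s]
      if (is.null(sam_cache[[g]])) {
        sam_cache[[g]] <- synonymous_alt_matrix(models, g, genome)
      }
      sam <- sam_cache[[g]]
      pos <- win$start[s] + cen - 1L
      ap <- site_alt_probs(code_list[[win$chrom[s]]], model, pos)
      j <- match(pos, sam$positions)
      fs <- numeric(length(cen))
      for (ii in seq_along(cen)) {
        if (is.na(j[ii])) next  # central-exon base outside CDS
        syn_row <- sam$syn[j[ii], ]
        if (sam$strand == "-") syn_row <- rev(syn_row)  # back to + strand
        want <- if (stratify == "synonymous") {
          !is.na(syn_row) & syn_row
        } else {
          !is.na(syn_row) & !syn_row
        }
        fs[ii] <- sum(ap[ii, want])
      }
      f[s, cen] <- fs
    }
  }
  tot <- rowSums(f)
  if (any(tot == 0)) {
    stop(sum(tot == 0), " window(s) with all-zero site frequency; ",
         "exclude them upstream")
  }
  list(f = f, fresc = f / tot)
}

#' Per-window site mutation frequencies
#'
#' @param windows A `dnm_windows` object.
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model`.
#' @return List with matrices `f` (raw per-site frequencies, one row per
#'   window) and `fresc` (rescaled to sum to 1 within each window).
#' @export
site_frequencies <- function(windows, genome, model) {
  window_site_freq(windows, genome, model)
}

# Map mutations onto window offsets. A mutation falling in two overlapping
# windows is counted in each. Returns data.frame (window, offset, row).
map_mutations_to_windows <- function(windows, dnms) {
  win <- windows$windows
  out <- list()
  for (chrom in unique(win$chrom)) {
    widx <- which(win$chrom == chrom)
    midx <- which(dnms$chrom == chrom)
    if (length(widx) == 0 || length(midx) == 0) next
    iw <- IRanges::IRanges(win$start[widx], win$end[widx])
    im <- IRanges::IRanges(dnms$pos[midx], width = 1L)
    hits <- IRanges::findOverlaps(im, iw)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits); su <- S4Vectors::subjectHits(hits)
    out[[chrom]] <- data.frame(
      window = widx[su],
      offset = dnms$pos[midx[q]] - win$start[widx[su]] + 1L,
      row = midx[q])
  }
  if (length(out) == 0) {
    return(data.frame(window = integer(), offset = integer(),
                      row = integer()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Restrict exonic mutations to one consequence class
#'
#' Keeps all mutations outside central-exon sites, and among central-exon
#' mutations only those of the requested class. Central-exon mutations
#' that cannot be classified (outside any CDS) raise an error.
#'
#' @param dnms DNM data.frame.
#' @param windows A `dnm_windows` object.
#' @param models A `gene_models` object with CDS records.
#' @param genome Named `DNAStringSet`.
#' @param class "synonymous" or "nonsynonymous".
#' @return The filtered DNM data.frame.
#' @export
stratify_by_consequence <- function(dnms, windows, models, genome,
                                    class = c("synonymous",
                                              "nonsynonymous")) {
  class <- match.arg(class)
  dnms <- validate_dnms(dnms)
  hits <- map_mutations_to_windows(windows, dnms)
  central <- hits[windows$labels[cbind(hits$window, hits$offset)] == 1L, ]
  cen_rows <- unique(central$row)
  if (length(cen_rows) == 0) return(dnms)
  labels <- classify_consequence(dnms[cen_rows, , drop = FALSE], models,
                                 genome)
  if (any(labels == "noncoding")) {
    stop("central-exon mutation without a coding consequence label")
  }
  drop_rows <- cen_rows[labels != class]
  if (length(drop_rows) == 0) dnms else dnms[-drop_rows, , drop = FALSE]
}

#' Build a stacked observed/expected mutation profile
#'
#' Observed counts are stacked per window offset. Each window's observed
#' total is redistributed over its sites according to the rescaled model
#' frequencies, and the redistributions are summed across windows to give
#' the expected profile; totals are conserved exactly per window.
#'
#' @param windows A `dnm_windows` object.
#' @param dnms DNM data.frame. For a stratified profile pass the output of
#'   [stratify_by_consequence()] and set `stratify` to the same class.
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model`.
#' @param stratify Optional consequence class; restricts expected
#'   frequencies at central-exon sites to alternates of that class.
#' @param models `gene_models`, required when `stratify` is set.
#' @param freq Optional precomputed [site_frequencies()] result (reused
#'   across replicate analyses); incompatible with `stratify`.
#' @return Object of class `stacked_profile`: list with `observed`,
#'   `expected`, `exon_density` (length-L vectors), `window_n` (per-window
#'   observed totals), `L`, `S`.
#' @export
build_profile <- function(windows, dnms, genome, model, stratify = NULL,
                          models = NULL, freq = NULL) {
  dnms <- validate_dnms(dnms)
  if (!is.null(freq) && !is.null(stratify)) {
    stop("'freq' cannot be combined with 'stratify'")
  }
  sf <- freq %||% window_site_freq(windows, genome, model, stratify, models)
  S <- nrow(windows$windows); L <- windows$width
  hits <- map_mutations_to_windows(windows, dnms)
  observed <- numeric(L)
  tab <- table(factor(hits$offset, levels = seq_len(L)))
  observed <- as.numeric(tab)
  n_s <- tabulate(hits$window, nbins = S)
  expected <- colSums(sf$fresc * n_s)
  exon_density <- colMeans(windows$labels <= 2L)
  structure(list(observed = observed, expected = expected,
                 exon_density = exon_density, window_n = n_s,
                 L = L, S = S),
            class = "stacked_profile")
}

#' @export
print.stacked_profile <- function(x, ...) {
  cat("<stacked_profile>", x$S, "windows x", x$L, "sites;",
      sum(x$observed), "observed mutations\n")
  invisible(x)
}

#' Bin a per-position profile for display
#'
#' Non-overlapping bins of `bin_size` positions from the window start; a
#' final partial bin is averaged over its actual length.
#'
#' @param profile A `stacked_profile` or a numeric vector.
#' @param bin_size Bin width in positions (default 25).
#' @return For a vector, the vector of bin means. For a profile, a
#'   data.frame with bin index, central offset (relative to the window
#'   center) and binned observed/expected means.
#' @export
bin_profile <- function(profile, bin_size = 25L) {
  bin_means <- function(v) {
    idx <- (seq_along(v) - 1L) %/% bin_size
    as.numeric(tapply(v, idx, mean))
  }
  if (is.numeric(profile)) return(bin_means(profile))
  stopifnot(inherits(profile, "stacked_profile"))
  obs <- bin_means(profile$observed)
  exp_ <- bin_means(profile$expected)
  idx <- (seq_len(profile$L) - 1L) %/% bin_size
  center <- as.numeric(tapply(seq_len(profile$L) - (profile$L + 1L) / 2,
                              idx, mean))
  data.frame(bin = seq_along(obs), offset = center, observed = obs,
             expected = exp_)
}

#' Permutation test of exonic mutation excess
#'
#' Counts observed mutations at central-exon sites across all windows and
#' compares them to permutations in which each window's mutation total is
#' redrawn over its sites according to the rescaled model frequencies
#' (independently across windows, single seeded generator). The effect
#' size is the percent deviation of the observed exonic count from the
#' permutation mean; its error is one permutation standard deviation. The
#' empirical one-sided p-value is the fraction of permutations with at
#' least (excess) or at most (deficit) as many exonic mutations as
#' observed, floored at 1/n_perm.
#'
#' @param windows A `dnm_windows` object.
#' @param dnms DNM data.frame (already stratified if `stratify` is set).
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed driving all permutation draws.
#' @param stratify Optional consequence class for the expected exonic
#'   frequencies (see [stratify_by_consequence()]).
#' @param models `gene_models`, required when `stratify` is set.
#' @param freq Optional precomputed [site_frequencies()] result (reused
#'   across replicate analyses); incompatible with `stratify`.
#' @return Object of class `permutation_result`: observed exonic count,
#'   `excess_pct`, `sd_pct`, `p_value`, the permutation exonic counts and
#'   the seed.
#' @export
exonic_excess_test <- function(windows, dnms, genome, model,
                               n_perm = 1000L, seed = 1L, stratify = NULL,
                               models = NULL, freq = NULL) {
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (!is.null(freq) && !is.null(stratify)) {
    stop("'freq' cannot be combined with 'stratify'")
  }
  dnms <- validate_dnms(dnms)
  sf <- freq %||% window_site_freq(windows, genome, model, stratify, models)
  S <- nrow(windows$windows)
  hits <- map_mutations_to_windows(windows, dnms)
  n_s <- tabulate(hits$window, nbins = S)
  central <- windows$labels == 1L
  obs_e <- sum(central[cbind(hits$window, hits$offset)])
  p_e <- rowSums(sf$fresc * central)
  perm_e <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(rbinom(S, n_s, p_e)), 0)
  })
  mean_e <- mean(perm_e)
  if (mean_e == 0) stop("permutation mean exonic count is zero")
  excess <- 100 * (obs_e - mean_e) / mean_e
  sd_pct <- 100 * sd(perm_e) / mean_e
  p <- if (obs_e >= mean_e) mean(perm_e >= obs_e) else mean(perm_e <= obs_e)
  p <- max(p, 1 / n_perm)
  structure(list(observed_exonic = obs_e, expected_exonic = mean_e,
                 excess_pct = excess, sd_pct = sd_pct, p_value = p,
                 n_permutations = n_perm, perm_exonic = perm_e,
                 seed = seed, stratify = stratify),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> exonic excess %.1f%% +/- %.1f%% (p = %.3g, %d permutations)\n",
              x$excess_pct, x$sd_pct, x$p_value, x$n_permutations))
  if (!is.null(x$stratify)) cat("  stratified:", x$stratify, "\n")
  invisible(x)
}

#' Export a stacked profile as TSV
#'
#' @param profile A `stacked_profile`.
#' @param path Output path. Columns: offset (relative to the window
#'   center), observed, expected, exon_density.
#' @export
write_profile <- function(profile, path) {
  off <- seq_len(profile$L) - (profile$L + 1L) / 2
  write.table(
    data.frame(offset = off, observed = profile$observed,
               expected = profile$expected,
               exon_density = profile$exon_density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
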