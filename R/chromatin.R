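# Chromatin-feature binned gene analysis: nucleosome peak calling from a
# coverage track, per-gene exon-to-intron coverage ratios, model-based
# expected exonic mutation counts, quantile binning, and a robust
# (iteratively re-weighted least squares) correlation across bins.

# Expand a piecewise-constant track into a per-base signal vector over
# [1, n]; uncovered bases are 0.
track_signal <- function(track, chrom, n) {
  sub <- track[track$chrom == chrom, , drop = FALSE]
  sig <- numeric(n)
  for (i in seq_len(nrow(sub))) {
    sig[sub$start[i]:min(sub$end[i], n)] <- sub$value[i]
  }
  sig
}

#' Call nucleosome peaks from a coverage track
#'
#' Local maxima of the per-base signal, with plateau ties resolved to the
#' plateau midpoint, filtered so accepted peaks (taken in decreasing
#' height order) are at least `min_separation` bases apart. Each peak
#' emits the inclusive region `[peak - half_window, peak + half_window]`
#' (147 bases with the default half window of 73).
#'
#' @param track Coverage data.frame (chrom, start, end, value), e.g. from
#'   [read_bedgraph()].
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param min_separation Minimum distance between accepted peaks.
#' @param half_window Bases emitted on each side of the peak coordinate.
#' @return data.frame chrom, start, end, peak (1-based inclusive).
#' @export
call_nucleosome_peaks <- function(track, chrom_lengths,
                                  min_separation = 150L, half_window = 73L) {
  out <- list()
  for (chrom in intersect(unique(track$chrom), names(chrom_lengths))) {
    sig <- track_signal(track, chrom, chrom_lengths[[chrom]])
    n <- length(sig)
    if (n == 0 || all(sig == 0)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    m <- length(r$values)
    # boundary runs have no neighbor on one side and are never maxima
    left <- c(Inf, r$values[-m])
    right <- c(r$values[-1], Inf)
    is_max <- r$values > left & r$values > right
    if (!any(is_max)) next
    peaks <- (starts[is_max] + ends[is_max]) %/% 2L
    heights <- r$values[is_max]
    ord <- order(heights, decreasing = TRUE)
    accepted <- integer(0)
    for (p in peaks[ord]) {
      if (all(abs(accepted - p) >= min_separation)) {
        accepted <- c(accepted, p)
      }
    }
    accepted <- sort(accepted)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = pmax(1L, accepted - half_window),
      end = pmin(n, accepted + half_window),
      peak = accepted, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak = integer()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-gene exon-to-intron chromatin coverage ratio
#'
#' The ratio between the number of exonic and intronic bases covered
#' (signal > 0) by the track. Genes with zero covered bases in either
#' compartment get NA (excluded downstream).
#'
#' @param models A `gene_models` object.
#' @param track Coverage data.frame.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return data.frame gene_id, exonic_covered, intronic_covered, ratio.
#' @export
gene_feature_enrichment <- function(models, track, chrom_lengths) {
  sig_cache <- new.env()
  covered_bp <- function(chrom, iv) {
    if (is.null(sig_cache[[chrom]])) {
      sig_cache[[chrom]] <- track_signal(track, chrom,
                                         chrom_lengths[[chrom]]) > 0
    }
    cov <- sig_cache[[chrom]]
    sum(vapply(seq_len(nrow(iv)),
               function(i) sum(cov[iv$start[i]:iv$end[i]]), 0))
  }
  genes <- models$genes
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]; chrom <- genes$chrom[i]
    e_bp <- covered_bp(chrom,
                       models$meta_exons[models$meta_exons$gene_id == g, ])
    introns <- models$meta_introns[models$meta_introns$gene_id == g, ]
    i_bp <- if (nrow(introns) > 0) covered_bp(chrom, introns) else 0
    data.frame(gene_id = g, exonic_covered = e_bp, intronic_covered = i_bp,
               ratio = if (e_bp > 0 && i_bp > 0) e_bp / i_bp else NA_real_)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Model-expected exonic mutations per gene
#'
#' The exonic and intronic target sizes of a gene are the sums of the
#' per-site mutation frequencies (three alternates) over its meta-exon and
#' meta-intron sites. The binomial probability of a mutation being exonic
#' is the exonic share of the total target size, and the expected exonic
#' count is that probability times the gene's observed mutation total.
#'
#' @param models A `gene_models` object.
#' @param dnms DNM data.frame.
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model` (a 3-mer model trained on
#'   healthy-proband mutations in the source analysis).
#' @return data.frame of class `gene_enrichment_input`: gene_id, n (total
#'   observed mutations in the gene span), n_e (observed exonic), target
#'   sizes, P_e and expected exonic count n_hat_e.
#' @export
expected_exonic_mutations <- function(models, dnms, genome, model) {
  dnms <- validate_dnms(dnms)
  fchrom <- site_mutation_freq(genome, model)
  genes <- models$genes
  sum_f <- function(chrom, iv) {
    if (nrow(iv) == 0) return(0)
    sum(vapply(seq_len(nrow(iv)),
               function(i) sum(fchrom[[chrom]][iv$start[i]:iv$end[i]]), 0))
  }
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]; chrom <- genes$chrom[i]
    ex <- models$meta_exons[models$meta_exons$gene_id == g, ]
    intr <- models$meta_introns[models$meta_introns$gene_id == g, ]
    L_e <- sum_f(chrom, ex)
    L_i <- sum_f(chrom, intr)
    if (L_e + L_i == 0) stop("zero total target size for gene ", g)
    in_gene <- dnms$chrom == chrom & dnms$pos >= genes$start[i] &
      dnms$pos <= genes$end[i]
    in_exon <- in_gene & vapply(dnms$pos, function(p) {
      any(p >= ex$start & p <= ex$end)
    }, TRUE)
    n <- sum(in_gene); n_e <- sum(in_exon)
    P_e <- L_e / (L_e + L_i)
    data.frame(gene_id = g, n = n, n_e = n_e, target_exonic = L_e,
               target_intronic = L_i, P_e = P_e, n_hat_e = P_e * n)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  class(out) <- c("gene_enrichment_input", "data.frame")
  out
}

#' Combine per-gene enrichment ratios and mutation expectations
#'
#' Applies the study's gene filters for the binned analysis: genes need
#' covered bases in both compartments and at least one observed exonic or
#' intronic mutation.
#'
#' @param enrich Output of [gene_feature_enrichment()].
#' @param expect Output of [expected_exonic_mutations()].
#' @return Filtered data.frame with ratio and mutation columns.
#' @export
gene_enrichment_table <- function(enrich, expect) {
  df <- merge(enrich, expect, by = "gene_id")
  df <- df[!is.na(df$ratio) & df$n > 0, , drop = FALSE]
  df[order(df$ratio), ]
}

#' Per-bin exonic mutation difference
#'
#' Genes are grouped into equal-count bins by their enrichment ratio. For
#' each bin the relative difference between total observed and total
#' expected exonic mutations is computed, together with the bin's median
#' ratio and the within-bin ratio variance (used as IRLS weights).
#'
#' @param genes Output of [gene_enrichment_table()].
#' @param n_bins Number of quantile bins (default 50).
#' @return data.frame bin, median_ratio, ratio_var, n_genes, sum_n_e,
#'   sum_n_hat_e, difference_pct.
#' @export
binned_difference <- function(genes, n_bins = 50L) {
  if (nrow(genes) < n_bins) {
    stop("fewer genes (", nrow(genes), ") than bins (", n_bins, ")")
  }
  ord <- order(genes$ratio)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  g <- genes[ord, , drop = FALSE]
  res <- lapply(seq_len(n_bins), function(b) {
    sub <- g[bin == b, , drop = FALSE]
    data.frame(bin = b, median_ratio = median(sub$ratio),
               ratio_var = if (nrow(sub) > 1) var(sub$ratio) else 0,
               n_genes = nrow(sub), sum_n_e = sum(sub$n_e),
               sum_n_hat_e = sum(sub$n_hat_e),
               difference_pct = 100 * (sum(sub$n_e) - sum(sub$n_hat_e)) /
                 sum(sub$n_hat_e))
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Robust weighted correlation across bins
#'
#' Weighted linear fit of the bin differences on the bin enrichment
#' medians, with weights proportional to the inverse within-bin variance
#' of the enrichment ratio, iterated to convergence. The reported r is the
#' slope-sign-consistent square root of the weighted R-squared; the
#' p-value is the two-sided t-test of the slope.
#'
#' @param x Bin enrichment medians.
#' @param y Bin differences (percent).
#' @param x_variances Within-bin variances of the enrichment ratio; if all
#'   are zero, equal weights are used with a warning.
#' @param max_iter,tol Convergence controls.
#' @return List with r, p_value, slope, intercept, weights, n_iter.
#' @export
irls_correlation <- function(x, y, x_variances = NULL, max_iter = 100L,
                             tol = 1e-8) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.null(x_variances) || all(x_variances == 0)) {
    if (!is.null(x_variances)) {
      warning("all bin variances are zero; using equal weights")
    }
    w <- rep(1, length(x))
  } else {
    eps <- min(x_variances[x_variances > 0])
    w <- 1 / pmax(x_variances, eps)
  }
  coefs <- c(0, 0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- lm(y ~ x, weights = w)
    new_coefs <- coef(fit)
    if (max(abs(new_coefs - coefs)) <
        tol * max(1, max(abs(new_coefs)))) break
    coefs <- new_coefs
  }
  res <- summary(fit)
  slope <- coef(fit)[["x"]]
  r2 <- res$r.squared
  r <- sign(slope) * sqrt(max(r2, 0))
  p <- coef(res)["x", "Pr(>|t|)"]
  list(r = unname(r), p_value = unname(p), slope = unname(slope),
       intercept = unname(coef(fit)[[1]]), weights = w, n_iter = it)
}

#' Rank-sum comparison of exonic vs intronic coverage fractions
#'
#' Thin optional report: per gene, the fraction of exonic and of intronic
#' bases covered by the track, compared by a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param models A `gene_models` object.
#' @param track Coverage data.frame.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return List with the two per-gene fraction vectors and the test
#'   p-value.
#' @export
coverage_fraction_report <- function(models, track, chrom_lengths) {
  sig_cache <- new.env()
  frac <- function(chrom, iv) {
    if (is.null(sig_cache[[chrom]])) {
      sig_cache[[chrom]] <- track_signal(track, chrom,
                                         chrom_lengths[[chrom]]) > 0
    }
    cov <- sig_cache[[chrom]]
    tot <- sum(iv$end - iv$start + 1)
    if (tot == 0) return(NA_real_)
    sum(vapply(seq_len(nrow(iv)),
               function(i) sum(cov[iv$start[i]:iv$end[i]]), 0)) / tot
  }
  genes <- models$genes
  e_frac <- vapply(seq_len(nrow(genes)), function(i) {
    frac(genes$chrom[i],
         models$meta_exons[models$meta_exons$gene_id == genes$gene_id[i], ])
  }, 0)
  i_frac <- vapply(seq_len(nrow(genes)), function(i) {
    frac(genes$chrom[i],
         models$meta_introns[models$meta_introns$gene_id ==
                               genes$gene_id[i], ])
  }, 0)
  ok <- !is.na(e_frac) & !is.na(i_frac)
  test <- stats::wilcox.test(e_frac[ok], i_frac[ok], exact = FALSE)
  list(exonic_fraction = e_frac, intronic_fraction = i_frac,
       p_value = test$p.value)
}
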