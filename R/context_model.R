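# k-mer sequence-context mutational models.
#
# A model is a lookup table of per-site, per-alternate mutation
# probabilities P(alt | ref context). The context is the k-mer centered on
# the mutated base. Probabilities are estimated as mutation counts divided
# by the genomic abundance of the reference k-mer, either directly at the
# full context width, or through a composite-likelihood decomposition that
# combines a core h-mer model with independent per-flank-position
# correction factors. k-mers are counted on the forward strand and
# mutations used as reported; no reverse-complement collapsing is applied
# in estimation (strand folding happens only in the 9-class spectrum
# display).

#' Define a context scheme
#'
#' @param kind One of "direct" (full k-mer table), "decomposed"
#'   (composite-likelihood h-mer core with per-flank factors), "mono"
#'   (single-nucleotide model) or "cpg" (single nucleotide with C and G
#'   split by CpG dinucleotide status).
#' @param k Odd total context width (ignored for mono/cpg, which use 1 and
#'   an effective dinucleotide context respectively).
#' @param h Odd core width for `kind = "decomposed"`; must satisfy h < k.
#' @return An object of class `context_scheme`.
#' @export
context_scheme <- function(kind = c("direct", "decomposed", "mono", "cpg"),
                           k = NULL, h = NULL) {
  kind <- match.arg(kind)
  if (kind == "mono") { k <- 1L; h <- 1L }
  if (kind == "cpg") { k <- 1L; h <- 1L }
  if (is.null(k)) stop("'k' is required")
  k <- as.integer(k)
  if (k %% 2 == 0) stop("'k' must be odd")
  if (kind == "direct") h <- k
  if (kind == "decomposed") {
    if (is.null(h)) stop("'h' is required for a decomposed scheme")
    h <- as.integer(h)
    if (h %% 2 == 0) stop("'h' must be odd")
    if (h >= k) stop("decomposed scheme requires h < k")
  }
  structure(list(kind = kind, k = k, h = as.integer(h)),
            class = "context_scheme")
}

#' @export
format.context_scheme <- function(x, ...) {
  switch(x$kind,
         mono = "1-mer",
         cpg = "CpG",
         direct = sprintf("%d-mer", x$k),
         decomposed = sprintf("%d-mer (h=%d)", x$k, x$h))
}

#' @export
print.context_scheme <- function(x, ...) {
  cat("<context_scheme>", format(x), "\n")
  invisible(x)
}

#' Number of free parameters of a context scheme
#'
#' Direct k-mer models have `4^k * 3` parameters (one per reference k-mer
#' and alternate). Decomposed models have `4^h * 3 * (1 + 3 * (k - h))`:
#' the core table plus, for each of the k - h flank positions, a table
#' over the core and the flanking base (the 4th value at each flank
#' position is fixed by the marginal, hence the factor 3). The mono model
#' has 12 parameters and the CpG model 18 (6 reference states: A, T and
#' C/G each split by CpG status, times 3 alternates).
#'
#' @param scheme A [context_scheme()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(scheme) {
  stopifnot(inherits(scheme, "context_scheme"))
  f <- function(x) as.integer(4^x * 3)
  switch(scheme$kind,
         mono = 12L,
         cpg = 18L,
         direct = f(scheme$k),
         decomposed = f(scheme$h) * (1L + 3L * (scheme$k - scheme$h)))
}

#' Count k-mer abundance across a genome
#'
#' Counts every k-mer window on the forward strand. Windows containing a
#' non-ACGT base are skipped. With `regions`, only k-mers lying entirely
#' within the given intervals are counted.
#'
#' @param genome Named `DNAStringSet`.
#' @param k Odd k-mer width.
#' @param regions Optional data.frame (chrom, start, end; 1-based
#'   inclusive) restricting the counted territory.
#' @return Named numeric vector of length `4^k`, in lexicographic k-mer
#'   order.
#' @export
count_kmer_abundance <- function(genome, k, regions = NULL) {
  if (k %% 2 == 0) stop("'k' must be odd")
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome")
  }
  if (is.null(regions)) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(genome, width = k))
  } else {
    counts <- setNames(numeric(4^k), kmer_strings(k))
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      if (!chrom %in% names(genome)) next
      s <- Biostrings::subseq(genome[[chrom]], regions$start[i],
                              regions$end[i])
      if (length(s) >= k) {
        counts <- counts + Biostrings::oligonucleotideFrequency(s, width = k)
      }
    }
  }
  counts
}

new_context_model <- function(scheme, k_eff, prob, counts = NULL,
                              abundance = NULL, n_skipped = 0L) {
  stopifnot(nrow(prob) == 4^k_eff, ncol(prob) == 4)
  dimnames(prob) <- list(kmer_strings(k_eff), BASES)
  structure(list(scheme = scheme, k_eff = as.integer(k_eff), prob = prob,
                 counts = counts, abundance = abundance,
                 n_params = parameter_count(scheme),
                 n_skipped = as.integer(n_skipped)),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  cat("<context_model>", format(x$scheme), "-", x$n_params, "parameters\n")
  f <- rowSums(x$prob)
  cat(sprintf("  mean per-site mutation frequency: %.3g (over %d contexts)\n",
              mean(f), length(f)))
  if (x$n_skipped > 0) {
    cat("  mutations skipped for unreadable context:", x$n_skipped, "\n")
  }
  invisible(x)
}

# Tabulate mutation counts into a (4^k x 4) matrix indexed by centered
# k-mer code and alternate base. Mutations whose context is unreadable
# (chromosome edge or N) are skipped and counted; a reference mismatch is
# an error.
mutation_count_matrix <- function(dnms, genome, k) {
  counts <- matrix(0, nrow = 4^k, ncol = 4)
  skipped <- 0L
  enc_list <- lapply(genome, encode_dna)
  for (chrom in unique(dnms$chrom)) {
    if (!chrom %in% names(genome)) {
      stop("mutation on chromosome absent from genome: ", chrom)
    }
    sub <- dnms[dnms$chrom == chrom, , drop = FALSE]
    enc <- enc_list[[chrom]]
    if (any(sub$pos < 1 | sub$pos > length(enc))) {
      stop("mutation position outside chromosome ", chrom)
    }
    refcode <- match(sub$ref, BASES) - 1L
    if (any(is.na(enc[sub$pos]) | enc[sub$pos] != refcode)) {
      stop("reference allele mismatch between DNM table and genome on ",
           chrom)
    }
    codes <- centered_kmer_codes(enc, k)[sub$pos]
    ok <- !is.na(codes)
    skipped <- skipped + sum(!ok)
    altcode <- match(sub$alt, BASES) - 1L
    idx <- altcode[ok] * 4^k + codes[ok] + 1
    tab <- tabulate(idx, nbins = 4^k * 4)
    counts <- counts + matrix(tab, nrow = 4^k, ncol = 4)
  }
  list(counts = counts, skipped = skipped)
}

#' Estimate a k-mer model by the direct method
#'
#' For every observed (reference k-mer, alternate) pair, the probability is
#' the genome-wide mutation count divided by the abundance of the reference
#' k-mer. Unobserved pairs have probability zero; no pseudocounts are
#' applied.
#'
#' @param dnms DNM data.frame (chrom, pos, ref, alt).
#' @param genome Named `DNAStringSet`.
#' @param k Odd context width.
#' @return A `context_model`.
#' @export
estimate_direct <- function(dnms, genome, k) {
  if (k %% 2 == 0) stop("'k' must be odd")
  dnms <- validate_dnms(dnms)
  cm <- mutation_count_matrix(dnms, genome, k)
  abund <- count_kmer_abundance(genome, k)
  prob <- cm$counts / ifelse(abund > 0, abund, Inf)
  new_context_model(context_scheme(if (k == 1) "mono" else "direct", k = k),
                    k_eff = k, prob = prob, counts = cm$counts,
                    abundance = abund, n_skipped = cm$skipped)
}

#' Estimate a k-mer model by composite-likelihood decomposition
#'
#' Approximates the full k-mer probability by the core h-mer probability
#' times, for each flank position, the ratio of the flank-conditioned
#' marginal probability to the core probability. Marginals are computed by
#' summing mutation counts and abundances over all flanking sequences that
#' agree at the given position. If the core probability or any factor's
#' denominator is zero, the composite probability is zero.
#'
#' @param dnms DNM data.frame.
#' @param genome Named `DNAStringSet`.
#' @param k Odd total context width.
#' @param h Odd core width, `h <= k` (with `h == k` the result equals the
#'   direct estimate).
#' @return A `context_model` with a probability table at full k-mer
#'   resolution.
#' @export
estimate_decomposed <- function(dnms, genome, k, h) {
  if (k %% 2 == 0 || h %% 2 == 0) stop("'k' and 'h' must be odd")
  if (h > k) stop("'h' must not exceed 'k'")
  dnms <- validate_dnms(dnms)
  cm <- mutation_count_matrix(dnms, genome, k)
  abund <- count_kmer_abundance(genome, k)
  g <- k - h
  codes <- 0:(4^k - 1)
  flank_pos <- setdiff(seq_len(k), (g / 2 + 1):(g / 2 + h))
  core_pos <- (g / 2 + 1):(g / 2 + h)
  core_code <- integer(4^k)
  for (j in core_pos) core_code <- core_code * 4L + kmer_digit(codes, j, k)

  n_core <- rowsum(cm$counts, core_code)
  g_core <- rowsum(abund, core_code)[, 1]
  p_core <- n_core / ifelse(g_core > 0, g_core, Inf)
  p_core_full <- p_core[core_code + 1, , drop = FALSE]

  res <- p_core_full
  for (i in seq_along(flank_pos)) {
    xi <- kmer_digit(codes, flank_pos[i], k)
    grp <- core_code * 4L + xi
    n_i <- rowsum(cm$counts, grp)
    g_i <- rowsum(abund, grp)[, 1]
    p_i <- n_i / ifelse(g_i > 0, g_i, Inf)
    p_i_full <- p_i[match(grp, sort(unique(grp))), , drop = FALSE]
    factor <- ifelse(p_core_full > 0, p_i_full / p_core_full, 0)
    res <- res * factor
  }
  scheme <- if (h == k) {
    context_scheme(if (k == 1) "mono" else "direct", k = k)
  } else {
    context_scheme("decomposed", k = k, h = h)
  }
  new_context_model(scheme, k_eff = k, prob = res, counts = cm$counts,
                    abundance = abund, n_skipped = cm$skipped)
}

#' Estimate the CpG-aware single-nucleotide model
#'
#' Six reference states (A, T, and C/G split by CpG dinucleotide status on
#' the forward strand: a C followed by G, or a G preceded by C) with three
#' alternates each, giving 18 parameters. Internally represented as a tied
#' trinucleotide table so it can be evaluated like any k-mer model.
#'
#' @param dnms DNM data.frame.
#' @param genome Named `DNAStringSet`.
#' @return A `context_model` with `k_eff = 3`.
#' @export
estimate_cpg <- function(dnms, genome) {
  dnms <- validate_dnms(dnms)
  cm <- mutation_count_matrix(dnms, genome, 3)
  abund <- count_kmer_abundance(genome, 3)
  state <- cpg_state_of_trimer()
  n_state <- rowsum(cm$counts, state)
  g_state <- rowsum(abund, state)[, 1]
  p_state <- n_state / ifelse(g_state > 0, g_state, Inf)
  prob <- p_state[state, , drop = FALSE]
  rownames(prob) <- NULL
  new_context_model(context_scheme("cpg"), k_eff = 3, prob = prob,
                    counts = cm$counts, abundance = abund,
                    n_skipped = cm$skipped)
}

# Map each trinucleotide (x, c, y) to one of 6 reference states:
# 1 A, 2 T, 3 C non-CpG, 4 C CpG (next base G), 5 G non-CpG,
# 6 G CpG (previous base C). Returns an integer vector over the 64 codes.
cpg_state_of_trimer <- function() {
  codes <- 0:63
  x <- kmer_digit(codes, 1, 3)
  c0 <- kmer_digit(codes, 2, 3)
  y <- kmer_digit(codes, 3, 3)
  state <- integer(64)
  state[c0 == 0L] <- 1L
  state[c0 == 3L] <- 2L
  state[c0 == 1L] <- ifelse(y[c0 == 1L] == 2L, 4L, 3L)
  state[c0 == 2L] <- ifelse(x[c0 == 2L] == 1L, 6L, 5L)
  state
}

#' Estimate a model for any context scheme
#'
#' @param dnms DNM data.frame.
#' @param genome Named `DNAStringSet`.
#' @param scheme A [context_scheme()].
#' @return A `context_model`.
#' @export
estimate_context_model <- function(dnms, genome, scheme) {
  stopifnot(inherits(scheme, "context_scheme"))
  switch(scheme$kind,
         mono = estimate_direct(dnms, genome, 1),
         cpg = estimate_cpg(dnms, genome),
         direct = estimate_direct(dnms, genome, scheme$k),
         decomposed = estimate_decomposed(dnms, genome, scheme$k, scheme$h))
}

#' Per-site total mutation frequency along each chromosome
#'
#' For every genomic position, the sum over the three alternates of the
#' model probability given the centered reference context. Positions with
#' unreadable context (chromosome edge or N-containing k-mer) get 0.
#'
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model`.
#' @return Named list of numeric vectors, one per chromosome.
#' @export
site_mutation_freq <- function(genome, model) {
  fvec <- unname(rowSums(model$prob))
  lapply(genome, function(s) {
    codes <- centered_kmer_codes(encode_dna(s), model$k_eff)
    f <- fvec[codes + 1]
    f[is.na(f)] <- 0
    f
  })
}

# Per-site per-alternate probabilities (n x 4 matrix) at given positions,
# from a precomputed per-chromosome code vector (see genome_codes()).
site_alt_probs <- function(codes_vec, model, positions) {
  codes <- codes_vec[positions]
  out <- matrix(0, nrow = length(positions), ncol = 4,
                dimnames = list(NULL, BASES))
  ok <- !is.na(codes)
  out[ok, ] <- model$prob[codes[ok] + 1, , drop = FALSE]
  out
}

#' Nine-class abundance-corrected mutation spectrum
#'
#' Mutations are folded onto the pyrimidine strand (G>* becomes C>*, A>*
#' becomes T>*) and assigned to the six base-substitution classes, with the
#' three C>* classes split by CpG status of the reference site. Each class
#' count is divided by the strand-collapsed genomic abundance of its
#' reference context.
#'
#' @param dnms DNM data.frame.
#' @param genome Named `DNAStringSet`.
#' @return data.frame with class, count, abundance and rate columns.
#' @export
mutation_spectrum <- function(dnms, genome) {
  dnms <- validate_dnms(dnms)
  classes <- c("C>A (CpG)", "C>G (CpG)", "C>T (CpG)",
               "C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- setNames(numeric(9), classes)
  enc_list <- lapply(genome, encode_dna)
  for (chrom in unique(dnms$chrom)) {
    sub <- dnms[dnms$chrom == chrom, , drop = FALSE]
    enc <- enc_list[[chrom]]
    n <- length(enc)
    prev <- ifelse(sub$pos > 1, enc[pmax(sub$pos - 1, 1)], NA)
    nxt <- ifelse(sub$pos < n, enc[pmin(sub$pos + 1, n)], NA)
    ref <- match(sub$ref, BASES) - 1L
    alt <- match(sub$alt, BASES) - 1L
    purine <- ref %in% c(0L, 2L)
    ref_f <- ifelse(purine, 3L - ref, ref)
    alt_f <- ifelse(purine, 3L - alt, alt)
    is_cpg <- ifelse(ref == 1L, !is.na(nxt) & nxt == 2L,
                     ifelse(ref == 2L, !is.na(prev) & prev == 1L, FALSE))
    cls <- paste0(BASES[ref_f + 1], ">", BASES[alt_f + 1],
                  ifelse(ref_f == 1L & is_cpg, " (CpG)", ""))
    tab <- table(factor(cls, levels = classes))
    counts <- counts + as.numeric(tab)
  }
  mono <- count_kmer_abundance(genome, 1)
  di <- colSums(Biostrings::dinucleotideFrequency(genome))
  cpg_c_sites <- 2 * di[["CG"]]  # C followed by G, plus G preceded by C
  abund <- c(rep(cpg_c_sites, 3),
             rep(mono[["C"]] + mono[["G"]] - cpg_c_sites, 3),
             rep(mono[["T"]] + mono[["A"]], 3))
  data.frame(class = classes, count = as.numeric(counts), abundance = abund,
             rate = as.numeric(counts) / abund, row.names = NULL)
}

#' Export a context model as TSV
#'
#' One row per (reference context, alternate) pair at the model's effective
#' context width, with the mutation count, reference abundance and
#' probability. The scheme is stored in a header comment.
#'
#' @param model A `context_model`.
#' @param path Output path.
#' @export
write_context_model <- function(model, path) {
  k_eff <- model$k_eff
  ctx <- rep(kmer_strings(k_eff), 4)
  alt <- rep(BASES, each = 4^k_eff)
  same_res <- !is.null(model$counts) && nrow(model$counts) == 4^k_eff
  df <- data.frame(
    context = ctx, alt = alt,
    count = if (same_res) as.vector(model$counts) else NA,
    abundance = if (same_res) rep(model$abundance, 4) else NA,
    probability = as.vector(model$prob)
  )
  df <- df[order(df$context, df$alt), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme\t%s\t%d\t%d", model$scheme$kind,
                     model$scheme$k, model$scheme$h %||% model$scheme$k),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a context model written by [write_context_model()]
#' @param path Path to the TSV.
#' @return A `context_model` (probability table only; counts kept when
#'   present).
#' @export
read_context_model <- function(path) {
  header <- readLines(path, n = 1)
  parts <- strsplit(sub("^# scheme\t", "", header), "\t")[[1]]
  scheme <- switch(parts[1],
                   mono = context_scheme("mono"),
                   cpg = context_scheme("cpg"),
                   direct = context_scheme("direct", k = as.integer(parts[2])),
                   decomposed = context_scheme("decomposed",
                                               k = as.integer(parts[2]),
                                               h = as.integer(parts[3])))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  k_eff <- nchar(df$context[1])
  prob <- matrix(0, 4^k_eff, 4)
  code <- match(df$context, kmer_strings(k_eff))
  altc <- match(df$alt, BASES)
  prob[cbind(code, altc)] <- df$probability
  counts <- NULL
  abund <- NULL
  if (!all(is.na(df$count))) {
    counts <- matrix(0, 4^k_eff, 4)
    counts[cbind(code, altc)] <- df$count
    abund <- numeric(4^k_eff)
    abund[code] <- df$abundance
    names(abund) <- kmer_strings(k_eff)
  }
  new_context_model(scheme, k_eff, prob, counts = counts, abundance = abund)
}
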