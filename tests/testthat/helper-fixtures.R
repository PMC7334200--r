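# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env()

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) assign(name, expr, .fixture_cache)
  get(name, .fixture_cache)
}

# Small simulated dataset used by most unit tests: ~0.2 Mb, 24 genes.
fix_small <- function() cached("small", {
  cfg <- sim_config(seed = 11, n_genes = 24, n_chromosomes = 2,
                    site_rate = 2e-6, n_trios = 500)
  sim <- simulate_genome(cfg)
  dnms <- simulate_dnms(sim)
  models <- build_gene_models(sim$annotation,
                              autosome_names = names(sim$genome))
  windows <- extract_windows(models, sim$genome)
  model <- estimate_direct(dnms, sim$genome, 3)
  list(sim = sim, dnms = dnms, models = models, windows = windows,
       model = model)
})

# Large simulated dataset for the calibration/recovery studies: ~5 Mb,
# 550 genes, 2000 gametogeneses, per-site rate chosen so the window
# territory carries >20,000 mutations.
fix_big <- function() cached("big", {
  cfg <- sim_config(seed = 101, n_genes = 550, n_chromosomes = 2,
                    site_rate = 3.5e-6, n_trios = 1000)
  sim <- simulate_genome(cfg)
  dnms <- simulate_dnms(sim)
  models <- build_gene_models(sim$annotation,
                              autosome_names = names(sim$genome))
  windows <- extract_windows(models, sim$genome)
  model <- estimate_direct(dnms, sim$genome, 3)
  list(sim = sim, dnms = dnms, models = models, windows = windows,
       model = model)
})

# A context-free model: every alternate has probability rate/3 at every
# site (0 for the reference base itself).
uniform_model <- function(rate) {
  prob <- matrix(rate / 3, 4, 4)
  diag(prob) <- 0
  exindnm:::new_context_model(context_scheme("mono"), 1, prob)
}

# Deterministic random DNA string.
random_dna <- function(n, seed = 1, gc = 0.5) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

# Hand-built annotation for one gene: UTR-like terminal exons and fully
# coding internal exons, all on the given strand.
toy_gene_annotation <- function(chrom = "chrT", gene_id = "gT",
                                strand = "+", exon_starts, exon_ends,
                                coding = seq(2, length(exon_starts) - 1)) {
  E <- length(exon_starts)
  stopifnot(length(exon_ends) == E)
  rec <- function(feature, s, e, frame = NA_integer_) {
    data.frame(chrom = chrom, feature = feature, start = s, end = e,
               strand = strand, frame = frame, gene_id = gene_id,
               transcript_id = paste0(gene_id, ".t1"),
               stringsAsFactors = FALSE)
  }
  lens <- exon_ends[coding] - exon_starts[coding] + 1L
  tx <- if (strand == "+") coding else rev(coding)
  frames <- integer(length(tx)); phase <- 0L
  for (j in seq_along(tx)) {
    frames[j] <- phase
    len <- exon_ends[tx[j]] - exon_starts[tx[j]] + 1L
    phase <- (3L - ((len - phase) %% 3L)) %% 3L
  }
  frame_by_exon <- setNames(frames, tx)
  utr_idx <- setdiff(seq_len(E), coding)
  do.call(rbind, c(
    list(rec("gene", exon_starts[1], exon_ends[E]),
         rec("transcript", exon_starts[1], exon_ends[E])),
    lapply(seq_len(E), function(e) rec("exon", exon_starts[e],
                                       exon_ends[e])),
    lapply(coding, function(e) {
      rec("CDS", exon_starts[e], exon_ends[e],
          frame = frame_by_exon[[as.character(e)]])
    }),
    lapply(utr_idx, function(e) rec("UTR", exon_starts[e], exon_ends[e]))
  ))
}

# Greedy non-overlapping subset of windows (per chromosome, left to
# right), so per-window simulation and per-window-site counting agree
# without double counting.
nonoverlapping_windows <- function(w) {
  keep <- logical(nrow(w$windows))
  for (chrom in unique(w$windows$chrom)) {
    idx <- which(w$windows$chrom == chrom)
    idx <- idx[order(w$windows$start[idx])]
    last_end <- -Inf
    for (i in idx) {
      if (w$windows$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- w$windows$end[i]
      }
    }
  }
  out <- w
  out$windows <- w$windows[keep, , drop = FALSE]
  out$windows$window_id <- seq_len(sum(keep))
  out$labels <- w$labels[keep, , drop = FALSE]
  out
}

# Build a dnm_windows object directly (for tiny hand-checked windows).
manual_windows <- function(chrom, starts, width, labels, gene_ids = NULL) {
  S <- length(starts)
  win <- data.frame(window_id = seq_len(S), chrom = chrom, start = starts,
                    end = starts + width - 1L,
                    center = starts + (width - 1L) %/% 2L,
                    gene_id = gene_ids %||% paste0("g", seq_len(S)),
                    stringsAsFactors = FALSE)
  structure(list(windows = win, labels = labels, width = width),
            class = "dnm_windows")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
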