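# Synthetic data with the statistical structure the analysis assumes:
# multi-exon genes with elevated exonic GC and CpG content, de novo
# mutations drawn from a known k-mer context process with an optional
# exonic rate multiplier and disease-ascertainment enrichment of
# nonsynonymous variants, and exon-enriched chromatin coverage tracks.
# Everything is deterministic under the configured seed.

#' Simulation configuration
#'
#' @param seed Master seed; all generator stages derive their streams
#'   from it.
#' @param n_chromosomes Number of autosome-like chromosomes.
#' @param n_genes Total genes, spread round-robin over chromosomes.
#' @param exons_per_gene Exons per gene (>= 3 so internal exons exist; the
#'   first and last exon are UTR-like, the internal ones are coding).
#' @param exon_length,intron_length,utr_length,intergenic_length Length
#'   ranges (min, max) in bases for internal exons, introns, terminal UTR
#'   exons and intergenic spacers.
#' @param chrom_length Optional fixed chromosome length; an error is
#'   raised if the placed genes exceed it (infeasible packing), otherwise
#'   the remainder is intergenic.
#' @param exonic_gc,intronic_gc GC-content targets for exonic and
#'   intronic/intergenic sequence.
#' @param cpg_factor Exonic CpG dinucleotide enrichment over the
#'   independent-base expectation, achieved by rejection sampling.
#' @param site_rate Mean per-site per-gametogenesis mutation probability
#'   of the generating process.
#' @param ts_tv Transition:transversion rate ratio of the generating
#'   process.
#' @param cpg_boost Rate multiplier for C>T at CpG sites (and G>A at the
#'   complementary position).
#' @param context_sd Standard deviation of the log-normal per-(context,
#'   alternate) heterogeneity of the generating 3-mer process.
#' @param true_model Optional `context_model` to use as the generating
#'   process; by default one is built from the shape parameters above.
#' @param exonic_multiplier Rate multiplier applied at internal-exon
#'   (central-exon) sites.
#' @param n_trios Number of trios; gametogeneses are twice this.
#' @param asd_fraction Fraction of gametogeneses from ASD probands
#'   (default the 1.7 percent population prevalence).
#' @param ascertainment_boost Relative oversampling of nonsynonymous
#'   exonic mutations in diseased probands; total diseased mutation rate
#'   is renormalized so only the composition changes.
#' @param track_params List: exon_intron_ratio (target per-gene
#'   exon-to-intron covered-base ratio of the H3K36me3-like track),
#'   ratio_jitter (log-normal sd of per-gene ratio variation), depth
#'   (read depth on covered bases), noise (0 for exact coverage, otherwise
#'   Poisson depth per chunk), nucleosome_period and nucleosome_amplitude
#'   (phased-sinusoid nucleosome signal), nucleosome_noise (Gaussian sd as
#'   a fraction of the amplitude), nucleosome_max_bp (per-base signal is
#'   generated for at most this many bases per chromosome).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       n_genes = 40L,
                       exons_per_gene = 5L,
                       exon_length = c(90L, 240L),
                       intron_length = c(600L, 2000L),
                       utr_length = c(150L, 300L),
                       intergenic_length = c(1000L, 4000L),
                       chrom_length = NULL,
                       exonic_gc = 0.52,
                       intronic_gc = 0.40,
                       cpg_factor = 2,
                       site_rate = 1.2e-8,
                       ts_tv = 2,
                       cpg_boost = 8,
                       context_sd = 0.3,
                       true_model = NULL,
                       exonic_multiplier = 1,
                       n_trios = 1291L,
                       asd_fraction = 0.017,
                       ascertainment_boost = 1,
                       track_params = list()) {
  if (exons_per_gene < 3) stop("'exons_per_gene' must be at least 3")
  if (exonic_multiplier < 0) stop("'exonic_multiplier' must be >= 0")
  if (asd_fraction < 0 || asd_fraction > 1) {
    stop("'asd_fraction' must be in [0, 1]")
  }
  tp <- list(exon_intron_ratio = 2, ratio_jitter = 0, depth = 20, noise = 0,
             nucleosome_period = 185L, nucleosome_amplitude = 10,
             nucleosome_noise = 0, nucleosome_max_bp = 200000L)
  tp[names(track_params)] <- track_params
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 n_genes = n_genes, exons_per_gene = exons_per_gene,
                 exon_length = exon_length, intron_length = intron_length,
                 utr_length = utr_length,
                 intergenic_length = intergenic_length,
                 chrom_length = chrom_length, exonic_gc = exonic_gc,
                 intronic_gc = intronic_gc, cpg_factor = cpg_factor,
                 site_rate = site_rate, ts_tv = ts_tv,
                 cpg_boost = cpg_boost, context_sd = context_sd,
                 true_model = true_model,
                 exonic_multiplier = exonic_multiplier,
                 n_trios = as.integer(n_trios),
                 asd_fraction = asd_fraction,
                 ascertainment_boost = ascertainment_boost,
                 track_params = tp),
            class = "sim_config")
}

#' Build a generating 3-mer context process
#'
#' Relative rates combine a transition:transversion ratio, a CpG C>T
#' (and G>A) deamination boost, and seeded log-normal heterogeneity
#' across (context, alternate) cells; the table is scaled so the mean
#' per-site total mutation frequency over contexts equals `site_rate`.
#'
#' @param site_rate Mean per-site total mutation probability.
#' @param ts_tv Transition:transversion ratio.
#' @param cpg_boost CpG deamination multiplier.
#' @param context_sd Log-normal heterogeneity sd.
#' @param seed Seed for the heterogeneity draw.
#' @return A `context_model` with `k_eff = 3` representing the truth.
#' @export
make_true_model <- function(site_rate = 1.2e-8, ts_tv = 2, cpg_boost = 8,
                            context_sd = 0.3, seed = 1L) {
  codes <- 0:63
  x <- kmer_digit(codes, 1, 3)
  c0 <- kmer_digit(codes, 2, 3)
  y <- kmer_digit(codes, 3, 3)
  w <- matrix(1, 64, 4)
  transition_of <- c(2L, 3L, 0L, 1L)  # A<->G, C<->T
  for (b in 0:3) {
    w[cbind(seq_len(64), b + 1L)] <-
      ifelse(c0 == b, 0, ifelse(transition_of[c0 + 1L] == b, ts_tv, 1))
  }
  # CpG deamination: C>T when followed by G; G>A when preceded by C
  w[c0 == 1L & y == 2L, 4] <- w[c0 == 1L & y == 2L, 4] * cpg_boost
  w[c0 == 2L & x == 1L, 1] <- w[c0 == 2L & x == 1L, 1] * cpg_boost
  if (context_sd > 0) {
    het <- withr::with_seed(seed, matrix(exp(rnorm(256, 0, context_sd)),
                                         64, 4))
    w <- w * het
    w[cbind(seq_len(64), c0 + 1L)] <- 0
  }
  prob <- w * site_rate / mean(rowSums(w))
  new_context_model(context_scheme("direct", k = 3), 3, prob)
}

rand_seq <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Exon sequence with CpG dinucleotide frequency pushed toward
# cpg_factor times the independent-base expectation. Extra CpGs are
# created by swapping adjacent "GC" dinucleotides to "CG", which leaves
# the base composition (and hence GC content) exactly unchanged.
exon_seq <- function(n, gc, cpg_factor) {
  s <- rand_seq(n, gc)
  if (cpg_factor <= 1 || n < 2) return(s)
  need <- round((cpg_factor - 1) * (gc / 2)^2 * (n - 1))
  if (need > 0) {
    idx <- which(s[-n] == "G" & s[-1] == "C")
    if (length(idx) > 0) {
      take <- idx[sample.int(length(idx), min(need, length(idx)))]
      s[take] <- "C"
      s[take + 1L] <- "G"
    }
  }
  s
}

runif_len <- function(range) {
  as.integer(round(runif(1, range[1], range[2])))
}

#' Simulate a genome with gene annotation
#'
#' Genes are placed sequentially (never overlapping) with intergenic
#' spacers. Each gene has UTR-like first and last exons and fully coding
#' internal exons whose concatenated length is a multiple of 3; CDS
#' records carry consistent reading frames. Exonic sequence has elevated
#' GC and CpG content relative to intronic/intergenic sequence.
#'
#' @param config A [sim_config()].
#' @return List of class `simulation`: `genome` (named `DNAStringSet`),
#'   `annotation` (GTF-style data.frame), `true_model` (the generating
#'   `context_model`) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    true_model <- config$true_model %||%
      make_true_model(config$site_rate, config$ts_tv, config$cpg_boost,
                      config$context_sd, seed = config$seed)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    gene_chrom <- rep(chroms, length.out = config$n_genes)
    seqs <- setNames(vector("list", length(chroms)), chroms)
    ann <- list()
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      parts <- list()
      cursor <- 0L
      for (gi in which(gene_chrom == chrom)) {
        gap <- runif_len(config$intergenic_length)
        parts[[length(parts) + 1L]] <- rand_seq(gap, config$intronic_gc)
        cursor <- cursor + gap
        gene_id <- sprintf("g%03d", gi)
        strand <- sample(c("+", "-"), 1)
        E <- config$exons_per_gene
        n_int <- E - 2L
        int_len <- vapply(seq_len(n_int), function(i) {
          runif_len(config$exon_length)
        }, 0L)
        excess <- sum(int_len) %% 3L
        if (excess > 0) int_len[n_int] <- int_len[n_int] + (3L - excess)
        utr5 <- runif_len(config$utr_length)
        utr3 <- runif_len(config$utr_length)
        exon_len <- c(utr5, int_len, utr3)
        intron_len <- vapply(seq_len(E - 1L), function(i) {
          runif_len(config$intron_length)
        }, 0L)
        starts <- integer(E); ends <- integer(E)
        pos <- cursor
        exon_parts <- vector("list", E)
        for (e in seq_len(E)) {
          starts[e] <- pos + 1L
          ends[e] <- pos + exon_len[e]
          is_coding <- e > 1L && e < E
          exon_parts[[e]] <- if (is_coding) {
            exon_seq(exon_len[e], config$exonic_gc, config$cpg_factor)
          } else {
            rand_seq(exon_len[e], config$exonic_gc)
          }
          pos <- ends[e]
          if (e < E) {
            parts[[length(parts) + 1L]] <- exon_parts[[e]]
            parts[[length(parts) + 1L]] <-
              rand_seq(intron_len[e], config$intronic_gc)
            pos <- pos + intron_len[e]
          } else {
            parts[[length(parts) + 1L]] <- exon_parts[[e]]
          }
        }
        cursor <- pos
        # CDS frames in transcription order
        coding_idx <- 2:(E - 1L)
        tx_order <- if (strand == "+") coding_idx else rev(coding_idx)
        frames <- integer(length(tx_order))
        phase <- 0L
        for (j in seq_along(tx_order)) {
          frames[j] <- phase
          len <- exon_len[tx_order[j]]
          phase <- (3L - ((len - phase) %% 3L)) %% 3L
        }
        frame_by_exon <- setNames(frames, tx_order)
        rec <- function(feature, s, e, frame = NA_integer_) {
          data.frame(chrom = chrom, feature = feature, start = s, end = e,
                     strand = strand, frame = frame, gene_id = gene_id,
                     transcript_id = paste0(gene_id, ".t1"),
                     stringsAsFactors = FALSE)
        }
        ann[[length(ann) + 1L]] <- do.call(rbind, c(
          list(rec("gene", starts[1], ends[E]),
               rec("transcript", starts[1], ends[E])),
          lapply(seq_len(E), function(e) rec("exon", starts[e], ends[e])),
          lapply(coding_idx, function(e) {
            rec("CDS", starts[e], ends[e],
                frame = frame_by_exon[[as.character(e)]])
          }),
          list(rec("UTR", starts[1], ends[1]),
               rec("UTR", starts[E], ends[E]))
        ))
      }
      tail_gap <- runif_len(config$intergenic_length)
      parts[[length(parts) + 1L]] <- rand_seq(tail_gap, config$intronic_gc)
      cursor <- cursor + tail_gap
      seq_str <- paste(unlist(parts), collapse = "")
      if (!is.null(config$chrom_length)) {
        if (nchar(seq_str) > config$chrom_length) {
          stop("infeasible packing: genes exceed chromosome length on ",
               chrom)
        }
        pad <- config$chrom_length - nchar(seq_str)
        if (pad > 0) {
          seq_str <- paste0(seq_str,
                            paste(rand_seq(pad, config$intronic_gc),
                                  collapse = ""))
        }
      }
      seqs[[chrom]] <- seq_str
    }
    annotation <- do.call(rbind, c(ann, make.row.names = FALSE))
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    structure(list(genome = genome, annotation = annotation,
                   true_model = true_model, config = config),
              class = "simulation")
  })
}

#' Per-window per-site alternate probabilities under a model
#'
#' @param windows A `dnm_windows` object.
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model`.
#' @return List of (width x 4) matrices, one per window.
#' @export
window_alt_probs <- function(windows, genome, model) {
  win <- windows$windows
  code_list <- genome_codes(genome, model$k_eff)
  lapply(seq_len(nrow(win)), function(s) {
    site_alt_probs(code_list[[win$chrom[s]]], model,
                   win$start[s]:win$end[s])
  })
}

# Internal exon intervals (the multiplier territory) straight from the
# generator's own annotation: per gene, exon records minus first and last.
internal_exon_intervals <- function(annotation) {
  ex <- annotation[annotation$feature == "exon", , drop = FALSE]
  out <- lapply(unique(ex$gene_id), function(g) {
    e <- ex[ex$gene_id == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) <= 2) return(NULL)
    e[-c(1, nrow(e)), c("chrom", "start", "end"), drop = FALSE]
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate de novo mutations from the generating process
#'
#' Per genomic site and alternate, the mutation count is binomial over
#' gametogeneses with probability given by the generating model, times the
#' exonic multiplier at internal-exon sites. Diseased (ASD) gametogeneses
#' additionally upweight nonsynonymous coding alternates by the
#' ascertainment boost, with the total diseased rate renormalized so only
#' the composition of their mutations changes.
#'
#' @param sim A `simulation` from [simulate_genome()].
#' @param seed Seed (defaults to the config seed plus 1, a stream distinct
#'   from genome generation).
#' @return DNM data.frame (chrom, pos, ref, alt, condition, dataset).
#' @export
simulate_dnms <- function(sim, seed = NULL) {
  config <- sim$config
  seed <- seed %||% (config$seed + 1L)
  model <- sim$true_model
  n_gen <- 2L * config$n_trios
  n_gen_asd <- round(n_gen * config$asd_fraction)
  n_gen_healthy <- n_gen - n_gen_asd

  internal <- internal_exon_intervals(sim$annotation)
  boost_needed <- n_gen_asd > 0 && config$ascertainment_boost != 1
  models <- if (boost_needed) {
    build_gene_models(sim$annotation, autosome_names = names(sim$genome))
  } else NULL

  withr::with_seed(seed, {
    res <- list()
    lam_sum <- 0; lam_boost_sum <- 0
    lam_list <- list(); boost_list <- list()
    for (chrom in names(sim$genome)) {
      enc <- encode_dna(sim$genome[[chrom]])
      n <- length(enc)
      lam <- matrix(0, n, 4)
      codes <- centered_kmer_codes(enc, model$k_eff)
      ok <- !is.na(codes)
      lam[ok, ] <- model$prob[codes[ok] + 1, , drop = FALSE]
      m <- rep(1, n)
      ii <- internal[internal$chrom == chrom, , drop = FALSE]
      for (r in seq_len(nrow(ii))) {
        m[ii$start[r]:ii$end[r]] <- config$exonic_multiplier
      }
      lam <- lam * m
      if (any(rowSums(lam) > 1)) {
        stop("per-site mutation probability exceeds 1 after multiplier")
      }
      boost <- NULL
      if (boost_needed) {
        boost <- matrix(1, n, 4)
        for (g in models$genes$gene_id[models$genes$chrom == chrom]) {
          sam <- synonymous_alt_matrix(models, g, sim$genome)
          syn <- sam$syn
          if (sam$strand == "-") syn <- syn[, 4:1]  # to + strand alternates
          nonsyn <- !is.na(syn) & !syn
          boost[sam$positions, ][nonsyn] <- config$ascertainment_boost
        }
      }
      lam_sum <- lam_sum + sum(lam)
      lam_boost_sum <- lam_boost_sum +
        if (boost_needed) sum(lam * boost) else sum(lam)
      lam_list[[chrom]] <- lam
      boost_list[[chrom]] <- boost
    }
    renorm <- if (boost_needed) lam_sum / lam_boost_sum else 1
    for (chrom in names(sim$genome)) {
      lam <- lam_list[[chrom]]
      chrom_seq <- strsplit(as.character(sim$genome[[chrom]]), "")[[1]]
      for (grp in c("healthy", "ASD")) {
        n_g <- if (grp == "healthy") n_gen_healthy else n_gen_asd
        if (n_g == 0) next
        rate <- if (grp == "ASD" && boost_needed) {
          pmin(lam * boost_list[[chrom]] * renorm, 1)
        } else lam
        for (a in 1:4) {
          cnt <- rbinom(nrow(rate), n_g, rate[, a])
          hit <- which(cnt > 0)
          if (length(hit) == 0) next
          pos <- rep(hit, cnt[hit])
          res[[length(res) + 1L]] <- data.frame(
            chrom = chrom, pos = pos, ref = chrom_seq[pos],
            alt = BASES[a], condition = grp, dataset = "sim",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(res) == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        condition = character(), dataset = character()))
    }
    dnms <- do.call(rbind, c(res, make.row.names = FALSE))
    dnms[order(dnms$chrom, dnms$pos, dnms$alt), ]
  })
}

#' Simulate mutations directly over analysis windows
#'
#' A fast null/alternative generator for calibration studies: per window,
#' the mutation total is Poisson with mean `n_gen` times the summed
#' (multiplier-adjusted) site frequencies, and sites and alternates are
#' drawn from the model's conditional distributions.
#'
#' @param windows A `dnm_windows` object.
#' @param genome Named `DNAStringSet`.
#' @param model A `context_model` (the generating process).
#' @param n_gen Number of gametogeneses.
#' @param multiplier Rate multiplier at central-exon sites.
#' @param seed Seed.
#' @param site_probs Optional precomputed [window_alt_probs()] result,
#'   reused across replicate simulations.
#' @return DNM data.frame.
#' @export
simulate_window_mutations <- function(windows, genome, model, n_gen,
                                      multiplier = 1, seed = 1L,
                                      site_probs = NULL) {
  win <- windows$windows
  enc_list <- lapply(genome, encode_dna)
  site_probs <- site_probs %||% window_alt_probs(windows, genome, model)
  withr::with_seed(seed, {
    res <- list()
    for (s in seq_len(nrow(win))) {
      enc <- enc_list[[win$chrom[s]]]
      pos <- win$start[s]:win$end[s]
      ap <- site_probs[[s]]
      m <- ifelse(windows$labels[s, ] == 1L, multiplier, 1)
      lam <- ap * m
      tot <- sum(lam)
      n_s <- rpois(1, n_gen * tot)
      if (n_s == 0) next
      site_p <- rowSums(lam) / tot
      counts <- rmultinom(1, n_s, site_p)[, 1]
      hit <- which(counts > 0)
      picks <- rep(hit, counts[hit])
      alt <- vapply(picks, function(i) {
        sample.int(4, 1, prob = lam[i, ])
      }, 0L)
      res[[length(res) + 1L]] <- data.frame(
        chrom = win$chrom[s], pos = pos[picks],
        ref = BASES[enc[pos[picks]] + 1L], alt = BASES[alt],
        condition = "healthy", dataset = "sim_window",
        stringsAsFactors = FALSE)
    }
    if (length(res) == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        condition = character(), dataset = character()))
    }
    do.call(rbind, c(res, make.row.names = FALSE))
  })
}

#' Simulate chromatin coverage tracks
#'
#' The H3K36me3-like track covers all internal meta-exon bases and, per
#' gene, a deterministic quota of meta-intron bases equal to the exonic
#' covered bases divided by the configured exon-to-intron ratio, so with
#' zero noise every gene's measured covered-base ratio equals the target.
#' The nucleosome track is a phased sinusoid with known maxima (truth
#' peaks), generated per base up to `nucleosome_max_bp` per chromosome.
#'
#' @param sim A `simulation`.
#' @param seed Seed (defaults to the config seed plus 2).
#' @return List with `h3k36me3` and `nucleosome` coverage data.frames and
#'   `truth_peaks` (data.frame chrom, pos of the sinusoid maxima).
#' @export
simulate_tracks <- function(sim, seed = NULL) {
  config <- sim$config
  tp <- config$track_params
  seed <- seed %||% (config$seed + 2L)
  models <- build_gene_models(sim$annotation,
                              autosome_names = names(sim$genome))
  withr::with_seed(seed, {
    h3k <- list()
    for (i in seq_len(nrow(models$genes))) {
      g <- models$genes$gene_id[i]; chrom <- models$genes$chrom[i]
      ex <- models$meta_exons[models$meta_exons$gene_id == g, , drop = FALSE]
      intr <- models$meta_introns[models$meta_introns$gene_id == g, ,
                                  drop = FALSE]
      value <- function() {
        if (tp$noise == 0) tp$depth else max(1, rpois(1, tp$depth))
      }
      for (r in seq_len(nrow(ex))) {
        h3k[[length(h3k) + 1L]] <- data.frame(
          chrom = chrom, start = ex$start[r], end = ex$end[r],
          value = value())
      }
      ratio_g <- tp$exon_intron_ratio *
        if (tp$ratio_jitter > 0) exp(rnorm(1, 0, tp$ratio_jitter)) else 1
      quota <- round(sum(ex$end - ex$start + 1) / ratio_g)
      for (r in seq_len(nrow(intr))) {
        if (quota <= 0) break
        take <- min(quota, intr$end[r] - intr$start[r] + 1L)
        h3k[[length(h3k) + 1L]] <- data.frame(
          chrom = chrom, start = intr$start[r],
          end = intr$start[r] + take - 1L, value = value())
        quota <- quota - take
      }
    }
    h3k <- do.call(rbind, c(h3k, make.row.names = FALSE))

    nuc <- list(); peaks <- list()
    period <- tp$nucleosome_period
    for (chrom in names(sim$genome)) {
      n <- min(Biostrings::width(sim$genome)[match(chrom,
                                                   names(sim$genome))],
               tp$nucleosome_max_bp)
      phase <- sample.int(period, 1)
      x <- seq_len(n)
      sig <- tp$nucleosome_amplitude *
        (1 + cos(2 * pi * (x - phase) / period))
      if (tp$nucleosome_noise > 0) {
        sig <- pmax(0, sig + rnorm(n, 0,
                                   tp$nucleosome_noise *
                                     tp$nucleosome_amplitude))
      }
      nuc[[chrom]] <- data.frame(chrom = chrom, start = x, end = x,
                                 value = round(sig, 4))
      pk <- seq(phase, n, by = period)
      peaks[[chrom]] <- data.frame(chrom = chrom, pos = pk)
    }
    list(h3k36me3 = h3k,
         nucleosome = do.call(rbind, c(nuc, make.row.names = FALSE)),
         truth_peaks = do.call(rbind, c(peaks, make.row.names = FALSE)))
  })
}

#' Write a complete simulated dataset to disk
#'
#' Writes FASTA, GTF, the DNM TSV, bedGraph tracks and a truth JSON
#' (generating model table, multiplier, peak positions) into a directory.
#'
#' @param sim A `simulation`.
#' @param dir Output directory (created if needed).
#' @param dnms Optional precomputed DNM table.
#' @param tracks Optional precomputed tracks.
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, dnms = NULL, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             dnms = file.path(dir, "dnms.tsv"),
             h3k36me3 = file.path(dir, "h3k36me3.bedGraph"),
             nucleosome = file.path(dir, "nucleosome.bedGraph"),
             truth = file.path(dir, "truth.json"))
  write_genome_fasta(sim$genome, paths["fasta"])
  write_gtf(sim$annotation, paths["gtf"])
  dnms <- dnms %||% simulate_dnms(sim)
  write_dnm_table(dnms, paths["dnms"])
  tracks <- tracks %||% simulate_tracks(sim)
  write_bedgraph(tracks$h3k36me3, paths["h3k36me3"])
  write_bedgraph(tracks$nucleosome, paths["nucleosome"])
  truth <- list(
    seed = sim$config$seed,
    exonic_multiplier = sim$config$exonic_multiplier,
    ascertainment_boost = sim$config$ascertainment_boost,
    site_rate = sim$config$site_rate,
    model_prob = as.data.frame(sim$true_model$prob),
    truth_peaks = tracks$truth_peaks)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Compose a representative mixed-condition sample
#'
#' Draws a fixed-size sample with an exact condition composition: for a
#' sample of `n_total` mutations at ASD fraction `asd_fraction`, exactly
#' `round(n_total * asd_fraction)` mutations come from ASD probands and
#' the rest from healthy probands.
#'
#' @param dnms DNM data.frame with a `condition` column.
#' @param n_total Sample size.
#' @param asd_fraction Fraction of ASD mutations (default 0.017).
#' @param seed Seed for the resampling.
#' @return DNM data.frame with exactly the requested composition.
#' @export
compose_representative_sample <- function(dnms, n_total,
                                          asd_fraction = 0.017,
                                          seed = 1L) {
  n_asd <- round(n_total * asd_fraction)
  n_healthy <- n_total - n_asd
  asd_pool <- which(dnms$condition == "ASD")
  healthy_pool <- which(dnms$condition == "healthy")
  withr::with_seed(seed, {
    idx <- c(sample(healthy_pool, n_healthy,
                    replace = n_healthy > length(healthy_pool)),
             sample(asd_pool, n_asd, replace = n_asd > length(asd_pool)))
    dnms[sort(idx), , drop = FALSE]
  })
}
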