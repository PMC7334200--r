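# End-to-end orchestration: simulate (or load) inputs, build gene models
# and windows, estimate the context model, run the exon-centered profile
# and excess test, compare schemes, run the chromatin analysis and
# estimate rates, writing TSV reports with the seed and a config hash
# embedded in every output.

#' Parse a scheme string
#'
#' "mono", "cpg", "3" (direct 3-mer), "5:3" (decomposed 5-mer with 3-mer
#' core), and so on.
#'
#' @param s Scheme string.
#' @return A [context_scheme()].
#' @export
parse_scheme <- function(s) {
  s <- tolower(trimws(s))
  if (s %in% c("mono", "1", "1-mer")) return(context_scheme("mono"))
  if (s == "cpg") return(context_scheme("cpg"))
  if (grepl("^[0-9]+$", s)) {
    return(context_scheme("direct", k = as.integer(s)))
  }
  if (grepl("^[0-9]+:[0-9]+$", s)) {
    kh <- as.integer(strsplit(s, ":")[[1]])
    return(context_scheme("decomposed", k = kh[1], h = kh[2]))
  }
  stop("cannot parse scheme string: ", s)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) genome, annotation, DNMs and tracks; build
#' gene models and internal-exon-centered windows (optionally filtered by
#' a mappability mask); estimate the working context model; build the
#' stacked profile and exonic-excess permutation test; compare context
#' schemes by AIC; run the chromatin binned-gene analysis; estimate
#' exonic and intronic mutation rates. Identical config and seed yield an
#' identical result bundle.
#'
#' @param config A list, or a path to a YAML file, with components:
#'   `seed`; either `simulate` (arguments for [sim_config()]) or `inputs`
#'   (paths fasta, gtf, dnms, optionally mask and track); `width` (window
#'   width, default 2001); `k` (working model context, default 3);
#'   `schemes` (character vector, default c("mono", "cpg", "3"));
#'   `n_perm` (default 1000); `stratify` (optional consequence class);
#'   `n_bins` (chromatin bins, default 10); `out_dir` (optional; when set,
#'   TSV reports are written there).
#' @return List of class `pipeline_result` with the intermediate objects
#'   and summary tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  log <- function(...) message("[exindnm] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  config_hash <- tools::md5sum(
    local({
      f <- tempfile()
      yaml::write_yaml(config[setdiff(names(config), "out_dir")], f)
      f
    }))[[1]]

  if (!is.null(config$simulate)) {
    log("simulating dataset (seed %d)", seed)
    sc <- do.call(sim_config, c(list(seed = seed), config$simulate))
    sim <- stage("simulate", simulate_genome(sc))
    genome <- sim$genome
    annotation <- sim$annotation
    dnms <- stage("simulate", simulate_dnms(sim))
    tracks <- stage("simulate", simulate_tracks(sim))
    track <- tracks$h3k36me3
    mask <- NULL
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    for (p in unlist(ins)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    log("loading inputs")
    genome <- stage("load", read_genome_fasta(ins$fasta))
    annotation <- stage("load", read_gtf(ins$gtf))
    dnms <- stage("load", read_dnm_table(ins$dnms))
    mask <- if (!is.null(ins$mask)) read_bed(ins$mask) else NULL
    track <- if (!is.null(ins$track)) read_bedgraph(ins$track) else NULL
  } else {
    stop("config needs either 'simulate' or 'inputs'")
  }

  log("building gene models")
  models <- stage("annotate",
                  build_gene_models(annotation,
                                    autosome_names = names(genome)))
  windows <- stage("annotate",
                   extract_windows(models, genome,
                                   width = config$width %||% 2001L))
  if (!is.null(mask)) {
    windows <- stage("annotate", filter_windows_by_mappability(windows, mask))
  }
  log("%d windows from %d genes", nrow(windows$windows), nrow(models$genes))

  k <- config$k %||% 3L
  log("estimating %d-mer context model from %d DNMs", k, nrow(dnms))
  model <- stage("signature", estimate_direct(dnms, genome, k))

  n_perm <- config$n_perm %||% 1000L
  log("profiling and permutation test (%d permutations)", n_perm)
  profile <- stage("profile", build_profile(windows, dnms, genome, model))
  strat <- config$stratify
  prof_dnms <- dnms
  if (!is.null(strat)) {
    prof_dnms <- stage("profile",
                       stratify_by_consequence(dnms, windows, models,
                                               genome, strat))
  }
  excess <- stage("profile",
                  exonic_excess_test(windows, prof_dnms, genome, model,
                                     n_perm = n_perm, seed = seed,
                                     stratify = strat, models = models))

  schemes <- lapply(config$schemes %||% c("mono", "cpg", "3"), parse_scheme)
  log("comparing %d context schemes", length(schemes))
  comparison <- stage("compare",
                      compare_models(windows, dnms, genome, schemes,
                                     n_perm = n_perm, seed = seed))

  chromatin <- NULL
  if (!is.null(track)) {
    log("chromatin binned-gene analysis")
    chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
    enrich <- stage("chromatin",
                    gene_feature_enrichment(models, track, chrom_lengths))
    expect <- stage("chromatin",
                    expected_exonic_mutations(models, dnms, genome, model))
    tab <- gene_enrichment_table(enrich, expect)
    n_bins <- min(config$n_bins %||% 10L, nrow(tab))
    bins <- stage("chromatin", binned_difference(tab, n_bins = n_bins))
    corr <- stage("chromatin",
                  irls_correlation(bins$median_ratio, bins$difference_pct,
                                   bins$ratio_var))
    chromatin <- list(genes = tab, bins = bins, correlation = corr)
  }

  n_gen <- config$n_gen %||%
    (if (!is.null(config$simulate)) {
      2L * (config$simulate$n_trios %||% sim_config()$n_trios)
    } else stop("'n_gen' required when loading external inputs"))
  rates <- stage("rate", window_mutation_rates(windows, dnms, n_gen))

  result <- structure(list(
    seed = seed, config_hash = config_hash, models = models,
    windows = windows, model = model, profile = profile, excess = excess,
    comparison = comparison, chromatin = chromatin, rates = rates),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# seed\t%d\n# config_md5\t%s", seed, config_hash)
    put <- function(df, name) {
      path <- file.path(out_dir, name)
      con <- file(path, "w")
      writeLines(stamp, con)
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    off <- seq_len(profile$L) - (profile$L + 1L) / 2
    put(data.frame(offset = off, observed = profile$observed,
                   expected = profile$expected,
                   exon_density = profile$exon_density), "profile.tsv")
    put(data.frame(dataset = "all", excess_pct = excess$excess_pct,
                   sd_pct = excess$sd_pct, p_value = excess$p_value),
        "excess.tsv")
    put(as.data.frame(comparison), "model_comparison.tsv")
    put(rates, "rates.tsv")
    if (!is.null(chromatin)) {
      put(chromatin$bins, "chromatin_bins.tsv")
      put(data.frame(r = chromatin$correlation$r,
                     p_value = chromatin$correlation$p_value),
          "chromatin_correlation.tsv")
    }
    windows_to_bed(windows, file.path(out_dir, "windows.bed"))
    write_context_model(model, file.path(out_dir, "model.tsv"))
    log("results written to %s", out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$seed, "\n")
  print(x$excess)
  cat("model comparison (best by AIC):",
      x$comparison$model[x$comparison$best], "\n")
  print(x$rates)
  invisible(x)
}
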