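# k-mer abundance, direct and decomposed estimation, spectrum.

test_that("k-mer abundance matches exhaustive enumeration", {
  g1 <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  a <- count_kmer_abundance(g1, 3)
  expect_equal(a[a > 0], c(ACG = 1, CGT = 1))
  g2 <- Biostrings::DNAStringSet(c(c1 = "AAAA"))
  expect_equal(count_kmer_abundance(g2, 1)[["A"]], 4)

  # N-containing windows are skipped
  g3 <- Biostrings::DNAStringSet(c(c1 = "ACGTNACG"))
  a3 <- count_kmer_abundance(g3, 3)
  expect_equal(sum(a3), 3)  # ACG, CGT, ACG

  # random 10-kb chromosome vs a naive sliding-window tally
  seq10 <- random_dna(10000, seed = 7)
  g4 <- Biostrings::DNAStringSet(c(c1 = seq10))
  a4 <- count_kmer_abundance(g4, 5)
  oracle <- table(vapply(1:(10000 - 4), function(i) {
    substr(seq10, i, i + 4)
  }, ""))
  expect_equal(a4[names(oracle)], unname(unclass(oracle)),
               ignore_attr = TRUE)
  expect_equal(sum(a4), 10000 - 4)

  expect_error(count_kmer_abundance(g1, 2), "odd")
  expect_error(count_kmer_abundance(Biostrings::DNAStringSet(), 3),
               "empty")
})

test_that("direct estimation normalizes counts by reference k-mer abundance", {
  genome <- Biostrings::DNAStringSet(c(c1 = "CAC"))
  dnms <- data.frame(chrom = "c1", pos = 2L, ref = "A", alt = "T")
  m <- estimate_direct(dnms, genome, 3)
  expect_equal(m$prob["CAC", "T"], 1.0)
  expect_equal(sum(m$prob), 1.0)

  # a mutation lacking full flanking context is skipped and logged
  dnms2 <- rbind(dnms, data.frame(chrom = "c1", pos = 1L, ref = "C",
                                  alt = "T"))
  m2 <- estimate_direct(dnms2, genome, 3)
  expect_equal(m2$n_skipped, 1L)
  expect_equal(m2$prob, m$prob)

  expect_error(estimate_direct(
    data.frame(chrom = "c1", pos = 2L, ref = "G", alt = "T"), genome, 3),
    "mismatch")
})

test_that("direct estimates converge to the generating probabilities", {
  fx <- fix_big()
  truth <- fx$sim$true_model
  est <- fx$model
  # the estimate aggregates over gametogeneses, so compare shapes:
  # abundance-weighted total variation after normalizing both to mean 1
  ab <- est$abundance
  norm <- function(f) f / (sum(f * ab) / sum(ab))
  f_e <- norm(rowSums(est$prob)); f_t <- norm(rowSums(truth$prob))
  tv <- sum(abs(f_e - f_t) * ab) / sum(ab)
  expect_lt(tv, 0.10)
  # brute-force recount on a subset: counts equal a direct tally
  sub <- fx$dnms[fx$dnms$chrom == "chr1", ][1:200, ]
  g1 <- as.character(fx$sim$genome[["chr1"]])
  tab <- table(paste(substr(rep(g1, 200), sub$pos - 1, sub$pos + 1),
                     sub$alt))
  m_sub <- estimate_direct(sub, fx$sim$genome["chr1"], 3)
  for (nm in names(tab)) {
    parts <- strsplit(nm, " ")[[1]]
    expect_equal(m_sub$counts[match(parts[1], rownames(m_sub$prob)),
                              match(parts[2], c("A", "C", "G", "T"))],
                 unname(unclass(tab[nm])))
  }
})

test_that("decomposed with h = k is bitwise identical to direct", {
  fx <- fix_small()
  m3 <- estimate_direct(fx$dnms, fx$sim$genome, 3)
  md <- estimate_decomposed(fx$dnms, fx$sim$genome, 3, 3)
  expect_identical(m3$prob, md$prob)
  expect_identical(m3$counts, md$counts)
  expect_error(estimate_decomposed(fx$dnms, fx$sim$genome, 3, 5), "exceed")
})

test_that("summing k-mer counts over flanks reproduces the mono model", {
  fx <- fix_small()
  m3 <- estimate_direct(fx$dnms, fx$sim$genome, 3)
  m1 <- estimate_direct(fx$dnms, fx$sim$genome, 1)
  center <- exindnm:::kmer_digit(0:63, 2, 3)
  agg_counts <- rowsum(m3$counts, center)
  # skipped mutations differ between widths: compare only the marginal
  # identity on mutations countable at k = 3
  expect_equal(unname(colSums(agg_counts)), unname(colSums(m3$counts)))
  agg_abund <- rowsum(m3$abundance, center)[, 1]
  # abundance marginalization: every interior site is counted once
  expect_equal(sum(agg_abund), sum(m3$abundance))
  # mono counts at least match the aggregated ones up to edge effects
  expect_true(all(m1$counts >= agg_counts))
  expect_lte(sum(m1$counts) - sum(agg_counts), m3$n_skipped)
})

test_that("decomposition recovers a product-form process, improving with n", {
  # truth: P(a | c, x, y) = core(a|c) * fx(x) * fy(y), exactly
  # multiplicative in the flanks
  base <- matrix(c(0, 1, 3, 1,
                   2, 0, 1, 4,
                   4, 1, 0, 2,
                   1, 3, 1, 0), 4, 4, byrow = TRUE) * 1e-3
  fx_fac <- c(0.5, 1.5, 0.8, 1.2)
  fy_fac <- c(1.3, 0.7, 1.1, 0.9)
  codes <- 0:63
  xv <- exindnm:::kmer_digit(codes, 1, 3)
  cv <- exindnm:::kmer_digit(codes, 2, 3)
  yv <- exindnm:::kmer_digit(codes, 3, 3)
  prob <- base[cv + 1, ] * fx_fac[xv + 1] * fy_fac[yv + 1]
  truth <- exindnm:::new_context_model(context_scheme("direct", k = 3), 3,
                                       prob)
  seq_str <- random_dna(150000, seed = 9)
  genome <- Biostrings::DNAStringSet(c(c1 = seq_str))
  sim_muts <- function(n_gen, seed) {
    withr::with_seed(seed, {
      enc <- exindnm:::encode_dna(seq_str)
      codes <- exindnm:::centered_kmer_codes(enc, 3)
      lam <- matrix(0, length(enc), 4)
      ok <- !is.na(codes)
      lam[ok, ] <- truth$prob[codes[ok] + 1, ]
      res <- list()
      for (a in 1:4) {
        cnt <- rbinom(length(enc), n_gen, lam[, a])
        hit <- which(cnt > 0)
        if (!length(hit)) next
        pos <- rep(hit, cnt[hit])
        res[[a]] <- data.frame(chrom = "c1", pos = pos,
                               ref = substring(seq_str, pos, pos),
                               alt = c("A", "C", "G", "T")[a])
      }
      do.call(rbind, res)
    })
  }
  err <- vapply(c(1, 9), function(mult) {
    d <- sim_muts(10 * mult, seed = 40 + mult)
    dir <- estimate_direct(d, genome, 3)
    dec <- estimate_decomposed(d, genome, 3, 1)
    ab <- dir$abundance
    sum(abs(dir$prob - dec$prob) * ab) / sum(dir$prob * ab)
  }, 0)
  expect_lt(err[2], err[1])   # tolerance shrinks with sample size
  expect_lt(err[2], 0.15)
})

test_that("CpG model ties probabilities within its six reference states", {
  fx <- fix_small()
  m <- estimate_cpg(fx$dnms, fx$sim$genome)
  expect_equal(m$n_params, 18L)
  state <- exindnm:::cpg_state_of_trimer()
  for (s in 1:6) {
    rows <- m$prob[state == s, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) {
      length(unique(col)) == 1
    })))
  }
  # state probabilities equal aggregate counts over aggregate abundance
  n_state <- rowsum(m$counts, state)
  g_state <- rowsum(m$abundance, state)[, 1]
  for (s in 1:6) {
    expect_equal(unname(m$prob[which(state == s)[1], ]),
                 unname(n_state[s, ] / g_state[s]))
  }
})

test_that("nine-class spectrum folds strands and matches a rule oracle", {
  fx <- fix_small()
  spec <- mutation_spectrum(fx$dnms, fx$sim$genome)
  expect_equal(nrow(spec), 9)
  expect_equal(sum(spec$count), nrow(fx$dnms))

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- vapply(seq_len(nrow(fx$dnms)), function(i) {
    r <- fx$dnms$ref[i]; a <- fx$dnms$alt[i]
    chrom <- as.character(fx$sim$genome[[fx$dnms$chrom[i]]])
    pos <- fx$dnms$pos[i]
    cpg <- (r == "C" && substr(chrom, pos + 1, pos + 1) == "G") ||
      (r == "G" && substr(chrom, pos - 1, pos - 1) == "C")
    if (r %in% c("G", "A")) { r <- comp[[r]]; a <- comp[[a]] }
    paste0(r, ">", a, if (r == "C" && cpg) " (CpG)" else "")
  }, "")
  expect_equal(spec$count, as.numeric(table(
    factor(oracle, levels = spec$class))))

  # single G>A at a CpG folds into the CpG C>T class
  g <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  one <- mutation_spectrum(
    data.frame(chrom = "c1", pos = 3L, ref = "G", alt = "A"), g)
  expect_equal(one$count[one$class == "C>T (CpG)"], 1)
  expect_equal(one$rate[one$class == "C>T (CpG)"], 1 / 2)  # 2 CpG-C sites
})

test_that("model probabilities are bounded and per-site frequencies valid", {
  fx <- fix_small()
  for (m in list(fx$model, estimate_cpg(fx$dnms, fx$sim$genome),
                 estimate_decomposed(fx$dnms, fx$sim$genome, 5, 3))) {
    expect_true(all(m$prob >= 0))
    expect_true(all(rowSums(m$prob) <= 1 + 1e-12))
  }
  f <- site_mutation_freq(fx$sim$genome, fx$model)
  expect_equal(lengths(f), setNames(Biostrings::width(fx$sim$genome),
                                    names(fx$sim$genome)))
  expect_true(all(unlist(f) >= 0))
  # edge positions have no full context
  expect_equal(f[[1]][1], 0)
})
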