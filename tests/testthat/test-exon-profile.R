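# Stacked profiles, rescaled frequencies, stratification and the
# permutation excess test.

test_that("rescaled site frequencies sum to one and are uniform under a flat model", {
  fx <- fix_small()
  sf <- site_frequencies(fx$windows, fx$sim$genome, fx$model)
  expect_equal(unname(rowSums(sf$fresc)),
               rep(1, nrow(fx$windows$windows)))
  um <- uniform_model(3e-6)
  sfu <- site_frequencies(fx$windows, fx$sim$genome, um)
  expect_equal(unname(sfu$fresc[1, ]), rep(1 / 2001, 2001))
})

test_that("site frequencies on a tiny window match a hand computation", {
  # chromosome ACGTACGTA, window = whole 9 bases, 3-mer model with two
  # nonzero cells: P(T | ACG) = 0.2 + 0.1, P(A | GTA) = 0.4
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTA"))
  prob <- matrix(0, 64, 4, dimnames = list(exindnm:::kmer_strings(3),
                                           c("A", "C", "G", "T")))
  prob["ACG", "T"] <- 0.2
  prob["ACG", "A"] <- 0.1
  prob["GTA", "A"] <- 0.4
  m <- exindnm:::new_context_model(context_scheme("direct", k = 3), 3, prob)
  w <- manual_windows("c1", 1L, 9L, matrix(3L, 1, 9))
  sf <- site_frequencies(w, genome, m)
  # positions (1-based centers): 2=CGT?  context at l is seq[l-1..l+1]:
  # l2 ACG -> 0.3, l3 CGT -> 0, l4 GTA -> 0.4, l5 TAC -> 0, l6 ACG -> 0.3,
  # l7 CGT -> 0, l8 GTA -> 0.4; edges l1, l9 -> 0
  hand <- c(0, 0.3, 0, 0.4, 0, 0.3, 0, 0.4, 0)
  expect_equal(unname(sf$f[1, ]), hand)
  expect_equal(unname(sf$fresc[1, ]), hand / sum(hand))

  # all-zero window is an error
  zero <- exindnm:::new_context_model(context_scheme("direct", k = 3), 3,
                                      matrix(0, 64, 4))
  expect_error(site_frequencies(w, genome, zero), "all-zero")
})

test_that("profiles conserve totals and match a naive double-loop oracle", {
  fx <- fix_small()
  prof <- build_profile(fx$windows, fx$dnms, fx$sim$genome, fx$model)
  expect_equal(sum(prof$observed), sum(prof$expected))
  expect_equal(sum(prof$observed), sum(prof$window_n))

  sf <- site_frequencies(fx$windows, fx$sim$genome, fx$model)
  # per-window conservation of the redistribution
  per_window <- rowSums(sf$fresc) * prof$window_n
  expect_equal(per_window, as.numeric(prof$window_n))

  # independent double loop over windows and positions
  S <- nrow(fx$windows$windows); L <- fx$windows$width
  obs_oracle <- numeric(L); exp_oracle <- numeric(L)
  for (s in seq_len(S)) {
    wrow <- fx$windows$windows[s, ]
    in_w <- fx$dnms$chrom == wrow$chrom & fx$dnms$pos >= wrow$start &
      fx$dnms$pos <= wrow$end
    n_s <- sum(in_w)
    for (p in fx$dnms$pos[in_w]) {
      obs_oracle[p - wrow$start + 1] <- obs_oracle[p - wrow$start + 1] + 1
    }
    exp_oracle <- exp_oracle + sf$fresc[s, ] * n_s
  }
  expect_equal(prof$observed, obs_oracle)
  expect_equal(prof$expected, exp_oracle)
})

test_that("a single window with a uniform model expects n/L per site", {
  fx <- fix_small()
  um <- uniform_model(3e-6)
  w1 <- fx$windows
  w1$windows <- w1$windows[1, , drop = FALSE]
  w1$windows$window_id <- 1L
  w1$labels <- w1$labels[1, , drop = FALSE]
  wrow <- w1$windows[1, ]
  chrom_seq <- as.character(fx$sim$genome[[wrow$chrom]])
  pos <- wrow$start + c(10L, 500L, 1200L, 1800L)
  ref <- substring(chrom_seq, pos, pos)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  dnms <- data.frame(chrom = wrow$chrom, pos = pos, ref = ref, alt = alt)
  prof <- build_profile(w1, dnms, fx$sim$genome, um)
  expect_equal(prof$expected, rep(4 / 2001, 2001))
})

test_that("binning averages non-overlapping chunks with a partial tail", {
  v <- c(1, 2, 3, 4, 5, 6, 7)
  expect_equal(bin_profile(v, 1L), v)
  expect_equal(bin_profile(rep(2, 100), 25L), rep(2, 4))
  set.seed(5)
  r <- runif(103)
  got <- bin_profile(r, 25L)
  oracle <- vapply(split(r, (seq_along(r) - 1) %/% 25), mean, 0)
  expect_equal(got, unname(oracle))
  expect_equal(length(got), 5)  # 4 full bins + tail of 3

  fx <- fix_small()
  prof <- build_profile(fx$windows, fx$dnms, fx$sim$genome, fx$model)
  b <- bin_profile(prof, 25L)
  expect_equal(nrow(b), ceiling(2001 / 25))
  expect_equal(mean(b$observed[1:80]),
               mean(bin_profile(prof$observed, 25L)[1:80]))
})

test_that("stratified exonic frequencies partition the full frequency", {
  fx <- fix_small()
  full <- exindnm:::window_site_freq(fx$windows, fx$sim$genome, fx$model)
  syn <- exindnm:::window_site_freq(fx$windows, fx$sim$genome, fx$model,
                                    "synonymous", fx$models)
  non <- exindnm:::window_site_freq(fx$windows, fx$sim$genome, fx$model,
                                    "nonsynonymous", fx$models)
  central <- fx$windows$labels == 1L
  expect_equal(syn$f[central] + non$f[central], full$f[central])
  # intronic and flanking sites keep the full frequency
  expect_equal(syn$f[!central], full$f[!central])
  expect_equal(non$f[!central], full$f[!central])
})

test_that("stratification filters central-exon mutations by class", {
  fx <- fix_small()
  strat <- stratify_by_consequence(fx$dnms, fx$windows, fx$models,
                                   fx$sim$genome, "synonymous")
  hits <- exindnm:::map_mutations_to_windows(fx$windows, strat)
  cen <- hits[fx$windows$labels[cbind(hits$window, hits$offset)] == 1L, ]
  if (nrow(cen) > 0) {
    labs <- classify_consequence(strat[unique(cen$row), , drop = FALSE],
                                 fx$models, fx$sim$genome)
    expect_true(all(labs == "synonymous"))
  }
  # non-central mutations are untouched
  hits_all <- exindnm:::map_mutations_to_windows(fx$windows, fx$dnms)
  cen_all <- unique(hits_all$row[
    fx$windows$labels[cbind(hits_all$window, hits_all$offset)] == 1L])
  expect_equal(nrow(strat), nrow(fx$dnms) -
                 sum(classify_consequence(
                   fx$dnms[cen_all, , drop = FALSE], fx$models,
                   fx$sim$genome) != "synonymous"))
})

test_that("excess is near zero when observations match expectations", {
  fx <- fix_small()
  um <- uniform_model(3e-6)
  w1 <- fx$windows
  keep <- 1:4
  w1$windows <- w1$windows[keep, , drop = FALSE]
  w1$windows$window_id <- seq_along(keep)
  w1$labels <- w1$labels[keep, , drop = FALSE]
  # one mutation at every site of every window: the exonic share of
  # observations equals the uniform expectation exactly
  dnms <- do.call(rbind, lapply(keep, function(s) {
    wrow <- fx$windows$windows[s, ]
    pos <- wrow$start:wrow$end
    ref <- strsplit(as.character(
      fx$sim$genome[[wrow$chrom]]), "")[[1]][pos]
    data.frame(chrom = wrow$chrom, pos = pos, ref = ref,
               alt = ifelse(ref == "A", "C", "A"))
  }))
  ex <- exonic_excess_test(w1, dnms, fx$sim$genome, um, n_perm = 400,
                           seed = 6)
  expect_lt(abs(ex$excess_pct), 3 * ex$sd_pct / sqrt(400) * 10)
  expect_gt(ex$p_value, 0.1)
  expect_equal(ex$n_permutations, 400)
  expect_error(exonic_excess_test(w1, dnms, fx$sim$genome, um, n_perm = 0),
               "at least 1")
})

test_that("injected exonic multipliers are recovered in order", {
  fx <- fix_small()
  truth <- fx$sim$true_model
  sp <- window_alt_probs(fx$windows, fx$sim$genome, truth)
  sfreq <- site_frequencies(fx$windows, fx$sim$genome, truth)
  excesses <- vapply(c(0.9, 1.0, 1.1), function(m) {
    d <- simulate_window_mutations(fx$windows, fx$sim$genome, truth,
                                   n_gen = 40000, multiplier = m,
                                   seed = round(1000 * m), site_probs = sp)
    ex <- exonic_excess_test(fx$windows, d, fx$sim$genome, truth,
                             n_perm = 300, seed = 8, freq = sfreq)
    ex$excess_pct
  }, 0)
  expect_true(all(diff(excesses) > 0))
  expect_lt(abs(excesses[2]), 10)
})

test_that("permutation p-values respect the reporting floor", {
  fx <- fix_small()
  truth <- fx$sim$true_model
  d <- simulate_window_mutations(fx$windows, fx$sim$genome, truth,
                                 n_gen = 30000, multiplier = 1.6,
                                 seed = 12)
  ex <- exonic_excess_test(fx$windows, d, fx$sim$genome, truth,
                           n_perm = 1000, seed = 13)
  expect_equal(ex$p_value, 1 / 1000)  # floor at 1/n_perm
  expect_gt(ex$excess_pct, 0)
})
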