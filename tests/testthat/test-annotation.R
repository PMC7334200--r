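# Gene-model construction, window extraction and consequence labels.

test_that("overlapping genes are both discarded and intronless genes removed", {
  a1 <- toy_gene_annotation(gene_id = "gA",
                            exon_starts = c(101L, 401L, 701L, 1001L),
                            exon_ends = c(200L, 490L, 790L, 1100L))
  a2 <- toy_gene_annotation(gene_id = "gB",
                            exon_starts = c(901L, 1301L, 1601L, 1901L),
                            exon_ends = c(1000L, 1390L, 1690L, 2000L))
  # gB starts inside gA's span -> both discarded
  models <- build_gene_models(rbind(a1, a2))
  expect_equal(nrow(models$genes), 0)
  expect_equal(unname(models$filter_stats["removed_overlapping"]), 2)

  single <- data.frame(chrom = "chrT", feature = "exon", start = 10L,
                       end = 100L, strand = "+", frame = NA_integer_,
                       gene_id = "gS", transcript_id = "gS.t1")
  models2 <- build_gene_models(rbind(a1, single))
  expect_equal(unname(models2$filter_stats["removed_intronless"]), 1)
  expect_equal(models2$genes$gene_id, "gA")
})

test_that("transcripts merge to meta-exons; internal exon is the union minus flanks", {
  # two transcripts sharing exon 2; exon 1 differs in extent
  t1 <- data.frame(chrom = "chrT", feature = "exon",
                   start = c(101L, 301L, 501L), end = c(200L, 400L, 600L),
                   strand = "+", frame = NA_integer_, gene_id = "gM",
                   transcript_id = "t1")
  t2 <- data.frame(chrom = "chrT", feature = "exon",
                   start = c(101L, 301L, 501L), end = c(220L, 400L, 620L),
                   strand = "+", frame = NA_integer_, gene_id = "gM",
                   transcript_id = "t2")
  models <- build_gene_models(rbind(t1, t2))
  # brute-force union of exon intervals: [101,220], [301,400], [501,620]
  expect_equal(nrow(models$meta_exons), 1)
  expect_equal(models$meta_exons$start, 301L)
  expect_equal(models$meta_exons$end, 400L)
  expect_equal(nrow(models$meta_introns), 0)
})

test_that("meta-exon plus meta-intron lengths equal the retained gene span", {
  fx <- fix_small()
  for (g in fx$models$genes$gene_id) {
    ex <- fx$models$meta_exons[fx$models$meta_exons$gene_id == g, ]
    intr <- fx$models$meta_introns[fx$models$meta_introns$gene_id == g, ]
    gene <- fx$models$genes[fx$models$genes$gene_id == g, ]
    expect_equal(sum(ex$end - ex$start + 1) +
                   sum(intr$end - intr$start + 1),
                 gene$end - gene$start + 1)
  }
})

test_that("window labels match a brute-force interval lookup", {
  # toy gene: exons of length 100 separated by 500-bp introns
  starts <- c(1001L, 1601L, 2201L, 2801L, 3401L)
  ends <- starts + 99L
  ends[3] <- starts[3] + 98L  # even-length middle exon exercises floor rule
  ann <- toy_gene_annotation(exon_starts = starts, exon_ends = ends,
                             coding = 2:4)
  genome <- Biostrings::DNAStringSet(c(chrT = random_dna(6000, seed = 3)))
  models <- build_gene_models(ann)
  w <- extract_windows(models, genome, width = 801L)
  expect_equal(nrow(w$windows), 3)
  expect_equal(w$windows$center,
               (models$meta_exons$start + models$meta_exons$end) %/% 2L)

  # independent per-position membership scan
  me <- models$meta_exons; mi <- models$meta_introns
  for (s in seq_len(3)) {
    pos <- w$windows$start[s]:w$windows$end[s]
    anchor <- me[s, ]
    expected <- vapply(pos, function(p) {
      if (p >= anchor$start && p <= anchor$end) return(1L)
      if (any(p >= me$start & p <= me$end)) return(2L)
      if (any(p >= mi$start & p <= mi$end)) return(3L)
      4L
    }, 0L)
    expect_identical(unname(w$labels[s, ]), expected)
  }
})

test_that("window labels are invariant under a constant coordinate shift", {
  starts <- c(1001L, 1601L, 2201L, 2801L)
  ends <- starts + 99L
  ann <- toy_gene_annotation(exon_starts = starts, exon_ends = ends,
                             coding = 2:3)
  genome <- Biostrings::DNAStringSet(c(chrT = random_dna(8000, seed = 4)))
  models <- build_gene_models(ann)
  w1 <- extract_windows(models, genome, width = 801L)

  shift <- 1234L
  ann2 <- ann
  ann2$start <- ann2$start + shift
  ann2$end <- ann2$end + shift
  models2 <- build_gene_models(ann2)
  w2 <- extract_windows(models2, genome, width = 801L)
  expect_identical(w1$labels, w2$labels)
  expect_equal(w2$windows$center, w1$windows$center + shift)
})

test_that("windows running off the chromosome are dropped and counted", {
  starts <- c(11L, 101L, 301L, 501L)
  ends <- starts + 59L
  ann <- toy_gene_annotation(exon_starts = starts, exon_ends = ends,
                             coding = 2:3)
  genome <- Biostrings::DNAStringSet(c(chrT = random_dna(700, seed = 5)))
  w <- extract_windows(build_gene_models(ann), genome, width = 301L)
  # first internal exon center ~130: window [  -20, 280] -> dropped
  expect_equal(attr(w, "n_dropped"), 1)
  expect_equal(nrow(w$windows), 1)
})

test_that("mappability filtering matches a pairwise overlap oracle", {
  fx <- fix_small()
  w <- fx$windows
  set.seed(21)
  mask <- do.call(rbind, lapply(1:30, function(i) {
    chrom <- sample(names(fx$sim$genome), 1)
    s <- sample.int(Biostrings::width(fx$sim$genome)[
      match(chrom, names(fx$sim$genome))] - 200L, 1)
    data.frame(chrom = chrom, start = s, end = s + sample.int(500, 1))
  }))
  filtered <- filter_windows_by_mappability(w, mask)
  keep_oracle <- vapply(seq_len(nrow(w$windows)), function(s) {
    !any(mask$chrom == w$windows$chrom[s] &
           mask$start <= w$windows$end[s] &
           mask$end >= w$windows$start[s])
  }, TRUE)
  expect_equal(nrow(filtered$windows), sum(keep_oracle))
  expect_equal(filtered$windows$center,
               w$windows$center[keep_oracle])

  # empty mask is the identity; single-base overlap removes the window
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  expect_equal(filter_windows_by_mappability(w, empty)$windows, w$windows)
  one <- data.frame(chrom = w$windows$chrom[1], start = w$windows$start[1],
                    end = w$windows$start[1])
  expect_false(w$windows$center[1] %in%
                 filter_windows_by_mappability(w, one)$windows$center)
})

test_that("consequence labels agree with whole-protein translation", {
  fx <- fix_small()
  genome <- fx$sim$genome
  models <- fx$models
  set.seed(31)
  picks <- list()
  for (g in sample(models$genes$gene_id, 6)) {
    st <- exindnm:::gene_cds_structure(models, g, genome)
    idx <- sample(seq_along(st$positions), 20, replace = FALSE)
    chrom <- st$chrom
    for (i in idx) {
      pos <- st$positions[i]
      ref <- substr(as.character(genome[[chrom]]), pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      picks[[length(picks) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, gene = g,
        cds_index = i, stringsAsFactors = FALSE)
    }
  }
  muts <- do.call(rbind, picks)
  got <- classify_consequence(muts, models, genome)

  # oracle: mutate the spliced CDS and compare full protein translations
  oracle <- vapply(seq_len(nrow(muts)), function(i) {
    st <- exindnm:::gene_cds_structure(models, muts$gene[i], genome)
    cds <- st$seq
    j <- muts$cds_index[i]
    alt_cs <- if (st$strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(muts$alt[i])))
    } else muts$alt[i]
    mut_cds <- cds
    substr(mut_cds, j, j) <- alt_cs
    p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             if.fuzzy.codon = "solve"))
    p2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut_cds),
                                             if.fuzzy.codon = "solve"))
    if (p1 == p2) "synonymous" else "nonsynonymous"
  }, "")
  expect_identical(got, oracle)
})

test_that("known codon changes classify correctly on both strands", {
  # + strand: CDS = ATG CTG AAA; CTG->CTA is Leu->Leu, ATG->GTG is Met->Val
  seq_plus <- paste0(strrep("T", 50), "ATGCTGAAA", strrep("T", 50))
  ann <- toy_gene_annotation(exon_starts = c(11L, 51L, 91L),
                             exon_ends = c(20L, 59L, 100L), coding = 2L)
  genome <- Biostrings::DNAStringSet(c(chrT = seq_plus))
  models <- build_gene_models(ann)
  expect_equal(classify_consequence(
    data.frame(chrom = "chrT", pos = 56L, ref = "G", alt = "A"),
    models, genome), "synonymous")
  expect_equal(classify_consequence(
    data.frame(chrom = "chrT", pos = 51L, ref = "A", alt = "G"),
    models, genome), "nonsynonymous")
  # stop gain groups with nonsynonymous: AAA -> TAA at first codon position
  expect_equal(classify_consequence(
    data.frame(chrom = "chrT", pos = 57L, ref = "A", alt = "T"),
    models, genome), "nonsynonymous")
  # reference mismatch is an error
  expect_error(classify_consequence(
    data.frame(chrom = "chrT", pos = 56L, ref = "C", alt = "A"),
    models, genome), "mismatch")
})
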