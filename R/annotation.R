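# Gene models, internal-exon-centered windows, and consequence
# classification.
#
# All coordinates inside the package are 1-based with inclusive ends (the
# native GTF and R convention); BED input/output is converted at the file
# boundary. A gene model holds the union of all transcripts' exons
# (meta-exons) with the first and last exon and all UTR bases removed; the
# gaps between the retained meta-exons are the meta-introns. Every
# retained meta-exon is an internal exon and anchors one analysis window.

#' Build filtered gene models from annotation records
#'
#' Applies the study's gene filters: only autosomal genes are kept; genes
#' without introns (single merged exon) and genes whose spans overlap
#' another gene are discarded; all transcripts are merged into meta-exon
#' coordinates; UTR bases and the first and last meta-exon are removed.
#' Genes left with no internal exon are excluded silently (counted in the
#' filter statistics).
#'
#' @param annotation data.frame as returned by [read_gtf()] (features gene,
#'   transcript, exon, CDS, UTR; 1-based inclusive coordinates).
#' @param autosome_names Character vector of chromosome names to keep.
#' @return An object of class `gene_models`: a list with data.frames
#'   `genes` (gene_id, chrom, strand, start, end of the retained span),
#'   `meta_exons`, `meta_introns`, `cds` (CDS intervals with reading-frame
#'   offsets), and a named integer vector `filter_stats`.
#' @export
build_gene_models <- function(annotation, autosome_names = NULL) {
  bad <- annotation$end < annotation$start
  if (any(bad)) {
    warning(sum(bad), " malformed annotation record(s) rejected")
    annotation <- annotation[!bad, , drop = FALSE]
  }
  ex <- annotation[annotation$feature == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("annotation contains no exon records")
  gene_ids <- unique(ex$gene_id)
  spans <- do.call(rbind, lapply(gene_ids, function(g) {
    e <- ex[ex$gene_id == g, ]
    data.frame(gene_id = g, chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  stats <- c(input = nrow(spans))

  if (!is.null(autosome_names)) {
    keep <- spans$chrom %in% autosome_names
    stats["removed_non_autosomal"] <- sum(!keep)
    spans <- spans[keep, , drop = FALSE]
  } else {
    stats["removed_non_autosomal"] <- 0L
  }

  # merged exons per gene; a single merged exon means no intron
  merged <- lapply(spans$gene_id, function(g) {
    merge_intervals(ex[ex$gene_id == g, c("start", "end")])
  })
  names(merged) <- spans$gene_id
  intronless <- vapply(merged, nrow, 0L) < 2

  overlapping <- rep(FALSE, nrow(spans))
  for (chrom in unique(spans$chrom)) {
    idx <- which(spans$chrom == chrom)
    if (length(idx) < 2) next
    ir <- IRanges::IRanges(spans$start[idx], spans$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    ov <- S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)
    overlapping[idx[unique(S4Vectors::queryHits(hits)[ov])]] <- TRUE
  }
  stats["removed_intronless"] <- sum(intronless)
  stats["removed_overlapping"] <- sum(overlapping & !intronless)
  keep <- !intronless & !overlapping
  spans <- spans[keep, , drop = FALSE]
  merged <- merged[keep]

  utr <- annotation[annotation$feature == "UTR", , drop = FALSE]
  cds <- annotation[annotation$feature == "CDS", , drop = FALSE]

  genes_out <- list(); exons_out <- list(); introns_out <- list()
  cds_out <- list()
  n_no_internal <- 0L
  for (i in seq_len(nrow(spans))) {
    g <- spans$gene_id[i]
    me <- merged[[i]]
    if (nrow(me) <= 2) { n_no_internal <- n_no_internal + 1L; next }
    internal <- me[-c(1, nrow(me)), , drop = FALSE]
    u <- utr[utr$gene_id == g, c("start", "end"), drop = FALSE]
    if (nrow(u) > 0) {
      ir <- IRanges::setdiff(
        IRanges::IRanges(internal$start, internal$end),
        IRanges::reduce(IRanges::IRanges(u$start, u$end)))
      internal <- data.frame(start = IRanges::start(ir),
                             end = IRanges::end(ir))
    }
    if (nrow(internal) == 0) { n_no_internal <- n_no_internal + 1L; next }
    gaps <- data.frame(start = internal$end[-nrow(internal)] + 1L,
                       end = internal$start[-1] - 1L)
    gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
    genes_out[[g]] <- data.frame(
      gene_id = g, chrom = spans$chrom[i], strand = spans$strand[i],
      start = internal$start[1], end = internal$end[nrow(internal)],
      stringsAsFactors = FALSE)
    exons_out[[g]] <- data.frame(
      gene_id = g, chrom = spans$chrom[i], strand = spans$strand[i],
      start = internal$start, end = internal$end,
      exon_index = seq_len(nrow(internal)), stringsAsFactors = FALSE)
    if (nrow(gaps) > 0) {
      introns_out[[g]] <- data.frame(
        gene_id = g, chrom = spans$chrom[i], strand = spans$strand[i],
        start = gaps$start, end = gaps$end, stringsAsFactors = FALSE)
    }
    gc <- cds[cds$gene_id == g, c("chrom", "start", "end", "strand", "frame"),
              drop = FALSE]
    if (nrow(gc) > 0) {
      gc$gene_id <- g
      cds_out[[g]] <- gc[order(gc$start), ]
    }
  }
  stats["removed_no_internal_exon"] <- n_no_internal
  stats["retained"] <- length(genes_out)

  empty_iv <- data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  structure(list(
    genes = if (length(genes_out)) do.call(rbind, c(genes_out,
      make.row.names = FALSE)) else empty_iv,
    meta_exons = if (length(exons_out)) do.call(rbind, c(exons_out,
      make.row.names = FALSE)) else cbind(empty_iv, exon_index = integer()),
    meta_introns = if (length(introns_out)) do.call(rbind, c(introns_out,
      make.row.names = FALSE)) else empty_iv,
    cds = if (length(cds_out)) do.call(rbind, c(cds_out,
      make.row.names = FALSE)) else NULL,
    filter_stats = stats
  ), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes,", nrow(x$meta_exons),
      "internal meta-exons\n")
  cat("  filters:", paste(names(x$filter_stats), x$filter_stats,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Window site labels
WINDOW_LABELS <- c(central_exon = 1L, other_exon = 2L, intron = 3L,
                   intergenic = 4L)

#' Extract internal-exon-centered analysis windows
#'
#' One window per internal meta-exon, centered on the exon's middle
#' position (floor of the midpoint for even-length exons) and spanning
#' `width` bases. Every window position is labeled central_exon (inside
#' the anchor exon), other_exon (inside any other retained meta-exon),
#' intron (inside any meta-intron) or intergenic. Windows extending past
#' a chromosome end are dropped and counted.
#'
#' @param models A `gene_models` object.
#' @param genome Named `DNAStringSet` (for chromosome lengths).
#' @param width Odd window width in bases (default 2001).
#' @return An object of class `dnm_windows`: list with `windows`
#'   (data.frame window_id, chrom, start, end, center, gene_id), `labels`
#'   (integer matrix, one row per window, codes per `WINDOW_LABELS`) and
#'   `width`. The number of windows dropped at chromosome ends is in
#'   `attr(, "n_dropped")`.
#' @export
extract_windows <- function(models, genome, width = 2001L) {
  width <- as.integer(width)
  if (width %% 2 == 0) stop("'width' must be odd")
  half <- (width - 1L) %/% 2L
  chrom_len <- setNames(Biostrings::width(genome), names(genome))

  # global per-chromosome label track from the retained gene models
  track <- lapply(chrom_len, function(n) rep(4L, n))
  for (i in seq_len(nrow(models$meta_exons))) {
    e <- models$meta_exons[i, ]
    track[[e$chrom]][e$start:e$end] <- 2L
  }
  for (i in seq_len(nrow(models$meta_introns))) {
    it <- models$meta_introns[i, ]
    track[[it$chrom]][it$start:it$end] <- 3L
  }

  me <- models$meta_exons
  centers <- (me$start + me$end) %/% 2L
  wstart <- centers - half
  wend <- centers + half
  ok <- wstart >= 1L & wend <= chrom_len[me$chrom]
  n_dropped <- sum(!ok)
  me <- me[ok, , drop = FALSE]
  centers <- centers[ok]; wstart <- wstart[ok]; wend <- wend[ok]

  S <- nrow(me)
  labels <- matrix(4L, nrow = S, ncol = width)
  for (s in seq_len(S)) {
    lab <- track[[me$chrom[s]]][wstart[s]:wend[s]]
    inside <- pmax(me$start[s], wstart[s]):pmin(me$end[s], wend[s])
    lab[inside - wstart[s] + 1L] <- 1L
    labels[s, ] <- lab
  }
  win <- data.frame(window_id = seq_len(S), chrom = me$chrom,
                    start = wstart, end = wend, center = centers,
                    gene_id = me$gene_id, stringsAsFactors = FALSE)
  structure(list(windows = win, labels = labels, width = width),
            class = "dnm_windows", n_dropped = n_dropped)
}

#' @export
print.dnm_windows <- function(x, ...) {
  cat("<dnm_windows>", nrow(x$windows), "windows of width", x$width, "\n")
  frac <- mean(x$labels == 1L)
  cat(sprintf("  central-exon site fraction: %.3f\n", frac))
  invisible(x)
}

#' Remove windows overlapping low-mappability regions
#'
#' A window overlapping any excluded interval by at least one base is
#' removed.
#'
#' @param windows A `dnm_windows` object.
#' @param mask data.frame of excluded intervals (chrom, start, end; 1-based
#'   inclusive, e.g. from [read_bed()]).
#' @return The filtered `dnm_windows`; the retained count is reported in
#'   `attr(, "n_retained")`.
#' @export
filter_windows_by_mappability <- function(windows, mask) {
  keep <- rep(TRUE, nrow(windows$windows))
  for (chrom in unique(mask$chrom)) {
    idx <- which(windows$windows$chrom == chrom)
    if (length(idx) == 0) next
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    iw <- IRanges::IRanges(windows$windows$start[idx],
                           windows$windows$end[idx])
    im <- IRanges::IRanges(m$start, m$end)
    hit <- unique(S4Vectors::queryHits(IRanges::findOverlaps(iw, im)))
    keep[idx[hit]] <- FALSE
  }
  out <- windows
  out$windows <- windows$windows[keep, , drop = FALSE]
  out$windows$window_id <- seq_len(nrow(out$windows))
  out$labels <- windows$labels[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Export windows as BED
#'
#' @param windows A `dnm_windows` object.
#' @param path Output path; window names carry the source gene and the
#'   count of central-exon sites.
#' @export
windows_to_bed <- function(windows, path) {
  df <- windows$windows
  df$name <- sprintf("%s|central=%d", df$gene_id,
                     rowSums(windows$labels == 1L))
  write_bed(df, path)
}

# ---- consequence classification ---------------------------------------------

# Per-gene spliced CDS structure: genomic position of every CDS base (in
# transcription order), the spliced coding sequence, and codon bookkeeping.
# Frames recorded in the annotation are validated against the cumulative
# frame implied by the exon lengths.
gene_cds_structure <- function(models, gene_id, genome) {
  cds <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  if (is.null(cds) || nrow(cds) == 0) {
    stop("no CDS records for gene ", gene_id)
  }
  strand <- cds$strand[1]
  cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
  chrom <- cds$chrom[1]
  seq_chr <- as.character(genome[[chrom]])

  pos_list <- list(); seq_list <- character(nrow(cds))
  phase <- 0L
  for (i in seq_len(nrow(cds))) {
    if (!is.na(cds$frame[i]) && cds$frame[i] != phase) {
      stop("ambiguous reading frame for gene ", gene_id)
    }
    s <- substr(seq_chr, cds$start[i], cds$end[i])
    p <- cds$start[i]:cds$end[i]
    if (strand == "-") {
      s <- revcomp_string(s)
      p <- rev(p)
    }
    seq_list[i] <- s
    pos_list[[i]] <- p
    len <- cds$end[i] - cds$start[i] + 1L
    phase <- (3L - ((len - phase) %% 3L)) %% 3L
  }
  cds_seq <- paste(seq_list, collapse = "")
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       positions = unlist(pos_list), seq = cds_seq)
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# For one gene: a logical matrix (CDS length x 4) saying whether
# substituting the coding-strand alternate at each CDS base leaves the
# amino acid unchanged. NA where alternate equals the reference base.
# Returned with the genomic position of each CDS base.
synonymous_alt_matrix <- function(models, gene_id, genome) {
  st <- gene_cds_structure(models, gene_id, genome)
  n <- nchar(st$seq)
  if (n %% 3 != 0) stop("CDS length of gene ", gene_id,
                        " is not a multiple of 3")
  bases <- strsplit(st$seq, "")[[1]]
  codon_idx <- (seq_len(n) - 1L) %/% 3L
  within <- (seq_len(n) - 1L) %% 3L + 1L
  codons <- vapply(split(bases, codon_idx), paste, "", collapse = "")
  ref_aa <- translate_codons(codons)[codon_idx + 1L]
  syn <- matrix(NA, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  for (b in seq_along(BASES)) {
    alt <- BASES[b]
    changed <- bases != alt
    mut_codons <- codons[codon_idx + 1L]
    substr(mut_codons, within, within) <- alt
    alt_aa <- translate_codons(mut_codons)
    syn[changed, b] <- (alt_aa == ref_aa)[changed]
  }
  list(positions = st$positions, strand = st$strand, chrom = st$chrom,
       syn = syn, ref = bases)
}

#' Classify coding mutations as synonymous or nonsynonymous
#'
#' Exonic CDS mutations are translated with the standard genetic code on
#' the annotated strand. A substitution leaving the amino acid unchanged is
#' synonymous; any other coding change (including stop gain/loss) is
#' nonsynonymous. Positions inside a gene model but outside its CDS are
#' noncoding.
#'
#' @param dnms DNM data.frame (chrom, pos, ref, alt).
#' @param models A `gene_models` object with CDS records.
#' @param genome Named `DNAStringSet`.
#' @return Character vector: "synonymous", "nonsynonymous" or "noncoding".
#' @export
classify_consequence <- function(dnms, models, genome) {
  dnms <- validate_dnms(dnms)
  out <- rep(NA_character_, nrow(dnms))
  gene_cache <- new.env()
  genes <- models$genes
  for (i in seq_len(nrow(dnms))) {
    hit <- which(genes$chrom == dnms$chrom[i] & genes$start <= dnms$pos[i] &
                   genes$end >= dnms$pos[i])
    if (length(hit) == 0) {
      stop("mutation at ", dnms$chrom[i], ":", dnms$pos[i],
           " lies outside every gene model")
    }
    g <- genes$gene_id[hit[1]]
    if (is.null(gene_cache[[g]])) {
      gene_cache[[g]] <- synonymous_alt_matrix(models, g, genome)
    }
    sam <- gene_cache[[g]]
    j <- match(dnms$pos[i], sam$positions)
    if (is.na(j)) { out[i] <- "noncoding"; next }
    ref_cs <- if (sam$strand == "-") {
      BASES[4 - match(dnms$ref[i], BASES) + 1]
    } else dnms$ref[i]
    alt_cs <- if (sam$strand == "-") {
      BASES[4 - match(dnms$alt[i], BASES) + 1]
    } else dnms$alt[i]
    if (sam$ref[j] != ref_cs) {
      stop("reference allele mismatch at ", dnms$chrom[i], ":", dnms$pos[i])
    }
    out[i] <- if (isTRUE(sam$syn[j, alt_cs])) "synonymous" else "nonsynonymous"
  }
  out
}
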