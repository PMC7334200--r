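# File readers/writers for the plain-text formats the pipeline consumes:
# FASTA (via Biostrings), GTF (1-based inclusive, read natively), BED
# (0-based half-open, converted to 1-based inclusive on read), 4-column
# bedGraph, and the tab-separated DNM table.

#' Read a reference genome from FASTA
#'
#' @param path Path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return A named `Biostrings::DNAStringSet`, sequences uppercased.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate chromosome names in FASTA")
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a genome to FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene annotation from a GTF file
#'
#' Understands the features gene, transcript, exon, CDS and UTR, and the
#' attributes `gene_id` and `transcript_id`. Coordinates are kept 1-based
#' inclusive. Records with `end < start` are rejected with a warning.
#'
#' @param path Path to a GTF file.
#' @return data.frame with columns chrom, feature, start, end, strand,
#'   frame, gene_id, transcript_id.
#' @export
read_gtf <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#", quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "source", "feature", "start", "end",
                                 "score", "strand", "frame", "attributes"))
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- regexpr(paste0(key, ' "[^"]*"'), attrs) > 0
    out[hit] <- sub(paste0(key, ' "([^"]*)"'), "\\1", m)
    out
  }
  ann <- data.frame(
    chrom = df$chrom, feature = df$feature,
    start = as.integer(df$start), end = as.integer(df$end),
    strand = df$strand,
    frame = suppressWarnings(as.integer(df$frame)),
    gene_id = get_attr(df$attributes, "gene_id"),
    transcript_id = get_attr(df$attributes, "transcript_id"),
    stringsAsFactors = FALSE
  )
  bad <- ann$end < ann$start
  if (any(bad)) {
    warning(sum(bad), " malformed annotation record(s) with end < start ",
            "rejected")
    ann <- ann[!bad, , drop = FALSE]
  }
  ann
}

#' Write gene annotation records to GTF
#' @param ann Annotation data.frame as returned by [read_gtf()].
#' @param path Output path.
#' @export
write_gtf <- function(ann, path) {
  frame <- ifelse(is.na(ann$frame), ".", as.character(ann$frame))
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   ann$gene_id, ifelse(is.na(ann$transcript_id), ann$gene_id,
                                       ann$transcript_id))
  lines <- paste(ann$chrom, "exindnm", ann$feature, ann$start, ann$end, ".",
                 ann$strand, frame, attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path Path to a BED file (3 columns minimum).
#' @return data.frame with chrom, start, end (1-based inclusive) plus any
#'   further BED columns as `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(df) > 3) {
    names(df)[4:min(6, ncol(df))] <- extra[seq_len(min(3, ncol(df) - 3))]
  }
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Write intervals to BED (converting to 0-based half-open)
#' @param df data.frame with chrom, start, end (1-based inclusive); optional
#'   `name` column becomes BED column 4.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if (!is.null(df$name)) out$name <- df$name
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph coverage track
#' @param path Path to a bedGraph file.
#' @return data.frame chrom, start, end (1-based inclusive), value.
#' @export
read_bedgraph <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  df <- df[!grepl("^track", df[[1]]), , drop = FALSE]
  if (ncol(df) < 4) stop("bedGraph file needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df$value <- as.numeric(df$value)
  if (any(df$value < 0)) stop("negative coverage values in bedGraph")
  df[order(df$chrom, df$start), c("chrom", "start", "end", "value")]
}

#' Write a coverage track to bedGraph
#' @param track data.frame chrom, start, end (1-based inclusive), value.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(chrom = track$chrom, start = track$start - 1L,
                    end = track$end, value = track$value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a de novo mutation table
#'
#' Expects a TSV with header columns chrom, pos (1-based), ref, alt and
#' optionally condition and dataset.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns chrom, pos, ref, alt, condition, dataset.
#' @export
read_dnm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("DNM table must have columns: ", paste(need, collapse = ", "))
  }
  df$condition <- df$condition %||% rep("unknown", nrow(df))
  df$dataset <- df$dataset %||% rep("default", nrow(df))
  validate_dnms(df[, c("chrom", "pos", "ref", "alt", "condition", "dataset")])
}

#' Write a de novo mutation table
#' @param dnms DNM data.frame.
#' @param path Output path.
#' @export
write_dnm_table <- function(dnms, path) {
  write.table(dnms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_dnms <- function(dnms) {
  dnms$chrom <- as.character(dnms$chrom)
  dnms$pos <- as.integer(dnms$pos)
  dnms$ref <- toupper(as.character(dnms$ref))
  dnms$alt <- toupper(as.character(dnms$alt))
  if (!all(dnms$ref %in% BASES) || !all(dnms$alt %in% BASES)) {
    stop("DNM ref/alt alleles must be A, C, G or T")
  }
  if (any(dnms$ref == dnms$alt)) stop("DNM with alt equal to ref")
  dnms
}
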