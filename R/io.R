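# On-disk formats for the simulated study: FASTA/FASTQ via Biostrings,
# GFF3 (1-based inclusive) for genes, BED (0-based half-open) for truth
# labels, and TSV for tables.

#' Write a reference set to disk
#'
#' Emits the segment FASTA, a GFF3 of gene records (with \code{ID} and
#' \code{gene_class} attributes) and the truth-label BED.
#'
#' @param ref a \code{reference_set}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "truth.bed")
  seqs <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(seqs, fasta)
  g <- ref$genes
  gff_lines <- c("##gff-version 3",
                 sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\tID=%s;gene_class=%s",
                         g$seqid, g$source, g$type, g$start, g$end, g$score,
                         g$strand, g$phase, g$gene_id, g$gene_class))
  writeLines(gff_lines, gff)
  writeLines(sprintf("%s\t%d\t%d\t%s", ref$truth$seqid, ref$truth$start,
                     ref$truth$end, ref$truth$class), bed)
  invisible(c(fasta = fasta, gff = gff, bed = bed))
}

#' Write simulated read pairs as FASTQ
#'
#' Phred+33 with constant quality (the reads are error-free).
#'
#' @param pairs a \code{read_pairs} data.frame.
#' @param prefix output path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (mate in 1:2) {
    s <- Biostrings::DNAStringSet(pairs[[paste0("seq", mate)]])
    names(s) <- paste0(pairs$id, "/", mate)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(s)))
    Biostrings::writeXStringSet(s, paths[mate], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' Read a FASTQ pair into a read-pairs table
#'
#' @param path1,path2 mated FASTQ files with equal record counts.
#' @return data.frame \code{id, seq1, seq2}.
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2))
    stop("pairing error: mate files have ", length(s1), " vs ", length(s2),
         " records")
  data.frame(id = sub("/1$", "", names(s1)), seq1 = as.character(s1),
             seq2 = as.character(s2), stringsAsFactors = FALSE)
}

#' Read a GFF3 gene file
#'
#' @param path GFF3 with \code{ID} and optionally \code{gene_class}
#'   attributes.
#' @return data.frame \code{seqid, source, type, start, end, strand, gene_id,
#'   gene_class}.
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 9L))
  m <- do.call(rbind, parts)
  attr_get <- function(attrs, key) {
    v <- sub(paste0(".*", key, "=([^;]*).*"), "\\1", attrs)
    ifelse(grepl(paste0(key, "="), attrs), v, NA_character_)
  }
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             strand = m[, 7], gene_id = attr_get(m[, 9], "ID"),
             gene_class = attr_get(m[, 9], "gene_class"),
             stringsAsFactors = FALSE)
}

#' Read a truth-label BED
#'
#' @param path BED with a class label in column 4.
#' @return data.frame \code{seqid, start, end, class}.
#' @export
read_truth_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("seqid", "start", "end", "class"),
                    stringsAsFactors = FALSE)
}
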