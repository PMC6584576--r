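# GC-content screening of reads and scaffolds, and k-mer based coverage
# estimation. This is the decontamination / QC stage: a host genome at ~45%
# GC mixed with microbial contaminants at ~65% GC separates cleanly on read
# GC, and the k-mer histogram peak estimates sequencing depth.

#' GC content of DNA sequences
#'
#' Fraction (G + C) / (A + C + G + T), case-insensitive; ambiguous bases (N
#' and other IUPAC codes) are excluded from both numerator and denominator.
#'
#' @param seqs character vector of DNA sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(seqs) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  freq <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  unamb <- rowSums(freq)
  if (any(unamb == 0))
    stop("GC undefined: sequence with no unambiguous bases at position ",
         which(unamb == 0)[1])
  unname((freq[, "C"] + freq[, "G"]) / unamb)
}

#' Filter paired reads by GC content
#'
#' Discards every read pair in which either mate has GC content strictly
#' greater than the threshold, keeping the files mated (a read whose mate
#' fails is discarded with it).
#'
#' @param pairs a \code{read_pairs} data.frame (columns \code{seq1},
#'   \code{seq2}) or any data.frame with those columns.
#' @param threshold GC fraction above which a read is contaminant-like.
#' @return list with \code{kept} and \code{discarded} (row subsets of
#'   \code{pairs}) and \code{report}: list with \code{n_input, n_kept,
#'   n_discarded} and per-partition GC histograms (density of per-read GC in
#'   bins of 0.01).
#' @export
filter_reads_by_gc <- function(pairs, threshold = 0.55) {
  stopifnot(all(c("seq1", "seq2") %in% names(pairs)))
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(kept = pairs, discarded = pairs,
                report = list(n_input = 0L, n_kept = 0L, n_discarded = 0L,
                              gc_hist_kept = NULL, gc_hist_discarded = NULL)))
  }
  gc1 <- gc_content(pairs$seq1)
  gc2 <- gc_content(pairs$seq2)
  fail <- gc1 > threshold | gc2 > threshold
  hist_of <- function(gc) {
    if (length(gc) == 0) return(NULL)
    h <- graphics::hist(gc, breaks = seq(0, 1, by = 0.01), plot = FALSE)
    data.frame(gc_mid = h$mids, count = h$counts)
  }
  list(kept = pairs[!fail, , drop = FALSE],
       discarded = pairs[fail, , drop = FALSE],
       report = list(n_input = n, n_kept = sum(!fail),
                     n_discarded = sum(fail),
                     gc_hist_kept = hist_of(c(gc1[!fail], gc2[!fail])),
                     gc_hist_discarded = hist_of(c(gc1[fail], gc2[fail]))))
}

#' Per-scaffold GC table with bimodality summary
#'
#' Computes length, GC and ambiguous-base count per scaffold and summarises
#' the length-weighted GC distribution by its two highest-density modes and
#' the antimode between them (kernel-smoothed, emulating the scaffold
#' length-vs-GC diagnostic plot that separates host from contaminant
#' clusters).
#'
#' @param seqs named character vector (or \code{DNAStringSet}) of scaffold
#'   sequences.
#' @param bandwidth kernel bandwidth on the GC axis.
#' @return list with \code{table} (data.frame \code{id, length, gc, n_count})
#'   and \code{bimodality}: list \code{modes} (numeric, up to 2, highest
#'   density first), \code{antimode} (NA when fewer than 2 modes).
#' @export
scaffold_gc_table <- function(seqs, bandwidth = 0.02) {
  if (length(seqs) == 0L) stop("empty FASTA: no scaffolds")
  seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("scaffold%d", seq_along(seqs))
  lens <- nchar(seqs)
  gc <- gc_content(seqs)
  x <- Biostrings::DNAStringSet(toupper(seqs))
  unamb <- rowSums(Biostrings::letterFrequency(
    x, letters = c("A", "C", "G", "T")))
  tab <- data.frame(id = names(seqs), length = lens, gc = gc,
                    n_count = lens - unamb, stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  w <- lens / sum(lens)
  if (length(seqs) == 1L) {
    bim <- list(modes = gc, antimode = NA_real_)
  } else {
    d <- stats::density(gc, weights = w, bw = bandwidth, from = 0, to = 1,
                        n = 1024)
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1L
    if (y[1] > y[2]) is_max <- c(1L, is_max)
    if (y[length(y)] > y[length(y) - 1]) is_max <- c(is_max, length(y))
    is_max <- is_max[order(y[is_max], decreasing = TRUE)]
    modes <- d$x[utils::head(is_max, 2)]
    if (length(modes) >= 2) {
      lo <- min(modes[1:2]); hi <- max(modes[1:2])
      between <- d$x > lo & d$x < hi
      antimode <- d$x[between][which.min(y[between])]
      bim <- list(modes = modes[1:2], antimode = antimode)
    } else {
      bim <- list(modes = modes, antimode = NA_real_)
    }
  }
  list(table = tab, bimodality = bim)
}

#' Canonical k-mer histogram and coverage estimate
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement; k-mers containing ambiguous bases are skipped) over a
#' set of reads and estimates sequencing coverage as the multiplicity of the
#' highest-count histogram bin after the first local minimum, excluding the
#' low-multiplicity error/contaminant region. The k-mer peak is also
#' converted to per-base coverage via \code{read_len / (read_len - k + 1)}.
#'
#' @param reads character vector of read sequences.
#' @param k odd word size, at most the read length.
#' @return list with \code{histogram} (data.frame \code{multiplicity,
#'   count}), \code{kmer_peak} (multiplicity at the coverage peak, NA when
#'   undetectable) and \code{base_coverage} (peak rescaled to per-base
#'   coverage).
#' @export
kmer_coverage <- function(reads, k = 31L) {
  if (length(reads) == 0L) stop("no reads supplied")
  reads <- toupper(reads)
  rl <- max(nchar(reads))
  if (k > min(nchar(reads))) stop("k exceeds read length")
  n_win <- nchar(reads) - k + 1L
  kmers <- unlist(lapply(seq_len(max(n_win)), function(off) {
    sel <- n_win >= off
    substring(reads[sel], off, off + k - 1L)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) stop("no unambiguous k-mers")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  mult <- table(canon)
  hist_tab <- table(as.integer(mult))
  histogram <- data.frame(multiplicity = as.integer(names(hist_tab)),
                          count = as.integer(hist_tab))
  histogram <- histogram[order(histogram$multiplicity), ]
  rownames(histogram) <- NULL
  peak <- kmer_peak(histogram)
  list(histogram = histogram, kmer_peak = peak,
       base_coverage = if (is.na(peak)) NA_real_ else peak * rl / (rl - k + 1))
}

#' Coverage peak of a k-mer histogram
#'
#' Scans the dense histogram from multiplicity 1 upward for the first local
#' minimum (ties broken toward lower multiplicity), then reports the global
#' maximum beyond it. If the histogram rises from the start (no error
#' region), the first local minimum is multiplicity 1 itself.
#'
#' @param histogram data.frame \code{multiplicity, count}.
#' @return integer multiplicity of the coverage peak, or NA.
#' @export
kmer_peak <- function(histogram) {
  if (nrow(histogram) == 0L) return(NA_integer_)
  m_max <- max(histogram$multiplicity)
  dense <- integer(m_max)
  dense[histogram$multiplicity] <- histogram$count
  if (m_max == 1L) return(1L)
  valley <- NA_integer_
  for (m in seq_len(m_max - 1L)) {
    left_ok <- if (m == 1L) TRUE else dense[m] <= dense[m - 1L]
    if (left_ok && dense[m] <= dense[m + 1L]) { valley <- m; break }
  }
  if (is.na(valley)) return(which.max(dense))  # monotone decreasing: no peak
  beyond <- valley:m_max
  beyond[which.max(dense[beyond])]
}
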