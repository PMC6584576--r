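# Sex-marker candidate cascade: differential-coverage regions are annotated
# with genes on the same scaffold, the genes' best homology hits, and the
# sex-chromosome class of those homologs in a reference species; regions
# whose coverage call and homolog class agree become sex-marker candidates.

#' Read a 12-column blast-like tabular file
#'
#' @param path tab-separated file in the standard outfmt-6 layout (qseqid,
#'   sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore).
#' @return data.frame with those columns.
#' @export
read_blast_tsv <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(stats::setNames(
      data.frame(matrix(ncol = 12, nrow = 0)), cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad) > 0)
    stop("malformed hit row at line ", bad[1], ": expected 12 columns, got ",
         lengths(parts)[bad[1]])
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (anyNA(v))
      stop("malformed hit row at line ", which(is.na(v))[1],
           ": non-numeric ", cn)
    out[[cn]] <- v
  }
  out
}

#' Select the single best hit per query
#'
#' Best = maximal bitscore; ties broken by lower e-value, then lexicographic
#' subject id, so selection is deterministic.
#'
#' @param hits data.frame with at least \code{qseqid, sseqid, evalue,
#'   bitscore}.
#' @return data.frame with one row per query.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Sex-marker candidate cascade
#'
#' Annotates each differential-coverage region with the furthest stage it
#' reaches: \code{region_only} (no predicted gene on its scaffold),
#' \code{has_gene}, \code{has_homolog} (a gene on the scaffold has a best
#' homology hit of known class), and \code{sex_concordant} (the coverage
#' call agrees with the homolog's sex-chromosome class: male-specific
#' coverage with a V homolog, or female-specific coverage with a U homolog,
#' under the A = male convention). Discordant combinations are retained at
#' stage \code{has_homolog} with a note, never dropped.
#'
#' @param regions region table from [merge_regions()] (needs \code{seg,
#'   start, end, sex_call}).
#' @param genes GFF3-style data.frame with \code{seqid, start, end, gene_id}
#'   (1-based inclusive).
#' @param besthits per-gene best hits, data.frame \code{qseqid, sseqid}
#'   (e.g. from [best_hit()]); queries are gene ids.
#' @param ref_classes named character vector mapping subject id to chromosome
#'   class in \code{c("U", "V", "autosome", "organelle", "unknown")}.
#' @param max_distance maximum bp between region and gene on the same
#'   scaffold (\code{Inf} = scaffold-wide, the default interpretation).
#' @param segments optional character vector of all assembly segment ids;
#'   when supplied, a region on a segment outside it is an input error.
#' @return list with \code{candidates} (one row per region: \code{seg, start,
#'   end, sex_call, gene_id, homolog, homolog_class, cascade_stage,
#'   sex_prediction, note}) and \code{stage_counts} (named cumulative counts,
#'   monotone non-increasing).
#' @export
cascade <- function(regions, genes, besthits, ref_classes,
                    max_distance = Inf, segments = NULL) {
  if (!is.null(segments)) {
    bad <- !regions$seg %in% segments
    if (any(bad)) stop("region references unknown segment: ",
                       regions$seg[bad][1])
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    out <- data.frame(seg = r$seg, start = r$start, end = r$end,
                      sex_call = r$sex_call, gene_id = NA_character_,
                      homolog = NA_character_, homolog_class = NA_character_,
                      cascade_stage = "region_only",
                      sex_prediction = NA_character_, note = "",
                      stringsAsFactors = FALSE)
    g <- genes[genes$seqid == r$seg, , drop = FALSE]
    if (is.finite(max_distance) && nrow(g) > 0) {
      # distance between region [start,end) (0-based) and gene (1-based)
      dist <- pmax(0, pmax((g$start - 1) - r$end, r$start - g$end))
      g <- g[dist <= max_distance, , drop = FALSE]
    }
    if (nrow(g) == 0L) return(out)
    out$cascade_stage <- "has_gene"
    out$gene_id <- g$gene_id[1]
    h <- besthits[besthits$qseqid %in% g$gene_id, , drop = FALSE]
    h$class <- unname(ref_classes[h$sseqid])
    h <- h[!is.na(h$class), , drop = FALSE]
    if (nrow(h) == 0L) return(out)
    wanted <- switch(r$sex_call, a_specific = "V", b_specific = "U", NA)
    conc <- if (!is.na(wanted)) which(h$class == wanted) else integer(0)
    pick <- if (length(conc)) conc[1] else 1L
    out$gene_id <- h$qseqid[pick]
    out$homolog <- h$sseqid[pick]
    out$homolog_class <- h$class[pick]
    if (length(conc)) {
      out$cascade_stage <- "sex_concordant"
      out$sex_prediction <- if (wanted == "V") "male" else "female"
    } else {
      out$cascade_stage <- "has_homolog"
      if (h$class[pick] %in% c("U", "V")) out$note <- "discordant"
    }
    out
  })
  candidates <- do.call(rbind, rows)
  stages <- c("region_only", "has_gene", "has_homolog", "sex_concordant")
  reached <- match(candidates$cascade_stage, stages)
  stage_counts <- stats::setNames(
    vapply(seq_along(stages), function(k) sum(reached >= k), integer(1)),
    stages)
  list(candidates = candidates, stage_counts = stage_counts)
}

#' Export sex-concordant candidates as BED and FASTA
#'
#' @param candidates candidate table from [cascade()].
#' @param seqs named character vector of segment sequences.
#' @param bed_path,fasta_path output files.
#' @return invisibly, the exported candidate subset.
#' @export
export_candidates <- function(candidates, seqs, bed_path, fasta_path) {
  cand <- candidates[candidates$cascade_stage == "sex_concordant", ,
                     drop = FALSE]
  bed_lines <- character(0)
  fasta <- Biostrings::DNAStringSet()
  if (nrow(cand) > 0) {
    seg_len <- nchar(seqs[cand$seg])
    if (any(cand$end > seg_len))
      stop("candidate region exceeds segment length on ",
           cand$seg[cand$end > seg_len][1])
    bed_lines <- sprintf("%s\t%d\t%d\t%s", cand$seg, cand$start, cand$end,
                         cand$sex_prediction)
    fasta <- Biostrings::DNAStringSet(
      substring(seqs[cand$seg], cand$start + 1L, cand$end))
    names(fasta) <- sprintf("%s:%d-%d:%s", cand$seg, cand$start, cand$end,
                            cand$sex_prediction)
  }
  writeLines(bed_lines, bed_path)
  Biostrings::writeXStringSet(fasta, fasta_path)
  invisible(cand)
}
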