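# Windowed male:female differential-coverage scan. Fixed non-overlapping
# windows tile each segment; per-window mean depths of the two samples are
# normalized by a median ratio, converted to pseudo-counted log2 ratios, and
# thresholded into sex-specific / enriched / balanced calls; flagged windows
# merge into regions.

#' Tile a coverage track into fixed-width windows
#'
#' Non-overlapping windows tile each segment from position 0; the terminal
#' partial window is emitted with its true width and marked partial. The mean
#' depth of a full window is the depth sum divided by the window width.
#'
#' @param track named list of per-base depth vectors, one per segment.
#' @param width window width in bp.
#' @return data.frame \code{seg, start, end, width, cov, partial} with
#'   0-based half-open coordinates.
#' @export
window_coverage <- function(track, width = 500L) {
  if (width <= 0) stop("width must be positive")
  width <- as.integer(width)
  out <- lapply(names(track), function(sid) {
    depth <- track[[sid]]
    len <- length(depth)
    if (len == 0L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = width)
    ends <- pmin(starts + width, len)
    cov <- vapply(seq_along(starts), function(i) {
      sum(depth[(starts[i] + 1L):ends[i]]) / (ends[i] - starts[i])
    }, numeric(1))
    data.frame(seg = sid, start = starts, end = ends,
               width = ends - starts, cov = cov,
               partial = (ends - starts) < width,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Join two samples' window tables
#'
#' @param windows_a,windows_b window tables from [window_coverage()] over the
#'   same reference (sample A = male, sample B = female by convention).
#' @return joined data.frame with \code{cov_a} and \code{cov_b}.
#' @export
join_windows <- function(windows_a, windows_b) {
  key_a <- paste(windows_a$seg, windows_a$start)
  key_b <- paste(windows_b$seg, windows_b$start)
  if (!identical(key_a, key_b))
    stop("window tables do not tile the same reference")
  out <- windows_a[, c("seg", "start", "end", "width", "partial")]
  out$cov_a <- windows_a$cov
  out$cov_b <- windows_b$cov
  out
}

#' Median-ratio normalization factor between two samples
#'
#' The scale is the median of \code{cov_a / cov_b} over baseline windows in
#' which both samples have positive depth, so that sex-specific regions
#' (zero in one sample) cannot distort library-size normalization. Ratios
#' are then computed as \code{cov_a / (scale * cov_b)}.
#'
#' @param windows joined window table from [join_windows()].
#' @param baseline character vector of segment ids to use as the baseline
#'   (e.g. putative autosomes), or \code{"all"}.
#' @return scale factor (scalar).
#' @export
estimate_scale <- function(windows, baseline = "all") {
  w <- windows
  if (!identical(baseline, "all")) w <- w[w$seg %in% baseline, , drop = FALSE]
  w <- w[w$cov_a > 0 & w$cov_b > 0, , drop = FALSE]
  if (nrow(w) == 0L) stop("no baseline window with positive depth in both samples")
  stats::median(w$cov_a / w$cov_b)
}

#' Pseudo-counted log2 coverage ratio
#'
#' \code{log2((cov_a / sqrt(scale) + p) / (cov_b * sqrt(scale) + p))}: the
#' normalization factor is split symmetrically over the two samples and the
#' pseudo-count added afterwards. This keeps the ratio finite at zero
#' coverage, leaves perfectly proportional samples at exactly zero, and gives
#' exact antisymmetry: swapping the samples and inverting the scale negates
#' the value.
#'
#' @param cov_a,cov_b mean window depths.
#' @param scale normalization factor from [estimate_scale()].
#' @param p pseudo-count depth.
#' @return numeric log2 ratios.
#' @export
log2_ratio <- function(cov_a, cov_b, scale = 1, p = 0.1) {
  if (p <= 0) stop("pseudo-count must be positive")
  if (scale <= 0) stop("scale must be positive")
  s <- sqrt(scale)
  log2((cov_a / s + p) / (cov_b * s + p))
}

#' Flag windows with genotype-specific coverage
#'
#' Windows with \code{|log2_ratio| > enrich_threshold} are flagged. A flagged
#' window whose depleted sample has raw mean depth at most \code{c0} is
#' called sample-specific (\code{a_specific} when \code{cov_b <= c0},
#' \code{b_specific} when \code{cov_a <= c0}); other flagged windows are
#' called enriched. Partial terminal windows are never flagged.
#'
#' @param windows joined window table.
#' @param scale normalization factor.
#' @param enrich_threshold absolute log2 ratio cutoff.
#' @param c0 raw depth at or below which the depleted sample counts as absent.
#' @param p pseudo-count.
#' @return the window table with \code{scale, log2_ratio, flagged, sex_call}
#'   columns added; \code{sex_call} one of \code{a_specific, b_specific,
#'   a_enriched, b_enriched, balanced}.
#' @export
flag_windows <- function(windows, scale = 1, enrich_threshold = 4,
                         c0 = 2, p = 0.1) {
  if (enrich_threshold <= 0 || c0 < 0) stop("invalid thresholds")
  r <- log2_ratio(windows$cov_a, windows$cov_b, scale, p)
  flagged <- abs(r) > enrich_threshold & !windows$partial
  call <- rep("balanced", nrow(windows))
  up <- flagged & r > 0
  dn <- flagged & r < 0
  call[up] <- ifelse(windows$cov_b[up] <= c0, "a_specific", "a_enriched")
  call[dn] <- ifelse(windows$cov_a[dn] <= c0, "b_specific", "b_enriched")
  windows$scale <- scale
  windows$log2_ratio <- r
  windows$flagged <- flagged
  windows$sex_call <- call
  windows
}

#' Merge adjacent flagged windows into regions
#'
#' Flagged windows on the same segment with identical sex calls merge when
#' separated by at most \code{max_gap} windows.
#'
#' @param windows flagged window table from [flag_windows()], sorted by
#'   segment and start.
#' @param width nominal window width (used to convert the gap to bp).
#' @param max_gap maximum number of intervening windows to bridge.
#' @return data.frame \code{seg, start, end, n_windows, mean_log2_ratio,
#'   sex_call}.
#' @export
merge_regions <- function(windows, width = 500L, max_gap = 0L) {
  if (nrow(windows) > 1) {
    segs <- windows$seg
    blocks <- rle(segs)$values
    same <- segs[-1] == segs[-length(segs)]
    if (anyDuplicated(blocks) ||
        any(same & diff(windows$start) <= 0))
      stop("windows must be sorted by segment and start")
  }
  fw <- windows[windows$flagged, , drop = FALSE]
  if (nrow(fw) == 0L)
    return(data.frame(seg = character(0), start = integer(0), end = integer(0),
                      n_windows = integer(0), mean_log2_ratio = numeric(0),
                      sex_call = character(0), stringsAsFactors = FALSE))
  gap_bp <- max_gap * width
  new_region <- c(TRUE, fw$seg[-1] != fw$seg[-nrow(fw)] |
                    fw$sex_call[-1] != fw$sex_call[-nrow(fw)] |
                    fw$start[-1] - fw$end[-nrow(fw)] > gap_bp)
  grp <- cumsum(new_region)
  out <- lapply(split(fw, grp), function(d) {
    data.frame(seg = d$seg[1], start = min(d$start), end = max(d$end),
               n_windows = nrow(d), mean_log2_ratio = mean(d$log2_ratio),
               sex_call = d$sex_call[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise differential-coverage regions
#'
#' @param regions region table from [merge_regions()].
#' @return list with \code{n_regions}, \code{total_bp} (sum of region
#'   lengths) and \code{per_call} (named region counts).
#' @export
summarize_regions <- function(regions) {
  list(n_regions = nrow(regions),
       total_bp = if (nrow(regions)) sum(regions$end - regions$start) else 0,
       per_call = if (nrow(regions)) table(regions$sex_call) else table(character(0)))
}

#' Read a BedGraph file into a coverage track
#'
#' @param path BedGraph file (0-based half-open intervals, fourth column
#'   depth).
#' @param seg_lengths named vector of segment lengths (bases not covered by
#'   any interval get depth 0).
#' @return named list of per-base depth vectors.
#' @export
read_bedgraph_track <- function(path, seg_lengths) {
  bg <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seg", "start", "end", "depth"),
                          stringsAsFactors = FALSE)
  out <- lapply(names(seg_lengths), function(sid) {
    depth <- numeric(seg_lengths[[sid]])
    rows <- bg[bg$seg == sid, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      depth[(rows$start[i] + 1L):rows$end[i]] <- rows$depth[i]
    depth
  })
  names(out) <- names(seg_lengths)
  out
}

#' Write a coverage track as BedGraph
#'
#' Runs of equal depth are collapsed into 0-based half-open intervals.
#'
#' @param track named list of per-base depth vectors.
#' @param path output file.
#' @export
write_bedgraph_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in names(track)) {
    r <- rle(track[[sid]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%g", sid, start, end, r$values), con)
  }
  invisible(path)
}
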