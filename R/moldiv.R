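# Pairwise molecular divergence: codon-aware alignment construction, NG86
# counting dN/dS with Jukes-Cantor correction, filtering conventions, and
# percent-identity summaries by sequence class.

#' NG86 synonymous/nonsynonymous site counts for one codon
#'
#' Counts mutational-fate site fractions for a single sense codon: at each of
#' the three positions the fraction of possible point mutations (excluding
#' those creating stop codons) that are synonymous. Each codon contributes
#' exactly three sites, so \code{s + n == 3}.
#'
#' @param codon a 3-letter string over A/C/G/T, not a stop codon.
#' @return named numeric vector \code{c(s = , n = )}.
#' @examples
#' ng86_sites("TTT")  # s = 1/3
#' ng86_sites("ATG")  # s = 0
#' @export
ng86_sites <- function(codon) {
  tab <- .codon_tables()
  codon <- toupper(codon)
  if (!codon %in% tab$codons) stop("not a valid codon: ", codon)
  if (tab$aa[codon] == "*") stop("stop codon has no NG86 sites: ", codon)
  s <- unname(tab$syn_sites[codon])
  c(s = s, n = 3 - s)
}

#' NG86 pathway-averaged difference counts between two codons
#'
#' Classifies the nucleotide differences between two sense codons as
#' synonymous or nonsynonymous by enumerating every ordering of the differing
#' positions, discarding pathways that pass through a stop codon, and
#' averaging step classifications over the remaining legal pathways. If every
#' pathway is blocked by stops, all pathways are used. The counts always sum
#' to the number of differing positions.
#'
#' @param codon_a,codon_b 3-letter sense codons.
#' @return named numeric vector \code{c(sd = , nd = )}.
#' @examples
#' ng86_diffs("TTT", "TTC")  # one synonymous difference
#' @export
ng86_diffs <- function(codon_a, codon_b) {
  tab <- .codon_tables()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!cd %in% tab$sense) stop("not a sense codon: ", cd)
  }
  c(sd = unname(tab$sd_mat[codon_a, codon_b]),
    nd = unname(tab$nd_mat[codon_a, codon_b]))
}

#' Jukes-Cantor distance correction
#'
#' @param p observed proportion of differences per site, in [0, 0.75).
#' @return corrected distance \code{-(3/4) * log(1 - 4p/3)}.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("proportion must be non-negative")
  if (any(p >= 0.75)) stop("proportion >= 0.75: Jukes-Cantor distance saturated")
  -0.75 * log(1 - 4 * p / 3)
}

#' Build a codon alignment by back-translating a protein alignment
#'
#' Expands each aligned amino-acid column to its source codon in the two
#' coding sequences, then removes every column that is gapped in either row
#' and every codon column where either codon is a stop. This mirrors the
#' PAL2NAL convention of stripping all gaps and internal stop codons before
#' dN/dS estimation.
#'
#' @param protein_alignment character vector of two aligned amino-acid
#'   strings of equal length (gap character \code{-}).
#' @param cds_a,cds_b ungapped coding sequences; each must be exactly three
#'   times its ungapped protein length and translate to its protein row under
#'   the standard code.
#' @return object of class \code{codon_alignment}: list with elements
#'   \code{a}, \code{b} (stripped codon-aligned DNA strings of equal length
#'   divisible by 3) and \code{keep} (logical mask over the original protein
#'   alignment columns).
#' @export
backtranslate_align <- function(protein_alignment, cds_a, cds_b) {
  stopifnot(length(protein_alignment) == 2L)
  pa <- toupper(protein_alignment[1]); pb <- toupper(protein_alignment[2])
  if (nchar(pa) != nchar(pb)) stop("aligned protein rows differ in length")
  aa_a <- strsplit(pa, "")[[1]]; aa_b <- strsplit(pb, "")[[1]]
  res_a <- aa_a[aa_a != "-"]; res_b <- aa_b[aa_b != "-"]
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != 3L * length(res_a))
    stop("frame error: cds_a length is not 3x its ungapped protein length")
  if (nchar(cds_b) != 3L * length(res_b))
    stop("frame error: cds_b length is not 3x its ungapped protein length")
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  tab <- .codon_tables()
  check_translation <- function(codons, residues, label) {
    tr <- tab$aa[codons]
    bad <- which(is.na(tr) | (tr != residues & residues != "X"))
    if (length(bad) > 0)
      stop("translation mismatch in ", label, " at residue ", bad[1],
           ": codon ", codons[bad[1]], " vs residue ", residues[bad[1]])
  }
  check_translation(cod_a, res_a, "cds_a")
  check_translation(cod_b, res_b, "cds_b")

  ncol_aln <- length(aa_a)
  # map alignment columns to codon indices
  idx_a <- cumsum(aa_a != "-"); idx_b <- cumsum(aa_b != "-")
  keep <- rep(TRUE, ncol_aln)
  out_a <- character(0); out_b <- character(0)
  for (i in seq_len(ncol_aln)) {
    if (aa_a[i] == "-" || aa_b[i] == "-") { keep[i] <- FALSE; next }
    ca <- cod_a[idx_a[i]]; cb <- cod_b[idx_b[i]]
    if (tab$aa[ca] == "*" || tab$aa[cb] == "*") { keep[i] <- FALSE; next }
    out_a <- c(out_a, ca); out_b <- c(out_b, cb)
  }
  structure(list(a = paste0(out_a, collapse = ""),
                 b = paste0(out_b, collapse = ""),
                 keep = keep),
            class = "codon_alignment")
}

#' Construct a codon alignment from two already codon-aligned sequences
#'
#' Convenience constructor for sequences that are already in frame with no
#' gaps (e.g. simulated ortholog pairs).
#'
#' @param a,b equal-length DNA strings, length divisible by 3, no stops.
#' @return a \code{codon_alignment}.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  cod_a <- split_codons(a); cod_b <- split_codons(b)
  drop <- .is_stop(cod_a) | .is_stop(cod_b)
  structure(list(a = paste0(cod_a[!drop], collapse = ""),
                 b = paste0(cod_b[!drop], collapse = ""),
                 keep = !drop),
            class = "codon_alignment")
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and pathway-averaged differences, converts the proportions to
#' distances with the Jukes-Cantor correction, and reports their ratio
#' \eqn{\omega = dN/dS}. Saturated proportions (>= 0.75) and dS = 0 are
#' recorded as filter flags rather than errors.
#'
#' @param alignment a \code{codon_alignment} (or list with equal-length
#'   in-frame \code{a} and \code{b}).
#' @param gene optional gene id carried through to the output.
#' @param class optional gene class label.
#' @return one-row data.frame with columns \code{gene, class, L, S, N, Sd,
#'   Nd, pS, pN, dS, dN, omega, flags} (flags comma-separated, empty when
#'   clean).
#' @export
dnds <- function(alignment, gene = NA_character_, class = NA_character_) {
  tab <- .codon_tables()
  cod_a <- split_codons(alignment$a)
  cod_b <- split_codons(alignment$b)
  if (length(cod_a) != length(cod_b)) stop("unequal codon counts")
  if (length(cod_a) == 0L) stop("empty alignment: no retained codons")
  if (any(.is_stop(cod_a)) || any(.is_stop(cod_b)))
    stop("internal stop codon present; strip stops first")

  s_a <- sum(tab$syn_sites[cod_a]); s_b <- sum(tab$syn_sites[cod_b])
  L <- length(cod_a)
  S <- (s_a + s_b) / 2
  N <- 3 * L - S
  ia <- match(cod_a, tab$sense); ib <- match(cod_b, tab$sense)
  Sd <- sum(tab$sd_mat[cbind(ia, ib)])
  Nd <- sum(tab$nd_mat[cbind(ia, ib)])

  # S can be exactly 0 (e.g. a lone ATG): no synonymous sites, dS undefined
  pS <- if (S > 0) Sd / S else NaN
  pN <- Nd / N
  flags <- character(0)
  dS <- NA_real_; dN <- NA_real_; omega <- NA_real_
  if (is.nan(pS)) flags <- c(flags, "dS_zero")
  else if (pS >= 0.75) flags <- c(flags, "pS_saturated")
  else dS <- jc_correct(pS)
  if (pN >= 0.75) flags <- c(flags, "pN_saturated") else dN <- jc_correct(pN)
  if (!is.na(dS) && dS == 0) flags <- c(flags, "dS_zero")
  if (!is.na(dS) && !is.na(dN) && dS > 0) {
    omega <- dN / dS
    if (dN > 2) flags <- c(flags, "dN_gt2")
    if (omega > 10) flags <- c(flags, "omega_gt10")
  }
  data.frame(gene = gene, class = class, L = L, S = S, N = N, Sd = Sd,
             Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Filter dN/dS estimates by the standard conventions
#'
#' Removes estimates with dS = 0, dN > 2 or dN/dS > 10 (and saturated
#' proportions, which have no defined distance), and attaches the natural-log
#' transformed ratio to the retained rows for downstream statistics. Ratios
#' of exactly zero are transformed as \code{log(omega + 1e-4)}.
#'
#' @param estimates data.frame of rows as produced by [dnds()].
#' @param eps offset added to zero ratios before the log transform.
#' @return list with \code{retained} (plus a \code{log_omega} column) and
#'   \code{removed} (plus a \code{reason} column).
#' @export
filter_estimates <- function(estimates, eps = 1e-4) {
  if (nrow(estimates) == 0L) {
    return(list(retained = cbind(estimates, log_omega = numeric(0)),
                removed = cbind(estimates, reason = character(0))))
  }
  reason <- character(nrow(estimates))
  sat <- grepl("saturated", estimates$flags)
  reason[sat] <- "saturated"
  ds0 <- !sat & (is.na(estimates$dS) | estimates$dS == 0)
  reason[ds0] <- "dS_zero"
  dn2 <- reason == "" & !is.na(estimates$dN) & estimates$dN > 2
  reason[dn2] <- "dN_gt2"
  om10 <- reason == "" & !is.na(estimates$omega) & estimates$omega > 10
  reason[om10] <- "omega_gt10"
  drop <- reason != ""
  retained <- estimates[!drop, , drop = FALSE]
  retained$log_omega <- ifelse(retained$omega == 0,
                               log(retained$omega + eps), log(retained$omega))
  removed <- estimates[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  list(retained = retained, removed = removed)
}

#' Percent identity of one pairwise alignment
#'
#' Identity is matches over aligned columns, where columns gapped in both
#' rows are ignored and columns gapped in one row count as mismatches.
#'
#' @param a,b aligned rows of equal length (gap character \code{-}).
#' @return named numeric vector \code{c(pid = , bp = )} with the identity in
#'   percent and the number of columns scored.
#' @export
percent_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned rows differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  scored <- !(ca == "-" & cb == "-")
  matches <- sum(ca[scored] == cb[scored] & ca[scored] != "-")
  bp <- sum(scored)
  if (bp == 0L) stop("alignment has no scorable columns")
  c(pid = 100 * matches / bp, bp = bp)
}

#' Summarise percent identity by sequence class
#'
#' @param pairs data.frame with columns \code{class}, \code{pid}, \code{bp}
#'   (one row per aligned pair, e.g. from [percent_identity()]).
#' @param weight_by_length weight the class mean by alignment length instead
#'   of averaging pairs equally.
#' @return data.frame with one row per class: \code{n, total_bp, mean_pid,
#'   se_pid}.
#' @export
identity_summary <- function(pairs, weight_by_length = FALSE) {
  stopifnot(all(c("class", "pid", "bp") %in% names(pairs)))
  out <- lapply(split(pairs, pairs$class), function(d) {
    m <- if (weight_by_length) sum(d$pid * d$bp) / sum(d$bp) else mean(d$pid)
    se <- if (nrow(d) > 1) stats::sd(d$pid) / sqrt(nrow(d)) else NA_real_
    data.frame(class = d$class[1], n = nrow(d), total_bp = sum(d$bp),
               mean_pid = m, se_pid = se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
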