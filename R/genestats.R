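# Group statistics over gene classes: dN/dS class summaries with orthogonal
# contrasts against autosomal genes, the positive-selection list, the
# candidate-gene copy-number scan, qPCR relative quantification with the
# factorial expression model, and completeness-percentage arithmetic.

.coarse_class <- function(class) {
  ifelse(class %in% c("male_specific", "female_specific", "male_allele",
                      "female_allele"), "sex_linked",
         ifelse(class %in% c("mitochondrial", "chloroplast"), "organellar",
                class))
}

#' Class-level summary and contrasts of dN/dS estimates
#'
#' Reports per-class n, untransformed mean ratio with standard error, and the
#' log-scale mean; then fits a linear model on the log-transformed ratios and
#' reports the omnibus test across classes plus targeted contrasts of each
#' class against the autosomal baseline. When a \code{scaffold} column is
#' present, scaffold is included as a random intercept (mixed model via
#' \pkg{lmerTest}); otherwise an ordinary fixed-effects model is used and a
#' message notes the difference.
#'
#' @param estimates filtered estimates from [filter_estimates()] (needs
#'   \code{class}, \code{omega}, \code{log_omega}, optionally
#'   \code{scaffold}).
#' @param grouping \code{"fine"} keeps the seven gene classes;
#'   \code{"coarse"} collapses them to autosomal / sex_linked / organellar.
#' @param baseline reference class for contrasts.
#' @return list with \code{summary} (per-class data.frame \code{class, n,
#'   mean_omega, se_omega, mean_log_omega}), \code{omnibus} (F statistic,
#'   df, p), \code{contrasts} (per non-baseline class: estimate on the log
#'   scale, t, p, Holm-adjusted p) and \code{model} (\code{"mixed"} or
#'   \code{"fixed"}).
#' @export
class_summary <- function(estimates, grouping = c("coarse", "fine"),
                          baseline = "autosomal") {
  grouping <- match.arg(grouping)
  est <- estimates[!is.na(estimates$omega), , drop = FALSE]
  est$grp <- if (grouping == "coarse") .coarse_class(est$class) else est$class
  est <- est[!is.na(est$grp), , drop = FALSE]
  if (length(unique(est$grp)) < 2) stop("need at least two gene classes")
  summ <- do.call(rbind, lapply(split(est, est$grp), function(d) {
    data.frame(class = d$grp[1], n = nrow(d), mean_omega = mean(d$omega),
               se_omega = if (nrow(d) > 1)
                 stats::sd(d$omega) / sqrt(nrow(d)) else NA_real_,
               mean_log_omega = mean(d$log_omega), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  lv <- unique(c(baseline, sort(unique(est$grp))))
  lv <- lv[lv %in% est$grp]
  est$grp <- factor(est$grp, levels = lv)
  use_mixed <- "scaffold" %in% names(est) && !anyNA(est$scaffold) &&
    length(unique(est$scaffold)) > 1
  if (use_mixed) {
    fit <- lmerTest::lmer(log_omega ~ grp + (1 | scaffold), data = est)
    an <- stats::anova(fit)
    omnibus <- list(F = an$`F value`[1], df1 = an$NumDF[1], df2 = an$DenDF[1],
                    p = an$`Pr(>F)`[1])
    co <- summary(fit)$coefficients
    tcol <- "t value"; pcol <- "Pr(>|t|)"
  } else {
    message("no scaffold column: fitting fixed-effects model")
    fit <- stats::lm(log_omega ~ grp, data = est)
    an <- stats::anova(fit)
    omnibus <- list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                    p = an$`Pr(>F)`[1])
    co <- summary(fit)$coefficients
    tcol <- "t value"; pcol <- "Pr(>|t|)"
  }
  rows <- grep("^grp", rownames(co))
  contrasts <- data.frame(class = sub("^grp", "", rownames(co)[rows]),
                          estimate = co[rows, "Estimate"],
                          t = co[rows, tcol], p = co[rows, pcol],
                          stringsAsFactors = FALSE)
  contrasts$p_holm <- stats::p.adjust(contrasts$p, method = "holm")
  rownames(contrasts) <- NULL
  list(summary = summ, omnibus = omnibus, contrasts = contrasts,
       model = if (use_mixed) "mixed" else "fixed")
}

#' Genes with dN/dS above one
#'
#' @param estimates filtered estimates.
#' @return list with \code{genes} (rows with \code{omega > 1}, sorted by
#'   omega descending) and \code{per_class} counts.
#' @export
positive_selection_list <- function(estimates) {
  sel <- estimates[!is.na(estimates$omega) & estimates$omega > 1, ,
                   drop = FALSE]
  sel <- sel[order(-sel$omega), , drop = FALSE]
  rownames(sel) <- NULL
  list(genes = sel, per_class = table(sel$class))
}

#' Candidate-gene copy-number scan
#'
#' Flags genes whose male:female log2 coverage ratio exceeds the cutoff in
#' magnitude. Positive ratios mean higher male coverage, negative ratios
#' higher female coverage.
#'
#' @param gene_ratios data.frame with \code{gene} and \code{log2_ratio}
#'   columns; optionally \code{sex_linkage} (U / V / autosomal).
#' @param threshold absolute log2 fold-change cutoff.
#' @return the table with \code{flagged} and \code{direction} columns added.
#' @export
dht_scan <- function(gene_ratios, threshold = 4) {
  if (anyDuplicated(gene_ratios$gene))
    stop("duplicate gene id: ",
         gene_ratios$gene[duplicated(gene_ratios$gene)][1])
  out <- gene_ratios
  out$flagged <- abs(out$log2_ratio) > threshold
  out$direction <- ifelse(out$log2_ratio > 0, "male_higher", "female_higher")
  if (!"sex_linkage" %in% names(out)) out$sex_linkage <- "autosomal"
  out
}

#' qPCR relative expression ratio
#'
#' Ratio of target to internal-control template,
#' \code{efficiency^(cq_control - cq_target)}. A missing target Cq (no
#' amplification) yields an \code{NA} ratio.
#'
#' @param cq_target,cq_control quantitation cycles (vectors recycle).
#' @param efficiency per-cycle amplification factor, in (1, 2].
#' @return numeric ratios.
#' @export
qpcr_relative <- function(cq_target, cq_control, efficiency = 2.0) {
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  efficiency^(cq_control - cq_target)
}

#' Derive relative-expression records from a Cq table
#'
#' Joins each target-gene measurement with the internal-control measurement
#' of the same sample and hydration state and computes the relative ratio.
#' Targets without amplification get an \code{NA} ratio and a
#' \code{no_amplification} note.
#'
#' @param cq_table data.frame \code{sample, sex, gene, state, cq}.
#' @param control_gene internal control gene id.
#' @param efficiency amplification efficiency.
#' @return the target rows with \code{relative_ratio} and \code{note} added.
#' @export
qpcr_ratios <- function(cq_table, control_gene = "actin", efficiency = 2.0) {
  ctrl <- cq_table[cq_table$gene == control_gene, , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("control gene '", control_gene, "' not in table")
  tgt <- cq_table[cq_table$gene != control_gene, , drop = FALSE]
  key <- function(d) paste(d$sample, d$state)
  cq_ctrl <- ctrl$cq[match(key(tgt), key(ctrl))]
  tgt$relative_ratio <- ifelse(is.na(tgt$cq) | is.na(cq_ctrl), NA_real_,
                               qpcr_relative(tgt$cq, cq_ctrl, efficiency))
  tgt$note <- ifelse(is.na(tgt$cq), "no_amplification", "")
  tgt
}

#' Factorial model of qPCR relative expression
#'
#' Fits a linear model of the relative ratio on gene, hydration state, sex
#' and their interactions (terms whose factor has a single observed level are
#' dropped with a warning), and tests the dehydrated-vs-hydrated contrast for
#' each gene. Records with missing ratios are excluded listwise.
#'
#' @param records output of [qpcr_ratios()] (needs \code{gene, state, sex,
#'   relative_ratio}).
#' @return list with \code{anova} (data.frame of effect F tests),
#'   \code{gene_contrasts} (per-gene dehydrated - hydrated estimate, t, p)
#'   and the fitted \code{model}.
#' @export
qpcr_model <- function(records) {
  d <- records[!is.na(records$relative_ratio), , drop = FALSE]
  if (length(unique(d$gene)) < 2 || length(unique(d$state)) < 2)
    stop("need at least two genes and both hydration states")
  terms <- c("gene", "state", "sex")
  keep <- terms[vapply(terms, function(t) length(unique(d[[t]])) > 1,
                       logical(1))]
  if (length(keep) < length(terms))
    warning("dropping single-level factor(s): ",
            paste(setdiff(terms, keep), collapse = ", "))
  for (t in keep) d[[t]] <- factor(d[[t]])
  form <- stats::as.formula(paste("relative_ratio ~",
                                  paste(keep, collapse = " * ")))
  fit <- stats::lm(form, data = d)
  an <- stats::anova(fit)
  an_df <- data.frame(term = rownames(an), df = an$Df, F = an$`F value`,
                      p = an$`Pr(>F)`, stringsAsFactors = FALSE)
  emm <- emmeans::emmeans(fit, ~ state | gene)
  ct <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  gene_contrasts <- data.frame(gene = ct$gene, estimate = ct$estimate,
                               t = ct$t.ratio, p = ct$p.value,
                               stringsAsFactors = FALSE)
  list(anova = an_df, gene_contrasts = gene_contrasts, model = fit)
}

.round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Ortholog-set completeness percentages
#'
#' Complete, fragmented and missing shares of a benchmark ortholog set,
#' rounded half-away-from-zero to one decimal.
#'
#' @param n_complete,n_fragmented,n_total ortholog counts.
#' @return named numeric vector \code{complete_pct, fragmented_pct,
#'   missing_pct}.
#' @export
completeness_summary <- function(n_complete, n_fragmented, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_complete + n_fragmented > n_total)
    stop("complete + fragmented exceeds total")
  c(complete_pct = .round_half_up(100 * n_complete / n_total),
    fragmented_pct = .round_half_up(100 * n_fragmented / n_total),
    missing_pct = .round_half_up(
      100 * (n_total - n_complete - n_fragmented) / n_total))
}
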