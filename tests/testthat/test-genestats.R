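make_estimates <- function(omega, class, scaffold = NULL) {
  d <- data.frame(gene = sprintf("g%04d", seq_along(omega)), class = class,
                  omega = omega,
                  log_omega = ifelse(omega == 0, log(1e-4), log(omega)),
                  stringsAsFactors = FALSE)
  if (!is.null(scaffold)) d$scaffold <- scaffold
  d
}

test_that("class summaries report means, SE and contrasts vs autosomal", {
  set.seed(2)
  est <- make_estimates(c(rlnorm(50, log(0.2), 0.3), rlnorm(20, log(0.8), 0.3)),
                        rep(c("autosomal", "male_specific"), c(50, 20)))
  res <- suppressMessages(class_summary(est, grouping = "fine"))
  expect_equal(res$model, "fixed")
  expect_setequal(res$summary$class, c("autosomal", "male_specific"))
  expect_equal(res$summary$n, c(50, 20))
  expect_gt(res$contrasts$estimate[1], 0)  # male_specific above autosomal
  expect_lt(res$contrasts$p[1], 0.01)
  # identically distributed classes: contrast near zero, p near one
  same <- make_estimates(rep(c(0.1, 0.2, 0.3), 2),
                         rep(c("autosomal", "mitochondrial"), each = 3))
  res2 <- suppressMessages(class_summary(same, grouping = "fine"))
  expect_equal(res2$contrasts$estimate[1], 0, tolerance = 1e-12)
  expect_gt(res2$contrasts$p[1], 0.99)
  # single observation in a class: SE reported as absent
  one <- make_estimates(c(0.1, 0.2, 0.5), c("autosomal", "autosomal",
                                            "chloroplast"))
  res3 <- suppressMessages(class_summary(one, grouping = "fine"))
  expect_true(is.na(res3$summary$se_omega[res3$summary$class == "chloroplast"]))
})

test_that("coarse grouping collapses classes and the mixed model engages", {
  set.seed(3)
  cls <- rep(c("autosomal", "male_specific", "female_allele", "mitochondrial",
               "chloroplast"), c(60, 10, 10, 10, 10))
  est <- make_estimates(rlnorm(100, log(0.3), 0.4), cls,
                        scaffold = sample(sprintf("sc%02d", 1:12), 100, TRUE))
  res <- class_summary(est, grouping = "coarse")
  expect_equal(res$model, "mixed")
  expect_setequal(res$summary$class, c("autosomal", "sex_linked", "organellar"))
  expect_setequal(res$contrasts$class, c("sex_linked", "organellar"))
  expect_true(all(is.finite(res$omnibus$F)))
})

test_that("class contrasts detect a simulated sex-linked elevation reliably", {
  hits <- 0L
  for (s in 1:25) {
    set.seed(s)
    est <- make_estimates(
      c(rlnorm(200, log(0.2), 0.5), rlnorm(30, log(0.8), 0.5)),
      rep(c("autosomal", "male_specific"), c(200, 30)))
    res <- suppressMessages(class_summary(est, grouping = "fine"))
    if (res$contrasts$p[1] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.95)
})

test_that("the positive-selection list uses a strict omega > 1 boundary", {
  est <- make_estimates(c(0.5, 1.0, 1.2), rep("autosomal", 3))
  res <- positive_selection_list(est)
  expect_equal(nrow(res$genes), 1L)
  expect_equal(res$genes$omega, 1.2)
  expect_equal(nrow(positive_selection_list(
    make_estimates(c(0.2, 0.9), rep("autosomal", 2)))$genes), 0L)
})

test_that("high-truth-omega simulated pairs land on the selection list", {
  pairs <- simulate_ortholog_pairs(20, omega = 2, kappa = 1, t = 0.3,
                                   L = 2000, seed = 12)
  est <- do.call(rbind, lapply(seq_along(pairs), function(i)
    dnds(codon_alignment(pairs[[i]]$a, pairs[[i]]$b),
         gene = sprintf("g%02d", i), class = "male_specific")))
  ret <- filter_estimates(est)$retained
  res <- positive_selection_list(ret)
  expect_gte(nrow(res$genes) / length(pairs), 0.90)
})

test_that("copy-number scan flags by magnitude with signed direction", {
  ratios <- data.frame(gene = c("HSF1", "SOD", "GRP94", "near"),
                       log2_ratio = c(14.3397, -4.095, -16.4576, 3.9))
  res <- dht_scan(ratios, threshold = 4)
  expect_equal(res$flagged, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$direction[1], "male_higher")
  expect_equal(res$direction[2:3], c("female_higher", "female_higher"))
  expect_error(dht_scan(rbind(ratios, ratios[1, ])), "duplicate")
  # flag set is monotone non-increasing in the threshold
  n_flag <- vapply(c(2, 4, 8, 15), function(th)
    sum(dht_scan(ratios, th)$flagged), integer(1))
  expect_true(all(diff(n_flag) <= 0))
})

test_that("relative expression follows the efficiency power law", {
  expect_equal(qpcr_relative(20, 20), 1)
  expect_equal(qpcr_relative(18, 20), 4)
  expect_equal(qpcr_relative(22, 20), 0.25)
  expect_error(qpcr_relative(20, 20, efficiency = 1), "efficiency")
  expect_error(qpcr_relative(20, 20, efficiency = 2.5), "efficiency")
  # log-ratio additivity: ratio(a,c) = ratio(a,b) * ratio(b,c)
  set.seed(4)
  a <- runif(20, 15, 30); b <- runif(20, 15, 30); cc <- runif(20, 15, 30)
  expect_equal(qpcr_relative(a, cc),
               qpcr_relative(a, b) * qpcr_relative(b, cc),
               tolerance = 1e-12)
})

test_that("Cq tables convert to relative ratios with amplification notes", {
  genes <- data.frame(gene = c("actin", "hsp", "cdpk"),
                      class = c("autosomal", "autosomal", "female_specific"),
                      baseline_cq = c(20, 22, 23))
  tab <- simulate_cq_table(genes, effects = c(hsp = -2), seed = 1,
                           noise_sd = 0)
  rr <- qpcr_ratios(tab, control_gene = "actin")
  hyd <- rr$relative_ratio[rr$gene == "hsp" & rr$state == "hydrated"]
  deh <- rr$relative_ratio[rr$gene == "hsp" & rr$state == "dehydrated"]
  # a -2 cycle shift quadruples the relative ratio
  expect_equal(unique(deh / hyd), 4)
  male_cdpk <- rr[rr$gene == "cdpk" & rr$sex == "male", ]
  expect_true(all(is.na(male_cdpk$relative_ratio)))
  expect_true(all(male_cdpk$note == "no_amplification"))
})

test_that("the factorial qPCR model isolates the induced gene", {
  genes <- data.frame(gene = c("actin", "hsp70", "grp94", "aldh"),
                      class = "autosomal", baseline_cq = c(20, 24, 23, 25))
  hits <- 0L; false_hits <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    tab <- simulate_cq_table(genes, effects = c(hsp70 = -2), seed = s,
                             noise_sd = 0.1)
    rr <- qpcr_ratios(tab)
    res <- qpcr_model(rr)
    p <- stats::setNames(res$gene_contrasts$p, res$gene_contrasts$gene)
    if (p[["hsp70"]] < 0.05) hits <- hits + 1L
    if (any(p[c("grp94", "aldh")] < 0.05)) false_hits <- false_hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
  expect_lte(false_hits / n_seeds, 0.25)
})

test_that("degenerate qPCR designs are handled explicitly", {
  genes <- data.frame(gene = c("actin", "g1", "g2", "cdpk"),
                      class = c("autosomal", "autosomal", "autosomal",
                                "female_specific"),
                      baseline_cq = c(20, 22, 22, 23))
  # identical ratios: per-gene contrasts are all zero
  tab <- simulate_cq_table(genes[1:3, ], seed = 1, noise_sd = 0)
  res <- suppressWarnings(qpcr_model(qpcr_ratios(tab)))
  expect_true(all(abs(res$gene_contrasts$estimate) < 1e-12))
  # a sex-specific gene missing in one sex still fits listwise
  tab2 <- simulate_cq_table(genes, effects = c(g1 = -1), seed = 2,
                            noise_sd = 0.1)
  expect_no_error(res2 <- qpcr_model(qpcr_ratios(tab2)))
  expect_true("cdpk" %in% res2$gene_contrasts$gene)
})

test_that("completeness percentages match half-up rounding and sum to 100", {
  expect_equal(completeness_summary(783, 51, 1440),
               c(complete_pct = 54.4, fragmented_pct = 3.5,
                 missing_pct = 42.1))
  expect_equal(unname(completeness_summary(867, 42, 1440)["complete_pct"]),
               60.2)
  expect_equal(unname(completeness_summary(0, 0, 10)),
               c(0, 0, 100))
  expect_error(completeness_summary(1, 0, 0), "positive")
  expect_error(completeness_summary(9, 2, 10), "exceeds")
  set.seed(6)
  for (i in 1:50) {
    tot <- sample(50:5000, 1)
    comp <- sample(0:tot, 1)
    frag <- sample(0:(tot - comp), 1)
    expect_lte(abs(sum(completeness_summary(comp, frag, tot)) - 100),
               0.1 + 1e-9)
  }
})
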