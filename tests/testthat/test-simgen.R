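test_that("reference simulation hits target GC and partitions the genome", {
  ref <- simulate_reference(sim_config(n_autosomes = 1, autosome_len = 50000,
                                       seed = 1))
  gc_auto <- gc_content(ref$seqs["chr1"])
  expect_gte(gc_auto, 0.43)
  expect_lte(gc_auto, 0.47)
  gc_contam <- gc_content(ref$seqs["contam1"])
  expect_gte(gc_contam, 0.63)
  expect_lte(gc_contam, 0.67)
  # truth labels cover every base of every segment exactly once
  expect_equal(ref$truth$seqid, ref$segments$id)
  expect_equal(ref$truth$end - ref$truth$start, ref$segments$length)
  # gene intervals lie within their segment, sex genes on their chromosome
  seg_len <- stats::setNames(ref$segments$length, ref$segments$id)
  expect_true(all(ref$genes$start >= 1))
  expect_true(all(ref$genes$end <= seg_len[ref$genes$seqid]))
  expect_true(all(ref$genes$seqid[ref$genes$gene_class %in%
                                    c("male_specific", "male_allele")] == "chrV"))
  expect_true(all(ref$genes$seqid[ref$genes$gene_class %in%
                                    c("female_specific", "female_allele")] == "chrU"))
})

test_that("empty-host configuration yields exactly one contaminant segment", {
  cfg <- sim_config(n_autosomes = 0, u_len = 0, v_len = 0,
                    organelle_lens = numeric(0), n_contaminants = 1,
                    n_genes_per_class = c(autosomal = 0), seed = 3)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$segments), 1L)
  expect_equal(ref$segments$class, "contaminant")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(seed = 9)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(ref1$seqs, ref2$seqs)
  expect_identical(ref1$genes, ref2$genes)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference(ref1, d1); write_reference(ref2, d2)
  for (f in c("reference.fa", "genes.gff3", "truth.bed"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  r1 <- simulate_reads(ref1, "male", 5, seed = 4)
  r2 <- simulate_reads(ref2, "male", 5, seed = 4)
  expect_identical(r1$seq1, r2$seq1)
})

test_that("read simulation respects sex exclusivity and target depth", {
  ref <- tiny_reference(seed = 21)
  male <- simulate_reads(ref, "male", 20, seed = 1)
  female <- simulate_reads(ref, "female", 20, seed = 2)
  expect_false("chrU" %in% male$segment)
  expect_false("chrV" %in% female$segment)
  # exact-substring placement of female reads on V finds nothing
  v_seq <- ref$seqs[["chrV"]]
  probe <- head(female$seq1, 300)
  expect_false(any(vapply(probe, grepl, logical(1), x = v_seq, fixed = TRUE)))
  # mean mapped depth near target on the autosome
  track <- coverage_track(male, ref)
  expect_gte(mean(track$chr1), 17)
  expect_lte(mean(track$chr1), 23)
  # organelles at elevated depth
  expect_gte(mean(track$mito), 100)
  # errors and the empty case
  expect_error(simulate_reads(ref, "hermaphrodite", 10), "sex")
  expect_equal(nrow(simulate_reads(ref, "male", 0)), 0L)
})

test_that("read-set GC is bimodal at host and contaminant targets", {
  ref <- tiny_reference(seed = 13)
  reads <- simulate_reads(ref, "female", 15, seed = 3)
  gc <- gc_content(c(reads$seq1, reads$seq2))
  d <- stats::density(gc, bw = 0.01, from = 0, to = 1, n = 1024)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  peaks <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
  modes <- sort(d$x[peaks])
  expect_lt(abs(modes[1] - 0.45), 0.02)
  expect_lt(abs(modes[2] - 0.65), 0.02)
})

test_that("ortholog pairs obey t = 0 and omega = 0 limits", {
  p0 <- simulate_ortholog_pairs(5, omega = 0.5, kappa = 2, t = 0, L = 50,
                                seed = 2)
  for (p in p0) expect_identical(p$a, p$b)
  # omega = 0: every accumulated difference is synonymous
  ps <- simulate_ortholog_pairs(10, omega = 0, kappa = 1, t = 1, L = 200,
                                seed = 8)
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  n_diff <- 0
  for (p in ps) {
    expect_identical(tr(p$a), tr(p$b))
    n_diff <- n_diff + sum(strsplit(p$a, "")[[1]] != strsplit(p$b, "")[[1]])
  }
  expect_gt(n_diff, 0)  # the limit is non-trivial: changes did occur
  expect_error(simulate_ortholog_pairs(1, omega = -1, kappa = 1, t = 1, L = 10),
               "omega")
  expect_error(simulate_ortholog_pairs(1, omega = 1, kappa = 0.5, t = 1, L = 10),
               "kappa")
})

test_that("simulated pairs never contain stop codons", {
  ps <- simulate_ortholog_pairs(5, omega = 2, kappa = 3, t = 2, L = 100,
                                seed = 4)
  has_stop <- function(s) {
    n <- nchar(s)
    any(substring(s, seq(1, n, 3), seq(3, n, 3)) %in% c("TAA", "TAG", "TGA"))
  }
  for (p in ps) {
    expect_false(has_stop(p$a))
    expect_false(has_stop(p$b))
  }
})

test_that("Cq tables encode design, sex specificity and induction", {
  genes <- data.frame(gene = c("actin", "hsp", "cdpk"),
                      class = c("autosomal", "autosomal", "female_specific"),
                      baseline_cq = c(20, 24, 23))
  tab <- simulate_cq_table(genes, effects = c(hsp = -2), seed = 1,
                           noise_sd = 0)
  expect_equal(nrow(tab), 6 * 2 * 3)
  # zero noise: baselines exact
  expect_true(all(tab$cq[tab$gene == "actin"] == 20))
  expect_true(all(tab$cq[tab$gene == "hsp" & tab$state == "hydrated"] == 24))
  expect_true(all(tab$cq[tab$gene == "hsp" & tab$state == "dehydrated"] == 22))
  # female-specific gene absent in males
  expect_true(all(is.na(tab$cq[tab$gene == "cdpk" & tab$sex == "male"])))
  expect_true(all(!is.na(tab$cq[tab$gene == "cdpk" & tab$sex == "female"])))
  expect_error(simulate_cq_table(genes[-1, ], seed = 1), "control")
})

test_that("FASTQ pair round-trips through disk", {
  ref <- tiny_reference(seed = 2)
  reads <- simulate_reads(ref, "male", 2, seed = 6)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_fastq_pair(reads, prefix)
  back <- read_fastq_pair(paths[1], paths[2])
  expect_equal(back$seq1, reads$seq1)
  expect_equal(back$seq2, reads$seq2)
})

test_that("reference files round-trip through GFF3 and BED readers", {
  ref <- tiny_reference(seed = 2)
  dir <- withr::local_tempdir()
  write_reference(ref, dir)
  genes <- read_genes_gff3(file.path(dir, "genes.gff3"))
  expect_equal(genes$gene_id, ref$genes$gene_id)
  expect_equal(genes$start, ref$genes$start)
  expect_equal(genes$gene_class, ref$genes$gene_class)
  truth <- read_truth_bed(file.path(dir, "truth.bed"))
  expect_equal(truth$class, ref$truth$class)
  expect_equal(truth$end, ref$truth$end)
})
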