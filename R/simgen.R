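# Synthetic-data generation: labelled reference genomes (autosomes, U, V,
# organelles, GC-distinct contaminants), sex-specific paired read sets,
# ortholog codon pairs evolved at controlled omega, and qPCR Cq tables.
# Every emitted object carries a truth table so downstream recovery can be
# scored exactly.

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study design. Defaults emulate a
#' male/female whole-genome resequencing experiment on a dioecious haploid
#' plant: a ~45% GC host genome mixed with ~65% GC microbial contaminants,
#' 100 bp paired-end reads with ~300 bp inserts, U segments covered only in
#' the female sample and V segments only in the male, and organelles at
#' elevated depth.
#'
#' @param n_autosomes number of autosomal segments.
#' @param autosome_len length of each autosome (bp).
#' @param u_len,v_len lengths of the U and V sex segments (bp; 0 omits them).
#' @param organelle_lens named numeric vector of organelle lengths, names in
#'   \code{c("mito", "chloro")}.
#' @param n_contaminants,contaminant_len contaminant segment count and length.
#' @param host_gc,contam_gc target GC fractions of host and contaminant
#'   segments.
#' @param contam_read_fraction fraction of simulated read pairs drawn from
#'   contaminant segments.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment insert size distribution (bp).
#' @param depth fold-coverage per sample on nuclear host segments.
#' @param organelle_depth_multiplier depth multiplier for organelles.
#' @param n_genes_per_class named integer vector of gene counts for classes
#'   \code{autosomal, male_specific, female_specific, male_allele,
#'   female_allele, mitochondrial, chloroplast}.
#' @param gene_len gene length in bp (multiple of 3).
#' @param omega_truth,kappa,branch_divergence codon-evolution parameters for
#'   ortholog pair simulation.
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_autosomes = 3, autosome_len = 100000,
                       u_len = 50000, v_len = 50000,
                       organelle_lens = c(mito = 20000, chloro = 15000),
                       n_contaminants = 2, contaminant_len = 50000,
                       host_gc = 0.45, contam_gc = 0.65,
                       contam_read_fraction = 0.3,
                       read_len = 100, insert_mean = 300, insert_sd = 30,
                       depth = 20, organelle_depth_multiplier = 10,
                       n_genes_per_class = c(autosomal = 30, male_specific = 6,
                                             female_specific = 6,
                                             male_allele = 4, female_allele = 4,
                                             mitochondrial = 4, chloroplast = 4),
                       gene_len = 900,
                       omega_truth = 0.5, kappa = 2, branch_divergence = 0.3,
                       seed = 1L) {
  cfg <- list(n_autosomes = n_autosomes, autosome_len = autosome_len,
              u_len = u_len, v_len = v_len, organelle_lens = organelle_lens,
              n_contaminants = n_contaminants, contaminant_len = contaminant_len,
              host_gc = host_gc, contam_gc = contam_gc,
              contam_read_fraction = contam_read_fraction,
              read_len = read_len, insert_mean = insert_mean,
              insert_sd = insert_sd, depth = depth,
              organelle_depth_multiplier = organelle_depth_multiplier,
              n_genes_per_class = n_genes_per_class, gene_len = gene_len,
              omega_truth = omega_truth, kappa = kappa,
              branch_divergence = branch_divergence, seed = as.integer(seed))
  for (f in c("host_gc", "contam_gc", "contam_read_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  lens <- c(cfg$autosome_len[cfg$n_autosomes > 0], cfg$u_len, cfg$v_len,
            cfg$organelle_lens, rep(cfg$contaminant_len, cfg$n_contaminants > 0))
  if (any(lens < 0)) stop("segment lengths must be non-negative")
  if (cfg$read_len <= 0) stop("read_len must be positive")
  if (cfg$gene_len %% 3 != 0) stop("gene_len must be a multiple of 3")
  class(cfg) <- "sim_config"
  cfg
}

.random_dna <- function(len, gc) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

.host_classes <- c("autosome", "U", "V", "mito", "chloro")

#' Simulate a labelled reference genome
#'
#' Draws i.i.d. base composition at the configured GC per segment class and
#' places non-overlapping genes of the appropriate class on each segment
#' (sex-specific genes only on their sex segment, organellar genes on their
#' organelle). The returned truth table labels every base of the genome.
#'
#' @param config a [sim_config()].
#' @return a \code{reference_set}: list with \code{segments} (data.frame
#'   \code{id, class, length}), \code{seqs} (named character vector),
#'   \code{genes} (GFF3-style 1-based inclusive data.frame with a
#'   \code{gene_class} column) and \code{truth} (BED-style 0-based half-open
#'   data.frame \code{seqid, start, end, class}).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seg <- data.frame(id = character(0), class = character(0),
                    length = numeric(0), stringsAsFactors = FALSE)
  add <- function(seg, id, class, len) {
    if (len == 0) return(seg)
    if (len < 0) stop("zero-length segment request")
    rbind(seg, data.frame(id = id, class = class, length = len,
                          stringsAsFactors = FALSE))
  }
  if (config$n_autosomes > 0)
    for (i in seq_len(config$n_autosomes))
      seg <- add(seg, sprintf("chr%d", i), "autosome", config$autosome_len)
  seg <- add(seg, "chrU", "U", config$u_len)
  seg <- add(seg, "chrV", "V", config$v_len)
  for (nm in names(config$organelle_lens))
    seg <- add(seg, nm, nm, config$organelle_lens[[nm]])
  if (config$n_contaminants > 0)
    for (i in seq_len(config$n_contaminants))
      seg <- add(seg, sprintf("contam%d", i), "contaminant",
                 config$contaminant_len)
  if (nrow(seg) == 0L) stop("configuration yields an empty genome")

  seqs <- vapply(seq_len(nrow(seg)), function(i) {
    gc <- if (seg$class[i] == "contaminant") config$contam_gc else config$host_gc
    .random_dna(seg$length[i], gc)
  }, character(1))
  names(seqs) <- seg$id

  # gene placement: evenly spaced starts, one class mixture per segment class
  class_map <- list(autosome = "autosomal",
                    U = c("female_specific", "female_allele"),
                    V = c("male_specific", "male_allele"),
                    mito = "mitochondrial", chloro = "chloroplast")
  genes <- list()
  counters <- stats::setNames(rep(0L, length(config$n_genes_per_class)),
                              names(config$n_genes_per_class))
  for (i in seq_len(nrow(seg))) {
    gclasses <- class_map[[seg$class[i]]]
    if (is.null(gclasses)) next
    want <- list()
    for (gc in gclasses) {
      total <- config$n_genes_per_class[[gc]]
      n_seg_of_class <- sum(seg$class == seg$class[i])
      # split the class total evenly over segments of this class
      per_seg <- total %/% n_seg_of_class +
        as.integer(which(seg$id[seg$class == seg$class[i]] == seg$id[i]) <=
                     total %% n_seg_of_class)
      want[[gc]] <- per_seg
    }
    n_here <- sum(unlist(want))
    if (n_here == 0) next
    slot <- seg$length[i] %/% n_here
    if (slot < config$gene_len + 2)
      stop("segment ", seg$id[i], " too short for requested genes")
    cls_vec <- rep(names(want), unlist(want))
    for (j in seq_len(n_here)) {
      start <- (j - 1L) * slot + 1L + (slot - config$gene_len) %/% 2L
      counters[cls_vec[j]] <- counters[cls_vec[j]] + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        seqid = seg$id[i], source = "uvlinker_sim", type = "gene",
        start = start, end = start + config$gene_len - 1L,
        score = ".", strand = "+", phase = ".",
        gene_id = sprintf("%s_g%03d", cls_vec[j], counters[cls_vec[j]]),
        gene_class = cls_vec[j], stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(seqid = character(0), source = character(0), type = character(0),
               start = integer(0), end = integer(0), score = character(0),
               strand = character(0), phase = character(0),
               gene_id = character(0), gene_class = character(0))

  truth <- data.frame(seqid = seg$id, start = 0L, end = seg$length,
                      class = seg$class, stringsAsFactors = FALSE)
  structure(list(segments = seg, seqs = seqs, genes = genes, truth = truth,
                 config = config),
            class = "reference_set")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a sex-specific paired-end read set
#'
#' Samples error-free read pairs from the segments visible to one sex: both
#' sexes see autosomes, organelles and contaminants; only males carry V and
#' only females carry U. Fragment counts per segment are Poisson around the
#' target depth (organelles multiplied), fragment starts are uniform, and
#' inserts are Gaussian around the configured mean.
#'
#' @param ref a \code{reference_set}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param depth target per-base fold-coverage of nuclear host segments.
#' @param seed integer seed.
#' @return a \code{read_pairs} data.frame with columns \code{id, segment,
#'   start, end, seq1, seq2} (1-based inclusive fragment coordinates) and
#'   attribute \code{read_len}.
#' @export
simulate_reads <- function(ref, sex, depth, seed = 1L) {
  stopifnot(inherits(ref, "reference_set"))
  if (!sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  if (nrow(ref$segments) == 0L) stop("empty reference")
  cfg <- ref$config
  set.seed(as.integer(seed))
  rl <- cfg$read_len
  visible <- c("autosome", "mito", "chloro",
               if (sex == "male") "V" else "U")
  empty <- data.frame(id = character(0), segment = character(0),
                      start = integer(0), end = integer(0),
                      seq1 = character(0), seq2 = character(0),
                      stringsAsFactors = FALSE)
  if (depth <= 0) {
    attr(empty, "read_len") <- rl
    class(empty) <- c("read_pairs", "data.frame")
    return(empty)
  }
  frags <- list()
  n_host_frags <- 0L
  for (i in seq_len(nrow(ref$segments))) {
    cls <- ref$segments$class[i]
    if (!cls %in% visible) next
    d <- depth * if (cls %in% c("mito", "chloro"))
      cfg$organelle_depth_multiplier else 1
    lambda <- d * ref$segments$length[i] / (2 * rl)
    n <- stats::rpois(1, lambda)
    n_host_frags <- n_host_frags + n
    if (n > 0) frags[[ref$segments$id[i]]] <- n
  }
  # contaminant pairs so that their realized share is ~contam_read_fraction
  f <- cfg$contam_read_fraction
  contam <- ref$segments[ref$segments$class == "contaminant", , drop = FALSE]
  if (f > 0 && nrow(contam) > 0 && n_host_frags > 0) {
    n_contam <- round(f / (1 - f) * n_host_frags)
    share <- contam$length / sum(contam$length)
    for (i in seq_len(nrow(contam))) {
      n <- stats::rpois(1, n_contam * share[i])
      if (n > 0) frags[[contam$id[i]]] <- n
    }
  }
  out <- lapply(names(frags), function(sid) {
    n <- frags[[sid]]
    seq <- ref$seqs[[sid]]
    len <- nchar(seq)
    ins <- pmax(2L * rl, pmin(len, round(stats::rnorm(n, cfg$insert_mean,
                                                      cfg$insert_sd))))
    start <- vapply(ins, function(w) sample.int(len - w + 1L, 1L), integer(1))
    end <- start + ins - 1L
    data.frame(id = sprintf("%s_%s_%06d", sex, sid, seq_len(n)),
               segment = sid, start = start, end = end,
               seq1 = substring(seq, start, start + rl - 1L),
               seq2 = .revcomp(substring(seq, end - rl + 1L, end)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else empty
  rownames(out) <- NULL
  attr(out, "read_len") <- rl
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Per-base coverage tracks from simulated read placements
#'
#' Converts the known placements of simulated read pairs into per-base depth
#' vectors (both mates of each pair contribute their aligned bases).
#'
#' @param pairs a \code{read_pairs} data.frame.
#' @param ref the \code{reference_set} the reads were drawn from.
#' @param segments optional subset of segment ids; default all non-contaminant
#'   segments.
#' @return named list of numeric per-base depth vectors (a coverage track).
#' @export
coverage_track <- function(pairs, ref, segments = NULL) {
  rl <- attr(pairs, "read_len")
  if (is.null(segments))
    segments <- ref$segments$id[ref$segments$class != "contaminant"]
  out <- lapply(segments, function(sid) {
    len <- ref$segments$length[ref$segments$id == sid]
    p <- pairs[pairs$segment == sid, , drop = FALSE]
    if (nrow(p) == 0L) return(numeric(len))
    ir <- IRanges::IRanges(start = c(p$start, p$end - rl + 1L),
                           width = rl)
    cov <- IRanges::coverage(ir, width = len)
    as.numeric(cov)
  })
  names(out) <- segments
  out
}

# codon-evolution rate tables for a given (omega, kappa), normalized so the
# mean total substitution rate over sense codons is 1 per unit time
.codon_rates <- function(omega, kappa) {
  tab <- .codon_tables()
  rates <- lapply(tab$sense, function(cd) {
    nb <- tab$neighbors[[cd]]
    r <- ifelse(nb$transition, kappa, 1) * ifelse(nb$synonymous, 1, omega)
    list(to = match(nb$codon, tab$sense), rate = r, total = sum(r))
  })
  tot <- vapply(rates, `[[`, numeric(1), "total")
  rho <- 1 / mean(tot)
  for (i in seq_along(rates)) {
    rates[[i]]$rate <- rates[[i]]$rate * rho
    rates[[i]]$total <- rates[[i]]$total * rho
  }
  rates
}

.evolve_codons <- function(state, t, rates) {
  remaining <- rep(t, length(state))
  active <- seq_along(state)
  while (length(active) > 0) {
    tot <- vapply(rates[state[active]], `[[`, numeric(1), "total")
    # codons with no allowed move (e.g. ATG/TGG at omega = 0) never jump
    wait <- ifelse(tot > 0, stats::rexp(length(active), pmax(tot, 1e-300)),
                   Inf)
    hit <- wait < remaining[active]
    idx <- active[hit]
    remaining[idx] <- remaining[idx] - wait[hit]
    for (i in idx) {
      r <- rates[[state[i]]]
      state[i] <- r$to[sample.int(length(r$rate), 1L, prob = r$rate)]
    }
    active <- idx
  }
  state
}

#' Simulate ortholog CDS pairs under a codon model with known omega
#'
#' Each pair descends from a random sense-codon ancestor and evolves along
#' two independent branches of length \code{t/2} under a continuous-time
#' codon process in which nonsynonymous changes occur at \code{omega} times
#' the synonymous rate and transitions are weighted \code{kappa} over
#' transversions. Mutations creating stop codons have rate zero, so stops are
#' never introduced. The overall rate is normalized (at the given
#' \code{omega} and \code{kappa}) so that \code{t} is the expected number of
#' substitutions per codon site between the two sequences.
#'
#' @param n number of pairs.
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa transition/transversion rate ratio (>= 1).
#' @param t total branch divergence (expected substitutions per codon).
#' @param L number of codons per sequence.
#' @param seed integer seed.
#' @return list of length \code{n}; each element a list \code{a}, \code{b}
#'   (CDS strings) and \code{omega_truth}.
#' @export
simulate_ortholog_pairs <- function(n, omega, kappa, t, L, seed = 1L) {
  if (L < 1) stop("L must be >= 1")
  if (omega < 0) stop("omega must be >= 0")
  if (kappa < 1) stop("kappa must be >= 1")
  set.seed(as.integer(seed))
  tab <- .codon_tables()
  rates <- .codon_rates(omega, kappa)
  lapply(seq_len(n), function(i) {
    anc <- sample.int(length(tab$sense), L, replace = TRUE)
    a <- .evolve_codons(anc, t / 2, rates)
    b <- .evolve_codons(anc, t / 2, rates)
    list(a = paste0(tab$sense[a], collapse = ""),
         b = paste0(tab$sense[b], collapse = ""),
         omega_truth = omega)
  })
}

#' Simulate a qPCR Cq table
#'
#' Generates one Cq measurement per sample x state x gene for three plants of
#' each sex under hydrated and dehydrated conditions. Sex-specific genes do
#' not amplify in the opposite sex (Cq recorded as \code{NA}); induced genes
#' have their Cq shifted by the configured number of cycles when dehydrated
#' (negative shift = induction); Gaussian technical noise is added.
#'
#' @param genes data.frame with columns \code{gene}, \code{class} and
#'   optionally \code{baseline_cq} (default 22 cycles).
#' @param effects named numeric vector of per-gene Cq shifts under
#'   dehydration (cycles; missing genes shift 0).
#' @param seed integer seed.
#' @param control_gene id of the internal control; must be present in
#'   \code{genes} and must amplify in both sexes.
#' @param noise_sd technical noise SD in cycles.
#' @param n_per_sex plants per sex.
#' @return data.frame \code{sample, sex, gene, state, cq}.
#' @export
simulate_cq_table <- function(genes, effects = numeric(0), seed = 1L,
                              control_gene = "actin", noise_sd = 0.2,
                              n_per_sex = 3L) {
  if (!control_gene %in% genes$gene)
    stop("control gene '", control_gene, "' missing from gene table")
  if (genes$class[genes$gene == control_gene] %in%
      c("male_specific", "female_specific"))
    stop("control gene must amplify in both sexes")
  if (is.null(genes$baseline_cq)) genes$baseline_cq <- 22
  set.seed(as.integer(seed))
  samples <- data.frame(
    sample = c(sprintf("M%d", seq_len(n_per_sex)),
               sprintf("F%d", seq_len(n_per_sex))),
    sex = rep(c("male", "female"), each = n_per_sex),
    stringsAsFactors = FALSE)
  grid <- expand.grid(sample = samples$sample,
                      state = c("hydrated", "dehydrated"),
                      gene = genes$gene, stringsAsFactors = FALSE)
  grid$sex <- samples$sex[match(grid$sample, samples$sample)]
  grid$class <- genes$class[match(grid$gene, genes$gene)]
  base <- genes$baseline_cq[match(grid$gene, genes$gene)]
  shift <- ifelse(grid$state == "dehydrated",
                  ifelse(is.na(effects[grid$gene]), 0, effects[grid$gene]), 0)
  cq <- base + shift + stats::rnorm(nrow(grid), 0, noise_sd)
  absent <- (grid$class == "male_specific" & grid$sex == "female") |
    (grid$class == "female_specific" & grid$sex == "male")
  cq[absent] <- NA_real_
  out <- data.frame(sample = grid$sample, sex = grid$sex, gene = grid$gene,
                    state = grid$state, cq = cq, stringsAsFactors = FALSE)
  out[order(out$sample, out$state, out$gene), ]
}
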