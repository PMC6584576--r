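# Precomputed codon lookup tables shared by the NG86 estimator and the codon
# evolution simulator. Built once at load time from Biostrings::GENETIC_CODE
# (standard code only).

.codon_env <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE),
                  1L, paste0, collapse = "")
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- unname(gc_tab[codons])
  names(aa) <- codons
  sense <- codons[aa != "*"]

  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }

  # per-codon NG86 synonymous site fraction; stop neighbors shrink the
  # per-position denominator so every codon still contributes 3 sites
  syn_sites <- vapply(sense, function(cd) {
    nt <- strsplit(cd, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L; legal <- 0L
      for (b in setdiff(bases, nt[pos])) {
        mut <- nt; mut[pos] <- b
        mc <- paste0(mut, collapse = "")
        if (aa[mc] == "*") next
        legal <- legal + 1L
        if (aa[mc] == aa[cd]) syn <- syn + 1L
      }
      if (legal > 0L) s <- s + syn / legal
    }
    s
  }, numeric(1))

  # neighbor table for the simulator: sense -> sense single-base mutations
  neighbors <- lapply(sense, function(cd) {
    nt <- strsplit(cd, "")[[1]]
    out <- list(codon = character(0), transition = logical(0),
                synonymous = logical(0))
    for (pos in 1:3) {
      for (b in setdiff(bases, nt[pos])) {
        mut <- nt; mut[pos] <- b
        mc <- paste0(mut, collapse = "")
        if (aa[mc] == "*") next
        out$codon <- c(out$codon, mc)
        out$transition <- c(out$transition, is_transition(nt[pos], b))
        out$synonymous <- c(out$synonymous, aa[mc] == aa[cd])
      }
    }
    out
  })
  names(neighbors) <- sense

  # pairwise difference classification: average syn/nonsyn step counts over
  # legal mutational pathways (those avoiding stop codons)
  n_sense <- length(sense)
  sd_mat <- matrix(0, n_sense, n_sense, dimnames = list(sense, sense))
  nd_mat <- sd_mat
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in seq_len(n_sense)) {
    a <- strsplit(sense[i], "")[[1]]
    for (j in seq_len(n_sense)) {
      if (i == j) next
      b <- strsplit(sense[j], "")[[1]]
      d <- which(a != b)
      k <- length(d)
      if (k == 1L) {
        syn <- aa[sense[i]] == aa[sense[j]]
        sd_mat[i, j] <- as.numeric(syn)
        nd_mat[i, j] <- as.numeric(!syn)
        next
      }
      perms <- if (k == 2L) perms2 else perms3
      path_sd <- numeric(0); path_nd <- numeric(0)
      all_sd <- numeric(0); all_nd <- numeric(0)
      for (ord in perms) {
        cur <- a; sd_p <- 0; nd_p <- 0; legal <- TRUE
        for (step in ord) {
          nxt <- cur; nxt[d[step]] <- b[d[step]]
          c_cur <- paste0(cur, collapse = ""); c_nxt <- paste0(nxt, collapse = "")
          if (aa[c_nxt] == "*") { legal <- FALSE }
          if (aa[c_nxt] == aa[c_cur]) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
          cur <- nxt
        }
        all_sd <- c(all_sd, sd_p); all_nd <- c(all_nd, nd_p)
        if (legal) { path_sd <- c(path_sd, sd_p); path_nd <- c(path_nd, nd_p) }
      }
      if (length(path_sd) == 0L) { path_sd <- all_sd; path_nd <- all_nd }
      sd_mat[i, j] <- mean(path_sd)
      nd_mat[i, j] <- mean(path_nd)
    }
  }

  list(codons = codons, aa = aa, sense = sense, syn_sites = syn_sites,
       neighbors = neighbors, sd_mat = sd_mat, nd_mat = nd_mat)
}

.codon_tables <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .build_codon_tables()
  .codon_env$tab
}

#' Split a coding sequence into codons
#'
#' @param seq a single DNA string with length divisible by 3.
#' @return character vector of codons (uppercase).
#' @keywords internal
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.is_stop <- function(codon) {
  tab <- .codon_tables()
  !is.na(tab$aa[codon]) & tab$aa[codon] == "*"
}
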