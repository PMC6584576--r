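# Independent brute-force NG86 oracle. Deliberately written as a separate,
# naive implementation (per-call enumeration, recursive pathway walk) so it
# shares no code path with the package's precomputed lookup tables.

oracle_aa <- function(codon) unname(Biostrings::GENETIC_CODE[[codon]])

oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  nt <- strsplit(codon, "")[[1]]
  S <- 0; N <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in bases) {
      if (b == nt[pos]) next
      mut <- nt; mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (oracle_aa(mc) == "*") next
      tot <- tot + 1
      if (oracle_aa(mc) == oracle_aa(codon)) syn <- syn + 1
    }
    frac <- if (tot > 0) syn / tot else 0
    S <- S + frac
    N <- N + 1 - frac
  }
  c(S = S, N = N)
}

# recursively walk every ordering of the differing positions, recording the
# synonymous / nonsynonymous step counts and whether the path hits a stop
oracle_paths <- function(cur, target) {
  diffs <- which(cur != target)
  if (length(diffs) == 0)
    return(data.frame(sd = 0, nd = 0, legal = TRUE))
  out <- NULL
  for (pos in diffs) {
    nxt <- cur
    nxt[pos] <- target[pos]
    c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
    step_syn <- oracle_aa(c_cur) == oracle_aa(c_nxt)
    step_legal <- oracle_aa(c_nxt) != "*"
    rest <- oracle_paths(nxt, target)
    rest$sd <- rest$sd + as.numeric(step_syn)
    rest$nd <- rest$nd + as.numeric(!step_syn)
    rest$legal <- rest$legal & step_legal
    out <- rbind(out, rest)
  }
  out
}

oracle_diffs <- function(codon_a, codon_b) {
  p <- oracle_paths(strsplit(codon_a, "")[[1]], strsplit(codon_b, "")[[1]])
  use <- if (any(p$legal)) p[p$legal, ] else p
  c(Sd = mean(use$sd), Nd = mean(use$nd))
}

oracle_dnds <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  cod_a <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cod_b <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  site_a <- t(vapply(cod_a, oracle_sites, numeric(2)))
  site_b <- t(vapply(cod_b, oracle_sites, numeric(2)))
  S <- (sum(site_a[, "S"]) + sum(site_b[, "S"])) / 2
  N <- (sum(site_a[, "N"]) + sum(site_b[, "N"])) / 2
  d <- t(mapply(oracle_diffs, cod_a, cod_b))
  list(S = S, N = N, Sd = sum(d[, "Sd"]), Nd = sum(d[, "Nd"]))
}

sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  all[vapply(all, oracle_aa, character(1)) != "*"]
}

random_codon_alignment <- function(n_codons) {
  sc <- sense_codons()
  list(a = paste(sample(sc, n_codons, replace = TRUE), collapse = ""),
       b = paste(sample(sc, n_codons, replace = TRUE), collapse = ""))
}
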