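# Shared small fixtures, generated in code.

# a reduced genome for fast end-to-end tests: one autosome, short U/V,
# no organelles
tiny_config <- function(seed = 5L, ...) {
  sim_config(n_autosomes = 1, autosome_len = 30000, u_len = 10000,
             v_len = 10000, organelle_lens = c(mito = 5000),
             n_contaminants = 1, contaminant_len = 10000,
             n_genes_per_class = c(autosomal = 4, male_specific = 2,
                                   female_specific = 2, male_allele = 1,
                                   female_allele = 1, mitochondrial = 1,
                                   chloroplast = 0),
             gene_len = 300, seed = seed, ...)
}

tiny_reference <- function(seed = 5L) simulate_reference(tiny_config(seed))
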