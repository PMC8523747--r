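# Shared fixtures, generated in code at test time.

# a small annotated toy genome
small_annotation <- function(seed = 1, n_probes = 400,
                             genome_length = 2e5) {
  make_annotation(n_probes = n_probes, genome_length = genome_length,
                  n_genes = 20, seed = seed)
}

# a small twin cohort; pass design overrides through ...
small_cohort <- function(seed = 1, n_probes = 400, ...) {
  ann <- small_annotation(seed, n_probes)
  des <- sim_design(seed = seed + 1, ...)
  refs <- make_reference_profiles(ann, des$cell_types, seed = seed + 2)
  c(simulate_cohort(des, ann, refs), list(annotation = ann,
                                          references = refs,
                                          design = des))
}

# a noise-free design with no mutations (deterministic mixture cohort)
quiet_design <- function(seed, ...) {
  sim_design(seed = seed, mutation_rates = c(TET2 = 0, DNMT3A = 0),
             noise_sd = 0, pair_sd = 0, batch_sd = 0,
             n_latent_factors = 0, monocyte_bump = 0, ...)
}

# random 2x2 table with total at most n_max
random_2x2 <- function(n_max = 200) {
  n <- sample.int(n_max - 4, 1) + 4
  repeat {
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# brute-force two-sided Fisher by complete enumeration of tables with
# the observed margins (independent of the dhyper-based implementation)
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(n, c1)
  sum(prob[prob <= obs * (1 + 1e-7)])
}
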