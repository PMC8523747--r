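#' The 15 chromatin-state labels used by the simulator
#'
#' Mnemonics follow the Roadmap Epigenomics 15-state ChromHMM model.
#' `Enh` (active enhancer) and `EnhG` (genic enhancer) together form the
#' "enhancer" class used throughout the package.
#'
#' @return Character vector of 15 state labels.
#' @export
chromhmm_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
    "ZNF_Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
    "ReprPCWk", "Quies")
}

#' Chromatin states counted as enhancers
#' @return Character vector.
#' @export
enhancer_states <- function() c("Enh", "EnhG")

default_state_proportions <- function() {
  p <- c(TssA = 0.08, TssAFlnk = 0.04, TxFlnk = 0.02, Tx = 0.10,
         TxWk = 0.12, EnhG = 0.03, Enh = 0.07, ZNF_Rpts = 0.01,
         Het = 0.03, TssBiv = 0.02, BivFlnk = 0.01, EnhBiv = 0.02,
         ReprPC = 0.05, ReprPCWk = 0.08, Quies = 0.32)
  p[chromhmm_states()]
}

#' Simulation design for a synthetic CHIP methylation cohort
#'
#' Captures the stated world the generator emulates: twins aged 70+,
#' per-gene driver mutation rates, clone sizes (VAF) drawn uniformly,
#' additive M-scale hypermethylation proportional to VAF at affected
#' probes, enhancer-biased placement of affected probes, pair-shared
#' random intercepts, Gaussian M-scale noise and per-batch probe shifts.
#'
#' Defaults give roughly 40 TET2 carriers among 120 samples, a mean
#' planted TET2 effect of 0.5 M units (effect size `0.5 / mean(VAF)`
#' per unit VAF), and ~1% of probes affected with a 10:1 enhancer bias.
#'
#' @param n_pairs Number of complete twin pairs.
#' @param n_singletons Number of unpaired samples.
#' @param cell_types Cell-type labels; must match the reference profiles.
#' @param mutation_rates Named per-gene mutation probabilities; a sample
#'   carries at most one driver gene.
#' @param vaf_range Lower/upper bound of the uniform VAF distribution.
#' @param effect_size Named per-gene M-value shift per unit VAF at
#'   affected probes (negative for hypomethylating drivers).
#' @param affected_fraction_by_state Named list per gene: probability a
#'   probe in each chromatin state is affected; `.default` covers
#'   unlisted states.
#' @param noise_sd Residual M-value standard deviation.
#' @param pair_sd SD of the pair-shared random intercept (M scale).
#' @param n_latent_factors,latent_sd Number and per-probe loading SD of
#'   latent sample-level factors (technical/biological structure such
#'   as residual batch chemistry or unmodelled cell variation).  These
#'   are what the principal-component covariates in the association
#'   model are meant to absorb; without them a synthetic cohort has no
#'   structured variance and data-derived PCs can lock onto the planted
#'   mutation signature instead.
#' @param n_batches,batch_sd Number of batches and SD of per-(probe,
#'   batch) shifts.
#' @param monocyte_bump Added monocyte fraction for TET2 carriers
#'   (higher monocyte proportions in carriers, magnitude a simulator
#'   assumption).
#' @param cell_alpha Dirichlet concentration for cell fractions.
#' @param seed Integer seed; mandatory.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(n_pairs = 60, n_singletons = 0,
                       cell_types = c("granulocyte", "monocyte", "CD4T", "B"),
                       mutation_rates = c(TET2 = 1 / 3, DNMT3A = 0.15),
                       vaf_range = c(0.1, 0.5),
                       effect_size = c(TET2 = 0.5 / 0.3, DNMT3A = -0.5 / 0.3),
                       affected_fraction_by_state = list(
                         TET2 = c(Enh = 0.055, EnhG = 0.055,
                                  .default = 0.0055),
                         DNMT3A = c(.default = 0.002)),
                       noise_sd = 0.2, pair_sd = 0.5 * noise_sd,
                       n_latent_factors = 4, latent_sd = 0.15,
                       n_batches = 2, batch_sd = 0.05,
                       monocyte_bump = 0.03,
                       cell_alpha = c(granulocyte = 12, monocyte = 2,
                                      CD4T = 4, B = 2),
                       seed) {
  stopifnot(!missing(seed), n_pairs >= 0, n_singletons >= 0,
            sum(mutation_rates) <= 1, all(mutation_rates >= 0),
            vaf_range[1] > 0, vaf_range[2] < 1,
            vaf_range[1] < vaf_range[2], noise_sd >= 0, pair_sd >= 0)
  for (g in names(affected_fraction_by_state)) {
    f <- affected_fraction_by_state[[g]]
    stopifnot(all(f >= 0), all(f <= 1))
  }
  structure(list(n_pairs = n_pairs, n_singletons = n_singletons,
                 cell_types = cell_types, mutation_rates = mutation_rates,
                 vaf_range = vaf_range, effect_size = effect_size,
                 affected_fraction_by_state = affected_fraction_by_state,
                 noise_sd = noise_sd, pair_sd = pair_sd,
                 n_latent_factors = n_latent_factors,
                 latent_sd = latent_sd,
                 n_batches = n_batches, batch_sd = batch_sd,
                 monocyte_bump = monocyte_bump, cell_alpha = cell_alpha,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# categorical island-relation probabilities given a chromatin state:
# enhancers are CpG poor, promoters CpG rich
island_probs_for_state <- function(state) {
  if (state %in% enhancer_states())
    c(island = 0.05, shore = 0.15, shelf = 0.10, open_sea = 0.70)
  else if (state %in% c("TssA", "TssAFlnk", "TssBiv", "BivFlnk"))
    c(island = 0.60, shore = 0.25, shelf = 0.05, open_sea = 0.10)
  else
    c(island = 0.25, shore = 0.20, shelf = 0.10, open_sea = 0.45)
}

#' Generate a synthetic probe manifest with chromatin states and genes
#'
#' Builds a single-chromosome toy genome tiled, independently per cell
#' type, by non-overlapping ChromHMM-style segments whose state labels
#' are drawn from `state_proportions`; places `n_probes` CpG probes at
#' distinct positions; assigns each probe the state of its containing
#' segment per cell type and a CpG-island relation whose distribution
#' depends on the (first-listed reference cell type's) state, so that
#' enhancer probes are CpG poor; and lays down a random gene TSS table.
#'
#' @param n_probes Number of probes.
#' @param genome_length Length of the single chromosome `chr1` in bp.
#' @param state_proportions Named numeric over [chromhmm_states()],
#'   summing to 1.
#' @param cell_types Cell types to segment.
#' @param n_genes Number of genes in the TSS table.
#' @param mean_segment_length Mean ChromHMM segment length in bp.
#' @param seed Integer seed.
#' @return Object of class `probe_annotation`: list with `probes` (data
#'   frame: `probe_id`, `chrom`, `pos` 1-based, `island_relation`, one
#'   `state_<cell type>` column each), `segments` (per cell type, 1-based
#'   inclusive intervals), `tss` (gene, chrom, tss, strand),
#'   `genome` (named chromosome lengths) and `cell_types`.
#' @export
make_annotation <- function(n_probes, genome_length = max(1e6, n_probes * 150),
                            state_proportions = default_state_proportions(),
                            cell_types = c("granulocyte", "monocyte",
                                           "CD4T", "B"),
                            n_genes = 150, mean_segment_length = 1000,
                            seed) {
  stopifnot(!missing(seed))
  states <- chromhmm_states()
  state_proportions <- state_proportions[states]
  if (anyNA(state_proportions) ||
      abs(sum(state_proportions) - 1) > 1e-8)
    stop("state_proportions must cover all 15 states and sum to 1")
  if (n_probes > genome_length)
    stop("n_probes exceeds genome capacity")
  set.seed(seed)

  segment_one <- function() {
    lens <- integer(0)
    total <- 0
    while (total < genome_length) {
      chunk <- pmax(200L, as.integer(round(rexp(256, 1 / mean_segment_length))))
      lens <- c(lens, chunk)
      total <- total + sum(chunk)
    }
    ends <- cumsum(as.numeric(lens))
    keep <- seq_len(which(ends >= genome_length)[1])
    lens <- lens[keep]
    ends <- ends[keep]
    ends[length(ends)] <- genome_length
    starts <- c(1, head(ends, -1) + 1)
    data.frame(chrom = "chr1", start = starts, end = ends,
               state = sample(states, length(starts), replace = TRUE,
                              prob = state_proportions))
  }
  segments <- lapply(setNames(cell_types, cell_types),
                     function(ct) segment_one())

  pos <- sort(sample.int(genome_length, n_probes))
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n_probes)),
    chrom = "chr1", pos = pos)
  for (ct in cell_types) {
    seg <- segments[[ct]]
    probes[[paste0("state_", ct)]] <-
      seg$state[findInterval(pos, seg$start)]
  }
  ref_state <- probes[[paste0("state_", cell_types[1])]]
  probes$island_relation <- vapply(ref_state, function(s) {
    p <- island_probs_for_state(s)
    sample(names(p), 1, prob = p)
  }, character(1))

  tss <- data.frame(
    gene = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = sort(sample.int(genome_length, n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE))

  structure(list(probes = probes, segments = segments, tss = tss,
                 genome = c(chr1 = genome_length), cell_types = cell_types),
            class = "probe_annotation")
}

#' Generate synthetic reference cell-type methylomes
#'
#' Produces a cell types x probes beta matrix with a bimodal baseline
#' shared across cell types plus a designated set of discriminative
#' probes: each discriminative probe is highly methylated (0.85-0.95) in
#' exactly one cell type and lowly methylated (0.05-0.15) in the others,
#' so every pair of cell types is separated by at least 0.5 beta at a
#' subset of probes and deconvolution is identifiable.
#'
#' @param annotation A `probe_annotation`.
#' @param cell_types Distinct cell-type labels (at least two).
#' @param discriminative_fraction Fraction of probes made discriminative
#'   (at least 10 per cell type).
#' @param seed Integer seed.
#' @return Cell types x probes beta matrix with attribute
#'   `discriminative` (probe ids).
#' @export
make_reference_profiles <- function(annotation, cell_types,
                                    discriminative_fraction = 0.05,
                                    seed) {
  stopifnot(!missing(seed))
  if (length(unique(cell_types)) < 2)
    stop("reference profiles require at least two distinct cell types")
  set.seed(seed)
  ids <- annotation$probes$probe_id
  n <- length(ids)
  q <- length(cell_types)
  high <- rbinom(n, 1, 0.4) == 1
  base <- ifelse(high, rbeta(n, 8, 2), rbeta(n, 2, 8))
  ref <- matrix(rep(base, each = q), nrow = q,
                dimnames = list(cell_types, ids))
  n_disc <- max(10 * q, ceiling(discriminative_fraction * n))
  n_disc <- min(n_disc, n)
  disc <- sample.int(n, n_disc)
  up <- rep_len(seq_len(q), n_disc)  # round robin over cell types
  for (k in seq_along(disc)) {
    j <- disc[k]
    ref[, j] <- runif(q, 0.05, 0.15)
    ref[up[k], j] <- runif(1, 0.85, 0.95)
  }
  attr(ref, "discriminative") <- ids[sort(disc)]
  ref
}

draw_dirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a twin methylation cohort with planted mutation effects
#'
#' Each sample's beta profile is a Dirichlet-weighted mixture of the
#' reference cell-type methylomes; on the M scale it then receives, at
#' the probes flagged affected for each driver gene, an additive shift
#' `effect_size[gene] * VAF` when the sample carries that gene, plus a
#' pair-shared Gaussian intercept, per-(probe, batch) shifts and
#' Gaussian noise, before mapping back to (0, 1).  TET2 carriers receive
#' a configurable monocyte-fraction bump.  Twins share age and sex.
#'
#' @param design A [sim_design()].
#' @param annotation A [make_annotation()] result covering the probes.
#' @param references A [make_reference_profiles()] beta matrix covering
#'   all probes in the annotation.
#' @return List with `cohort` (class `methylation_cohort`: `beta`, `M`,
#'   `samples` data frame, `cell_fractions` truth) and `truth` (the
#'   per-probe truth table).
#' @export
simulate_cohort <- function(design, annotation, references) {
  stopifnot(inherits(design, "sim_design"))
  probes <- annotation$probes
  if (!all(probes$probe_id %in% colnames(references)))
    stop("reference profiles do not cover all probes")
  references <- references[, probes$probe_id, drop = FALSE]
  if (!setequal(rownames(references), design$cell_types))
    stop("reference cell types do not match the design")
  set.seed(design$seed)

  n_probes <- nrow(probes)
  n <- 2 * design$n_pairs + design$n_singletons
  sample_id <- sprintf("S%04d", seq_len(n))
  pair_id <- c(rep(sprintf("P%04d", seq_len(design$n_pairs)), each = 2),
               rep(NA_character_, design$n_singletons))
  # pair-shared demographics; singletons get their own
  group <- ifelse(is.na(pair_id), paste0("G", seq_len(n)), pair_id)
  ug <- unique(group)
  age_g <- setNames(round(runif(length(ug), 70, 90)), ug)
  sex_g <- setNames(sample(c("F", "M"), length(ug), replace = TRUE), ug)
  batch <- sample(sprintf("B%02d", seq_len(design$n_batches)), n,
                  replace = TRUE)

  genes <- names(design$mutation_rates)
  u <- runif(n)
  cuts <- cumsum(design$mutation_rates)
  gene_of <- rep(NA_character_, n)
  for (k in rev(seq_along(genes))) gene_of[u < cuts[k]] <- genes[k]
  vaf <- matrix(0, n, length(genes), dimnames = list(sample_id, genes))
  for (g in genes) {
    idx <- which(gene_of == g)
    vaf[idx, g] <- runif(length(idx), design$vaf_range[1],
                         design$vaf_range[2])
  }

  # truth table: affected probes per gene, by (first cell type) state
  state <- probes[[paste0("state_", design$cell_types[1])]]
  truth <- data.frame(probe_id = probes$probe_id, state = state,
                      island_relation = probes$island_relation)
  for (g in genes) {
    frac <- design$affected_fraction_by_state[[g]]
    if (is.null(frac)) frac <- c(.default = 0)
    p_aff <- frac[state]
    p_aff[is.na(p_aff)] <- if (".default" %in% names(frac))
      frac[[".default"]] else 0
    affected <- runif(n_probes) < p_aff
    truth[[paste0("affected_", g)]] <- affected
    truth[[paste0("effect_", g)]] <-
      ifelse(affected, design$effect_size[[g]], 0)
  }

  fractions <- draw_dirichlet(n, design$cell_alpha[design$cell_types])
  colnames(fractions) <- design$cell_types
  rownames(fractions) <- sample_id
  if ("monocyte" %in% design$cell_types && "TET2" %in% genes) {
    carriers <- which(gene_of == "TET2")
    for (i in carriers) {
      old <- fractions[i, "monocyte"]
      new <- min(old + design$monocyte_bump, 1)
      others <- setdiff(design$cell_types, "monocyte")
      fractions[i, others] <- fractions[i, others] *
        (1 - new) / (1 - old)
      fractions[i, "monocyte"] <- new
    }
  }

  beta_mix <- t(references) %*% t(fractions)  # probes x samples
  M <- beta_to_m(beta_mix)

  for (g in genes) {
    eff <- truth[[paste0("effect_", g)]]
    aff <- which(eff != 0)
    if (!length(aff)) next
    M[aff, ] <- M[aff, , drop = FALSE] +
      outer(eff[aff], vaf[, g])
  }

  if (design$pair_sd > 0) {
    b <- matrix(rnorm(n_probes * length(ug), 0, design$pair_sd),
                n_probes, length(ug), dimnames = list(NULL, ug))
    M <- M + b[, group, drop = FALSE]
  }
  if (design$n_latent_factors > 0 && design$latent_sd > 0) {
    k <- design$n_latent_factors
    scores <- matrix(rnorm(n * k), n, k)
    loadings <- matrix(rnorm(n_probes * k, 0, design$latent_sd),
                       n_probes, k)
    M <- M + loadings %*% t(scores)
  }
  if (design$batch_sd > 0) {
    ub <- unique(batch)
    shift <- matrix(rnorm(n_probes * length(ub), 0, design$batch_sd),
                    n_probes, length(ub), dimnames = list(NULL, ub))
    M <- M + shift[, batch, drop = FALSE]
  }
  if (design$noise_sd > 0)
    M <- M + matrix(rnorm(n_probes * n, 0, design$noise_sd), n_probes, n)

  beta <- m_to_beta(M)
  dimnames(beta) <- dimnames(M) <- list(probes$probe_id, sample_id)

  samples <- data.frame(sample_id = sample_id, pair_id = pair_id,
                        age = age_g[group], sex = sex_g[group],
                        batch = batch, row.names = NULL)
  for (g in genes) {
    samples[[g]] <- gene_of == g & !is.na(gene_of)
    samples[[paste0("vaf_", g)]] <- vaf[, g]
  }

  cohort <- structure(list(beta = beta, M = M, samples = samples,
                           cell_fractions = fractions),
                      class = "methylation_cohort")
  list(cohort = cohort, truth = truth)
}

#' Generate a random set of sharply informative PWMs
#'
#' Each motif has a random consensus; consensus bases carry probability
#' `consensus_prob` with the remainder spread over the other bases.
#' Family labels cycle over `families`.  Defaults (widths 10-12,
#' consensus probability 0.97) are chosen so that, under the package's
#' zero-bit log-odds hit rule, a random 200 bp background region is a
#' hit with moderate probability (~0.15-0.35) while a region carrying
#' the consensus is essentially always a hit — the regime in which
#' ranked enrichment is informative.
#'
#' @param n_motifs Number of motifs.
#' @param width_range Inclusive motif width range.
#' @param families Family labels to cycle over.
#' @param consensus_prob Probability mass of the consensus base.
#' @param background Named background nucleotide frequencies.
#' @param seed Integer seed.
#' @return Named list of PWMs; each PWM is a list with `id`, `family`,
#'   `matrix` (4 x width, rows ACGT, columns summing to 1) and
#'   `background`.
#' @export
make_pwm_set <- function(n_motifs = 10, width_range = c(10, 12),
                         families = c("ETS", "CEBP", "OTHER"),
                         consensus_prob = 0.97,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25),
                         seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  fam <- rep_len(families, n_motifs)
  pwms <- lapply(seq_len(n_motifs), function(i) {
    w <- sample(seq(width_range[1], width_range[2]), 1)
    cons <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    mat <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = w,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(w)) mat[cons[j], j] <- consensus_prob
    list(id = sprintf("MOTIF%02d_%s", i, fam[i]), family = fam[i],
         matrix = mat, background = background)
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  pwms
}

pwm_consensus <- function(pwm) {
  rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)]
}

#' Simulate ranked 200 bp regions with a planted motif in the top ranks
#'
#' Generates i.i.d. background sequences from the stated nucleotide
#' frequencies, assigns a strictly decreasing ranking score, and embeds
#' the consensus of one chosen PWM (with a configurable per-base
#' mutation rate) at a random position within each of the top
#' `planted_top_fraction` regions.
#'
#' @param pwm_set A [make_pwm_set()] result.
#' @param n_regions Number of regions.
#' @param region_length Region length in bp.
#' @param planted_top_fraction Fraction of top-ranked regions that
#'   receive the motif (0 disables planting; must be <= 1).
#' @param planted_motif Id of the motif to plant (default: first).
#' @param mutation_rate Per-base probability of mutating a planted
#'   consensus base.
#' @param background Named nucleotide frequencies for the background.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `scores`
#'   (decreasing ranking scores), `planted` (logical truth labels) and
#'   `motif` (planted motif id).
#' @export
simulate_motif_regions <- function(pwm_set, n_regions,
                                   region_length = 200,
                                   planted_top_fraction = 0.2,
                                   planted_motif = names(pwm_set)[1],
                                   mutation_rate = 0,
                                   background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                   seed) {
  stopifnot(!missing(seed))
  if (planted_top_fraction > 1 || planted_top_fraction < 0)
    stop("planted_top_fraction must lie in [0, 1]")
  pwm <- pwm_set[[planted_motif]]
  w <- ncol(pwm$matrix)
  if (region_length < w)
    stop("region_length must be at least the motif length")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_regions), function(i) {
    paste(sample(bases, region_length, replace = TRUE,
                 prob = background[bases]), collapse = "")
  }, character(1))
  scores <- sort(rnorm(n_regions), decreasing = TRUE)
  k <- round(planted_top_fraction * n_regions)
  planted <- c(rep(TRUE, k), rep(FALSE, n_regions - k))
  cons <- pwm_consensus(pwm)
  for (i in seq_len(k)) {
    motif <- cons
    mut <- runif(w) < mutation_rate
    if (any(mut))
      motif[mut] <- vapply(motif[mut], function(b)
        sample(setdiff(bases, b), 1), character(1))
    at <- sample.int(region_length - w + 1, 1)
    s <- strsplit(seqs[i], "")[[1]]
    s[at:(at + w - 1)] <- motif
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("region_%04d", seq_len(n_regions))
  list(sequences = seqs, scores = scores, planted = planted,
       motif = planted_motif)
}
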