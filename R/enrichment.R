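#' Annotate 1-bp sites with chromatin states and island relations
#'
#' Each site (a 1-bp interval at the probe position) is assigned the
#' state of the overlapping ChromHMM segment.  Segmentations are assumed
#' to tile the genome; should malformed overlapping segments occur, the
#' first interval after sorting wins, with a warning.
#'
#' @param sites Data frame with `probe_id`, `chrom`, `pos` (1-based).
#' @param chromhmm A `GRanges` with a `state` column (e.g. from
#'   [read_chromhmm_bed()]) or a BED path.
#' @param island_map Optional named character vector (probe id to
#'   island relation) merged into the result.
#' @return Data frame `probe_id`, `state` and (if supplied)
#'   `island_relation`.
#' @export
annotate_sites <- function(sites, chromhmm, island_map = NULL) {
  if (is.character(chromhmm) && length(chromhmm) == 1)
    chromhmm <- read_chromhmm_bed(chromhmm)
  chromhmm <- GenomicRanges::sort(chromhmm)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(gr, chromhmm)
  if (anyDuplicated(S4Vectors::queryHits(hits))) {
    warning("overlapping segments in the segmentation; first interval wins")
    hits <- hits[!duplicated(S4Vectors::queryHits(hits))]
  }
  state <- rep(NA_character_, nrow(sites))
  state[S4Vectors::queryHits(hits)] <-
    S4Vectors::mcols(chromhmm)$state[S4Vectors::subjectHits(hits)]
  out <- data.frame(probe_id = sites$probe_id, state = state)
  if (!is.null(island_map))
    out$island_relation <- unname(island_map[sites$probe_id])
  out
}

#' Category composition of a site set versus the background
#'
#' For every level of a categorical annotation (chromatin state, CpG
#' island relation, ...), builds the 2x2 table of (in set vs not) by
#' (in category vs not) over all annotated sites, reports the in-set and
#' background proportions and their ratio, and tests association with
#' the chi-squared/Fisher dispatcher.
#'
#' @param hyper_set A `hyper_set` or character vector of probe ids.
#' @param all_sites Data frame with `probe_id` and the category column;
#'   the background is `all_sites` minus the set.
#' @param category_field Name of the category column.
#' @return Data frame, one row per category: counts, proportions,
#'   `ratio`, `p_value`, `method`, `p_bonferroni`.
#' @export
composition_enrichment <- function(hyper_set, all_sites, category_field) {
  ids <- if (inherits(hyper_set, "hyper_set")) hyper_set$probe_ids
         else hyper_set
  stopifnot(category_field %in% names(all_sites))
  in_set <- all_sites$probe_id %in% ids
  cat_v <- as.character(all_sites[[category_field]])
  levels <- sort(unique(cat_v))
  rows <- lapply(levels, function(lv) {
    in_cat <- cat_v == lv
    tab <- matrix(c(sum(in_set & in_cat), sum(in_set & !in_cat),
                    sum(!in_set & in_cat), sum(!in_set & !in_cat)),
                  nrow = 2, byrow = TRUE)
    res <- assoc_test_2x2(tab)
    prop_set <- tab[1, 1] / sum(tab[1, ])
    prop_bg <- tab[2, 1] / sum(tab[2, ])
    data.frame(category = lv, n_set = tab[1, 1],
               set_size = sum(tab[1, ]), n_background = tab[2, 1],
               background_size = sum(tab[2, ]),
               prop_set = prop_set, prop_background = prop_bg,
               ratio = prop_set / prop_bg, p_value = res$p_value,
               method = res$method)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Build GREAT-style basal-plus-extension regulatory domains
#'
#' Every gene receives a strand-aware basal domain (`basal_up` bp
#' upstream to `basal_down` bp downstream of its TSS) which is always
#' included, extended outward to the nearer of `max_extension` from the
#' TSS or the neighboring gene's basal domain, and clipped at the
#' chromosome ends.
#'
#' @param tss_table Data frame with `gene`, `chrom`, `tss`, `strand`.
#' @param basal_up,basal_down Basal window in bp (promoter-proximal).
#' @param max_extension Maximum distal extension in bp.
#' @param chrom_sizes Named chromosome lengths.
#' @return Data frame with `gene`, `chrom`, `start`, `end` (the full
#'   domain, 1-based inclusive) and the basal window coordinates.
#' @export
build_regulatory_domains <- function(tss_table, basal_up = 5000,
                                     basal_down = 1000,
                                     max_extension = 1e6, chrom_sizes) {
  out <- lapply(split(tss_table, tss_table$chrom), function(tt) {
    L <- chrom_sizes[[tt$chrom[1]]]
    if (is.null(L) || is.na(L)) stop("missing chromosome size")
    tt <- tt[order(tt$tss), , drop = FALSE]
    plus <- tt$strand == "+"
    b_start <- ifelse(plus, tt$tss - basal_up, tt$tss - basal_down)
    b_end <- ifelse(plus, tt$tss + basal_down, tt$tss + basal_up)
    b_start <- pmax(1, b_start)
    b_end <- pmin(L, b_end)
    n <- nrow(tt)
    prev_end <- c(0, b_end[-n])
    next_start <- c(b_start[-1], L + 1)
    start <- pmin(b_start, pmax(tt$tss - max_extension, prev_end + 1))
    end <- pmax(b_end, pmin(tt$tss + max_extension, next_start - 1))
    data.frame(gene = tt$gene, chrom = tt$chrom,
               start = pmax(1, start), end = pmin(L, end),
               basal_start = b_start, basal_end = b_end)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

domain_union <- function(domains) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    domains$chrom, IRanges::IRanges(domains$start, domains$end)))
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos, sites$pos))
}

term_gene_list <- function(term_to_genes) {
  if (is.data.frame(term_to_genes))
    split(term_to_genes$gene, term_to_genes$term)
  else term_to_genes
}

#' GREAT region-based binomial enrichment test
#'
#' Treats each selected CpG site as a 1-bp region.  For a term whose
#' genes' regulatory domains cover a fraction `p_t` of the genome, the
#' number of selected sites falling inside that domain union is compared
#' to `Binomial(n_sites, p_t)`; the P value is the upper tail at the
#' observed count, Bonferroni-corrected over terms.
#'
#' @param selected_sites Data frame with `chrom` and `pos`.
#' @param term_to_genes Data frame (`term`, `gene`) or named list of
#'   gene vectors.
#' @param domains A [build_regulatory_domains()] result.
#' @param genome_size Total genome length in bp (defaults to the sum of
#'   the domains' chromosome extents is not assumed; required).
#' @return Data frame per term: `k` (sites in domain), `n`, coverage
#'   fraction `p_t`, `fold`, `p_value`, `p_bonferroni`.
#' @export
great_binomial <- function(selected_sites, term_to_genes, domains,
                           genome_size) {
  terms <- term_gene_list(term_to_genes)
  gr_sites <- sites_granges(selected_sites)
  n <- length(gr_sites)
  rows <- lapply(names(terms), function(tm) {
    dom <- domains[domains$gene %in% terms[[tm]], , drop = FALSE]
    if (!nrow(dom))
      return(data.frame(term = tm, k = 0L, n = n, p_t = 0,
                        fold = NA_real_, p_value = 1))
    un <- domain_union(dom)
    p_t <- min(1, sum(as.numeric(GenomicRanges::width(un))) / genome_size)
    k <- sum(IRanges::overlapsAny(gr_sites, un))
    p <- if (p_t >= 1) 1 else pbinom(k - 1, n, p_t, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, p_t = p_t,
               fold = (k / n) / p_t, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' GREAT gene-based hypergeometric enrichment test
#'
#' A gene counts as "hit" when at least one selected site lies in its
#' regulatory domain.  For each term, the number of hit genes annotated
#' to the term is tested against the hypergeometric distribution given
#' the total gene count, the term's gene count and the number of hit
#' genes; upper tail, Bonferroni-corrected over terms.
#'
#' @inheritParams great_binomial
#' @return Data frame per term: `hit_in_term`, `term_genes`,
#'   `hit_genes`, `total_genes`, `p_value`, `p_bonferroni`.
#' @export
gene_hypergeometric <- function(selected_sites, term_to_genes, domains) {
  terms <- term_gene_list(term_to_genes)
  gr_sites <- sites_granges(selected_sites)
  gr_dom <- GenomicRanges::GRanges(domains$chrom,
                                   IRanges::IRanges(domains$start,
                                                    domains$end))
  hit <- domains$gene[IRanges::overlapsAny(gr_dom, gr_sites)]
  all_genes <- unique(domains$gene)
  N <- length(all_genes)
  K <- length(unique(hit))
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(terms[[tm]], all_genes)
    m <- length(tg)
    q <- length(intersect(tg, hit))
    p <- if (m == 0) 1 else phyper(q - 1, m, N - m, K, lower.tail = FALSE)
    data.frame(term = tm, hit_in_term = q, term_genes = m,
               hit_genes = K, total_genes = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Combined GREAT-style term enrichment
#'
#' Runs both the region-based binomial and the gene-based
#' hypergeometric test and flags terms significant in both after
#' Bonferroni correction.
#'
#' @inheritParams great_binomial
#' @param alpha Significance level applied to both corrected P values.
#' @return Merged data frame with an `enriched` flag.
#' @export
great_enrichment <- function(selected_sites, term_to_genes, domains,
                             genome_size, alpha = 0.05) {
  bin <- great_binomial(selected_sites, term_to_genes, domains,
                        genome_size)
  hyp <- gene_hypergeometric(selected_sites, term_to_genes, domains)
  names(bin)[names(bin) == "p_value"] <- "p_binomial"
  names(bin)[names(bin) == "p_bonferroni"] <- "p_binomial_bonf"
  names(hyp)[names(hyp) == "p_value"] <- "p_hypergeometric"
  names(hyp)[names(hyp) == "p_bonferroni"] <- "p_hypergeometric_bonf"
  out <- merge(bin, hyp, by = "term", sort = FALSE)
  out$enriched <- out$p_binomial_bonf < alpha &
    out$p_hypergeometric_bonf < alpha
  out
}

#' Compare effect sizes at cell-type-specific enhancers
#'
#' Effect estimates are z-scaled over every probe in the table; probes
#' in A's enhancers but not B's ("A-specific") are compared with
#' B-specific probes by group means with normal-approximation 95%
#' confidence intervals and a two-sided t test (Welch by default).
#'
#' @param ewas_table EWAS table with `probe_id` and `estimate`.
#' @param enhancers_a,enhancers_b Probe ids inside each cell type's
#'   enhancers.
#' @param labels Length-2 labels for the two groups.
#' @param var_equal Use the classical equal-variance Student t test.
#' @return List with a two-row `groups` data frame (mean, CI, n) and
#'   `p_value`.
#' @export
enhancer_specificity_compare <- function(ewas_table, enhancers_a,
                                         enhancers_b,
                                         labels = c("A_specific",
                                                    "B_specific"),
                                         var_equal = FALSE) {
  z <- (ewas_table$estimate - mean(ewas_table$estimate)) /
    sd(ewas_table$estimate)
  ids <- ewas_table$probe_id
  a_spec <- ids %in% enhancers_a & !(ids %in% enhancers_b)
  b_spec <- ids %in% enhancers_b & !(ids %in% enhancers_a)
  if (sum(a_spec) < 2 || sum(b_spec) < 2)
    stop("each specific-enhancer group needs at least two sites")
  za <- z[a_spec]
  zb <- z[b_spec]
  ci <- function(x) mean(x) + c(-1, 1) * 1.96 * sd(x) / sqrt(length(x))
  groups <- data.frame(group = labels, n = c(length(za), length(zb)),
                       mean = c(mean(za), mean(zb)),
                       ci_lower = c(ci(za)[1], ci(zb)[1]),
                       ci_upper = c(ci(za)[2], ci(zb)[2]))
  tt <- t.test(za, zb, var.equal = var_equal)
  list(groups = groups, p_value = tt$p.value,
       statistic = unname(tt$statistic))
}

#' Probe ids lying in given chromatin states for one cell type
#'
#' @param annotation A `probe_annotation`.
#' @param cell_type Cell type whose segmentation to use.
#' @param states States to match (default: enhancer states).
#' @return Character vector of probe ids.
#' @export
probes_in_states <- function(annotation, cell_type,
                             states = enhancer_states()) {
  st <- annotation$probes[[paste0("state_", cell_type)]]
  annotation$probes$probe_id[st %in% states]
}
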