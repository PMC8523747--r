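test_that("site annotation matches a linear-scan oracle and conventions", {
  ann <- small_annotation(seed = 70, n_probes = 100)
  dir <- file.path(tempdir(), "ann_enr")
  write_annotation(ann, dir)
  bed <- file.path(dir, "chromhmm_monocyte.bed")
  sites <- ann$probes[, c("probe_id", "chrom", "pos")]
  res <- annotate_sites(sites, bed,
                        island_map = setNames(ann$probes$island_relation,
                                              ann$probes$probe_id))
  # oracle: direct findInterval against the 1-based segments
  seg <- ann$segments$monocyte
  oracle <- seg$state[findInterval(sites$pos, seg$start)]
  expect_equal(res$state, oracle)
  expect_equal(res$state, ann$probes$state_monocyte)
  expect_equal(res$island_relation, ann$probes$island_relation)

  # boundary convention: BED is 0-based half-open, so a 1-based site at
  # the written `end` belongs to that interval, `end + 1` to the next
  s2 <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                   pos = c(seg$end[1], seg$end[1] + 1))
  r2 <- annotate_sites(s2, bed)
  expect_equal(r2$state, seg$state[1:2])

  # malformed overlapping segments: first interval wins, with warning
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 50), c(100, 150)),
                               state = c("Enh", "Quies"))
  expect_warning(
    r3 <- annotate_sites(data.frame(probe_id = "x", chrom = "chr1",
                                    pos = 60), gr),
    "overlap")
  expect_equal(r3$state, "Enh")
})

test_that("composition enrichment reports folds and sane proportions", {
  ann <- small_annotation(seed = 71, n_probes = 500)
  states <- data.frame(probe_id = ann$probes$probe_id,
                       state = ann$probes$state_monocyte)
  enh_ids <- probes_in_states(ann, "monocyte")
  # set made exclusively of enhancer sites: fold = 1 / background prop
  comp <- composition_enrichment(enh_ids, states, "state")
  enh_rows <- comp[comp$category %in% enhancer_states(), ]
  expect_equal(sum(enh_rows$n_set), length(enh_ids))
  expect_equal(sum(comp$n_set), length(enh_ids))
  # proportions sum to one within set and background
  expect_equal(sum(comp$prop_set), 1)
  expect_equal(sum(comp$prop_background), 1)
  # uniformly drawn set: ratios near 1, no tiny P values expected
  set.seed(5)
  rnd <- sample(states$probe_id, 200)
  comp2 <- composition_enrichment(rnd, states, "state")
  big <- comp2[comp2$set_size * comp2$prop_background > 10, ]
  expect_true(all(abs(big$ratio - 1) < 0.6))
  expect_equal(comp2$p_bonferroni,
               pmin(1, comp2$p_value * nrow(comp2)))
})

test_that("regulatory domains follow basal-plus-extension rules", {
  sizes <- c(chr1 = 1e6)
  # single gene mid-chromosome: basal +- max extension, clipped
  one <- data.frame(gene = "G1", chrom = "chr1", tss = 5e5, strand = "+")
  d1 <- build_regulatory_domains(one, 5000, 1000, 1e6, sizes)
  expect_equal(d1$start, 1)          # clipped at chromosome start
  expect_equal(d1$end, 1e6)          # clipped at chromosome end
  expect_equal(d1$basal_start, 5e5 - 5000)
  expect_equal(d1$basal_end, 5e5 + 1000)

  # two adjacent genes: extensions stop at each other's basal edge
  two <- data.frame(gene = c("A", "B"), chrom = "chr1",
                    tss = c(4e5, 5e5), strand = c("+", "-"))
  d2 <- build_regulatory_domains(two, 5000, 1000, 1e6, sizes)
  a <- d2[d2$gene == "A", ]
  b <- d2[d2$gene == "B", ]
  # B is on the minus strand: basal is tss - 1000 .. tss + 5000
  expect_equal(b$basal_start, 5e5 - 1000)
  expect_equal(b$basal_end, 5e5 + 5000)
  expect_equal(a$end, b$basal_start - 1)
  expect_equal(b$start, a$basal_end + 1)
  expect_equal(a$start, 1)
  expect_equal(b$end, 1e6)

  # gene whose basal window would cross position zero is clipped
  near0 <- data.frame(gene = "Z", chrom = "chr1", tss = 2000,
                      strand = "+")
  d3 <- build_regulatory_domains(near0, 5000, 1000, 1e4, sizes)
  expect_equal(d3$basal_start, 1)
  expect_equal(d3$start, 1)
})

test_that("GREAT binomial matches direct summation", {
  sizes <- c(chr1 = 1e5)
  tss <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                    tss = c(25000, 75000), strand = "+")
  dom <- build_regulatory_domains(tss, 5000, 1000, 20000, sizes)
  terms <- list(T_half = "G1", T_all = c("G1", "G2"))
  # coverage fraction oracle by brute-force base-pair counting
  covered <- function(genes) {
    v <- logical(1e5)
    for (g in genes) {
      d <- dom[dom$gene == g, ]
      v[d$start:d$end] <- TRUE
    }
    mean(v)
  }
  set.seed(6)
  sites <- data.frame(chrom = "chr1",
                      pos = sample.int(1e5, 40))
  res <- great_binomial(sites, terms, dom, genome_size = 1e5)
  for (tm in names(terms)) {
    row <- res[res$term == tm, ]
    expect_equal(row$p_t, covered(terms[[tm]]), tolerance = 1e-12)
    # direct summation oracle for the upper tail
    oracle <- sum(dbinom(row$k:row$n, row$n, row$p_t))
    expect_equal(row$p_value, oracle, tolerance = 1e-12)
  }
  # p = 0.5, n = 10, k = 5 upper tail equals direct summation
  whole <- data.frame(gene = "W", chrom = "chr1", tss = 5e4,
                      strand = "+")
  dom_w <- data.frame(gene = "W", chrom = "chr1", start = 1,
                      end = 5e4, basal_start = 1, basal_end = 5e4)
  s10 <- data.frame(chrom = "chr1", pos = c(seq(1, 5e4, length.out = 5),
                                            seq(50001, 1e5,
                                                length.out = 5)))
  r10 <- great_binomial(s10, list(TT = "W"), dom_w, genome_size = 1e5)
  expect_equal(r10$k, 5)
  expect_equal(r10$p_value, sum(dbinom(5:10, 10, 0.5)),
               tolerance = 1e-9)
  # a term covering the whole genome: k = n and P = 1
  dom_full <- data.frame(gene = "W", chrom = "chr1", start = 1,
                         end = 1e5, basal_start = 1, basal_end = 1e5)
  rf <- great_binomial(s10, list(TT = "W"), dom_full, genome_size = 1e5)
  expect_equal(rf$k, rf$n)
  expect_equal(rf$p_value, 1)
})

test_that("gene hypergeometric test matches brute-force summation", {
  sizes <- c(chr1 = 1e5)
  tss <- data.frame(gene = paste0("G", 1:8), chrom = "chr1",
                    tss = seq(10000, 94000, length.out = 8),
                    strand = "+")
  dom <- build_regulatory_domains(tss, 2000, 500, 4000, sizes)
  # sites hitting the basal domains of G1..G3 only
  sites <- data.frame(chrom = "chr1", pos = tss$tss[1:3])
  terms <- list(T1 = c("G1", "G2"), T2 = c("G7", "G8"),
                T3 = paste0("G", 1:8))
  res <- gene_hypergeometric(sites, terms, dom)
  expect_equal(res$hit_genes[1], 3)
  brute <- function(q, m, N, K) {
    sum(vapply(q:min(m, K), function(i)
      choose(m, i) * choose(N - m, K - i) / choose(N, K), numeric(1)))
  }
  for (tm in names(terms)) {
    row <- res[res$term == tm, ]
    expect_equal(row$p_value,
                 brute(row$hit_in_term, row$term_genes, row$total_genes,
                       row$hit_genes), tolerance = 1e-12)
  }
  # no term genes hit: P stays large
  expect_gte(res$p_value[res$term == "T2"], 0.5)
  # all and only term genes hit: the minimum achievable P
  expect_equal(res$p_value[res$term == "T1"],
               brute(2, 2, 8, 3), tolerance = 1e-12)
  # combined GREAT wrapper flags doubly significant terms only
  gg <- great_enrichment(sites, terms, dom, genome_size = 1e5)
  expect_true(all(gg$enriched %in% c(TRUE, FALSE)))
  expect_equal(gg$p_binomial_bonf, pmin(1, gg$p_binomial * 3))
})

test_that("enhancer specificity comparison detects planted shifts", {
  set.seed(7)
  tab <- data.frame(probe_id = paste0("cg", 1:2000),
                    estimate = rnorm(2000))
  a_ids <- paste0("cg", 1:200)
  b_ids <- paste0("cg", 201:400)
  # identical distributions: no significant difference on average
  r0 <- enhancer_specificity_compare(tab, a_ids, b_ids)
  expect_gt(r0$p_value, 1e-4)
  # +1 SD shift planted in group A
  tab2 <- tab
  tab2$estimate[1:200] <- tab2$estimate[1:200] + 1
  r1 <- enhancer_specificity_compare(tab2, a_ids, b_ids)
  expect_lt(r1$p_value, 1e-10)
  expect_gt(r1$groups$mean[1], r1$groups$mean[2])
  # z-scaling: overall mean 0, SD 1 reference
  expect_lt(abs(mean(r1$groups$mean * r1$groups$n) / 400), 1)
  # probes in both enhancer sets belong to neither specific group
  r2 <- enhancer_specificity_compare(tab2, a_ids,
                                     c(b_ids, a_ids[1:50]))
  expect_equal(r2$groups$n[1], 150)
  expect_error(enhancer_specificity_compare(tab, "cg1", "cg2"),
               "at least two")
})
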