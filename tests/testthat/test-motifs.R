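# naive position-by-position scorer, independent of the vectorized path
naive_score <- function(seq, pwm, pseudocount = 0) {
  S <- log_odds_matrix(pwm, pseudocount)
  w <- ncol(S)
  score_str <- function(s) {
    ch <- strsplit(s, "")[[1]]
    best <- -Inf
    for (i in seq_len(nchar(s) - w + 1)) {
      tot <- 0
      for (j in seq_len(w)) {
        row <- match(ch[i + j - 1], c("A", "C", "G", "T"))
        tot <- tot + if (is.na(row)) 0 else S[row, j]
      }
      best <- max(best, tot)
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  max(score_str(seq), score_str(rc))
}

test_that("log-odds scoring gives 2 bits per consensus base", {
  det <- list(id = "DET", family = "X",
              matrix = matrix(c(1, 0, 0, 0), 4, 6,
                              dimnames = list(c("A", "C", "G", "T"),
                                              NULL)),
              background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  S <- log_odds_matrix(det)
  expect_equal(unname(S["A", 1]), 2)
  expect_equal(score_region("AAAAAA", S), 12)
  # reverse complement of the consensus scores identically
  expect_equal(score_region("TTTTTT", S), 12)
  # N bases contribute zero log-odds
  expect_equal(score_region("AAANAA", S), 10)
})

test_that("vectorized scorer matches the naive oracle on random input", {
  set.seed(1)
  pwms <- make_pwm_set(n_motifs = 3, seed = 2)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
          collapse = ""), character(1))
  for (pwm in pwms) {
    expect_equal(score_regions(seqs, pwm),
                 vapply(seqs, naive_score, numeric(1), pwm = pwm,
                        USE.NAMES = FALSE), tolerance = 1e-12)
  }
  # strand symmetry on whole regions
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  expect_equal(score_regions(rc, pwms[[1]]),
               score_regions(seqs, pwms[[1]]), tolerance = 1e-12)
})

test_that("region extraction slices [pos - flank, pos + flank)", {
  set.seed(3)
  genome <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                  collapse = "")
  fasta <- Biostrings::DNAStringSet(setNames(genome, "chr1"))
  sites <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                      pos = c(1000, 3000), score = c(2, 1))
  rr <- extract_regions(sites, fasta, flank = 100)
  expect_s3_class(rr, "ranked_regions")
  expect_equal(unname(nchar(rr$sequences)), c(200, 200))
  # 1-based slice 900..1099 for the site at 1000
  expect_equal(unname(rr$sequences["a"]), substr(genome, 900, 1099))
  expect_equal(unname(rr$sequences["b"]), substr(genome, 2900, 3099))
  # ranked by decreasing score
  expect_equal(names(rr$sequences), c("a", "b"))
  # clipping near the contig start warns and shortens
  s2 <- data.frame(probe_id = "c", chrom = "chr1", pos = 50, score = 1)
  expect_warning(rr2 <- extract_regions(s2, fasta, 100), "clipped")
  expect_equal(unname(rr2$sequences["c"]), substr(genome, 1, 149))
})

test_that("composite score averages z-normalized effects", {
  a <- c(cg1 = 1.0, cg2 = 2.0, cg3 = 0.5, cg4 = 3.0, cg5 = 1.5)
  expect_equal(composite_score(a, a), (a - mean(a)) / sd(a))
  expect_equal(composite_score(a, -a), setNames(rep(0, 5), names(a)))
  b <- c(cg1 = 0.2, cg2 = 1.1, cg3 = 0.9, cg4 = 2.2, cg5 = 0.6)
  manual <- ((a - mean(a)) / sd(a) + (b - mean(b)) / sd(b)) / 2
  expect_equal(composite_score(a, b), manual)
  # alignment by names
  expect_equal(composite_score(a, rev(b)), manual)
})

test_that("partition-maximized Fisher equals a brute-force scan", {
  set.seed(4)
  pwms <- make_pwm_set(n_motifs = 4, seed = 5)
  sim <- simulate_motif_regions(pwms, n_regions = 120,
                                planted_top_fraction = 0.25, seed = 6)
  rr <- list(sequences = sim$sequences, scores = sim$scores)
  res <- ame_partition_fisher(rr, pwms)
  # brute force: every partition, fisher.test one-sided
  for (k in seq_along(pwms)) {
    hits <- score_regions(sim$sequences, pwms[[k]]) >= 0
    n <- length(hits)
    ps <- vapply(1:(n - 1), function(i) {
      tab <- matrix(c(sum(hits[1:i]), i - sum(hits[1:i]),
                      sum(hits[-(1:i)]),
                      n - i - sum(hits[-(1:i)])), 2)
      fisher.test(tab, alternative = "greater")$p.value
    }, numeric(1))
    expect_equal(res$p_value[k], min(ps), tolerance = 1e-9)
    expect_equal(res$best_partition[k], which.min(ps))
    expect_equal(res$e_value[k],
                 min(1, min(ps) * length(pwms) * (n - 1)))
    expect_gte(res$e_value[k], res$p_value[k])
  }
  # the planted motif is detected near the planted boundary
  planted <- res[res$motif == sim$motif, ]
  expect_true(planted$enriched)
  expect_lt(abs(planted$best_partition - 30), 12)
  expect_error(ame_partition_fisher(
    list(sequences = sim$sequences, scores = rev(sim$scores)), pwms),
    "decreasing")
})

test_that("degenerate partitions and long motifs are handled", {
  pwms <- make_pwm_set(n_motifs = 2, width_range = c(4, 4), seed = 7)
  # two regions, top one a hit, bottom one not: the only partition gives
  # one-sided Fisher P = 0.5
  det <- list(DET = list(id = "DET", family = "X",
                         matrix = matrix(c(1, 0, 0, 0,  0, 1, 0, 0,
                                           0, 0, 1, 0,  0, 0, 0, 1),
                                         4, 4,
                                         dimnames = list(c("A", "C",
                                                           "G", "T"),
                                                         NULL)),
                         background = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25)))
  rr <- list(sequences = c(top = "CCACGTCC", bottom = "AAAAAAAA"),
             scores = c(2, 1))
  hit_exact <- function(s) s >= 8  # 2 bits x 4 consensus bases
  res <- ame_partition_fisher(rr, det, hit_rule = hit_exact)
  expect_equal(res$p_value, 0.5)
  expect_equal(res$e_value, min(1, 0.5 * 1 * 1))
  # a motif longer than the regions is skipped with a warning
  long <- make_pwm_set(n_motifs = 1, width_range = c(30, 30), seed = 8)
  expect_warning(res2 <- ame_partition_fisher(rr, c(det, long),
                                              hit_rule = hit_exact),
                 "skipped")
  expect_equal(nrow(res2), 1)
})

test_that("family enrichment reproduces printed-style proportions", {
  # 25 ETS motifs of which 21 enriched; 50 others of which 5 enriched
  res <- data.frame(
    motif = paste0("M", 1:75),
    family = rep(c("ETS", "OTHER"), c(25, 50)),
    enriched = c(rep(c(TRUE, FALSE), c(21, 4)),
                 rep(c(TRUE, FALSE), c(5, 45))))
  fam <- family_enrichment(res)
  ets <- fam[fam$family == "ETS", ]
  expect_equal(ets$n_enriched, 21)
  expect_equal(ets$n_total, 25)
  expect_equal(ets$proportion, 0.84)
  expect_equal(ets$p_value,
               fisher.test(matrix(c(21, 4, 5, 45), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # nothing enriched anywhere: every family P = 1
  res0 <- res
  res0$enriched <- FALSE
  fam0 <- suppressWarnings(family_enrichment(res0))
  expect_true(all(fam0$p_value == 1))
  # family covering all motifs: degenerate margin
  res1 <- res
  res1$family <- "ALL"
  fam1 <- suppressWarnings(family_enrichment(res1))
  expect_equal(fam1$p_value, 1)
})

test_that("MEME minimal format round-trips", {
  pwms <- make_pwm_set(n_motifs = 3, seed = 9,
                       background = c(A = 0.3, C = 0.2, G = 0.2,
                                      T = 0.3))
  path <- file.path(tempdir(), "motifs.meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), names(pwms))
  for (k in seq_along(pwms)) {
    expect_equal(unname(back[[k]]$matrix), unname(pwms[[k]]$matrix),
                 tolerance = 1e-5)
    expect_equal(back[[k]]$background, pwms[[k]]$background,
                 tolerance = 1e-5)
    expect_equal(back[[k]]$family, pwms[[k]]$family)
  }
  # background line optional -> uniform default
  lines <- readLines(path)
  bg_at <- grep("Background", lines)
  writeLines(lines[-c(bg_at, bg_at + 1)], path)
  back2 <- read_meme(path)
  expect_equal(unname(back2[[1]]$background), rep(0.25, 4))
})
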