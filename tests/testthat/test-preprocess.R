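test_that("beta/M transforms match known values and invert", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  set.seed(1)
  b <- runif(500, 1e-5, 1 - 1e-5)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  # strictly monotone
  bs <- sort(b)
  expect_true(all(diff(beta_to_m(bs)) > 0))
  # boundary clipping keeps M finite
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
  expect_error(beta_to_m(1.2), "0, 1")
})

test_that("probe QC applies each exclusion rule on a crafted array", {
  # 6 probes x 4 samples: one zero-signal probe, one low-bead probe,
  # one chrX probe, one cross-reactive probe -> exactly 2 survivors
  probes <- paste0("cg", 1:6)
  samples <- paste0("S", 1:4)
  beta <- matrix(0.5, 6, 4, dimnames = list(probes, samples))
  detp <- matrix(0.001, 6, 4, dimnames = list(probes, samples))
  beads <- matrix(10L, 6, 4, dimnames = list(probes, samples))
  beta[1, 2] <- 0; beads[1, 2] <- 0L          # zero signal
  beads[2, 3] <- 2L                           # < 3 beads
  ann <- data.frame(probe_id = probes,
                    chrom = c(rep("chr1", 3), "chrX", "chr1", "chr1"))
  qc <- filter_probes(list(beta = beta, detection_p = detp,
                           bead_count = beads),
                      ann, cross_reactive_list = "cg5")
  expect_setequal(qc$probes, c("cg3", "cg6"))
  expect_setequal(qc$samples, samples)
  rep <- setNames(qc$report$n, qc$report$rule)
  # cg1 fails both the zero-signal and (bead count 0) the low-bead rule
  expect_equal(unname(rep[c("zero_signal", "low_beads", "sex_chromosome",
                            "cross_reactive", "surviving_probes")]),
               c(1, 2, 1, 1, 2))

  # all-clean array: everything survives
  qc2 <- filter_probes(list(beta = matrix(0.5, 6, 4,
                                          dimnames = list(probes, samples)),
                            detection_p = detp, bead_count =
                              matrix(10L, 6, 4,
                                     dimnames = list(probes, samples))),
                       data.frame(probe_id = probes, chrom = "chr1"))
  expect_setequal(qc2$probes, probes)

  # disabled thresholds: only list/sex rules act
  qc3 <- filter_probes(list(beta = beta, detection_p = detp,
                            bead_count = beads),
                       ann, snp_probe_list = "cg6",
                       detection_p_max = 1, min_beads = 0)
  expect_setequal(qc3$probes, c("cg2", "cg3", "cg5"))
  expect_error(filter_probes(list(beta = beta, detection_p = detp,
                                  bead_count = beads),
                             ann, cross_reactive_list = probes),
               "survive")
})

test_that("probe QC drops low call-rate samples first and is idempotent", {
  set.seed(2)
  probes <- paste0("cg", 1:40)
  samples <- paste0("S", 1:6)
  beta <- matrix(runif(240, 0.2, 0.8), 40, 6,
                 dimnames = list(probes, samples))
  detp <- matrix(0.001, 40, 6, dimnames = list(probes, samples))
  beads <- matrix(9L, 40, 6, dimnames = list(probes, samples))
  detp[1:10, 1] <- 0.5     # sample S1 fails 25% of calls
  detp[11, 2] <- 0.5       # probe cg11 fails in one retained sample
  ann <- data.frame(probe_id = probes, chrom = "chr1")
  raw <- list(beta = beta, detection_p = detp, bead_count = beads)
  qc <- filter_probes(raw, ann)
  expect_false("S1" %in% qc$samples)
  # cg1..cg10 only failed in the dropped sample, so they survive;
  # cg11 has call rate 4/5 = 0.8 among retained samples
  expect_true(all(paste0("cg", 1:10) %in% qc$probes))
  expect_false("cg11" %in% qc$probes)

  # idempotence: re-filtering the filtered data removes nothing
  raw2 <- lapply(raw, function(m) m[qc$probes, qc$samples])
  qc2 <- filter_probes(raw2, ann)
  expect_setequal(qc2$probes, qc$probes)
  expect_setequal(qc2$samples, qc$samples)
})

test_that("cell-fraction deconvolution recovers exact and noisy mixtures", {
  ann <- small_annotation(seed = 5, n_probes = 300)
  refs <- make_reference_profiles(ann, c("granulocyte", "monocyte"),
                                  seed = 6)
  disc <- attr(refs, "discriminative")
  # exact 0.3/0.7 mixture, no noise
  mix <- 0.3 * refs["granulocyte", ] + 0.7 * refs["monocyte", ]
  beta <- matrix(mix, ncol = 1,
                 dimnames = list(colnames(refs), "S1"))
  f <- estimate_cell_fractions(beta, refs, disc)
  expect_equal(unname(f["S1", ]), c(0.3, 0.7), tolerance = 1e-6)
  # a pure sample maps to an indicator vector
  pure <- matrix(refs["monocyte", ], ncol = 1,
                 dimnames = list(colnames(refs), "S2"))
  f2 <- estimate_cell_fractions(pure, refs, disc)
  expect_equal(unname(f2["S2", ]), c(0, 1), tolerance = 1e-6)
  # identical profiles are not identifiable
  bad <- refs; bad["monocyte", ] <- bad["granulocyte", ]
  expect_error(estimate_cell_fractions(beta, bad, disc), "identifiable")
})

test_that("deconvolution of simulated cohorts has small error", {
  sim <- small_cohort(seed = 11, n_probes = 500)
  refs <- sim$references
  f <- estimate_cell_fractions(sim$cohort$beta, refs,
                               attr(refs, "discriminative"))
  err <- abs(f - sim$cohort$cell_fractions[rownames(f), colnames(f)])
  expect_lt(mean(err), 0.05)
  expect_true(all(f >= 0))
  expect_true(all(rowSums(f) <= 1 + 1e-9))
})

test_that("PCA outlier screen flags displaced samples only", {
  set.seed(3)
  M <- matrix(rnorm(2000 * 40), 2000, 40,
              dimnames = list(NULL, paste0("S", 1:40)))
  sc <- pca_outlier_screen(M, n_components = 7, z_max = 6)
  expect_false(any(sc$flagged))
  # displace one sample far along the first component
  M2 <- M
  M2[1:500, 40] <- M2[1:500, 40] + 6
  sc2 <- pca_outlier_screen(M2, n_components = 7, z_max = 6)
  expect_true(sc2$flagged[40])
  expect_lt(sum(sc2$flagged), 3)
  # infinite cutoff flags nothing
  expect_false(any(pca_outlier_screen(M2, z_max = Inf)$flagged))
})

test_that("batch centering aligns batch means and nothing else", {
  set.seed(4)
  M <- matrix(rnorm(50 * 12), 50, 12)
  expect_equal(batch_center(M, rep("A", 12)), M)
  # two batches offset by +1: offset removed exactly
  M2 <- M
  M2[, 7:12] <- M2[, 7:12] + 1
  adj <- batch_center(M2, rep(c("A", "B"), each = 6))
  for (probe in c(1, 25, 50))
    expect_equal(mean(adj[probe, 1:6]), mean(adj[probe, 7:12]))
  # adjusted matrix differs from input only by per-(probe, batch) shifts
  batches <- sample(c("A", "B", "C"), 12, replace = TRUE)
  adj2 <- batch_center(M, batches)
  delta <- adj2 - M
  for (b in unique(batches)) {
    cols <- which(batches == b)
    expect_equal(apply(delta[, cols, drop = FALSE], 1, var),
                 rep(0, 50), tolerance = 1e-20)
  }
})

test_that("variant-call filtering applies VAF, MAF and germline rules", {
  calls <- data.frame(
    sample_id = paste0("S", 1:6), gene = "TET2",
    vaf = c(0.015, 0.45, 0.45, 0.10, 0.05, 0.41),
    maf = c(0, 0, 0, 0.02, 0, 0),
    twin_concordant = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  kept <- filter_variant_calls(calls)
  # VAF 1.5% fails the 2% cutoff; VAF 45% twin-concordant is germline;
  # MAF 2% exceeds 1%; the rest are retained
  expect_setequal(kept$sample_id, c("S3", "S5"))
  # boundary: VAF exactly 2% is retained
  expect_equal(nrow(filter_variant_calls(
    data.frame(sample_id = "S", gene = "G", vaf = 0.02, maf = 0,
               twin_concordant = FALSE))), 1)
})
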