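#' Convert methylation beta values to M values
#'
#' M values are the log2-logit transform of the methylation fraction,
#' `M = log2(beta / (1 - beta))`.  Beta values at or near the boundary are
#' clipped to `[eps, 1 - eps]` before the transform so that M values stay
#' finite; with the default `eps = 1e-6` the induced bias is negligible
#' relative to array noise.
#'
#' @param beta Numeric vector or matrix of beta values in `[0, 1]`.
#' @param eps Boundary clipping constant, strictly positive.
#' @return Object of the same shape holding M values.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param M Numeric vector or matrix of M values.
#' @return Beta values in `(0, 1)`.
#' @export
m_to_beta <- function(M) {
  1 / (1 + 2^(-M))
}

#' Probe- and sample-level quality control for a raw methylation array
#'
#' Applies the standard exclusion rules for Illumina methylation arrays:
#' samples with detection call rate below `min_call_rate` are dropped
#' first; a probe then survives if and only if it has no zero-signal
#' sample, no sample with fewer than `min_beads` beads, a per-probe call
#' rate of at least `min_call_rate` (a probe/sample call fails when its
#' detection P value exceeds `detection_p_max`), is autosomal, and appears
#' in neither the cross-reactive nor the SNP-affected exclusion list.
#'
#' @param raw List with matrices `beta`, `detection_p`, `bead_count`
#'   (probes x samples, identical dimnames).  An optional logical matrix
#'   `zero_signal` marks probe/sample pairs with zero signal; when absent,
#'   `beta == 0 & bead_count == 0` stands in.
#' @param annotation Probe manifest data frame with columns `probe_id`
#'   and `chrom`; probes on `chrX`/`chrY` are removed.
#' @param cross_reactive_list,snp_probe_list Character vectors of probe
#'   ids to exclude (may be empty).
#' @param detection_p_max Maximum detection P value for a passing call.
#' @param min_beads Minimum bead count.
#' @param min_call_rate Minimum call rate for both samples and probes.
#' @return List with `probes` (surviving probe ids), `samples`
#'   (surviving sample ids) and `report`, a data frame counting
#'   exclusions per rule.
#' @export
filter_probes <- function(raw, annotation,
                          cross_reactive_list = character(),
                          snp_probe_list = character(),
                          detection_p_max = 0.01, min_beads = 3,
                          min_call_rate = 0.95) {
  beta <- raw$beta
  detp <- raw$detection_p
  beads <- raw$bead_count
  stopifnot(identical(dim(beta), dim(detp)),
            identical(dim(beta), dim(beads)),
            !is.null(rownames(beta)), !is.null(colnames(beta)))
  zero <- raw$zero_signal
  if (is.null(zero)) zero <- beta == 0 & beads == 0

  fail_call <- detp > detection_p_max
  # sample-level screen first, then probe-level rates on retained samples
  sample_rate <- 1 - colMeans(fail_call)
  keep_samples <- sample_rate >= min_call_rate
  fail_call <- fail_call[, keep_samples, drop = FALSE]
  zero <- zero[, keep_samples, drop = FALSE]
  beads <- beads[, keep_samples, drop = FALSE]

  probe_ids <- rownames(beta)
  ann <- annotation[match(probe_ids, annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("all probes must be present in the manifest")

  rule_zero <- rowSums(zero) > 0
  rule_beads <- apply(beads, 1, min) < min_beads
  rule_rate <- (1 - rowMeans(fail_call)) < min_call_rate
  rule_sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  rule_xr <- probe_ids %in% cross_reactive_list
  rule_snp <- probe_ids %in% snp_probe_list

  keep <- !(rule_zero | rule_beads | rule_rate | rule_sex | rule_xr | rule_snp)
  if (!any(keep))
    stop("no probes survive quality control")

  report <- data.frame(
    rule = c("sample_call_rate", "zero_signal", "low_beads",
             "probe_call_rate", "sex_chromosome", "cross_reactive",
             "snp_probe", "surviving_probes"),
    n = c(sum(!keep_samples), sum(rule_zero), sum(rule_beads),
          sum(rule_rate), sum(rule_sex), sum(rule_xr), sum(rule_snp),
          sum(keep)))
  list(probes = probe_ids[keep],
       samples = colnames(beta)[keep_samples],
       report = report)
}

#' Reference-based cell-type deconvolution
#'
#' Estimates leukocyte subtype fractions per sample by constrained
#' projection of its beta profile onto reference cell-type methylomes
#' (the Houseman approach): minimize `||beta_s - t(ref) %*% f||^2` over
#' the discriminative probes, subject to `f >= 0` and `sum(f) <= 1`.
#' Solved exactly as a quadratic program.
#'
#' @param beta Probes x samples beta matrix.
#' @param reference_profiles Cell types x probes beta matrix (rownames
#'   are cell-type labels).
#' @param discriminative_probes Probe ids to restrict the projection to;
#'   default all shared probes.
#' @return Samples x cell-types matrix of fractions, with attribute
#'   `residual_mass` (`1 - rowSums`) per sample.
#' @export
estimate_cell_fractions <- function(beta, reference_profiles,
                                    discriminative_probes = NULL) {
  if (nrow(reference_profiles) < 2)
    stop("at least two reference cell types are required")
  probes <- intersect(rownames(beta), colnames(reference_profiles))
  if (!is.null(discriminative_probes))
    probes <- intersect(probes, discriminative_probes)
  if (length(probes) < nrow(reference_profiles))
    stop("too few shared discriminative probes for deconvolution")
  R <- reference_profiles[, probes, drop = FALSE]  # q x k
  q <- nrow(R)
  D <- R %*% t(R)
  if (rcond(D) < 1e-10)
    stop("reference profiles are not identifiable (rank deficient)")
  B <- beta[probes, , drop = FALSE]
  # constraints: f_i >= 0 (q rows), -sum(f) >= -1
  Amat <- cbind(diag(q), -1)
  bvec <- c(rep(0, q), -1)
  out <- t(apply(B, 2, function(y) {
    quadprog::solve.QP(D, as.numeric(R %*% y), Amat, bvec)$solution
  }))
  out[out < 0 & out > -1e-10] <- 0
  colnames(out) <- rownames(R)
  attr(out, "residual_mass") <- 1 - rowSums(out)
  out
}

#' Flag outlier samples in principal component space
#'
#' Runs a PCA on samples (probes as variables, centered) and flags any
#' sample whose score lies more than `z_max` robust standard deviations
#' (median/MAD) from the center in any of the first `n_components`
#' components.  Flags are reported; removal is left to the caller.
#'
#' @param M Probes x samples M-value matrix.
#' @param n_components Number of leading components to screen.
#' @param z_max Robust z-score cutoff.
#' @return Data frame with `sample`, `flagged`, and `max_abs_z`.
#' @export
pca_outlier_screen <- function(M, n_components = 7, z_max = 6) {
  n <- ncol(M)
  n_components <- min(n_components, n - 1)
  stopifnot(n >= n_components + 1)
  pc <- prcomp(t(M), center = TRUE, scale. = FALSE, rank. = n_components)
  z <- apply(pc$x, 2, function(s) {
    scale <- mad(s)
    if (scale < .Machine$double.eps) scale <- sd(s)
    if (scale < .Machine$double.eps) return(rep(0, length(s)))
    (s - median(s)) / scale
  })
  z <- abs(matrix(z, nrow = n))
  data.frame(sample = colnames(M),
             flagged = apply(z, 1, max) > z_max,
             max_abs_z = apply(z, 1, max))
}

#' Center batches per probe
#'
#' A documented stand-in for full batch correction: for every probe, each
#' batch's mean is shifted to the probe's grand mean, leaving
#' within-batch variance untouched.
#'
#' @param M Probes x samples M-value matrix.
#' @param batch_ids Batch label per sample (length `ncol(M)`).
#' @return Adjusted matrix of the same shape.
#' @export
batch_center <- function(M, batch_ids) {
  stopifnot(length(batch_ids) == ncol(M))
  grand <- rowMeans(M)
  out <- M
  for (b in unique(batch_ids)) {
    idx <- which(batch_ids == b)
    out[, idx] <- M[, idx, drop = FALSE] -
      rowMeans(M[, idx, drop = FALSE]) + grand
  }
  out
}

#' Filter somatic variant calls for CHIP analyses
#'
#' Keeps a call if and only if its variant allele frequency (VAF) is at
#' least `vaf_min`, its population minor allele frequency is at most
#' `maf_max`, and it is not a suspected germline variant, i.e. a variant
#' with VAF inside `germline_band` that is concordant between co-twins.
#'
#' @param calls Data frame with columns `sample_id`, `gene`, `vaf`,
#'   `maf`, `twin_concordant` (logical).
#' @param vaf_min Minimum VAF (clone-size floor).
#' @param maf_max Maximum population MAF.
#' @param germline_band Length-2 numeric, the heterozygous VAF band.
#' @return The retained rows of `calls`.
#' @export
filter_variant_calls <- function(calls, vaf_min = 0.02, maf_max = 0.01,
                                 germline_band = c(0.40, 0.60)) {
  stopifnot(all(c("vaf", "maf", "twin_concordant") %in% names(calls)))
  in_band <- calls$vaf >= germline_band[1] & calls$vaf <= germline_band[2]
  keep <- calls$vaf >= vaf_min & calls$maf <= maf_max &
    !(in_band & calls$twin_concordant)
  calls[keep, , drop = FALSE]
}
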