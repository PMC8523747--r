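#' Specify an epigenome-wide association design
#'
#' Describes one per-CpG association analysis: which mutation (or its
#' VAF) is the exposure, which covariates to adjust for, how many
#' principal components of the M matrix to include, whether Houseman
#' cell fractions enter the model, and whether twin pairs contribute a
#' random intercept.
#'
#' Samples carrying a driver mutation other than the exposure gene are
#' excluded by default, so the contrast is carriers versus samples
#' without any CHIP mutation.
#'
#' @param exposure Gene name (e.g. `"TET2"`) for a mutated-vs-no-CHIP
#'   contrast, or `"vaf_<gene>"` to use the clone size as a continuous
#'   exposure.
#' @param covariates Metadata columns to adjust for.
#' @param n_pcs Number of leading principal components of the centered
#'   M matrix to include.
#' @param use_cell_fractions Include estimated cell fractions (all but
#'   the first cell type, which is absorbed by the intercept).
#' @param grouping `"pair"` for the twin mixed model, `"none"` for
#'   ordinary least squares.
#' @param exclude_other_mutations Drop carriers of other driver genes.
#' @param moderated Apply limma-style empirical-Bayes variance
#'   moderation to the OLS fits (off by default; requires limma).
#' @return Object of class `ewas_design`.
#' @export
ewas_design <- function(exposure = "TET2",
                        covariates = c("age", "sex", "batch"),
                        n_pcs = 4, use_cell_fractions = TRUE,
                        grouping = c("pair", "none"),
                        exclude_other_mutations = TRUE,
                        moderated = FALSE) {
  grouping <- match.arg(grouping)
  structure(list(exposure = exposure, covariates = covariates,
                 n_pcs = n_pcs, use_cell_fractions = use_cell_fractions,
                 grouping = grouping,
                 exclude_other_mutations = exclude_other_mutations,
                 moderated = moderated),
            class = "ewas_design")
}

# Orthogonal within-pair transform that diagonalizes the
# compound-symmetry covariance: pair-sum rows (variance 1 + 2 theta),
# pair-difference rows (variance 1) and singleton rows (variance
# 1 + theta), all times sigma^2.
cs_transform <- function(X, Y, pair_ids) {
  n <- nrow(X)
  stopifnot(nrow(Y) == n, length(pair_ids) == n)
  tab <- table(pair_ids[!is.na(pair_ids)])
  if (any(tab > 2)) stop("pair ids must group at most two samples")
  pair_lab <- names(tab)[tab == 2]
  single <- which(is.na(pair_ids) | pair_ids %in% names(tab)[tab == 1])
  i1 <- match(pair_lab, pair_ids)
  i2 <- n + 1L - match(pair_lab, rev(pair_ids))
  s <- 1 / sqrt(2)
  Xs <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) * s
  Xd <- (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) * s
  Ys <- (Y[i1, , drop = FALSE] + Y[i2, , drop = FALSE]) * s
  Yd <- (Y[i1, , drop = FALSE] - Y[i2, , drop = FALSE]) * s
  X1 <- X[single, , drop = FALSE]
  Y1 <- Y[single, , drop = FALSE]
  list(G0 = crossprod(Xd), G1 = crossprod(X1), G2 = crossprod(Xs),
       B0 = crossprod(Xd, Yd), B1 = crossprod(X1, Y1),
       B2 = crossprod(Xs, Ys),
       S0 = colSums(Yd^2), S1 = colSums(Y1^2), S2 = colSums(Ys^2),
       n = n, n1 = length(single), n2 = length(pair_lab))
}

# Batch compound-symmetry REML across the columns of Y (samples x probes
# transposed outside); returns one row per probe.
fit_mixed_matrix <- function(Y, X, pair_ids, expo_idx) {
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  tr <- cs_transform(X, Y, pair_ids)
  fit <- reml_cs_batch(tr$G0, tr$G1, tr$G2, tr$B0, tr$B1, tr$B2,
                       tr$S0, tr$S1, tr$S2, tr$n, tr$n1, tr$n2,
                       expo_idx, -12, 12, 1e-8)
  stat <- fit$estimate / fit$se
  data.frame(estimate = fit$estimate, se = fit$se, statistic = stat,
             p_value = 2 * pt(-abs(stat), df = fit$df), df = fit$df,
             theta = fit$theta, boundary_theta = fit$boundary == 1)
}

# Vectorized OLS across probes: Y is samples x probes, X shared.
fit_ols_matrix <- function(Y, X, expo_idx, moderated = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  XtXinv <- chol2inv(chol(crossprod(X)))
  coefs <- XtXinv %*% crossprod(X, Y)      # p x m
  resid <- Y - X %*% coefs
  df <- n - p
  s2 <- colSums(resid^2) / df
  est <- coefs[expo_idx, ]
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("limma is required for moderated = TRUE")
    sq <- limma::squeezeVar(s2, df)
    s2 <- sq$var.post
    df <- df + sq$df.prior
  }
  se <- sqrt(s2 * XtXinv[expo_idx, expo_idx])
  stat <- est / se
  data.frame(estimate = est, se = se, statistic = stat,
             p_value = 2 * pt(-abs(stat), df = df), df = df)
}

#' Fit the twin mixed model at a single CpG
#'
#' Compound-symmetry model `y = X beta + b_pair + e` with a shared
#' random intercept per twin pair, fitted by REML with the variance
#' ratio `theta = sigma2_pair / sigma2_resid` profiled out by
#' golden-section search on `log(theta)`.  The Wald test on the exposure
#' column uses a t reference with Satterthwaite degrees of freedom
#' computed from the observed REML information (capped at
#' `n - rank(X)`; at the `theta = 0` boundary, where the model collapses
#' to OLS, the exact residual df is used).
#'
#' @param y Outcome vector (M values).
#' @param X Design matrix, full rank, including the intercept.
#' @param pair_ids Pair labels (`NA` for singletons; at most 2 per pair).
#' @param exposure Column index of the exposure in `X`.
#' @return One-row data frame: `estimate`, `se`, `statistic`, `p_value`,
#'   `theta` (fitted variance ratio), `boundary_theta`.
#' @export
fit_cpg_mixed <- function(y, X, pair_ids, exposure = 2) {
  fit_mixed_matrix(matrix(y, ncol = 1), X, pair_ids, exposure)
}

#' Fit the per-CpG linear model by ordinary least squares
#'
#' Classical OLS coefficient, standard error and two-sided t test for
#' the exposure column; with `moderated = TRUE`, residual variances are
#' shrunk limma-style before the test.
#'
#' @inheritParams fit_cpg_mixed
#' @param moderated Empirical-Bayes variance moderation flag.
#' @return One-row data frame: `estimate`, `se`, `statistic`, `p_value`.
#' @export
fit_cpg_ols <- function(y, X, exposure = 2, moderated = FALSE) {
  fit_ols_matrix(matrix(y, ncol = 1), X, exposure, moderated)
}

build_design_matrix <- function(meta, design, M = NULL,
                                cell_fractions = NULL) {
  exposure_col <- design$exposure
  dat <- data.frame(.exposure = as.numeric(meta[[exposure_col]]))
  for (v in design$covariates) dat[[v]] <- meta[[v]]
  fml <- stats::as.formula(paste("~ .exposure +",
                                 paste(design$covariates, collapse = " + ")))
  X <- model.matrix(fml, dat)
  if (design$use_cell_fractions && !is.null(cell_fractions)) {
    cf <- cell_fractions[, -1, drop = FALSE]  # first absorbed by intercept
    colnames(cf) <- paste0("frac_", colnames(cf))
    X <- cbind(X, cf)
  }
  if (design$n_pcs > 0 && !is.null(M)) {
    k <- min(design$n_pcs, ncol(M) - 1)
    pc <- prcomp(t(M), center = TRUE, scale. = FALSE, rank. = k)
    pcs <- pc$x[, seq_len(k), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(k))
    X <- cbind(X, pcs)
  }
  # exposure sits right after the intercept
  expo_idx <- match(".exposure", colnames(X))
  list(X = X, expo_idx = expo_idx)
}

#' Run an epigenome-wide association analysis
#'
#' One association model per probe, with the model chosen by the
#' design's grouping: a twin-pair random-intercept mixed model or plain
#' least squares.  Covariate principal components are computed on the
#' centered M matrix of the analysis samples.
#'
#' @param cohort A `methylation_cohort` (fields `M`, `samples`, and
#'   optionally `cell_fractions`).
#' @param design An [ewas_design()].
#' @return An EWAS table: data frame with `probe_id`, `estimate` (M
#'   units), `se`, `statistic`, `p_value`, `direction` and, for the
#'   mixed model, `theta`/`boundary_theta`.
#' @export
run_ewas <- function(cohort, design = ewas_design()) {
  meta <- cohort$samples
  gene <- sub("^vaf_", "", design$exposure)
  genes <- sub("^vaf_", "", grep("^vaf_", names(meta), value = TRUE))
  keep <- rep(TRUE, nrow(meta))
  if (design$exclude_other_mutations)
    for (g in setdiff(genes, gene)) keep <- keep & !meta[[g]]
  meta <- meta[keep, , drop = FALSE]
  M <- cohort$M[, keep, drop = FALSE]
  cf <- cohort$cell_fractions
  if (!is.null(cf)) cf <- cf[keep, , drop = FALSE]

  expo <- as.numeric(meta[[design$exposure]])
  if (length(unique(expo[!is.na(expo)])) < 2 ||
      (is.logical(meta[[design$exposure]]) &&
       min(table(meta[[design$exposure]])) < 2))
    stop("fewer than 2 samples per exposure group")

  dm <- build_design_matrix(meta, design, M = M, cell_fractions = cf)
  Y <- t(M)
  fit <- if (design$grouping == "pair")
    fit_mixed_matrix(Y, dm$X, meta$pair_id, dm$expo_idx)
  else
    fit_ols_matrix(Y, dm$X, dm$expo_idx, moderated = design$moderated)
  fit <- cbind(probe_id = rownames(M), fit)
  fit$direction <- sign(fit$estimate)
  rownames(fit) <- NULL
  fit
}

#' Genomic inflation factor
#'
#' `lambda = median(chisq_obs) / median(chisq_expected)`, where each
#' two-sided P value is converted to a 1-df chi-squared quantile and the
#' expected median is `qchisq(0.5, 1)`.
#'
#' @param p_values P values in (0, 1].
#' @return The scalar inflation factor.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Check the direction of VAF association at selected sites
#'
#' Regresses the M value at each selected site on the clone size (VAF),
#' optionally adjusting for covariates and a twin-pair random intercept,
#' and counts sites whose VAF coefficient is positive.
#'
#' @param M Probes x samples M matrix.
#' @param sites Probe ids to test.
#' @param vaf Numeric VAF per sample (0 for non-carriers).
#' @param covariates Optional data frame / matrix of adjustment
#'   covariates.
#' @param pair_ids Optional pair labels to use the mixed model.
#' @return List with `n_positive`, `n_total` and `fraction`.
#' @export
vaf_direction_check <- function(M, sites, vaf, covariates = NULL,
                                pair_ids = NULL) {
  sites <- intersect(sites, rownames(M))
  if (!length(sites)) return(list(n_positive = 0L, n_total = 0L,
                                  fraction = NaN))
  X <- cbind(`(Intercept)` = 1, vaf = vaf)
  if (!is.null(covariates)) {
    cv <- model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                              drop = FALSE]
    X <- cbind(X, cv)
  }
  Y <- t(M[sites, , drop = FALSE])
  fit <- if (is.null(pair_ids)) fit_ols_matrix(Y, X, 2)
         else fit_mixed_matrix(Y, X, pair_ids, 2)
  npos <- sum(fit$estimate > 0, na.rm = TRUE)
  list(n_positive = npos, n_total = length(sites),
       fraction = npos / length(sites))
}
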