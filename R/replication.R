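#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction, matching the convention used for the
#' cohort-level contingency tests.  A zero row or column margin yields
#' `P = 1` with a warning.
#'
#' @param table 2x2 integer matrix.
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin in 2x2 table; returning P = 1")
    return(list(statistic = 0, p_value = 1))
  }
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - E)^2 / E)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided P by the point-probability method: the sum of the
#' probabilities of all tables (with the observed margins) whose
#' hypergeometric point probability does not exceed that of the observed
#' table.  One-sided alternatives give the upper/lower hypergeometric
#' tail for the top-left cell.
#'
#' @param table 2x2 integer matrix.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return The P value.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided",
                                                    "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  a <- table[1, 1]
  m <- sum(table[1, ])            # white balls
  n_ <- sum(table[2, ])           # black balls
  k <- sum(table[, 1])            # drawn
  if (m + n_ == 0 || k == 0 || k == m + n_ || m == 0 || n_ == 0) {
    warning("zero margin in 2x2 table; returning P = 1")
    return(1)
  }
  support <- max(0, k - n_):min(k, m)
  dens <- dhyper(support, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  p <- switch(alternative,
    two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]))
  min(p, 1)
}

#' Dispatch between chi-squared and Fisher tests
#'
#' Uses the chi-squared test unless the expected value of one or more
#' cells is below five, in which case Fisher's exact test is used.
#'
#' @param table 2x2 integer matrix.
#' @return List with `p_value`, `method` (`"chisq"` or `"fisher"`) and,
#'   for chi-squared, the `statistic`.
#' @export
assoc_test_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)))
  tot <- sum(table)
  if (tot == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin in 2x2 table; returning P = 1")
    return(list(p_value = 1, method = "chisq", statistic = 0))
  }
  E <- outer(rowSums(table), colSums(table)) / tot
  if (min(E) < 5) {
    list(p_value = fisher_exact_2x2(table), method = "fisher",
         statistic = NA_real_)
  } else {
    ct <- chi_square_2x2(table)
    list(p_value = ct$p_value, method = "chisq",
         statistic = ct$statistic)
  }
}

#' Directional concordance of a site set in a second cohort
#'
#' Of the member sites also present in the target EWAS table (sites lost
#' to quality control are dropped from numerator and denominator), how
#' many have the expected effect direction there.
#'
#' @param site_set A `hyper_set` or character vector of probe ids.
#' @param target_ewas EWAS table from the replication cohort.
#' @param direction Expected direction (defaults to the set's own).
#' @return List with `n_available`, `n_concordant` and `fraction`.
#' @export
direction_concordance <- function(site_set, target_ewas,
                                  direction = NULL) {
  ids <- if (inherits(site_set, "hyper_set")) site_set$probe_ids
         else site_set
  if (is.null(direction))
    direction <- if (inherits(site_set, "hyper_set")) site_set$direction
                 else 1
  avail <- intersect(ids, target_ewas$probe_id)
  if (!length(avail)) {
    warning("no member sites available in the target cohort")
    return(list(n_available = 0L, n_concordant = 0L, fraction = NaN))
  }
  dir <- target_ewas$direction[match(avail, target_ewas$probe_id)]
  nc <- sum(dir == direction, na.rm = TRUE)
  list(n_available = length(avail), n_concordant = nc,
       fraction = nc / length(avail))
}

#' Test set membership against direction in a target cohort
#'
#' Builds the 2x2 table of (in set vs out of set) by (direction-positive
#' vs not) over the target cohort's probes and applies the
#' chi-squared/Fisher dispatcher.  P values that underflow are reported
#' via the `p_label` sentinel `"<1e-300"`.
#'
#' @inheritParams direction_concordance
#' @return List with `table`, `p_value`, `p_label` and `method`.
#' @export
concordance_test <- function(site_set, target_ewas, direction = NULL) {
  ids <- if (inherits(site_set, "hyper_set")) site_set$probe_ids
         else site_set
  if (is.null(direction))
    direction <- if (inherits(site_set, "hyper_set")) site_set$direction
                 else 1
  in_set <- target_ewas$probe_id %in% ids
  is_dir <- target_ewas$direction == direction
  tab <- matrix(c(sum(in_set & is_dir), sum(in_set & !is_dir),
                  sum(!in_set & is_dir), sum(!in_set & !is_dir)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("in_set", "out_of_set"),
                                direction = c("concordant", "other")))
  res <- assoc_test_2x2(tab)
  p_label <- if (res$p_value < 1e-300) "<1e-300"
             else format(res$p_value)
  list(table = tab, p_value = res$p_value, p_label = p_label,
       method = res$method)
}

#' Quadrant counts for two cohorts' effect signs
#'
#' For probes shared between two EWAS tables, counts the four
#' (sign in A) x (sign in B) quadrants, optionally restricted by
#' per-cohort significance flags — the corner counts of a cross-cohort
#' volcano comparison.
#'
#' @param resultsA,resultsB EWAS tables.
#' @param p_cutoff_a,p_cutoff_b Optional P cutoffs; when given, only
#'   probes significant in the respective cohort are counted.
#' @return Data frame with `sign_a`, `sign_b` and `n`.
#' @export
set_overlap_report <- function(resultsA, resultsB, p_cutoff_a = NULL,
                               p_cutoff_b = NULL) {
  shared <- intersect(resultsA$probe_id, resultsB$probe_id)
  ia <- match(shared, resultsA$probe_id)
  ib <- match(shared, resultsB$probe_id)
  keep <- rep(TRUE, length(shared))
  if (!is.null(p_cutoff_a)) keep <- keep & resultsA$p_value[ia] <= p_cutoff_a
  if (!is.null(p_cutoff_b)) keep <- keep & resultsB$p_value[ib] <= p_cutoff_b
  sa <- resultsA$direction[ia][keep]
  sb <- resultsB$direction[ib][keep]
  grid <- expand.grid(sign_a = c(1, -1), sign_b = c(1, -1))
  grid$n <- mapply(function(x, y) sum(sa == x & sb == y),
                   grid$sign_a, grid$sign_b)
  grid
}
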