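#' Directionality curve of an EWAS table
#'
#' At every distinct P value cutoff `c` (inclusive), the proportion of
#' sites with `P <= c` whose effect sign matches `direction`.  This is
#' the curve used to pick the significance threshold: as the cutoff
#' decreases, a genuine one-sided signal drives the proportion toward 1.
#'
#' @param ewas_table EWAS table with `p_value` and `direction` columns.
#' @param direction `+1` for hypermethylation, `-1` for hypomethylation.
#' @return Data frame with `cutoff` (increasing distinct P values),
#'   `n_below` and `proportion`.
#' @export
directionality_curve <- function(ewas_table, direction = 1) {
  tab <- ewas_table[!is.na(ewas_table$p_value), , drop = FALSE]
  if (!nrow(tab)) stop("empty EWAS table")
  ord <- order(tab$p_value)
  p <- tab$p_value[ord]
  hit <- tab$direction[ord] == direction
  cum_hit <- cumsum(hit)
  n <- seq_along(p)
  last <- !duplicated(p, fromLast = TRUE)  # inclusive handling of ties
  data.frame(cutoff = p[last], n_below = n[last],
             proportion = cum_hit[last] / n[last])
}

#' Select the directionality-based significance threshold
#'
#' Returns the largest observed P value `c` such that at least
#' `min_proportion` of the sites with `P <= c` have the requested
#' direction, or `NA` when no cutoff qualifies.  Ties in P are handled
#' inclusively: all sites at the boundary P value count.
#'
#' @inheritParams directionality_curve
#' @param min_proportion Required directional proportion (default 95%).
#' @return The cutoff P value, or `NA_real_` if none qualifies.
#' @export
select_threshold <- function(ewas_table, direction = 1,
                             min_proportion = 0.95) {
  curve <- directionality_curve(ewas_table, direction)
  ok <- curve$proportion >= min_proportion
  if (!any(ok)) return(NA_real_)
  max(curve$cutoff[ok])
}

#' Build the directional significant-site set
#'
#' Applies the proportion-threshold rule: when a cutoff exists, the set
#' is every site with the requested direction and `P <=` cutoff.  When
#' no cutoff reaches `min_proportion` (the AML-like situation), the
#' `fallback_k` smallest-P directional sites are taken instead and the
#' rule is recorded as `top_k`.
#'
#' @inheritParams select_threshold
#' @param fallback_k Number of sites for the top-K fallback.
#' @param source Label for the originating cohort.
#' @return Object of class `hyper_set`: list with `probe_ids`,
#'   `direction`, `rule`, `cutoff`, `k` and `source`.
#' @export
select_hyper_set <- function(ewas_table, direction = 1,
                             min_proportion = 0.95, fallback_k = 2000,
                             source = "cohort") {
  tab <- ewas_table[!is.na(ewas_table$p_value), , drop = FALSE]
  cutoff <- select_threshold(tab, direction, min_proportion)
  directional <- tab[tab$direction == direction, , drop = FALSE]
  if (!is.na(cutoff)) {
    ids <- directional$probe_id[directional$p_value <= cutoff]
    rule <- "proportion_threshold"
    k <- NA_integer_
  } else {
    rule <- "top_k"
    k <- fallback_k
    if (fallback_k > nrow(directional)) {
      warning("fallback_k exceeds the number of directional sites; ",
              "taking all ", nrow(directional))
      k <- nrow(directional)
    }
    ord <- order(directional$p_value)
    ids <- directional$probe_id[ord[seq_len(k)]]
    cutoff <- NA_real_
  }
  structure(list(probe_ids = ids, direction = direction, rule = rule,
                 cutoff = cutoff, k = k, source = source),
            class = "hyper_set")
}

#' @export
print.hyper_set <- function(x, ...) {
  cat(sprintf("<hyper_set> %d sites, direction %+d, rule %s",
              length(x$probe_ids), x$direction, x$rule))
  if (!is.na(x$cutoff)) cat(sprintf(", cutoff P = %.3g", x$cutoff))
  if (!is.na(x$k)) cat(sprintf(", k = %d", x$k))
  cat(sprintf(" [%s]\n", x$source))
  invisible(x)
}
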