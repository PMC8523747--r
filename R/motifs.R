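#' Log-odds scoring matrix for a PWM
#'
#' `log2((p + pseudocount) / background)` per base and position.  A
#' fifth row of zeros handles `N` bases (they contribute background-level
#' evidence, i.e. nothing).
#'
#' @param pwm A PWM (list with `matrix` and `background`).
#' @param pseudocount Added to probabilities before the log; the default
#'   0 keeps a deterministic consensus at exactly 2 bits per position
#'   under a uniform background.
#' @return 5 x width numeric matrix, rows `A, C, G, T, N`.
#' @export
log_odds_matrix <- function(pwm, pseudocount = 0) {
  m <- pwm$matrix
  bg <- pwm$background[rownames(m)]
  S <- log2((m + pseudocount) / bg)
  rbind(S, N = 0)
}

encode_seq <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]],
             c("A", "C", "G", "T"))
  x[is.na(x)] <- 5L
  x
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

score_one_strand <- function(code, S) {
  L <- length(code)
  w <- ncol(S)
  if (L < w) return(-Inf)
  npos <- L - w + 1
  total <- numeric(npos)
  for (j in seq_len(w))
    total <- total + S[code[j:(j + npos - 1)], j]
  max(total)
}

#' Maximum log-odds score of a PWM over a region
#'
#' Slides the motif over every position of the region on both the
#' forward and the reverse-complement strand and returns the maximum
#' log-odds score.
#'
#' @param seq A DNA string.
#' @param S A [log_odds_matrix()].
#' @return The maximum score in bits.
#' @export
score_region <- function(seq, S) {
  max(score_one_strand(encode_seq(seq), S),
      score_one_strand(encode_seq(revcomp(seq)), S))
}

#' Score many regions against one PWM
#'
#' @param sequences Character vector of DNA regions.
#' @param pwm A PWM.
#' @param pseudocount Passed to [log_odds_matrix()].
#' @return Numeric vector of max log-odds scores.
#' @export
score_regions <- function(sequences, pwm, pseudocount = 0) {
  S <- log_odds_matrix(pwm, pseudocount)
  vapply(sequences, score_region, numeric(1), S = S, USE.NAMES = FALSE)
}

#' Extract ranked 200 bp regions around CpG sites
#'
#' The region for a site at position `pos` is `[pos - flank,
#' pos + flank)` on the reference strand (length `2 * flank`).  Regions
#' running off a contig end are clipped with a warning.
#'
#' @param sites Data frame with `probe_id`, `chrom`, `pos` and a
#'   ranking `score` column (e.g. effect estimates or a
#'   [composite_score()]).
#' @param fasta A `DNAStringSet` (or FASTA path) whose names match
#'   `sites$chrom`.
#' @param flank Half-width in bp.
#' @return Object of class `ranked_regions`: list with `sequences`
#'   (named by probe id, sorted by decreasing score), `scores`, and
#'   `clipped` flags.
#' @export
extract_regions <- function(sites, fasta, flank = 100) {
  if (is.character(fasta) && length(fasta) == 1)
    fasta <- read_fasta(fasta)
  stopifnot(all(c("probe_id", "chrom", "pos", "score") %in% names(sites)),
            !anyNA(sites$score))
  lens <- setNames(Biostrings::width(fasta), names(fasta))
  start <- sites$pos - flank
  end <- sites$pos + flank - 1
  L <- lens[sites$chrom]
  clipped <- start < 1 | end > L
  if (any(clipped))
    warning(sum(clipped), " region(s) clipped at contig boundaries")
  start <- pmax(1, start)
  end <- pmin(L, end)
  seqs <- vapply(seq_len(nrow(sites)), function(i)
    as.character(Biostrings::subseq(fasta[[sites$chrom[i]]],
                                    start[i], end[i])), character(1))
  names(seqs) <- sites$probe_id
  ord <- order(sites$score, decreasing = TRUE)
  structure(list(sequences = seqs[ord], scores = sites$score[ord],
                 clipped = clipped[ord]),
            class = "ranked_regions")
}

#' Combine two effect-estimate vectors into a composite ranking score
#'
#' Each vector is z-normalized (mean 0, SD 1) over the scored sites and
#' the composite is their arithmetic mean.  Named vectors are aligned by
#' name.
#'
#' @param effects_a,effects_b Numeric vectors of effect estimates.
#' @return Numeric vector of composite scores.
#' @export
composite_score <- function(effects_a, effects_b) {
  if (!is.null(names(effects_a)) && !is.null(names(effects_b))) {
    shared <- intersect(names(effects_a), names(effects_b))
    effects_a <- effects_a[shared]
    effects_b <- effects_b[shared]
  }
  stopifnot(length(effects_a) == length(effects_b))
  z <- function(x) (x - mean(x)) / sd(x)
  (z(effects_a) + z(effects_b)) / 2
}

#' Ranked motif enrichment by partition-maximized Fisher tests
#'
#' For each motif, regions are labelled hits by `hit_rule` applied to
#' their maximum log-odds scores; for every partition point `i` the
#' one-sided Fisher (hypergeometric upper-tail) P value of the 2x2 table
#' (top-`i` vs rest) x (hit vs not) is computed, and the minimum over
#' partitions is corrected into an E value: `E = min(1, P* x #motifs x
#' #partitions)` (set `correct_partitions = FALSE` to correct for the
#' motif count only).  A motif is enriched when `E < alpha`.
#'
#' @param ranked_regions A `ranked_regions` (or list with `sequences`
#'   and decreasing `scores`).
#' @param pwm_set Named list of PWMs.
#' @param hit_rule Function mapping a score vector to logical hits;
#'   default: max log-odds >= 0 bits (the match is likelier under the
#'   motif than under the background).
#' @param pseudocount Passed to the scorer.
#' @param max_partitions Partition grid cap: every rank for up to this
#'   many regions, evenly spaced beyond.
#' @param correct_partitions Include the partition count in the
#'   correction (conservative default).
#' @param alpha E-value significance level.
#' @return Data frame per motif: `motif`, `family`, `n_hits`,
#'   `best_partition`, `p_value`, `e_value`, `enriched`.
#' @export
ame_partition_fisher <- function(ranked_regions, pwm_set,
                                 hit_rule = function(s) s >= 0,
                                 pseudocount = 0,
                                 max_partitions = 1000,
                                 correct_partitions = TRUE,
                                 alpha = 0.05) {
  seqs <- ranked_regions$sequences
  n <- length(seqs)
  stopifnot(n >= 2)
  if (is.unsorted(rev(ranked_regions$scores)))
    stop("ranking scores must be sorted in decreasing order")
  min_len <- min(nchar(seqs))
  parts <- if (n - 1 <= max_partitions) seq_len(n - 1)
           else unique(round(seq(1, n - 1, length.out = max_partitions)))
  rows <- lapply(pwm_set, function(pwm) {
    if (ncol(pwm$matrix) > min_len) {
      warning("motif ", pwm$id, " longer than the shortest region; skipped")
      return(NULL)
    }
    hit <- hit_rule(score_regions(seqs, pwm, pseudocount))
    H <- sum(hit)
    a <- cumsum(hit)[parts]
    p <- phyper(a - 1, H, n - H, parts, lower.tail = FALSE)
    best <- which.min(p)
    correction <- length(pwm_set) *
      if (correct_partitions) length(parts) else 1
    e <- min(1, p[best] * correction)
    data.frame(motif = pwm$id,
               family = if (is.null(pwm$family)) NA_character_
                        else pwm$family,
               n_hits = H, best_partition = parts[best],
               p_value = p[best], e_value = e, enriched = e < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif-family enrichment summary
#'
#' For each family, tests whether its motifs are enriched more often
#' than all other motifs (2x2 family membership by enriched flag,
#' two-sided Fisher's exact test).
#'
#' @param results An [ame_partition_fisher()] table.
#' @param family_map Optional named vector motif id -> family,
#'   overriding the `family` column.
#' @return Data frame per family: `n_enriched`, `n_total`,
#'   `proportion`, `p_value`.
#' @export
family_enrichment <- function(results, family_map = NULL) {
  fam <- if (is.null(family_map)) results$family
         else unname(family_map[results$motif])
  families <- sort(unique(fam[!is.na(fam)]))
  rows <- lapply(families, function(f) {
    in_f <- fam == f
    tab <- matrix(c(sum(in_f & results$enriched),
                    sum(in_f & !results$enriched),
                    sum(!in_f & results$enriched),
                    sum(!in_f & !results$enriched)),
                  nrow = 2, byrow = TRUE)
    data.frame(family = f, n_enriched = tab[1, 1],
               n_total = sum(tab[1, ]),
               proportion = tab[1, 1] / sum(tab[1, ]),
               p_value = fisher_exact_2x2(tab))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
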