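# Cutoff filtering and cross-population "x-trend" candidate selection.
#
# A desirable ON/OFF promoter is read more often in the medium/high bins of
# the activated arm and more often in the low bin of the non-activated arm;
# the selection keeps variants showing either trend and ranks them by a
# symmetric log-ratio score.

count_matrix <- function(table) {
  stopifnot("key" %in% names(table))
  as.matrix(table[, setdiff(names(table), "key"), drop = FALSE])
}

#' Remove variants with too few reads overall
#'
#' Drops variants whose summed read count across the six sorted populations
#' falls below `min_total` (default 150, the screen's published cutoff).
#' Idempotent; removed keys are reported in the `"removed"` attribute.
#'
#' @param table Count table (tibble: `key` + six population columns).
#' @param min_total Minimum summed count to retain a variant.
#' @return Filtered count table; `attr(, "removed")` holds the removed keys.
#' @export
filter_low_count <- function(table, min_total = 150) {
  m <- count_matrix(table)
  keep <- rowSums(m) >= min_total
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- table$key[!keep]
  out
}

#' Convert counts to within-population frequencies
#'
#' `f(v, p) = (count + pseudocount) / (total_p + pseudocount * n_variants)`,
#' so each population's frequencies sum to 1 and every frequency is
#' strictly positive when `pseudocount > 0` (Anscombe-style stabilization;
#' downstream log-ratio scores stay finite).
#'
#' @param table Count table (tibble: `key` + population columns).
#' @param pseudocount Added to every cell (default 0.5).
#' @return Frequency table with the same shape; population read totals are
#'   kept in the `"totals"` attribute.
#' @export
normalize_frequencies <- function(table, pseudocount = 0.5) {
  m <- count_matrix(table)
  totals <- colSums(m)
  if (any(totals == 0) && pseudocount == 0) {
    abort(sprintf("Population '%s' has zero total reads.",
                  colnames(m)[totals == 0][1]))
  }
  f <- sweep(m + pseudocount, 2, totals + pseudocount * nrow(m), "/")
  out <- tibble(key = table$key, as_tibble(f))
  attr(out, "totals") <- totals
  out
}

#' Score the activated/non-activated cross-population trend
#'
#' For each variant with frequencies `f` in the six populations, the
#' activated trend flag is
#' `f[act_low] < min(f[act_med], f[act_high])` and the relaxed trend flag is
#' `f[non_low] > max(f[non_med], f[non_high])`; a variant is a candidate if
#' either holds. The ranking score is the symmetric log-ratio
#' `S = log2((f_am + f_ah) / (2 f_al)) + log2((2 f_nl) / (f_nm + f_nh))`,
#' which is 0 for a flat profile, positive for the desired "x" pattern, and
#' negates when the two arms are swapped (with bin order reversed). The
#' score is this package's operationalization of the published ranking,
#' which states the trend criteria without a formula.
#'
#' @param freqs Frequency table from [normalize_frequencies()] with the six
#'   standard population columns.
#' @return Tibble: `key`, `activated_trend`, `relaxed_trend`, `candidate`,
#'   `score`.
#' @export
trend_scores <- function(freqs) {
  missing <- setdiff(POPULATION_LABELS, names(freqs))
  if (length(missing) > 0) {
    abort(sprintf("Frequency table is missing population(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  f <- freqs
  act <- f$act_low < pmin(f$act_med, f$act_high)
  rel <- f$non_low > pmax(f$non_med, f$non_high)
  score <- log2((f$act_med + f$act_high) / (2 * f$act_low)) +
    log2((2 * f$non_low) / (f$non_med + f$non_high))
  tibble(
    key = f$key,
    activated_trend = act,
    relaxed_trend = rel,
    candidate = act | rel,
    score = score
  )
}

#' Select and rank candidate promoters from a count table
#'
#' The full selection pipeline: low-count filtering, frequency
#' normalization, trend scoring, retention of variants satisfying the trend
#' condition (`"or"`: either arm shows the trend, the published criterion;
#' `"and"`: both, a stricter option), ranking by score (ties broken by
#' total read count, then key), and truncation to the top `n_top`
#' (default 17, the published shortlist size).
#'
#' @param table Count table (`key` + the six standard population columns).
#' @param n_top Number of candidates to keep.
#' @param min_total Low-count cutoff passed to [filter_low_count()].
#' @param pseudocount Passed to [normalize_frequencies()].
#' @param mode `"or"` or `"and"` trend condition.
#' @return Tibble of candidates: `key`, the six counts, the six
#'   frequencies (suffix `_freq`), `total`, both trend flags, `score`,
#'   `rank` (1 = best); at most `n_top` rows, sorted by rank.
#' @export
select_candidates <- function(table, n_top = 17, min_total = 150,
                              pseudocount = 0.5,
                              mode = c("or", "and")) {
  mode <- match.arg(mode)
  kept <- filter_low_count(table, min_total)
  freqs <- normalize_frequencies(kept, pseudocount)
  tr <- trend_scores(freqs)
  qualifies <- if (mode == "or") {
    tr$activated_trend | tr$relaxed_trend
  } else {
    tr$activated_trend & tr$relaxed_trend
  }
  fr <- freqs
  names(fr)[-1] <- paste0(names(fr)[-1], "_freq")
  out <- kept |>
    mutate(total = rowSums(count_matrix(kept))) |>
    left_join(fr, by = "key") |>
    left_join(tr, by = "key") |>
    filter(qualifies) |>
    arrange(desc(.data$score), desc(.data$total), .data$key) |>
    head(n_top) |>
    mutate(rank = row_number())
  out
}
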