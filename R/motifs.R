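# Per-variable-position base composition of selected candidates. Because
# every variant is keyed by its alleles at the template's variable
# positions, the "multiple sequence alignment" is positional by
# construction: no aligner is run.

#' Per-position base composition of a candidate set
#'
#' For each variable position of the template, tallies the base frequencies
#' over the supplied variants and reports the frequency of the designated
#' allele. The designated allele of a position is defined in this package
#' as the first base of its IUPAC expansion in alphabetical order (Y -> C,
#' S -> C, R -> A); the complementary orientation is always recoverable as
#' `1 - designated_ratio` for two-fold degenerate positions, and
#' [element_summary()] reports both.
#'
#' @param variants Tibble with a `key` column (e.g. from
#'   [select_candidates()]), or a character vector of allele keys.
#' @param template The `degenerate_template` the keys refer to.
#' @param elements Optional element labels per variable position; defaults
#'   to the template's own `element` column when present.
#' @return A tibble with one row per (variable position, allowed base):
#'   `slot`, `index` (0-based template coordinate), `code`, `element`,
#'   `base`, `freq`, `designated` (logical), `designated_ratio` (repeated
#'   within a position). Frequencies sum to 1 within each position.
#' @export
position_profiles <- function(variants, template, elements = NULL) {
  stopifnot(inherits(template, "degenerate_template"))
  keys <- if (is.character(variants)) variants else variants$key
  if (length(keys) == 0) abort("No variants supplied.")
  pos <- template$positions
  if (nrow(pos) == 0) abort("Template has no variable positions.")
  if (any(nchar(keys) != nrow(pos))) {
    abort(sprintf("Variant key '%s' does not have length %d.",
                  keys[nchar(keys) != nrow(pos)][1], nrow(pos)))
  }
  elements <- elements %||%
    (if ("element" %in% names(pos)) pos$element else rep(NA_character_, nrow(pos)))
  km <- matrix(unlist(strsplit(keys, "", fixed = TRUE), use.names = FALSE),
               ncol = nrow(pos), byrow = TRUE)
  rows <- lapply(seq_len(nrow(pos)), function(j) {
    allowed <- sort(pos$allowed[[j]])
    obs <- km[, j]
    bad <- setdiff(unique(obs), allowed)
    if (length(bad) > 0) {
      abort(sprintf(
        "Variant key with base '%s' at slot %d violates code %s (key '%s').",
        bad[1], j, pos$code[j], keys[obs == bad[1]][1]))
    }
    freq <- vapply(allowed, function(b) mean(obs == b), numeric(1))
    tibble(
      slot = j, index = pos$index[j], code = pos$code[j],
      element = elements[j], base = allowed, freq = unname(freq),
      designated = allowed == pos$designated[j],
      designated_ratio = unname(freq[allowed == pos$designated[j]])
    )
  })
  bind_rows(rows)
}

#' Summarise designated-allele ratios per response element
#'
#' Collapses [position_profiles()] to one row per element label and
#' orientation: the min, mean and max of the designated-allele ratio
#' (`orientation = "designated"`) and of its complement
#' (`orientation = "alternate"`, i.e. `1 - ratio`, exact for two-fold
#' degenerate positions). Reporting both orientations guards against the
#' two possible reading conventions of a per-position ratio.
#'
#' @param profiles Output of [position_profiles()].
#' @return Tibble: `element`, `orientation`, `n_positions`, `min`, `mean`,
#'   `max`.
#' @export
element_summary <- function(profiles) {
  per_pos <- profiles |>
    distinct(.data$slot, .data$element, .data$designated_ratio)
  bind_rows(
    per_pos |> mutate(orientation = "designated",
                      ratio = .data$designated_ratio),
    per_pos |> mutate(orientation = "alternate",
                      ratio = 1 - .data$designated_ratio)
  ) |>
    group_by(.data$element, .data$orientation) |>
    summarise(
      n_positions = n(),
      min = min(.data$ratio),
      mean = mean(.data$ratio),
      max = max(.data$ratio),
      .groups = "drop"
    )
}

#' Bar plot of per-position base composition
#'
#' @param profiles Output of [position_profiles()].
#' @return A ggplot object: stacked base frequencies per variable position,
#'   faceted by element.
#' @export
plot_position_profiles <- function(profiles) {
  ggplot2::ggplot(
    profiles,
    ggplot2::aes(factor(.data$slot), .data$freq, fill = .data$base)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$element),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(x = "variable position", y = "base frequency",
                  fill = "base") +
    ggplot2::theme_minimal()
}
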