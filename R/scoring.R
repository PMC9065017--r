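# Promoter activity metrics from per-condition reporter geometric means:
# fold induction, background, synergism, and the composite potency index
#   f(x) = x(GK)/bg(GK) - x/bg + x(GK)/(xG + xK)
# where x is the promoter's GeoMean under the given stimulation and bg is
# the matched-condition GeoMean of the miniTK reference.

CONDITIONS <- c("none", "G", "K", "GK", "H", "GH", "KH", "GKH")
REFERENCE_IDS <- c(minitk = "minitk", uninfected = "uninfected")

#' Assemble a tidy MFI panel
#'
#' The scoring functions consume a long tibble with one row per promoter
#' and stimulation condition: columns `promoter`, `condition` (one of
#' `none`, `G`, `K`, `GK`, `H`, `GH`, `KH`, `GKH`; `G` = IFN-gamma,
#' `K` = TNF-alpha, `H` = hypoxia) and `geomean` (geometric-mean reporter
#' fluorescence, strictly positive). Reference measurements use the
#' reserved promoter ids `"minitk"` (cells carrying the minimal TK core
#' alone) and `"uninfected"` (non-transduced cells in the same well).
#'
#' @param promoter,condition,geomean Vectors of equal length.
#' @return A validated tibble.
#' @export
mfi_panel <- function(promoter, condition, geomean) {
  out <- tibble(promoter = as.character(promoter),
                condition = as.character(condition),
                geomean = as.numeric(geomean))
  validate_mfi(out)
  out
}

validate_mfi <- function(mfi) {
  need <- c("promoter", "condition", "geomean")
  if (!all(need %in% names(mfi))) {
    abort("MFI data needs columns promoter, condition, geomean.")
  }
  bad <- setdiff(unique(mfi$condition), CONDITIONS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(mfi$geomean) | mfi$geomean <= 0)) {
    abort("All geometric means must be finite and > 0.")
  }
  if (anyDuplicated(mfi[, c("promoter", "condition")])) {
    abort("Duplicate (promoter, condition) rows in MFI data.")
  }
  invisible(mfi)
}

mfi_lookup <- function(mfi, promoter, condition, what = "condition") {
  v <- mfi$geomean[mfi$promoter == promoter & mfi$condition == condition]
  if (length(v) != 1) {
    abort(sprintf("Missing %s '%s' for promoter '%s'.",
                  what, condition, promoter))
  }
  v
}

#' Fold induction relative to the unstimulated condition
#'
#' `geomean(condition) / geomean(none)` per promoter; by construction the
#' fold induction of `none` is 1.
#'
#' @param mfi Tidy MFI panel (see [mfi_panel()]).
#' @param conditions Conditions to report (default: every condition present
#'   for each promoter).
#' @return Tibble: `promoter`, `condition`, `fold_induction`.
#' @export
fold_induction <- function(mfi, conditions = NULL) {
  validate_mfi(mfi)
  base <- mfi |>
    filter(.data$condition == "none") |>
    select("promoter", baseline = "geomean")
  missing <- setdiff(unique(mfi$promoter), base$promoter)
  if (length(missing) > 0) {
    abort(sprintf("No 'none' measurement for promoter(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- mfi |>
    left_join(base, by = "promoter") |>
    mutate(fold_induction = .data$geomean / .data$baseline) |>
    select("promoter", "condition", "fold_induction")
  if (!is.null(conditions)) {
    got <- out |> filter(.data$condition %in% conditions)
    miss <- dplyr::anti_join(
      tidyr::expand_grid(promoter = unique(mfi$promoter),
                         condition = conditions),
      got, by = c("promoter", "condition"))
    if (nrow(miss) > 0) {
      abort(sprintf("Missing condition '%s' for promoter '%s'.",
                    miss$condition[1], miss$promoter[1]))
    }
    out <- got
  }
  out
}

#' Synergism of combined IFN-gamma + TNF-alpha stimulation
#'
#' `geomean(GK) / (geomean(G) + geomean(K))` per promoter: 1 at exact
#' additivity, above 1 when the combined response is super-additive.
#' Invariant under rescaling all MFIs by a common factor.
#'
#' @param mfi Tidy MFI panel.
#' @return Tibble: `promoter`, `synergism`.
#' @export
synergism <- function(mfi) {
  validate_mfi(mfi)
  proms <- setdiff(unique(mfi$promoter), REFERENCE_IDS["uninfected"])
  tibble(
    promoter = proms,
    synergism = vapply(proms, function(p) {
      mfi_lookup(mfi, p, "GK") /
        (mfi_lookup(mfi, p, "G") + mfi_lookup(mfi, p, "K"))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Background (basal leakiness) relative to a reference
#'
#' `geomean(none) / reference(none)`: the promoter's unstimulated level
#' relative to either cells carrying the miniTK core alone
#' (`reference = "minitk"`) or non-infected cells in the same well
#' (`reference = "uninfected"`). Only the unstimulated entries are read.
#'
#' @param mfi Tidy MFI panel containing the chosen reference promoter.
#' @param reference `"minitk"` or `"uninfected"`.
#' @return Tibble: `promoter`, `background`.
#' @export
background_ratio <- function(mfi, reference = c("minitk", "uninfected")) {
  reference <- match.arg(reference)
  validate_mfi(mfi)
  if (!reference %in% mfi$promoter) {
    abort(sprintf("Reference '%s' not present in the MFI panel.", reference))
  }
  ref0 <- mfi_lookup(mfi, reference, "none", what = "reference condition")
  proms <- setdiff(unique(mfi$promoter), REFERENCE_IDS)
  tibble(
    promoter = proms,
    background = vapply(proms, function(p) {
      mfi_lookup(mfi, p, "none") / ref0
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Potency index of a promoter
#'
#' The composite score
#' `potency = x(GK)/bg(GK) - x(none)/bg(none) + x(GK)/(x(G) + x(K))`,
#' where `x` is the promoter's GeoMean and `bg` the miniTK reference
#' GeoMean under the matching condition: induced activity over the
#' reference, minus basal leakiness over the reference, plus synergism. At
#' the fixed point — a promoter identical to miniTK in every condition with
#' an exactly additive GK response — the index is `1 - 1 + 1 = 1`.
#'
#' `x_mode` controls the normalization of `x`: `"raw"` (default) uses raw
#' GeoMeans, so the bg divisions provide the normalization; `"fold"` first
#' divides every promoter's (and the reference's) GeoMeans by its own
#' unstimulated level, making the second term identically 1. The published
#' per-promoter index values cannot be reconstructed from published
#' summaries alone, so both readings are exposed; they agree at the fixed
#' point.
#'
#' @param mfi Tidy MFI panel containing the `"minitk"` reference with
#'   conditions `none`, `G`, `K`, `GK`.
#' @param x_mode `"raw"` or `"fold"`.
#' @return Tibble: `promoter`, `term_induced`, `term_background`,
#'   `term_synergy`, `potency`.
#' @export
potency <- function(mfi, x_mode = c("raw", "fold")) {
  x_mode <- match.arg(x_mode)
  validate_mfi(mfi)
  if (!"minitk" %in% mfi$promoter) {
    abort("Potency requires the 'minitk' reference in the MFI panel.")
  }
  proms <- setdiff(unique(mfi$promoter), REFERENCE_IDS)
  rows <- lapply(proms, function(p) {
    x <- vapply(c("none", "G", "K", "GK"),
                function(cc) mfi_lookup(mfi, p, cc), numeric(1))
    bg <- vapply(c("none", "GK"),
                 function(cc) mfi_lookup(mfi, "minitk", cc,
                                         what = "miniTK condition"),
                 numeric(1))
    if (x_mode == "fold") {
      bg <- bg / bg[["none"]]
      x <- x / x[["none"]]
    }
    tibble(
      promoter = p,
      term_induced = x[["GK"]] / bg[["GK"]],
      term_background = x[["none"]] / bg[["none"]],
      term_synergy = x[["GK"]] / (x[["G"]] + x[["K"]])
    )
  })
  bind_rows(rows) |>
    mutate(potency = .data$term_induced - .data$term_background +
             .data$term_synergy)
}

#' Score a panel of promoters
#'
#' One row per promoter combining fold inductions (per stimulation),
#' background, synergism and the potency index, ordered by promoter id.
#' Reference rows (`minitk`, `uninfected`) are consumed, not scored,
#' except that `minitk` itself is scored when `include_reference = TRUE`.
#'
#' @param mfi Tidy MFI panel with the `minitk` reference.
#' @param reference Background reference mode (see [background_ratio()]).
#' @param x_mode Potency normalization (see [potency()]).
#' @return Tibble with columns `promoter`, `fold_G`, `fold_K`, `fold_GK`,
#'   `background`, `synergism`, the three potency terms and `potency`.
#' @export
score_panel <- function(mfi, reference = c("minitk", "uninfected"),
                        x_mode = c("raw", "fold")) {
  reference <- match.arg(reference)
  validate_mfi(mfi)
  proms <- setdiff(unique(mfi$promoter), REFERENCE_IDS)
  if (length(proms) == 0) {
    return(tibble(promoter = character(), fold_G = numeric(),
                  fold_K = numeric(), fold_GK = numeric(),
                  background = numeric(), synergism = numeric(),
                  term_induced = numeric(), term_background = numeric(),
                  term_synergy = numeric(), potency = numeric()))
  }
  fi <- fold_induction(mfi, conditions = c("G", "K", "GK")) |>
    filter(.data$promoter %in% proms) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "fold_induction",
                       names_prefix = "fold_")
  fi <- select(fi, "promoter", "fold_G", "fold_K", "fold_GK")
  fi |>
    left_join(background_ratio(mfi, reference), by = "promoter") |>
    left_join(synergism(mfi), by = "promoter") |>
    left_join(potency(mfi, x_mode), by = "promoter") |>
    arrange(.data$promoter)
}

#' Read a GeoMean table from TSV
#'
#' Accepts either long format (`promoter`, `condition`, `geomean`) or wide
#' format (first column `promoter`, remaining columns named by condition).
#'
#' @param path TSV path.
#' @return A tidy MFI panel.
#' @export
read_mfi <- function(path) {
  raw <- as_tibble(utils::read.delim(path, check.names = FALSE))
  if (all(c("promoter", "condition", "geomean") %in% names(raw))) {
    validate_mfi(raw[, c("promoter", "condition", "geomean")])
  } else {
    if (names(raw)[1] != "promoter") names(raw)[1] <- "promoter"
    long <- tidyr::pivot_longer(raw, -"promoter", names_to = "condition",
                                values_to = "geomean")
    validate_mfi(long)
  }
}
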