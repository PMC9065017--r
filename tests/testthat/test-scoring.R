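panel_row <- function(promoter, none, G, K, GK) {
  tibble::tibble(promoter = promoter,
                 condition = c("none", "G", "K", "GK"),
                 geomean = c(none, G, K, GK))
}

test_that("fold induction divides by the unstimulated geometric mean", {
  mfi <- panel_row("p", none = 100, G = 250, K = 400, GK = 1192)
  fi <- fold_induction(mfi)
  expect_equal(fi$fold_induction[fi$condition == "none"], 1)
  expect_equal(fi$fold_induction[fi$condition == "GK"], 11.92)
  expect_equal(fi$fold_induction[fi$condition == "G"], 2.5)

  # strictly monotone in the stimulated geomean
  hi <- panel_row("p", 100, 250, 400, 1500)
  expect_gt(fold_induction(hi)$fold_induction[4],
            fi$fold_induction[fi$condition == "GK"])

  expect_error(fold_induction(mfi[mfi$condition != "none", ]), "none")
  expect_error(fold_induction(mfi, conditions = "H"), "Missing condition")
})

test_that("synergism is 1 at additivity and scale-invariant", {
  expect_equal(synergism(panel_row("p", 5, 10, 10, 20))$synergism, 1)
  expect_equal(synergism(panel_row("p", 5, 10, 10, 30))$synergism, 1.5)
  a <- synergism(panel_row("p", 5, 13, 21, 47))$synergism
  b <- synergism(panel_row("p", 5 * 37, 13 * 37, 21 * 37, 47 * 37))$synergism
  expect_equal(a, b)
})

test_that("background compares unstimulated levels to the chosen reference", {
  mfi <- dplyr::bind_rows(
    panel_row("p", none = 30, G = 100, K = 100, GK = 300),
    panel_row("minitk", none = 30, G = 31, K = 32, GK = 33),
    panel_row("uninfected", none = 15, G = 15, K = 15, GK = 15)
  )
  expect_equal(background_ratio(mfi, "minitk")$background, 1)
  expect_equal(background_ratio(mfi, "uninfected")$background, 2)

  # only the unstimulated entries are read
  jig <- mfi
  jig$geomean[jig$promoter == "p" & jig$condition == "GK"] <- 9999
  expect_equal(background_ratio(jig, "minitk")$background, 1)

  expect_error(background_ratio(mfi[mfi$promoter != "minitk", ], "minitk"),
               "minitk")
})

test_that("potency hits its fixed point and its arithmetic decomposition", {
  # promoter identical to miniTK with an exactly additive GK response:
  # 1 - 1 + 1 = 1 under both normalizations
  fixed <- dplyr::bind_rows(
    panel_row("p", none = 10, G = 20, K = 30, GK = 50),
    panel_row("minitk", none = 10, G = 20, K = 30, GK = 50)
  )
  expect_equal(potency(fixed, "raw")$potency, 1)
  expect_equal(potency(fixed, "fold")$potency, 1)

  # constructed inputs: 100/10 - 5/5 + 100/(20+30) = 10 - 1 + 2 = 11
  made <- dplyr::bind_rows(
    panel_row("p", none = 5, G = 20, K = 30, GK = 100),
    panel_row("minitk", none = 5, G = 6, K = 7, GK = 10)
  )
  got <- potency(made, "raw")
  expect_equal(got$term_induced, 10)
  expect_equal(got$term_background, 1)
  expect_equal(got$term_synergy, 2)
  expect_equal(got$potency, 11)

  # strictly increasing in the promoter's GK level, all else fixed
  more <- made
  more$geomean[more$promoter == "p" & more$condition == "GK"] <- 120
  expect_gt(potency(more, "raw")$potency, got$potency)

  expect_error(potency(panel_row("p", 1, 2, 3, 4)), "minitk")
})

test_that("all activity metrics are invariant under cytometer rescaling", {
  mfi <- dplyr::bind_rows(
    panel_row("p", none = 12, G = 40, K = 90, GK = 400),
    panel_row("q", none = 50, G = 60, K = 120, GK = 200),
    panel_row("minitk", none = 10, G = 12, K = 14, GK = 18),
    panel_row("uninfected", none = 8, G = 8, K = 8, GK = 8)
  )
  scaled <- mfi
  scaled$geomean <- scaled$geomean * 3.7
  for (mode in c("raw", "fold")) {
    expect_equal(score_panel(scaled, x_mode = mode),
                 score_panel(mfi, x_mode = mode))
  }
})

test_that("panel scoring is complete, ordered, and permutation-invariant", {
  mfi <- dplyr::bind_rows(
    panel_row("b", none = 12, G = 40, K = 90, GK = 400),
    panel_row("a", none = 50, G = 60, K = 120, GK = 200),
    panel_row("minitk", none = 10, G = 12, K = 14, GK = 18)
  )
  sp <- score_panel(mfi)
  expect_equal(sp$promoter, c("a", "b"))
  expect_equal(sp$fold_GK, c(4, 400 / 12))
  expect_equal(sp$background, c(5, 1.2))
  expect_equal(sp$synergism, sp$term_synergy)
  expect_equal(sp$potency,
               sp$term_induced - sp$term_background + sp$term_synergy)

  shuffled <- mfi[rev(seq_len(nrow(mfi))), ]
  expect_equal(score_panel(shuffled), sp)

  empty <- score_panel(panel_row("minitk", 10, 12, 14, 18))
  expect_equal(nrow(empty), 0L)

  # miniTK scored against itself: first two terms cancel, leaving only
  # its synergism term
  with_ref <- dplyr::bind_rows(
    panel_row("minitk_clone", none = 10, G = 12, K = 14, GK = 18),
    panel_row("minitk", none = 10, G = 12, K = 14, GK = 18)
  )
  self <- potency(with_ref)
  expect_equal(self$potency, 18 / 26)
})

test_that("scoring simulated panels recovers the planted synergy ordering", {
  # a validation panel varying the synergy knob (basal varies too and must
  # cancel out of the metric; single-cue responses are held shared so the
  # ordering being recovered is the planted syn ordering)
  for (s in 1:3) {
    withr::with_seed(s, {
      lib <- tibble::tibble(
        key = sprintf("P%02d", 1:50),
        basal = stats::rlnorm(50, 0, 0.5),
        aG = 1,
        aK = 2,
        aH = 0,
        syn = stats::runif(50, 0, 12),
        cell_noise_sd = 0.8
      )
    })
    mfi <- simulated_mfi_panel(lib, n_cells = 8000, seed = 100 * s)
    got <- synergism(mfi)
    ord <- match(got$promoter, lib$key)
    rho <- stats::cor(got$synergism, lib$syn[ord], method = "spearman")
    expect_gt(rho, 0.9)
  }
})

test_that("MFI tables read from TSV in wide and long form", {
  mfi <- dplyr::bind_rows(
    panel_row("p", none = 12, G = 40, K = 90, GK = 400),
    panel_row("minitk", none = 10, G = 12, K = 14, GK = 18)
  )
  long <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(mfi, long, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_mfi(long), mfi, ignore_attr = TRUE)

  wide <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    tidyr::pivot_wider(mfi, names_from = "condition",
                       values_from = "geomean"),
    wide, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_mfi(wide)
  expect_equal(dplyr::arrange(got, promoter, condition),
               dplyr::arrange(mfi, promoter, condition), ignore_attr = TRUE)

  expect_error(mfi_panel("p", "bogus", 1), "Unknown condition")
  expect_error(mfi_panel("p", "G", -1), "finite")
  expect_error(mfi_panel(c("p", "p"), c("G", "G"), c(1, 2)), "Duplicate")
})
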