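# Simulator for the multi-round ON/OFF FACS sort-seq screen: library in
# cells, cytokine-dependent log-normal reporter expression, quantile-gated
# sorting, six final populations, overdispersed multinomial sequencing.

POPULATION_LABELS <- c("act_low", "act_med", "act_high",
                       "non_low", "non_med", "non_high")

#' Per-variant promoter activity parameters
#'
#' Expected reporter expression of a variant under a stimulation condition
#' `(g, k, h)` (indicators for IFN-gamma, TNF-alpha and hypoxia) is
#' multiplicative log-normal around
#' `mu = basal * (1 + g*aG + k*aK + h*aH + g*k*syn)`:
#' `basal` sets the unstimulated level (arbitrary fluorescence units),
#' `aG`/`aK`/`aH` the single-cue responses, `syn` the extra super-additive
#' response when IFN-gamma and TNF-alpha are combined, and `cell_noise_sd`
#' the log-scale cell-to-cell spread.
#'
#' @param basal Positive basal expression scale.
#' @param aG,aK,aH Non-negative response coefficients for IFN-gamma,
#'   TNF-alpha and hypoxia.
#' @param syn Non-negative synergy coefficient (active when g and k are both
#'   present).
#' @param cell_noise_sd Positive log-scale standard deviation.
#' @return A one-row tibble of activity parameters.
#' @export
activity_params <- function(basal = 1, aG = 0, aK = 0, aH = 0, syn = 0,
                            cell_noise_sd = 0.8) {
  stopifnot(basal > 0, aG >= 0, aK >= 0, aH >= 0, syn >= 0,
            cell_noise_sd > 0)
  tibble(basal = basal, aG = aG, aK = aK, aH = aH, syn = syn,
         cell_noise_sd = cell_noise_sd)
}

expected_mu <- function(params, g = 0, k = 0, h = 0) {
  aH <- params$aH %||% 0
  aH[is.na(aH)] <- 0
  params$basal * (1 + g * params$aG + k * params$aK + h * aH +
                    g * k * params$syn)
}

#' Simulate per-cell reporter fluorescence
#'
#' Draws `n_cells` fluorescence values `mu * exp(eps)` with
#' `eps ~ Normal(0, cell_noise_sd^2)`, where `mu` is the condition-dependent
#' expected expression of [activity_params()]. The geometric mean of a large
#' sample converges to `mu`.
#'
#' @param params A one-row data frame (or named list) with fields `basal`,
#'   `aG`, `aK`, `syn`, `cell_noise_sd` and optionally `aH`.
#' @param condition Named vector with indicator entries `g`, `k`, `h`
#'   (missing entries default to 0), e.g. `c(g = 1, k = 1)`.
#' @param n_cells Number of cells to draw.
#' @param seed Optional integer seed (caller RNG state untouched).
#' @return Numeric vector of length `n_cells`.
#' @examples
#' x <- simulate_expression(activity_params(basal = 2, aG = 1, aK = 1, syn = 2),
#'                          condition = c(g = 1, k = 1), n_cells = 1e4, seed = 1)
#' exp(mean(log(x)))  # close to 2 * (1 + 1 + 1 + 2) = 10
#' @export
simulate_expression <- function(params, condition = c(g = 0, k = 0, h = 0),
                                n_cells, seed = NULL) {
  stopifnot(n_cells >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  g <- unname(condition["g"] %|na|% 0)
  k <- unname(condition["k"] %|na|% 0)
  h <- unname(condition["h"] %|na|% 0)
  mu <- expected_mu(params, g, k, h)
  mu * exp(rnorm(n_cells, 0, params$cell_noise_sd))
}

`%|na|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' Build a screen library with planted improved variants
#'
#' Assigns activity parameters to `n_variants` variants sampled from a
#' degenerate template. Every library member is a functional promoter
#' variant, so the background is a continuum: log-normal basal levels and
#' uniformly distributed response and synergy coefficients. The
#' `n_planted` "improved" variants sit at the favorable extreme of that
#' continuum (low basal, strong TNF-alpha-dominant response, synergy above
#' the background range) — the planted-recovery benchmark configuration
#' for the screen.
#'
#' @param template A `degenerate_template` supplying the variant space.
#' @param n_variants Library size (distinct variants).
#' @param n_planted Number of planted improved variants (placed first).
#' @param planted Parameters for planted variants (one-row tibble from
#'   [activity_params()]).
#' @param background_basal_meanlog,background_basal_sdlog Log-normal
#'   parameters for background basal levels.
#' @param background_aG_max,background_aK_max,background_syn_max Background
#'   `aG`, `aK` and `syn` are uniform on `[0, max]`.
#' @param cell_noise_sd Log-scale noise for every variant.
#' @param seed Optional integer seed.
#' @return A tibble with columns `key`, `realized`, `basal`, `aG`, `aK`,
#'   `aH`, `syn`, `cell_noise_sd`, `planted` (logical).
#' @export
screen_library <- function(template, n_variants, n_planted = 0,
                           planted = activity_params(basal = 1, aG = 2,
                                                     aK = 6, syn = 12),
                           background_basal_meanlog = 0.5,
                           background_basal_sdlog = 0.8,
                           background_aG_max = 2,
                           background_aK_max = 6,
                           background_syn_max = 6,
                           cell_noise_sd = 0.8,
                           seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"),
            n_variants >= 1, n_planted >= 0, n_planted <= n_variants)
  if (complexity(template) < n_variants) {
    abort(sprintf(
      "Template encodes only %s distinct variants; cannot draw %d.",
      format(complexity(template), big.mark = ","), n_variants))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  keys <- character(0)
  while (length(keys) < n_variants) {
    keys <- unique(c(keys, sample_variants(template, 2L * n_variants)$key))
  }
  keys <- keys[seq_len(n_variants)]
  lib <- tibble(
    key = keys,
    realized = realize_variant(template, keys),
    basal = stats::rlnorm(n_variants, background_basal_meanlog,
                          background_basal_sdlog),
    aG = stats::runif(n_variants, 0, background_aG_max),
    aK = stats::runif(n_variants, 0, background_aK_max),
    aH = 0,
    syn = stats::runif(n_variants, 0, background_syn_max),
    cell_noise_sd = cell_noise_sd,
    planted = FALSE
  )
  if (n_planted > 0) {
    idx <- seq_len(n_planted)
    lib$basal[idx] <- planted$basal
    lib$aG[idx] <- planted$aG
    lib$aK[idx] <- planted$aK
    lib$aH[idx] <- planted$aH
    lib$syn[idx] <- planted$syn
    lib$cell_noise_sd[idx] <- planted$cell_noise_sd
    lib$planted[idx] <- TRUE
  }
  lib
}

#' Configure the sort-seq screen simulator
#'
#' Defaults mirror the screened library's conditions: transduction at
#' MOI < 0.3 (under 30% reporter-positive cells, at most one construct per
#' positive cell), three consecutive ON/OFF sorting rounds, a final split
#' into activated and non-activated arms binned into low/med/high tertiles
#' (six sequenced populations), and an average of 22,368 reads per
#' population with PCR-driven overdispersion.
#'
#' @param cells_per_round Cells entering each sort (default 1e5).
#' @param moi_positive_fraction Fraction of round-1 cells carrying a
#'   construct (default 0.3); the rest are autofluorescent untransduced
#'   cells removed by the first positive gate and never sequenced.
#' @param rounds Number of ON/OFF selection rounds (default 3).
#' @param positive_gate Upper quantile fraction kept in ON sorts
#'   (default 0.15: top 15% of fluorescence).
#' @param negative_gate Lower quantile fraction kept in OFF sorts
#'   (default 0.30: bottom 30%).
#' @param off_pool_background_weight Weight given to the lower half of the
#'   OFF gate (cells returned to background) when pooling with the upper
#'   half (low-expressing cells); default 0.5 = the two sub-gates contribute
#'   equally, i.e. uniform across the gate.
#' @param final_bins Quantile breakpoints splitting each final arm into
#'   low/med/high bins (default tertiles `c(1/3, 2/3)`).
#' @param on_condition Stimulation used for ON sorts and the activated arm
#'   (default IFN-gamma + TNF-alpha).
#' @param read_depth Reads sequenced per population (default 22368).
#' @param overdispersion Dirichlet concentration for sequencing counts,
#'   modelling the PCR template bottleneck: roughly the number of sorted
#'   genomes entering amplification, i.e. the cells collected per final bin
#'   (default 30000); `Inf` recovers a plain multinomial.
#' @param error_rate Per-base substitution probability used by
#'   [emit_fastq()] (default 0.001).
#' @param autofluorescence Expression scale of untransduced cells
#'   (default 0.05).
#' @param seed Integer seed making the whole screen reproducible.
#' @return A `screen_config` list.
#' @export
screen_config <- function(cells_per_round = 1e5,
                          moi_positive_fraction = 0.3,
                          rounds = 3,
                          positive_gate = 0.15,
                          negative_gate = 0.30,
                          off_pool_background_weight = 0.5,
                          final_bins = c(1 / 3, 2 / 3),
                          on_condition = c(g = 1, k = 1, h = 0),
                          read_depth = 22368,
                          overdispersion = 30000,
                          error_rate = 0.001,
                          autofluorescence = 0.05,
                          seed = 1L) {
  on_condition <- unlist(on_condition)
  if (!all(c("g", "k") %in% names(on_condition))) {
    abort("`on_condition` needs named entries g and k (h optional).")
  }
  if (!"h" %in% names(on_condition)) on_condition <- c(on_condition, h = 0)
  stopifnot(
    cells_per_round >= 1, rounds >= 1,
    moi_positive_fraction > 0, moi_positive_fraction <= 1,
    positive_gate > 0, positive_gate < 1,
    negative_gate > 0, negative_gate < 1,
    off_pool_background_weight >= 0, off_pool_background_weight <= 1,
    length(final_bins) == 2, all(final_bins > 0), all(final_bins < 1),
    final_bins[1] < final_bins[2],
    read_depth >= 1, overdispersion > 0,
    error_rate >= 0, error_rate < 1,
    autofluorescence > 0
  )
  structure(
    list(
      cells_per_round = as.integer(cells_per_round),
      moi_positive_fraction = moi_positive_fraction,
      rounds = as.integer(rounds),
      positive_gate = positive_gate,
      negative_gate = negative_gate,
      off_pool_background_weight = off_pool_background_weight,
      final_bins = final_bins,
      on_condition = on_condition,
      read_depth = as.integer(read_depth),
      overdispersion = overdispersion,
      error_rate = error_rate,
      autofluorescence = autofluorescence,
      seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

#' Read / write a screen configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_screen_config()` returns a `screen_config`;
#'   `write_screen_config()` returns `path` invisibly.
#' @export
read_screen_config <- function(path) {
  do.call(screen_config, yaml::read_yaml(path))
}

#' @rdname read_screen_config
#' @param config A `screen_config`.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  plain <- unclass(config)
  plain$on_condition <- as.list(plain$on_condition)  # keep names in YAML
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

# One quantile-gated sort. Cells are sampled from `abund`, fluorescence is
# simulated per cell, and the kept subset's composition becomes the new
# abundance vector. `mu`/`sd` are per-variant (index 0 = untransduced).
sort_once <- function(abund, mu, sd, n_cells, keep, side,
                      off_split_weight = NULL) {
  idx <- sample.int(length(abund), n_cells, replace = TRUE, prob = abund)
  fluor <- mu[idx] * exp(rnorm(n_cells) * sd[idx])
  if (side == "top") {
    thr <- quantile(fluor, 1 - keep, names = FALSE)
    kept <- idx[fluor >= thr]
    counts <- tabulate(kept, nbins = length(abund))
  } else {
    thr <- quantile(fluor, keep, names = FALSE)
    in_gate <- fluor <= thr
    mid <- quantile(fluor[in_gate], 0.5, names = FALSE)
    lower <- tabulate(idx[in_gate & fluor <= mid], nbins = length(abund))
    upper <- tabulate(idx[in_gate & fluor > mid], nbins = length(abund))
    w <- off_split_weight
    counts <- w * lower / max(sum(lower), 1) +
      (1 - w) * upper / max(sum(upper), 1)
    kept <- idx[in_gate]
  }
  if (sum(counts) == 0) return(NULL)
  list(abund = counts / sum(counts), n_kept = length(kept))
}

dirichlet_multinomial <- function(abund, depth, concentration) {
  p <- abund / sum(abund)
  if (is.finite(concentration)) {
    gam <- rgamma(length(p), shape = concentration * p)
    if (sum(gam) == 0) gam[which.max(p)] <- 1
    p <- gam / sum(gam)
  }
  drop(rmultinom(1, depth, p))
}

#' Run the full sort-seq screen simulation
#'
#' Simulates the screen end to end: the library is transduced into cells at
#' low MOI, each of `rounds` rounds applies an ON sort (stimulation, keep
#' the brightest `positive_gate` fraction) followed by an OFF sort (no
#' stimulation, keep the dimmest `negative_gate` fraction, pooling the
#' background-returned and low-expressing sub-gates), the surviving pool is
#' split into an activated and a non-activated arm, each arm is binned into
#' low/med/high fluorescence tertiles, and each of the six populations is
#' sequenced with Dirichlet-multinomial noise at `read_depth` reads.
#'
#' @param library Tibble of per-variant activity parameters
#'   ([screen_library()] or columns `key`, `basal`, `aG`, `aK`, `syn`,
#'   `cell_noise_sd`, optionally `aH`, `realized`).
#' @param config A [screen_config()].
#' @return A `cartiv_screen` object: list with `counts` (tibble, `key` plus
#'   the six population columns), `trajectory` (per-variant frequency after
#'   each sort), `stages` (cells entering and kept per sort), `bins` (cells
#'   per final population), `library`, and `config`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' tpl <- parse_template("AYRNN")
#' lib <- screen_library(tpl, n_variants = 8, n_planted = 2, seed = 1)
#' scr <- run_screen(lib, screen_config(cells_per_round = 2e4,
#'                                      read_depth = 1000, seed = 1))
#' head(scr$counts)
#' @export
run_screen <- function(library, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  need <- c("key", "basal", "aG", "aK", "syn", "cell_noise_sd")
  if (!all(need %in% names(library)) || nrow(library) == 0) {
    abort("`library` must be a non-empty tibble with columns key, basal, aG, aK, syn, cell_noise_sd.")
  }
  if (anyDuplicated(library$key)) abort("`library` keys must be unique.")
  withr::local_seed(config$seed)

  on <- config$on_condition
  # index 1 = untransduced pseudo-variant; variants at 2..(n+1)
  mu_on <- c(config$autofluorescence,
             expected_mu(library, g = on["g"], k = on["k"], h = on["h"]))
  mu_off <- c(config$autofluorescence, expected_mu(library, 0, 0, 0))
  sds <- c(0.5, library$cell_noise_sd)
  n_var <- nrow(library)

  abund <- c(1 - config$moi_positive_fraction,
             rep(config$moi_positive_fraction / n_var, n_var))
  trajectory <- list()
  stages <- list()
  for (r in seq_len(config$rounds)) {
    s <- sort_once(abund, mu_on, sds, config$cells_per_round,
                   config$positive_gate, "top")
    if (is.null(s)) {
      abort(sprintf("Positive gate emptied the population in round %d.", r))
    }
    abund <- s$abund
    stages[[length(stages) + 1]] <- tibble(
      round = r, stage = "on", n_cells = config$cells_per_round,
      n_kept = s$n_kept
    )
    trajectory[[length(trajectory) + 1]] <- tibble(
      round = r, stage = "on", key = library$key, freq = abund[-1] / max(sum(abund[-1]), .Machine$double.eps)
    )
    s <- sort_once(abund, mu_off, sds, config$cells_per_round,
                   config$negative_gate, "bottom",
                   off_split_weight = config$off_pool_background_weight)
    if (is.null(s)) {
      abort(sprintf("Negative gate emptied the population in round %d.", r))
    }
    abund <- s$abund
    stages[[length(stages) + 1]] <- tibble(
      round = r, stage = "off", n_cells = config$cells_per_round,
      n_kept = s$n_kept
    )
    trajectory[[length(trajectory) + 1]] <- tibble(
      round = r, stage = "off", key = library$key, freq = abund[-1] / max(sum(abund[-1]), .Machine$double.eps)
    )
  }

  # Final split: activated and non-activated arms, tertile bins.
  counts <- matrix(0L, nrow = n_var, ncol = 6,
                   dimnames = list(library$key, POPULATION_LABELS))
  bins <- list()
  for (arm in c("act", "non")) {
    mu <- if (arm == "act") mu_on else mu_off
    idx <- sample.int(length(abund), config$cells_per_round,
                      replace = TRUE, prob = abund)
    fluor <- mu[idx] * exp(rnorm(length(idx)) * sds[idx])
    brk <- quantile(fluor, config$final_bins, names = FALSE)
    bin <- cut(fluor, c(-Inf, brk, Inf), labels = c("low", "med", "high"))
    for (b in levels(bin)) {
      label <- paste(arm, b, sep = "_")
      cells <- tabulate(idx[bin == b], nbins = length(abund))[-1]
      bins[[length(bins) + 1]] <- tibble(
        population = label, arm = arm, bin = b, n_cells = sum(cells)
      )
      if (sum(cells) == 0) {
        abort(sprintf("Final bin '%s' received no transduced cells.", label))
      }
      counts[, label] <- dirichlet_multinomial(
        cells, config$read_depth, config$overdispersion
      )
    }
  }

  structure(
    list(
      counts = tibble(key = library$key, as_tibble(counts)),
      trajectory = bind_rows(trajectory),
      stages = bind_rows(stages),
      bins = bind_rows(bins),
      library = library,
      config = config
    ),
    class = "cartiv_screen"
  )
}

#' @export
print.cartiv_screen <- function(x, ...) {
  cat(sprintf(
    "<cartiv_screen> %d variants, %d rounds, %s reads per population\n",
    nrow(x$library), x$config$rounds,
    format(x$config$read_depth, big.mark = ",")
  ))
  print(head(x$counts))
  invisible(x)
}

#' Tidy the six-population count table of a screen
#'
#' @param x A `cartiv_screen`.
#' @param ... Unused.
#' @return Long tibble with columns `key`, `population`, `arm`, `bin`,
#'   `count`.
#' @method tidy cartiv_screen
#' @export
tidy.cartiv_screen <- function(x, ...) {
  tidyr::pivot_longer(x$counts, -"key",
                      names_to = "population", values_to = "count") |>
    tidyr::separate_wider_delim("population", "_", names = c("arm", "bin"),
                                cols_remove = FALSE) |>
    select("key", "population", "arm", "bin", "count")
}

#' One-row summary of a screen simulation
#'
#' @param x A `cartiv_screen`.
#' @param ... Unused.
#' @return One-row tibble: library size, planted variants, rounds, read
#'   depth, total reads, and distinct keys observed in the counts.
#' @method glance cartiv_screen
#' @export
glance.cartiv_screen <- function(x, ...) {
  cts <- as.matrix(x$counts[, -1])
  tibble(
    n_variants = nrow(x$library),
    n_planted = sum(x$library$planted %||% FALSE),
    rounds = x$config$rounds,
    read_depth = x$config$read_depth,
    total_reads = sum(cts),
    n_observed = sum(rowSums(cts) > 0)
  )
}

#' Plot variant-frequency trajectories across sorting rounds
#'
#' Shows the pooled frequency of planted variants (when the library marks
#' them) or the ten most abundant final variants across the ON/OFF sorts.
#'
#' @param object A `cartiv_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cartiv_screen
#' @export
autoplot.cartiv_screen <- function(object, ...) {
  traj <- object$trajectory |>
    mutate(step = (.data$round - 1) * 2 + (.data$stage == "off") + 1)
  if (!is.null(object$library$planted)) {
    dat <- traj |>
      left_join(select(object$library, "key", "planted"), by = "key") |>
      group_by(.data$step, .data$round, .data$stage, .data$planted) |>
      summarise(freq = sum(.data$freq), .groups = "drop") |>
      mutate(group = ifelse(.data$planted, "planted", "background"))
  } else {
    top <- traj |>
      filter(.data$step == max(.data$step)) |>
      arrange(desc(.data$freq)) |>
      head(10) |>
      pull("key")
    dat <- traj |>
      filter(.data$key %in% top) |>
      mutate(group = .data$key)
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$step, .data$freq,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = seq_len(max(dat$step)),
      labels = paste0("R", rep(seq_len(max(dat$step) / 2), each = 2),
                      c(" on", " off"))
    ) +
    ggplot2::labs(x = "sort", y = "library frequency", colour = NULL) +
    ggplot2::theme_minimal()
}
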