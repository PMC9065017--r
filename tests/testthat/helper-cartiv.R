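# Shared fixtures and independent oracles, all built in code.

# A small degenerate template with an invariant 12-mer prefix to anchor on.
toy_template <- function() {
  parse_template("GGACCTTAGCATAYRSCCWTGGKAA")
}

# Independent oracle: expand a degenerate IUPAC string recursively, one
# position at a time, returning every allele string. Deliberately naive.
oracle_expand_alleles <- function(iupac_string) {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  chars <- strsplit(toupper(sub("\\.$", "", iupac_string)), "")[[1]]
  degenerate <- chars[!chars %in% c("A", "C", "G", "T")]
  rec <- function(sets) {
    if (length(sets) == 0) return("")
    rest <- rec(sets[-1])
    unlist(lapply(sets[[1]], function(b) paste0(b, rest)))
  }
  rec(codes[degenerate])
}

# Independent per-read classifier for template-anchored extraction: assumes
# reads already aligned at position 1 and full-length (as emitted by the
# simulator), checks fixed positions and allowed sets base by base.
oracle_classify_read <- function(read, template, max_fixed_mismatches = 2) {
  rc <- strsplit(read, "")[[1]]
  tc <- strsplit(template$sequence, "")[[1]]
  if (length(rc) != length(tc)) return(list(key = NA, reason = "length"))
  vidx <- template$positions$index + 1
  mism <- 0L
  for (i in seq_along(tc)) {
    if (!(i %in% vidx) && rc[i] != tc[i]) mism <- mism + 1L
  }
  if (mism > max_fixed_mismatches) {
    return(list(key = NA, reason = "fixed_mismatch"))
  }
  for (j in seq_along(vidx)) {
    if (!rc[vidx[j]] %in% template$positions$allowed[[j]]) {
      return(list(key = NA, reason = "disallowed_allele"))
    }
  }
  list(key = paste(rc[vidx], collapse = ""), reason = NA)
}

# A six-population count table with chosen row sums.
toy_count_table <- function(totals, n_pop = 6) {
  keys <- sprintf("V%03d", seq_along(totals))
  m <- t(vapply(totals, function(tt) {
    base <- rep(tt %/% n_pop, n_pop)
    base[seq_len(tt %% n_pop)] <- base[seq_len(tt %% n_pop)] + 1
    base
  }, numeric(n_pop)))
  colnames(m) <- cartivscreen:::POPULATION_LABELS[seq_len(n_pop)]
  dplyr::bind_cols(tibble::tibble(key = keys), tibble::as_tibble(m))
}

# A neutral library: every variant shares the same activity parameters.
neutral_library <- function(template, n_variants, seed) {
  stopifnot(complexity(template) >= n_variants)
  v <- sample_variants(template, 20 * n_variants, seed = seed)
  keys <- unique(v$key)[seq_len(n_variants)]
  stopifnot(!anyNA(keys))
  tibble::tibble(
    key = keys, realized = realize_variant(template, keys),
    basal = 1, aG = 0, aK = 0, aH = 0, syn = 0, cell_noise_sd = 0.8
  )
}

# Variance-adjusted chi-square consistency check of one population's counts
# against expected frequencies p0. The screen's sequential cell sampling
# and Dirichlet-multinomial sequencing inflate count variance relative to a
# plain multinomial by a factor computable from the sampling design:
#   F = (N + A) / (1 + A)  +  N * sum_s 1 / m_s
# (N = read depth, A = Dirichlet concentration, m_s = cells kept at each
# sequential sorting stage feeding this population).
neutral_chisq_rejects <- function(counts, p0, depth, concentration,
                                  stage_cells, alpha = 0.01) {
  infl <- (depth + concentration) / (1 + concentration) +
    depth * sum(1 / stage_cells)
  x2 <- sum((counts - depth * p0)^2 / (depth * p0))
  x2 / infl > stats::qchisq(1 - alpha, df = length(p0) - 1)
}

# Geometric-mean MFI panel simulated from activity parameters (large-n
# geometric means of simulate_expression draws).
simulated_mfi_panel <- function(lib, n_cells = 20000, seed = 1) {
  conds <- list(none = c(g = 0, k = 0), G = c(g = 1, k = 0),
                K = c(g = 0, k = 1), GK = c(g = 1, k = 1))
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    p <- lib[i, ]
    tibble::tibble(
      promoter = p$key,
      condition = names(conds),
      geomean = vapply(seq_along(conds), function(ci) {
        exp(mean(log(simulate_expression(p, conds[[ci]], n_cells,
                                         seed = seed + 10 * i + ci))))
      }, numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}
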