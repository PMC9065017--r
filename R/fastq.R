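# FASTQ emission for simulated populations.

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  n_mut <- rbinom(length(seqs), len, error_rate)
  hit <- which(n_mut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(len[i], n_mut[i])
    for (p in at) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Emit simulated sequencing reads as FASTQ, one file per population
#'
#' Each population's counts are expanded into reads of the corresponding
#' variant's realized sequence, i.i.d. per-base substitution errors are
#' applied at `error_rate`, and the reads are written as
#' `<label>.fastq` under `dir` with a constant placeholder quality string.
#' With `error_rate = 0`, re-counting the files with [count_population()]
#' reproduces the input counts exactly.
#'
#' @param x A `cartiv_screen` (its config supplies the defaults below) or a
#'   counts tibble with a `key` column and one column per population.
#' @param template The `degenerate_template` the library was drawn from
#'   (used to realize sequences when `x` is a counts tibble without
#'   realized sequences).
#' @param dir Output directory (created if needed).
#' @param error_rate Per-base substitution probability; default taken from
#'   the screen config, else 0.
#' @param seed Integer seed; default taken from the screen config.
#' @return Named character vector of file paths (one per population),
#'   invisibly.
#' @export
emit_fastq <- function(x, template, dir, error_rate = NULL, seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"))
  if (inherits(x, "cartiv_screen")) {
    counts <- x$counts
    error_rate <- error_rate %||% x$config$error_rate
    seed <- seed %||% (x$config$seed + 1L)
  } else {
    counts <- x
    error_rate <- error_rate %||% 0
  }
  stopifnot("key" %in% names(counts), ncol(counts) >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  realized <- realize_variant(template, counts$key)
  labels <- setdiff(names(counts), "key")
  paths <- setNames(file.path(dir, paste0(labels, ".fastq")), labels)
  for (lab in labels) {
    cts <- counts[[lab]]
    seqs <- rep(realized, cts)
    seqs <- apply_substitutions(seqs, error_rate)
    n <- length(seqs)
    if (n == 0) {
      writeLines(character(0), paths[[lab]])
      next
    }
    qual <- strrep("I", nchar(seqs))
    writeLines(
      as.vector(rbind(sprintf("@%s_%06d", lab, seq_len(n)), seqs,
                      "+", qual)),
      paths[[lab]]
    )
  }
  invisible(paths)
}
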