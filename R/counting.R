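# Template-anchored variant counting: reads -> variant keys -> count table.
# Because all true library members differ only at the template's variable
# positions, single-base resolution is obtained directly by anchoring each
# read on the template and reading the bases at those positions; no
# denoising or alignment is needed.

#' Read-to-variant extraction policy
#'
#' @param max_fixed_mismatches Maximum substitutions tolerated at fixed
#'   (non-variable) template positions (default 2).
#' @param require_variable_in_allowed Reject reads whose base at a variable
#'   position falls outside that position's allowed set (default `TRUE`).
#'   When `FALSE`, such reads are kept and their keys simply record the
#'   observed bases (a distinct namespace from designed alleles).
#' @param try_reverse_complement Retry a failing read as its reverse
#'   complement before rejecting it (default `TRUE`).
#' @param anchor_length Length of the exact-match seed, taken from the
#'   template's first run of fixed bases, used to locate the amplicon in
#'   the read (default 12).
#' @return An `extract_policy` list.
#' @export
extract_policy <- function(max_fixed_mismatches = 2,
                           require_variable_in_allowed = TRUE,
                           try_reverse_complement = TRUE,
                           anchor_length = 12) {
  stopifnot(max_fixed_mismatches >= 0, anchor_length >= 4)
  structure(
    list(
      max_fixed_mismatches = as.integer(max_fixed_mismatches),
      require_variable_in_allowed = isTRUE(require_variable_in_allowed),
      try_reverse_complement = isTRUE(try_reverse_complement),
      anchor_length = as.integer(anchor_length)
    ),
    class = "extract_policy"
  )
}

# First run of >= n consecutive fixed positions in the template; returns the
# seed string and its 0-based start.
anchor_seed <- function(template, n) {
  chars <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  fixed <- chars %in% c("A", "C", "G", "T")
  r <- rle(fixed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n)
  if (length(ok) == 0) {
    abort(sprintf(
      "Template has no run of %d fixed bases to anchor on.", n))
  }
  s <- starts[ok[1]]
  list(seed = paste(chars[s:(s + n - 1L)], collapse = ""), start0 = s - 1L)
}

# One anchoring + classification pass over a character vector of reads.
classify_reads <- function(reads, template, policy) {
  n <- length(reads)
  key <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n == 0) return(tibble(key = key, reason = reason))

  anch <- anchor_seed(template, policy$anchor_length)
  L <- template$length
  hit <- regexpr(anch$seed, reads, fixed = TRUE)
  start <- hit - anch$start0
  # seed not found but read already template-length: sequencing errors may
  # sit inside the seed itself, so fall back to offset-0 alignment
  exact_len <- hit == -1L & nchar(reads) == L
  start[exact_len] <- 1L
  found <- hit != -1L | exact_len
  reason[!found] <- "no_anchor"
  short <- found & (start < 1L | start + L - 1L > nchar(reads))
  reason[short] <- "length"
  use <- which(found & !short)
  if (length(use) == 0) return(tibble(key = key, reason = reason))

  aligned <- substr(reads[use], start[use], start[use] + L - 1L)
  tch <- strsplit(template$sequence, "", fixed = TRUE)[[1]]
  m <- matrix(unlist(strsplit(aligned, "", fixed = TRUE), use.names = FALSE),
              ncol = L, byrow = TRUE)
  vidx <- template$positions$index + 1L
  fidx <- setdiff(seq_len(L), vidx)
  mism <- if (length(fidx)) {
    rowSums(m[, fidx, drop = FALSE] !=
              matrix(tch[fidx], nrow(m), length(fidx), byrow = TRUE))
  } else {
    rep(0L, nrow(m))
  }
  bad_fixed <- mism > policy$max_fixed_mismatches
  alleles <- if (length(vidx)) {
    do.call(paste0, lapply(seq_along(vidx),
                           function(j) m[, vidx[j], drop = TRUE]))
  } else {
    rep("", nrow(m))
  }
  bad_allele <- rep(FALSE, nrow(m))
  if (policy$require_variable_in_allowed && length(vidx)) {
    for (j in seq_along(vidx)) {
      bad_allele <- bad_allele |
        !(m[, vidx[j]] %in% template$positions$allowed[[j]])
    }
  }
  ok <- !bad_fixed & !bad_allele
  key[use[ok]] <- alleles[ok]
  reason[use[bad_fixed]] <- "fixed_mismatch"
  reason[use[!bad_fixed & bad_allele]] <- "disallowed_allele"
  tibble(key = key, reason = reason)
}

#' Extract variant keys from reads by template anchoring
#'
#' Locates the amplicon in each read by an exact match of a short seed from
#' the template's invariant prefix (falling back to offset-0 alignment when
#' the seed is absent but the read is exactly template-length, so that
#' errors inside the seed do not lose reads), checks the fixed positions
#' against the template (tolerating up to `max_fixed_mismatches`
#' substitutions), and
#' reads the bases at the variable positions verbatim as the allele-string
#' key. A read failing any step is retried as its reverse complement (when
#' enabled) and otherwise rejected with a reason: `"no_anchor"`,
#' `"length"` (the template does not fit in the read at the anchored
#' offset), `"fixed_mismatch"`, or `"disallowed_allele"` (a variable-position
#' base outside the designed set).
#'
#' @param reads Character vector of read sequences (any case).
#' @param template A `degenerate_template`.
#' @param policy An [extract_policy()].
#' @return A tibble with one row per read: `key` (`NA` when rejected) and
#'   `reason` (`NA` when assigned).
#' @export
extract_variant_key <- function(reads, template,
                                policy = extract_policy()) {
  stopifnot(inherits(template, "degenerate_template"),
            inherits(policy, "extract_policy"))
  reads <- toupper(reads)
  res <- classify_reads(reads, template, policy)
  if (policy$try_reverse_complement && anyNA(res$key)) {
    fail <- which(is.na(res$key))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[fail])))
    res2 <- classify_reads(rc, template, policy)
    rescued <- !is.na(res2$key)
    res$key[fail[rescued]] <- res2$key[rescued]
    res$reason[fail[rescued]] <- NA_character_
  }
  res
}

read_fastq_seqs <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    abort(sprintf("Malformed FASTQ '%s': record %d is truncated.",
                  path, n_lines %/% 4L + 1L))
  }
  toupper(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}

#' Count one sorted population's reads into variant keys
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param template A `degenerate_template`.
#' @param label Population label for the resulting column (e.g.
#'   `"act_high"`).
#' @param policy An [extract_policy()].
#' @return A tibble with columns `label`, `key`, `count`; unassignable
#'   reads are tallied by reason in the `"rejections"` attribute (a tibble
#'   `label`, `reason`, `n`). Assigned + rejected reads equal the number of
#'   reads in the file.
#' @export
count_population <- function(fastq, template, label,
                             policy = extract_policy()) {
  seqs <- read_fastq_seqs(fastq)
  res <- extract_variant_key(seqs, template, policy)
  assigned <- res |>
    filter(!is.na(.data$key)) |>
    dplyr::count(.data$key, name = "count") |>
    mutate(label = label, .before = 1) |>
    arrange(.data$key)
  rej <- res |>
    filter(is.na(.data$key)) |>
    dplyr::count(.data$reason, name = "n") |>
    mutate(label = label, .before = 1)
  attr(assigned, "rejections") <- rej
  attr(assigned, "label") <- label
  assigned
}

#' Merge per-population count columns into one count table
#'
#' @param ... Tibbles from [count_population()] (or one list of them).
#' @return A wide count table: `key` plus one integer column per population
#'   label, absent cells 0; rejection ledgers concatenated in the
#'   `"rejections"` attribute. Duplicate labels are an error; the merge is
#'   order-invariant up to column order.
#' @export
merge_counts <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && !is.data.frame(cols[[1L]])) cols <- cols[[1L]]
  labs <- vapply(cols, function(x) {
    attr(x, "label") %||% x$label[1] %||% NA_character_
  }, character(1))
  labs[is.na(labs)] <- paste0("pop", which(is.na(labs)))
  if (anyDuplicated(labs)) {
    abort(sprintf("Duplicate population label '%s'.",
                  labs[duplicated(labs)][1]))
  }
  wide <- bind_rows(cols) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "label",
                       values_from = "count", values_fill = 0L) |>
    arrange(.data$key)
  for (lab in setdiff(labs, names(wide))) {
    wide[[lab]] <- integer(nrow(wide))  # population with no assigned reads
  }
  attr(wide, "rejections") <-
    bind_rows(lapply(cols, function(x) attr(x, "rejections")))
  wide
}

#' Count all six sorted populations from a directory of FASTQ files
#'
#' Convenience wrapper expecting the [emit_fastq()] layout
#' (`<label>.fastq` or `.fastq.gz` per population).
#'
#' @param dir Directory holding the per-population FASTQ files.
#' @param template A `degenerate_template`.
#' @param labels Population labels to read (default the six standard ones).
#' @param policy An [extract_policy()].
#' @return A wide count table as from [merge_counts()].
#' @export
count_screen_fastq <- function(dir, template, labels = POPULATION_LABELS,
                               policy = extract_policy()) {
  cols <- lapply(labels, function(lab) {
    path <- file.path(dir, paste0(lab, ".fastq"))
    if (!file.exists(path)) path <- paste0(path, ".gz")
    if (!file.exists(path)) {
      abort(sprintf("No FASTQ found for population '%s' in '%s'.", lab, dir))
    }
    count_population(path, template, lab, policy)
  })
  merge_counts(cols)
}

#' Read / write a variant-by-population count table as TSV
#'
#' @param path TSV path (first column `key`, one column per population).
#' @return `read_count_table()` returns the count tibble;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              colClasses = c(key = "character")))
}

#' @rdname read_count_table
#' @param counts Count table tibble.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
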