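mutate_at_pos <- function(seq, pos1, base) {
  substr(seq, pos1, pos1) <- base
  seq
}

test_that("exact reads map to their variant key; fixed-position errors are tolerated", {
  tpl <- toy_template()
  v <- enumerate_variants(tpl)
  res <- extract_variant_key(v$realized, tpl)
  expect_equal(res$key, v$key)
  expect_true(all(is.na(res$reason)))

  read <- v$realized[5]
  fidx <- setdiff(seq_len(tpl$length), tpl$positions$index + 1)
  # one then two substitutions at fixed positions: still assigned
  r1 <- mutate_at_pos(read, fidx[3], "N")  # guaranteed mismatch
  r1 <- gsub("N", setdiff(c("A", "C", "G", "T"),
                          substr(read, fidx[3], fidx[3]))[1], r1)
  expect_equal(extract_variant_key(r1, tpl)$key, v$key[5])
  r2 <- mutate_at_pos(r1, fidx[9], setdiff(
    c("A", "C", "G", "T"), substr(read, fidx[9], fidx[9]))[1])
  expect_equal(extract_variant_key(r2, tpl)$key, v$key[5])
  # a third pushes past max_fixed_mismatches = 2
  r3 <- mutate_at_pos(r2, fidx[12], setdiff(
    c("A", "C", "G", "T"), substr(read, fidx[12], fidx[12]))[1])
  out3 <- extract_variant_key(r3, tpl)
  expect_true(is.na(out3$key))
  expect_equal(out3$reason, "fixed_mismatch")
})

test_that("disallowed bases at variable positions reject under the strict policy only", {
  tpl <- toy_template()  # first variable slot is Y = C/T
  v <- enumerate_variants(tpl)
  y_pos <- tpl$positions$index[tpl$positions$code == "Y"][1] + 1
  bad <- mutate_at_pos(v$realized[1], y_pos, "G")
  strict <- extract_variant_key(bad, tpl)
  expect_true(is.na(strict$key))
  expect_equal(strict$reason, "disallowed_allele")

  permissive <- extract_variant_key(
    bad, tpl, extract_policy(require_variable_in_allowed = FALSE))
  expect_false(is.na(permissive$key))
  expect_equal(substr(permissive$key, 1, 1), "G")
  expect_false(permissive$key %in% v$key)
})

test_that("reverse-complement reads are rescued and off-template reads rejected", {
  tpl <- toy_template()
  v <- enumerate_variants(tpl)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(v$realized[1:4])))
  res <- extract_variant_key(rc, tpl)
  expect_equal(res$key, v$key[1:4])

  no_rc <- extract_variant_key(rc, tpl,
                               extract_policy(try_reverse_complement = FALSE))
  expect_true(all(is.na(no_rc$key)))

  res2 <- extract_variant_key(strrep("ACGTT", 8), tpl)
  expect_equal(res2$reason, "no_anchor")
  # anchor present but template does not fit in the read
  short <- substr(v$realized[1], 1, tpl$length - 3)
  res3 <- extract_variant_key(short, tpl)
  expect_equal(res3$reason, "length")
})

test_that("population counting is exhaustive, deterministic and order-insensitive", {
  tpl <- toy_template()
  lib <- screen_library(tpl, 15, 0, seed = 6)
  scr <- run_screen(lib, screen_config(cells_per_round = 4000,
                                       read_depth = 800, seed = 31))
  d <- withr::local_tempdir()
  paths <- emit_fastq(scr, tpl, d, error_rate = 0.02, seed = 8)

  col <- count_population(paths[["act_low"]], tpl, "act_low")
  rej <- attr(col, "rejections")
  expect_equal(sum(col$count) + sum(rej$n), 800)

  # shuffling the FASTQ does not change the counts
  lines <- readLines(paths[["act_low"]])
  recs <- matrix(lines, nrow = 4)
  recs <- recs[, sample(ncol(recs))]
  shuf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(as.vector(recs), shuf)
  col2 <- count_population(shuf, tpl, "act_low")
  expect_equal(dplyr::arrange(col2, key)$count,
               dplyr::arrange(col, key)$count)

  # empty FASTQ: all-zero column, no rejections
  ef <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), ef)
  ec <- count_population(ef, tpl, "non_low")
  expect_equal(nrow(ec), 0L)
  expect_equal(sum(attr(ec, "rejections")$n), 0)

  # truncated record is a hard failure naming the record
  mf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), mf)
  expect_error(count_population(mf, tpl, "x"), "record 1")
})

test_that("assigned fractions under sequencing errors match a per-read oracle", {
  tpl <- toy_template()
  lib <- screen_library(tpl, 10, 0, seed = 7)
  scr <- run_screen(lib, screen_config(cells_per_round = 3000,
                                       read_depth = 1000, seed = 41))
  d <- withr::local_tempdir()
  paths <- emit_fastq(scr, tpl, d, error_rate = 0.01, seed = 15)
  reads <- toupper(as.character(
    Biostrings::readDNAStringSet(paths[["non_high"]], format = "fastq")))

  got <- extract_variant_key(reads, tpl)
  want <- lapply(unname(reads), oracle_classify_read, template = tpl)
  expect_equal(got$key,
               vapply(want, function(w) as.character(w$key), character(1)))
  expect_equal(got$reason,
               vapply(want, function(w) as.character(w$reason), character(1)))
})

test_that("error-free emission and counting round-trip exactly across seeds", {
  tpl <- toy_template()
  for (s in 1:3) {
    lib <- screen_library(tpl, 12, 2, seed = s)
    scr <- run_screen(lib, screen_config(cells_per_round = 3000,
                                         read_depth = 700, seed = 50 + s))
    d <- withr::local_tempdir()
    emit_fastq(scr, tpl, d, error_rate = 0)
    got <- count_screen_fastq(d, tpl)
    truth <- scr$counts[rowSums(scr$counts[, -1]) > 0, ] |>
      dplyr::arrange(key)
    expect_equal(got$key, truth$key)
    expect_equal(as.matrix(got[, names(truth)[-1]]),
                 as.matrix(truth[, -1]), ignore_attr = TRUE)
  }
})

test_that("merging columns is order-invariant and rejects duplicate labels", {
  tpl <- toy_template()
  lib <- screen_library(tpl, 10, 0, seed = 9)
  scr <- run_screen(lib, screen_config(cells_per_round = 3000,
                                       read_depth = 400, seed = 61))
  d <- withr::local_tempdir()
  paths <- emit_fastq(scr, tpl, d, error_rate = 0)
  cols <- lapply(names(paths), function(lab) {
    count_population(paths[[lab]], tpl, lab)
  })
  a <- merge_counts(cols)
  b <- merge_counts(rev(cols))
  expect_equal(a, b[, names(a)], ignore_attr = TRUE)
  expect_equal(colSums(a[, -1]),
               setNames(vapply(cols, function(x) sum(x$count), numeric(1)),
                        vapply(cols, function(x) attr(x, "label"),
                               character(1)))[names(a)[-1]])
  expect_error(merge_counts(cols[[1]], cols[[1]]), "Duplicate")

  # disjoint keys stack: row count adds up
  c1 <- cols[[1]][1:3, ]
  attr(c1, "label") <- "p1"
  c1$label <- "p1"
  c2 <- cols[[2]][4:6, ]
  attr(c2, "label") <- "p2"
  c2$label <- "p2"
  if (length(intersect(c1$key, c2$key)) == 0) {
    expect_equal(nrow(merge_counts(c1, c2)), nrow(c1) + nrow(c2))
  }

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(a, tsv)
  expect_equal(read_count_table(tsv), a, ignore_attr = TRUE)
})
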