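# IUPAC degenerate template model: parsing, rendering, enumeration, sampling.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Parse a degenerate IUPAC promoter template
#'
#' Builds a `degenerate_template` object from a DNA string that may contain
#' IUPAC degeneracy codes (Y, S, R, W, K, M, B, D, H, V, N). Every degenerate
#' code becomes a variable position carrying its allowed-base set; A/C/G/T
#' positions are fixed. Input case is ignored (library oligos are often
#' printed with lower-case cloning flanks); the template is stored upper-case
#' and case carries no meaning, so a degenerate code in a lower-case flank is
#' treated as variable like any other.
#'
#' Coordinates are 0-based throughout the package.
#'
#' @param iupac_string A single non-empty DNA string over the IUPAC alphabet
#'   (either case). A single trailing `"."` (as in printed oligo listings) is
#'   stripped.
#' @param elements Optional character vector labelling each variable position
#'   (in template order) with the response element it belongs to, e.g.
#'   `"GAS"` or `"kappa"`. Recycled errors are not allowed: length must equal
#'   the number of variable positions.
#'
#' @return An object of class `degenerate_template`: a list with
#'   `sequence` (upper-case template string), `length`, and `positions`, a
#'   tibble with one row per variable position (`slot` 1-based ordinal,
#'   `index` 0-based template coordinate, `code`, `allowed` list-column of
#'   allowed bases, `designated` first allowed base in alphabetical order,
#'   and `element` label if supplied).
#'
#' @examples
#' tpl <- parse_template("AYTTCCSGGAART")
#' tpl$positions
#' complexity(tpl)
#' @export
parse_template <- function(iupac_string, elements = NULL) {
  if (!is.character(iupac_string) || length(iupac_string) != 1L ||
      is.na(iupac_string)) {
    abort("`iupac_string` must be a single DNA string.")
  }
  seq <- toupper(sub("\\.$", "", iupac_string))
  if (!nzchar(seq)) abort("`iupac_string` must be non-empty.")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_DNA))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-IUPAC character '%s' at position %d (0-based).",
      chars[bad[1L]], bad[1L] - 1L
    ))
  }
  var <- which(!chars %in% c("A", "C", "G", "T"))
  allowed <- IUPAC_DNA[chars[var]]
  positions <- tibble(
    slot = seq_along(var),
    index = var - 1L,
    code = chars[var],
    allowed = unname(allowed),
    designated = vapply(allowed, function(a) sort(a)[1L], character(1))
  )
  if (!is.null(elements)) {
    if (length(elements) != nrow(positions)) {
      abort(sprintf(
        "`elements` has length %d but the template has %d variable positions.",
        length(elements), nrow(positions)
      ))
    }
    positions$element <- as.character(elements)
  }
  structure(
    list(sequence = seq, length = nchar(seq), positions = positions),
    class = "degenerate_template"
  )
}

#' @export
print.degenerate_template <- function(x, ...) {
  cat(sprintf(
    "<degenerate_template> %d bp, %d variable positions, complexity %s\n",
    x$length, nrow(x$positions), format(complexity(x), big.mark = ",")
  ))
  if (nrow(x$positions) > 0L) print(x$positions, n = nrow(x$positions))
  invisible(x)
}

#' Render a template back to its IUPAC string
#'
#' Inverse of [parse_template()]: `render_template(parse_template(s))`
#' equals `toupper(s)` for any valid IUPAC string `s`.
#'
#' @param template A `degenerate_template`.
#' @return A single upper-case IUPAC string.
#' @export
render_template <- function(template) {
  stopifnot(inherits(template, "degenerate_template"))
  template$sequence
}

#' Library complexity of a degenerate template
#'
#' The number of distinct concrete sequences the template encodes: the
#' product over variable positions of the allowed-base set sizes. The
#' CARTIV GK library template ([cartiv_template()]) has 16 two-fold
#' degenerate positions, hence complexity 65,536.
#'
#' @param template A `degenerate_template`.
#' @return A positive number (1 for a fully fixed template).
#' @export
complexity <- function(template) {
  stopifnot(inherits(template, "degenerate_template"))
  prod(vapply(template$positions$allowed, length, integer(1)))
}

#' Realize full-length sequences from allele strings
#'
#' @param template A `degenerate_template`.
#' @param alleles Character vector of allele strings, one base per variable
#'   position in template order.
#' @return Character vector of full-length sequences.
#' @export
realize_variant <- function(template, alleles) {
  stopifnot(inherits(template, "degenerate_template"))
  pos <- template$positions
  if (nrow(pos) == 0L) {
    if (!all(!nzchar(alleles))) {
      abort("Template has no variable positions; alleles must be \"\".")
    }
    return(rep(template$sequence, length(alleles)))
  }
  if (any(nchar(alleles) != nrow(pos))) {
    abort(sprintf("Allele strings must have length %d.", nrow(pos)))
  }
  base <- strsplit(template$sequence, "", fixed = TRUE)[[1L]]
  amat <- matrix(
    unlist(strsplit(alleles, "", fixed = TRUE), use.names = FALSE),
    ncol = nrow(pos), byrow = TRUE
  )
  for (j in seq_len(nrow(pos))) {
    ok <- amat[, j] %in% pos$allowed[[j]]
    if (!all(ok)) {
      abort(sprintf(
        "Allele '%s' is not allowed at variable position %d (code %s).",
        amat[!ok, j][1L], pos$index[j], pos$code[j]
      ))
    }
  }
  vapply(seq_along(alleles), function(i) {
    s <- base
    s[pos$index + 1L] <- amat[i, ]
    paste(s, collapse = "")
  }, character(1))
}

#' Enumerate every variant of a degenerate template
#'
#' Expands the full allele space in deterministic lexicographic order over
#' the allele strings. Refuses templates whose complexity exceeds `limit`
#' (combinatorial guard) and suggests [sample_variants()] instead.
#'
#' @param template A `degenerate_template`.
#' @param limit Maximum complexity accepted for full enumeration
#'   (default `65536`, the CARTIV GK library size).
#' @return A tibble with columns `key` (the allele string, the canonical
#'   variant identifier) and `realized` (full-length sequence), one row per
#'   variant, `complexity(template)` rows in total.
#' @export
enumerate_variants <- function(template, limit = 65536) {
  stopifnot(inherits(template, "degenerate_template"))
  cx <- complexity(template)
  if (cx > limit) {
    abort(sprintf(
      paste0("Template complexity %s exceeds the enumeration limit %s; ",
             "use sample_variants() or raise `limit`."),
      format(cx, big.mark = ","), format(limit, big.mark = ",")
    ))
  }
  pos <- template$positions
  if (nrow(pos) == 0L) {
    return(tibble(key = "", realized = template$sequence))
  }
  grid <- expand.grid(
    lapply(pos$allowed, sort),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  keys <- sort(do.call(paste0, grid))
  tibble(key = keys, realized = realize_variant(template, keys))
}

#' Sample variants uniformly from the allele space
#'
#' Draws `n` i.i.d. uniform variants (each variable position sampled
#' independently and uniformly over its allowed set). Duplicates are
#' permitted; draws are reproducible given `seed`.
#'
#' @param template A `degenerate_template`.
#' @param n Number of draws (`n = 0` returns an empty tibble).
#' @param seed Optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @return A tibble with columns `key` and `realized`, `n` rows.
#' @export
sample_variants <- function(template, n, seed = NULL) {
  stopifnot(inherits(template, "degenerate_template"), n >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  pos <- template$positions
  if (n == 0L) return(tibble(key = character(), realized = character()))
  if (nrow(pos) == 0L) {
    return(tibble(key = rep("", n), realized = rep(template$sequence, n)))
  }
  draws <- lapply(pos$allowed, function(a) sample(sort(a), n, replace = TRUE))
  keys <- do.call(paste0, draws)
  tibble(key = keys, realized = realize_variant(template, keys))
}

#' The CARTIV GK promoter library template
#'
#' The degenerate single-stranded oligo used to build the GK CARTIV promoter
#' library: two GAS (STAT1/IFN-gamma) cores `AYTTCCSGGAART` separated by a
#' linker, followed by two kappa-B (NF-kB/TNF-alpha) cores `GGRRRTTYYC`
#' separated by a linker, upstream of a minimal TK core, with fixed cloning
#' flanks. It carries 16 two-fold degenerate positions (6 in the GAS block:
#' Y/S/R twice; 10 in the kappa block: R,R,R,Y,Y twice), giving a library
#' complexity of 65,536. Each variable position is labelled with its element
#' (`"GAS"` or `"kappa"`).
#'
#' @return A `degenerate_template` with an `element` column in `positions`.
#' @examples
#' tpl <- cartiv_template()
#' complexity(tpl)
#' @export
cartiv_template <- function() {
  oligo <- paste0(
    "cccggtcgcactagttctaga",
    "AYTTCCSGGAART", "AGGGTGGGCAAGT", "AYTTCCSGGAART",
    "tctaga",
    "GGRRRTTYYC", "GGGGACTTTCC", "GGRRRTTYYC",
    "tctaga",
    "TATTAAGGTGACGCGTGTGGCCTCGAACACCGAGCGACCCTGCAGCGACCCGCTTAAAA",
    "gcggccgcc", "ATG"
  )
  parse_template(oligo, elements = c(rep("GAS", 6), rep("kappa", 10)))
}

#' Read a template from plain text or single-record FASTA
#'
#' @param path Path to a file holding either a bare IUPAC string (one line,
#'   whitespace ignored) or a single-record FASTA.
#' @param elements Passed to [parse_template()].
#' @return A `degenerate_template`.
#' @export
read_template <- function(path, elements = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("No sequence found in '%s'.", path))
  if (startsWith(lines[[1L]], ">")) {
    headers <- which(startsWith(lines, ">"))
    if (length(headers) > 1L) {
      abort(sprintf("'%s' holds %d FASTA records; expected one.",
                    path, length(headers)))
    }
    lines <- lines[-1L]
  }
  parse_template(paste(gsub("\\s", "", lines), collapse = ""), elements)
}

#' Write variants to FASTA or TSV
#'
#' FASTA headers are the allele keys; the TSV has columns `key` and
#' `realized`.
#'
#' @param variants Tibble with columns `key` and `realized`
#'   (from [enumerate_variants()] or [sample_variants()]).
#' @param path Output file path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  stopifnot(all(c("key", "realized") %in% names(variants)))
  if (format == "fasta") {
    writeLines(rbind(paste0(">", variants$key), variants$realized), path)
  } else {
    utils::write.table(
      variants[, c("key", "realized")], path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
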