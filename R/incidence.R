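#' Binary haplotype-by-site data with haplotype frequencies
#'
#' An incidence matrix is the tabular form of an infinite-sites sample:
#' one row per distinct haplotype, one 0/1 column per segregating site
#' (0 = ancestral state, 1 = derived), plus a `freq` column giving the
#' number of sampled copies of each haplotype. The sample size `n` is the
#' sum of the frequencies.
#'
#' @param x Integer or logical matrix of 0/1 values, one row per distinct
#'   haplotype and one column per site.
#' @param freq Positive integer vector of haplotype frequencies, one per
#'   row of `x`.
#' @param site_labels Character vector of unique site labels; defaults to
#'   the column names of `x`, or `S1`, `S2`, ... when `x` has none.
#'
#' @return A tibble of class `incidence_matrix` with one column per site
#'   and a final `freq` column.
#'
#' @examples
#' m <- incidence_matrix(
#'   rbind(c(0, 1, 1, 0), c(1, 1, 1, 0), c(0, 0, 0, 0), c(0, 0, 0, 1)),
#'   freq = c(1, 1, 1, 1),
#'   site_labels = c("M1", "M2", "M3", "M4")
#' )
#' sample_size(m)
#' @export
incidence_matrix <- function(x, freq, site_labels = colnames(x)) {
  x <- as.matrix(x)
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (is.null(site_labels)) {
    site_labels <- if (ncol(x)) paste0("S", seq_len(ncol(x))) else character()
  }
  validate_incidence_parts(x, freq, site_labels)
  new_incidence_matrix(x, as.integer(freq), site_labels)
}

new_incidence_matrix <- function(x, freq, site_labels) {
  cols <- c(
    setNames(lapply(seq_along(site_labels), function(j) as.integer(x[, j])),
             site_labels),
    list(freq = as.integer(freq))
  )
  out <- tibble::new_tibble(cols, nrow = nrow(x),
                            class = "incidence_matrix")
  out
}

validate_incidence_parts <- function(x, freq, site_labels) {
  if (!nrow(x)) abort_format("incidence matrix must have at least one row")
  if (length(site_labels) != ncol(x)) {
    abort_format("number of site labels must equal the number of site columns")
  }
  if (anyDuplicated(site_labels)) {
    dup <- site_labels[duplicated(site_labels)][1]
    abort_format(sprintf("duplicate site label '%s'", dup))
  }
  if (any(!nzchar(site_labels)) || any(is.na(site_labels))) {
    abort_format("site labels must be non-empty")
  }
  if (any(site_labels == "freq")) {
    abort_format("'freq' is reserved for the frequency column")
  }
  bad_label <- grepl("[{}|(),\t ]", site_labels)
  if (any(bad_label)) {
    abort_format(sprintf(
      "site label '%s' contains a reserved character ({}|(), space or tab)",
      site_labels[bad_label][1]))
  }
  bad <- which(!(x %in% c(0L, 1L)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    abort_format(sprintf(
      "non-binary value '%s' at row %d, site '%s'", x[i, j], i, site_labels[j]))
  }
  if (length(freq) != nrow(x)) {
    abort_format("one frequency is required per haplotype row")
  }
  if (any(is.na(freq)) || any(freq != as.integer(freq)) || any(freq < 1)) {
    abort_format("frequencies must be positive integers")
  }
  if (ncol(x)) {
    key <- apply(x, 1, paste, collapse = "")
    if (anyDuplicated(key)) {
      abort_format(sprintf("duplicate haplotype pattern at row %d",
                           which(duplicated(key))[1]))
    }
  } else if (nrow(x) > 1) {
    abort_format("a zero-site matrix has a single (all-ancestral) haplotype")
  }
  invisible(TRUE)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d haplotype(s), %d site(s), n = %d\n",
              nrow(x), length(site_labels(x)), sample_size(x)))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Accessors for incidence matrices
#'
#' `site_labels()` returns the ordered site labels, `haplotype_patterns()`
#' the 0/1 matrix of distinct haplotypes, `haplotype_freq()` the per-row
#' frequencies, and `sample_size()` the total sample size `n`.
#'
#' @param m An [incidence_matrix].
#' @return A character vector, integer matrix, integer vector, or a single
#'   integer respectively.
#' @export
site_labels <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  setdiff(names(m), "freq")
}

#' @rdname site_labels
#' @export
haplotype_patterns <- function(m) {
  lab <- site_labels(m)
  out <- matrix(0L, nrow = nrow(m), ncol = length(lab),
                dimnames = list(NULL, lab))
  for (j in seq_along(lab)) out[, j] <- m[[lab[j]]]
  out
}

#' @rdname site_labels
#' @export
haplotype_freq <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  m[["freq"]]
}

#' @rdname site_labels
#' @export
sample_size <- function(m) {
  sum(haplotype_freq(m))
}

# Collapse possibly repeated per-individual rows into distinct patterns with
# counts, preserving first-occurrence order.
collapse_patterns <- function(x) {
  if (!nrow(x)) abort_format("no data rows")
  key <- if (ncol(x)) apply(x, 1, paste, collapse = "") else rep("", nrow(x))
  first <- !duplicated(key)
  freq <- as.integer(table(factor(key, levels = key[first])))
  list(patterns = x[first, , drop = FALSE], freq = freq)
}

# Drop all-zero (non-segregating) columns with a warning; mutations absent
# from every haplotype carry no information for the recursion.
drop_nonsegregating <- function(x, site_labels) {
  if (!ncol(x)) return(list(patterns = x, site_labels = site_labels))
  zero <- colSums(x) == 0L
  if (any(zero)) {
    warn(sprintf("dropped %d non-segregating (all-zero) site column(s): %s",
                 sum(zero), paste(site_labels[zero], collapse = ", ")),
         class = "coalexact_dropped_sites")
  }
  list(patterns = x[, !zero, drop = FALSE], site_labels = site_labels[!zero])
}

#' Read an incidence matrix from a TSV file
#'
#' Two dialects are supported. The haplotype-frequency dialect has a header
#' of site labels whose last column is literally named `freq`; each row is a
#' distinct haplotype with its count. The per-individual dialect has no
#' `freq` column and one row per sampled individual; repeated rows are
#' collapsed into distinct haplotypes with counts, preserving first-occurrence
#' order. Lines starting with `#` are comments. In both dialects all-zero
#' (non-segregating) columns are dropped with a warning.
#'
#' @param file Path to a TSV file (or a connection).
#' @param dialect `"auto"` (default; decided by the presence of a trailing
#'   `freq` header column), `"haplotype-frequency"`, or `"per-individual"`.
#'
#' @return An [incidence_matrix].
#' @export
read_incidence_matrix <- function(file,
                                  dialect = c("auto", "haplotype-frequency",
                                              "per-individual")) {
  dialect <- arg_match(dialect)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(sub("\\s+$", "", lines))]
  if (!length(lines)) abort_format("empty input: no header line")

  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_freq <- length(header) >= 1 && header[length(header)] == "freq"
  if (dialect == "auto") {
    dialect <- if (has_freq) "haplotype-frequency" else "per-individual"
  }
  if (dialect == "haplotype-frequency" && !has_freq) {
    abort_format("haplotype-frequency dialect requires a final 'freq' column")
  }
  if (dialect == "per-individual" && has_freq) {
    abort_format("per-individual dialect must not have a 'freq' column")
  }
  labels <- if (has_freq) header[-length(header)] else header
  if (anyDuplicated(labels)) {
    abort_format(sprintf("duplicate site label '%s' in header",
                         labels[duplicated(labels)][1]))
  }

  body <- lines[-1]
  if (!length(body)) abort_format("no data rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  width <- length(header)
  lens <- lengths(cells)
  if (any(lens != width)) {
    abort_format(sprintf("row %d has %d field(s); expected %d",
                         which(lens != width)[1], lens[lens != width][1], width))
  }

  parse_bin <- function(row, i) {
    v <- row[seq_along(labels)]
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      abort_format(sprintf("non-binary value '%s' at data row %d, site '%s'",
                           v[!ok][1], i, labels[!ok][1]))
    }
    as.integer(v)
  }
  x <- matrix(0L, nrow = length(cells), ncol = length(labels))
  for (i in seq_along(cells)) if (length(labels)) x[i, ] <- parse_bin(cells[[i]], i)

  if (has_freq) {
    fr <- vapply(cells, function(row) row[width], "")
    fr_ok <- grepl("^[0-9]+$", fr) & suppressWarnings(as.numeric(fr) >= 1)
    if (!all(fr_ok)) {
      bad <- which(!fr_ok)[1]
      abort_format(sprintf("frequency '%s' at data row %d is not a positive integer",
                           fr[bad], bad))
    }
    freq <- as.integer(fr)
  } else {
    collapsed <- collapse_patterns(x)
    x <- collapsed$patterns
    freq <- collapsed$freq
  }

  kept <- drop_nonsegregating(x, labels)
  x <- kept$patterns
  labels <- kept$site_labels
  if (!ncol(x) && nrow(x) > 1) {
    # all sites dropped: haplotypes merge into the single ancestral pattern
    freq <- sum(freq)
    x <- x[1, , drop = FALSE]
  }
  incidence_matrix(x, freq, labels)
}

#' Write an incidence matrix as TSV
#'
#' Writes the haplotype-frequency dialect understood by
#' [read_incidence_matrix()]; a write/read cycle reproduces the matrix
#' exactly.
#'
#' @param m An [incidence_matrix].
#' @param file Path or connection to write to.
#' @return `m`, invisibly.
#' @export
write_incidence_matrix <- function(m, file) {
  stopifnot(inherits(m, "incidence_matrix"))
  lab <- site_labels(m)
  pat <- haplotype_patterns(m)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(pat[i, ], haplotype_freq(m)[i]), collapse = "\t")
  }, "")
  writeLines(c(paste(c(lab, "freq"), collapse = "\t"), rows), con = file)
  invisible(m)
}
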