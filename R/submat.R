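# The 20 standard amino acids in NCBI matrix order.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse an amino-acid substitution matrix in NCBI BLAST text format
#'
#' Reads the whitespace-separated matrix format distributed with standalone
#' BLAST (header row of residue codes, one labelled score row per residue,
#' `#` comment lines). Ambiguity and stop codes (B, Z, X, *) present in the
#' file are parsed and then dropped: the returned object is restricted to
#' the 20 standard residues, and all downstream probability calculus
#' operates on that alphabet only.
#'
#' @param file Path to a matrix file, or a character vector of its lines.
#' @param name Matrix name; defaults to the file's base name.
#' @return An object of class `substitution_matrix`: a list with `name`,
#'   `alphabet` (the 20 standard one-letter codes) and `scores`, a 20 x 20
#'   symmetric integer matrix with dimnames equal to the alphabet, where
#'   `scores[x, y]` is the score of substituting residue y by residue x.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' m$scores["L", "L"]  # 4
#' m$scores["I", "V"]  # 3
#' @export
parse_substitution_matrix <- function(file, name = NULL) {
  if (length(file) == 1L && file.exists(file)) {
    if (is.null(name)) name <- basename(file)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(name)) name <- "matrix"
  }
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix format error: need a header row and at least one score row")

  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  row_labels <- vapply(rows, `[`, character(1L), 1L)
  bad <- vapply(rows, length, integer(1L)) != length(header) + 1L
  if (any(bad))
    stop("matrix format error: row '", row_labels[which(bad)[1L]],
         "' has the wrong number of scores")

  full <- matrix(NA_integer_, length(row_labels), length(header),
                 dimnames = list(row_labels, header))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.integer(rows[[i]][-1L]))
    if (anyNA(v))
      stop("matrix format error: non-integer score in row '",
           row_labels[i], "'")
    full[i, ] <- v
  }

  missing <- setdiff(AA_ALPHABET, intersect(rownames(full), colnames(full)))
  if (length(missing))
    stop("matrix format error: missing standard residue(s): ",
         paste(missing, collapse = ", "))
  scores <- full[AA_ALPHABET, AA_ALPHABET]
  if (!identical(scores, t(scores))) {
    ij <- which(scores != t(scores), arr.ind = TRUE)[1L, ]
    stop("matrix validation error: asymmetric entry S(",
         AA_ALPHABET[ij[1L]], ",", AA_ALPHABET[ij[2L]], ")")
  }
  if (any(diag(scores) <= 0L))
    stop("matrix validation error: non-positive diagonal score")

  structure(list(name = name, alphabet = AA_ALPHABET, scores = scores),
            class = "substitution_matrix")
}

#' Load a bundled substitution matrix
#'
#' BLOSUM45, BLOSUM62, BLOSUM80, PAM30, PAM70 and PAM250 are shipped
#' verbatim in the NCBI text format under `inst/extdata/matrices`.
#'
#' @param name Matrix name, e.g. `"BLOSUM62"` (case-insensitive).
#' @return A `substitution_matrix`.
#' @export
load_substitution_matrix <- function(name = "BLOSUM62") {
  name <- toupper(name)
  path <- system.file("extdata", "matrices", name, package = "ddsm")
  if (!nzchar(path))
    stop("no bundled matrix named '", name, "'; available: ",
         paste(bundled_matrix_names(), collapse = ", "))
  parse_substitution_matrix(path, name = name)
}

#' Names of the bundled substitution matrices
#' @return Character vector of matrix names.
#' @export
bundled_matrix_names <- function() {
  sort(dir(system.file("extdata", "matrices", package = "ddsm")))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("Substitution matrix", x$name, "(20 x 20, symmetric)\n")
  print(x$scores[1:5, 1:5])
  cat("...\n")
  invisible(x)
}

#' Per-residue conservation probability
#'
#' The probability that residue `x` does not mutate to any other residue,
#' defined from the matrix as the diagonal score divided by the sum of all
#' strictly positive scores in x's row:
#' `P(x) = S(x,x) / sum over y with S(x,y) > 0 of S(x,y)`.
#' It equals 1 exactly when the diagonal is the row's only positive entry
#' (e.g. G, C and P under BLOSUM62).
#'
#' @param m A `substitution_matrix`.
#' @param x A single standard residue code.
#' @return A probability in (0, 1].
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' residue_conservation(m, "G")  # 1
#' residue_conservation(m, "L")  # 4/9
#' @export
residue_conservation <- function(m, x) {
  stopifnot(inherits(m, "substitution_matrix"))
  if (!(is.character(x) && length(x) == 1L && x %in% m$alphabet))
    stop("'", x, "' is not a standard amino-acid residue")
  row <- m$scores[x, ]
  m$scores[x, x] / sum(row[row > 0L])
}
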