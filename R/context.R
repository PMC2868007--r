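# Binary learning/test context construction and ARFF/CSV serialization.

#' Build a binary learning context
#'
#' Encodes a labeled sequence set against a feature list as a 0/1 table
#' (the learning context). In `exact` mode a cell is 1 iff the feature
#' occurs as a substring of the sequence. In `substitute_aware` mode — the
#' DDSM rule — a cell is 1 iff some window of the sequence (same length as
#' the feature, not spanning a non-standard residue) is substitutable by
#' the feature under the matrix and threshold, so the presence of a motif
#' or of one of its substitutes is marked alike. A test context must be
#' built with the learning context's frozen feature list.
#'
#' @param s A `labeled_set`.
#' @param f A `feature_set` or character vector of features.
#' @param mode `"exact"` or `"substitute_aware"`.
#' @param m A `substitution_matrix`; required in substitute-aware mode.
#' @param T Substitution threshold; required in substitute-aware mode.
#' @return An object of class `binary_context`: list with `features`,
#'   `data` (integer 0/1 matrix, sequences x features), `ids`, `labels`.
#' @examples
#' s <- labeled_set("s1", "MRVM", "A")
#' m <- load_substitution_matrix("BLOSUM62")
#' build_context(s, "RI", "exact")$data[1, 1]                   # 0
#' build_context(s, "RI", "substitute_aware", m, 0.5)$data[1, 1] # 1
#' @export
build_context <- function(s, f, mode = c("exact", "substitute_aware"),
                          m = NULL, T = NULL) {
  stopifnot(inherits(s, "labeled_set"))
  mode <- match.arg(mode)
  feats <- if (inherits(f, "feature_set")) f$features else as.character(f)
  if (!length(feats)) stop("empty feature set")
  if (anyDuplicated(feats))
    stop("duplicate feature name(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  if (mode == "substitute_aware" && (is.null(m) || is.null(T)))
    stop("substitute-aware mode requires a substitution matrix and T")

  dat <- matrix(0L, nrow(s), length(feats),
                dimnames = list(s$id, feats))
  if (mode == "exact") {
    for (j in seq_along(feats))
      dat[, j] <- as.integer(grepl(feats[j], s$sequence, fixed = TRUE))
  } else {
    seg_list <- lapply(s$sequence, standard_segments)
    for (j in seq_along(feats)) {
      fe <- feats[j]
      k <- nchar(fe)
      dat[, j] <- vapply(seg_list, function(segs) {
        for (seg in segs) {
          n <- nchar(seg)
          if (n < k) next
          for (w in unique(substring(seg, 1:(n - k + 1L), k:n)))
            if (can_substitute(fe, w, m, T)) return(1L)
        }
        0L
      }, integer(1L))
    }
  }
  structure(list(features = feats, data = dat, ids = s$id,
                 labels = s$family,
                 params = list(mode = mode,
                               matrix = if (!is.null(m)) m$name,
                               T = T)),
            class = "binary_context")
}

#' @export
print.binary_context <- function(x, ...) {
  cat("Binary context: ", length(x$ids), " sequences x ",
      length(x$features), " features (", x$params$mode, ")\n", sep = "")
  invisible(x)
}

arff_quote <- function(x) {
  needs <- grepl("[ ,'\"{}%]", x)
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs]), "'")
  x
}

#' Write a binary context in ARFF format
#'
#' WEKA dialect: every feature is a nominal `{0,1}` attribute named by its
#' motif string, and the class labels form the final nominal attribute.
#'
#' @param c A `binary_context`.
#' @param path Output path; omit to return the text invisibly.
#' @param relation_name `@relation` name.
#' @return The ARFF text, invisibly.
#' @export
write_arff <- function(c, path = NULL, relation_name = "ddsm") {
  stopifnot(inherits(c, "binary_context"))
  if (anyDuplicated(c$features)) stop("duplicate feature names")
  if (length(c$ids) == 0L) stop("context has no rows")
  classes <- sort(unique(c$labels), method = "radix")
  lines <- c(
    paste0("@relation ", arff_quote(relation_name)),
    "",
    paste0("@attribute ", arff_quote(c$features), " {0,1}"),
    paste0("@attribute class {",
           paste(arff_quote(classes), collapse = ","), "}"),
    "",
    "@data",
    paste0(apply(c$data, 1L, paste, collapse = ","), ",",
           arff_quote(c$labels))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}

#' Write a binary context as CSV
#'
#' Header is the feature names plus a final `class` column; RFC-4180
#' quoting via [utils::write.csv()].
#'
#' @param c A `binary_context`.
#' @param path Output path.
#' @export
write_context_csv <- function(c, path) {
  stopifnot(inherits(c, "binary_context"))
  df <- as.data.frame(c$data, check.names = FALSE)
  df$class <- c$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a context CSV back into a binary context
#'
#' Inverse of [write_context_csv()]; ids are regenerated as row numbers
#' unless supplied.
#'
#' @param path CSV path.
#' @param ids Optional sequence ids.
#' @return A `binary_context`.
#' @export
read_context_csv <- function(path, ids = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  feats <- setdiff(names(df), "class")
  dat <- as.matrix(df[feats])
  storage.mode(dat) <- "integer"
  if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
  rownames(dat) <- ids
  structure(list(features = feats, data = dat, ids = ids,
                 labels = df$class, params = list(mode = "exact",
                                                  matrix = NULL, T = NULL)),
            class = "binary_context")
}
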