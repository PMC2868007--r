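# FASTA and label I/O, the labeled sequence set container.

#' Read a FASTA file of protein sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]. Record ids are the
#' first whitespace-delimited token of each header; sequences are uppercased
#' with line breaks joined.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = ids), in file order.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA format error: '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Build a labeled sequence set
#'
#' A labeled sequence set holds n protein sequences partitioned into
#' families (classes). Residues outside the 20-letter standard alphabet are
#' kept in the strings but act as motif separators everywhere downstream:
#' no extracted motif or matched window may span one.
#'
#' @param ids Character vector of unique sequence ids.
#' @param sequences Character vector of residue strings (uppercased here).
#' @param families Character vector of class labels, one per sequence.
#' @return An object of class `labeled_set`: a data.frame with columns
#'   `id`, `sequence`, `family`.
#' @export
labeled_set <- function(ids, sequences, families) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(families))
  if (length(ids) == 0L) stop("empty sequence set")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(is.na(families) | !nzchar(families)))
    stop("every sequence must carry a family label")
  df <- data.frame(id = as.character(ids),
                   sequence = toupper(as.character(sequences)),
                   family = as.character(families),
                   stringsAsFactors = FALSE)
  class(df) <- c("labeled_set", "data.frame")
  df
}

#' @export
print.labeled_set <- function(x, ...) {
  tab <- table(x$family)
  cat("Labeled sequence set: ", nrow(x), " sequences, ",
      length(tab), " families\n", sep = "")
  for (f in names(tab)) cat("  ", f, ": ", tab[[f]], "\n", sep = "")
  invisible(x)
}

#' Load a labeled set from class-partitioned FASTA files or a label table
#'
#' Two input layouts are supported, mirroring how classification corpora
#' are distributed: one FASTA file per class (`fasta_paths` named by class
#' label), or a single FASTA plus a two-column id/label table.
#'
#' @param fasta_paths Named character vector of FASTA paths; names are the
#'   family labels. Or a single unnamed path when `labels` is given.
#' @param labels Optional data.frame (or TSV path) with columns id, family.
#' @return A `labeled_set`.
#' @export
load_labeled_set <- function(fasta_paths, labels = NULL) {
  if (is.null(labels)) {
    if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths))))
      stop("fasta_paths must be named by family label")
    parts <- lapply(names(fasta_paths), function(lab) {
      seqs <- read_fasta(fasta_paths[[lab]])
      data.frame(id = names(seqs), sequence = unname(seqs), family = lab,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, parts)
  } else {
    stopifnot(length(fasta_paths) == 1L)
    seqs <- read_fasta(fasta_paths)
    if (is.character(labels) && length(labels) == 1L)
      labels <- utils::read.delim(labels, header = TRUE,
                                  stringsAsFactors = FALSE)
    names(labels)[1:2] <- c("id", "family")
    miss <- setdiff(names(seqs), labels$id)
    if (length(miss))
      stop("unlabeled sequence id(s): ", paste(miss, collapse = ", "))
    df <- data.frame(id = names(seqs), sequence = unname(seqs),
                     family = labels$family[match(names(seqs), labels$id)],
                     stringsAsFactors = FALSE)
  }
  labeled_set(df$id, df$sequence, df$family)
}

# Maximal runs of standard residues; non-standard codes (B, Z, X, U, *, ...)
# separate motifs.
standard_segments <- function(seq) {
  pat <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]+")
  segs <- strsplit(gsub(pat, "\n", toupper(seq)), "\n", fixed = TRUE)[[1L]]
  segs[nzchar(segs)]
}
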