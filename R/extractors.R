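# Feature construction: N-grams, amino acid composition, active motifs,
# discriminative descriptors (repeats + alpha/beta discrimination +
# minimality), and the substitution-matrix-clustered DDSM features.

feature_set <- function(method, features, params = list()) {
  structure(list(method = method, features = as.character(features),
                 params = params),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set [", x$method, "]: ", length(x$features),
      " features\n", sep = "")
  cat(paste(utils::head(x$features, 10L), collapse = " "), "\n")
  invisible(x)
}

#' Write a feature set as a plain text list
#'
#' One motif per line, preceded by a `# method/params` comment header.
#' @param f A `feature_set`.
#' @param path Output file path.
#' @export
write_feature_set <- function(f, path) {
  stopifnot(inherits(f, "feature_set"))
  hdr <- paste0("# ", f$method,
                if (length(f$params))
                  paste0(" ", paste(names(f$params), unlist(f$params),
                                    sep = "=", collapse = " ")))
  writeLines(c(hdr, f$features), path)
  invisible(path)
}

all_substrings <- function(segment, min_len, max_len) {
  n <- nchar(segment)
  if (n < min_len) return(character(0L))
  out <- vector("list", min(max_len, n) - min_len + 1L)
  k <- 0L
  for (len in min_len:min(max_len, n)) {
    k <- k + 1L
    out[[k]] <- substring(segment, 1:(n - len + 1L), len:n)
  }
  unlist(out)
}

#' Extract distinct N-grams from a sequence set
#'
#' Slides a window of N residues character by character over every
#' sequence and keeps the distinct subsequences. Windows containing a
#' non-standard residue are skipped.
#'
#' @param s A `labeled_set`.
#' @param N Window length (>= 1).
#' @return A `feature_set` with method `"NG"`, features in first-occurrence
#'   order.
#' @export
extract_ngrams <- function(s, N = 3L) {
  stopifnot(inherits(s, "labeled_set"), N >= 1L)
  grams <- unlist(lapply(s$sequence, function(seq)
    unlist(lapply(standard_segments(seq), all_substrings, N, N))))
  if (is.null(grams) || !length(grams)) {
    warning("no sequence admits a window of length ", N)
    grams <- character(0L)
  }
  feature_set("NG", unique(grams), list(N = N))
}

#' Amino acid composition of a protein sequence
#'
#' Occurrence frequency of each of the 20 standard amino acids in the
#' sequence. Non-standard codes are ignored; the frequencies sum to 1
#' whenever at least one standard residue is present.
#'
#' @param seq A residue string.
#' @return Named numeric vector of length 20 (names = residues).
#' @export
amino_acid_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ch <- ch[ch %in% AA_ALPHABET]
  if (!length(ch))
    stop("sequence contains no standard amino-acid residue")
  counts <- table(factor(ch, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(ch), AA_ALPHABET)
}

# Does `sequence` contain a window matching `motif` within <= mut Hamming
# substitutions, with windows confined to runs of standard residues?
matches_within <- function(motif, sequence, mut = 0L) {
  k <- nchar(motif)
  if (mut == 0L) return(grepl(motif, sequence, fixed = TRUE))
  mc <- strsplit(motif, "", fixed = TRUE)[[1L]]
  for (seg in standard_segments(sequence)) {
    n <- nchar(seg)
    if (n < k) next
    sc <- strsplit(seg, "", fixed = TRUE)[[1L]]
    for (i in 1:(n - k + 1L))
      if (sum(sc[i:(i + k - 1L)] != mc) <= mut) return(TRUE)
  }
  FALSE
}

#' Extract active motifs
#'
#' Commonly occurring motifs longer than a minimum length. The activity of
#' a motif is the number of sequences that contain a match within an
#' allowed number of point mutations (Hamming substitutions, no indels);
#' motifs whose activity reaches `activity_pct` percent of the sequence set
#' are retained. Activity counts sequences across all families.
#'
#' @param s A `labeled_set`.
#' @param min_length Minimum motif length (>= 1).
#' @param activity_pct Activity threshold as a percentage in (0, 100].
#' @param mutations Allowed Hamming substitutions per match (default 0).
#' @param feature_cap Abort with an error when the candidate count exceeds
#'   this cap; motif enumeration blows up on large heterogeneous sets.
#' @return A `feature_set` with method `"AM"`.
#' @export
extract_active_motifs <- function(s, min_length = 3L, activity_pct = 25,
                                  mutations = 0L, feature_cap = 20000L) {
  stopifnot(inherits(s, "labeled_set"), min_length >= 1L,
            activity_pct > 0, activity_pct <= 100, mutations >= 0L)
  cands <- unique(unlist(lapply(s$sequence, function(seq)
    unlist(lapply(standard_segments(seq), function(seg)
      all_substrings(seg, min_length, nchar(seg)))))))
  if (is.null(cands)) cands <- character(0L)
  if (length(cands) > feature_cap)
    stop("too many attributes: ", length(cands),
         " candidate motifs exceed the cap of ", feature_cap)
  need <- activity_pct / 100 * nrow(s)
  active <- vapply(cands, function(mo)
    sum(vapply(s$sequence, function(seq)
      matches_within(mo, seq, mutations), logical(1L))) >= need,
    logical(1L))
  feats <- cands[active]
  feats <- feats[order(-nchar(feats), feats, method = "radix")]
  feature_set("AM", feats,
              list(min_length = min_length, activity_pct = activity_pct,
                   mutations = mutations))
}

#' Extract repeated motifs within a family
#'
#' Identifies the substrings of length within `[min_length, max_length]`
#' that repeat across a family: present in at least two distinct sequences,
#' or — for a single-sequence family — occurring at least twice within that
#' sequence. Equivalent to KMR-style repeat finding at these scales. The
#' finder itself is alphabet-agnostic; protein callers (the discriminative
#' descriptor pipeline) set `nonstandard_separators` so that no repeat
#' spans an ambiguity code.
#'
#' @param family Character vector of strings.
#' @param min_length,max_length Length bounds for the repeats.
#' @param nonstandard_separators When TRUE, characters outside the
#'   20-letter amino-acid alphabet split each string into independent
#'   segments before enumeration.
#' @return Character vector of repeat motifs (length desc, then
#'   lexicographic).
#' @export
extract_repeats <- function(family, min_length = 3L, max_length = 10L,
                            nonstandard_separators = FALSE) {
  stopifnot(length(family) >= 1L, min_length >= 1L,
            max_length >= min_length)
  pieces <- if (nonstandard_separators) standard_segments else identity
  per_seq <- lapply(family, function(seq)
    unlist(lapply(pieces(seq), all_substrings, min_length, max_length)))
  if (length(family) == 1L) {
    counts <- table(per_seq[[1L]])
    reps <- names(counts)[counts >= 2L]
  } else {
    seen <- table(unlist(lapply(per_seq, unique)))
    reps <- names(seen)[seen >= 2L]
  }
  if (is.null(reps)) reps <- character(0L)
  reps[order(-nchar(reps), reps, method = "radix")]
}

# Fraction of a family's sequences containing motif X as a substring.
containment_rate <- function(X, sequences) {
  mean(grepl(X, sequences, fixed = TRUE))
}

#' Filter repeats into discriminative, minimal descriptors
#'
#' A motif X is a discriminative descriptor of family F_i when it covers
#' the family (contained in at least a fraction `alpha` of F_i's
#' sequences) and is near-exclusive to it (contained in at most a fraction
#' `beta` of every other family's sequences). Minimality pruning then
#' removes any retained motif that has a proper substring retained for the
#' same family.
#'
#' @param repeats_by_family Named list, family label -> repeat motifs.
#' @param s A `labeled_set` covering the same families.
#' @param alpha Coverage threshold in [0, 1].
#' @param beta Exclusivity bound in [0, 1]; `beta = 1` disables the
#'   cross-family check.
#' @return A `feature_set` with method `"DD"` (union over families,
#'   deduplicated, length desc then lexicographic order).
#' @export
dd_filter <- function(repeats_by_family, s, alpha = 0, beta = 0) {
  stopifnot(inherits(s, "labeled_set"),
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  fams <- names(repeats_by_family)
  stopifnot(!is.null(fams), all(fams %in% s$family))
  seqs_of <- split(s$sequence, s$family)
  kept <- lapply(fams, function(fi) {
    reps <- unique(repeats_by_family[[fi]])
    if (!length(reps)) return(character(0L))
    ok <- vapply(reps, function(X) {
      if (containment_rate(X, seqs_of[[fi]]) < alpha) return(FALSE)
      if (beta < 1) {
        for (fj in setdiff(names(seqs_of), fi))
          if (containment_rate(X, seqs_of[[fj]]) > beta) return(FALSE)
      }
      TRUE
    }, logical(1L))
    disc <- reps[ok]
    # minimality: drop X when a proper substring of X is also retained
    minimal <- vapply(disc, function(X)
      !any(vapply(disc, function(Y)
        nchar(Y) < nchar(X) && grepl(Y, X, fixed = TRUE), logical(1L))),
      logical(1L))
    disc[minimal]
  })
  feats <- unique(unlist(kept))
  if (is.null(feats)) feats <- character(0L)
  feats <- feats[order(-nchar(feats), feats, method = "radix")]
  feature_set("DD", feats, list(alpha = alpha, beta = beta))
}

#' Discriminative descriptors for a labeled set
#'
#' Convenience pipeline: per-family repeat extraction followed by
#' [dd_filter()].
#'
#' @inheritParams dd_filter
#' @inheritParams extract_repeats
#' @return A `feature_set` with method `"DD"`.
#' @export
extract_dd <- function(s, alpha = 0, beta = 0, min_length = 3L,
                       max_length = 10L) {
  reps <- lapply(split(s$sequence, s$family), extract_repeats,
                 min_length, max_length, nonstandard_separators = TRUE)
  f <- dd_filter(reps, s, alpha, beta)
  f$params <- c(f$params, list(min_length = min_length,
                               max_length = max_length))
  f
}

#' DDSM features: discriminative descriptors collapsed by substitutability
#'
#' Runs the discriminative-descriptor pipeline, then clusters the features
#' under a substitution matrix and keeps one main motif per cluster of
#' mutually substitutable, equal-length motifs. The feature count never
#' exceeds the DD feature count.
#'
#' @inheritParams extract_dd
#' @param m A `substitution_matrix`.
#' @param T Substitution probability threshold in [0, 1].
#' @return A `feature_set` with method `"DDSM"`; the clustering is kept in
#'   `$clustering` for substitute-aware context construction.
#' @export
extract_ddsm <- function(s, alpha = 0, beta = 0,
                         m = load_substitution_matrix("BLOSUM62"),
                         T = 0.9, min_length = 3L, max_length = 10L) {
  dd <- extract_dd(s, alpha, beta, min_length, max_length)
  if (!length(dd$features)) {
    f <- feature_set("DDSM", character(0L),
                     c(dd$params, list(matrix = m$name, T = T)))
    f$clustering <- NULL
    return(f)
  }
  cl <- cluster_motifs(dd$features, m, T)
  f <- feature_set("DDSM", filter_main_motifs(cl),
                   c(dd$params, list(matrix = m$name, T = T)))
  f$clustering <- cl
  f
}
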