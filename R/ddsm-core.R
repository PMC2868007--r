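# The DDSM motif calculus: mutation probability, motif substitution
# score/probability, the three substitution conditions, clustering into
# main-motif clusters, and filtering.

check_motif <- function(M, alphabet = AA_ALPHABET) {
  if (!(is.character(M) && length(M) == 1L && nzchar(M)))
    stop("motif must be a single non-empty string")
  ch <- strsplit(M, "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, alphabet)
  if (length(bad))
    stop("motif '", M, "' contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "))
  ch
}

#' Motif mutation probability P_m
#'
#' The probability that a motif mutates to another motif, computed as one
#' minus the product of its residues' conservation probabilities:
#' `P_m(M) = 1 - prod_i P(M[i])`. It is 0 exactly when every residue of the
#' motif is fully conserved (its matrix row has no positive off-diagonal
#' score), and always strictly below 1.
#'
#' @param M Motif string over the 20-letter amino-acid alphabet.
#' @param m A `substitution_matrix`.
#' @return A probability in [0, 1).
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' motif_mutation_prob("LLK", m)  # 0.8902...
#' motif_mutation_prob("GGP", m)  # 0
#' @export
motif_mutation_prob <- function(M, m) {
  ch <- check_motif(M)
  p <- vapply(ch, function(x) residue_conservation(m, x), numeric(1L))
  1 - prod(p)
}

#' Motif substitution score S_m
#'
#' Position-wise sum of residue substitution scores between two motifs of
#' equal length: `S_m(X, Y) = sum_i S(X[i], Y[i])`.
#'
#' @param X,Y Motif strings of equal length.
#' @param m A `substitution_matrix`.
#' @return An integer score; `S_m(X, X) > 0` always.
#' @export
motif_substitution_score <- function(X, Y, m) {
  cx <- check_motif(X); cy <- check_motif(Y)
  if (length(cx) != length(cy))
    stop("motifs must have equal length")
  sum(m$scores[cbind(cx, cy)])
}

#' Substitution probability SP
#'
#' The probability that motif `M` substitutes motif `Mp`, normalised by M's
#' self-score: `SP(M, M') = S_m(M, M') / S_m(M, M)`. The best substitute of
#' any motif is itself, so `SP(M, M) = 1`.
#'
#' @param M,Mp Motif strings of equal length.
#' @param m A `substitution_matrix`.
#' @return A numeric value; within [0, 1] whenever the position-wise
#'   non-negativity condition holds.
#' @export
substitution_prob <- function(M, Mp, m) {
  motif_substitution_score(M, Mp, m) / motif_substitution_score(M, M, m)
}

#' Can motif M substitute motif M'?
#'
#' True iff all three substitution conditions hold: (1) equal length,
#' (2) every position-wise score `S(M[i], M'[i])` is >= 0, and
#' (3) `SP(M, M') >= T`.
#'
#' @param M,Mp Motif strings.
#' @param m A `substitution_matrix`.
#' @param T Substitution probability threshold in [0, 1].
#' @return Logical.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' can_substitute("RI", "RV", m, T = 0.5)  # TRUE  (SP = 8/9)
#' can_substitute("RI", "RA", m, T = 0)    # FALSE (S(I,A) = -1)
#' @export
can_substitute <- function(M, Mp, m, T = 0.9) {
  stopifnot(T >= 0, T <= 1)
  cx <- check_motif(M); cy <- check_motif(Mp)
  if (length(cx) != length(cy)) return(FALSE)
  pos <- m$scores[cbind(cx, cy)]
  if (any(pos < 0L)) return(FALSE)
  sum(pos) / motif_substitution_score(M, M, m) >= T
}

# Canonical motif order: length descending, then P_m descending, then
# lexicographic. Radix sort gives locale-independent (C) collation.
order_motifs <- function(motifs, pm) {
  order(-nchar(motifs), -pm, motifs, method = "radix")
}

#' Cluster motifs into main-motif clusters
#'
#' Assigns every motif M' to a main motif: the motif M, among all motifs
#' that can substitute M' (M' itself always qualifies), with the highest
#' mutation probability P_m; ties break to the lexicographically smaller
#' motif. A motif may be substitutable by members of several clusters; it
#' then belongs to the cluster whose main motif wins the P_m comparison,
#' while possibly being the main motif of another cluster itself.
#'
#' @param motifs Character vector of motifs (duplicates removed).
#' @param m A `substitution_matrix`.
#' @param T Substitution probability threshold in [0, 1].
#' @return An object of class `motif_clustering`: list with `main_of`
#'   (named character vector, motif -> main motif), `clusters` (list, main
#'   motif -> member motifs), `pm` (named numeric), and `params`.
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' cl <- cluster_motifs(c("LLK", "IMK", "VMK", "GGP", "RI", "RV",
#'                        "RF", "RA", "PP"), m, T = 0.5)
#' cl$main_of[["RA"]]     # "RV"
#' length(cl$clusters)    # 5
#' @export
cluster_motifs <- function(motifs, m, T = 0.9) {
  stopifnot(length(motifs) > 0L, T >= 0, T <= 1)
  motifs <- unique(motifs)
  for (M in motifs) check_motif(M)
  pm <- vapply(motifs, function(M) motif_mutation_prob(M, m), numeric(1L))
  ord <- order_motifs(motifs, pm)
  motifs <- motifs[ord]
  pm <- pm[ord]
  names(pm) <- motifs

  len <- nchar(motifs)
  main_of <- character(length(motifs))
  names(main_of) <- motifs
  for (i in seq_along(motifs)) {
    Mp <- motifs[i]
    cand <- motifs[len == len[i]]
    ok <- vapply(cand, function(M) can_substitute(M, Mp, m, T), logical(1L))
    cand <- cand[ok]  # always contains Mp itself
    best <- cand[pm[cand] == max(pm[cand])]
    main_of[Mp] <- sort(best, method = "radix")[1L]
  }
  clusters <- split(names(main_of), factor(main_of, levels = unique(main_of)))
  structure(list(main_of = main_of, clusters = clusters, pm = pm,
                 params = list(matrix = m$name, T = T)),
            class = "motif_clustering")
}

#' @export
print.motif_clustering <- function(x, ...) {
  cat("Motif clustering (", x$params$matrix, ", T = ", x$params$T, "): ",
      length(x$main_of), " motifs -> ", length(x$clusters),
      " clusters\n", sep = "")
  for (mm in names(x$clusters))
    cat("  ", mm, " <- {", paste(x$clusters[[mm]], collapse = ", "),
        "}\n", sep = "")
  invisible(x)
}

#' Keep only the main motifs of a clustering
#'
#' Filtering retains one representative per cluster — the main motif — and
#' removes the other, substitutable, motifs. Every removed motif remains
#' substitutable by a retained main motif, so the reduced set carries the
#' same information once presence marking accepts substitutes.
#'
#' @param clustering A `motif_clustering`.
#' @return Character vector of main motifs, ordered by length descending,
#'   P_m descending, then lexicographically.
#' @export
filter_main_motifs <- function(clustering) {
  stopifnot(inherits(clustering, "motif_clustering"))
  mains <- unique(unname(clustering$main_of))
  pm <- clustering$pm[mains]
  mains[order_motifs(mains, pm)]
}
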