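# One-call encoding pipeline shared by the R API and the command line.

#' Encode a labeled sequence set into a binary context
#'
#' Dispatches on encoding method, builds the feature set, and constructs
#' the learning context. Defaults mirror the conventional settings of the
#' comparison study this package implements: N = 3 for N-grams;
#' min-length 3 and 25% activity for active motifs; alpha = 0 and beta = 0
#' for the discriminative filters; BLOSUM62 with T = 0.9 for DDSM. The
#' DDSM context is substitute-aware; all others are exact.
#'
#' @param s A `labeled_set`.
#' @param method `"NG"`, `"AM"`, `"DD"` or `"DDSM"` (for amino acid
#'   composition, which is frequency- not presence-based, see
#'   [amino_acid_composition()]).
#' @param N N-gram window length.
#' @param min_length,max_length Motif length bounds (AM uses only the
#'   minimum).
#' @param activity_pct Active-motif activity threshold (percent).
#' @param mutations Allowed mutations in active-motif matching.
#' @param alpha,beta Discriminative-descriptor thresholds.
#' @param matrix_name Bundled substitution matrix name for DDSM.
#' @param T Substitution probability threshold for DDSM.
#' @param verbose Log feature counts at each stage.
#' @return A list with `features` (the `feature_set`) and `context` (the
#'   `binary_context`).
#' @export
encode_sequences <- function(s, method = c("DDSM", "DD", "NG", "AM"),
                             N = 3L, min_length = 3L, max_length = 10L,
                             activity_pct = 25, mutations = 0L,
                             alpha = 0, beta = 0,
                             matrix_name = "BLOSUM62", T = 0.9,
                             verbose = FALSE) {
  stopifnot(inherits(s, "labeled_set"))
  method <- match.arg(method)
  say <- function(...) if (verbose) message(...)
  if (method == "NG") {
    f <- extract_ngrams(s, N)
    say("NG: ", length(f$features), " distinct ", N, "-grams")
    ctx <- build_context(s, f, "exact")
  } else if (method == "AM") {
    f <- extract_active_motifs(s, min_length, activity_pct, mutations)
    say("AM: ", length(f$features), " active motifs")
    ctx <- build_context(s, f, "exact")
  } else if (method == "DD") {
    f <- extract_dd(s, alpha, beta, min_length, max_length)
    say("DD: ", length(f$features), " discriminative minimal motifs")
    ctx <- build_context(s, f, "exact")
  } else {
    m <- load_substitution_matrix(matrix_name)
    f <- extract_ddsm(s, alpha, beta, m, T, min_length, max_length)
    n_dd <- if (is.null(f$clustering)) 0L else length(f$clustering$main_of)
    say("DD stage: ", n_dd, " discriminative motifs")
    say("DDSM: ", length(f$features), " main motifs (",
        n_dd - length(f$features), " removed by clustering)")
    ctx <- build_context(s, f, "substitute_aware", m, T)
  }
  list(features = f, context = ctx)
}
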