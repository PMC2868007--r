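# Synthetic sequence-family generator with implanted motifs and
# positive-score substituted variants; used as the package's test-bed for
# discriminative motif recovery and feature-count reduction.

sample_variant <- function(motif, m, T, max_changes = 2L) {
  ch <- check_motif(motif)
  self <- sum(m$scores[cbind(ch, ch)])
  # feasible single-position replacements: y != x with S(x, y) >= 0
  # (condition 2) whose score drop keeps SP above the threshold
  feasible <- function(cur) {
    out <- list()
    cur_score <- sum(m$scores[cbind(ch, cur)])
    for (i in seq_along(ch)) {
      x <- ch[i]
      for (y in m$alphabet) {
        if (y == cur[i]) next
        s <- m$scores[x, y]
        if (s < 0L) next
        if ((cur_score - m$scores[x, cur[i]] + s) / self >= T)
          out[[length(out) + 1L]] <- c(i = i, y = y)
      }
    }
    out
  }
  if (all(vapply(seq_along(ch), function(i)
    sum(m$scores[ch[i], ] >= 0L) == 1L, logical(1L))))
    stop("motif '", motif, "' admits no substituted variant: every ",
         "position is fully conserved under ", m$name)
  cur <- ch
  changed <- FALSE
  for (step in seq_len(max_changes)) {
    cand <- feasible(cur)
    # never substitute the same position back to break an applied change
    if (changed)
      cand <- Filter(function(cg) cur[as.integer(cg[["i"]])] ==
                       ch[as.integer(cg[["i"]])], cand)
    if (!length(cand)) break
    pick <- cand[[sample.int(length(cand), 1L)]]
    cur[as.integer(pick[["i"]])] <- pick[["y"]]
    changed <- TRUE
    if (stats::runif(1L) < 0.5) break
  }
  v <- paste(cur, collapse = "")
  if (!changed || v == motif || !can_substitute(motif, v, m, T))
    stop("motif '", motif, "' admits no substituted variant distinct ",
         "from itself at T = ", T, " under ", m$name)
  v
}

#' Generate a synthetic labeled sequence set with implanted motifs
#'
#' Emulates a corpus of distinct protein families: each family's sequences
#' are uniform-random residue strings with the family's signature motifs
#' implanted at random positions. A fraction `variant_rate` of the implants
#' is replaced by a substituted variant — built by sampling, per position,
#' residues with a non-negative substitution score, and accepted only when
#' the original motif can substitute the variant at the configured
#' threshold — so the variants satisfy the substitution conditions by
#' construction and should collapse onto their source motif under DDSM
#' clustering.
#'
#' @param families Number of families.
#' @param per_family Sequences per family.
#' @param motif_length Length of each implanted signature motif.
#' @param motifs_per_family Signature motifs per family.
#' @param variant_rate Fraction of implants replaced by variants, in [0,1].
#' @param variants_per_motif Size of the variant pool drawn per motif;
#'   implants sample from this pool, so each variant recurs across
#'   sequences the way a real mutated motif recurs within a family.
#' @param seq_length Length of the random background sequences.
#' @param m A `substitution_matrix` (used to build variants).
#' @param T Substitution threshold the variants must satisfy.
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of its arguments.
#' @return A list with `set` (a `labeled_set`) and `truth` (a data.frame of
#'   family, implanted motif, and the variants actually used).
#' @export
generate_fixture <- function(families = 3L, per_family = 20L,
                             motif_length = 6L, motifs_per_family = 1L,
                             variant_rate = 0, variants_per_motif = 2L,
                             seq_length = 100L,
                             m = load_substitution_matrix("BLOSUM62"),
                             T = 0.9, seed = 1L) {
  stopifnot(families >= 1L, per_family >= 1L, motif_length >= 1L,
            variant_rate >= 0, variant_rate <= 1,
            seq_length >= motif_length)
  set.seed(seed)
  fam_labels <- paste0("F", seq_len(families))
  rand_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                collapse = "")
  motifs <- lapply(fam_labels, function(f)
    vapply(seq_len(motifs_per_family), function(i)
      rand_seq(motif_length), character(1L)))
  names(motifs) <- fam_labels
  pools <- if (variant_rate > 0)
    lapply(motifs, function(ms) lapply(ms, function(mo)
      unique(vapply(seq_len(variants_per_motif), function(i)
        sample_variant(mo, m, T), character(1L)))))
  else NULL

  ids <- character(0L); seqs <- character(0L); fams <- character(0L)
  truth <- list()
  for (f in fam_labels) {
    for (j in seq_len(per_family)) {
      bg <- rand_seq(seq_length)
      for (mi in seq_along(motifs[[f]])) {
        mo <- motifs[[f]][[mi]]
        implant <- mo
        if (variant_rate > 0 && stats::runif(1L) < variant_rate) {
          pool <- pools[[f]][[mi]]
          implant <- pool[[sample.int(length(pool), 1L)]]
          truth[[length(truth) + 1L]] <-
            data.frame(family = f, motif = mo, variant = implant,
                       stringsAsFactors = FALSE)
        }
        pos <- sample.int(nchar(bg) - nchar(implant) + 1L, 1L)
        substr(bg, pos, pos + nchar(implant) - 1L) <- implant
      }
      ids <- c(ids, paste0(f, "_", j))
      seqs <- c(seqs, bg)
      fams <- c(fams, f)
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(family = character(0L), motif = character(0L),
               variant = character(0L))
  list(set = labeled_set(ids, seqs, fams),
       truth = list(motifs = motifs, variants = truth_df))
}

#' Write a labeled set as one FASTA file per family
#'
#' @param s A `labeled_set`.
#' @param dir Output directory.
#' @return Named character vector of the FASTA paths (names = families).
#' @export
write_family_fastas <- function(s, dir) {
  stopifnot(inherits(s, "labeled_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fams <- unique(s$family)
  paths <- stats::setNames(file.path(dir, paste0(fams, ".fasta")), fams)
  for (f in fams) {
    sub <- s[s$family == f, ]
    writeLines(paste0(">", sub$id, "\n", sub$sequence), paths[[f]])
  }
  paths
}
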