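# Brute-force oracles kept deliberately independent of the package
# internals: plain loops over characters and pairs.

STD_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# split a sequence at non-standard residues
bf_segments <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  segs <- character(0)
  cur <- ""
  for (c in ch) {
    if (c %in% STD_AA) cur <- paste0(cur, c)
    else { if (nzchar(cur)) segs <- c(segs, cur); cur <- "" }
  }
  if (nzchar(cur)) segs <- c(segs, cur)
  segs
}

bf_substrings <- function(seq, min_len, max_len) {
  out <- character(0)
  for (seg in bf_segments(seq)) {
    n <- nchar(seg)
    for (len in seq_len(min(max_len, n))) {
      if (len < min_len) next
      for (i in seq_len(n - len + 1))
        out <- c(out, substr(seg, i, i + len - 1))
    }
  }
  out
}

bf_repeats <- function(family, min_len, max_len) {
  if (length(family) == 1) {
    tab <- table(bf_substrings(family, min_len, max_len))
    sort(names(tab)[tab >= 2])
  } else {
    per <- lapply(family, function(s) unique(bf_substrings(s, min_len, max_len)))
    tab <- table(unlist(per))
    sort(names(tab)[tab >= 2])
  }
}

bf_hamming_contains <- function(motif, seq, mut) {
  k <- nchar(motif)
  for (seg in bf_segments(seq)) {
    n <- nchar(seg)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(seg, i, i + k - 1)
      d <- sum(strsplit(w, "")[[1]] != strsplit(motif, "")[[1]])
      if (d <= mut) return(TRUE)
    }
  }
  FALSE
}

bf_active_motifs <- function(sequences, min_len, pct, mut) {
  cands <- unique(unlist(lapply(sequences, function(s)
    bf_substrings(s, min_len, max(nchar(sequences))))))
  keep <- character(0)
  for (mo in cands) {
    act <- sum(vapply(sequences, function(s)
      bf_hamming_contains(mo, s, mut), logical(1)))
    if (act >= pct / 100 * length(sequences)) keep <- c(keep, mo)
  }
  sort(keep)
}

# exhaustive O(n^2) main-motif assignment from first principles
bf_main_of <- function(motifs, m, T) {
  pm <- vapply(motifs, function(x) motif_mutation_prob(x, m), numeric(1))
  out <- character(length(motifs))
  names(out) <- motifs
  for (Mp in motifs) {
    cand <- character(0)
    for (M in motifs) {
      if (nchar(M) != nchar(Mp)) next
      cm <- strsplit(M, "")[[1]]; cp <- strsplit(Mp, "")[[1]]
      scores <- mapply(function(a, b) m$scores[a, b], cm, cp)
      if (any(scores < 0)) next
      sp <- sum(scores) / sum(mapply(function(a) m$scores[a, a], cm))
      if (sp >= T) cand <- c(cand, M)
    }
    best <- cand[pm[cand] == max(pm[cand])]
    out[Mp] <- sort(best)[1]
  }
  out
}

# random motif over the standard alphabet
rand_motif <- function(k) paste(sample(STD_AA, k, replace = TRUE),
                                collapse = "")

table1_motifs <- c("LLK", "IMK", "VMK", "GGP", "RI", "RV", "RF", "RA", "PP")

tiny_set <- function() {
  labeled_set(c("a1", "a2", "b1", "b2"),
              c("MKLVAGGH", "MKLVCGGH", "GGPQRWWA", "GGPQSWWA"),
              c("A", "A", "B", "B"))
}

trunc2 <- function(x) floor(x * 100) / 100
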