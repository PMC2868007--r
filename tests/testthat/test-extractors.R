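m62 <- load_substitution_matrix("BLOSUM62")

one_family <- function(...) {
  seqs <- c(...)
  labeled_set(paste0("s", seq_along(seqs)), seqs, rep("F1", length(seqs)))
}

test_that("n-gram extraction slides windows and keeps distinct grams", {
  expect_identical(extract_ngrams(one_family("MKLV"), 3)$features,
                   c("MKL", "KLV"))
  expect_identical(extract_ngrams(one_family("AAAA"), 2)$features, "AA")
  # non-standard residue separates motifs: no 3-window avoids the X
  expect_warning(f <- extract_ngrams(one_family("MKXLV"), 3),
                 "no sequence admits")
  expect_length(f$features, 0L)
  s <- one_family("MKLVAGH", "KLVMM")
  f <- extract_ngrams(s, 3)
  expect_true(all(nchar(f$features) == 3))
  expect_lte(length(f$features), sum(pmax(nchar(s$sequence) - 2, 0)))
  expect_false(anyDuplicated(f$features) > 0)
})

test_that("amino acid composition is a frequency vector over the 20 residues", {
  v <- amino_acid_composition("AAAA")
  expect_equal(v[["A"]], 1)
  expect_equal(sum(v), 1)
  v <- amino_acid_composition("ARAR")
  expect_equal(v[["A"]], 0.5)
  expect_equal(v[["R"]], 0.5)
  v <- amino_acid_composition("ARNDCQEGHILKMFPSTWYV")
  expect_equal(unname(v), rep(0.05, 20))
  # non-standard codes ignored, still sums to 1
  expect_equal(sum(amino_acid_composition("AXXA")), 1)
  expect_error(amino_acid_composition("XXX"), "no standard")
})

test_that("active motifs match brute-force enumeration", {
  s <- one_family("MKLVA", "MKLVC", "MKLVD")
  f <- extract_active_motifs(s, min_length = 3, activity_pct = 100)
  expect_setequal(f$features, c("MKL", "KLV", "MKLV"))
  expect_setequal(f$features, bf_active_motifs(s$sequence, 3, 100, 0))
  # length-1 motifs at 100% activity are exactly the universal residues
  f1 <- extract_active_motifs(s, 1, 100)
  univ <- Reduce(intersect, lapply(s$sequence, function(x)
    unique(strsplit(x, "")[[1]])))
  expect_setequal(f1$features[nchar(f1$features) == 1], univ)
  expect_length(extract_active_motifs(one_family("AAA"), 5, 100)$features, 0L)
  # mutation-tolerant matching
  s2 <- one_family("MKL", "MRL")
  f2 <- extract_active_motifs(s2, 3, 100, mutations = 1)
  expect_setequal(f2$features, c("MKL", "MRL"))
  expect_setequal(f2$features, bf_active_motifs(s2$sequence, 3, 100, 1))
  # randomized cross-check at a lower activity threshold
  set.seed(23)
  seqs <- vapply(1:4, function(i) rand_motif(sample(8:14, 1)), character(1))
  s3 <- one_family(seqs)
  f3 <- extract_active_motifs(s3, 2, 50)
  expect_setequal(f3$features, bf_active_motifs(seqs, 2, 50, 0))
  expect_error(extract_active_motifs(s3, 1, 25, feature_cap = 3),
               "too many attributes")
})

test_that("repeat extraction equals brute force", {
  expect_identical(extract_repeats("ABCAB", 2, 5), "AB")
  expect_identical(extract_repeats(c("MKL", "MKV"), 2), "MK")
  expect_setequal(extract_repeats(c("MKL", "MKL"), 1, 3),
                  c("M", "K", "L", "MK", "KL", "MKL"))
  set.seed(29)
  for (rep in 1:4) {
    fam <- vapply(1:3, function(i) rand_motif(sample(20:60, 1)), character(1))
    expect_setequal(extract_repeats(fam, 2, 6), bf_repeats(fam, 2, 6))
  }
  # single long sequence, against brute force
  seq1 <- paste(rep(rand_motif(25), 2), collapse = "")
  expect_setequal(extract_repeats(seq1, 3, 8), bf_repeats(seq1, 3, 8))
  # the protein mode blocks repeats spanning an ambiguity code
  expect_identical(extract_repeats("MKXMK", 2, 4,
                                   nonstandard_separators = TRUE), "MK")
  expect_setequal(extract_repeats("MKXMK", 2, 4,
                                  nonstandard_separators = TRUE),
                  bf_repeats("MKXMK", 2, 4))
})

test_that("discriminative filtering keeps family-exclusive minimal motifs", {
  s <- labeled_set(c("a1", "a2", "b1", "b2"),
                   c("MKLVA", "MKLVC", "GGPQR", "GGPQS"),
                   c("A", "A", "B", "B"))
  reps <- lapply(split(s$sequence, s$family), extract_repeats, 2, 5)
  f <- dd_filter(reps, s, alpha = 0, beta = 0)
  # every retained motif is absent from the other family
  seqs_of <- split(s$sequence, s$family)
  for (mo in f$features) {
    fams_with <- vapply(seqs_of, function(ss)
      any(grepl(mo, ss, fixed = TRUE)), logical(1))
    expect_identical(sum(fams_with), 1L, label = mo)
  }
  expect_true("MK" %in% f$features)
  expect_false("MKL" %in% f$features)  # pruned: MK is a retained substring
  # beta = 1 disables the cross-family check
  f_any <- dd_filter(reps, s, alpha = 0, beta = 1)
  expect_true(length(f_any$features) >= length(f$features))
  # a motif shared by both families is excluded at beta = 0
  s2 <- labeled_set(c("a1", "a2", "b1", "b2"),
                    c("MKLV", "MKLC", "MKGG", "MKGH"),
                    c("A", "A", "B", "B"))
  reps2 <- lapply(split(s2$sequence, s2$family), extract_repeats, 2, 4)
  f2 <- dd_filter(reps2, s2, 0, 0)
  expect_false("MK" %in% f2$features)
})

test_that("substitution clustering never increases the DD feature count", {
  fx <- generate_fixture(families = 2, per_family = 6, motif_length = 5,
                         variant_rate = 0.5, seq_length = 40, T = 0.8,
                         seed = 101)
  for (T in c(0.5, 0.8, 1)) {
    dd <- extract_dd(fx$set, 0, 0, 3, 8)
    dm <- extract_ddsm(fx$set, 0, 0, m62, T, 3, 8)
    expect_lte(length(dm$features), length(dd$features))
  }
  # T = 1: identity clustering, counts equal
  dd <- extract_dd(fx$set, 0, 0, 3, 8)
  dm1 <- extract_ddsm(fx$set, 0, 0, m62, 1, 3, 8)
  expect_setequal(dm1$features, dd$features)
})

test_that("implanted positive-score variants collapse onto one feature", {
  fx <- generate_fixture(families = 2, per_family = 8, motif_length = 6,
                         variant_rate = 0.6, seq_length = 50, T = 0.8,
                         seed = 202)
  expect_gt(nrow(fx$truth$variants), 0)
  # clustered at the worked-example threshold, where short fragments of an
  # implanted motif and of its variants are mutually substitutable
  dd <- extract_dd(fx$set, 0, 0, 3, 8)
  dm <- extract_ddsm(fx$set, 0, 0, m62, 0.5, 3, 8)
  expect_lt(length(dm$features), length(dd$features))
})
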