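m62 <- load_substitution_matrix("BLOSUM62")

test_that("mutation probability reproduces the worked-example values", {
  # truncated (not rounded) to two decimals, matching printed precision
  expected <- c(LLK = 0.89, IMK = 0.87, VMK = 0.86, GGP = 0,
                RI = 0.75, RV = 0.72, RA = 0.5, PP = 0)
  for (mo in names(expected))
    expect_equal(trunc2(motif_mutation_prob(mo, m62)), expected[[mo]],
                 label = mo)
  # exact values behind two of them
  expect_equal(motif_mutation_prob("LLK", m62), 1 - (4/9) * (4/9) * (5/9))
  expect_equal(motif_mutation_prob("RA", m62), 1 - (5/8) * (4/5))
  expect_equal(trunc2(motif_mutation_prob("RV", m62)), 0.72)
  expect_error(motif_mutation_prob("RX", m62), "non-standard")
})

test_that("motif substitution score is the position-wise sum", {
  expect_identical(motif_substitution_score("RI", "RV", m62), 8L)
  expect_identical(motif_substitution_score("RI", "RI", m62), 9L)
  expect_identical(motif_substitution_score("LLK", "IMK", m62), 9L)
  expect_error(motif_substitution_score("RI", "LLK", m62), "equal length")
})

test_that("substitution probability is self-normalised", {
  expect_equal(substitution_prob("RI", "RI", m62), 1)
  expect_equal(substitution_prob("RI", "RV", m62), 8 / 9)
  expect_equal(substitution_prob("RV", "RA", m62), 5 / 9)
})

test_that("the three substitution conditions gate can_substitute", {
  expect_true(can_substitute("RI", "RI", m62, T = 1))
  expect_false(can_substitute("RI", "RA", m62, T = 0))   # S(I,A) = -1
  expect_true(can_substitute("RI", "RF", m62, T = 0.5))  # S(I,F)=0, SP=5/9
  expect_false(can_substitute("RI", "LLK", m62, T = 0))  # length mismatch
})

test_that("clustering the nine worked-example motifs yields 5 clusters", {
  cl <- cluster_motifs(table1_motifs, m62, T = 0.5)
  expect_identical(
    cl$main_of[table1_motifs],
    c(LLK = "LLK", IMK = "LLK", VMK = "LLK", GGP = "GGP",
      RI = "RI", RV = "RI", RF = "RI", RA = "RV", PP = "PP"))
  expect_length(cl$clusters, 5L)
  # RV sits in RI's cluster yet is the main motif of RA's cluster
  expect_true("RV" %in% cl$clusters[["RI"]])
  expect_identical(cl$clusters[["RV"]], "RA")
})

test_that("filtering keeps one ordered representative per cluster", {
  cl <- cluster_motifs(table1_motifs, m62, T = 0.5)
  expect_identical(filter_main_motifs(cl),
                   c("LLK", "GGP", "RI", "RV", "PP"))
  expect_identical(filter_main_motifs(cluster_motifs("RI", m62, 0.5)), "RI")
})

test_that("BLOSUM62 diagonal is strictly row-maximal, so T = 1 clusters to identity", {
  # brute-force precondition check
  for (x in STD_AA) for (y in STD_AA)
    if (x != y)
      expect_true(m62$scores[x, y] < m62$scores[x, x])
  set.seed(7)
  motifs <- unique(vapply(1:12, function(i) rand_motif(sample(2:4, 1)),
                          character(1)))
  cl <- cluster_motifs(motifs, m62, T = 1)
  expect_identical(unname(cl$main_of[motifs]), motifs)
})

test_that("self-substitution probability is 1 under every bundled matrix", {
  set.seed(11)
  for (name in bundled_matrix_names()) {
    m <- load_substitution_matrix(name)
    for (i in 1:10) {
      mo <- rand_motif(sample(1:6, 1))
      expect_equal(substitution_prob(mo, mo, m), 1,
                   label = paste(name, mo))
    }
  }
})

test_that("mutation probability lies in [0,1) and vanishes only on conserved residues", {
  # brute-force the residues whose only positive BLOSUM62 entry is diagonal
  conserved <- STD_AA[vapply(STD_AA, function(x) {
    row <- m62$scores[x, ]
    sum(row > 0) == 1
  }, logical(1))]
  expect_identical(sort(conserved), c("C", "G", "P"))
  set.seed(13)
  for (i in 1:60) {
    mo <- rand_motif(sample(1:5, 1))
    pm <- motif_mutation_prob(mo, m62)
    expect_true(pm >= 0 && pm < 1)
    all_cons <- all(strsplit(mo, "")[[1]] %in% conserved)
    expect_identical(pm == 0, all_cons, label = mo)
  }
})

test_that("every filtered-out motif is substitutable by a retained main motif", {
  set.seed(17)
  for (rep in 1:5) {
    motifs <- unique(vapply(1:15, function(i) rand_motif(sample(2:3, 1)),
                            character(1)))
    cl <- cluster_motifs(motifs, m62, T = 0.4)
    mains <- filter_main_motifs(cl)
    removed <- setdiff(motifs, mains)
    for (mo in removed)
      expect_true(any(vapply(mains, function(M)
        can_substitute(M, mo, m62, 0.4), logical(1))), label = mo)
    expect_lte(length(mains), length(motifs))
  }
})

test_that("clustering matches exhaustive candidate enumeration on small sets", {
  set.seed(19)
  for (rep in 1:6) {
    motifs <- unique(vapply(1:8, function(i) rand_motif(sample(2:3, 1)),
                            character(1)))
    T <- sample(c(0.3, 0.5, 0.8), 1)
    cl <- cluster_motifs(motifs, m62, T)
    oracle <- bf_main_of(motifs, m62, T)
    expect_identical(cl$main_of[motifs], oracle[motifs])
  }
  oracle <- bf_main_of(table1_motifs, m62, 0.5)
  expect_identical(cluster_motifs(table1_motifs, m62, 0.5)$main_of[table1_motifs],
                   oracle[table1_motifs])
})
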