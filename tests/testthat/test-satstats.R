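test_that("consensus of identical clones is the clone, with no ambiguity codes", {
  set.seed(81)
  mono <- rand_seq(120)
  cl <- seq_set(sprintf("c%d", 1:10), rep(mono, 10))
  cc <- build_consensus(cl)
  expect_equal(cc$bases, mono)
  expect_equal(cc$depth, 10L)
  expect_error(build_consensus(cl[1, ]), ">= 2 clones")
})

test_that("majority rule and IUPAC tie rule act per column", {
  set.seed(82)
  base <- rand_seq(60)
  v1 <- base
  v2 <- base
  v3 <- mutate_at(base, 0, positions = NULL)
  # column 10: A/A/G -> majority A
  substr(v1, 10, 10) <- "A"; substr(v2, 10, 10) <- "A"; substr(v3, 10, 10) <- "G"
  cc <- build_consensus(seq_set(c("a", "b", "c"), c(v1, v2, v3)))
  expect_equal(substr(cc$bases, 10, 10), "A")
  # column 20: A/A/G/G -> tie -> R (puRine)
  w <- rep(base, 4)
  substr(w[1], 20, 20) <- "A"; substr(w[2], 20, 20) <- "A"
  substr(w[3], 20, 20) <- "G"; substr(w[4], 20, 20) <- "G"
  cc4 <- build_consensus(seq_set(c("a", "b", "c", "d"), w))
  expect_equal(substr(cc4$bases, 20, 20), "R")
})

test_that("intra identity is 100 for identical clones and tracks planted divergence", {
  set.seed(83)
  mono <- rand_seq(344)
  g_same <- seq_set(sprintf("s%d", 1:4), rep(mono, 4))
  intra <- identity_matrix(list(same = g_same), "intra")
  expect_equal(intra$identity, 100)
  expect_equal(intra$monomer_length, 344L)
  # clones at a known mean pairwise divergence
  g_div <- seq_set(sprintf("d%d", 1:3),
                   c(mono, mutate_at(mono, 10), mutate_at(mono, 10)))
  got <- identity_matrix(list(div = g_div), "intra")$identity
  pairs <- combn(3, 2)
  want <- 100 * mean(vapply(seq_len(ncol(pairs)), function(k)
    pairwise_identity(g_div$bases[pairs[1, k]], g_div$bases[pairs[2, k]]), 0))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("consensuses differing at 7 of 350 positions give 98% inter identity", {
  set.seed(84)
  anc <- rand_seq(350)
  other <- mutate_at(anc, 7)
  gA <- seq_set(c("a1", "a2"), rep(anc, 2))
  gB <- seq_set(c("b1", "b2"), rep(other, 2))
  inter <- identity_matrix(list(A = gA, B = gB), "inter")
  expect_equal(dim(inter), c(2L, 2L))
  expect_equal(diag(inter), c(A = 100, B = 100))
  expect_equal(inter["A", "B"], 100 * 343 / 350, tolerance = 1e-9)
  expect_equal(inter["A", "B"], inter["B", "A"])
})

test_that("ambiguity codes count as matches when they contain the other base", {
  # consensus R (A/G) against A: compatible, so identical
  expect_equal(pairwise_identity("ARGT", "AAGT", ambiguity = TRUE), 1.0)
  expect_lt(pairwise_identity("ARGT", "ACGT", ambiguity = TRUE), 1.0)
})

test_that("concerted-evolution flags follow the asterisk rule", {
  intra <- data.frame(label = c("A", "B"), identity = c(99, 99))
  inter <- matrix(c(100, 90, 90, 100), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nrow(concerted_evolution_test(intra, inter)), 0L)
  intra2 <- data.frame(label = c("A", "B"), identity = c(79.2, 99))
  inter2 <- matrix(c(100, 85, 85, 100), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  fl <- concerted_evolution_test(intra2, inter2)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$species, "A")
  expect_equal(fl$inter_identity, 85)
})

test_that("a verbatim CENP-B box scores 9/9 critical matches", {
  mot <- cenpb_motif()
  expect_equal(nchar(mot$motif), 17L)
  expect_length(mot$critical, 9L)
  set.seed(85)
  cons <- paste0(rand_seq(40), mot$motif, rand_seq(40))
  hit <- scan_cenpb(cons, mot)
  expect_equal(hit$critical_matches, 9L)
  expect_equal(hit$offset, 40L)
  expect_equal(hit$strand, "+")
  # and on the reverse strand at the mirrored offset
  hit_rc <- scan_cenpb(revcomp(cons), mot)
  expect_equal(hit_rc$critical_matches, 9L)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$offset, nchar(cons) - 17L - 40L)
})

test_that("motif scan equals the exhaustive window-scan oracle on random consensuses", {
  mot <- cenpb_motif()
  set.seed(86)
  for (i in 1:4) {
    cons <- rand_seq(120)
    got <- scan_cenpb(cons, mot)
    want <- scan_oracle(cons, mot$motif, mot$critical)
    expect_equal(got$critical_matches, want$crit)
    expect_equal(got$total_matches, want$total)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("tandem-array digestion yields the monomer ladder", {
  set.seed(87)
  mono <- random_monomer(345)
  arr <- build_array(mono, 10, site_ablation_prob = 0, seed = 88)
  d <- digest_array(arr, monomer_length = 345L)
  expect_equal(sum(d$fragment_lengths), nchar(arr$bases))
  expect_equal(sum(d$fragment_lengths == 345L), 9L)   # internal fragments
  terminals <- d$fragment_lengths[d$fragment_lengths != 345L]
  expect_length(terminals, 2L)
  expect_equal(sum(terminals), 345L)
  # no sites at all: one fragment, the array itself
  d0 <- digest_array(list(bases = "ATATATATAT"), site = "CCGG")
  expect_equal(d0$fragment_lengths, 10L)
})

test_that("the MspI cut falls after the first C of CCGG", {
  d <- digest_array(list(bases = paste0(strrep("A", 10), "CCGG", strrep("T", 10))),
                    site = "CCGG", monomer_length = 12L)
  expect_equal(d$fragment_lengths, c(11L, 13L))  # cut at C^CGG
})

test_that("fragment lengths always sum to the array length", {
  set.seed(89)
  for (i in 1:5) {
    mono <- random_monomer(200, site_pos = 50L)
    arr <- build_array(mono, sample(5:30, 1),
                       site_ablation_prob = runif(1, 0, 0.6), seed = 90 + i,
                       site = "CCGG")
    d <- digest_array(arr, monomer_length = 200L)
    expect_equal(sum(d$fragment_lengths), nchar(arr$bases))
  }
})

test_that("ablated arrays decay geometrically across ladder rungs", {
  set.seed(91)
  mono <- random_monomer(345)
  q <- 0.3
  M <- 10000L
  arr <- build_array(mono, M, site_ablation_prob = q, seed = 92)
  ls <- ladder_summary(digest_array(arr, monomer_length = 345L))
  for (k in 1:4) {
    obs <- ls$count[ls$rung == k] / M
    want <- (1 - q)^2 * q^(k - 1)
    # Monte-Carlo tolerance: ~4 sd of the binomial count
    tol <- 4 * sqrt(want / M) + 2 / M
    expect_lt(abs(obs - want), tol)
  }
})
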