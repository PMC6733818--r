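test_that("pairwise identity matches hand-worked cases and strand symmetry", {
  set.seed(61)
  a <- rand_seq(344)
  expect_equal(pairwise_identity(a, a), 1.0)
  expect_equal(pairwise_identity(a, revcomp(a)), 1.0)
  # one substitution in 10 columns: 9/10 by the hand DP table
  expect_equal(pairwise_identity("ACGTACGTAC", "ACGAACGTAC"), 0.9)
  # k planted substitutions in length L
  for (k in c(5, 17, 34)) {
    b <- mutate_at(a, k)
    expect_equal(pairwise_identity(a, b), (344 - k) / 344, tolerance = 1e-9)
  }
})

test_that("identity is symmetric and bounded", {
  set.seed(62)
  for (i in 1:5) {
    a <- rand_seq(sample(100:200, 1))
    b <- mutate_at(a, sample(10:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-9)
    expect_gte(pairwise_identity(a, b), 0)
    expect_lte(pairwise_identity(a, b), 1)
  }
})

test_that("identical copies collapse into one cluster", {
  set.seed(63)
  mono <- rand_seq(345)
  seqs <- seq_set(sprintf("c%02d", 1:20), rep(mono, 20))
  for (th in c(0.95, 0.97, 0.99)) {
    cl <- cluster_greedy(seqs, th)
    expect_length(cl, 1L)
    expect_length(cl[[1]]$members, 20L)
  }
})

test_that("a 90%-identity pair splits at 0.95 and joins at 0.85", {
  set.seed(64)
  a <- rand_seq(340)
  b <- mutate_at(a, 34)  # 90% identity by construction
  expect_equal(pairwise_identity(a, b), 0.9, tolerance = 1e-9)
  seqs <- seq_set(c("a", "b"), c(a, b))
  expect_length(cluster_greedy(seqs, 0.95), 2L)
  expect_length(cluster_greedy(seqs, 0.85), 1L)
})

test_that("planted two-family data is recovered exactly and matches the brute-force greedy oracle", {
  set.seed(65)
  ancA <- rand_seq(345)
  ancB <- mutate_at(ancA, 35)                    # ~90% between families
  famA <- replicate(15, mutate_at(ancA, sample(1:2, 1)))  # ~99.5% within
  famB <- replicate(15, mutate_at(ancB, sample(1:2, 1)))
  seqs <- seq_set(c(sprintf("famA_m%02d", 1:15), sprintf("famB_m%02d", 1:15)),
                  c(famA, famB))
  for (th in c(0.95, 0.97)) {
    cl <- cluster_greedy(seqs, th)
    expect_length(cl, 2L)
    fams <- lapply(cl, function(x) unique(sub("_m.*", "", x$members)))
    expect_setequal(unlist(fams), c("famA", "famB"))
    expect_true(all(lengths(fams) == 1L))
    oracle <- greedy_oracle(seqs, th)
    got <- lapply(cl, `[[`, "members")
    expect_equal(lapply(got, sort), lapply(oracle, sort))
  }
})

test_that("clusters partition the input and members reach their representative", {
  cfg <- sim_config("drive", seed = 66,
                    tree = "(famA:0.04,famB:0.04);", n_monomers = 10L)
  lib <- evolve_library(cfg)
  seqs <- seq_set(c(lib$famA$id, lib$famB$id),
                  c(lib$famA$bases, lib$famB$bases))
  cl <- cluster_greedy(seqs, 0.95)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(members, seqs$id)
  expect_equal(length(members), nrow(seqs))  # disjoint
  for (x in cl) {
    for (m in x$members) {
      expect_gte(pairwise_identity(x$representative$bases,
                                   seqs$bases[seqs$id == m]) + 1e-9, 0.95)
    }
  }
})

test_that("length_diff_cutoff gates membership eligibility", {
  set.seed(67)
  long <- rand_seq(300)
  short <- substr(long, 1, 200)  # identity 1 over the shorter span
  seqs <- seq_set(c("long", "short"), c(long, short))
  expect_length(cluster_greedy(seqs, 0.95, length_diff_cutoff = 0.8), 2L)
  expect_length(cluster_greedy(seqs, 0.95, length_diff_cutoff = 0.6), 1L)
})

test_that("Shannon's H closed forms hold in nats", {
  expect_equal(shannon_index(8), 0)
  expect_equal(shannon_index(c(4, 4)), log(2))
  expect_equal(shannon_index(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_index(c(5, 0, 0)), 0)
})

test_that("summarize_clusters tallies composition, normalizations and H", {
  set.seed(68)
  mono <- rand_seq(345)
  seqs <- seq_set(sprintf("r%02d", 1:8), rep(mono, 8))
  cl <- cluster_greedy(seqs, 0.97)
  src <- setNames(rep(c("spA", "spB"), each = 4), seqs$id)
  cs <- summarize_clusters(cl, src,
                           initial_totals = c(spA = 100, spB = 50),
                           filtered_totals = c(spA = 10, spB = 5))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$raw_count, 8L)
  expect_equal(cs$shannon_h, log(2))
  expect_equal(cs$norm_initial, 4 / 100 + 4 / 50)
  expect_equal(cs$norm_filtered, 4 / 10 + 4 / 5)
  expect_equal(unname(attr(cs, "composition")[[1]]), c(4, 4))
  # single-source cluster has H = 0
  cs0 <- summarize_clusters(cl, setNames(rep("spA", 8), seqs$id),
                            c(spA = 100), c(spA = 8))
  expect_equal(cs0$shannon_h, 0)
  # a missing label is an error naming the read
  expect_error(summarize_clusters(cl, src[-1], c(spA = 1, spB = 1),
                                  c(spA = 1, spB = 1)), "r01")
})

test_that("raw counts and normalized sums respect their invariants", {
  cfg <- sim_config("frozen", seed = 69, tree = "(spA:0.02,spB:0.02);",
                    n_monomers = 10L)
  lib <- evolve_library(cfg)
  seqs <- seq_set(c(lib$spA$id, lib$spB$id),
                  c(lib$spA$bases, lib$spB$bases),
                  source = c(lib$spA$source, lib$spB$source))
  cl <- cluster_greedy(seqs, 0.95)
  src <- setNames(seqs$source, seqs$id)
  cs <- summarize_clusters(cl, src, c(spA = 10, spB = 10),
                           c(spA = 10, spB = 10))
  expect_equal(sum(cs$raw_count), nrow(seqs))
  expect_lte(sum(cs$norm_filtered), 2 + 1e-9)  # <= number of libraries
  expect_true(all(cs$shannon_h >= 0))
  expect_true(all(cs$shannon_h <= log(2) + 1e-9))
})

test_that("best-hit source assignment recovers the nearest library", {
  set.seed(70)
  a <- rand_seq(345)
  b <- mutate_at(a, 40)
  lib <- seq_set(c("cloneA", "cloneB"), c(a, b),
                 source = c("spA", "spB"))
  reads <- seq_set(c("x", "y"), c(mutate_at(a, 2), mutate_at(b, 2)))
  got <- assign_source_by_best_hit(reads, lib)
  expect_equal(unname(got), c("spA", "spB"))
})
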