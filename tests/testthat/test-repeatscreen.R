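test_that("a read equal to a library monomer masks completely", {
  set.seed(51)
  mono <- rand_seq(345)
  lib <- seq_set("mono1", mono, source = "spA")
  ann <- mask_read(list(id = "r", bases = mono), lib)
  expect_equal(ann$repeat_fraction, 1.0)
  expect_equal(ann$best_hit, "mono1")
  expect_equal(unname(ann$intervals[1, ]), c(0L, 345L))
})

test_that("a random read has zero repeat fraction, by the SW oracle too", {
  set.seed(52)
  read <- rand_seq(300)
  mono <- rand_seq(345)
  lib <- seq_set("mono1", mono)
  ann <- mask_read(list(id = "r", bases = read), lib, 0.7)
  expect_equal(ann$repeat_fraction, 0.0)
  # oracle verification at the (traceback-invariant) score level: the
  # best local alignment on either strand sits at the random-sequence
  # noise floor, nowhere near a genuine monomer hit (score ~ read length)
  for (q in c(mono, revcomp(mono))) {
    expect_lt(sw_oracle(q, read)$score, 15)
  }
})

test_that("a half-monomer read masks to about half, at the oracle's interval", {
  set.seed(53)
  mono <- rand_seq(345)
  read <- paste0(substr(mono, 1, 100), rand_seq(100))
  lib <- seq_set("mono1", mono)
  ann <- mask_read(list(id = "r", bases = read), lib, 0.7)
  expect_lt(abs(ann$repeat_fraction - 0.5), 0.05)
  h <- sw_oracle(mono, read)
  expect_equal(unname(ann$intervals[1, "start"]), h$b_start)
  expect_equal(unname(ann$intervals[1, "end"]), h$b_end)
})

test_that("repeat fraction is invariant under read reverse-complementation", {
  set.seed(54)
  mono <- rand_seq(345)
  lib <- seq_set("mono1", mono)
  for (i in 1:3) {
    read <- paste0(substr(mono, sample(100, 1), 345), rand_seq(sample(30:80, 1)))
    f1 <- mask_read(list(id = "r", bases = read), lib)$repeat_fraction
    f2 <- mask_read(list(id = "r", bases = revcomp(read)), lib)$repeat_fraction
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("iterative masking recovers several monomer copies on one read", {
  set.seed(55)
  mono <- rand_seq(150)
  read <- paste0(mono, rand_seq(60), mono)
  ann <- mask_read(list(id = "r", bases = read), seq_set("m", mono))
  expect_equal(nrow(ann$intervals), 2L)
  expect_equal(ann$repeat_fraction, 300 / 360, tolerance = 0.02)
})

test_that("filter_reads keeps pure-repeat reads and drops random ones", {
  set.seed(56)
  mono <- rand_seq(345)
  lib <- seq_set("mono1", mono)
  reads <- seq_set(sprintf("r%02d", 1:15),
                   c(rep(mono, 10), replicate(5, rand_seq(300))))
  res <- filter_reads(reads, lib, threshold = 0.99)
  expect_equal(res$stats$initial, 15L)
  expect_equal(res$stats$retained, 10L)
  expect_setequal(res$retained$id, sprintf("r%02d", 1:10))
  expect_equal(sum(res$stats$report$kept), 10L)
})

test_that("retention is monotone in the threshold and respects boundaries", {
  set.seed(57)
  mono <- rand_seq(345)
  lib <- seq_set("mono1", mono)
  # one read slightly imperfect: fraction strictly between 0.99 and 1
  near <- paste0(substr(mono, 1, 343), "NN")
  reads <- seq_set(c("pure", "near", "junk"),
                   c(mono, near, rand_seq(300)))
  fr <- filter_reads(reads, lib, threshold = 0.99)$stats$report
  f_near <- fr$repeat_fraction[fr$read_id == "near"]
  expect_gt(f_near, 0.99)
  expect_lt(f_near, 1.0)
  kept_99 <- filter_reads(reads, lib, threshold = 0.99)$retained$id
  kept_100 <- filter_reads(reads, lib, threshold = 1.0)$retained$id
  expect_true(all(kept_100 %in% kept_99))
  expect_true("near" %in% kept_99)
  expect_false("near" %in% kept_100)
  # monotone retained counts over a threshold ladder
  ns <- vapply(c(0.2, 0.5, 0.9, 0.99, 1.0), function(th)
    filter_reads(reads, lib, threshold = th)$stats$retained, 0L)
  expect_true(all(diff(ns) <= 0))
})

test_that("anchor_window finds the modal start window, ties to smallest s", {
  set.seed(58)
  ref <- seq_set("ref", rand_seq(400))
  mk_reads <- function(starts) {
    seq_set(sprintf("a%02d", seq_along(starts)),
            vapply(starts, function(s)
              substr(ref$bases, s + 1, s + 80), ""))
  }
  iv <- function(w) as.integer(w)[1:2]  # strip names and the count attribute
  # all start at 0
  w <- anchor_window(mk_reads(rep(0, 4)), ref, window = 25L)
  expect_equal(iv(w), c(0L, 25L))
  # modal start at 100 beats 3 starts at 0; equals the exhaustive scan.
  # The smallest-s tie-break picks the leftmost window covering the modal
  # start, [76, 101), since every s in 76..100 covers it.
  starts <- c(0, 0, 0, rep(100, 5))
  w2 <- anchor_window(mk_reads(starts), ref, window = 25L)
  expect_equal(iv(w2), as.integer(anchor_oracle(starts, 400, 25L)))
  expect_equal(iv(w2), c(76L, 101L))
  expect_equal(attr(w2, "count"), 5L)
  # uniform starts 0..9 all fit one window: smallest-s tie-break
  w3 <- anchor_window(mk_reads(0:9), ref, window = 25L)
  expect_equal(iv(w3), c(0L, 25L))
  # reverse-complemented reads anchor at the same leftmost coordinate
  rc_reads <- mk_reads(rep(100, 4))
  rc_reads$bases <- revcomp(rc_reads$bases)
  w4 <- anchor_window(rc_reads, ref, window = 25L)
  expect_equal(iv(w4), iv(anchor_window(mk_reads(rep(100, 4)), ref, window = 25L)))
  # no read aligning at all is an error
  junk <- seq_set("x", rand_seq(80))
  expect_error(anchor_window(junk, ref, min_score = 60), "no anchors")
})
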