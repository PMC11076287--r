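test_that("k-mer enumeration is the sliding window count L - k + 1", {
  set.seed(21)
  expect_equal(nrow(enumerate_kmers(rand_dna(1000), 19)), 982L)
  one <- enumerate_kmers("ACGTACGT", 8)
  expect_equal(nrow(one), 1L)
  expect_equal(one$kmer, "ACGTACGT")
  expect_equal(one$query_offset, 0L)
  km <- enumerate_kmers("ACGTNACGT", 4)
  expect_equal(nrow(km), 6L)
  expect_equal(km$matchable, !grepl("N", km$kmer))
  expect_error(enumerate_kmers("ACGT", 5), "must lie in")
  # offsets are consecutive and k-mers are the contiguous substrings
  s <- rand_dna(60)
  km <- enumerate_kmers(s, 19)
  expect_equal(km$query_offset, 0:41)
  expect_equal(km$kmer, substring(s, 1:42, 19:60))
})

test_that("single k-mer matching finds sense and antisense hits exactly", {
  set.seed(22)
  target <- rand_dna(300)
  sub <- substr(target, 101, 119)
  # a k-mer equal to the rc of a target substring: one "-" hit, 0 mismatches
  h <- hamming_match(reverse_complement(sub), target, max_mm = 0)
  anti <- h[h$strand == "-", ]
  expect_equal(anti$target_start, 100L)
  expect_equal(anti$target_end, 119L)
  expect_equal(anti$mismatches, 0L)
  # 3 substitutions leave no hit at max_mm = 2
  mut <- mutate_block(sub, 3, seed = 1)$block
  h3 <- hamming_match(mut, target, max_mm = 2)
  expect_false(any(h3$strand == "+" & h3$target_start == 100L))
})

test_that("the compiled scanner equals the naive oracle on random input", {
  set.seed(23)
  for (i in 1:5) {
    pool <- tx_table(stats::setNames(
      replicate(2, rand_dna(500)), c("q", "t")))
    for (mm in 0:2) {
      got <- map_pool(pool, k_values = 19L, max_mm = mm)
      want <- naive_scan_pool(pool, k_values = 19L, max_mm = mm)
      expect_identical(hit_key(got), hit_key(want))
    }
  }
})

test_that("a planted rc 25-mer yields nested antisense hits for k = 19..25", {
  set.seed(24)
  a <- rand_dna(100)
  block <- substr(a, 41, 65)
  b <- paste0(rand_dna(50), reverse_complement(block), rand_dna(25))
  pool <- tx_table(c(A = a, B = b))
  hits <- filter_antisense(map_pool(pool, 19:25, max_mm = 0))
  ab <- hits[hits$query_id == "A", ]
  for (k in 19:25) {
    hk <- ab[ab$k == k, ]
    expect_equal(nrow(hk), 25L - k + 1L)
    # nested coordinates inside the planted segment [50, 75) of B
    expect_true(all(hk$target_start >= 50L & hk$target_end <= 75L))
    expect_true(all(hk$mismatches == 0L))
  }
})

test_that("self-mapping keeps hairpins but never the trivial self-match", {
  set.seed(25)
  x <- rand_dna(30)
  hairpin <- paste0(rand_dna(40), x, rand_dna(10), reverse_complement(x),
                    rand_dna(40))
  pool <- tx_table(c(H = hairpin))
  hits <- map_pool(pool, k_values = 19:25, max_mm = 0, include_self = TRUE)
  expect_true(any(hits$strand == "-"))  # the hairpin is seen
  expect_false(any(hits$strand == "+" &
                     hits$query_offset == hits$target_start))
  # self-pairs are excluded entirely by default
  expect_equal(nrow(map_pool(pool, 19:25, max_mm = 0)), 0L)
  # duplicate ids are rejected
  expect_error(map_pool(rbind(pool, pool), 19L, 0L), "duplicate")
})

test_that("hit sets grow monotonically with the mismatch allowance", {
  set.seed(26)
  pool <- tx_table(stats::setNames(replicate(3, rand_dna(300)),
                                   c("s1", "s2", "s3")))
  prev <- character()
  for (mm in 0:2) {
    keys <- hit_key(map_pool(pool, k_values = c(19L, 22L, 25L), max_mm = mm))
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("antisense complementarity is symmetric at zero mismatches", {
  set.seed(27)
  a <- rand_dna(120)
  b <- paste0(rand_dna(30), reverse_complement(substr(a, 20, 50)),
              rand_dna(40))
  pool <- tx_table(c(A = a, B = b))
  hits <- filter_antisense(map_pool(pool, 19:22, max_mm = 0))
  fwd <- hits[hits$query_id == "A" & hits$mismatches == 0L, ]
  rev <- hits[hits$query_id == "B" & hits$mismatches == 0L, ]
  expect_gt(nrow(fwd), 0L)
  # each A->B hit has the mirrored B->A hit at swapped coordinates
  expect_setequal(paste(fwd$query_offset, fwd$target_start, fwd$k),
                  paste(rev$target_start, rev$query_offset, rev$k))
})

test_that("antisense filtering keeps exactly the minus-strand hits", {
  h <- data.frame(query_id = "q", query_offset = 0:3, target_id = "t",
                  target_start = c(0L, 5L, 9L, 12L),
                  target_end = c(19L, 24L, 28L, 31L),
                  strand = c("+", "-", "+", "-"),
                  mismatches = 0L, k = 19L, stringsAsFactors = FALSE)
  out <- filter_antisense(h)
  expect_equal(out$strand, c("-", "-"))
  expect_equal(filter_antisense(out), out)              # idempotent
  expect_equal(nrow(filter_antisense(h[h$strand == "+", ])), 0L)
})

test_that("region merging unions overlapping and book-ended hits per pair", {
  mk <- function(starts, k = 19L, pair = c("q", "t"), mm = 0L) {
    data.frame(query_id = pair[1], query_offset = 0L, target_id = pair[2],
               target_start = starts, target_end = starts + k,
               strand = "-", mismatches = mm, k = k,
               stringsAsFactors = FALSE)
  }
  r <- merge_regions(mk(c(10L, 15L)))
  expect_equal(r[, c("start", "end", "n_hits")],
               data.frame(start = 10L, end = 34L, n_hits = 2L))
  r <- merge_regions(mk(c(10L, 40L)))
  expect_equal(r$start, c(10L, 40L))
  r <- merge_regions(mk(c(10L, 29L)))                    # book-ended: gap 0
  expect_equal(r$end - r$start, 38L)
  r <- merge_regions(rbind(mk(10L, mm = 2L), mk(12L, mm = 1L)))
  expect_equal(r$min_mismatches, 1L)
  # separate pairs never merge
  r <- merge_regions(rbind(mk(10L), mk(12L, pair = c("q", "u"))))
  expect_equal(nrow(r), 2L)
  expect_error(merge_regions(within(mk(10L), strand <- "+")), "antisense")
  expect_equal(nrow(merge_regions(mk(10L)[0, ])), 0L)
})
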