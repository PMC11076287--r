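test_that("pattern construction applies the frequency threshold per position", {
  logo <- matrix(c(0.05, 0.05, 0.30, 0.60,
                   0.25, 0.25, 0.25, 0.25,
                   0.10, 0.00, 0.30, 0.60),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  pat <- build_dse_pattern(logo, 0.10)
  expect_equal(pat$allowed[[1]], c("G", "T"))
  expect_equal(pat$allowed[[2]], c("A", "C", "G", "T"))
  expect_equal(pat$allowed[[3]], c("A", "G", "T"))  # 0.10 is inclusive
  expect_equal(pat$length, 3L)

  # no base reaches 0.61 at position 1 -> error naming the position
  expect_error(build_dse_pattern(logo, 0.61), "position 1")
  expect_error(build_dse_pattern(logo, 0), "threshold")
  bad <- logo; bad[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(build_dse_pattern(bad, 0.1), "summing")
})

test_that("the packaged stand-in logo loads and builds at the default cutoff", {
  logo <- read_sequence_logo()
  expect_equal(colnames(logo), c("A", "C", "G", "T"))
  expect_true(all(abs(rowSums(logo) - 1) < 1e-6))
  pat <- build_dse_pattern(logo)
  expect_equal(pat$threshold, 0.10)
  # T is always frequent in a T/G-rich element
  expect_true(all(vapply(pat$allowed, function(b) "T" %in% b, NA)))
})

test_that("window scanning reports all matching starts", {
  tpat <- build_dse_pattern(matrix(c(0, 0, 0, 1), 4, 4, byrow = TRUE,
                                   dimnames = list(NULL, c("A", "C", "G", "T"))))
  h <- scan_dse("AATTTTAA", tpat)
  expect_equal(h$start, 2L)
  expect_equal(h$match, "TTTT")
  expect_equal(nrow(scan_dse("AACCGGAA", tpat)), 0L)

  # an all-permissive pattern of length m matches every start: 50 - m + 1
  for (m in c(4L, 8L)) {
    pat <- build_dse_pattern(uniform_logo(m), 0.25)
    expect_equal(nrow(scan_dse(rand_dna(50), pat)), 50L - m + 1L)
  }

  expect_error(scan_dse("AANTTT", tpat), "rejected")
  expect_error(scan_dse("ATT", tpat), "longer than the window")
})

test_that("overlapping matches are counted and equal a per-position check", {
  set.seed(12)
  logo <- read_sequence_logo()
  pat <- build_dse_pattern(logo, 0.10)
  brute <- function(w, pat) {
    chars <- strsplit(w, "")[[1]]
    m <- pat$length
    which(vapply(0:(nchar(w) - m), function(s) {
      all(vapply(seq_len(m), function(i) {
        chars[s + i] %in% pat$allowed[[i]]
      }, NA))
    }, NA)) - 1L
  }
  for (i in 1:400) {
    w <- rand_dna(50, prob = c(0.15, 0.1, 0.25, 0.5))  # T/G rich windows
    expect_equal(scan_dse(w, pat)$start, brute(w, pat))
  }
})

test_that("lowering the threshold is monotone in allowed sets and hits", {
  set.seed(13)
  logo <- read_sequence_logo()
  thresholds <- c(0.30, 0.20, 0.10, 0.05)
  pats <- lapply(thresholds, function(th) build_dse_pattern(logo, th))
  for (j in seq_len(length(pats) - 1L)) {
    for (i in seq_len(pats[[j]]$length)) {
      expect_true(all(pats[[j]]$allowed[[i]] %in% pats[[j + 1L]]$allowed[[i]]))
    }
  }
  for (i in 1:50) {
    w <- rand_dna(50, prob = c(0.15, 0.1, 0.25, 0.5))
    n_hits <- vapply(pats, function(p) nrow(scan_dse(w, p)), 0L)
    expect_false(is.unsorted(n_hits))
  }
})

test_that("batch scanning rejects ambiguous windows and counts the rest", {
  pat <- build_dse_pattern(uniform_logo(4), 0.25)
  res <- scan_dse_windows(c(a = rand_dna(50), b = paste0("N", rand_dna(49))),
                          pat)
  expect_equal(res$rejected, "b")
  expect_equal(res$counts[["a"]], 47L)
  expect_false("b" %in% names(res$counts))
})

test_that("PAS/DSE co-occurrence tables are exact and safe on empty input", {
  calls <- data.frame(
    transcript_id = c("a", "b", "c", "d"), gene_id = c("a", "b", "c", "d"),
    gene_class = "mRNA",
    assigned_variant = c("AATAAA", "AATAAA", "NONE", "NONE"),
    n_distinct_variants = c(1L, 1L, 0L, 0L), n_total_hits = c(1L, 1L, 0L, 0L),
    excluded = FALSE, reason = "none", stringsAsFactors = FALSE)
  tab <- pas_dse_cooccurrence(calls, c(a = 2L, b = 0L, c = 1L, d = 0L))
  expect_equal(tab$pas_dse, 1L)
  expect_equal(tab$pas_only, 1L)
  expect_equal(tab$dse_only, 1L)
  expect_equal(tab$neither, 1L)
  expect_equal(tab$rate_joint, 0.25)

  # all PAS+ and DSE+: rates 100%, off-diagonals zero
  calls2 <- calls; calls2$assigned_variant <- "AATAAA"
  tab2 <- pas_dse_cooccurrence(calls2, c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(tab2$rate_pas, 1)
  expect_equal(tab2$rate_dse, 1)
  expect_equal(tab2$pas_only + tab2$dse_only + tab2$neither, 0L)

  expect_equal(nrow(pas_dse_cooccurrence(calls[0, ], integer())), 0L)
  expect_error(pas_dse_cooccurrence(calls, c(a = 1L)), "lacks")
})

test_that("independently planted PAS and DSE co-occur at the product rate", {
  cfg <- synth_transcript_config(
    n_per_class = 400, len_range = c(300L, 500L),
    pas_rates = list(mRNA = c(AATAAA = 0.5), lncRNA = c(AATAAA = 0.5)),
    dse_rate = 0.4, seed = 77)
  sim <- generate_transcripts(cfg)
  calls <- call_pas(sim$records, downstream_windows = sim$downstream)
  scan <- scan_dse_windows(sim$downstream, cfg$dse_pattern)
  tab <- pas_dse_cooccurrence(calls, scan$counts)
  n <- sum(tab$n)
  joint <- sum(tab$pas_dse) / n
  se <- sqrt(0.5 * 0.4 * (1 - 0.5 * 0.4) / n)
  expect_lt(abs(joint - 0.5 * 0.4), 3 * se)
})
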