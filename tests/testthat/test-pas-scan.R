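tab <- pas_variant_table()

test_that("the packaged variant table is consensus-led and well ordered", {
  expect_equal(tab$hexamer[1], "AATAAA")
  expect_equal(tab$consensus_distance[1], 0L)
  expect_equal(tab$usage_rank[1], 1L)
  expect_false(is.unsorted(tab$consensus_distance))
  expect_false(any(duplicated(tab$hexamer)))
})

test_that("the search-set filter applies length and window-ambiguity rules", {
  recs <- tx_table(c(
    short = rand_dna(150),                                   # too short
    ambig = paste0(rand_dna(290), "N", rand_dna(9)),         # N at L-10
    okN   = paste0(rand_dna(5), "N", rand_dna(294)),         # N outside windows
    clean = rand_dna(300)
  ), class = "mRNA")
  flt <- filter_search_set(recs, min_len = 200L, window = 50L)
  expect_setequal(flt$kept$transcript_id, c("okN", "clean"))
  expect_equal(flt$excluded$reason[flt$excluded$transcript_id == "short"],
               "short")
  expect_equal(flt$excluded$reason[flt$excluded$transcript_id == "ambig"],
               "ambiguous_window")
  expect_true(all(flt$excluded$excluded))
  expect_true(all(flt$excluded$n_total_hits == 0L))

  # exactly 200 nt is not "greater than 200": excluded
  flt2 <- filter_search_set(tx_table(c(edge = rand_dna(200)), "mRNA"))
  expect_equal(flt2$excluded$reason, "short")

  # an ambiguous downstream window also excludes
  flt3 <- filter_search_set(
    tx_table(c(t1 = rand_dna(300)), "mRNA"),
    downstream_windows = c(t1 = paste0(rand_dna(20), "N", rand_dna(29))))
  expect_equal(flt3$excluded$reason, "ambiguous_window")

  expect_error(filter_search_set(recs, min_len = 40L, window = 50L),
               "must not exceed")
})

test_that("window scanning finds fully contained hexamers with 3' offsets", {
  seq <- paste0(strrep("C", 60), "AATAAA", strrep("C", 10))
  h <- scan_pas_window(seq, tab)
  expect_equal(nrow(h), 1L)
  expect_equal(h$hexamer, "AATAAA")
  expect_equal(h$offset_from_3prime, 10L)
  expect_equal(h$start, 60L)

  # containment at the window boundary (L = 100, window start = 50):
  place <- function(start0) {                    # 0-based hexamer start
    paste0(strrep("C", start0), "AATAAA", strrep("C", 100 - start0 - 6))
  }
  expect_equal(nrow(scan_pas_window(place(44), tab)), 0L)  # fully outside
  expect_equal(nrow(scan_pas_window(place(49), tab)), 0L)  # straddles edge
  h <- scan_pas_window(place(50), tab)                     # first base inside
  expect_equal(h$offset_from_3prime, 44L)

  # overlapping occurrences are all reported
  h <- scan_pas_window(paste0(strrep("C", 60), "AATAAATAAA", strrep("C", 10)),
                       tab)
  expect_equal(h$hexamer, c("AATAAA", "AATAAA"))
  expect_equal(sort(h$offset_from_3prime), c(10L, 14L))
  expect_equal(count_tandem(h), 2L)

  expect_error(scan_pas_window(paste0(rand_dna(60), "N", rand_dna(10)), tab),
               "ambiguous")
})

test_that("window scanning equals a brute-force substring oracle", {
  brute <- function(seq, table, window = 50L) {
    L <- nchar(seq)
    out <- list()
    for (hx in table$hexamer) {
      for (s in seq_len(L - 5L) - 1L) {           # 0-based starts
        inside <- s >= L - window && s + 6L <= L
        if (inside && substr(seq, s + 1L, s + 6L) == hx) {
          out[[length(out) + 1L]] <- data.frame(
            hexamer = hx, start = s, offset_from_3prime = L - (s + 6L),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(out, list(NULL)))
  }
  set.seed(101)
  for (i in 1:15) {
    # AT-rich so that variant hits actually occur
    seq <- rand_dna(sample(60:5000, 1), prob = c(0.35, 0.15, 0.15, 0.35))
    got <- scan_pas_window(seq, tab)
    want <- brute(seq, tab)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$start, want$hexamer), ]
      rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("5' extension never changes the 3'-anchored hit offsets", {
  set.seed(11)
  for (i in 1:10) {
    seq <- rand_dna(300, prob = c(0.35, 0.15, 0.15, 0.35))
    ext <- paste0(rand_dna(sample(1:500, 1)), seq)
    expect_setequal(scan_pas_window(seq, tab)$offset_from_3prime,
                    scan_pas_window(ext, tab)$offset_from_3prime)
  }
})

test_that("assignment takes the variant closest to consensus, ties by usage", {
  h <- function(hexamers) {
    data.frame(hexamer = hexamers, start = seq_along(hexamers) * 7L,
               offset_from_3prime = 40L - seq_along(hexamers) * 7L,
               stringsAsFactors = FALSE)
  }
  expect_equal(assign_pas(h(c("ATTAAA", "AATAAA")), tab)$assigned_variant,
               "AATAAA")
  expect_equal(assign_pas(h(character(0)), tab)$assigned_variant, "NONE")
  # equal consensus distance (both 1): usage rank decides (ATTAAA = rank 2)
  expect_equal(assign_pas(h(c("TATAAA", "ATTAAA")), tab)$assigned_variant,
               "ATTAAA")
  expect_error(assign_pas(h("GGGGGG"), tab), "absent")

  # permutation invariance
  set.seed(3)
  hx <- c("AATAAA", "ATTAAA", "TATAAA", "AATACA", "TTTAAA")
  for (i in 1:10) {
    perm <- h(sample(hx))
    expect_equal(assign_pas(perm, tab)$assigned_variant, "AATAAA")
  }
  call <- assign_pas(h(hx), tab, "t", "g", "mRNA")
  expect_equal(call$n_distinct_variants, 5L)
  expect_equal(call$n_total_hits, 5L)
})

test_that("planted consensus rate is recovered within binomial error", {
  p <- 0.6
  cfg <- synth_transcript_config(
    n_per_class = 300, len_range = c(300L, 600L),
    pas_rates = list(mRNA = c(AATAAA = p), lncRNA = c(AATAAA = p)),
    dse_rate = 0, seed = 2024)
  sim <- generate_transcripts(cfg)
  calls <- call_pas(sim$records)
  frac <- mean(calls$assigned_variant[!calls$excluded] == "AATAAA")
  se <- sqrt(p * (1 - p) / sum(!calls$excluded))
  expect_lt(abs(frac - p), 3 * se)
})
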