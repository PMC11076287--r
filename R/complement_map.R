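# Mismatch-tolerant k-mer mapping of lncRNA pools.
#
# Every k-mer (k = 19-25 by default) of each query sequence is matched
# against every position of every pool member on both strands, scoring
# full-length Hamming distance (no indels) with an allowance of 0-2
# mismatches. Antisense hits -- the k-mer matching the reverse complement
# of the target sense strand -- indicate RNA:RNA base-pairing potential
# and are the hits of interest; merged per sequence pair they give the
# predicted complementary regions between pool members.
#
# The inner scan is compiled (src/hamming_scan.cpp); naive_scan_pool()
# is an independent, deliberately brute-force R reference used in tests
# and by the synthetic pool generator.

DNA_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# integer-encode a sequence; non-ACGT characters become -1 (ambiguous)
enc_dna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- DNA_CODES[chars]
  codes[is.na(codes)] <- -1L
  unname(codes)
}

# complement in code space; ambiguity stays ambiguous
comp_codes <- function(codes) {
  ifelse(codes < 0L, -1L, 3L - codes)
}

#' Enumerate all k-mers of a sequence by sliding window
#'
#' A sequence of length L yields exactly L - k + 1 k-mers at consecutive
#' offsets 0..L-k. k-mers containing ambiguous bases are emitted but
#' flagged unmatchable (they never match anywhere).
#'
#' @param seq nucleotide string.
#' @param k k-mer length, 1 <= k <= nchar(seq).
#' @param query_id optional id copied onto the entries.
#' @return data.frame with columns `query_id`, `query_offset` (0-based),
#'   `kmer`, `matchable`.
#' @examples
#' nrow(enumerate_kmers(strrep("A", 1000), 19))  # 982
#' @export
enumerate_kmers <- function(seq, k, query_id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (k < 1L || k > L) {
    stop("k (", k, ") must lie in [1, sequence length = ", L, "]")
  }
  offsets <- 0:(L - k)
  kmers <- substring(seq, offsets + 1L, offsets + k)
  data.frame(query_id = query_id, query_offset = offsets, kmer = kmers,
             matchable = !grepl("[^ACGT]", kmers),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_id = character(), query_offset = integer(),
             target_id = character(), target_start = integer(),
             target_end = integer(), strand = character(),
             mismatches = integer(), k = integer(),
             stringsAsFactors = FALSE)
}

# assemble a hit data.frame from scanner output (n taken from target_start)
hits_frame <- function(query_id, query_offset, target_id, target_start,
                       mismatches, k, strand) {
  n <- length(target_start)
  data.frame(query_id = rep_len(query_id, n),
             query_offset = as.integer(query_offset),
             target_id = rep_len(target_id, n),
             target_start = as.integer(target_start),
             target_end = as.integer(target_start) + as.integer(k),
             strand = rep_len(strand, n),
             mismatches = as.integer(mismatches),
             k = rep_len(as.integer(k), n),
             stringsAsFactors = FALSE)
}

# scan one query sequence against one target on both strands.
# Minus-strand semantics: the k-mer matches the reverse complement of
# the target sense substring, i.e. Hamming(kmer, rc(target[p, p+k))).
# Implemented by scanning the reverse-complemented query forward along
# the target and mapping offsets back: qrc offset i' <-> query offset
# Lq - k - i'.
scan_pair <- function(query_id, qseq, target_id, tseq, k, max_mm) {
  Lq <- nchar(qseq)
  qe <- enc_dna(qseq)
  te <- enc_dna(tseq)
  plus <- .scan_hamming_pairs(qe, te, k, max_mm)
  qrc <- rev(comp_codes(qe))
  minus <- .scan_hamming_pairs(qrc, te, k, max_mm)
  rbind(
    hits_frame(query_id, plus$a_off, target_id, plus$b_off,
               plus$mm, k, "+"),
    hits_frame(query_id, Lq - k - minus$a_off, target_id, minus$b_off,
               minus$mm, k, "-")
  )
}

#' Match a single k-mer against a target sequence
#'
#' Reports, for every target position, a `"+"` hit when the k-mer matches
#' the target sense substring and a `"-"` (antisense) hit when it matches
#' the reverse complement of that substring, each within `max_mm`
#' mismatches (full-length Hamming distance, no indels).
#'
#' @param kmer query k-mer over {A,C,G,T}.
#' @param target_seq target nucleotide string.
#' @param max_mm maximum allowed mismatches (default caps at 2; larger
#'   values are permitted but depart from the intended use).
#' @param target_id,query_id,query_offset identifiers copied onto hits.
#' @return hit data.frame with columns `query_id`, `query_offset`,
#'   `target_id`, `target_start`, `target_end` (0-based half-open on the
#'   target sense strand), `strand`, `mismatches`, `k`.
#' @export
hamming_match <- function(kmer, target_seq, max_mm = 2L,
                          target_id = "target", query_id = "query",
                          query_offset = 0L) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  if (grepl("[^ACGT]", kmer)) stop("k-mer must be over {A,C,G,T}")
  if (max_mm < 0L) stop("max_mm must be >= 0")
  k <- nchar(kmer)
  hits <- scan_pair(query_id, kmer, target_id, target_seq, k, max_mm)
  hits$query_offset <- hits$query_offset + query_offset
  order_hits(hits)
}

#' Map all k-mers of every pool member against the whole pool
#'
#' The union over `k_values` and all query/target pairs of
#' [hamming_match()] results. Self-pairs are excluded unless
#' `include_self = TRUE`; the degenerate exact self sense-match of a
#' k-mer at its own coordinates is always excluded. Pair/k combinations
#' where k exceeds either sequence length are skipped.
#'
#' @param pool transcript table (unique `transcript_id`s).
#' @param k_values k-mer lengths to scan (default 19:25).
#' @param max_mm maximum allowed mismatches (default 2).
#' @param include_self also scan each sequence against itself
#'   (hairpin-style matches).
#' @return hit data.frame as in [hamming_match()], ordered by
#'   (query_id, target_id, k, strand, target_start, query_offset).
#' @export
map_pool <- function(pool, k_values = 19:25, max_mm = 2L,
                     include_self = FALSE) {
  check_transcripts(pool)
  if (nrow(pool) == 0L) stop("pool is empty")
  if (length(k_values) == 0L) stop("k_values is empty")
  if (max_mm < 0L) stop("max_mm must be >= 0")
  lens <- nchar(pool$sequence)
  out <- list()
  for (qi in seq_len(nrow(pool))) {
    for (ti in seq_len(nrow(pool))) {
      if (qi == ti && !include_self) next
      for (k in k_values) {
        if (k > lens[qi] || k > lens[ti]) next
        hits <- scan_pair(pool$transcript_id[qi], pool$sequence[qi],
                          pool$transcript_id[ti], pool$sequence[ti],
                          k, max_mm)
        if (qi == ti && nrow(hits)) {
          trivial <- hits$strand == "+" & hits$query_offset == hits$target_start
          hits <- hits[!trivial, , drop = FALSE]
        }
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  hits <- do.call(rbind, c(out, list(empty_hits())))
  order_hits(hits)
}

order_hits <- function(hits) {
  hits <- hits[order(hits$query_id, hits$target_id, hits$k, hits$strand,
                     hits$target_start, hits$query_offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Keep only antisense matches
#'
#' @param hits hit data.frame.
#' @return the rows with strand `"-"`, order preserved.
#' @export
filter_antisense <- function(hits) {
  hits[hits$strand == "-", , drop = FALSE]
}

#' Merge antisense hits into complementary regions
#'
#' Per (query_id, target_id) pair, target intervals that overlap or are
#' book-ended (gap 0) are unioned; each merged region records its
#' supporting hit count and the minimum mismatch count among supporters.
#'
#' @param hits antisense-filtered hit data.frame.
#' @return data.frame with columns `query_id`, `target_id`, `start`,
#'   `end` (0-based half-open on the target), `n_hits`,
#'   `min_mismatches`, sorted by (query_id, target_id, start).
#' @export
merge_regions <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      n_hits = integer(), min_mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  if (any(hits$strand != "-")) {
    stop("merge_regions expects antisense-filtered hits (strand '-')")
  }
  key <- paste(hits$query_id, hits$target_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(i) {
    ir <- IRanges::IRanges(start = hits$target_start[i] + 1L,
                           end = hits$target_end[i])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(
      query_id = hits$query_id[i[1]],
      target_id = hits$target_id[i[1]],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      n_hits = lengths(revmap),
      min_mismatches = vapply(revmap, function(j) {
        min(hits$mismatches[i][j])
      }, 0L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$query_id, out$target_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force reference scanner (test oracle)
#'
#' An independent, naive realization of [map_pool()]: every query k-mer
#' is compared against every target position on both strands by direct
#' per-position Hamming counting, with no early exit and no shared code
#' with the compiled scanner. Used to verify the scanner and to certify
#' synthetic pools free of unplanned matches. Quadratic: intended for
#' pools of at most a few kilobases.
#'
#' @inheritParams map_pool
#' @return hit data.frame identical in format and content to
#'   [map_pool()] on the same input.
#' @export
naive_scan_pool <- function(pool, k_values = 19:25, max_mm = 2L,
                            include_self = FALSE) {
  check_transcripts(pool)
  enc <- lapply(pool$sequence, enc_dna)
  lens <- nchar(pool$sequence)
  out <- list()
  for (qi in seq_len(nrow(pool))) {
    for (ti in seq_len(nrow(pool))) {
      if (qi == ti && !include_self) next
      for (k in k_values) {
        if (k > lens[qi] || k > lens[ti]) next
        hits <- naive_scan_one(pool$transcript_id[qi], enc[[qi]],
                               pool$transcript_id[ti], enc[[ti]],
                               k, max_mm)
        if (qi == ti && nrow(hits)) {
          trivial <- hits$strand == "+" & hits$query_offset == hits$target_start
          hits <- hits[!trivial, , drop = FALSE]
        }
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  hits <- do.call(rbind, c(out, list(empty_hits())))
  order_hits(hits)
}

# one (query, target, k) cell of the naive scan. Plus strand compares
# the k-mer directly; minus strand uses the identity
# Hamming(x, rc(t[p, p+k))) = Hamming(reverse(x), complement(t)[p, p+k)).
naive_scan_one <- function(query_id, qe, target_id, te, k, max_mm) {
  nq <- length(qe) - k + 1L
  nt <- length(te) - k + 1L
  tc <- comp_codes(te)
  # recode ambiguity so query(-1) never equals target(-2)
  te2 <- ifelse(te < 0L, -2L, te)
  tc2 <- ifelse(tc < 0L, -2L, tc)
  res <- list()
  for (i in seq_len(nq)) {
    x <- qe[i:(i + k - 1L)]
    if (any(x < 0L)) next  # unmatchable k-mer
    mm_plus <- integer(nt)
    mm_minus <- integer(nt)
    xr <- rev(x)
    for (l in seq_len(k)) {
      tl <- l:(l + nt - 1L)
      mm_plus <- mm_plus + (te2[tl] != x[l])
      mm_minus <- mm_minus + (tc2[tl] != xr[l])
    }
    p <- which(mm_plus <= max_mm)
    m <- which(mm_minus <= max_mm)
    if (length(p)) {
      res[[length(res) + 1L]] <-
        hits_frame(query_id, i - 1L, target_id, p - 1L, mm_plus[p], k, "+")
    }
    if (length(m)) {
      res[[length(res) + 1L]] <-
        hits_frame(query_id, i - 1L, target_id, m - 1L, mm_minus[m], k, "-")
    }
  }
  do.call(rbind, c(res, list(empty_hits())))
}
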