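# Seeded synthetic-data generators with ground truth.
#
# Two stated worlds are emulated:
#  * transcript sets for the 3'-end analysis: two gene classes, uniform
#    lengths, i.i.d. background, PAS hexamers planted inside the terminal
#    window at per-variant, per-class rates (defaults reflect the
#    headline class difference: consensus in 60% of mRNA genes vs 23% of
#    lncRNA genes), DSE motifs planted in downstream windows, optional
#    short / ambiguous-window records to exercise the filter;
#  * lncRNA pools for the complementarity analysis: reverse-complement
#    blocks planted with an exact mismatch count d, background certified
#    free of unplanned antisense matches by the brute-force oracle.
#
# All randomness flows from a single integer seed through an isolated
# RNG scope (withr::with_seed); no global state is touched.

#' Configuration for the synthetic transcript generator
#'
#' @param n_per_class records per gene class.
#' @param len_range inclusive range of transcript lengths (uniform).
#' @param base_comp background base probabilities, named A/C/G/T.
#' @param pas_rates named list (`mRNA`, `lncRNA`) of named per-variant
#'   planting probabilities; each vector must sum to at most 1, the
#'   remainder being unplanted. Defaults emulate consensus usage of 60%
#'   (mRNA) vs 23% (lncRNA) with a thinner tail of degenerate variants.
#' @param window terminal window length motifs are planted into.
#' @param dse_rate probability that a record's downstream window carries
#'   a planted DSE motif (independent of PAS planting).
#' @param dse_pattern `dse_pattern` the planted DSE motifs are drawn
#'   from (default: packaged logo at threshold 0.10).
#' @param short_rate probability of a deliberately short record
#'   (length 50..min_len, expected to be filtered out).
#' @param amb_rate probability of a record with one N injected into its
#'   terminal window (expected to be filtered out).
#' @param min_len filter length the short records undershoot.
#' @param seed integer seed (mandatory).
#' @return validated config list of class `transcript_synth_config`.
#' @export
synth_transcript_config <- function(n_per_class = 2000L,
                                    len_range = c(500L, 2000L),
                                    base_comp = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                    pas_rates = list(
                                      mRNA = c(AATAAA = 0.60, ATTAAA = 0.15,
                                               TATAAA = 0.04),
                                      lncRNA = c(AATAAA = 0.23, ATTAAA = 0.08,
                                                 TATAAA = 0.02)),
                                    window = 50L,
                                    dse_rate = 0.4,
                                    dse_pattern = NULL,
                                    short_rate = 0,
                                    amb_rate = 0,
                                    min_len = 200L,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_per_class >= 1L, length(len_range) == 2L,
            len_range[1] <= len_range[2])
  if (short_rate == 0 && len_range[1] <= min_len) {
    stop("min length must exceed ", min_len,
         " unless short records are requested via short_rate")
  }
  if (!setequal(names(base_comp), c("A", "C", "G", "T")) ||
      abs(sum(base_comp) - 1) > 1e-6) {
    stop("base_comp must be named A/C/G/T probabilities summing to 1")
  }
  stopifnot(setequal(names(pas_rates), c("mRNA", "lncRNA")))
  for (cls in names(pas_rates)) {
    r <- pas_rates[[cls]]
    if (any(r < 0) || sum(r) > 1) {
      stop("pas_rates$", cls, " must be probabilities summing to <= 1")
    }
    if (any(nchar(names(r)) != 6L)) stop("planted PAS variants must be hexamers")
  }
  rates01 <- c(dse_rate, short_rate, amb_rate)
  if (any(rates01 < 0 | rates01 > 1)) stop("rates must lie in [0, 1]")
  if (is.null(dse_pattern)) {
    dse_pattern <- build_dse_pattern(read_sequence_logo(), 0.10)
  }
  if (window < 6L) stop("window too short for a hexamer")
  if (dse_pattern$length > 50L) stop("DSE pattern longer than the 50-nt window")
  structure(list(n_per_class = as.integer(n_per_class),
                 len_range = as.integer(len_range), base_comp = base_comp,
                 pas_rates = pas_rates, window = as.integer(window),
                 dse_rate = dse_rate, dse_pattern = dse_pattern,
                 short_rate = short_rate, amb_rate = amb_rate,
                 min_len = as.integer(min_len), seed = as.integer(seed)),
            class = "transcript_synth_config")
}

random_bases <- function(n, base_comp) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_comp)
}

# sample a terminal window free of any table hexamer (bounded rejection)
clean_window <- function(window, base_comp, hexamers, max_attempts = 1000L) {
  rx <- paste(hexamers, collapse = "|")
  for (a in seq_len(max_attempts)) {
    w <- paste(random_bases(window, base_comp), collapse = "")
    if (!grepl(rx, w)) return(w)
  }
  stop("could not sample a motif-free window after ", max_attempts,
       " attempts; lower the A/T content or lengthen the window")
}

#' Generate a synthetic transcript set with ground truth
#'
#' Background bases are i.i.d. from `base_comp`. Every non-short,
#' non-ambiguous record's terminal window is rejection-sampled to be
#' free of *all* table hexamers before planting, so an unplanted record
#' can never be assigned a PAS and a planted record is assigned exactly
#' its planted variant — recovery error is pure binomial planting noise.
#' Downstream windows are likewise sampled free of DSE-pattern matches
#' before optional motif planting. Deterministic given the seed.
#'
#' @param config from [synth_transcript_config()].
#' @param table PAS variant table used for the rejection sampling
#'   (default: packaged table).
#' @return list with `records` (transcript table), `downstream` (named
#'   character vector of 50-nt downstream windows) and `truth`
#'   (data.frame: one row per record with `planted_variant`,
#'   `pas_start`, `dse_planted`, `dse_start`, `dse_motif`, `short`,
#'   `ambiguous`).
#' @export
generate_transcripts <- function(config, table = pas_variant_table()) {
  stopifnot(inherits(config, "transcript_synth_config"))
  hexamers <- unique(c(table$hexamer,
                       unlist(lapply(config$pas_rates, names))))
  withr::with_seed(config$seed, {
    rows <- list()
    records <- list()
    downstream <- character()
    idx <- 0L
    for (cls in c("mRNA", "lncRNA")) {
      rates <- config$pas_rates[[cls]]
      for (i in seq_len(config$n_per_class)) {
        idx <- idx + 1L
        id <- sprintf("SYN%s_%04d", cls, i)
        short <- runif(1) < config$short_rate
        ambiguous <- !short && runif(1) < config$amb_rate
        if (short) {
          L <- sample(50L:config$min_len, 1L)
          seq <- paste(random_bases(L, config$base_comp), collapse = "")
          planted <- "NONE"; pas_start <- NA_integer_
        } else {
          L <- sample(config$len_range[1]:config$len_range[2], 1L)
          body <- paste(random_bases(L - config$window, config$base_comp),
                        collapse = "")
          win <- clean_window(config$window, config$base_comp, hexamers)
          planted <- "NONE"; pas_start <- NA_integer_
          if (!ambiguous) {
            u <- runif(1)
            cum <- cumsum(rates)
            pick <- which(u < cum)
            if (length(pick)) {
              planted <- names(rates)[pick[1]]
              repeat {
                off <- sample(0:(config$window - 6L), 1L)
                w2 <- paste0(substr(win, 1L, off),
                             planted,
                             substr(win, off + 7L, config$window))
                # reject windows where planting spawned a second variant
                found <- unlist(lapply(hexamers, function(hx) {
                  m <- gregexpr(paste0("(?=", hx, ")"), w2, perl = TRUE)[[1]]
                  if (m[1] == -1L) character() else rep(hx, length(m))
                }))
                if (all(found == planted)) { win <- w2; break }
                win <- clean_window(config$window, config$base_comp, hexamers)
              }
              pas_start <- L - config$window + off
            }
          } else {
            npos <- sample(config$window, 1L)
            substr(win, npos, npos) <- "N"
          }
          seq <- paste0(body, win)
        }
        dse_planted <- FALSE; dse_start <- NA_integer_; dse_motif <- NA_character_
        dw <- sample_dse_window(config)
        if (!short && !ambiguous && runif(1) < config$dse_rate) {
          dse_planted <- TRUE
          m <- config$dse_pattern$length
          dse_motif <- paste(vapply(config$dse_pattern$allowed, function(b) {
            if (length(b) == 1L) b else sample(b, 1L)
          }, ""), collapse = "")
          dse_start <- sample(0:(50L - m), 1L)
          substr(dw, dse_start + 1L, dse_start + m) <- dse_motif
        }
        downstream[[id]] <- dw
        records[[idx]] <- data.frame(
          transcript_id = id, gene_id = id, gene_class = cls,
          sequence = seq, chrom = NA_character_, start = NA_integer_,
          end = NA_integer_, strand = NA_character_,
          stringsAsFactors = FALSE)
        rows[[idx]] <- data.frame(
          transcript_id = id, gene_class = cls, length = nchar(seq),
          short = short, ambiguous = ambiguous,
          planted_variant = planted, pas_start = pas_start,
          dse_planted = dse_planted, dse_start = dse_start,
          dse_motif = dse_motif, stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, records),
         downstream = downstream,
         truth = do.call(rbind, rows))
  })
}

# 50-nt downstream window free of DSE pattern matches
sample_dse_window <- function(config, max_attempts = 1000L) {
  for (a in seq_len(max_attempts)) {
    w <- paste(random_bases(50L, config$base_comp), collapse = "")
    if (nrow(scan_dse(w, config$dse_pattern)) == 0L) return(w)
  }
  stop("could not sample a DSE-free downstream window after ",
       max_attempts, " attempts; use a more specific pattern")
}

#' Substitute exactly d positions of a block
#'
#' Each chosen position is replaced by a base different from the
#' original, so the Hamming distance between input and output is exactly
#' `d`. Positions are drawn uniformly from `candidates` (1-based;
#' default: all positions).
#'
#' @param block nucleotide string over {A,C,G,T}.
#' @param d exact number of substitutions, `0 <= d <= nchar(block)`.
#' @param seed optional integer seed for an isolated RNG scope; omit to
#'   use the ambient RNG (e.g. inside a seeded generator).
#' @param candidates positions eligible for substitution.
#' @return list with `block` (mutated string) and `positions` (1-based
#'   substituted positions, increasing).
#' @export
mutate_block <- function(block, d, seed = NULL,
                         candidates = seq_len(nchar(block))) {
  if (d < 0L) stop("d must be >= 0")
  if (d > length(candidates)) {
    stop("d (", d, ") exceeds the ", length(candidates),
         " candidate positions")
  }
  if (grepl("[^ACGT]", block)) stop("block must be over {A,C,G,T}")
  run <- function() {
    pos <- sort(sample(candidates, d))
    chars <- strsplit(block, "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    list(block = paste(chars, collapse = ""), positions = pos)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Configuration for the synthetic complement-pool generator
#'
#' @param n_seqs pool size.
#' @param len_range inclusive range of sequence lengths (uniform).
#' @param blocks data.frame of planted antisense blocks with columns
#'   `query` and `target` (1-based pool indices, distinct), `length`
#'   (block length, 19..60) and `d` (exact mismatch count, 0..2);
#'   optional `query_pos` / `target_pos` (0-based; `NA` = sampled).
#' @param base_comp background base probabilities.
#' @param central_mismatches place the d substitutions inside the
#'   intersection of all 19-mer sub-windows of the block (requires block
#'   length <= 37), so every k in 19..25 sees exactly d mismatches and a
#'   block is recovered iff `max_mm >= d` at every k. Default TRUE.
#' @param max_attempts bound on rejection-sampling rounds.
#' @param seed integer seed (mandatory).
#' @return validated config list of class `pool_synth_config`.
#' @export
pool_synth_config <- function(n_seqs = 4L,
                              len_range = c(200L, 400L),
                              blocks = data.frame(query = integer(),
                                                  target = integer(),
                                                  length = integer(),
                                                  d = integer()),
                              base_comp = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                              central_mismatches = TRUE,
                              max_attempts = 1000L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_seqs >= 1L, length(len_range) == 2L,
            len_range[1] >= 19L, len_range[1] <= len_range[2])
  stopifnot(is.data.frame(blocks),
            all(c("query", "target", "length", "d") %in% names(blocks)))
  if (!"query_pos" %in% names(blocks)) {
    blocks$query_pos <- rep(NA_integer_, nrow(blocks))
  }
  if (!"target_pos" %in% names(blocks)) {
    blocks$target_pos <- rep(NA_integer_, nrow(blocks))
  }
  if (nrow(blocks)) {
    if (any(blocks$query == blocks$target)) {
      stop("hairpin blocks (query == target) are not supported by the generator")
    }
    if (any(blocks$query < 1L | blocks$query > n_seqs |
            blocks$target < 1L | blocks$target > n_seqs)) {
      stop("block indices must lie in 1..n_seqs")
    }
    if (any(blocks$length < 19L | blocks$length > 60L)) {
      stop("block lengths must lie in [19, 60]")
    }
    if (any(blocks$d < 0L | blocks$d > 2L)) stop("d must lie in {0, 1, 2}")
    if (central_mismatches &&
        any(blocks$d > 0L & (36L - blocks$length) < blocks$d)) {
      stop("central mismatch placement needs block length <= ",
           "36 - d (mismatches must fit inside every 18-base overlap window)")
    }
    if (any(blocks$length > len_range[1])) {
      stop("blocks must fit inside the shortest possible sequence")
    }
  }
  structure(list(n_seqs = as.integer(n_seqs),
                 len_range = as.integer(len_range), blocks = blocks,
                 base_comp = base_comp,
                 central_mismatches = isTRUE(central_mismatches),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "pool_synth_config")
}

#' Generate a synthetic lncRNA pool with planted antisense blocks
#'
#' Each planted block copies `length` bases from the query sequence,
#' reverse-complements them, substitutes exactly `d` positions and
#' writes the result into the target. With `central_mismatches` the
#' substitutions are confined to positions that every window overlapping
#' the block by at least 18 bases contains, and the three target bases on
#' each side of the block are rewritten so that they do *not* pair with
#' their query counterparts ("mismatch guards"): windows fully inside
#' the block then carry exactly `d` mismatches while every partially
#' overlapping window carries at least `d + 1`, so the block is
#' recovered with exact coordinates at `max_mm = d` and invisible below.
#'
#' The pool is certified with the brute-force oracle
#' ([naive_scan_pool()]) at k = 19 (any k >= 19 match contains a 19-mer
#' match, so k = 19 cleanliness covers all k), level by level for
#' `max_mm` 0..2: in-block hits of every block with `d <= max_mm` must
#' be present exactly, and any further hit must overlap a block with
#' `d < max_mm` (a flank-extended planted match); anything else —
#' an accidental background match in particular — triggers resampling,
#' up to `max_attempts` times.
#'
#' @param config from [pool_synth_config()].
#' @return list with `pool` (transcript table, gene_class `"lncRNA"`)
#'   and `truth` (blocks with realized positions and the 1-based
#'   substituted positions as a comma-separated string).
#' @export
generate_complement_pool <- function(config) {
  stopifnot(inherits(config, "pool_synth_config"))
  blocks <- config$blocks
  withr::with_seed(config$seed, {
    for (attempt in seq_len(config$max_attempts)) {
      lens <- sample(config$len_range[1]:config$len_range[2],
                     config$n_seqs, replace = TRUE)
      seqs <- vapply(lens, function(L) {
        paste(random_bases(L, config$base_comp), collapse = "")
      }, "")
      truth <- blocks
      truth$mm_positions <- character(nrow(truth))
      if (nrow(blocks)) {
        for (b in seq_len(nrow(blocks))) {
          len <- blocks$length[b]
          q <- blocks$query[b]; t <- blocks$target[b]
          qpos <- blocks$query_pos[b]
          if (is.na(qpos)) qpos <- sample(0:(lens[q] - len), 1L)
          tpos <- blocks$target_pos[b]
          if (is.na(tpos)) tpos <- sample(0:(lens[t] - len), 1L)
          if (qpos + len > lens[q] || tpos + len > lens[t]) {
            stop("block ", b, " does not fit inside its sequences")
          }
          content <- substr(seqs[q], qpos + 1L, qpos + len)
          cand <- if (config$central_mismatches && blocks$d[b] > 0L) {
            seq.int(max(len - 17L, 1L), min(18L, len))
          } else seq_len(len)
          mut <- mutate_block(reverse_complement(content), blocks$d[b],
                              candidates = cand)
          substr(seqs[t], tpos + 1L, tpos + len) <- mut$block
          if (config$central_mismatches) {
            seqs[t] <- place_guards(seqs[t], seqs[q], tpos, qpos, len,
                                    lens[t], lens[q])
          }
          truth$query_pos[b] <- qpos
          truth$target_pos[b] <- tpos
          truth$mm_positions[b] <- paste(mut$positions, collapse = ",")
        }
      }
      pool <- data.frame(
        transcript_id = sprintf("SYNPOOL_%02d", seq_len(config$n_seqs)),
        gene_id = sprintf("SYNPOOL_%02d", seq_len(config$n_seqs)),
        gene_class = "lncRNA", sequence = seqs,
        chrom = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, stringsAsFactors = FALSE)
      if (pool_is_clean(pool, truth)) {
        return(list(pool = pool, truth = truth))
      }
    }
    stop("could not generate a clean pool after ", config$max_attempts,
         " attempts; use longer sequences or a less biased base composition")
  })
}

# rewrite the 3 target bases on each side of a planted block so they do
# not pair with their query counterparts under the antisense alignment
# (query base qpos+u pairs with target base tpos+len-1-u; extending the
# diagonal, target tpos+len+e pairs with query qpos-1-e and target
# tpos-1-e with query qpos+len+e)
place_guards <- function(tseq, qseq, tpos, qpos, len, lt, lq) {
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  for (e in 0:2) {
    tp <- tpos + len + e          # right flank, 0-based
    qp <- qpos - 1L - e
    if (tp < lt && qp >= 0L) {
      forbidden <- comp1(substr(qseq, qp + 1L, qp + 1L))
      substr(tseq, tp + 1L, tp + 1L) <-
        sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
    }
    tp <- tpos - 1L - e           # left flank
    qp <- qpos + len + e
    if (tp >= 0L && qp < lq) {
      forbidden <- comp1(substr(qseq, qp + 1L, qp + 1L))
      substr(tseq, tp + 1L, tp + 1L) <-
        sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
    }
  }
  tseq
}

# oracle certification, level by level: at each max_mm level m the
# antisense k=19 hit set must contain exactly the in-block hits of
# blocks with d <= m, plus only flank extensions of blocks with d < m
pool_is_clean <- function(pool, truth) {
  ids <- pool$transcript_id
  for (m in 0:2) {
    observed <- filter_antisense(
      naive_scan_pool(pool, k_values = 19L, max_mm = m))
    required <- expected_antisense_19(truth[truth$d <= m, , drop = FALSE],
                                      ids)
    obs_key <- hit_keys(observed)
    if (!all(hit_keys(required) %in% obs_key)) return(FALSE)
    extras <- observed[!obs_key %in% hit_keys(required), , drop = FALSE]
    if (nrow(extras)) {
      lax <- truth[truth$d < m, , drop = FALSE]
      covered <- vapply(seq_len(nrow(extras)), function(i) {
        hit_touches_block(extras[i, ], lax, ids)
      }, NA)
      if (!all(covered)) return(FALSE)
    }
  }
  TRUE
}

hit_keys <- function(h) {
  paste(h$query_id, h$query_offset, h$target_id, h$target_start,
        h$mismatches, sep = "\r")
}

# does a hit's target interval overlap a planted block (either
# direction of the symmetric pair)?
hit_touches_block <- function(hit, blocks, ids) {
  if (nrow(blocks) == 0L) return(FALSE)
  for (b in seq_len(nrow(blocks))) {
    qid <- ids[blocks$query[b]]; tid <- ids[blocks$target[b]]
    len <- blocks$length[b]
    if (hit$query_id == qid && hit$target_id == tid &&
        hit$target_start < blocks$target_pos[b] + len &&
        hit$target_start + hit$k > blocks$target_pos[b]) {
      return(TRUE)
    }
    if (hit$query_id == tid && hit$target_id == qid &&
        hit$target_start < blocks$query_pos[b] + len &&
        hit$target_start + hit$k > blocks$query_pos[b]) {
      return(TRUE)
    }
  }
  FALSE
}

# the k = 19 antisense hits a planted-block pool must show, exactly.
# Antisense complementarity is symmetric, so each block is seen from
# both directions: query k-mers into the target and vice versa.
expected_antisense_19 <- function(truth, ids) {
  if (nrow(truth) == 0L) return(empty_hits())
  out <- lapply(seq_len(nrow(truth)), function(b) {
    len <- truth$length[b]
    i <- 0:(len - 19L)
    qo <- truth$query_pos[b] + i
    ts <- truth$target_pos[b] + (len - 19L - i)
    d <- rep(truth$d[b], length(i))
    rbind(
      hits_frame(ids[truth$query[b]], qo, ids[truth$target[b]], ts,
                 d, 19L, "-"),
      hits_frame(ids[truth$target[b]], ts, ids[truth$query[b]], qo,
                 d, 19L, "-")
    )
  })
  order_hits(do.call(rbind, out))
}
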