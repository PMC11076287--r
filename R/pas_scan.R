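# Polyadenylation-signal (PAS) scanning of transcript 3' terminal windows.
#
# The consensus PAS is AATAAA; degenerate variants are used less often.
# Scanning covers the last `window` (default 50) nucleotides of each
# transcript, sense strand only, and a hexamer counts only when all six
# bases lie inside the window. When several variants hit one transcript,
# the assignment takes the variant closest to consensus, breaking ties by
# usage rank (the more commonly used variant wins).

PAS_CONSENSUS <- "AATAAA"

#' Load a PAS variant table
#'
#' Reads a two-column delimited configuration file (`hexamer`,
#' `usage_rank`), computes each variant's Hamming distance to the AATAAA
#' consensus, and orders rows by (consensus_distance, usage_rank). The
#' packaged default is the classical poly(A)-signal usage survey:
#' consensus AATAAA plus twelve lower-usage variants.
#'
#' @param path path to a tab- or whitespace-delimited file with header
#'   columns `hexamer` and `usage_rank`; `NULL` loads the packaged table.
#' @return data.frame with columns `hexamer`, `consensus_distance`,
#'   `usage_rank`, ordered as above.
#' @export
pas_variant_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pas_variants.tsv", package = "pasmap",
                        mustWork = TRUE)
  }
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("hexamer", "usage_rank") %in% names(tab))) {
    stop("PAS variant table needs columns 'hexamer' and 'usage_rank'")
  }
  tab$hexamer <- toupper(tab$hexamer)
  if (any(nchar(tab$hexamer) != 6L) || any(grepl("[^ACGT]", tab$hexamer))) {
    stop("PAS variants must be hexamers over {A,C,G,T}")
  }
  if (anyDuplicated(tab$hexamer)) stop("duplicate hexamers in PAS table")
  tab$usage_rank <- as.integer(tab$usage_rank)
  tab$consensus_distance <- vapply(tab$hexamer, hamming_distance, 0L,
                                   PAS_CONSENSUS)
  if (!PAS_CONSENSUS %in% tab$hexamer) {
    stop("PAS table must contain the consensus ", PAS_CONSENSUS)
  }
  if (tab$usage_rank[tab$hexamer == PAS_CONSENSUS] != 1L) {
    stop("the consensus ", PAS_CONSENSUS, " must have usage_rank 1")
  }
  tab <- tab[order(tab$consensus_distance, tab$usage_rank),
             c("hexamer", "consensus_distance", "usage_rank")]
  rownames(tab) <- NULL
  tab
}

# Hamming distance between equal-length strings (no indels)
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("Hamming distance needs equal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Filter the PAS search set
#'
#' Keeps transcripts longer than `min_len` nucleotides whose terminal
#' search window — and, when supplied, whose downstream window — contains
#' only unambiguous bases {A,C,G,T}. Excluded transcripts are returned as
#' call records with a reason (`short` or `ambiguous_window`), so the
#' denominator of any later summary is explicit.
#'
#' @param records transcript table (see [read_transcript_fasta()]).
#' @param min_len minimum transcript length, exclusive (default 200: a
#'   transcript must be *greater than* 200 nt).
#' @param window terminal search-window length (default 50).
#' @param downstream_windows optional named character vector of
#'   downstream window sequences, indexed by `transcript_id`.
#' @return list with elements `kept` (transcript table) and `excluded`
#'   (call table as from [assign_pas()], with `excluded = TRUE`).
#' @export
filter_search_set <- function(records, min_len = 200L, window = 50L,
                              downstream_windows = NULL) {
  check_transcripts(records)
  if (window > min_len) stop("window (", window, ") must not exceed min_len (",
                             min_len, ")")
  len <- nchar(records$sequence)
  short <- len <= min_len
  terminal <- substr(records$sequence, pmax(len - window + 1L, 1L), len)
  ambiguous <- grepl("[^ACGT]", terminal)
  if (!is.null(downstream_windows)) {
    dw <- downstream_windows[records$transcript_id]
    ambiguous <- ambiguous | (!is.na(dw) & grepl("[^ACGT]", dw))
  }
  reason <- ifelse(short, "short", ifelse(ambiguous, "ambiguous_window", "none"))
  excl <- short | ambiguous
  excluded <- empty_pas_calls()
  if (any(excl)) {
    r <- records[excl, , drop = FALSE]
    excluded <- data.frame(
      transcript_id = r$transcript_id,
      gene_id = r$gene_id,
      gene_class = r$gene_class,
      assigned_variant = "NONE",
      n_distinct_variants = 0L,
      n_total_hits = 0L,
      excluded = TRUE,
      reason = reason[excl],
      stringsAsFactors = FALSE
    )
    rownames(excluded) <- NULL
  }
  list(kept = records[!excl, , drop = FALSE], excluded = excluded)
}

empty_pas_calls <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             gene_class = character(), assigned_variant = character(),
             n_distinct_variants = integer(), n_total_hits = integer(),
             excluded = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Scan a transcript's terminal window for PAS hexamers
#'
#' Reports every occurrence (overlaps allowed) of every table hexamer
#' whose six bases lie entirely within the last `window` bases of the
#' sequence. Sense strand only.
#'
#' @param seq transcript sequence (length >= `window`, window over
#'   {A,C,G,T}).
#' @param table PAS variant table from [pas_variant_table()].
#' @param window terminal window length (default 50).
#' @return data.frame with columns `hexamer`, `start` (0-based position
#'   in the full sequence) and `offset_from_3prime` (distance from the
#'   hexamer's last base to the transcript's last base).
#' @export
scan_pas_window <- function(seq, table, window = 50L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than the search window")
  win_start <- L - window  # 0-based start of the window
  terminal <- substr(seq, win_start + 1L, L)
  if (grepl("[^ACGT]", terminal)) {
    stop("ambiguous base in the terminal search window")
  }
  hits <- lapply(table$hexamer, function(hx) {
    m <- gregexpr(paste0("(?=", hx, ")"), terminal, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    start <- win_start + as.integer(m) - 1L  # 0-based in full sequence
    data.frame(hexamer = hx, start = start,
               offset_from_3prime = L - (start + 6L),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(hexamer = character(), start = integer(),
                       offset_from_3prime = integer(),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$start, hits$hexamer), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign one PAS variant from a transcript's hits
#'
#' With no hits the assignment is `"NONE"`. Otherwise the assigned
#' variant minimizes (consensus_distance, usage_rank) lexicographically:
#' "closest to consensus first, most commonly used among equals". The
#' result does not depend on hit order.
#'
#' @param hits hit table from [scan_pas_window()] (one transcript).
#' @param table PAS variant table.
#' @param transcript_id,gene_id,gene_class identifiers copied onto the
#'   call record.
#' @return one-row data.frame: `transcript_id`, `gene_id`, `gene_class`,
#'   `assigned_variant`, `n_distinct_variants`, `n_total_hits`,
#'   `excluded`, `reason`.
#' @export
assign_pas <- function(hits, table, transcript_id = NA_character_,
                       gene_id = NA_character_,
                       gene_class = NA_character_) {
  unknown <- setdiff(unique(hits$hexamer), table$hexamer)
  if (length(unknown)) {
    stop("hit hexamer(s) absent from the PAS table: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(hits) == 0L) {
    assigned <- "NONE"
  } else {
    idx <- match(hits$hexamer, table$hexamer)
    key <- order(table$consensus_distance[idx], table$usage_rank[idx])
    assigned <- hits$hexamer[key[1L]]
  }
  data.frame(
    transcript_id = transcript_id,
    gene_id = gene_id,
    gene_class = gene_class,
    assigned_variant = assigned,
    n_distinct_variants = length(unique(hits$hexamer)),
    n_total_hits = nrow(hits),
    excluded = FALSE,
    reason = "none",
    stringsAsFactors = FALSE
  )
}

#' Count distinct PAS hit positions in one transcript window
#'
#' Two or more hits at distinct start positions constitute a tandem
#' arrangement; overlapping hits at different starts count separately.
#'
#' @param hits hit table from [scan_pas_window()].
#' @return integer number of distinct hit start positions.
#' @export
count_tandem <- function(hits) {
  length(unique(hits$start))
}

#' Run the full PAS calling pipeline over a transcript table
#'
#' Filters the search set, scans each kept transcript's terminal window,
#' and assigns one variant per transcript. Excluded transcripts are
#' returned as calls flagged `excluded` with their reason.
#'
#' @inheritParams filter_search_set
#' @param table PAS variant table (default: packaged table).
#' @return call table: one row per input transcript, columns as in
#'   [assign_pas()] plus `n_tandem_positions`.
#' @export
call_pas <- function(records, table = pas_variant_table(), min_len = 200L,
                     window = 50L, downstream_windows = NULL) {
  flt <- filter_search_set(records, min_len = min_len, window = window,
                           downstream_windows = downstream_windows)
  kept <- flt$kept
  calls <- lapply(seq_len(nrow(kept)), function(i) {
    hits <- scan_pas_window(kept$sequence[i], table, window = window)
    call <- assign_pas(hits, table,
                       transcript_id = kept$transcript_id[i],
                       gene_id = kept$gene_id[i],
                       gene_class = kept$gene_class[i])
    call$n_tandem_positions <- count_tandem(hits)
    call
  })
  calls <- do.call(rbind, c(calls, list(NULL)))
  excluded <- flt$excluded
  if (nrow(excluded)) excluded$n_tandem_positions <- 0L
  if (is.null(calls)) calls <- cbind(empty_pas_calls(),
                                     n_tandem_positions = integer())
  out <- rbind(calls, excluded)
  rownames(out) <- NULL
  out
}
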