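# Downstream sequence element (DSE) matching.
#
# The DSE is the T/G-rich element downstream of the cleavage site. It is
# described by a sequence logo (per-position nucleotide frequencies); the
# matching rule is a hard frequency threshold, not a log-odds score: at
# each position every base seen at >= threshold of the time is allowed,
# and a window position matches when all pattern positions are satisfied.

#' Read a sequence logo (position frequency matrix)
#'
#' The file is a delimited matrix with header columns `A`, `C`, `G`, `T`;
#' one row per motif position, each row summing to 1 (tolerance 1e-6).
#' The packaged default `dse_logo_synthetic.tsv` is a synthetic T/G-rich
#' stand-in of length 8; supply the real logo for production use.
#'
#' @param path path to the logo file; `NULL` loads the packaged stand-in.
#' @return numeric matrix, rows = positions, columns A/C/G/T.
#' @export
read_sequence_logo <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dse_logo_synthetic.tsv",
                        package = "pasmap", mustWork = TRUE)
  }
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("A", "C", "G", "T") %in% names(tab))) {
    stop("sequence logo needs columns A, C, G, T")
  }
  logo <- as.matrix(tab[, c("A", "C", "G", "T")])
  validate_logo(logo)
  logo
}

validate_logo <- function(logo) {
  if (!is.matrix(logo) || ncol(logo) != 4L || nrow(logo) < 1L) {
    stop("logo must be a matrix with >= 1 row and columns A, C, G, T")
  }
  if (is.null(colnames(logo)) || !identical(colnames(logo), c("A", "C", "G", "T"))) {
    stop("logo columns must be named A, C, G, T in order")
  }
  if (any(logo < 0 | logo > 1)) stop("logo frequencies must lie in [0, 1]")
  sums <- rowSums(logo)
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop("logo row(s) not summing to 1: ", paste(which(off), collapse = ", "))
  }
  invisible(logo)
}

#' Build a DSE matching pattern from a logo at a frequency threshold
#'
#' Position `i` of the pattern allows exactly the bases whose logo
#' frequency at `i` is at least `threshold` ("found 10% or more of the
#' time" at the default). A position where no base reaches the threshold
#' is an error naming the position.
#'
#' @param logo frequency matrix from [read_sequence_logo()].
#' @param threshold frequency cutoff in (0, 1] (default 0.10).
#' @return object of class `dse_pattern`: list with `allowed` (list of
#'   character vectors per position), `length` and `threshold`.
#' @examples
#' logo <- matrix(c(0.05, 0.05, 0.30, 0.60), 1,
#'                dimnames = list(NULL, c("A", "C", "G", "T")))
#' build_dse_pattern(logo, 0.10)$allowed[[1]]  # "G" "T"
#' @export
build_dse_pattern <- function(logo, threshold = 0.10) {
  validate_logo(logo)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  allowed <- lapply(seq_len(nrow(logo)), function(i) {
    bases <- colnames(logo)[logo[i, ] >= threshold]
    if (length(bases) == 0L) {
      stop("no base reaches threshold ", threshold, " at logo position ", i)
    }
    bases
  })
  structure(list(allowed = allowed, length = nrow(logo),
                 threshold = threshold),
            class = "dse_pattern")
}

#' @export
print.dse_pattern <- function(x, ...) {
  classes <- vapply(x$allowed, function(b) {
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, "")
  cat("DSE pattern (threshold ", x$threshold, "): ",
      paste(classes, collapse = ""), "\n", sep = "")
  invisible(x)
}

# regex realization of the pattern: per-position character classes
dse_pattern_regex <- function(pattern) {
  stopifnot(inherits(pattern, "dse_pattern"))
  paste0(vapply(pattern$allowed, function(b) {
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan a downstream window for DSE pattern matches
#'
#' Reports every start position (overlaps allowed) where all pattern
#' positions are satisfied. Windows containing ambiguous bases are
#' rejected, mirroring the search-window ambiguity filter.
#'
#' @param window_seq downstream window sequence over {A,C,G,T}.
#' @param pattern `dse_pattern` from [build_dse_pattern()].
#' @param transcript_id optional id copied onto the hits.
#' @return data.frame with columns `transcript_id`, `start` (0-based
#'   offset within the window) and `match` (the matched substring).
#' @export
scan_dse <- function(window_seq, pattern, transcript_id = NA_character_) {
  stopifnot(is.character(window_seq), length(window_seq) == 1L,
            inherits(pattern, "dse_pattern"))
  if (grepl("[^ACGT]", window_seq)) {
    stop("ambiguous base in downstream window; window rejected")
  }
  if (pattern$length > nchar(window_seq)) {
    stop("pattern longer than the window")
  }
  rx <- dse_pattern_regex(pattern)
  m <- gregexpr(paste0("(?=", rx, ")"), window_seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  data.frame(transcript_id = transcript_id, start = start,
             match = substring(window_seq, start + 1L,
                               start + pattern$length),
             stringsAsFactors = FALSE)
}

#' Scan many downstream windows, tracking rejected ones
#'
#' @param windows named character vector of downstream windows
#'   (names = transcript ids).
#' @param pattern `dse_pattern`.
#' @return list with `hits` (row-bound [scan_dse()] results), `counts`
#'   (named integer vector of hit counts per scanned window) and
#'   `rejected` (ids of windows containing ambiguous bases).
#' @export
scan_dse_windows <- function(windows, pattern) {
  stopifnot(!is.null(names(windows)))
  ambiguous <- grepl("[^ACGT]", windows)
  ids <- names(windows)[!ambiguous]
  hits <- do.call(rbind, c(lapply(ids, function(id) {
    scan_dse(windows[[id]], pattern, transcript_id = id)
  }), list(NULL)))
  if (is.null(hits)) {
    hits <- data.frame(transcript_id = character(), start = integer(),
                       match = character(), stringsAsFactors = FALSE)
  }
  counts <- table(factor(hits$transcript_id, levels = ids))
  list(hits = hits,
       counts = stats::setNames(as.integer(counts), ids),
       rejected = names(windows)[ambiguous])
}

#' Cross-tabulate PAS assignment against DSE presence
#'
#' For each gene class, a 2x2 table of (PAS assigned vs NONE) x
#' (>= 1 DSE hit vs 0), with marginal and joint rates. Excluded
#' transcripts are dropped; the transcript universes of `calls` and
#' `dse_counts` must agree on the remaining ids.
#'
#' @param calls call table from [call_pas()].
#' @param dse_counts named integer vector: DSE hits per transcript.
#' @return data.frame, one row per gene class, columns `gene_class`,
#'   `n`, `pas_dse`, `pas_only`, `dse_only`, `neither`, `rate_pas`,
#'   `rate_dse`, `rate_joint` (rates as fractions; `NA` for empty
#'   classes).
#' @export
pas_dse_cooccurrence <- function(calls, dse_counts) {
  calls <- calls[!calls$excluded, , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(data.frame(gene_class = character(), n = integer(),
                      pas_dse = integer(), pas_only = integer(),
                      dse_only = integer(), neither = integer(),
                      rate_pas = numeric(), rate_dse = numeric(),
                      rate_joint = numeric(), stringsAsFactors = FALSE))
  }
  if (!all(calls$transcript_id %in% names(dse_counts))) {
    stop("dse_counts lacks transcript id(s): ",
         paste(utils::head(setdiff(calls$transcript_id, names(dse_counts)), 5),
               collapse = ", "))
  }
  pas <- calls$assigned_variant != "NONE"
  dse <- dse_counts[calls$transcript_id] >= 1L
  out <- lapply(split(seq_len(nrow(calls)), calls$gene_class), function(i) {
    n <- length(i)
    data.frame(
      gene_class = calls$gene_class[i[1]],
      n = n,
      pas_dse = sum(pas[i] & dse[i]),
      pas_only = sum(pas[i] & !dse[i]),
      dse_only = sum(!pas[i] & dse[i]),
      neither = sum(!pas[i] & !dse[i]),
      rate_pas = mean(pas[i]),
      rate_dse = mean(dse[i]),
      rate_joint = mean(pas[i] & dse[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
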