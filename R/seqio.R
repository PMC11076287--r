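# FASTA/BED input-output and strand-aware window extraction.
#
# Transcript sets are plain data.frames (one row per transcript) with
# columns: transcript_id, gene_id, gene_class, sequence, and optional
# genomic location columns chrom / start / end / strand (0-based,
# half-open, BED convention). FlyBase-style 1-based "loc=" header
# coordinates are converted on parse.

GENE_CLASSES <- c("mRNA", "lncRNA")

#' Read a transcript FASTA into a transcript table
#'
#' Each FASTA entry becomes one row; sequences are uppercased. With
#' `header_dialect = "flybase"` the FlyBase bulk-file header fields are
#' parsed: `parent=` supplies the gene id (first FBgn accession) and
#' `loc=chrom:start..end` (optionally wrapped in `complement(...)` and/or
#' `join(...)`) supplies the genomic location, converted from 1-based
#' inclusive to 0-based half-open. With `"plain"` the gene id equals the
#' transcript id and no location is recorded.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param gene_class `"mRNA"` or `"lncRNA"`; recorded on every row.
#' @param header_dialect `"plain"` or `"flybase"`.
#' @return a data.frame with columns `transcript_id`, `gene_id`,
#'   `gene_class`, `sequence`, `chrom`, `start`, `end`, `strand`
#'   (location columns `NA` when absent).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "acgtACGT", ">tx2", "TTTTAAAA"), fa)
#' read_transcript_fasta(fa, "lncRNA")
#' @export
read_transcript_fasta <- function(path,
                                  gene_class = c("mRNA", "lncRNA"),
                                  header_dialect = c("plain", "flybase")) {
  gene_class <- match.arg(gene_class)
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(seqs)
  transcript_id <- sub("\\s.*$", "", headers)
  if (anyDuplicated(transcript_id)) {
    stop("duplicate transcript_id in '", path, "': ",
         paste(unique(transcript_id[duplicated(transcript_id)]),
               collapse = ", "))
  }
  sequence <- toupper(as.character(seqs))
  if (any(nchar(sequence) == 0L)) {
    stop("empty sequence for: ",
         paste(transcript_id[nchar(sequence) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTUMRWSYKVHDBN]", sequence)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(transcript_id[bad], collapse = ", "))
  }
  sequence <- chartr("U", "T", sequence)

  out <- data.frame(
    transcript_id = unname(transcript_id),
    gene_id = unname(transcript_id),
    gene_class = gene_class,
    sequence = unname(sequence),
    chrom = NA_character_,
    start = NA_integer_,
    end = NA_integer_,
    strand = NA_character_,
    stringsAsFactors = FALSE
  )
  if (header_dialect == "flybase") {
    meta <- lapply(headers, parse_flybase_header)
    out$gene_id <- vapply(meta, `[[`, "", "gene_id")
    out$gene_id[is.na(out$gene_id)] <- out$transcript_id[is.na(out$gene_id)]
    out$chrom <- vapply(meta, `[[`, "", "chrom")
    out$start <- vapply(meta, `[[`, 0L, "start")
    out$end <- vapply(meta, `[[`, 0L, "end")
    out$strand <- vapply(meta, `[[`, "", "strand")
  }
  out
}

# FlyBase bulk-FASTA header: ">FBtr... type=mRNA; loc=2L:7529..9484; ...;
# parent=FBgn0031208,FBtr...; ...". loc may wrap the span in join(...) and/or
# complement(...); the min..max of all listed coordinates is the gene-span
# interval used for 3'-terminus windows.
parse_flybase_header <- function(header) {
  res <- list(gene_id = NA_character_, chrom = NA_character_,
              start = NA_integer_, end = NA_integer_,
              strand = NA_character_)
  parent <- regmatches(header, regexpr("parent=[^;]+", header))
  if (length(parent) == 1L) {
    ids <- strsplit(sub("^parent=", "", parent), ",")[[1]]
    fbgn <- grep("^FBgn", ids, value = TRUE)
    res$gene_id <- if (length(fbgn)) fbgn[[1]] else trimws(ids[[1]])
  }
  loc <- regmatches(header, regexpr("loc=[^;]+", header))
  if (length(loc) == 1L) {
    loc <- sub("^loc=", "", loc)
    res$chrom <- sub(":.*$", "", loc)
    rest <- sub("^[^:]+:", "", loc)
    res$strand <- if (grepl("complement", rest, fixed = TRUE)) "-" else "+"
    coords <- as.numeric(regmatches(rest, gregexpr("[0-9]+", rest))[[1]])
    if (length(coords) >= 2L) {
      res$start <- as.integer(min(coords) - 1)  # 1-based incl -> 0-based
      res$end <- as.integer(max(coords))
    }
  }
  res
}

#' Read a genome FASTA as a chromosome lookup
#'
#' @param path path to a genome FASTA file.
#' @return named character vector, one uppercase sequence per chromosome;
#'   names are the first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) stop("duplicate chromosome names in ", path)
  out
}

#' Reverse complement of a nucleotide string
#'
#' Standard IUPAC complement (N maps to N), then reversed. Length is
#' preserved; non-IUPAC characters are an error.
#'
#' @param seq nucleotide string over the IUPAC alphabet.
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    error = function(e) stop("invalid nucleotide string: ",
                             conditionMessage(e), call. = FALSE)
  )
}

#' Extract the window downstream of a transcript 3' terminus
#'
#' For a plus-strand transcript the `n` genome bases immediately after the
#' interval end; for a minus-strand transcript the reverse complement of
#' the `n` bases immediately before the interval start. Returned in the
#' transcript's reading orientation. Windows truncated by a chromosome
#' edge are returned shorter and flagged, not dropped.
#'
#' @param genome named character vector as from [read_genome_fasta()].
#' @param chrom,start,end,strand genomic interval of the transcript,
#'   0-based half-open, strand `"+"` or `"-"`.
#' @param n window length in nucleotides (default 50).
#' @return list with elements `sequence` (character) and `truncated`
#'   (logical).
#' @export
extract_downstream_window <- function(genome, chrom, start, end, strand,
                                      n = 50L) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (n < 1L) stop("window length n must be >= 1")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  L <- nchar(genome[[chrom]])
  if (start < 0L || end <= start || end > L) {
    stop("interval out of chromosome bounds: ", chrom, ":", start, "-", end)
  }
  if (strand == "+") {
    to <- min(end + n, L)
    win <- substr(genome[[chrom]], end + 1L, to)  # 0-based -> substr 1-based
    truncated <- to < end + n
  } else {
    from <- max(start - n, 0L)
    win <- reverse_complement(substr(genome[[chrom]], from + 1L, start))
    truncated <- from > start - n
  }
  list(sequence = win, truncated = truncated)
}

#' Write match hits or intervals as BED6
#'
#' Match-hit tables (columns `target_id`, `target_start`, `target_end`,
#' `strand`, plus `query_id`/`k`/`mismatches`) are serialized with the
#' target as the BED chrom, name `queryID|k|mm` and the mismatch count as
#' score. Generic interval tables use columns `chrom`, `start`, `end` and
#' optional `name`, `score`, `strand`. Lines are ordered by
#' (target, start, name); coordinates are 0-based half-open throughout.
#'
#' @param hits data.frame of hits or intervals (may have zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write BED file: ", path)
    return(invisible(path))
  }
  if (all(c("target_id", "target_start", "target_end") %in% names(hits))) {
    bed <- data.frame(
      chrom = hits$target_id,
      start = hits$target_start,
      end = hits$target_end,
      name = if (all(c("query_id", "k", "mismatches") %in% names(hits))) {
        paste(hits$query_id, hits$k, hits$mismatches, sep = "|")
      } else ".",
      score = if ("mismatches" %in% names(hits)) hits$mismatches else 0L,
      strand = hits$strand,
      stringsAsFactors = FALSE
    )
  } else if (all(c("chrom", "start", "end") %in% names(hits))) {
    bed <- data.frame(
      chrom = hits$chrom,
      start = hits$start,
      end = hits$end,
      name = if ("name" %in% names(hits)) hits$name else ".",
      score = if ("score" %in% names(hits)) hits$score else 0L,
      strand = if ("strand" %in% names(hits)) hits$strand else ".",
      stringsAsFactors = FALSE
    )
  } else {
    stop("hits must carry target_id/target_start/target_end ",
         "or chrom/start/end columns")
  }
  if (any(bed$end <= bed$start)) stop("BED intervals must satisfy start < end")
  bed <- bed[order(bed$chrom, bed$start, bed$name), , drop = FALSE]
  ok <- tryCatch({
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write BED file: ", path)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path path to a headerless BED file with up to 6 columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (zero rows for an empty file).
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  bed <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"),
                    stringsAsFactors = FALSE)
  names(bed) <- cols[seq_len(ncol(bed))]
  bed
}

# internal: validate a transcript table's required columns
check_transcripts <- function(records) {
  req <- c("transcript_id", "gene_id", "gene_class", "sequence")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("transcript table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$transcript_id)) stop("duplicate transcript_id")
  invisible(records)
}
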