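# Aggregation of per-transcript calls and per-pair regions into the
# summary tables of the analysis: per-class PAS percentages (exclusive
# categories summing to 100), tandem/DSE co-occurrence rates, and
# pairwise interactor tables.

#' Summarise PAS calls per gene class
#'
#' Transcript calls are first reduced to one call per gene: among a
#' gene's non-excluded transcripts the best call wins, using the same
#' lexicographic (consensus_distance, usage_rank) key as the assignment,
#' with `NONE` ranked last. The denominator is the number of genes that
#' survived the filters (genes whose transcripts were all excluded are
#' not counted). Per-variant percentages plus the no-PAS percentage sum
#' to 100 within rounding.
#'
#' @param calls call table from [call_pas()].
#' @param table PAS variant table (for the reduction key).
#' @param gene_reduction reduction rule; only `"best_transcript"` is
#'   implemented.
#' @param dse_counts optional named vector of DSE hit counts per
#'   transcript, used for the per-class percent-with-DSE column (a gene
#'   counts as DSE-positive when its best transcript has >= 1 hit).
#' @param digits decimal places for percentages (default 1).
#' @return list with `by_variant` (gene_class, variant incl. `NONE`,
#'   n_genes, percent) and `overview` (gene_class, n_genes_searched,
#'   percent_no_PAS, percent_tandem, percent_with_DSE).
#' @export
summarize_pas_by_class <- function(calls, table = pas_variant_table(),
                                   gene_reduction = "best_transcript",
                                   dse_counts = NULL, digits = 1L) {
  gene_reduction <- match.arg(gene_reduction, "best_transcript")
  if (nrow(calls) == 0L) stop("no calls to summarise")
  searched <- calls[!calls$excluded, , drop = FALSE]
  if (nrow(searched) == 0L) stop("all transcripts were excluded by the filters")

  idx <- match(searched$assigned_variant, table$hexamer)
  dist <- ifelse(is.na(idx), Inf, table$consensus_distance[idx])
  rank <- ifelse(is.na(idx), Inf, table$usage_rank[idx])
  best <- vapply(split(seq_len(nrow(searched)), searched$gene_id),
                 function(i) i[order(dist[i], rank[i])][1L], 0L)
  genes <- searched[best, , drop = FALSE]

  variants <- c(table$hexamer, "NONE")
  by_variant <- do.call(rbind, lapply(split(genes, genes$gene_class),
                                      function(g) {
    counts <- base::table(factor(g$assigned_variant, levels = variants))
    data.frame(gene_class = g$gene_class[1L], variant = variants,
               n_genes = as.integer(counts),
               percent = round(100 * as.integer(counts) / nrow(g), digits),
               stringsAsFactors = FALSE)
  }))
  rownames(by_variant) <- NULL

  overview <- do.call(rbind, lapply(split(genes, genes$gene_class),
                                    function(g) {
    dse <- if (is.null(dse_counts)) NA_real_ else {
      round(100 * mean(dse_counts[g$transcript_id] >= 1L, na.rm = TRUE),
            digits)
    }
    tandem <- if ("n_tandem_positions" %in% names(g)) {
      round(100 * mean(g$n_tandem_positions >= 2L), digits)
    } else NA_real_
    data.frame(gene_class = g$gene_class[1L],
               n_genes_searched = nrow(g),
               percent_no_PAS = round(100 * mean(g$assigned_variant == "NONE"),
                                      digits),
               percent_tandem = tandem,
               percent_with_DSE = dse,
               stringsAsFactors = FALSE)
  }))
  rownames(overview) <- NULL
  list(by_variant = by_variant, overview = overview)
}

#' Aggregate complementary regions into a pairwise interactor table
#'
#' One row per ordered (query, target) pair having at least one merged
#' region, with the region count, summed region length and the minimum
#' mismatch count, sorted by region count (descending).
#'
#' @param regions region table from [merge_regions()].
#' @return data.frame with columns `query_id`, `target_id`, `n_regions`,
#'   `total_bp`, `min_mismatches`.
#' @export
summarize_interactors <- function(regions) {
  if (nrow(regions) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      n_regions = integer(), total_bp = integer(),
                      min_mismatches = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(regions$query_id, regions$target_id, sep = "\r")
  out <- do.call(rbind, lapply(split(regions, key), function(r) {
    data.frame(query_id = r$query_id[1L], target_id = r$target_id[1L],
               n_regions = nrow(r),
               total_bp = sum(r$end - r$start),
               min_mismatches = min(r$min_mismatches),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_regions, out$query_id, out$target_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write summary tables and a deterministic run log
#'
#' Each table in `tables` is written as `<name>.tsv`; the log records
#' the parameter set, seed and package version. Given identical inputs
#' the outputs are byte-identical (no timestamps).
#'
#' @param tables named list of data.frames.
#' @param params named list of run parameters (seed included when
#'   randomness was involved).
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(tables, params, dir) {
  stopifnot(is.list(tables), is.list(params))
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  written <- character()
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, path)
  }
  log_path <- file.path(dir, "run_log.txt")
  n_records <- vapply(tables, nrow, 0L)
  lines <- c(
    paste0("pasmap version: ", as.character(packageVersion("pasmap"))),
    "parameters:",
    paste0("  ", names(params), " = ",
           vapply(params, function(p) paste(format(p), collapse = ","), "")),
    "tables:",
    paste0("  ", names(tables), ": ", n_records, " record(s)")
  )
  if (all(n_records == 0L)) lines <- c(lines, "note: zero records in all tables")
  writeLines(lines, log_path)
  invisible(c(written, log_path))
}
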