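# shared fixture builders: everything is generated in code at test time

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

rand_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# a minimal transcript table row
tx_record <- function(id, seq, class = "lncRNA", gene = id) {
  data.frame(transcript_id = id, gene_id = gene, gene_class = class,
             sequence = seq, chrom = NA_character_, start = NA_integer_,
             end = NA_integer_, strand = NA_character_,
             stringsAsFactors = FALSE)
}

tx_table <- function(seqs, class = "lncRNA",
                     genes = names(seqs)) {
  do.call(rbind, Map(tx_record, names(seqs), unname(seqs), class, genes))
}

# canonical form for comparing hit tables irrespective of row order
hit_key <- function(h) {
  sort(paste(h$query_id, h$query_offset, h$target_id, h$target_start,
             h$target_end, h$strand, h$mismatches, h$k, sep = "|"))
}

# uniform logo of a given length (every base allowed at threshold 0.25)
uniform_logo <- function(m) {
  matrix(0.25, nrow = m, ncol = 4,
         dimnames = list(NULL, c("A", "C", "G", "T")))
}
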