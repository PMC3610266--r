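# Small in-code fixtures shared across test files.

make_counts <- function(m, timepoints, kind = "long", depth = NULL) {
  libs <- data.frame(library_id = paste0(kind, "_", timepoints, "h"),
                     timepoint = timepoints, kind = kind,
                     stringsAsFactors = FALSE)
  if (!is.null(depth)) libs$depth <- depth
  count_table(m, libs)
}

long_counts <- function(m, timepoints, depth = NULL) {
  make_counts(m, timepoints, kind = "long", depth = depth)
}

frag_counts <- function(m, timepoints, depth = NULL) {
  make_counts(m, timepoints, kind = "fragment", depth = depth)
}

# matched one-timepoint full/fragment tables for DI closed forms
two_gene_tables <- function(f, s, depth_f = 1000, depth_s = 1000) {
  ids <- paste0("g", seq_along(f))
  list(full = long_counts(matrix(f, ncol = 1, dimnames = list(ids, NULL)),
                          40, depth = depth_f),
       frag = frag_counts(matrix(s, ncol = 1, dimnames = list(ids, NULL)),
                          40, depth = depth_s))
}

toy_genes <- function(ids, lengths, rRNA = FALSE) {
  n <- length(ids)
  starts <- cumsum(c(0, lengths[-n] + 10))
  g <- data.frame(gene_id = ids, start = starts, end = starts + lengths,
                  strand = "+")
  g <- switchtome:::complete_gene_columns(g)
  g$rRNA <- rRNA
  validate_genes(g, chromosome_model("chr", sum(lengths) + 10 * n + 100))
}
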