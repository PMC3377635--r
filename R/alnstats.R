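# Alignment information content: de-gapped lengths, variable sites,
# parsimony-informative sites, and the one-row summary used to build
# marker-comparison tables.

# Per-column state sets. Under the default policy a column's states are the
# distinct symbols among {A,C,G,T} only: gaps and IUPAC ambiguity codes
# contribute no state. With gaps_as_state = TRUE the gap is a fifth state.
column_states <- function(col, gaps_as_state = FALSE) {
  allowed <- c("A", "C", "G", "T", if (gaps_as_state) "-")
  unique(col[col %in% allowed])
}

#' De-gapped sequence length range
#'
#' Number of non-gap symbols in each row; the minimum and maximum over rows
#' give the shortest and longest de-gapped sequences in the alignment.
#'
#' @param aln A [coral_alignment()].
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @examples
#' aln <- coral_alignment(c(a = "AC-T", b = "ACGT"))
#' degapped_length_range(aln)  # 3 4
#' @export
degapped_length_range <- function(aln) {
  n <- rowSums(aln$seqs != "-")
  c(min = min(n), max = max(n))
}

#' Count variable sites
#'
#' A site (column) is variable when its state set has at least two elements.
#' Under the default policy only A, C, G and T contribute states, so a column
#' with symbols \{A, A, R\} is not variable while \{A, A, G\} is.
#'
#' @param aln A [coral_alignment()].
#' @param gaps_as_state Treat the gap as a fifth state (default `FALSE`).
#' @return Integer count.
#' @export
count_variable_sites <- function(aln, gaps_as_state = FALSE) {
  sum(vapply(seq_len(ncol(aln$seqs)), function(j) {
    length(column_states(aln$seqs[, j], gaps_as_state)) >= 2L
  }, logical(1)))
}

#' Count parsimony-informative sites
#'
#' A site is parsimony-informative when at least two of its states are each
#' carried by at least two rows. States follow the same policy as
#' [count_variable_sites()]; informative sites are always a subset of
#' variable sites.
#'
#' @inheritParams count_variable_sites
#' @return Integer count.
#' @export
count_parsimony_informative_sites <- function(aln, gaps_as_state = FALSE) {
  allowed <- c("A", "C", "G", "T", if (gaps_as_state) "-")
  sum(vapply(seq_len(ncol(aln$seqs)), function(j) {
    col <- aln$seqs[, j]
    tab <- table(col[col %in% allowed])
    sum(tab >= 2L) >= 2L
  }, logical(1)))
}

#' Summarize the information content of an alignment
#'
#' One row per alignment with taxon count, length, de-gapped length range,
#' variable and parsimony-informative site counts and their percentages of
#' total alignment length (rounded to the nearest integer).
#'
#' @inheritParams count_variable_sites
#' @return One-row data.frame with columns `marker`, `n_taxa`, `n_columns`,
#'   `degapped_min`, `degapped_max`, `n_variable`, `pct_variable`,
#'   `n_parsinf`, `pct_parsinf`.
#' @examples
#' aln <- coral_alignment(c(a = "AAT", b = "AAT", c = "AAG", d = "AAG"))
#' summarize_alignment(aln)
#' @export
summarize_alignment <- function(aln, gaps_as_state = FALSE) {
  rng <- degapped_length_range(aln)
  nv <- count_variable_sites(aln, gaps_as_state)
  np <- count_parsimony_informative_sites(aln, gaps_as_state)
  L <- n_sites(aln)
  data.frame(
    marker = aln$marker,
    n_taxa = n_sequences(aln),
    n_columns = L,
    degapped_min = unname(rng["min"]),
    degapped_max = unname(rng["max"]),
    n_variable = nv,
    pct_variable = as.integer(round(100 * nv / L)),
    n_parsinf = np,
    pct_parsinf = as.integer(round(100 * np / L)),
    stringsAsFactors = FALSE
  )
}
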