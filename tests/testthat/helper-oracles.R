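# Independent brute-force oracles and small fixture generators. These stay
# deliberately naive (per-column loops, all-pairs comparison, textbook
# median-of-halves hinges) so they share no code path with the package.

oracle_variable_sites <- function(m, gaps_as_state = FALSE) {
  allowed <- c("A", "C", "G", "T", if (gaps_as_state) "-")
  n <- 0L
  for (j in seq_len(ncol(m))) {
    states <- character(0)
    for (i in seq_len(nrow(m)))
      if (m[i, j] %in% allowed) states <- union(states, m[i, j])
    if (length(states) >= 2) n <- n + 1L
  }
  n
}

oracle_parsinf_sites <- function(m, gaps_as_state = FALSE) {
  allowed <- c("A", "C", "G", "T", if (gaps_as_state) "-")
  n <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% allowed]
    counts <- table(col)
    if (sum(counts >= 2) >= 2) n <- n + 1L
  }
  n
}

# all-pairs equality partition (exact string identity, transitively closed)
oracle_collapse_strict <- function(strings) {
  n <- length(strings)
  cls <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (strings[i] == strings[j]) {
      joint <- min(cls[i], cls[j])
      cls[cls %in% c(cls[i], cls[j])] <- joint
    }
  }
  match(cls, unique(cls))
}

# textbook Tukey hinges: split sorted data at the median, include the median
# in both halves when n is odd, hinge = median of each half
oracle_hinges <- function(x) {
  x <- sort(x)
  n <- length(x)
  med <- if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  lower <- if (n %% 2 == 1) x[1:((n + 1) / 2)] else x[1:(n / 2)]
  upper <- if (n %% 2 == 1) x[((n + 1) / 2):n] else x[(n / 2 + 1):n]
  mid <- function(v) {
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  c(min = x[1], lower = mid(lower), median = med, upper = mid(upper), max = x[n])
}

random_alignment <- function(n, L, symbols = c("A", "C", "G", "T"),
                             seed = 1, meta = NULL, marker = "test") {
  set.seed(seed)
  m <- matrix(sample(symbols, n * L, replace = TRUE), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  coral_alignment(m, meta, marker = marker)
}

# Printed marker-information table used as input data: per marker/subset,
# taxon count, alignment length, variable and parsimony-informative site
# counts, and the percentages printed alongside them.
marker_info_table <- function() {
  read.csv(text = "label,n_taxa,n_columns,n_var,pct_var,n_pars,pct_pars
mtMutS_5prime,105,829,384,46,259,31
mtMutS_5prime_gblocks,105,688,316,46,227,33
mtMutS_full,46,3150,896,28,594,19
mtMutS_full_gblocks,46,2871,837,29,571,20
cox1,64,786,133,17,92,12
r18S,64,1315,215,16,181,14
concat_5prime,64,2924,645,22,478,16
concat_full,42,5236,1192,23,819,16
mtMutS_5prime_42,42,781,245,31,168,22
r18S_42,42,1300,189,15,160,12
cox1_42,42,786,108,14,72,9
mtMutS_full_42,42,3150,895,28,587,19
", stringsAsFactors = FALSE)
}
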