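# Uncorrected p-distances with pairwise deletion, transition/transversion
# tallies, within/between group distance extrema, and the distance-threshold
# family-delimitation rule.

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of differing sites among compared sites, with no
#' substitution-model correction. Comparison is restricted to columns where
#' both symbols are unambiguous bases (pairwise deletion of gaps and
#' ambiguity codes).
#'
#' @param row_a,row_b Equal-length character vectors of symbols, or single
#'   sequence strings.
#' @return List with `p` (proportion in \[0, 1\]) and `n_compared` (number of
#'   columns compared).
#' @examples
#' p_distance("AC-TACGT", "ACGTACCT")  # 1 mismatch over 7 compared sites
#' @export
p_distance <- function(row_a, row_b) {
  a <- as_symbols(row_a); b <- as_symbols(row_b)
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  list(p = sum(a[ok] != b[ok]) / n, n_compared = n)
}

as_symbols <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
}

#' Pairwise uncorrected p-distance matrix
#'
#' All pairs via [p_distance()]. A pair with no comparable sites does not
#' abort the matrix: its distance is `NA`, its compared count 0, and the pair
#' is reported in a warning.
#'
#' @param aln A [coral_alignment()].
#' @return Object of class `p_distance_matrix`: list with `ids`, `p`
#'   (symmetric proportion matrix, zero diagonal) and `compared` (symmetric
#'   matrix of compared-site counts).
#' @export
distance_matrix <- function(aln) {
  m <- aln$seqs
  ids <- rownames(m)
  n <- nrow(m)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  cmp <- matrix(0L, n, n, dimnames = list(ids, ids))
  plain <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  diag(cmp) <- as.integer(rowSums(plain))
  failed <- character(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ok <- plain[i, ] & plain[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        p[i, j] <- p[j, i] <- NA_real_
        failed <- c(failed, paste(ids[i], ids[j], sep = " ~ "))
      } else {
        p[i, j] <- p[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
        cmp[i, j] <- cmp[j, i] <- nc
      }
    }
  }
  if (length(failed))
    warning("pairs with no comparable sites (distance set to NA): ",
            paste(failed, collapse = "; "))
  structure(list(ids = ids, p = p, compared = cmp),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat(sprintf("<p_distance_matrix> %d sequences; p range %.4f-%.4f\n",
              length(x$ids), min(x$p, na.rm = TRUE), max(x$p, na.rm = TRUE)))
  invisible(x)
}

#' Pooled transition/transversion tally
#'
#' Counts transitions (A<->G, C<->T) and transversions over all sequence
#' pairs, comparing each pair under pairwise deletion as in [p_distance()].
#' The ratio is undefined (NA, with `ratio_defined = FALSE`) when no
#' transversions are observed.
#'
#' @param aln A [coral_alignment()].
#' @return List with `transitions`, `transversions`, `ratio`,
#'   `ratio_defined`.
#' @export
titv_tally <- function(aln) {
  m <- aln$seqs
  n <- nrow(m)
  plain <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  ti <- 0L; tv <- 0L
  if (n > 1L) {
    purine <- matrix(m %in% c("A", "G"), nrow = n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ok <- plain[i, ] & plain[j, ]
      diff <- ok & (m[i, ] != m[j, ])
      same_class <- purine[i, ] == purine[j, ]
      ti <- ti + sum(diff & same_class)
      tv <- tv + sum(diff & !same_class)
    }
  }
  list(transitions = ti, transversions = tv,
       ratio = if (tv > 0L) ti / tv else NA_real_,
       ratio_defined = tv > 0L)
}

#' Within- and between-group distance extrema
#'
#' For each group with at least two members, the maximum intra-group
#' p-distance; for each pair of groups, the minimum inter-group p-distance.
#' Every reported extremum names the pair of sequences attaining it.
#'
#' @param dm A [distance_matrix()] result.
#' @param group_labels Named character vector mapping every sequence id in
#'   `dm` to a group label (e.g. family).
#' @return List of class `group_distance_summary` with data.frames `intra`
#'   (`group`, `max_p`, `id_a`, `id_b`) and `inter`
#'   (`group_a`, `group_b`, `min_p`, `id_a`, `id_b`).
#' @export
group_distance_summary <- function(dm, group_labels) {
  ids <- dm$ids
  miss <- setdiff(ids, names(group_labels))
  if (length(miss)) stop("unlabeled ids: ", paste(miss, collapse = ", "))
  g <- group_labels[ids]
  if (anyNA(g)) stop("unlabeled ids: ", paste(ids[is.na(g)], collapse = ", "))
  groups <- unique(unname(g))

  pick_extremum <- function(rows, cols, fun) {
    sub <- dm$p[rows, cols, drop = FALSE]
    if (all(is.na(sub))) return(NULL)
    k <- which(sub == fun(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    list(value = fun(sub, na.rm = TRUE),
         id_a = rows[k[1L]], id_b = cols[k[2L]])
  }

  intra <- list()
  for (gr in groups) {
    mem <- ids[g == gr]
    if (length(mem) < 2L) next
    pr <- t(combn(mem, 2L))
    vals <- dm$p[cbind(pr[, 1L], pr[, 2L])]
    if (all(is.na(vals))) next
    k <- which.max(vals)
    intra[[length(intra) + 1L]] <- data.frame(
      group = gr, max_p = vals[k], id_a = pr[k, 1L], id_b = pr[k, 2L],
      stringsAsFactors = FALSE)
  }
  inter <- list()
  if (length(groups) > 1L) {
    gp <- t(combn(groups, 2L))
    for (r in seq_len(nrow(gp))) {
      ex <- pick_extremum(ids[g == gp[r, 1L]], ids[g == gp[r, 2L]], min)
      if (is.null(ex)) next
      inter[[length(inter) + 1L]] <- data.frame(
        group_a = gp[r, 1L], group_b = gp[r, 2L], min_p = ex$value,
        id_a = ex$id_a, id_b = ex$id_b, stringsAsFactors = FALSE)
    }
  }
  empty_intra <- data.frame(group = character(), max_p = numeric(),
                            id_a = character(), id_b = character(),
                            stringsAsFactors = FALSE)
  empty_inter <- data.frame(group_a = character(), group_b = character(),
                            min_p = numeric(), id_a = character(),
                            id_b = character(), stringsAsFactors = FALSE)
  structure(list(
    intra = if (length(intra)) do.call(rbind, intra) else empty_intra,
    inter = if (length(inter)) do.call(rbind, inter) else empty_inter),
    class = "group_distance_summary")
}

#' Family-delimitation distance thresholds
#'
#' Data-derived constants from a calcaxonian reference dataset: the maximum
#' uncorrected p-distance observed within a family (4.9%) and the minimum
#' observed between families (3.8%). Because the two thresholds overlap, a
#' candidate whose distances fall between them is deliberately left
#' ambiguous by [assess_rank_delimitation()].
#'
#' @param intra_max Maximum within-family distance (proportion).
#' @param inter_min Minimum between-family distance (proportion).
#' @return List of class `delimitation_thresholds`.
#' @export
delimitation_thresholds <- function(intra_max = 0.049, inter_min = 0.038) {
  stopifnot(inter_min > 0, intra_max > 0)
  structure(list(intra_max = intra_max, inter_min = inter_min),
            class = "delimitation_thresholds")
}

#' Assess family membership of a candidate taxon by genetic distance
#'
#' Given the uncorrected p-distances from a candidate taxon to the members
#' of a family, returns `"within_family"` when every distance is at or below
#' the minimum inter-family threshold, `"distinct_family"` when every
#' distance is at or above the maximum intra-family threshold, and
#' `"ambiguous"` otherwise (the thresholds overlap, so an ambiguous zone
#' exists by construction).
#'
#' @param candidate_to_group_distances Nonempty numeric vector of
#'   proportions.
#' @param thresholds A [delimitation_thresholds()].
#' @return One of `"within_family"`, `"distinct_family"`, `"ambiguous"`.
#' @examples
#' assess_rank_delimitation(c(0.031, 0.034))  # within_family
#' assess_rank_delimitation(c(0.067, 0.080))  # distinct_family
#' @export
assess_rank_delimitation <- function(candidate_to_group_distances,
                                     thresholds = delimitation_thresholds()) {
  d <- candidate_to_group_distances
  if (length(d) == 0L || anyNA(d)) stop("need a nonempty vector of distances")
  stopifnot(inherits(thresholds, "delimitation_thresholds"))
  if (all(d <= thresholds$inter_min)) "within_family"
  else if (all(d >= thresholds$intra_max)) "distinct_family"
  else "ambiguous"
}
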