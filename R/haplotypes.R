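# Haplotype collapsing and richness tabulation. A haplotype is an identity
# class of aligned sequences under a stated comparison policy; richness is
# tabulated per taxonomic group and per ocean basin.

#' Collapse aligned sequences into haplotypes
#'
#' Two policies are provided. `strict` compares full symbol strings
#' literally, so an ambiguity code (or gap) differing between two otherwise
#' identical sequences separates them — this is the behaviour that inflates
#' richness at markers with many ambiguous base calls. `mask_ambiguity`
#' compares two sequences only on columns where both carry an unambiguous
#' symbol (A, C, G, T or the gap); because that relation is not transitive,
#' sequences are assigned greedily to the first existing class whose
#' representative they match, in input order, which keeps the partition
#' deterministic.
#'
#' Haplotype indices are assigned in order of first appearance and the
#' representative of a class is its first member in input order.
#'
#' @param aln A [coral_alignment()].
#' @param policy `"strict"` (default) or `"mask_ambiguity"`.
#' @return Object of class `haplotype_assignment`: list with `members`
#'   (named integer vector seq_id -> haplotype index), `representatives`
#'   (character vector indexed by haplotype), `policy`.
#' @examples
#' aln <- coral_alignment(c(a = "ACGT", b = "ACGT", c = "ACGR"))
#' collapse_haplotypes(aln, "strict")$members          # a=1 b=1 c=2
#' collapse_haplotypes(aln, "mask_ambiguity")$members  # a=1 b=1 c=1
#' @export
collapse_haplotypes <- function(aln, policy = c("strict", "mask_ambiguity")) {
  policy <- match.arg(policy)
  m <- aln$seqs
  ids <- rownames(m)
  if (policy == "strict") {
    key <- apply(m, 1L, paste, collapse = "")
    idx <- match(key, unique(key))
  } else {
    plain <- matrix(m %in% c("A", "C", "G", "T", "-"), nrow = nrow(m))
    idx <- integer(nrow(m))
    reps <- integer(0)        # row numbers of representatives
    for (i in seq_len(nrow(m))) {
      hit <- 0L
      for (k in seq_along(reps)) {
        r <- reps[k]
        shared <- plain[i, ] & plain[r, ]
        if (all(m[i, shared] == m[r, shared])) { hit <- k; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
      idx[i] <- hit
    }
  }
  members <- setNames(idx, ids)
  representatives <- ids[!duplicated(idx)]
  structure(list(members = members, representatives = representatives,
                 policy = policy),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("<haplotype_assignment> %d sequences in %d haplotypes (policy: %s)\n",
              length(x$members), length(x$representatives), x$policy))
  invisible(x)
}

#' Number of haplotypes in an assignment
#' @param assignment A [collapse_haplotypes()] result.
#' @return Integer count of identity classes.
#' @export
n_haplotypes <- function(assignment) length(assignment$representatives)

#' Specimen counts per haplotype
#'
#' @param assignment A [collapse_haplotypes()] result.
#' @return Integer vector indexed by haplotype; sums to the number of input
#'   sequences.
#' @export
haplotype_frequencies <- function(assignment) {
  tabulate(assignment$members, nbins = n_haplotypes(assignment))
}

#' Haplotype richness by taxonomic group and ocean basin
#'
#' One row per group with the total number of haplotypes sampled in the
#' group, the number of haplotypes with at least one member in each basin,
#' the number of genotyped specimens, and the depth span of those specimens.
#' Specimens lacking a basin label contribute to the total but to no basin
#' column.
#'
#' @param assignment A [collapse_haplotypes()] result for `aln`.
#' @param aln The [coral_alignment()] the assignment was computed from.
#' @param group_field Metadata column to group by: `"genus"` (default),
#'   `"family"` or `"species"`.
#' @return data.frame with columns `group`, `n_haplotypes`, one count per
#'   basin in [OCEAN_BASINS], `n_specimens`, `depth_min_m`, `depth_max_m`.
#' @export
richness_by_group <- function(assignment, aln,
                              group_field = c("genus", "family", "species")) {
  group_field <- match.arg(group_field)
  meta <- aln$meta
  stopifnot(identical(names(assignment$members), meta$seq_id))
  grp <- meta[[group_field]]
  if (anyNA(grp)) stop("sequences without a '", group_field, "' label: ",
                       paste(meta$seq_id[is.na(grp)], collapse = ", "))
  bad <- setdiff(unique(meta$basin[!is.na(meta$basin)]), OCEAN_BASINS)
  if (length(bad)) stop("unknown basin label(s): ", paste(bad, collapse = ", "))

  out <- lapply(unique(grp), function(g) {
    sel <- grp == g
    hap <- assignment$members[sel]
    row <- data.frame(group = g, n_haplotypes = length(unique(hap)),
                      stringsAsFactors = FALSE)
    for (b in OCEAN_BASINS) {
      inb <- sel & !is.na(meta$basin) & meta$basin == b
      row[[b]] <- length(unique(assignment$members[inb]))
    }
    d <- meta$depth_m[sel]
    row$n_specimens <- sum(sel)
    row$depth_min_m <- if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
    row$depth_max_m <- if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
    row
  })
  do.call(rbind, out)
}

#' Haplotypes shared between two ocean basins
#'
#' @param assignment A [collapse_haplotypes()] result for `aln`.
#' @param aln The source [coral_alignment()].
#' @param basin_a,basin_b Basin labels from [OCEAN_BASINS].
#' @return Integer vector of haplotype indices with at least one member
#'   sampled in each of the two basins; symmetric in its basin arguments.
#' @export
shared_haplotypes <- function(assignment, aln, basin_a, basin_b) {
  for (b in c(basin_a, basin_b))
    if (!b %in% OCEAN_BASINS) stop("unknown basin label: ", b)
  meta <- aln$meta
  stopifnot(identical(names(assignment$members), meta$seq_id))
  in_a <- !is.na(meta$basin) & meta$basin == basin_a
  in_b <- !is.na(meta$basin) & meta$basin == basin_b
  sort(intersect(unique(assignment$members[in_a]),
                 unique(assignment$members[in_b])))
}
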