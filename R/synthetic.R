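# Seeded generators: birth trees, alignments evolving under a two-parameter
# (transition/transversion-biased) substitution process with post-hoc
# ambiguity and gap injection, fixed-count alignment fixtures, and occurrence
# records with known curation flags. Every generator is fully deterministic
# under its seed.

TI_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
# ambiguity codes compatible with each base
AMBIG_FOR_BASE <- list(
  A = c("R", "W", "M", "D", "H", "V", "N"),
  C = c("Y", "S", "M", "B", "H", "V", "N"),
  G = c("R", "S", "K", "B", "D", "V", "N"),
  T = c("Y", "W", "K", "B", "D", "H", "N"))

#' Simulate a birth tree
#'
#' Pure-birth (Yule) tree with `n_taxa` leaves via [ape::rphylo()];
#' deterministic under `seed`.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed.
#' @return An [ape::rphylo()] `phylo` object (binary, rooted, positive
#'   branch lengths).
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  set.seed(seed)
  ape::rphylo(n_taxa, birth = birth_rate, death = 0)
}

#' Configuration for sequence simulation
#'
#' @param n_taxa Number of sequences (leaves).
#' @param n_columns Alignment length in nucleotides.
#' @param rate Expected substitutions per site per unit branch length.
#' @param kappa Transition/transversion bias of the substitution process: a
#'   substitution event is a transition with probability
#'   `kappa / (kappa + 2)`, so the expected realized transition:transversion
#'   event ratio is `kappa / 2`.
#' @param ambiguity_rate Per-symbol probability that a leaf base is replaced
#'   by a compatible IUPAC ambiguity code (mimics ambiguous base calls).
#' @param gap_rate Per-symbol probability of replacement by a gap.
#' @param seed Integer seed fixing the full output.
#' @param tree Optional `phylo` or newick string; simulated if `NULL`.
#' @param birth_rate Birth rate used when simulating the tree.
#' @param basins Basin labels sampled uniformly for leaf metadata.
#' @return List of class `seqsim_config`.
#' @export
seqsim_config <- function(n_taxa = 20, n_columns = 800, rate = 0.05,
                          kappa = 4, ambiguity_rate = 0, gap_rate = 0,
                          seed = 1, tree = NULL, birth_rate = 1,
                          basins = c("Atlantic", "Pacific")) {
  stopifnot(n_taxa >= 2, n_columns >= 1, rate >= 0, kappa > 0,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            gap_rate >= 0, gap_rate <= 1,
            all(basins %in% OCEAN_BASINS))
  structure(list(n_taxa = n_taxa, n_columns = n_columns, rate = rate,
                 kappa = kappa, ambiguity_rate = ambiguity_rate,
                 gap_rate = gap_rate, seed = seed, tree = tree,
                 birth_rate = birth_rate, basins = basins),
            class = "seqsim_config")
}

mutate_along_branch <- function(seq, expected_subs, kappa) {
  L <- length(seq)
  n_events <- rpois(L, expected_subs)
  ti <- 0L; tv <- 0L
  for (site in which(n_events > 0L)) {
    base <- seq[site]
    for (k in seq_len(n_events[site])) {
      if (runif(1) < kappa / (kappa + 2)) {
        base <- TI_PARTNER[[base]]
        ti <- ti + 1L
      } else {
        base <- sample(TV_PARTNERS[[base]], 1L)
        tv <- tv + 1L
      }
    }
    seq[site] <- base
  }
  list(seq = seq, ti = ti, tv = tv)
}

#' Simulate an alignment on a tree with known ground truth
#'
#' A root sequence is drawn uniformly over A/C/G/T and evolved along each
#' branch under a symmetric two-parameter process: per site, the number of
#' substitution events on a branch is Poisson with mean `rate` times branch
#' length, and each event is a transition with probability
#' `kappa / (kappa + 2)`. Ambiguity codes and gaps are injected post hoc at
#' the configured per-symbol rates; the returned truth records the
#' pre-injection sequences, their haplotype partition, and the realized
#' transition/transversion event tallies.
#'
#' @param config A [seqsim_config()].
#' @return List with `alignment` (a [coral_alignment()]) and `truth`: list
#'   with `tree`, `true_seqs` (named character vector of strings),
#'   `partition` (named haplotype indices of the pre-injection sequences),
#'   `n_haplotypes`, `transitions`, `transversions`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "seqsim_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = config$birth_rate, death = 0)
  } else if (is.character(tree)) {
    tree <- ape::read.tree(text = tree)
  }
  n_tip <- length(tree$tip.label)
  L <- config$n_columns
  tree <- stats::reorder(tree, "cladewise")  # parents precede children

  node_seq <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  node_seq[[root]] <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ti_total <- 0L; tv_total <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    res <- mutate_along_branch(node_seq[[parent]],
                               config$rate * tree$edge.length[e],
                               config$kappa)
    node_seq[[child]] <- res$seq
    ti_total <- ti_total + res$ti
    tv_total <- tv_total + res$tv
  }

  tips <- do.call(rbind, node_seq[seq_len(n_tip)])
  rownames(tips) <- tree$tip.label
  true_strings <- setNames(apply(tips, 1L, paste, collapse = ""),
                           tree$tip.label)
  partition <- setNames(match(true_strings, unique(true_strings)),
                        tree$tip.label)

  obs <- tips
  if (config$ambiguity_rate > 0) {
    mask <- matrix(runif(length(obs)) < config$ambiguity_rate, nrow = nrow(obs))
    for (k in which(mask)) {
      obs[k] <- sample(AMBIG_FOR_BASE[[obs[k]]], 1L)
    }
  }
  if (config$gap_rate > 0) {
    gmask <- matrix(runif(length(obs)) < config$gap_rate, nrow = nrow(obs))
    obs[gmask] <- "-"
  }

  meta <- data.frame(
    seq_id = tree$tip.label,
    genus = "Simugorgia",
    species = NA_character_, family = "Simulatidae",
    basin = sample(config$basins, n_tip, replace = TRUE),
    depth_m = round(qlnorm(runif(n_tip), meanlog = log(800), sdlog = 0.5)),
    stringsAsFactors = FALSE)

  aln <- coral_alignment(obs, meta, marker = "simulated")
  truth <- list(tree = tree, true_seqs = true_strings, partition = partition,
                n_haplotypes = max(partition),
                transitions = ti_total, transversions = tv_total)
  list(alignment = aln, truth = truth)
}

#' Construct an alignment with exact site-count summary
#'
#' Builds a fixture alignment whose [summarize_alignment()] returns exactly
#' the requested number of columns, variable sites and parsimony-informative
#' sites: informative columns carry two states on two rows each, variable
#' non-informative columns a singleton state, and all remaining columns are
#' constant.
#'
#' @param n_taxa Number of rows (>= 2; >= 4 when `n_parsinf > 0`).
#' @param n_columns Alignment length.
#' @param n_variable Requested variable-site count.
#' @param n_parsinf Requested parsimony-informative count
#'   (`n_parsinf <= n_variable <= n_columns`).
#' @param marker Marker name recorded on the alignment.
#' @return A [coral_alignment()].
#' @examples
#' a <- construct_alignment_with_counts(105, 829, 384, 259)
#' summarize_alignment(a)[, c("pct_variable", "pct_parsinf")]  # 46, 31
#' @export
construct_alignment_with_counts <- function(n_taxa, n_columns, n_variable,
                                            n_parsinf, marker = "synthetic") {
  if (!(n_parsinf <= n_variable && n_variable <= n_columns))
    stop("need n_parsinf <= n_variable <= n_columns")
  if (n_taxa < 2L) stop("need at least 2 taxa")
  if (n_parsinf > 0L && n_taxa < 4L)
    stop("parsimony-informative sites need at least 4 taxa")
  m <- matrix("A", nrow = n_taxa, ncol = n_columns,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (n_parsinf > 0L) m[1:2, seq_len(n_parsinf)] <- "G"
  n_singleton <- n_variable - n_parsinf
  if (n_singleton > 0L) m[1L, n_parsinf + seq_len(n_singleton)] <- "G"
  coral_alignment(m, marker = marker)
}

#' Configuration for occurrence-record simulation
#'
#' Defaults emulate the structure of the study database: ten genera totaling
#' 985 records with genus sample sizes and depth spans shaped like the
#' observed ones, a 35% trawl fraction, truncated log-normal depth laws, 24
#' forced depth-range violations and 2 forced manual exclusions.
#'
#' @param genera Named list; each element a list with `median` and `sigma`
#'   (log-normal depth law, meters), truncation bounds `lo`/`hi`,
#'   `n_records`, and `n_species`.
#' @param trawl_fraction Fraction of records reporting a min--max depth
#'   interval rather than a point depth.
#' @param n_forced_range_violations Records constructed to violate the
#'   depth-range curation rule.
#' @param n_forced_manual_exclusions Records (always rule-passing) whose ids
#'   are returned as the manual exclusion list.
#' @param colony_rate Poisson rate for extra colonies per record
#'   (`n_colonies = 1 + Pois(colony_rate)`).
#' @param seed Integer seed fixing the full output.
#' @return List of class `recordsim_config`.
#' @export
recordsim_config <- function(genera = NULL, trawl_fraction = 0.35,
                             n_forced_range_violations = 24,
                             n_forced_manual_exclusions = 2,
                             colony_rate = 1.4, seed = 1) {
  if (is.null(genera)) {
    law <- function(median, sigma, lo, hi, n_records, n_species)
      list(median = median, sigma = sigma, lo = lo, hi = hi,
           n_records = n_records, n_species = n_species)
    genera <- list(
      Chrysogorgia      = law(1300, 0.60,  31, 4327, 615, 63),
      Metallogorgia     = law(1400, 0.30, 570, 2262, 120,  4),
      Iridogorgia       = law(1400, 0.30, 567, 2311,  40,  5),
      Rhodaniridogorgia = law(1300, 0.30, 568, 2229,   5,  2),
      Radicipes         = law(1200, 0.50, 196, 3580,  78,  7),
      Pseudochrysogorgia = law(1100, 0.20, 861, 1429,  3,  1),
      Stephanogorgia    = law(20,   0.40,   7,   90,  12,  3),
      Helicogorgia      = law(150,  0.70,  20, 1000,  23,  5),
      Trichogorgia      = law(120,  0.70,  10, 1000,  43,  5),
      Pleurogorgia      = law(800,  0.60, 250, 2509,  46,  4))
  }
  n_total <- sum(vapply(genera, `[[`, numeric(1), "n_records"))
  if (n_forced_range_violations + n_forced_manual_exclusions > n_total)
    stop("forced exclusion counts exceed total record count")
  structure(list(genera = genera, trawl_fraction = trawl_fraction,
                 n_forced_range_violations = n_forced_range_violations,
                 n_forced_manual_exclusions = n_forced_manual_exclusions,
                 colony_rate = colony_rate, seed = seed),
            class = "recordsim_config")
}

rtrunc_lnorm <- function(n, median, sigma, lo, hi) {
  mu <- log(median)
  u <- runif(n, plnorm(lo, mu, sigma), plnorm(hi, mu, sigma))
  qlnorm(u, mu, sigma)
}

#' Simulate occurrence records with known curation truth
#'
#' Generates per-genus records with truncated log-normal point depths; a
#' configured fraction are trawl stations whose depth interval is drawn
#' narrow enough to pass the depth-range curation rule. Exactly
#' `n_forced_range_violations` records are rebuilt with intervals wide
#' enough to violate the rule, and `n_forced_manual_exclusions` rule-passing
#' records are designated as manual exclusions; all remaining records pass
#' curation by construction.
#'
#' @param config A [recordsim_config()].
#' @return List with `records` (validated specimen-record data.frame),
#'   `manual_ids` (ids to pass to [curate_records()]) and `truth`: data.frame
#'   of per-record flags `excluded_range`/`excluded_manual` plus
#'   `species_intervals`, the per-species realized depth intervals over
#'   records passing curation.
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "recordsim_config"))
  set.seed(config$seed)
  rows <- lapply(names(config$genera), function(g) {
    law <- config$genera[[g]]
    n <- law$n_records
    d <- rtrunc_lnorm(n, law$median, law$sigma, law$lo, law$hi)
    data.frame(
      genus = g,
      species = paste0(substr(g, 1, 3), "_sp", sample.int(law$n_species, n, TRUE)),
      basin = sample(OCEAN_BASINS, n, TRUE, prob = c(0.35, 0.1, 0.5, 0.05)),
      lat = round(runif(n, -60, 60), 3), lon = round(runif(n, -180, 180), 3),
      depth_point = round(d, 1),
      source = sample(c("literature", "museum", "collection"), n, TRUE),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$record_id <- sprintf("SIM-%04d", seq_len(n))
  df$n_colonies <- 1L + rpois(n, config$colony_rate)

  is_trawl <- runif(n) < config$trawl_fraction
  half <- ifelse(is_trawl, df$depth_point / 4 * runif(n, 0.05, 0.90), 0)

  viol <- sample.int(n, config$n_forced_range_violations)
  half[viol] <- df$depth_point[viol] / 4 *
    runif(config$n_forced_range_violations, 1.2, 1.9)
  manual <- sample(setdiff(seq_len(n), viol), config$n_forced_manual_exclusions)

  df$depth_min_m <- round(df$depth_point - half, 1)
  df$depth_max_m <- round(df$depth_point + half, 1)
  # rounding must not tip a record across the rule boundary; recheck exactly
  mid <- (df$depth_min_m + df$depth_max_m) / 2
  stopifnot(identical(which((df$depth_max_m - df$depth_min_m) > 0.5 * mid),
                      sort(viol)))
  df$depth_point <- NULL

  excluded_range <- seq_len(n) %in% viol
  excluded_manual <- seq_len(n) %in% manual
  keep <- !excluded_range & !excluded_manual
  mid_keep <- mid[keep]
  lab <- paste(df$genus[keep], df$species[keep])
  species_intervals <- do.call(rbind, lapply(unique(lab), function(s) {
    d <- mid_keep[lab == s]
    data.frame(species = s, depth_lo = min(d), depth_hi = max(d),
               stringsAsFactors = FALSE)
  }))

  parsed <- as_specimen_records(df)
  stopifnot(nrow(parsed$rejected) == 0L)
  list(records = parsed$records,
       manual_ids = df$record_id[manual],
       truth = list(flags = data.frame(record_id = df$record_id,
                                       excluded_range = excluded_range,
                                       excluded_manual = excluded_manual,
                                       stringsAsFactors = FALSE),
                    species_intervals = species_intervals))
}
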