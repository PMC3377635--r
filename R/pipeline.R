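# End-to-end orchestration: read an input bundle (alignment FASTA + metadata
# + occurrence records), run every analysis stage, and write the full set of
# output tables with a content-hash manifest.

#' Build and validate a pipeline run configuration
#'
#' @param fasta Path to the aligned FASTA.
#' @param metadata Path to the sequence metadata CSV.
#' @param records Path to the occurrence-record CSV (or `NULL` to skip the
#'   biogeographic stages).
#' @param out_dir Output directory (created if absent).
#' @param marker Marker name for the alignment.
#' @param policy Haplotype comparison policy (see [collapse_haplotypes()]).
#' @param group_field Grouping field for richness and distance summaries.
#' @param thresholds A [delimitation_thresholds()].
#' @param manual_exclusions Record ids excluded manually during curation.
#' @param bin_width,max_depth Diversity-profile binning (meters).
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, metadata, records = NULL, out_dir,
                       marker = "mtMutS",
                       policy = "strict", group_field = "genus",
                       thresholds = delimitation_thresholds(),
                       manual_exclusions = KNOWN_BAD_DEPTH_RECORDS,
                       bin_width = 100, max_depth = 4500) {
  for (p in c(fasta, metadata, records))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(fasta = fasta, metadata = metadata, records = records,
                 out_dir = out_dir, marker = marker, policy = policy,
                 group_field = group_field, thresholds = thresholds,
                 manual_exclusions = manual_exclusions,
                 bin_width = bin_width, max_depth = max_depth),
            class = "run_config")
}

#' Run every analysis stage on an input bundle
#'
#' Produces, under `config$out_dir`: the alignment information-content
#' summary, the haplotype assignment and richness-by-basin table, the
#' p-distance matrix (long form) with transition/transversion tally, the
#' group distance extrema and family-delimitation verdicts per group pair,
#' and — when records are supplied — the curation report, per-genus depth
#' summaries, species depth ranges and the diversity profile. A
#' `manifest.csv` lists every artifact with its MD5 content hash; the run is
#' fully deterministic, so identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` (data.frame of file, md5) and
#'   the in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  results <- list()

  aln <- read_alignment(config$fasta, config$metadata, marker = config$marker)
  results$alignment_summary <- summarize_alignment(aln)
  write_table(results$alignment_summary, out("alignment_summary.csv"))

  assign <- collapse_haplotypes(aln, config$policy)
  results$assignment <- assign
  write_table(data.frame(seq_id = names(assign$members),
                         haplotype = unname(assign$members)),
              out("haplotype_assignment.csv"))
  if (all(!is.na(aln$meta[[config$group_field]]))) {
    results$richness <- richness_by_group(assign, aln, config$group_field)
    write_table(results$richness, out("haplotype_richness.csv"))
  }

  dm <- distance_matrix(aln)
  results$distances <- dm
  long <- data.frame(
    id_a = rep(dm$ids, times = length(dm$ids)),
    id_b = rep(dm$ids, each = length(dm$ids)),
    p = as.vector(dm$p), n_compared = as.vector(dm$compared))
  write_table(long[long$id_a < long$id_b, ], out("p_distances.csv"))
  tally <- titv_tally(aln)
  write_table(data.frame(transitions = tally$transitions,
                         transversions = tally$transversions,
                         ratio = tally$ratio),
              out("titv_tally.csv"))

  labels <- setNames(aln$meta[[config$group_field]], aln$meta$seq_id)
  if (all(!is.na(labels))) {
    gds <- group_distance_summary(dm, labels)
    results$group_distances <- gds
    write_table(gds$intra, out("intra_group_max_p.csv"))
    write_table(gds$inter, out("inter_group_min_p.csv"))
    if (nrow(gds$inter)) {
      verdicts <- gds$inter[, c("group_a", "group_b")]
      verdicts$verdict <- vapply(seq_len(nrow(gds$inter)), function(r) {
        a <- labels == gds$inter$group_a[r]
        b <- labels == gds$inter$group_b[r]
        d <- dm$p[names(labels)[a], names(labels)[b]]
        assess_rank_delimitation(d[!is.na(d)], config$thresholds)
      }, character(1))
      results$delimitation <- verdicts
      write_table(verdicts, out("delimitation_verdicts.csv"))
    }
  }

  if (!is.null(config$records)) {
    rec <- read_specimen_table(config$records)
    cur <- curate_records(rec$records, config$manual_exclusions)
    results$curation <- cur
    write_table(cur$curated, out("curated_records.csv"))
    write_table(as.data.frame(unclass(cur$report)), out("curation_report.csv"))
    results$depth_summary <- genus_depth_summary(cur$retained)
    ds <- results$depth_summary
    ds$outliers <- vapply(ds$outliers, paste, character(1), collapse = ";")
    write_table(ds, out("genus_depth_summary.csv"))
    results$ranges <- species_depth_ranges(cur$retained)
    write_table(results$ranges, out("species_depth_ranges.csv"))
    results$profile <- diversity_profile(results$ranges,
                                         bin_width = config$bin_width,
                                         max_depth = config$max_depth)
    write_table(results$profile, out("diversity_profile.csv"))
  }

  files <- sort(list.files(config$out_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_table(manifest, out("manifest.csv"))
  results$manifest <- manifest
  invisible(results)
}
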