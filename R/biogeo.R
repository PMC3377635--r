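# Occurrence-record curation and bathymetric diversity profiling. Trawl
# stations report a depth interval; the record's point depth is the interval
# midpoint, and records whose interval is too wide relative to that midpoint
# are excluded as uninformative.

#' Museum records with erroneous shallow depths
#'
#' Default manual-exclusion list for [curate_records()]: two historical
#' records whose extremely shallow depths are most probably recording
#' errors (a *Metallogorgia* colony, USNM 56792, and an *Iridogorgia
#' pourtalesii* colony from Blake station 259).
#'
#' @format Character vector of record ids.
#' @export
KNOWN_BAD_DEPTH_RECORDS <- c("USNM 56792", "Blake stn 259 Iridogorgia pourtalesii")

#' Curate occurrence records by the depth-range rule
#'
#' Each record's point depth is the average of its minimum and maximum
#' station depths. Records whose depth range (max - min) is more than half
#' of that average depth are excluded as too imprecise; point records
#' (min = max) trivially pass. Records whose id appears in
#' `manual_exclusion_ids` are excluded manually, and the manual flag takes
#' precedence in the report when both rules apply.
#'
#' @param records data.frame of validated specimen records (the `records`
#'   element of [read_specimen_table()]).
#' @param manual_exclusion_ids Character vector of record ids to drop;
#'   defaults to [KNOWN_BAD_DEPTH_RECORDS].
#' @return List with `curated` (all input rows plus `depth_point_m`,
#'   `excluded_range_rule`, `excluded_manual`), `retained` (the surviving
#'   subset) and `report` (class `curation_report`: `n_input`,
#'   `n_excluded_range`, `n_excluded_manual`, `n_retained`,
#'   `n_colonies_retained`).
#' @examples
#' rec <- as_specimen_records(data.frame(
#'   record_id = c("a", "b"), genus = "Chrysogorgia",
#'   depth_min_m = c(100, 500), depth_max_m = c(400, 500)))$records
#' curate_records(rec, manual_exclusion_ids = character(0))$report
#' @export
curate_records <- function(records, manual_exclusion_ids = KNOWN_BAD_DEPTH_RECORDS) {
  r <- records
  r$depth_point_m <- (r$depth_min_m + r$depth_max_m) / 2
  range_viol <- (r$depth_max_m - r$depth_min_m) > 0.5 * r$depth_point_m
  manual <- r$record_id %in% manual_exclusion_ids
  r$excluded_manual <- manual
  r$excluded_range_rule <- range_viol & !manual
  retained <- r[!r$excluded_manual & !r$excluded_range_rule, , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(list(
    n_input = nrow(r),
    n_excluded_range = sum(r$excluded_range_rule),
    n_excluded_manual = sum(r$excluded_manual),
    n_retained = nrow(retained),
    n_colonies_retained = sum(retained$n_colonies)),
    class = "curation_report")
  list(curated = r, retained = retained, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(paste0("<curation_report> %d records in; %d excluded by range rule, ",
                     "%d manually; %d retained (%d colonies)\n"),
              x$n_input, x$n_excluded_range, x$n_excluded_manual,
              x$n_retained, x$n_colonies_retained))
  invisible(x)
}

#' Tukey five-number depth summary per genus
#'
#' Box-and-whisker statistics of point depths for each genus: minimum,
#' lower hinge, median, upper hinge, maximum, with statistical outliers
#' flagged beyond 1.5 times the inter-hinge spread from the hinges. Hinges
#' follow Tukey's construction ([stats::fivenum()]), matching conventional
#' box-plot quartiles. Genera with no retained records are omitted with a
#' notice.
#'
#' @param retained data.frame of retained curated records (must carry
#'   `genus` and `depth_point_m`).
#' @return data.frame with one row per genus: `genus`, `n_records`,
#'   `depth_min`, `lower_hinge`, `median`, `upper_hinge`, `depth_max`, plus
#'   a list-column `outliers` of outlying depths.
#' @export
genus_depth_summary <- function(retained) {
  stopifnot(all(c("genus", "depth_point_m") %in% names(retained)))
  genera <- unique(retained$genus)
  rows <- lapply(genera, function(g) {
    d <- retained$depth_point_m[retained$genus == g]
    d <- d[!is.na(d)]
    if (length(d) == 0L) {
      message("genus with no retained depth records omitted: ", g)
      return(NULL)
    }
    fn <- fivenum(d)
    iqr <- fn[4L] - fn[2L]
    out <- d[d < fn[2L] - 1.5 * iqr | d > fn[4L] + 1.5 * iqr]
    df <- data.frame(genus = g, n_records = length(d),
                     depth_min = fn[1L], lower_hinge = fn[2L],
                     median = fn[3L], upper_hinge = fn[4L], depth_max = fn[5L],
                     stringsAsFactors = FALSE)
    df$outliers <- list(sort(out))
    df
  })
  do.call(rbind, rows)
}

#' Species depth ranges from curated records
#'
#' Per-species minimum and maximum of the curated point depths. Rows without
#' a species label are skipped; species labels are `genus species`.
#'
#' @param retained data.frame of retained curated records.
#' @return data.frame with `species`, `genus`, `depth_lo`, `depth_hi`,
#'   `n_records`, ordered by genus then increasing median depth.
#' @export
species_depth_ranges <- function(retained) {
  has_sp <- !is.na(retained$species) & retained$species != ""
  r <- retained[has_sp, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(species = character(), genus = character(),
                      depth_lo = numeric(), depth_hi = numeric(),
                      n_records = integer(), stringsAsFactors = FALSE))
  lab <- paste(r$genus, r$species)
  rows <- lapply(unique(lab), function(s) {
    d <- r$depth_point_m[lab == s]
    data.frame(species = s, genus = r$genus[lab == s][1L],
               depth_lo = min(d), depth_hi = max(d),
               med = median(d), n_records = length(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genus, out$med), , drop = FALSE]
  out$med <- NULL
  rownames(out) <- NULL
  out
}

#' Species extending shallower than a depth threshold
#'
#' @param ranges A [species_depth_ranges()] result.
#' @param threshold_m Depth threshold in meters (default 200). A species is
#'   counted when its shallowest record is strictly above (shallower than)
#'   the threshold.
#' @return List with `count` and `species` (character vector).
#' @export
species_shallower_than <- function(ranges, threshold_m = 200) {
  sel <- ranges$depth_lo < threshold_m
  list(count = sum(sel), species = ranges$species[sel])
}

#' Species-diversity profile across depth
#'
#' Counts the number of species found in every `bin_width`-meter depth
#' interval between 0 and `max_depth`. By default species are counted by
#' range-through overlap: a species whose depth range is \[lo, hi\] is
#' present in every half-open bin \[a, b) its interval overlaps, so a
#' species lying wholly between bin boundaries is still counted once.
#' `method = "level"` instead counts species whose range spans each exact
#' level depth (0, 100, 200, ... m).
#'
#' @param ranges A [species_depth_ranges()] result.
#' @param bin_width Bin width in meters (default 100).
#' @param max_depth Deepest bin edge in meters (default 4500). Ranges
#'   extending below it are counted in the terminal bin and noted.
#' @param method `"bin"` (default, interval overlap) or `"level"` (point
#'   sampling at multiples of `bin_width`).
#' @return data.frame with `bin_lo`, `bin_hi`, `n_species` (for
#'   `method = "level"`, `bin_lo = bin_hi` = the level).
#' @examples
#' rng <- data.frame(species = "x", genus = "g",
#'                   depth_lo = 150, depth_hi = 450, n_records = 2L)
#' diversity_profile(rng)[2:5, ]  # bins 100-500 each hold the species
#' @export
diversity_profile <- function(ranges, bin_width = 100, max_depth = 4500,
                              method = c("bin", "level")) {
  method <- match.arg(method)
  too_deep <- ranges$depth_hi > max_depth
  if (any(too_deep))
    message(sum(too_deep), " species range(s) extend below ", max_depth,
            " m; counted in the terminal bin")
  if (method == "bin") {
    lo_edges <- seq(0, max_depth - bin_width, by = bin_width)
    hi_edges <- lo_edges + bin_width
    counts <- vapply(seq_along(lo_edges), function(k) {
      top_bin <- k == length(lo_edges)
      sum(ranges$depth_lo < hi_edges[k] & ranges$depth_hi >= lo_edges[k] |
            (top_bin & ranges$depth_lo >= hi_edges[k]))
    }, numeric(1))
    data.frame(bin_lo = lo_edges, bin_hi = hi_edges, n_species = counts)
  } else {
    levels <- seq(0, max_depth, by = bin_width)
    counts <- vapply(levels, function(z) {
      sum(ranges$depth_lo <= z & ranges$depth_hi >= z)
    }, numeric(1))
    data.frame(bin_lo = levels, bin_hi = levels, n_species = counts)
  }
}
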