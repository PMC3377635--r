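# Shared data model: aligned sequence collections with per-row taxonomy /
# basin / depth metadata, and specimen occurrence records with depth ranges.

#' Construct a coral_alignment object
#'
#' An alignment is a rectangular block of IUPAC nucleotide symbols with one
#' row per sequence, plus a metadata table carrying taxonomy (genus, species,
#' family), ocean basin and collection depth for each row. Symbols are
#' upper-cased and U is mapped to T so that a single canonical alphabet is
#' used downstream.
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   character matrix of single symbols with row names giving sequence ids.
#' @param meta Optional data.frame with one row per sequence. Must contain a
#'   `seq_id` column matching the sequence names; recognized columns are
#'   `genus`, `species`, `family`, `basin` (one of [OCEAN_BASINS]) and
#'   `depth_m` (positive meters). Missing columns are filled with `NA`.
#' @param marker Marker name, e.g. `"mtMutS"`.
#'
#' @return Object of class `coral_alignment`: a list with elements `seqs`
#'   (character matrix, rows = sequences), `meta` (data.frame) and `marker`.
#' @examples
#' aln <- coral_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' n_sites(aln)
#' @export
coral_alignment <- function(seqs, meta = NULL, marker = "unknown") {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) stop("sequence matrix must have row names (seq ids)")
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by seq_id")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != max(lens)]
      stop("sequences are not all the same length; offending ids: ",
           paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("alignment must be nonempty")
  if (anyDuplicated(rownames(m)))
    stop("duplicated seq ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))

  m[] <- toupper(m)
  m[m == "U"] <- "T"
  bad <- which(!(m %in% IUPAC_SYMBOLS))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("illegal symbol '%s' in sequence '%s' at position %d",
                 m[bad[1L]], rownames(m)[i], j))
  }

  meta <- normalize_seq_meta(meta, rownames(m))
  structure(list(seqs = m, meta = meta, marker = marker),
            class = "coral_alignment")
}

normalize_seq_meta <- function(meta, ids) {
  cols <- c("genus", "species", "family", "basin", "depth_m")
  if (is.null(meta)) {
    meta <- data.frame(seq_id = ids, stringsAsFactors = FALSE)
  }
  if (!"seq_id" %in% names(meta)) stop("metadata must have a 'seq_id' column")
  if (anyDuplicated(meta$seq_id))
    stop("duplicated seq_id in metadata: ",
         paste(unique(meta$seq_id[duplicated(meta$seq_id)]), collapse = ", "))
  missing <- setdiff(ids, meta$seq_id)
  if (length(missing))
    stop("metadata rows missing for ids: ", paste(missing, collapse = ", "))
  for (cl in cols) if (!cl %in% names(meta)) meta[[cl]] <- NA
  meta <- meta[match(ids, meta$seq_id), c("seq_id", cols), drop = FALSE]
  rownames(meta) <- NULL
  bad_basin <- setdiff(unique(meta$basin[!is.na(meta$basin)]), OCEAN_BASINS)
  if (length(bad_basin))
    stop("unknown basin label(s): ", paste(bad_basin, collapse = ", "))
  d <- meta$depth_m
  if (any(!is.na(d) & d <= 0)) stop("depth_m must be positive meters")
  meta
}

#' @rdname coral_alignment
#' @param x A `coral_alignment`.
#' @export
n_sequences <- function(x) nrow(x$seqs)

#' @rdname coral_alignment
#' @export
n_sites <- function(x) ncol(x$seqs)

#' @export
print.coral_alignment <- function(x, ...) {
  cat(sprintf("<coral_alignment> %s: %d sequences x %d sites\n",
              x$marker, n_sequences(x), n_sites(x)))
  invisible(x)
}

#' Read an alignment from FASTA plus a metadata sidecar table
#'
#' Sequence ids in the FASTA must resolve one-to-one against rows of the
#' metadata CSV keyed by `seq_id`. Lowercase input is upper-cased and U is
#' mapped to T; sequences of unequal length or with symbols outside the IUPAC
#' set are a hard error naming the offending id/position.
#'
#' @param fasta_path Path to a FASTA file of aligned sequences.
#' @param metadata_path Path to a CSV with a `seq_id` column (see
#'   [coral_alignment()] for recognized columns). `NULL` for no metadata.
#' @param marker Marker name recorded on the alignment.
#' @return A [coral_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path = NULL, marker = "unknown") {
  fas <- seqinr::read.fasta(fasta_path, seqtype = "DNA", as.string = TRUE,
                            forceDNAtolower = FALSE)
  seqs <- setNames(toupper(unlist(fas)), names(fas))
  meta <- if (!is.null(metadata_path)) {
    read.csv(metadata_path, stringsAsFactors = FALSE)
  }
  if (!is.null(meta)) {
    extra <- setdiff(meta$seq_id, names(seqs))
    if (length(extra))
      stop("metadata rows with no matching FASTA record: ",
           paste(extra, collapse = ", "))
  }
  coral_alignment(seqs, meta, marker = marker)
}

#' Write an alignment to FASTA plus a metadata sidecar table
#'
#' Inverse of [read_alignment()]: `read_alignment(write_alignment(x))`
#' returns an identical object.
#'
#' @param aln A [coral_alignment()].
#' @param fasta_path Output FASTA path.
#' @param metadata_path Output CSV path, or `NULL` to skip metadata.
#' @return Invisibly, the paths written.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln$seqs)), function(i) aln$seqs[i, ]),
    names = rownames(aln$seqs), file.out = fasta_path)
  if (!is.null(metadata_path)) write_table(aln$meta, metadata_path)
  invisible(c(fasta_path, metadata_path))
}

#' Read specimen occurrence records from a CSV file
#'
#' Each input row either becomes a validated specimen record or is rejected
#' with a reason; accepted plus rejected row counts always equal the input
#' row count. A point-depth station may supply a single `depth_m` column,
#' copied into both `depth_min_m` and `depth_max_m`. Rows with nonpositive
#' depths, or with `depth_min_m > depth_max_m`, are rejected.
#'
#' @param csv_path Path to a CSV with columns `record_id`, `genus`,
#'   `depth_min_m`/`depth_max_m` (or a single `depth_m`), and optionally
#'   `species`, `basin`, `lat`, `lon`, `n_colonies` (default 1) and `source`.
#' @return A list with elements `records` (accepted rows as a data.frame)
#'   and `rejected` (data.frame of rejected rows with a `reason` column).
#' @export
read_specimen_table <- function(csv_path) {
  raw <- read.csv(csv_path, stringsAsFactors = FALSE)
  as_specimen_records(raw)
}

#' Validate a data.frame of specimen records
#'
#' The in-memory counterpart of [read_specimen_table()].
#'
#' @param raw data.frame of candidate records.
#' @return A list with elements `records` and `rejected` (with reasons).
#' @export
as_specimen_records <- function(raw) {
  need <- c("record_id", "genus")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!("depth_m" %in% names(raw)) &&
      !all(c("depth_min_m", "depth_max_m") %in% names(raw)))
    stop("need either a 'depth_m' column or 'depth_min_m'/'depth_max_m'")
  if ("depth_m" %in% names(raw)) {
    if (!"depth_min_m" %in% names(raw)) raw$depth_min_m <- NA_real_
    if (!"depth_max_m" %in% names(raw)) raw$depth_max_m <- NA_real_
    pt <- is.na(raw$depth_min_m) & !is.na(raw$depth_m)
    raw$depth_min_m[pt] <- raw$depth_m[pt]
    raw$depth_max_m[pt] <- raw$depth_m[pt]
    raw$depth_m <- NULL
  }
  for (cl in c("species", "basin", "source"))
    if (!cl %in% names(raw)) raw[[cl]] <- NA_character_
  for (cl in c("lat", "lon"))
    if (!cl %in% names(raw)) raw[[cl]] <- NA_real_
  if (!"n_colonies" %in% names(raw)) raw$n_colonies <- 1L

  reason <- rep(NA_character_, nrow(raw))
  bad <- is.na(raw$depth_min_m) | is.na(raw$depth_max_m)
  reason[bad & is.na(reason)] <- "missing depth"
  bad2 <- !bad & (raw$depth_min_m <= 0 | raw$depth_max_m <= 0)
  reason[bad2] <- "nonpositive depth"
  bad3 <- !bad & !bad2 & raw$depth_min_m > raw$depth_max_m
  reason[bad3] <- "depth_min_m > depth_max_m"
  bad4 <- is.na(reason) & (is.na(raw$n_colonies) | raw$n_colonies < 1)
  reason[bad4] <- "n_colonies < 1"
  bad5 <- is.na(reason) & !is.na(raw$basin) & !(raw$basin %in% OCEAN_BASINS)
  reason[bad5] <- "unknown basin label"

  keep <- is.na(reason)
  rejected <- raw[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!keep]
    message(sprintf("rejected %d of %d record rows (%s)",
                    nrow(rejected), nrow(raw),
                    paste(unique(rejected$reason), collapse = "; ")))
  }
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- rownames(rejected) <- NULL
  list(records = records, rejected = rejected)
}

#' Write a table of rows as delimited text
#'
#' Plain CSV with header; [read_table_file()] reads it back losslessly.
#'
#' @param rows data.frame.
#' @param csv_path Output path.
#' @return Invisibly, `csv_path`.
#' @export
write_table <- function(rows, csv_path) {
  write.csv(rows, csv_path, row.names = FALSE, quote = TRUE)
  invisible(csv_path)
}

#' @rdname write_table
#' @export
read_table_file <- function(csv_path) {
  read.csv(csv_path, stringsAsFactors = FALSE)
}
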