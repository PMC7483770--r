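# SEG input/output and gain/loss calling.
#
# Internal coordinate convention is 0-based half-open [start, end), the BED
# convention. SEG files on disk are 1-based inclusive, so a file row
# (start=10001, end=20000) becomes the internal interval (10000, 20000).
# Half-open intervals make book-ended segments (1000-2000 followed by
# 2000-3000) non-overlapping by construction, which the partition sweep
# relies on.

# header aliases, matched after lower-casing and stripping non-alphanumerics
.seg_aliases <- list(
  sample_id  = c("sample", "id", "sampleid", "samplename"),
  chromosome = c("chromosome", "chrom", "chr"),
  start      = c("start", "locstart", "startposition"),
  end        = c("end", "locend", "endposition"),
  num_probes = c("numprobes", "nummarkers", "nummark", "markers", "probes"),
  seg_mean   = c("segmentmean", "segmean", "log2ratio", "mean")
)

.normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.resolve_seg_columns <- function(header) {
  norm <- .normalize_header(header)
  idx <- vapply(names(.seg_aliases), function(field) {
    hit <- which(norm %in% .seg_aliases[[field]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing) > 0L) {
    stop("SEG format error: no column found for ", paste(missing, collapse = ", "),
         " (header: ", paste(header, collapse = ", "), ")", call. = FALSE)
  }
  idx
}

.parse_numeric_column <- function(x, field, integer = FALSE) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0L) {
    # +1 for the header row so the reported number matches the file line
    stop(sprintf("SEG parse error: non-numeric %s '%s' at line %d",
                 field, x[bad[1L]], bad[1L] + 1L), call. = FALSE)
  }
  if (integer) as.integer(round(val)) else val
}

#' Read a SEG file of segmented copy-number calls
#'
#' Reads tab-delimited segmented copy-number tables in the Broad/Firehose SEG
#' dialect (one row per sample x segment), as produced downstream of Circular
#' Binary Segmentation. Column names are matched case-insensitively against
#' the common aliases (`Sample`/`ID`, `Chromosome`/`chrom`,
#' `Num_Probes`/`Num_markers`, `Segment_Mean`/`seg.mean`, ...). Genomic
#' coordinates in the file are taken as 1-based inclusive and converted to
#' the package's internal 0-based half-open convention; `chr` prefixes are
#' stripped from chromosome labels.
#'
#' @param path Path to a tab-delimited SEG file with a header row.
#' @return A data frame of segment records, in file order, with columns
#'   `sample_id`, `chromosome`, `start`, `end` (0-based half-open),
#'   `num_probes`, `seg_mean`.
#' @seealso [write_seg()], [filter_and_call()]
#' @examples
#' f <- tempfile(fileext = ".seg")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
#'              "T1\tchr7\t10001\t20000\t57\t0.83"), f)
#' read_seg(f)
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  idx <- .resolve_seg_columns(names(raw))
  start1 <- .parse_numeric_column(raw[[idx["start"]]], "start coordinate")
  end1   <- .parse_numeric_column(raw[[idx["end"]]],   "end coordinate")
  rec <- data.frame(
    sample_id  = raw[[idx["sample_id"]]],
    chromosome = sub("^chr", "", raw[[idx["chromosome"]]], ignore.case = TRUE),
    start      = start1 - 1,   # 1-based inclusive -> 0-based half-open
    end        = end1,
    num_probes = .parse_numeric_column(raw[[idx["num_probes"]]], "probe count",
                                       integer = TRUE),
    seg_mean   = .parse_numeric_column(raw[[idx["seg_mean"]]], "segment mean"),
    stringsAsFactors = FALSE
  )
  bad <- which(!(rec$start < rec$end))
  if (length(bad) > 0L) {
    stop(sprintf("SEG parse error: empty or inverted segment at line %d",
                 bad[1L] + 1L), call. = FALSE)
  }
  if (any(rec$num_probes < 0L)) {
    stop("SEG parse error: negative probe count", call. = FALSE)
  }
  rec
}

#' Write segment records as a SEG file
#'
#' Inverse of [read_seg()]: writes the canonical Firehose header
#' (`Sample, Chromosome, Start, End, Num_Probes, Segment_Mean`) and converts
#' internal 0-based half-open coordinates back to 1-based inclusive.
#' `write_seg(read_seg(f))` is byte-identical to `f` for files in this
#' canonical dialect.
#'
#' @param records Data frame of segment records as returned by [read_seg()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(records, path) {
  out <- data.frame(
    Sample       = records$sample_id,
    Chromosome   = records$chromosome,
    Start        = format(records$start + 1, scientific = FALSE, trim = TRUE),
    End          = format(records$end, scientific = FALSE, trim = TRUE),
    Num_Probes   = records$num_probes,
    Segment_Mean = vapply(records$seg_mean, function(x) as.character(x), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filtering and calling configuration
#'
#' Bundles the thresholds used by [filter_and_call()] to turn segment records
#' into discrete gain/loss calls. The defaults (at least 10 probes, log2
#' segment mean at or beyond +/-0.2) are conventional SNP-array cut-offs, not
#' derived from any particular cohort; real-data results depend on them and
#' they should be chosen to match the platform at hand.
#'
#' @param min_probes Minimum number of probes supporting a segment; segments
#'   with fewer probes are dropped. Must be >= 1.
#' @param gain_threshold Log2 segment-mean threshold at or above which a
#'   segment is called `GAIN`. Must be positive.
#' @param loss_threshold Log2 segment-mean threshold at or below which a
#'   segment is called `LOSS`. Must be negative.
#' @param mode `"separate"` keeps `GAIN` and `LOSS` as distinct call types;
#'   `"combined"` relabels both as `ALTERED` so gains and losses are pooled.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_probes = 10L, gain_threshold = 0.2,
                          loss_threshold = -0.2,
                          mode = c("separate", "combined")) {
  mode <- match.arg(mode)
  stopifnot(min_probes >= 1L, gain_threshold > 0, loss_threshold < 0)
  structure(list(min_probes = as.integer(min_probes),
                 gain_threshold = gain_threshold,
                 loss_threshold = loss_threshold,
                 mode = mode),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf("filter_config: min_probes >= %d, GAIN at seg_mean >= %g, LOSS at <= %g, mode '%s'\n",
              x$min_probes, x$gain_threshold, x$loss_threshold, x$mode))
  invisible(x)
}

#' Filter segment records and call gains and losses
#'
#' Drops segments supported by fewer than `cfg$min_probes` probes and all
#' sex-chromosome (X, Y) segments, then calls the remainder: `GAIN` when the
#' log2 segment mean is at or above `cfg$gain_threshold`, `LOSS` when at or
#' below `cfg$loss_threshold` (closed comparisons, so a segment exactly at a
#' threshold is called altered), dropped otherwise. In `"combined"` mode both
#' calls are relabelled `ALTERED`.
#'
#' @param records Segment records from [read_seg()].
#' @param cfg A [filter_config()].
#' @return A data frame of altered segments with columns `sample_id`,
#'   `chromosome`, `start`, `end`, `call`. An empty result is not an error.
#' @export
filter_and_call <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- records$num_probes >= cfg$min_probes &
    !(toupper(records$chromosome) %in% c("X", "Y"))
  rec <- records[keep, , drop = FALSE]
  call <- ifelse(rec$seg_mean >= cfg$gain_threshold, "GAIN",
                 ifelse(rec$seg_mean <= cfg$loss_threshold, "LOSS", NA))
  rec <- rec[!is.na(call), , drop = FALSE]
  call <- call[!is.na(call)]
  if (cfg$mode == "combined") call <- rep("ALTERED", length(call))
  out <- data.frame(sample_id = rec$sample_id, chromosome = rec$chromosome,
                    start = rec$start, end = rec$end, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge each subject's overlapping segments into disjoint intervals
#'
#' Within one chromosome and one call type, unions each subject's
#' overlapping or book-ended (shared-boundary) segments into maximal disjoint
#' intervals. This is required before partitioning real cohorts: a subject
#' whose calls overlap would otherwise be counted twice in the regions it
#' covers, biasing the estimated probability of alteration.
#'
#' @param segments Altered segments (from [filter_and_call()]) all on one
#'   chromosome and with one call type; anything else is a contract violation.
#' @return Altered segments, sorted by subject then start, with at most one
#'   segment of each subject covering any base pair.
#' @export
merge_subject_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  if (length(unique(segments$chromosome)) > 1L ||
      length(unique(segments$call)) > 1L) {
    stop("contract violation: merge_subject_segments requires a single ",
         "chromosome and call type", call. = FALSE)
  }
  pieces <- lapply(split(segments, segments$sample_id), function(s) {
    s <- s[order(s$start, s$end), , drop = FALSE]
    ms <- s$start[1L]; me <- s$end[1L]
    starts <- numeric(0); ends <- numeric(0)
    for (i in seq_len(nrow(s))[-1L]) {
      if (s$start[i] <= me) {           # overlap or book-ended: extend
        me <- max(me, s$end[i])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- s$start[i]; me <- s$end[i]
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    data.frame(sample_id = s$sample_id[1L], chromosome = s$chromosome[1L],
               start = starts, end = ends, call = s$call[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  out
}

# merge per subject within every (chromosome, call) stratum; pipeline helper
merge_cohort_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  key <- paste(segments$chromosome, segments$call, sep = "\r")
  out <- do.call(rbind, lapply(split(segments, key), merge_subject_segments))
  rownames(out) <- NULL
  out
}

#' Write altered segments as BED
#'
#' Writes one line per segment in BED3+2 layout (`chrom`, `start`, `end`,
#' `sample_id`, `call`), 0-based half-open per the BED convention (the
#' package's internal convention, so no coordinate shift is applied).
#'
#' @param segments Altered-segment data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  out <- segments[, c("chromosome", "start", "end", "sample_id", "call")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write common regions as BED
#'
#' BED4+1 layout: `chrom`, `start`, `end`, `call`, `n_occurrences`.
#'
#' @param regions Common-region data frame from [find_common_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  out <- regions[, c("chromosome", "start", "end", "call", "n_occurrences")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
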