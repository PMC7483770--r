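# Sweep-line partition of a cohort's altered segments into common regions.
#
# Every segment contributes a start breakpoint (kind 1) and an end breakpoint
# (kind 0). Sorting the pooled breakpoints and sweeping a counter (+1 at each
# start, -1 at each end) across them yields, between each pair of adjacent
# distinct positions, the number of subjects altered there. Adjacent distinct
# breakpoint positions bound the common regions; identical positions from
# different subjects collapse to a single boundary.

#' Collect the sorted breakpoints of a set of altered segments
#'
#' Pools one start (kind = 1) and one end (kind = 0) breakpoint per segment
#' and sorts them ascending by position. At equal positions, ends order
#' before starts: with half-open intervals this makes a shared boundary
#' (one segment ending where another starts) carry zero width, so book-ended
#' segments stay separate regions. Ties within (position, kind) break by
#' sample id, making the ordering fully deterministic.
#'
#' @param segments Altered segments, all on one chromosome and of one call
#'   type (per-subject merged for real cohorts; see
#'   [merge_subject_segments()]).
#' @return A data frame of breakpoints (`position`, `kind`, `sample_id`) with
#'   the source chromosome and call attached as attributes. Empty input gives
#'   an empty result.
#' @export
collect_breakpoints <- function(segments) {
  if (nrow(segments) > 0L &&
      (length(unique(segments$chromosome)) > 1L ||
       length(unique(segments$call)) > 1L)) {
    stop("contract violation: collect_breakpoints requires a single ",
         "chromosome and call type", call. = FALSE)
  }
  bp <- data.frame(
    position  = c(segments$start, segments$end),
    kind      = rep(c(1L, 0L), each = nrow(segments)),
    sample_id = rep(segments$sample_id, 2L),
    stringsAsFactors = FALSE
  )
  bp <- bp[order(bp$position, bp$kind, bp$sample_id), , drop = FALSE]
  rownames(bp) <- NULL
  attr(bp, "chromosome") <- if (nrow(segments)) segments$chromosome[1L] else NA_character_
  attr(bp, "call") <- if (nrow(segments)) segments$call[1L] else NA_character_
  bp
}

#' Find common regions of alteration by a counter sweep
#'
#' Sweeps a subject counter across the sorted breakpoints: +1 at every start,
#' -1 at every end. Each pair of adjacent distinct positions with a positive
#' counter in between defines one common region whose `n_occurrences` is the
#' counter value there — the number of subjects altered across that whole
#' region. Zero-coverage gaps between altered blocks are not emitted; the
#' estimated probability of alteration is zero there by construction.
#'
#' @param breakpoints Breakpoints from [collect_breakpoints()].
#' @param n_subjects Cohort size (the roster size, including subjects with no
#'   alterations), carried along for downstream estimation checks.
#' @param chromosome,call Region annotations; default to the attributes set
#'   by [collect_breakpoints()].
#' @return A data frame of disjoint, sorted common regions with columns
#'   `chromosome`, `start`, `end`, `call`, `n_occurrences`.
#' @export
find_common_regions <- function(breakpoints, n_subjects,
                                chromosome = attr(breakpoints, "chromosome"),
                                call = attr(breakpoints, "call")) {
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), call = character(0),
                      n_occurrences = integer(0), stringsAsFactors = FALSE)
  if (is.null(breakpoints) || nrow(breakpoints) == 0L) return(empty)
  pos <- unique(breakpoints$position)  # already sorted ascending
  n_end   <- tabulate(match(breakpoints$position[breakpoints$kind == 0L], pos),
                      nbins = length(pos))
  n_start <- tabulate(match(breakpoints$position[breakpoints$kind == 1L], pos),
                      nbins = length(pos))
  counter <- 0L
  counts <- integer(length(pos))
  for (i in seq_along(pos)) {
    counter <- counter - n_end[i]      # ends process before starts at a locus
    if (counter < 0L) {
      stop("contract violation: unbalanced breakpoints (counter negative) at ",
           "position ", format(pos[i], scientific = FALSE), call. = FALSE)
    }
    counter <- counter + n_start[i]
    counts[i] <- counter
  }
  if (counter != 0L) {
    stop("contract violation: unbalanced breakpoints (counter ", counter,
         " after last position)", call. = FALSE)
  }
  k <- length(pos)
  keep <- which(counts[-k] > 0L)
  out <- data.frame(
    chromosome = rep(chromosome, length(keep)),
    start = pos[keep],
    end = pos[keep + 1L],
    call = rep(call, length(keep)),
    n_occurrences = counts[keep],
    stringsAsFactors = FALSE
  )
  if (!missing(n_subjects) && nrow(out) > 0L &&
      max(out$n_occurrences) > n_subjects) {
    warning("region subject count exceeds the stated cohort size; input ",
            "segments are probably not per-subject merged")
  }
  rownames(out) <- NULL
  out
}

# convenience: segments (one chromosome+call) -> regions
partition_segments <- function(segments, n_subjects) {
  find_common_regions(collect_breakpoints(segments), n_subjects)
}

#' Build the subjects x common-regions incidence matrix
#'
#' By construction of the partition, a subject's merged segments cover each
#' common region entirely or not at all; the incidence cell (s, r) is 1 iff
#' subject s has a segment covering every base of region r. Column sums must
#' reproduce each region's `n_occurrences`; a mismatch means the regions were
#' not derived from these segments and is raised as a consistency error.
#'
#' @param segments The altered segments the regions were partitioned from.
#' @param regions Common regions from [find_common_regions()].
#' @param subjects Ordered sample ids for the rows; defaults to the sorted
#'   ids present in `segments`. May include subjects with no alterations.
#' @return A binary integer matrix with subjects as rows and
#'   `chrom:start-end` region labels as columns.
#' @export
build_incidence <- function(segments, regions,
                            subjects = sort(unique(segments$sample_id))) {
  m <- matrix(0L, nrow = length(subjects), ncol = nrow(regions),
              dimnames = list(subjects,
                              sprintf("%s:%s-%s", regions$chromosome,
                                      format(regions$start, scientific = FALSE, trim = TRUE),
                                      format(regions$end, scientific = FALSE, trim = TRUE))))
  if (nrow(regions) == 0L) return(m)
  for (i in seq_len(nrow(segments))) {
    covers <- segments$chromosome[i] == regions$chromosome &
      segments$call[i] == regions$call &
      segments$start[i] <= regions$start & segments$end[i] >= regions$end
    if (any(covers)) m[segments$sample_id[i], covers] <- 1L
  }
  if (!all(colSums(m) == regions$n_occurrences)) {
    stop("consistency error: incidence column sums do not match region ",
         "occurrence counts; regions were not derived from these segments",
         call. = FALSE)
  }
  m
}
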