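# Group comparison: harmonized profiles, band-overlap differential regions,
# and a length-weighted profile distance.

# count, per region, the subjects of `segments` covering the region entirely
.count_occurrences <- function(segments, regions) {
  if (nrow(regions) == 0L) return(integer(0))
  vapply(seq_len(nrow(regions)), function(r) {
    covers <- segments$chromosome == regions$chromosome[r] &
      segments$call == regions$call[r] &
      segments$start <= regions$start[r] & segments$end >= regions$end[r]
    length(unique(segments$sample_id[covers]))
  }, integer(1))
}

#' Fit two group profiles on one shared region set
#'
#' Two profiles are only comparable region by region if their regions
#' coincide, so the partition is computed once on the pooled segments of both
#' groups (one shared boundary set) and each group's occurrence counts and
#' probabilities are then estimated against its own cohort size on those
#' shared regions. A region altered in only one group appears in both
#' profiles, with `phat = 0` (and a proportion interval at 0 successes) in
#' the other.
#'
#' @param segments_a,segments_b Altered segments of the two groups.
#' @param n_a,n_b Group cohort sizes; default to the distinct sample ids
#'   present in each group's segments.
#' @param labels Length-2 character vector of group labels.
#' @param conf_level,ci_method Band settings, see [proportion_ci()].
#' @param merge Merge per-subject overlaps first (default), see
#'   [cna_profile()].
#' @return A list of two `cna_profile` objects (`a`, `b`) with identical
#'   region frames, suitable for [compare_profiles()].
#' @export
harmonize_profiles <- function(segments_a, segments_b,
                               n_a = length(unique(segments_a$sample_id)),
                               n_b = length(unique(segments_b$sample_id)),
                               labels = c("A", "B"), conf_level = 0.95,
                               ci_method = c("wilson", "wald", "clopper-pearson"),
                               merge = TRUE) {
  ci_method <- match.arg(ci_method)
  if (nrow(segments_a) == 0L) stop("domain error: group '", labels[1L],
                                   "' has no altered segments", call. = FALSE)
  if (nrow(segments_b) == 0L) stop("domain error: group '", labels[2L],
                                   "' has no altered segments", call. = FALSE)
  if (merge) {
    segments_a <- merge_cohort_segments(segments_a)
    segments_b <- merge_cohort_segments(segments_b)
  }
  pooled <- rbind(segments_a, segments_b)
  key <- paste(pooled$call, pooled$chromosome, sep = "\r")
  regions <- do.call(rbind, lapply(split(pooled, key), function(s) {
    partition_segments(s, n_a + n_b)
  }))
  regions <- regions[order(regions$call, .chrom_rank(regions$chromosome),
                           regions$chromosome, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  make_group <- function(segs, n, label) {
    reg <- regions
    reg$n_occurrences <- .count_occurrences(segs, regions)
    estimate_profile(reg, n, conf_level, ci_method, group_label = label)
  }
  list(a = make_group(segments_a, n_a, labels[1L]),
       b = make_group(segments_b, n_b, labels[2L]))
}

#' Compare two harmonized alteration profiles
#'
#' Flags a region as differential when the two groups' confidence bands do
#' not overlap (`ci_low` of one group above `ci_high` of the other), the
#' band-overlap rule used to read group differences off the plotted
#' signatures. Note this is a descriptive screen, not a calibrated
#' two-proportion test: non-overlap of two 95% intervals is conservative at
#' any single region, and no multiple-testing correction is applied across
#' regions.
#'
#' The profile distance is the region-length-weighted mean absolute
#' difference of the two probability vectors,
#' `sum(|phat_a - phat_b| * len) / sum(len)` — a pseudometric in \[0, 1\]
#' (regions have unequal sizes, so unweighted means would over-count short
#' regions).
#'
#' @param a,b `cna_profile` objects on an identical region set, as produced
#'   by [harmonize_profiles()].
#' @return An object of class `cna_comparison`: the per-region table with
#'   both groups' estimates and the `differential` flag, the distance, and
#'   counts.
#' @export
compare_profiles <- function(a, b) {
  ra <- a$regions; rb <- b$regions
  same <- nrow(ra) == nrow(rb) &&
    all(ra$chromosome == rb$chromosome) && all(ra$start == rb$start) &&
    all(ra$end == rb$end) && all(ra$call == rb$call)
  if (!same) {
    stop("consistency error: profiles are not on the same region set; ",
         "use harmonize_profiles()", call. = FALSE)
  }
  differential <- ra$ci_low > rb$ci_high | rb$ci_low > ra$ci_high
  len <- ra$end - ra$start
  distance <- if (nrow(ra) == 0L) 0 else
    sum(abs(ra$phat - rb$phat) * len) / sum(len)
  tab <- data.frame(chromosome = ra$chromosome, start = ra$start, end = ra$end,
                    call = ra$call,
                    phat_a = ra$phat, ci_low_a = ra$ci_low, ci_high_a = ra$ci_high,
                    phat_b = rb$phat, ci_low_b = rb$ci_low, ci_high_b = rb$ci_high,
                    differential = differential, stringsAsFactors = FALSE)
  structure(list(regions = tab, distance = distance,
                 n_differential = sum(differential),
                 groups = c(a = a$group_label %||% "A", b = b$group_label %||% "B"),
                 conf_level = a$conf_level),
            class = "cna_comparison")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.cna_comparison <- function(x, ...) {
  cat(sprintf("Profile comparison %s vs %s: %d/%d regions differential at %d%% band overlap; length-weighted L1 distance %.4f\n",
              x$groups["a"], x$groups["b"], x$n_differential, nrow(x$regions),
              round(100 * x$conf_level), x$distance))
  invisible(x)
}

#' Stratified subsampling of a cohort
#'
#' Draws `n` subjects without replacement while maintaining the group
#' proportions of the full cohort: per-group quotas are the group proportions
#' times `n`, rounded by the largest-remainder rule so they sum exactly to
#' `n`. Used for robustness checks of the profile against cohort size.
#'
#' @param segments Altered segments of the full cohort.
#' @param group_labels Named character vector mapping every roster sample id
#'   (including subjects with no altered segments) to its group.
#' @param n Number of subjects to draw; at most the roster size.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @return A list with `sample_ids` (the drawn roster), `segments` (the
#'   subset of `segments` belonging to drawn subjects) and `group_labels`
#'   restricted to the draw.
#' @export
stratified_subsample <- function(segments, group_labels, n, seed) {
  roster <- names(group_labels)
  if (is.null(roster) || any(!nzchar(roster))) {
    stop("group_labels must be a named vector (names are sample ids)", call. = FALSE)
  }
  if (n > length(roster)) {
    stop("domain error: n (", n, ") exceeds the cohort size (",
         length(roster), ")", call. = FALSE)
  }
  counts <- table(group_labels)
  if (any(counts == 0L)) stop("domain error: empty group class", call. = FALSE)
  quota <- n * as.numeric(counts) / length(roster)
  base <- floor(quota)
  rem <- quota - base
  extra <- n - sum(base)
  if (extra > 0L) {
    # largest remainders get the leftover draws; ties break by class order
    give <- order(-rem, seq_along(rem))[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  quotas <- stats::setNames(as.integer(base), names(counts))
  set.seed(seed)
  ids <- unlist(lapply(names(quotas), function(g) {
    pool <- roster[group_labels == g]
    sample(pool, quotas[[g]])
  }), use.names = FALSE)
  list(sample_ids = ids,
       segments = segments[segments$sample_id %in% ids, , drop = FALSE],
       group_labels = group_labels[ids])
}
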