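# Estimation of the probability-of-alteration generator function.
#
# Each common region r is treated as an independent Bernoulli experiment per
# subject; the estimated generator function is the exact integer ratio
#   phat(r) = n_occurrences(r) / N_subjects,
# with a proportion confidence interval per region forming the confidence
# band of the disease signature.

#' Proportion confidence intervals
#'
#' Per-region confidence bounds for a binomial proportion. The default is the
#' Wilson score interval, which is well behaved at observed proportions of 0
#' and 1 (both occur routinely in alteration profiles); the Wald interval
#' (clipped to \[0, 1\]) and the exact Clopper-Pearson interval are available
#' for sensitivity analyses.
#'
#' @param x Number of successes (subjects altered), vectorized.
#' @param n Number of trials (cohort size).
#' @param conf_level Confidence level, in (0, 1).
#' @param method One of `"wilson"`, `"wald"`, `"clopper-pearson"`.
#' @return A two-column matrix with columns `low` and `high`.
#' @export
proportion_ci <- function(x, n, conf_level = 0.95,
                          method = c("wilson", "wald", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(conf_level > 0, conf_level < 1, n >= 1, all(x >= 0), all(x <= n))
  alpha <- 1 - conf_level
  p <- x / n
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    low <- centre - half
    high <- centre + half
  } else if (method == "wald") {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    low <- p - half
    high <- p + half
  } else {
    low <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
    high <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  }
  cbind(low = pmax(0, pmin(low, p)), high = pmin(1, pmax(high, p)))
}

#' Estimate the probability-of-alteration profile over common regions
#'
#' Applies the generator-function estimator to a set of common regions:
#' `phat = n_occurrences / n_subjects`, an exact ratio of integers, with a
#' proportion confidence band per region.
#'
#' This is the low-level constructor; [cna_profile()] runs the whole
#' segments-to-profile fit.
#'
#' @param regions Common regions from [find_common_regions()] (possibly
#'   concatenated over chromosomes and call types).
#' @param n_subjects Cohort size. Must be at least the largest region count.
#' @param conf_level Confidence level of the band (default 0.95).
#' @param ci_method Proportion-interval method, see [proportion_ci()].
#' @param group_label Optional label for the cohort or phenotypic group.
#' @return An object of class `cna_profile`; see [cna_profile()].
#' @export
estimate_profile <- function(regions, n_subjects, conf_level = 0.95,
                             ci_method = c("wilson", "wald", "clopper-pearson"),
                             group_label = NULL) {
  ci_method <- match.arg(ci_method)
  if (n_subjects <= 0) stop("domain error: n_subjects must be positive", call. = FALSE)
  if (nrow(regions) > 0L && max(regions$n_occurrences) > n_subjects) {
    stop("consistency error: a region has more occurrences than subjects",
         call. = FALSE)
  }
  phat <- regions$n_occurrences / n_subjects
  ci <- proportion_ci(regions$n_occurrences, n_subjects, conf_level, ci_method)
  reg <- regions
  reg$phat <- phat
  reg$ci_low <- if (nrow(reg)) ci[, "low"] else numeric(0)
  reg$ci_high <- if (nrow(reg)) ci[, "high"] else numeric(0)
  structure(list(regions = reg, n_subjects = as.integer(n_subjects),
                 conf_level = conf_level, ci_method = ci_method,
                 group_label = group_label),
            class = "cna_profile")
}

# numeric chromosome rank ("2" before "10"; non-numeric labels last)
.chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), Inf, num)
}

#' Fit a probability-of-alteration profile to a cohort of altered segments
#'
#' The main fitting function. For each call type and chromosome it merges
#' each subject's overlapping segments, partitions the pooled breakpoints
#' into common regions of alteration ([find_common_regions()]), and estimates
#' the per-region probability of alteration `phat = n_occurrences /
#' n_subjects` with a proportion confidence band. The fitted object is the
#' cohort's disease signature: an ordered set of disjoint regions, each with
#' an exact alteration frequency and its confidence interval.
#'
#' @param segments Altered segments from [filter_and_call()] (or from
#'   [matrix_to_segments()] for simulated cohorts).
#' @param n_subjects Cohort size. Defaults to the number of distinct sample
#'   ids in `segments`, but should be passed explicitly whenever the roster
#'   includes subjects with no called alterations — the estimator divides by
#'   the roster size, not by the number of altered subjects.
#' @param conf_level,ci_method Confidence band settings, see
#'   [proportion_ci()].
#' @param group_label Optional cohort/group label used in printing and plots.
#' @param merge Merge each subject's overlapping segments first (default).
#'   Disable only for inputs already guaranteed disjoint per subject, e.g.
#'   the simulator's book-ended output, where merging cannot change counts.
#' @return An object of class `cna_profile` with components `regions` (data
#'   frame: `chromosome`, `start`, `end`, `call`, `n_occurrences`, `phat`,
#'   `ci_low`, `ci_high`), `n_subjects`, `conf_level`, `ci_method`,
#'   `group_label`. Methods: [print()], [summary()], [coef()], [confint()],
#'   [predict()], [plot()], [simulate()], [as.data.frame()].
#' @examples
#' cohort <- sample_cohort(generator_function(c(0, .2, .7, .8, .6)), 40, seed = 7)
#' fit <- cna_profile(matrix_to_segments(cohort), n_subjects = 40)
#' fit
#' coef(fit)
#' @export
cna_profile <- function(segments, n_subjects = length(unique(segments$sample_id)),
                        conf_level = 0.95,
                        ci_method = c("wilson", "wald", "clopper-pearson"),
                        group_label = NULL, merge = TRUE) {
  ci_method <- match.arg(ci_method)
  if (nrow(segments) == 0L) {
    regions <- data.frame(chromosome = character(0), start = numeric(0),
                          end = numeric(0), call = character(0),
                          n_occurrences = integer(0), stringsAsFactors = FALSE)
    return(estimate_profile(regions, max(n_subjects, 1L), conf_level,
                            ci_method, group_label))
  }
  key <- paste(segments$call, segments$chromosome, sep = "\r")
  parts <- lapply(split(segments, key), function(s) {
    if (merge) s <- merge_subject_segments(s)
    partition_segments(s, n_subjects)
  })
  regions <- do.call(rbind, parts)
  regions <- regions[order(regions$call, .chrom_rank(regions$chromosome),
                           regions$chromosome, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  fit <- estimate_profile(regions, n_subjects, conf_level, ci_method, group_label)
  fit$call <- match.call()
  fit
}

#' @export
print.cna_profile <- function(x, ...) {
  cat("Probability-of-alteration profile",
      if (!is.null(x$group_label)) paste0(" [", x$group_label, "]"), "\n", sep = "")
  cat(sprintf("  %d subjects, %d common regions (%s), %d%% %s bands\n",
              x$n_subjects, nrow(x$regions),
              paste(unique(x$regions$call), collapse = "+"),
              round(100 * x$conf_level), x$ci_method))
  if (nrow(x$regions) > 0L) {
    top <- x$regions[order(-x$regions$phat), , drop = FALSE]
    top <- utils::head(top, 5L)
    cat("  most frequently altered regions:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s:%s-%s  %s  phat=%.3f (%.3f, %.3f)\n",
                  top$chromosome[i],
                  format(top$start[i], scientific = FALSE),
                  format(top$end[i], scientific = FALSE),
                  top$call[i], top$phat[i], top$ci_low[i], top$ci_high[i]))
    }
  }
  invisible(x)
}

#' @export
summary.cna_profile <- function(object, ...) {
  reg <- object$regions
  by_call <- if (nrow(reg)) split(reg, reg$call) else list()
  stats <- lapply(by_call, function(r) {
    len <- r$end - r$start
    c(n_regions = nrow(r), total_bp = sum(len),
      mean_phat = mean(r$phat), max_phat = max(r$phat),
      weighted_mean_phat = sum(r$phat * len) / sum(len))
  })
  structure(list(profile = object, by_call = stats), class = "summary.cna_profile")
}

#' @export
print.summary.cna_profile <- function(x, ...) {
  print(x$profile)
  for (cl in names(x$by_call)) {
    s <- x$by_call[[cl]]
    cat(sprintf("  %s: %d regions over %s bp; mean phat %.3f (length-weighted %.3f), max %.3f\n",
                cl, s["n_regions"], format(s["total_bp"], big.mark = ",", scientific = FALSE),
                s["mean_phat"], s["weighted_mean_phat"], s["max_phat"]))
  }
  invisible(x)
}

.region_labels <- function(regions) {
  lab <- sprintf("%s:%s-%s", regions$chromosome,
                 format(regions$start, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE))
  if (length(unique(regions$call)) > 1L) lab <- paste0(regions$call, "/", lab)
  lab
}

#' @export
coef.cna_profile <- function(object, ...) {
  stats::setNames(object$regions$phat, .region_labels(object$regions))
}

#' @export
confint.cna_profile <- function(object, parm, level = object$conf_level, ...) {
  ci <- proportion_ci(object$regions$n_occurrences, object$n_subjects,
                      level, object$ci_method)
  rownames(ci) <- .region_labels(object$regions)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.cna_profile <- function(x, ...) {
  reg <- x$regions
  reg$n_subjects <- x$n_subjects
  reg$group <- if (is.null(x$group_label)) NA_character_ else x$group_label
  reg
}

#' Predict the alteration probability at genomic positions
#'
#' Looks up the fitted per-region probability at arbitrary positions;
#' positions falling in no common region (zero-coverage gaps) have estimated
#' probability 0.
#'
#' @param object A fitted [cna_profile()].
#' @param newdata Data frame with columns `chromosome` and `position` (bp),
#'   and optionally `call` when the profile holds several call types.
#' @param ... Unused.
#' @return Numeric vector of estimated probabilities.
#' @export
predict.cna_profile <- function(object, newdata, ...) {
  reg <- object$regions
  vapply(seq_len(nrow(newdata)), function(i) {
    hit <- reg$chromosome == newdata$chromosome[i] &
      reg$start <= newdata$position[i] & newdata$position[i] < reg$end
    if (!is.null(newdata$call)) hit <- hit & reg$call == newdata$call[i]
    if (any(hit)) reg$phat[which(hit)[1L]] else 0
  }, numeric(1))
}

#' Simulate incidence matrices from a fitted profile
#'
#' Treats the fitted `phat` vector as the generator function of the
#' population and draws new cohorts: each cell is an independent Bernoulli
#' draw with the region's fitted probability.
#'
#' @param object A fitted [cna_profile()].
#' @param nsim Number of cohorts to draw.
#' @param seed Integer seed.
#' @param n_subjects Size of each simulated cohort; defaults to the fitted
#'   cohort size.
#' @param ... Unused.
#' @return A list of `nsim` binary incidence matrices (subjects x regions).
#' @export
simulate.cna_profile <- function(object, nsim = 1, seed = NULL,
                                 n_subjects = object$n_subjects, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$regions$phat
  labs <- .region_labels(object$regions)
  lapply(seq_len(nsim), function(k) {
    m <- matrix(stats::rbinom(n_subjects * length(p), 1L, rep(p, each = n_subjects)),
                nrow = n_subjects,
                dimnames = list(sprintf("S%d", seq_len(n_subjects)), labs))
    m
  })
}
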