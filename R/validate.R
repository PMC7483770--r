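# Error metrics between a true generator function and its cohort estimate,
# and the convergence study over increasing cohort sizes.

#' Squared error between true and estimated generator functions
#'
#' `error_sq` is the cohort-size-normalised squared error
#' `sum((phi - phat)^2) / n_subjects` of one simulated dataset; averaging it
#' over replicates at increasing cohort sizes gives the convergence curve of
#' the estimator (its expectation decays like 1/n^2, since
#' `E[sum((phi - phat)^2)] = sum(phi * (1 - phi)) / n`).
#'
#' @param true_phi True per-region probabilities.
#' @param est_phi Estimated per-region probabilities on the same region grid.
#' @param n_subjects Cohort size used for the estimate.
#' @return Non-negative scalar; 0 iff the vectors are identical.
#' @export
error_sq <- function(true_phi, est_phi, n_subjects) {
  if (length(true_phi) != length(est_phi)) {
    stop("consistency error: probability vectors differ in length", call. = FALSE)
  }
  stopifnot(n_subjects >= 1L)
  sum((true_phi - est_phi)^2) / n_subjects
}

#' Percentage (chi-square-like) error between generator functions
#'
#' `error_pct` is `sum((phi - phat)^2 / phi)` over the regions with positive
#' true probability. Regions with `phi = 0` are excluded from the sum: the
#' estimator returns `phat = 0` there almost always, contributing 0/0; the
#' rare `phi = 0, phat > 0` regions (impossible under the simulator, possible
#' for mismatched grids) would contribute an infinite term and are instead
#' counted in the `"flagged"` attribute of the result. Scaled by cohort size,
#' this statistic behaves like a chi-square across replicates.
#'
#' @inheritParams error_sq
#' @return Non-negative scalar with an integer attribute `flagged` counting
#'   the excluded `phi = 0, phat > 0` regions.
#' @export
error_pct <- function(true_phi, est_phi) {
  if (length(true_phi) != length(est_phi)) {
    stop("consistency error: probability vectors differ in length", call. = FALSE)
  }
  pos <- true_phi > 0
  val <- sum((true_phi[pos] - est_phi[pos])^2 / true_phi[pos])
  structure(val, flagged = sum(!pos & est_phi > 0))
}

#' Align an estimated profile to a generator's uniform region grid
#'
#' Maps the common regions recovered by the partition back onto the uniform
#' grid of a [generator_function()]: each grid cell takes the `phat` of the
#' common region covering its midpoint, and grid cells in zero-coverage gaps
#' take 0. This puts the estimate and the truth on the same region grid so
#' [error_sq()] / [error_pct()] apply.
#'
#' @param regions Common regions with `n_occurrences` (from
#'   [find_common_regions()]) or a fitted [cna_profile()].
#' @param n_subjects Cohort size (ignored when a fitted profile is passed —
#'   its own size is used).
#' @param generator The [generator_function()] defining the grid.
#' @return Numeric vector of length `generator$n_regions`.
#' @export
phi_on_grid <- function(regions, n_subjects, generator) {
  if (inherits(regions, "cna_profile")) {
    n_subjects <- regions$n_subjects
    regions <- regions$regions
  }
  rs <- generator$region_size
  mids <- (seq_len(generator$n_regions) - 0.5) * rs
  vapply(mids, function(p) {
    hit <- regions$start <= p & p < regions$end
    if (any(hit)) regions$n_occurrences[which(hit)[1L]] / n_subjects else 0
  }, numeric(1))
}

#' Convergence study of the profile estimator
#'
#' For each generator function and cohort size, repeatedly runs the full
#' recovery pipeline — draw a cohort, expand it to segments, partition, and
#' estimate the profile on the generator's grid — and accumulates the two
#' error metrics. The mean squared error decreases as cohorts grow,
#' quantifying how fast the estimated signature converges to the population
#' signature.
#'
#' @param generators A [generator_function()] or (named) list of them.
#' @param sizes Strictly increasing integer vector of cohort sizes.
#' @param replicates Number of simulated datasets per (generator, size) cell.
#' @param seed Integer root seed; the study is reproducible for a fixed seed.
#' @return A data frame with one row per (generator, size): mean and standard
#'   deviation of `error_sq` and `error_pct`, the replicate count, and the
#'   mean raw squared deviation `sum((phi - phat)^2)` (before cohort-size
#'   normalisation) for closed-form comparisons.
#' @export
convergence_study <- function(generators, sizes, replicates = 10, seed = 1) {
  if (inherits(generators, "generator_function")) generators <- list(generators)
  if (is.null(names(generators))) {
    names(generators) <- vapply(seq_along(generators), function(i) {
      generators[[i]]$label %||% sprintf("g%d", i)
    }, "")
  }
  stopifnot(all(diff(sizes) > 0), replicates >= 1)
  set.seed(seed)
  run_seeds <- array(sample.int(.Machine$integer.max,
                                length(generators) * length(sizes) * replicates),
                     dim = c(length(generators), length(sizes), replicates))
  rows <- list()
  for (g in seq_along(generators)) {
    gen <- generators[[g]]
    for (s in seq_along(sizes)) {
      n <- sizes[s]
      eps <- numeric(replicates)
      epp <- numeric(replicates)
      raw <- numeric(replicates)
      for (k in seq_len(replicates)) {
        cohort <- sample_cohort(gen, n, run_seeds[g, s, k])
        segs <- matrix_to_segments(cohort)
        regions <- if (nrow(segs)) partition_segments(segs, n) else
          data.frame(chromosome = character(0), start = numeric(0),
                     end = numeric(0), call = character(0),
                     n_occurrences = integer(0))
        est <- phi_on_grid(regions, n, gen)
        raw[k] <- sum((gen$probs - est)^2)
        eps[k] <- error_sq(gen$probs, est, n)
        epp[k] <- as.numeric(error_pct(gen$probs, est))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        generator = names(generators)[g], n_subjects = n,
        replicates = replicates,
        epsilon_mean = mean(eps), epsilon_sd = stats::sd(eps),
        epsilon_pct_mean = mean(epp), epsilon_pct_sd = stats::sd(epp),
        raw_sq_mean = mean(raw), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
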