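# Cohort simulator: Bernoulli draws from a known generator function, and
# conversion of binary status matrices into segment datasets that feed the
# partition. This is the package's validation harness — with the generator
# known, the estimation error of the recovered profile can be measured.

#' Define a generator function
#'
#' A generator function is the discrete disease signature of a population:
#' a vector of per-region probabilities of alteration over uniform fixed-size
#' regions. Simulated subjects are independent Bernoulli draws from it.
#'
#' @param probs Numeric vector of per-region alteration probabilities, each
#'   in \[0, 1\].
#' @param region_size Region width in base pairs (uniform across regions).
#' @param label Optional identifier used in reports.
#' @return An object of class `generator_function` with fields `probs`,
#'   `region_size`, `n_regions`, `label`.
#' @export
generator_function <- function(probs, region_size = 1000, label = NULL) {
  stopifnot(length(probs) >= 1L, all(probs >= 0), all(probs <= 1),
            region_size > 0)
  structure(list(probs = as.numeric(probs),
                 region_size = region_size,
                 n_regions = length(probs),
                 label = label),
            class = "generator_function")
}

#' @export
print.generator_function <- function(x, ...) {
  cat(sprintf("generator_function%s: %d regions of %s bp\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$n_regions, format(x$region_size, scientific = FALSE)))
  cat("  probs:", paste(format(x$probs, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Built-in example generator functions
#'
#' Four illustrative signatures used by the package's own convergence checks:
#' a single-peak profile, a bimodal profile, a flat profile and a sparse
#' two-spike profile. They are examples chosen to span qualitatively
#' different signature shapes, not estimates from any cohort.
#'
#' @param region_size Region width in base pairs.
#' @return Named list of four [generator_function()] objects.
#' @export
builtin_generators <- function(region_size = 1000) {
  list(
    peak    = generator_function(c(0, 0.2, 0.7, 0.8, 0.6, 0.4, 0.1, 0, 0, 0),
                                 region_size, "peak"),
    bimodal = generator_function(c(0.1, 0.6, 0.3, 0, 0, 0.2, 0.7, 0.5, 0.1, 0),
                                 region_size, "bimodal"),
    flat    = generator_function(rep(0.3, 10), region_size, "flat"),
    sparse  = generator_function(c(0, 0, 0.9, 0, 0, 0, 0, 0.4, 0, 0),
                                 region_size, "sparse")
  )
}

#' Wrap a binary status matrix as a simulated cohort
#'
#' @param matrix Binary subjects x regions matrix (0 = normal, 1 = altered).
#'   Row names are used as sample ids (defaults `S1`, `S2`, ...).
#' @param region_size Region width in base pairs.
#' @param call Call type carried onto derived segments
#'   (`"ALTERED"`, `"GAIN"` or `"LOSS"`).
#' @param generator The [generator_function()] that produced the matrix, if
#'   any.
#' @param seed The seed used, if any.
#' @return An object of class `simulated_cohort`.
#' @export
simulated_cohort <- function(matrix, region_size = 1000, call = "ALTERED",
                             generator = NULL, seed = NA_integer_) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("R%d", seq_len(ncol(m)))
  if (is.null(generator)) {
    generator <- generator_function(rep(0, ncol(m)), region_size)
    generator$probs <- NULL  # unknown truth for hand-built matrices
  }
  structure(list(matrix = m, generator = generator, call = call, seed = seed),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d subjects x %d regions (%s), %s altered cells\n",
              nrow(x$matrix), ncol(x$matrix), x$call, sum(x$matrix)))
  invisible(x)
}

# deterministic per-subject uniform streams from one root seed, so cohorts
# are reproducible independent of subject iteration order
.subject_uniforms <- function(seed, n_subjects, n_regions) {
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  u <- matrix(0, n_subjects, n_regions)
  for (s in seq_len(n_subjects)) {
    set.seed(subject_seeds[s])
    u[s, ] <- stats::runif(n_regions)
  }
  u
}

#' Draw a simulated cohort from a generator function
#'
#' Each cell (subject, region) is an independent Bernoulli draw with the
#' region's generator probability: subject s is altered in region r iff its
#' uniform draw is below `gen$probs[r]`.
#'
#' @param gen A [generator_function()].
#' @param n_subjects Cohort size, >= 1.
#' @param seed Integer root seed; one root seed spawns one deterministic
#'   stream per subject.
#' @return A `simulated_cohort` whose binary matrix has `n_subjects` rows.
#' @export
sample_cohort <- function(gen, n_subjects, seed) {
  stopifnot(inherits(gen, "generator_function"), n_subjects >= 1L)
  u <- .subject_uniforms(seed, n_subjects, gen$n_regions)
  m <- matrix(as.integer(u < rep(gen$probs, each = n_subjects)),
              nrow = n_subjects,
              dimnames = list(sprintf("S%d", seq_len(n_subjects)),
                              sprintf("R%d", seq_len(gen$n_regions))))
  simulated_cohort(m, gen$region_size, "ALTERED", gen, seed)
}

#' @rdname sample_cohort
#' @param object A [generator_function()] (S3 `simulate` method).
#' @param nsim Number of cohorts to draw.
#' @param ... Unused.
#' @export
simulate.generator_function <- function(object, nsim = 1, seed = NULL,
                                        n_subjects, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- lapply(seq_len(nsim) - 1L, function(k) {
    sample_cohort(object, n_subjects, seed + k)
  })
  if (nsim == 1L) out[[1L]] else out
}

#' Convert a cohort status matrix to altered segments
#'
#' Each altered cell (subject s, region r) becomes one segment covering
#' exactly that region, `[(r-1) * region_size, r * region_size)` in 0-based
#' half-open coordinates. Runs of contiguous altered regions are emitted as
#' separate book-ended segments, not merged — mirroring how per-region calls
#' arrive with individual starts and ends in real segmented data. The
#' partition sweep keeps book-ended same-subject segments separate, and
#' occurrence counts are unaffected by merging either way.
#'
#' @param cohort A `simulated_cohort`.
#' @param chromosome Chromosome label assigned to all segments.
#' @return Altered-segment data frame ordered by subject then start.
#' @export
matrix_to_segments <- function(cohort, chromosome = "1") {
  stopifnot(inherits(cohort, "simulated_cohort"))
  m <- cohort$matrix
  rs <- cohort$generator$region_size
  idx <- which(m == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(
    sample_id = rownames(m)[idx[, "row"]],
    chromosome = rep(chromosome, nrow(idx)),
    start = (idx[, "col"] - 1) * rs,
    end = idx[, "col"] * rs,
    call = rep(cohort$call, nrow(idx)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Draw a three-state (gain / loss / normal) cohort
#'
#' Per cell, one of gain, loss or normal is drawn with the probabilities of
#' the two generator functions (which must agree in region count and size and
#' satisfy `gain + loss <= 1` per region): the subject's uniform draw u gives
#' a gain when `u < p_gain`, a loss when `p_gain <= u < p_gain + p_loss`, and
#' normal otherwise. A cell is never both. With `gain = 0` everywhere the
#' loss matrix is identical to a two-state [sample_cohort()] run with the
#' loss generator and the same seed.
#'
#' @param gen_gain,gen_loss Gain and loss [generator_function()]s.
#' @param n_subjects Cohort size.
#' @param seed Integer root seed (same discipline as [sample_cohort()]).
#' @return List of two `simulated_cohort`s, `gain` and `loss`.
#' @export
three_state_cohort <- function(gen_gain, gen_loss, n_subjects, seed) {
  stopifnot(inherits(gen_gain, "generator_function"),
            inherits(gen_loss, "generator_function"),
            gen_gain$n_regions == gen_loss$n_regions,
            gen_gain$region_size == gen_loss$region_size)
  tot <- gen_gain$probs + gen_loss$probs
  if (any(tot > 1)) {
    stop("domain error: gain + loss probability exceeds 1 at region ",
         which(tot > 1)[1L], call. = FALSE)
  }
  u <- .subject_uniforms(seed, n_subjects, gen_gain$n_regions)
  pg <- rep(gen_gain$probs, each = n_subjects)
  pl <- rep(gen_loss$probs, each = n_subjects)
  dims <- list(sprintf("S%d", seq_len(n_subjects)),
               sprintf("R%d", seq_len(gen_gain$n_regions)))
  mg <- matrix(as.integer(u < pg), nrow = n_subjects, dimnames = dims)
  ml <- matrix(as.integer(u >= pg & u < pg + pl), nrow = n_subjects, dimnames = dims)
  list(gain = simulated_cohort(mg, gen_gain$region_size, "GAIN", gen_gain, seed),
       loss = simulated_cohort(ml, gen_loss$region_size, "LOSS", gen_loss, seed))
}

#' Convert altered segments to SEG records
#'
#' Gives simulated segments the remaining SEG columns so they can be written
#' with [write_seg()] and exercised through the full I/O path: segment mean
#' +1 for gains (and generic alterations), -1 for losses, and a probe count
#' of one probe per kb of segment length (minimum 1).
#'
#' @param segments Altered-segment data frame.
#' @return SEG record data frame accepted by [write_seg()].
#' @export
as_seg_records <- function(segments) {
  data.frame(
    sample_id = segments$sample_id,
    chromosome = segments$chromosome,
    start = segments$start,
    end = segments$end,
    num_probes = pmax(1L, as.integer(floor((segments$end - segments$start) / 1000))),
    seg_mean = ifelse(segments$call == "LOSS", -1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a generator function from a YAML or JSON config
#'
#' The config holds `probs` (list of probabilities), optional `region_size`
#' (default 1000) and optional `label`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [generator_function()].
#' @export
read_generator <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$probs)) stop("generator config must contain 'probs'", call. = FALSE)
  generator_function(unlist(cfg$probs),
                     region_size = cfg$region_size %||% 1000,
                     label = cfg$label %||% NULL)
}
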