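# Shared fixtures and brute-force oracles.

# five-subject, five-region worked example: binary status matrix (1 kb regions)
example_matrix <- function() {
  rbind(S1 = c(0, 0, 0, 0, 1),
        S2 = c(0, 0, 0, 1, 1),
        S3 = c(0, 1, 1, 1, 0),
        S4 = c(0, 0, 0, 1, 1),
        S5 = c(0, 0, 1, 0, 1))
}

# the ten segments the worked-example matrix expands to (book-ended, unmerged)
example_segments <- function() {
  data.frame(
    sample_id = c("S1", "S2", "S2", "S3", "S3", "S3", "S4", "S4", "S5", "S5"),
    chromosome = "1",
    start = c(4000, 3000, 4000, 1000, 2000, 3000, 3000, 4000, 2000, 4000),
    end   = c(5000, 4000, 5000, 2000, 3000, 4000, 4000, 5000, 3000, 5000),
    call = "ALTERED", stringsAsFactors = FALSE
  )
}

# five example patient profiles over ten regions
example_f_vectors <- function() {
  rbind(f1 = c(0, 1, 1, 1, 0, 0, 0, 0, 0, 0),
        f2 = c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
        f3 = c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0),
        f4 = c(0, 1, 0, 1, 1, 0, 0, 0, 0, 0),
        f5 = c(0, 1, 0, 1, 1, 1, 0, 0, 0, 0))
}

peak_phi <- c(0, 0.2, 0.7, 0.8, 0.6, 0.4, 0.1, 0, 0, 0)

# brute-force per-base oracle: number of distinct subjects covering each base
# (base b, 1-indexed, is the half-open interval [b-1, b))
base_coverage <- function(segments, max_pos = max(segments$end)) {
  cov <- integer(max_pos)
  for (sid in unique(segments$sample_id)) {
    mask <- logical(max_pos)
    s <- segments[segments$sample_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(s))) mask[(s$start[i] + 1):s$end[i]] <- TRUE
    cov <- cov + as.integer(mask)
  }
  cov
}

# random altered-segment instances for property tests
random_segments <- function(n_subjects, max_segments = 6, max_pos = 1000,
                            chromosome = "1", call = "ALTERED") {
  rows <- lapply(seq_len(n_subjects), function(s) {
    k <- sample.int(max_segments, 1)
    start <- sort(sample.int(max_pos - 1, k))
    len <- sample.int(max_pos %/% 4, k, replace = TRUE)
    data.frame(sample_id = sprintf("S%02d", s), chromosome = chromosome,
               start = start, end = pmin(start + len, max_pos),
               call = call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
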