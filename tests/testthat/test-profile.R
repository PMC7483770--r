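f_profile <- function(conf_level = 0.95, ci_method = "wilson") {
  cohort <- simulated_cohort(example_f_vectors(), region_size = 1000)
  cna_profile(matrix_to_segments(cohort), n_subjects = 5,
              conf_level = conf_level, ci_method = ci_method, merge = FALSE)
}

test_that("the estimator recovers the column means of the five example patient vectors", {
  fit <- f_profile()
  gen_grid <- generator_function(rep(0, 10), region_size = 1000)
  est <- phi_on_grid(fit, generator = gen_grid)
  expect_equal(est, c(0, 0.6, 0.6, 1.0, 0.6, 0.2, 0, 0, 0, 0))
  # region 1: no patient altered -> probability 0 (a gap, phat 0 on the grid)
  expect_equal(est[1], 0)
  # region 4: every patient altered -> probability 1
  expect_equal(est[4], 1.0)
  # phat is an exact integer ratio
  expect_true(all(fit$regions$phat * 5 == round(fit$regions$phat * 5)))
})

test_that("estimate_profile validates its domain", {
  regions <- data.frame(chromosome = "1", start = 0, end = 10, call = "ALTERED",
                        n_occurrences = 3L)
  expect_error(estimate_profile(regions, 0), "domain error")
  expect_error(estimate_profile(regions, 2), "consistency error")
})

test_that("confidence bounds bracket phat, stay in [0,1], and behave at the extremes", {
  for (method in c("wilson", "wald", "clopper-pearson")) {
    x <- 0:20
    ci <- proportion_ci(x, 20, 0.95, method)
    p <- x / 20
    expect_true(all(ci[, "low"] >= 0 & ci[, "low"] <= p), info = method)
    expect_true(all(ci[, "high"] <= 1 & ci[, "high"] >= p), info = method)
    if (method != "wald") {
      # wilson and clopper-pearson stay non-degenerate at phat = 0 and 1
      # (the wald interval collapses there, which is why it is not the default)
      expect_gt(ci[1, "high"], 0)
      expect_lt(ci[21, "low"], 1)
    }
  }
})

test_that("Wilson band width shrinks monotonically as the cohort grows", {
  widths <- sapply(c(50, 100, 200), function(n) {
    ci <- proportion_ci(round(0.3 * n), n, 0.95, "wilson")
    ci[, "high"] - ci[, "low"]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("harmonize_profiles puts both groups on the pooled boundary set", {
  a <- data.frame(sample_id = "A1", chromosome = "1", start = 0, end = 100,
                  call = "ALTERED", stringsAsFactors = FALSE)
  b <- data.frame(sample_id = "B1", chromosome = "1", start = 50, end = 150,
                  call = "ALTERED", stringsAsFactors = FALSE)
  pair <- harmonize_profiles(a, b, n_a = 1, n_b = 1)
  expect_equal(pair$a$regions$start, c(0, 50, 100))
  expect_equal(pair$a$regions$end, c(50, 100, 150))
  expect_equal(pair$a$regions$phat, c(1, 1, 0))
  expect_equal(pair$b$regions$phat, c(0, 1, 1))
  expect_error(harmonize_profiles(a[0, ], b), "domain error.*A")
})

test_that("per-group mass is conserved on the pooled partition", {
  set.seed(31)
  for (rep in 1:5) {
    a <- merge_subject_segments(random_segments(6, max_pos = 500))
    b <- merge_subject_segments(random_segments(4, max_pos = 500))
    pair <- harmonize_profiles(a, b, n_a = 6, n_b = 4)
    len <- pair$a$regions$end - pair$a$regions$start
    expect_equal(sum(pair$a$regions$n_occurrences * len), sum(base_coverage(a, 500)))
    expect_equal(sum(pair$b$regions$n_occurrences * len), sum(base_coverage(b, 500)))
  }
})

test_that("identical groups give identical profiles and zero distance", {
  a <- merge_subject_segments(random_segments(5, max_pos = 400))
  pair <- harmonize_profiles(a, a, n_a = 5, n_b = 5)
  cmp <- compare_profiles(pair$a, pair$b)
  expect_equal(cmp$distance, 0)
  expect_equal(cmp$n_differential, 0L)
})

test_that("disjoint confidence bands flag a region as differential", {
  regions <- data.frame(chromosome = "1", start = 0, end = 100, call = "ALTERED",
                        n_occurrences = 0L, stringsAsFactors = FALSE)
  mk <- function(phat, lo, hi, n) {
    p <- estimate_profile(transform(regions, n_occurrences = as.integer(phat * n)), n)
    p$regions$phat <- phat; p$regions$ci_low <- lo; p$regions$ci_high <- hi
    p
  }
  a <- mk(0.6, 0.5, 0.7, 100)
  b <- mk(0.2, 0.1, 0.3, 100)
  cmp <- compare_profiles(a, b)
  expect_true(cmp$regions$differential)
  expect_equal(cmp$distance, 0.4)
  # mismatched region sets are a consistency error
  bad <- mk(0.2, 0.1, 0.3, 100)
  bad$regions$end <- 200
  expect_error(compare_profiles(a, bad), "consistency error")
})

test_that("under the null, few regions are flagged differential", {
  # two groups drawn from one generator: the band-overlap rule should flag
  # regions at well below the nominal error rate
  gen <- generator_function(peak_phi, region_size = 1000)
  flagged <- 0; total <- 0
  for (k in 1:10) {
    ca <- sample_cohort(gen, 500, seed = 800 + k)
    cb <- sample_cohort(gen, 500, seed = 900 + k)
    pair <- harmonize_profiles(matrix_to_segments(ca), matrix_to_segments(cb),
                               n_a = 500, n_b = 500, merge = FALSE)
    cmp <- compare_profiles(pair$a, pair$b)
    flagged <- flagged + cmp$n_differential
    total <- total + nrow(cmp$regions)
  }
  expect_lte(flagged / total, 2 * 0.05)
})

test_that("the profile distance is a pseudometric on random triples", {
  set.seed(77)
  gen <- generator_function(runif(8), region_size = 100)
  profs <- lapply(1:3, function(k) {
    co <- sample_cohort(gen, 30, seed = 50 + k)
    cna_profile(matrix_to_segments(co), n_subjects = 30, merge = FALSE)
  })
  # harmonize all three pairwise via a shared grid
  grid_phat <- lapply(profs, phi_on_grid, generator = gen)
  d <- function(x, y) mean(abs(x - y))  # equal region sizes -> plain mean
  d12 <- d(grid_phat[[1]], grid_phat[[2]])
  d13 <- d(grid_phat[[1]], grid_phat[[3]])
  d23 <- d(grid_phat[[2]], grid_phat[[3]])
  expect_equal(d12, d(grid_phat[[2]], grid_phat[[1]]))
  expect_equal(d(grid_phat[[1]], grid_phat[[1]]), 0)
  expect_lte(d13, d12 + d23 + 1e-12)
})

test_that("stratified subsampling rounds quotas by largest remainder and is reproducible", {
  labels <- setNames(c(rep("neg", 423), rep("pos", 99)),
                     sprintf("P%03d", 1:522))
  segs <- data.frame(sample_id = names(labels), chromosome = "1",
                     start = 0, end = 100, call = "ALTERED",
                     stringsAsFactors = FALSE)
  sub <- stratified_subsample(segs, labels, n = 200, seed = 4)
  expect_equal(length(sub$sample_ids), 200)
  expect_equal(unname(table(sub$group_labels)["neg"]), 162, ignore_attr = TRUE)
  expect_equal(unname(table(sub$group_labels)["pos"]), 38, ignore_attr = TRUE)
  # determinism
  sub2 <- stratified_subsample(segs, labels, n = 200, seed = 4)
  expect_identical(sort(sub$sample_ids), sort(sub2$sample_ids))
  # identity draw
  all_in <- stratified_subsample(segs, labels, n = 522, seed = 1)
  expect_setequal(all_in$sample_ids, names(labels))
  expect_error(stratified_subsample(segs, labels, n = 523, seed = 1),
               "domain error")
})

test_that("fitted-profile methods are coherent", {
  fit <- f_profile()
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)), fit$regions$phat)
  ci <- confint(fit)
  expect_equal(unname(ci[, "low"]), fit$regions$ci_low)
  wide <- confint(fit, level = 0.99)
  expect_true(all(wide[, "high"] - wide[, "low"] >= ci[, "high"] - ci[, "low"]))
  # predict: inside regions, in gaps, off-chromosome
  p <- predict(fit, data.frame(chromosome = c("1", "1", "2"),
                               position = c(3500, 50, 3500)))
  expect_equal(p, c(1.0, 0, 0))
  sims <- simulate(fit, nsim = 2, seed = 9, n_subjects = 10)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:1))
  expect_equal(dim(sims[[1]]), c(10L, nrow(fit$regions)))
  expect_output(print(fit), "common regions")
  expect_output(print(summary(fit)), "regions over")
})
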