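# End-to-end pipeline: SEG -> filter/call -> per-subject merge -> partition
# -> profile (per group when labels are given) -> comparison -> tables and
# plots, with a machine-readable run manifest.

#' Write a fitted profile as TSV
#'
#' One row per common region with columns `chromosome`, `start`, `end`,
#' `call`, `n_occurrences`, `n_subjects`, `phat`, `ci_low`, `ci_high`,
#' `group`.
#'
#' @param profile A fitted [cna_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  df <- df[, c("chromosome", "start", "end", "call", "n_occurrences",
               "n_subjects", "phat", "ci_low", "ci_high", "group")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group comparison as TSV
#'
#' Per-region table of both groups' estimates and the `differential` flag; a
#' comment line at the top carries the summary (distance, counts).
#'
#' @param comparison A [compare_profiles()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s vs %s: distance=%.6g differential=%d/%d conf_level=%g",
                     comparison$groups["a"], comparison$groups["b"],
                     comparison$distance, comparison$n_differential,
                     nrow(comparison$regions), comparison$conf_level), con)
  utils::write.table(comparison$regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(min_probes = 10L, gain_threshold = 0.2,
                   loss_threshold = -0.2, mode = "separate",
                   conf_level = 0.95, ci_method = "wilson",
                   seed = 1L, plot = TRUE, out_dir = "cnaprofiler_out")
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$seg_file)) stop("config must name a 'seg_file'", call. = FALSE)
  config
}

#' Run the full profiling pipeline
#'
#' Executes read -> filter/call -> per-subject merge -> per-chromosome
#' partition -> profile estimation (per phenotypic group when a label table
#' is given) -> group comparison -> tables and plots, logging per-stage
#' record counts, and writes a JSON run manifest listing every output with
#' the settings that produced it. Identical config and seed give
#' byte-identical tables.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list. Fields: `seg_file` (required), `labels_file` (optional two-column
#'   TSV, sample id then group, exactly two groups), `min_probes`,
#'   `gain_threshold`, `loss_threshold`, `mode` (`"separate"`/`"combined"`),
#'   `conf_level`, `ci_method`, `seed`, `plot`, `out_dir`.
#' @param out_dir Output directory; overrides the config field.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- .read_pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  warnings_log <- character(0)
  note <- function(fmt, ...) message(sprintf(fmt, ...))

  records <- read_seg(cfg$seg_file)
  note("read: %d segment records, %d subjects", nrow(records),
       length(unique(records$sample_id)))
  fc <- filter_config(cfg$min_probes, cfg$gain_threshold, cfg$loss_threshold,
                      cfg$mode)
  called <- filter_and_call(records, fc)
  note("filtered/called: %d altered segments (GAIN %d, LOSS %d, ALTERED %d)",
       nrow(called), sum(called$call == "GAIN"), sum(called$call == "LOSS"),
       sum(called$call == "ALTERED"))

  labels <- NULL
  if (!is.null(cfg$labels_file)) {
    lab_df <- utils::read.delim(cfg$labels_file, header = FALSE,
                                col.names = c("sample_id", "group"),
                                colClasses = "character")
    labels <- stats::setNames(lab_df$group, lab_df$sample_id)
    missing_in_seg <- setdiff(names(labels), records$sample_id)
    if (length(missing_in_seg) > 0L) {
      w <- paste("labelled subjects absent from SEG input:",
                 paste(missing_in_seg, collapse = ", "))
      warning(w, call. = FALSE)
      warnings_log <- c(warnings_log, w)
    }
    unlabelled <- setdiff(unique(called$sample_id), names(labels))
    if (length(unlabelled) > 0L) {
      w <- paste("unlabelled subjects excluded:",
                 paste(unlabelled, collapse = ", "))
      warning(w, call. = FALSE)
      warnings_log <- c(warnings_log, w)
      called <- called[called$sample_id %in% names(labels), , drop = FALSE]
    }
  }

  add_output <- function(file, what) {
    outputs[[length(outputs) + 1L]] <<- list(file = basename(file), what = what)
    file
  }

  if (nrow(called) == 0L) {
    note("no altered segments after filtering; writing empty manifest")
    manifest <- list(inputs = list(seg_file = cfg$seg_file,
                                   labels_file = cfg$labels_file),
                     settings = cfg, seed = cfg$seed,
                     versions = list(r = R.version.string,
                                     cnaprofiler = as.character(utils::packageVersion("cnaprofiler"))),
                     note = "empty result: zero altered segments after filtering",
                     warnings = warnings_log, outputs = list())
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    return(invisible(manifest))
  }

  merged <- merge_cohort_segments(called)
  note("merged per subject: %d segments", nrow(merged))

  profiles <- list()
  comparison <- NULL
  if (is.null(labels)) {
    n_sub <- length(unique(records$sample_id))
    fit <- cna_profile(merged, n_subjects = n_sub, conf_level = cfg$conf_level,
                       ci_method = cfg$ci_method, group_label = "cohort",
                       merge = FALSE)
    profiles <- list(cohort = fit)
  } else {
    groups <- sort(unique(labels[names(labels) %in% records$sample_id]))
    if (length(groups) != 2L) {
      stop("label table must define exactly two groups, got ",
           length(groups), call. = FALSE)
    }
    ids_a <- names(labels)[labels == groups[1L]]
    ids_b <- names(labels)[labels == groups[2L]]
    pair <- harmonize_profiles(
      merged[merged$sample_id %in% ids_a, , drop = FALSE],
      merged[merged$sample_id %in% ids_b, , drop = FALSE],
      n_a = length(ids_a), n_b = length(ids_b), labels = groups,
      conf_level = cfg$conf_level, ci_method = cfg$ci_method, merge = FALSE)
    profiles <- stats::setNames(list(pair$a, pair$b), groups)
    comparison <- compare_profiles(pair$a, pair$b)
    note("comparison: %d/%d differential regions, distance %.4f",
         comparison$n_differential, nrow(comparison$regions),
         comparison$distance)
  }

  regions_all <- do.call(rbind, lapply(profiles, function(p) p$regions))
  write_regions_bed(unique(regions_all[, c("chromosome", "start", "end",
                                           "call", "n_occurrences")]),
                    add_output(file.path(cfg$out_dir, "regions.bed"),
                               "common regions (BED4+1)"))
  note("regions emitted: %d", nrow(profiles[[1L]]$regions))
  for (g in names(profiles)) {
    write_profile_tsv(profiles[[g]],
                      add_output(file.path(cfg$out_dir,
                                           sprintf("profile_%s.tsv", g)),
                                 sprintf("probability profile, group %s", g)))
  }
  if (!is.null(comparison)) {
    write_comparison_tsv(comparison,
                         add_output(file.path(cfg$out_dir, "comparison.tsv"),
                                    "group comparison"))
  }
  if (isTRUE(cfg$plot)) {
    plot_file <- add_output(file.path(cfg$out_dir, "profile_genome.png"),
                            "genome-wide profile plot")
    grDevices::png(plot_file, width = 1200, height = 500)
    plot_profile(unname(profiles))
    grDevices::dev.off()
  }

  manifest <- list(
    inputs = list(seg_file = cfg$seg_file, labels_file = cfg$labels_file),
    settings = cfg[c("min_probes", "gain_threshold", "loss_threshold", "mode",
                     "conf_level", "ci_method")],
    seed = cfg$seed,
    versions = list(r = R.version.string,
                    cnaprofiler = as.character(utils::packageVersion("cnaprofiler"))),
    counts = list(records = nrow(records), called = nrow(called),
                  merged = nrow(merged),
                  regions = nrow(profiles[[1L]]$regions)),
    warnings = warnings_log,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
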