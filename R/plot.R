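# Step plots of alteration probability along the genome with shaded
# confidence bands; one trace per group, chromosomes concatenated with
# boundary ticks, losses optionally drawn as negative values.

.profile_list <- function(profiles) {
  if (inherits(profiles, "cna_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "cna_profile")))
  profiles
}

# per-chromosome x offsets so chromosomes concatenate along one axis
.chrom_offsets <- function(regions) {
  chroms <- unique(regions$chromosome)
  chroms <- chroms[order(.chrom_rank(chroms), chroms)]
  span <- vapply(chroms, function(c) max(regions$end[regions$chromosome == c]),
                 numeric(1))
  offsets <- c(0, cumsum(span))[seq_along(chroms)]
  list(chroms = chroms, span = span, offsets = stats::setNames(offsets, chroms))
}

.band_colour <- function(col, alpha) {
  rgb <- grDevices::col2rgb(col) / 255
  grDevices::rgb(rgb[1], rgb[2], rgb[3], alpha)
}

.draw_trace <- function(regions, offsets, col, band_alpha, sign = 1) {
  if (nrow(regions) == 0L) return(invisible())
  x0 <- regions$start + offsets[regions$chromosome]
  x1 <- regions$end + offsets[regions$chromosome]
  band <- .band_colour(col, band_alpha)
  for (i in seq_len(nrow(regions))) {
    graphics::polygon(c(x0[i], x1[i], x1[i], x0[i]),
                      sign * c(regions$ci_low[i], regions$ci_low[i],
                               regions$ci_high[i], regions$ci_high[i]),
                      col = band, border = NA)
  }
  graphics::segments(x0, sign * regions$phat, x1, sign * regions$phat,
                     col = col, lwd = 2)
}

#' Plot probability-of-alteration profiles with confidence bands
#'
#' Draws each region's estimated probability as a horizontal step at its
#' genomic span with a shaded confidence band, one colour per group profile.
#' Genome scope concatenates chromosomes along the x axis with boundary
#' ticks; a single chromosome can be selected instead. In `"combined"`
#' layout, loss probabilities are drawn as negative values on a symmetric
#' axis so gains and losses read off one panel.
#'
#' @param profiles A fitted [cna_profile()] or a list of them (harmonized
#'   groups overlay in different colours).
#' @param chromosome Chromosome label to restrict to; `NULL` (default) plots
#'   the genome.
#' @param layout `"gains"`, `"losses"`, or `"combined"` (losses negative).
#'   Defaults to `"combined"` when both call types are present.
#' @param band_alpha Opacity of the shaded confidence bands.
#' @param colors One colour per profile.
#' @param main Plot title.
#' @param legend Draw a group legend when several profiles are given.
#' @return Invisibly, `NULL`. Called for its side effect on the active
#'   graphics device.
#' @export
plot_profile <- function(profiles, chromosome = NULL,
                         layout = c("auto", "gains", "losses", "combined"),
                         band_alpha = 0.3,
                         colors = c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728"),
                         main = NULL, legend = TRUE) {
  profiles <- .profile_list(profiles)
  layout <- match.arg(layout)
  all_reg <- do.call(rbind, lapply(profiles, function(p) p$regions))
  if (!is.null(chromosome)) {
    all_reg <- all_reg[all_reg$chromosome == chromosome, , drop = FALSE]
  }
  if (nrow(all_reg) == 0L) stop("nothing to plot: no regions in scope", call. = FALSE)
  calls <- unique(all_reg$call)
  if (layout == "auto") {
    layout <- if (all(calls == "GAIN")) "gains"
    else if (all(calls == "LOSS")) "losses"
    else "combined"
  }
  geo <- .chrom_offsets(all_reg)
  xmax <- sum(geo$span)
  ylim <- if (layout == "combined") c(-1, 1) else c(0, 1)
  graphics::plot(NA, xlim = c(0, xmax), ylim = ylim, xaxt = "n",
                 xlab = if (is.null(chromosome)) "chromosome" else
                   sprintf("chromosome %s position (bp)", chromosome),
                 ylab = "probability of alteration",
                 main = main %||% "Alteration probability profile")
  graphics::abline(h = 0, col = "grey40")
  if (is.null(chromosome)) {
    graphics::abline(v = geo$offsets[-1L], col = "grey80", lty = 3)
    graphics::axis(1, at = geo$offsets + geo$span / 2, labels = geo$chroms,
                   tick = FALSE, cex.axis = 0.8)
  } else {
    graphics::axis(1)
  }
  for (i in seq_along(profiles)) {
    reg <- profiles[[i]]$regions
    if (!is.null(chromosome)) reg <- reg[reg$chromosome == chromosome, , drop = FALSE]
    col <- colors[(i - 1L) %% length(colors) + 1L]
    if (layout == "gains") {
      .draw_trace(reg[reg$call %in% c("GAIN", "ALTERED"), , drop = FALSE],
                  geo$offsets, col, band_alpha)
    } else if (layout == "losses") {
      .draw_trace(reg[reg$call %in% c("LOSS", "ALTERED"), , drop = FALSE],
                  geo$offsets, col, band_alpha)
    } else {
      .draw_trace(reg[reg$call != "LOSS", , drop = FALSE],
                  geo$offsets, col, band_alpha, sign = 1)
      .draw_trace(reg[reg$call == "LOSS", , drop = FALSE],
                  geo$offsets, col, band_alpha, sign = -1)
    }
  }
  if (legend && length(profiles) > 1L) {
    labs <- vapply(seq_along(profiles), function(i) {
      profiles[[i]]$group_label %||% sprintf("group %d", i)
    }, "")
    graphics::legend("topright", legend = labs, bty = "n", lwd = 2,
                     col = colors[seq_along(profiles)])
  }
  invisible(NULL)
}

#' @export
plot.cna_profile <- function(x, y = NULL, ...) {
  profiles <- if (inherits(y, "cna_profile")) list(x, y) else x
  plot_profile(profiles, ...)
}
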