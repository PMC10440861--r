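# Per-sample profile bar charts and breakpoint rainfall plots. Data assembly
# is separated from rendering so tests can assert numbers rather than pixels.

.SV_TYPE_COLORS <- c(del = "#E8522A", tds = "#2C7FB8", inv = "#31A354",
                     trans = "#756BB1")
.CN_STATE_COLORS <- c(homdel = "#5E4FA2", LOH = "#D53E4F", het = "#3288BD")

#' Bar data behind a sample's profile plot
#'
#' Returns, for one sample, the per-channel counts together with the grouping
#' used for plotting: for CN48, heterozygosity state and total-copy-number
#' class (size bins run within groups); for SV32, clustered status and event
#' type. [plot_profile()] draws exactly these heights.
#'
#' @param matrix A \code{channel_matrix}.
#' @param sample Sample identifier (must be a column of \code{matrix}).
#' @return A data.frame with columns \code{channel}, \code{count},
#'   \code{group} (bar-group label), and \code{color}.
#' @export
profile_data <- function(matrix, sample) {
  stopifnot(inherits(matrix, "channel_matrix"))
  if (!sample %in% colnames(matrix)) {
    stop("sample '", sample, "' not present in matrix", call. = FALSE)
  }
  channels <- rownames(matrix)
  counts <- as.integer(matrix[, sample])
  if (attr(matrix, "schema") == "CN48") {
    parts <- strsplit(channels, ":", fixed = TRUE)
    state <- vapply(parts, `[`, "", 2)
    tcn <- vapply(parts, `[`, "", 1)
    data.frame(channel = channels, count = counts,
               group = paste(state, tcn),
               color = unname(.CN_STATE_COLORS[state]),
               stringsAsFactors = FALSE)
  } else {
    cl <- ifelse(startsWith(channels, "clustered"), "clustered",
                 "non-clustered")
    svtype <- vapply(strsplit(sub("^(non-)?clustered_", "", channels), "_"),
                     `[`, "", 1)
    data.frame(channel = channels, count = counts,
               group = paste(cl, svtype),
               color = unname(.SV_TYPE_COLORS[svtype]),
               stringsAsFactors = FALSE)
  }
}

.open_device <- function(out, format, width, height) {
  switch(format,
         png = grDevices::png(out, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(out, width = width, height = height),
         stop("format must be 'png' or 'pdf'", call. = FALSE))
}

#' Plot a per-sample channel profile
#'
#' Draws the sample's count vector as a bar chart with one bar per channel in
#' canonical order. CN48 bars are colored by heterozygosity state and grouped
#' by total-copy-number class with size bins within groups; SV32 bars are
#' grouped clustered vs non-clustered and colored by event type.
#'
#' @inheritParams profile_data
#' @param out Output file path.
#' @param format \code{"png"} or \code{"pdf"}.
#' @return The plotted data (as from [profile_data()]), invisibly.
#' @export
plot_profile <- function(matrix, sample, out, format = c("png", "pdf")) {
  format <- match.arg(format)
  pd <- profile_data(matrix, sample)
  .open_device(out, format, width = 12, height = 4)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(8, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylim <- c(0, max(pd$count, 1) * 1.15)
  mids <- graphics::barplot(pd$count, col = pd$color, border = NA,
                            ylim = ylim, las = 2, names.arg = pd$channel,
                            cex.names = 0.55, ylab = "Number of events",
                            main = sample)
  # separators between bar groups
  brk <- which(pd$group[-1] != pd$group[-nrow(pd)])
  if (length(brk) > 0) {
    graphics::abline(v = (mids[brk] + mids[brk + 1]) / 2,
                     col = "grey70", lty = 2)
  }
  grp <- split(seq_len(nrow(pd)), pd$group)
  for (g in names(grp)) {
    graphics::mtext(g, side = 3, line = 0, cex = 0.55,
                    at = mean(mids[grp[[g]]]))
  }
  invisible(pd)
}

#' Rainfall data for one sample's SV breakpoints
#'
#' @param records SV records as returned by [read_bedpe()], single sample.
#' @return A data.frame with one row per breakpoint: \code{chromosome},
#'   \code{position}, \code{imd}, \code{log10_imd} (\code{log10(imd + 1)}),
#'   and \code{svtype} of the parent record. Breakpoints without a defined
#'   IMD (single-breakpoint chromosomes) are dropped.
#' @export
rainfall_data <- function(records) {
  stopifnot(nrow(records) > 0, length(unique(records$sample)) == 1)
  bp <- .breakpoint_table(records)
  bp$svtype <- records$svclass[bp$record]
  out <- do.call(rbind, lapply(split(bp, bp$chromosome), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    d$imd <- compute_imd(d$position)
    d
  }))
  out <- out[is.finite(out$imd), , drop = FALSE]
  out$log10_imd <- log10(out$imd + 1)
  rownames(out) <- NULL
  out[, c("chromosome", "position", "imd", "log10_imd", "svtype")]
}

#' Plot rainfall panels of SV breakpoints
#'
#' One panel per chromosome carrying breakpoints: x is the breakpoint
#' coordinate, y is log10 of the inter-mutational distance, points colored by
#' SV type. Runs of low points reveal clustered rearrangements.
#'
#' @inheritParams rainfall_data
#' @param out Output file path.
#' @param format \code{"png"} or \code{"pdf"}.
#' @return The plotted data (as from [rainfall_data()]), invisibly.
#' @export
plot_rainfall <- function(records, out, format = c("png", "pdf")) {
  format <- match.arg(format)
  rd <- rainfall_data(records)
  chroms <- intersect(.CHROMS, unique(rd$chromosome))
  n <- max(length(chroms), 1)
  .open_device(out, format, width = 10, height = 2.2 * n)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(n, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (ch in chroms) {
    d <- rd[rd$chromosome == ch, , drop = FALSE]
    graphics::plot(d$position / 1e6, d$log10_imd,
                   pch = 16, cex = 0.8,
                   col = .SV_TYPE_COLORS[d$svtype],
                   xlab = "Position (Mb)", ylab = "log10 IMD",
                   main = paste0("chr", ch, " (", records$sample[1], ")"))
  }
  invisible(rd)
}
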