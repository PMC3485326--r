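# Trajectory reporting: calibrated allele frequencies per locus over an
# ordered series of timepoints, the shape in which experimental-evolution
# time courses are read and plotted.

#' Build a trajectory table from frequency estimates
#'
#' Joins per-sample frequency estimates with a pool layout mapping each
#' sample to its (locus, timepoint) cell.  Timepoints keep the order in
#' which they appear in `layout`.  With `sparse = FALSE` (default) a missing
#' (locus, timepoint) cell is an error; with `sparse = TRUE` missing cells
#' are omitted with a message.
#'
#' @param estimates Data frame from [estimate_frequencies()].
#' @param layout Data frame with columns `sample_id`, `locus`, `timepoint`.
#' @param sparse Allow missing cells.
#' @return Object of class `freq_trajectory`: data frame with columns
#'   `locus`, `allele`, `timepoint`, `n_allele`, `n_total`, `freq`,
#'   `ci_low`, `ci_high` and (when present in `estimates`)
#'   `calibrated_freq`.
#' @export
trajectory_table <- function(estimates, layout, sparse = FALSE) {
  stopifnot(is.data.frame(estimates), is.data.frame(layout),
            all(c("sample_id", "locus", "timepoint") %in% names(layout)))
  key <- paste(estimates$sample_id, estimates$locus, estimates$allele,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("conflicting duplicate (sample, locus, allele) rows in estimates",
         call. = FALSE)
  }
  out <- merge(layout[c("sample_id", "locus", "timepoint")], estimates,
               by = c("sample_id", "locus"), sort = FALSE)
  missing_cells <- layout[!layout$sample_id %in% out$sample_id, , drop = FALSE]
  if (nrow(missing_cells)) {
    msg <- paste0(missing_cells$locus, "@", missing_cells$timepoint,
                  collapse = ", ")
    if (!sparse) {
      stop("no estimates for cells: ", msg,
           " (use sparse = TRUE to omit them)", call. = FALSE)
    }
    message("omitting cells without estimates: ", msg)
  }
  tp_order <- unique(layout$timepoint)
  out <- out[order(match(out$locus, unique(layout$locus)),
                   match(out$timepoint, tp_order), out$allele), ]
  keep <- intersect(c("locus", "allele", "timepoint", "n_allele", "n_total",
                      "freq", "ci_low", "ci_high", "calibrated_freq"),
                    names(out))
  out <- out[keep]
  rownames(out) <- NULL
  class(out) <- c("freq_trajectory", "data.frame")
  out
}

#' Write a trajectory report (CSV and optional figure)
#'
#' @param traj A `freq_trajectory` (or the inputs of [trajectory_table()]
#'   via `estimates` + `layout`).
#' @param csv Output CSV path (`NULL` to skip).
#' @param plot_file Optional PNG/SVG path for a lines-per-allele trajectory
#'   figure; uses `calibrated_freq` where available, `freq` otherwise.
#' @param estimates,layout Alternative inputs if `traj` is missing.
#' @param sparse Passed to [trajectory_table()].
#' @return The trajectory table, invisibly.
#' @export
write_report <- function(traj = NULL, csv = NULL, plot_file = NULL,
                         estimates = NULL, layout = NULL, sparse = FALSE) {
  if (is.null(traj)) {
    traj <- trajectory_table(estimates, layout, sparse = sparse)
  }
  stopifnot(inherits(traj, "freq_trajectory"))
  if (!is.null(csv)) {
    write.csv(as.data.frame(traj), csv, row.names = FALSE)
  }
  if (!is.null(plot_file)) {
    ext <- tolower(tools::file_ext(plot_file))
    dev <- switch(ext, png = grDevices::png, svg = grDevices::svg,
                  stop("unsupported figure format: ", ext, call. = FALSE))
    if (ext == "png") dev(plot_file, width = 900, height = 600)
    else dev(plot_file, width = 9, height = 6)
    on.exit(grDevices::dev.off())
    plot(traj)
  }
  invisible(traj)
}

#' @export
plot.freq_trajectory <- function(x, ...) {
  y <- if ("calibrated_freq" %in% names(x)) x$calibrated_freq else x$freq
  tps <- unique(x$timepoint)
  xi <- match(x$timepoint, tps)
  series <- interaction(x$locus, x$allele, drop = TRUE)
  cols <- grDevices::hcl.colors(nlevels(series), "Dark 3")
  plot(NA, xlim = range(xi), ylim = c(0, 1), xaxt = "n",
       xlab = "timepoint", ylab = "allele frequency", ...)
  graphics::axis(1, at = seq_along(tps), labels = tps)
  for (k in seq_len(nlevels(series))) {
    i <- as.integer(series) == k
    o <- order(xi[i])
    graphics::lines(xi[i][o], y[i][o], col = cols[k], lwd = 2)
    graphics::points(xi[i][o], y[i][o], col = cols[k], pch = 16)
  }
  graphics::legend("topleft", legend = levels(series), col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}
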