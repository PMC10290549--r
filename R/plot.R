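# Figures for the five standard views of a clustered ensemble. All plot
# functions draw from already-computed tables/objects; they never recompute
# statistics, so figures always agree with the exported TSVs.

#' Plot mean time courses with fluctuation envelopes
#'
#' One line per observable (mean across trials) with a shaded mean +/- sd
#' envelope.
#'
#' @param x a [timecourse_stats()] object.
#' @param observables which observables to draw (default all).
#' @param col line colors, recycled.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_timecourse <- function(x, observables = names(x$mean),
                            col = grDevices::hcl.colors(max(length(observables), 2L),
                                                        "Dark 2"), ...) {
  if (!length(observables)) {
    graphics::plot.new()
    graphics::title(main = "no observables recorded")
    return(invisible(x))
  }
  hi <- max(vapply(observables, function(o)
    max(x$mean[[o]] + x$sd[[o]]), 0))
  graphics::plot(range(x$times), c(0, max(hi, 1)), type = "n",
                 xlab = "time", ylab = "observable (copies)", ...)
  for (i in seq_along(observables)) {
    o <- observables[i]
    up <- x$mean[[o]] + x$sd[[o]]
    lo <- pmax(x$mean[[o]] - x$sd[[o]], 0)
    graphics::polygon(c(x$times, rev(x$times)), c(up, rev(lo)),
                      col = grDevices::adjustcolor(col[i], 0.25),
                      border = NA)
    graphics::lines(x$times, x$mean[[o]], col = col[i], lwd = 2)
  }
  graphics::legend("topright", legend = observables, col = col[seq_along(observables)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot the occupancy distribution with ACO marker and binned inset
#'
#' Bars give the fraction of all molecules in each cluster size; the dashed
#' line marks the average cluster occupancy (ACO). When a binned
#' distribution is supplied it is drawn as an inset.
#'
#' @param occ data frame with `size` and `fraction` columns
#'   ([occupancy_distribution()] or its TSV read back).
#' @param aco average cluster occupancy to mark (default: the `aco`
#'   attribute if present).
#' @param binned optional [bin_distribution()] data frame for the inset.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, `occ`.
#' @export
plot_occupancy <- function(occ, aco = attr(occ, "aco"), binned = NULL, ...) {
  mids <- graphics::barplot(occ$fraction, names.arg = occ$size,
                            xlab = "cluster size (molecules)",
                            ylab = "fraction of molecules",
                            col = "steelblue", border = NA, ...)
  if (!is.null(aco) && nrow(occ) > 1L) {
    # map ACO onto the bar axis by interpolating between bar centers
    pos <- stats::approx(occ$size, mids, xout = aco, rule = 2)$y
    graphics::abline(v = pos, lty = 2, lwd = 2, col = "grey25")
    graphics::mtext(sprintf("ACO = %.3g", aco), side = 3, adj = 1,
                    cex = 0.8)
  }
  if (!is.null(binned) && nrow(binned) > 1L) {
    op <- graphics::par(fig = c(0.55, 0.98, 0.5, 0.95), new = TRUE,
                        mar = c(2, 2, 0.5, 0.5), cex = 0.6)
    on.exit(graphics::par(op), add = TRUE)
    graphics::barplot(binned$fraction, names.arg = binned$label,
                      col = "indianred", border = NA, las = 2)
  }
  invisible(occ)
}

#' Plot a bonds-per-molecule histogram
#'
#' @param bh data frame with `bonds` and `fraction` columns
#'   ([bond_histogram()] or its TSV read back).
#' @param scope label for the title (default: the `scope` attribute).
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, `bh`.
#' @export
plot_bond_histogram <- function(bh, scope = attr(bh, "scope"), ...) {
  graphics::barplot(bh$fraction, names.arg = bh$bonds,
                    xlab = "bonds per molecule", ylab = "fraction of molecules",
                    main = if (!is.null(scope)) paste("scope:", scope),
                    col = "darkseagreen4", border = NA, ...)
  mb <- attr(bh, "mean_bonds")
  if (!is.null(mb))
    graphics::mtext(sprintf("mean = %.3g", mb), side = 3, adj = 1, cex = 0.8)
  invisible(bh)
}

#' Plot the bound-fraction-by-size matrix as a heat map
#'
#' Color encodes the relative frequency of each (size bin, bound-fraction
#' bin) configuration, normalized within each size bin; a color bar is
#' drawn alongside.
#'
#' @param bm a [bf_matrix()] (or plain matrix with dimnames).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `bm`.
#' @export
plot_bf_matrix <- function(bm, ...) {
  m <- unclass(bm)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(1:2, 1L), widths = c(5, 1))
  graphics::par(mar = c(5, 5, 2, 1))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = pal, zlim = c(0, max(m, 1e-12)), axes = FALSE,
                  xlab = "cluster size bin", ylab = "bound fraction", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 1,
                 cex.axis = 0.6)
  graphics::box()
  graphics::par(mar = c(5, 1, 2, 3))
  zl <- seq(0, max(m, 1e-12), length.out = 65)
  graphics::image(x = 1, y = zl[-1], z = matrix(zl[-1], 1L), col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, las = 1, cex.axis = 0.7)
  invisible(bm)
}

#' Plot per-size cluster composition as stacked bars
#'
#' Each bar is one cluster size (bin); stacked segments give the fraction
#' of member molecules per molecule type (summing to 1).
#'
#' @param cmp a [composition_table()] (or plain matrix, types x sizes).
#' @param col one color per type.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, `cmp`.
#' @export
plot_composition <- function(cmp,
                             col = grDevices::hcl.colors(max(nrow(cmp), 2L),
                                                         "Set 2"), ...) {
  m <- unclass(cmp)
  graphics::barplot(m, col = col[seq_len(nrow(m))], border = NA, las = 2,
                    xlab = "cluster size (bin)",
                    ylab = "fraction of molecules",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(cmp)
}

#' @export
#' @rdname run_ensemble
#' @param x an `nf_ensemble` (for `plot`).
plot.nf_ensemble <- function(x, ...) {
  pool <- pool_clusters(x)
  occ <- occupancy_distribution(pool)
  plot_occupancy(occ,
                 binned = bin_distribution(
                   occ, default_size_breaks(max(occ$size))), ...)
}
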