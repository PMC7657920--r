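#' Assemble a component diagram
#'
#' A component diagram is the per-component multi-panel object behind the
#' study's figures: one small heatmap per active view, showing the
#' original (pre-scaling) difference values of the top-loading variables,
#' with the same pair order in every panel. Pairs are ordered by
#' descending posterior-mean component score, variables within a panel by
#' signed posterior-mean loading (descending).
#'
#' @param posterior a \code{gfa_posterior}.
#' @param views the difference views on their original scale (named list
#'   of \code{difference_view} objects or matrices, as passed to the
#'   sampler but before/instead of standardization).
#' @param k component index; must be active in at least one view.
#' @param top_n variables kept per panel (default 10).
#' @param threshold activity threshold (default 0.5).
#' @return an object of class \code{component_diagram}: `component`,
#'   `pair_order`, `score` (ordered posterior-mean scores) and `panels`
#'   (per active view: `variables`, `loadings`, `values` submatrix).
#' @export
assemble_component_diagram <- function(posterior, views, k, top_n = 10,
                                       threshold = 0.5) {
  act <- component_activity(posterior, threshold)
  if (k < 1 || k > ncol(act$active))
    tgfa_stop("tgfa_bad_component", sprintf("no component %s", k))
  active_views <- posterior$view_names[act$active[, k]]
  if (!length(active_views))
    tgfa_stop("tgfa_empty_component", sprintf(
      "component %d is empty (inactive in every view)", k))
  score <- posterior$Zmean[, k]
  ord <- order(score, decreasing = TRUE)
  pair_ids <- posterior$pair_ids[ord]
  vmat <- function(v) if (inherits(v, "difference_view")) v$values else
    as.matrix(v)
  panels <- lapply(active_views, function(vw) {
    w <- posterior$Wmean[[vw]][, k]
    sel <- order(abs(w), decreasing = TRUE)[seq_len(min(top_n, length(w)))]
    sel <- sel[order(w[sel], decreasing = TRUE)]
    vars <- posterior$var_names[[vw]][sel]
    vals <- vmat(views[[vw]])[ord, sel, drop = FALSE]
    rownames(vals) <- pair_ids
    colnames(vals) <- vars
    list(view = vw, variables = vars, loadings = w[sel], values = vals)
  })
  structure(list(component = k, pair_order = pair_ids, score = score[ord],
                 panels = setNames(panels, active_views)),
            class = "component_diagram")
}

#' @export
print.component_diagram <- function(x, ...) {
  cat(sprintf("component %d diagram: %d panels (%s), %d pairs\n",
              x$component, length(x$panels),
              paste(names(x$panels), collapse = ", "),
              length(x$pair_order)))
  invisible(x)
}

panel_plot <- function(panel) {
  vals <- panel$values
  df <- data.frame(
    pair = factor(rep(rownames(vals), ncol(vals)),
                  levels = rev(rownames(vals))),
    variable = factor(rep(colnames(vals), each = nrow(vals)),
                      levels = colnames(vals)),
    value = as.vector(vals))
  lim <- quantile(abs(df$value), 0.98, na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  df$value <- pmin(pmax(df$value, -lim), lim)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$pair,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim), name = "difference",
                                  # vector legend keeps svg output free of
                                  # rasters, so renders are byte-identical
                                  guide = ggplot2::guide_colourbar(
                                    display = "rectangles",
                                    ticks = FALSE)) +
    ggplot2::labs(title = panel$view, x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Render a component diagram as a multi-panel heatmap
#'
#' One heatmap per active view on a diverging palette centred at zero
#' (positive differences red, negative blue; symmetric range clipped at
#' the 98th percentile of absolute values per panel), one row per twin
#' pair, variable labels on the columns. The output format follows the
#' file extension (`.svg`, `.png` or `.pdf`); output is deterministic for
#' fixed input.
#'
#' @param diagram a [assemble_component_diagram()] result.
#' @param outfile output path.
#' @param width,height device size in inches.
#' @return invisibly, `outfile`.
#' @export
render_heatmaps <- function(diagram, outfile, width = 3 * length(diagram$panels),
                            height = 4) {
  dir <- dirname(outfile)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    tgfa_stop("tgfa_unwritable", sprintf("cannot write to %s", dir))
  plots <- lapply(diagram$panels, panel_plot)
  combined <- patchwork::wrap_plots(plots, nrow = 1) +
    patchwork::plot_annotation(title = sprintf("Component %d",
                                               diagram$component))
  ext <- tolower(tools::file_ext(outfile))
  switch(ext,
         svg = grDevices::svg(outfile, width = width, height = height),
         png = grDevices::png(outfile, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(outfile, width = width, height = height),
         tgfa_stop("tgfa_bad_format", sprintf(
           "unsupported image format '%s' (use svg, png or pdf)", ext)))
  print(combined)
  grDevices::dev.off()
  invisible(outfile)
}
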