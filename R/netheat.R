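#' Cluster ordering of a Q-difference matrix
#'
#' Orders the rows/columns of the Q-difference matrix so that designs with
#' similar inconsistency-change patterns are adjacent: the distance
#' between labels \eqn{i} and \eqn{j} is the sum of the Manhattan
#' distances between their rows and between their columns,
#' \deqn{d(i,j) = \sum_k |Q_{i,k} - Q_{j,k}| + \sum_k |Q_{k,i} - Q_{k,j}|,}
#' followed by complete-linkage hierarchical clustering; the dendrogram
#' leaf order is returned. Labels are pre-sorted so ties break
#' deterministically.
#'
#' @param qdiff a square labelled matrix (typically a
#'   \code{qdiff_matrix}).
#' @return Character vector: the row/column labels in display order.
#' @export
cluster_order <- function(qdiff) {
  M <- unclass_qdiff_any(qdiff)
  if (!is.matrix(M) || nrow(M) != ncol(M) ||
      !identical(rownames(M), colnames(M)))
    stop("qdiff must be a square matrix with matching row/column labels")
  if (nrow(M) < 2L) return(rownames(M))
  input_order <- rownames(M)
  ord0 <- order(input_order)
  M <- M[ord0, ord0, drop = FALSE]
  D <- as.matrix(stats::dist(M, method = "manhattan")) +
    as.matrix(stats::dist(t(M), method = "manhattan"))
  if (all(D == 0)) return(input_order)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  rownames(M)[hc$order]
}

unclass_qdiff_any <- function(x) {
  if (inherits(x, "qdiff_matrix")) unclass_qdiff(x) else x
}

#' Net heat layout
#'
#' Computes everything the net heat plot displays: the (optionally
#' clustered) ordering of the detachable design contrasts, the reordered
#' Q-difference matrix, the matching absolute hat-matrix entries, and the
#' color saturation cap.
#'
#' @param fit a \code{netgls} fit.
#' @param color_cap colors saturate at this absolute Q-difference
#'   (default 8).
#' @param cluster reorder rows/columns by [cluster_order()]? If
#'   \code{FALSE} the input order is kept.
#' @return An object of class \code{netheat_layout}.
#' @export
netheat_layout <- function(fit, color_cap = 8, cluster = TRUE) {
  stopifnot(inherits(fit, "netgls"), color_cap > 0)
  qd <- q_diff_matrix(fit)
  labels <- rownames(qd)
  ord <- if (cluster) cluster_order(qd) else labels
  M <- unclass_qdiff(qd)[ord, ord, drop = FALSE]
  Habs <- abs(fit$H)[ord, ord, drop = FALSE]
  structure(list(order = ord, qdiff = M, hat_areas = Habs,
                 color_cap = color_cap,
                 row_design = attr(qd, "row_design")[match(ord, labels)]),
            class = "netheat_layout")
}

netheat_palette <- function(n_bins = 13) {
  stopifnot(n_bins %% 2 == 1)
  half <- (n_bins - 1) / 2
  neg <- grDevices::colorRampPalette(c("#053061", "#4393C3",
                                       "#F7F7F7"))(half + 1)[1:half]
  pos <- grDevices::colorRampPalette(c("#F7F7F7", "#FFFF00", "#FF7F00",
                                       "#D7191C"))(half + 1)[-1]
  c(neg, "#F7F7F7", pos)
}

#' Plot a net heat layout
#'
#' Renders the net heat plot: cell \eqn{(d', d)} is colored by the change
#' in design \eqn{d'}'s inconsistency summand when design \eqn{d} is
#' detached (warm colors: detachment reduces inconsistency; blue:
#' detachment increases it), on a discrete diverging scale saturating at
#' \code{color_cap}. A centered gray square with area proportional to
#' \eqn{|H_{d',d}|} shows how strongly the direct estimate of \eqn{d}
#' drives the network estimate of \eqn{d'}.
#'
#' @param x a \code{netheat_layout}.
#' @param main plot title.
#' @param ... unused.
#' @export
plot.netheat_layout <- function(x, main = "Net heat plot", ...) {
  M <- x$qdiff
  n <- nrow(M)
  cap <- x$color_cap
  pal <- netheat_palette(13)
  breaks <- seq(-cap, cap, length.out = length(pal) + 1)
  bin <- function(v) {
    v <- pmin(pmax(v, -cap), cap)
    idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    pal[idx]
  }
  op <- graphics::par(mar = c(1, 6, 6, 4.5), xpd = NA)
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, n), ylim = c(0, n), asp = 1)
  for (i in seq_len(n)) {       # row i drawn from the top
    for (j in seq_len(n)) {
      xl <- j - 1; yb <- n - i
      graphics::rect(xl, yb, xl + 1, yb + 1, col = bin(M[i, j]),
                     border = "grey70", lwd = 0.3)
      side <- sqrt(min(x$hat_areas[i, j], 1))
      if (side > 0) {
        cx <- xl + 0.5; cy <- yb + 0.5
        graphics::rect(cx - side / 2, cy - side / 2,
                       cx + side / 2, cy + side / 2,
                       col = grDevices::gray(0.35, alpha = 0.55),
                       border = NA)
      }
    }
  }
  graphics::text(x = seq_len(n) - 0.5, y = n + 0.15, labels = colnames(M),
                 srt = 90, adj = c(0, 0.5), cex = 0.8)
  graphics::text(x = -0.15, y = n - seq_len(n) + 0.5, labels = rownames(M),
                 adj = c(1, 0.5), cex = 0.8)
  graphics::title(main = main, line = 4.5)
  # color key
  kx <- n + 0.6
  kh <- n / length(pal)
  for (k in seq_along(pal)) {
    graphics::rect(kx, (k - 1) * kh, kx + 0.4, k * kh, col = pal[k],
                   border = "grey70", lwd = 0.3)
  }
  at <- c(1, (length(pal) + 1) / 2, length(pal) + 1)
  graphics::text(kx + 0.55, (at - 1) * kh,
                 labels = sprintf("%g", c(-cap, 0, cap)),
                 adj = c(0, 0.5), cex = 0.7)
  invisible(x)
}

#' Net heat plot of a network fit
#'
#' Computes the net heat layout of a fit and renders it, either on the
#' active device or into a file (SVG, PNG or PDF chosen from the file
#' extension or \code{format}).
#'
#' @param fit a \code{netgls} fit.
#' @param file output path; \code{NULL} plots on the current device.
#' @param format one of \code{"svg"}, \code{"png"}, \code{"pdf"}; defaults
#'   to the file extension.
#' @param color_cap,cluster see [netheat_layout()].
#' @param width,height device size in inches.
#' @param ... passed to [plot.netheat_layout()].
#' @return The \code{netheat_layout}, invisibly.
#' @examples
#' fit <- netgls(make_scenario("fig1_a"))
#' netheat(fit)
#' @export
netheat <- function(fit, file = NULL, format = NULL, color_cap = 8,
                    cluster = TRUE, width = 7, height = 7, ...) {
  layout <- netheat_layout(fit, color_cap = color_cap, cluster = cluster)
  if (is.null(file)) {
    plot(layout, ...)
    return(invisible(layout))
  }
  if (is.null(format)) {
    format <- tolower(tools::file_ext(file))
    if (!format %in% c("svg", "png", "pdf")) format <- "svg"
  }
  format <- match.arg(format, c("svg", "png", "pdf"))
  switch(format,
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(file, width = width, height = height))
  on.exit(grDevices::dev.off())
  plot(layout, ...)
  invisible(layout)
}
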