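#' @export
print.netgls <- function(x, digits = 4, ...) {
  cat("Fixed-effects network meta-analysis (two-stage GLS)\n")
  cat(sprintf("%d studies, %d designs, %d treatments (reference: %s)\n",
              x$net$S, x$net$D, length(x$net$treatments), x$net$reference))
  cat("\nBasic parameters (versus", paste0(x$net$reference, "):\n"))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$theta, se = se), digits))
  cat(sprintf("\nQ_net = %.2f (df %d, p %.3f); Q_het = %.2f (df %d); Q_inc = %.2f (df %d, p %.3f)\n",
              x$Q$Q_net, x$Q$df_net, x$Q$p_net, x$Q$Q_het, x$Q$df_het,
              x$Q$Q_inc, x$Q$df_inc, x$Q$p_inc))
  invisible(x)
}

#' Summarize a network GLS fit
#'
#' @param object a \code{netgls} fit.
#' @param ... unused.
#' @return A \code{summary.netgls} object holding the basic parameter
#'   table, per-design direct versus network estimates with the diagonal
#'   hat weights, and the Q decomposition.
#' @export
summary.netgls <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  basics <- data.frame(estimate = object$theta, se = se,
                       z = object$theta / se,
                       p = 2 * stats::pnorm(-abs(object$theta / se)))
  designs <- data.frame(
    contrast = object$model$row_labels,
    direct = unname(object$model$theta_dir),
    network = unname(object$fitted),
    residual = unname(object$resid),
    self_weight = unname(diag(object$H)),
    stringsAsFactors = FALSE)
  structure(list(call = object$call, basics = basics, designs = designs,
                 Q = q_decomposition(object), net = object$net),
            class = "summary.netgls")
}

#' @export
print.summary.netgls <- function(x, digits = 4, ...) {
  cat("Fixed-effects network meta-analysis (two-stage GLS)\n\n")
  cat("Basic parameters (versus", paste0(x$net$reference, "):\n"))
  print(round(x$basics, digits))
  cat("\nDirect vs network estimates by design contrast:\n")
  out <- x$designs
  out[-1] <- lapply(out[-1], round, digits = 3)
  print(out, row.names = FALSE)
  cat("\n")
  print(x$Q)
  invisible(x)
}

#' @export
coef.netgls <- function(object, ...) object$theta

#' @export
vcov.netgls <- function(object, ...) object$vcov

#' @export
fitted.netgls <- function(object, ...) object$fitted

#' Residuals of a network fit
#'
#' Design-level residuals \eqn{\hat\theta^{dir} - X_a \hat\theta^{net}},
#' either raw or standardized by the direct-estimate standard errors
#' (block-wise whitening, so the squared standardized residuals of a
#' design sum to its inconsistency summand \eqn{Q_d^{inc}}).
#'
#' @param object a \code{netgls} fit.
#' @param type \code{"design"} for raw residuals, \code{"standardized"}
#'   for whitened ones.
#' @param ... unused.
#' @return A named numeric vector, one entry per design contrast.
#' @export
residuals.netgls <- function(object,
                             type = c("design", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$resid
  if (type == "standardized") {
    out <- r
    for (d in names(object$model$Va_blocks)) {
      idx <- which(object$model$row_design == d)
      U <- chol(object$model$Va_blocks[[d]])
      out[idx] <- forwardsolve(t(U), r[idx])
    }
    r <- out
  }
  r
}

#' @importFrom stats hatvalues
#' @export
hatvalues.netgls <- function(model, ...) diag(model$H)

#' Network estimates for all treatment contrasts
#'
#' League-style table of the estimated relative effects between every pair
#' of treatments under the consistency model, derived from the basic
#' parameters, with standard errors.
#'
#' @param fit a \code{netgls} fit.
#' @return A list of two matrices, \code{estimate} (row minus column
#'   treatment) and \code{se}.
#' @export
relative_effects <- function(fit) {
  stopifnot(inherits(fit, "netgls"))
  trts <- fit$net$treatments
  theta_full <- c(0, fit$theta)
  names(theta_full) <- trts
  est <- outer(theta_full, theta_full, "-")
  k <- length(trts)
  se <- matrix(0, k, k, dimnames = list(trts, trts))
  Vfull <- matrix(0, k, k, dimnames = list(trts, trts))
  Vfull[-1, -1] <- fit$vcov
  for (i in seq_len(k)) for (j in seq_len(k)) {
    se[i, j] <- sqrt(Vfull[i, i] + Vfull[j, j] - 2 * Vfull[i, j])
  }
  list(estimate = est, se = se)
}

#' Plot the treatment network
#'
#' Draws the treatment graph of a fit with nodes on a circle and edge
#' widths proportional to the inverse standard errors of the direct
#' estimates (one edge per design contrast).
#'
#' @param x a \code{netgls} fit.
#' @param ... further arguments passed to \code{plot.igraph}.
#' @export
plot.netgls <- function(x, ...) {
  g <- design_graph(x$net)
  ends <- igraph::as_edgelist(g)
  w <- numeric(nrow(ends))
  for (i in seq_len(nrow(ends))) {
    d <- igraph::E(g)$design[i]
    V <- x$model$Va_blocks[[d]]
    w[i] <- 1 / sqrt(mean(diag(V)))
  }
  igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                      edge.width = 2 * w / max(w),
                      vertex.color = "grey90", vertex.label.color = "black",
                      ...)
  invisible(x)
}
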