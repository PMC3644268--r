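#' Designs whose detachment can be assessed
#'
#' A design can be detached (given a freed, deviating effect) only if the
#' rest of the network still identifies the contrasts it involves: at
#' least two of its treatments must appear in other designs, and after
#' removing all its studies its treatments must lie in one connected
#' component of the remaining treatment graph. Designs failing these rules
#' (e.g. bridge comparisons, or comparisons introducing a treatment seen
#' nowhere else) do not contribute to the inconsistency assessment and are
#' excluded from the net heat plot.
#'
#' @param x a \code{netgls} fit or \code{network_data} object.
#' @return Character vector of detachable design labels (possibly empty).
#' @export
detachable_designs <- function(x) {
  net <- if (inherits(x, "netgls")) x$net else x
  stopifnot(inherits(net, "network_data"))
  if (net$D < 2L) return(character(0))
  out <- character(0)
  for (d in names(net$designs)) {
    trts <- net$designs[[d]]$treatments
    others <- net$designs[names(net$designs) != d]
    other_trts <- unique(unlist(lapply(others, `[[`, "treatments")))
    if (sum(trts %in% other_trts) < 2L) next
    if (!all(trts %in% other_trts)) next
    edges <- design_edges(others)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = other_trts)
    comp <- igraph::components(g)$membership
    if (length(unique(comp[trts])) == 1L) out <- c(out, d)
  }
  out
}

#' Detach one design from the consistency model
#'
#' Refits the aggregated model with the effect of one design freed from
#' the consistency constraints: the design matrix is extended by
#' \eqn{N_d - 1} indicator columns for the design's contrasts and the GLS
#' fit repeated. The extra coefficients estimate the difference between
#' the design's direct evidence and the indirect evidence of the remaining
#' network; the residuals equal those of a consistency model fitted after
#' holding out the design's studies, and are exactly zero for the detached
#' design itself. The remaining inconsistency
#' \eqn{Q_{(d)}^{inc} = R_{(d)}' V_a^{-1} R_{(d)}} is chi-squared with
#' \eqn{df^{inc} - N_d + 1} degrees of freedom. When detaching saturates
#' the model (zero remaining degrees of freedom) the statistic is exactly
#' zero and the p-value 1.
#'
#' @param fit a \code{netgls} fit.
#' @param design the design label to detach; must be detachable (see
#'   [detachable_designs()]).
#' @return An object of class \code{detach_result} with the deviation
#'   estimates \code{theta_dir_ind}, the statistic \code{Q}, \code{df},
#'   \code{p}, the per-design \code{residual_components} (summing to
#'   \code{Q}), and the refitted basic parameters \code{theta_net}.
#' @examples
#' fit <- netgls(make_scenario("fig1_a"))
#' detach_design(fit, "1:3")
#' @export
detach_design <- function(fit, design) {
  stopifnot(inherits(fit, "netgls"))
  if (!design %in% names(fit$net$designs))
    stop("unknown design: ", design)
  det <- detachable_designs(fit)
  if (!design %in% det) {
    trts <- fit$net$designs[[design]]$treatments
    others <- fit$net$designs[names(fit$net$designs) != design]
    other_trts <- unique(unlist(lapply(others, `[[`, "treatments")))
    reason <- if (sum(trts %in% other_trts) < 2L)
      "fewer than two of its treatments appear in other designs"
    else
      "removing its studies disconnects the treatments it compares"
    stop("design '", design, "' is not detachable: ", reason)
  }
  res <- detach_core(fit$model, design, fit$Q$df_inc)
  structure(c(list(design = design), res), class = "detach_result")
}

# Whitened least squares on the extended design matrix; shared by
# detach_design() and q_diff_matrix(). Whitening the block-diagonal Va
# turns the quadratic-form statistic into a plain residual sum of squares.
detach_core <- function(model, design, df_inc) {
  Xa <- model$Xa
  rows_d <- which(model$row_design == design)
  Ind <- matrix(0, nrow(Xa), length(rows_d))
  Ind[cbind(rows_d, seq_along(rows_d))] <- 1
  colnames(Ind) <- paste0("dev:", rownames(Xa)[rows_d])
  Xe <- cbind(Xa, Ind)

  white <- whiten(model)
  Xw <- white$W(Xe)
  yw <- white$W(model$theta_dir)
  qrX <- qr(Xw)
  saturated <- qrX$rank >= nrow(Xw)
  rw <- if (saturated) numeric(nrow(Xw)) else drop(yw - qr.fitted(qrX, yw))
  Q <- sum(rw^2)
  theta_ext <- qr.coef(qrX, yw)
  theta_ext[is.na(theta_ext)] <- 0
  names(theta_ext) <- colnames(Xe)

  comps <- numeric(length(model$Va_blocks))
  names(comps) <- names(model$Va_blocks)
  for (d in names(model$Va_blocks)) {
    idx <- which(model$row_design == d)
    comps[d] <- sum(rw[idx]^2)
  }
  comps[design] <- 0
  k <- length(rows_d)
  df <- max(df_inc - k, 0L)
  list(theta_dir_ind = theta_ext[colnames(Ind)],
       theta_net = theta_ext[colnames(Xa)],
       Q = Q, df = df, p = chi2_pvalue(Q, df),
       residual_components = comps,
       residuals = drop(white$unW(rw)))
}

# Block-wise whitening transform of the aggregated model: W maps into the
# space where Va is the identity, unW maps residuals back.
whiten <- function(model) {
  n <- nrow(model$Xa)
  Ut <- vector("list", length(model$Va_blocks))
  names(Ut) <- names(model$Va_blocks)
  for (d in names(model$Va_blocks)) Ut[[d]] <- t(chol(model$Va_blocks[[d]]))
  W <- function(x) {
    x <- as.matrix(x)
    out <- x
    for (d in names(Ut)) {
      idx <- which(model$row_design == d)
      out[idx, ] <- forwardsolve(Ut[[d]], x[idx, , drop = FALSE])
    }
    out
  }
  unW <- function(x) {
    x <- as.matrix(x)
    out <- x
    for (d in names(Ut)) {
      idx <- which(model$row_design == d)
      out[idx, ] <- Ut[[d]] %*% x[idx, , drop = FALSE]
    }
    out
  }
  list(W = W, unW = unW)
}

#' @export
print.detach_result <- function(x, ...) {
  cat("Detached design:", x$design, "\n")
  cat("Deviation (direct minus indirect):",
      paste(sprintf("%s = %.3f", names(x$theta_dir_ind), x$theta_dir_ind),
            collapse = ", "), "\n")
  cat(sprintf("Remaining inconsistency: Q = %.2f (df %d, p %.3f)\n",
              x$Q, x$df, x$p))
  invisible(x)
}

#' Q-difference matrix over detachable designs
#'
#' For every detachable design \eqn{d} (columns), detaches it and records
#' the change of every design's inconsistency summand,
#' \eqn{Q_{d',d}^{diff} = Q_{d'}^{inc} - Q_{d'}^{(d)inc}} (rows \eqn{d'}).
#' The diagonal equals the per-design inconsistency summands, and a
#' column sums to \eqn{Q^{inc} - Q_{(d)}^{inc}}. Rows and columns are
#' indexed by design contrast; a multi-arm design contributes one
#' (asterisked) row and column per contrast, all carrying its design-level
#' value, and detaching it means detaching the whole design. Designs that
#' are not detachable are dropped from both axes.
#'
#' @param fit a \code{netgls} fit.
#' @return An object of class \code{qdiff_matrix}: the labelled
#'   contrast-level matrix, with the design-level matrix in attribute
#'   \code{by_design} and the detach results in attribute \code{detach}.
#' @export
q_diff_matrix <- function(fit) {
  stopifnot(inherits(fit, "netgls"))
  det <- detachable_designs(fit)
  if (length(det) == 0L)
    stop("net heat plot undefined (no loops): no design is detachable")
  per_inc <- fit$Q$per_design_inc
  Dq <- matrix(NA_real_, length(det), length(det),
               dimnames = list(det, det))
  detres <- vector("list", length(det))
  names(detres) <- det
  for (d in det) {
    res <- detach_core(fit$model, d, fit$Q$df_inc)
    detres[[d]] <- res
    Dq[, d] <- per_inc[det] - res$residual_components[det]
  }
  # expand designs to their contrast rows/columns
  labels <- fit$model$row_labels[fit$model$row_design %in% det]
  lab_design <- fit$model$row_design[fit$model$row_design %in% det]
  M <- Dq[lab_design, lab_design, drop = FALSE]
  dimnames(M) <- list(labels, labels)
  structure(M, by_design = Dq, row_design = lab_design, detach = detres,
            class = c("qdiff_matrix", "matrix"))
}

#' @export
print.qdiff_matrix <- function(x, digits = 2, ...) {
  cat("Q-difference matrix (rows: design contrast d'; columns: detached ",
      "design d)\n", sep = "")
  print(round(unclass_qdiff(x), digits))
  invisible(x)
}

unclass_qdiff <- function(x) {
  attr(x, "by_design") <- NULL
  attr(x, "row_design") <- NULL
  attr(x, "detach") <- NULL
  class(x) <- NULL
  x
}
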