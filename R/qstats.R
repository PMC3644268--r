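#' Upper-tail chi-squared p-value
#'
#' Upper-tail probability of the chi-squared distribution, with the
#' convention that zero degrees of freedom (a saturated statistic) gives
#' p = 1.
#'
#' @param Q non-negative test statistic.
#' @param df non-negative integer degrees of freedom.
#' @return The upper-tail probability.
#' @export
chi2_pvalue <- function(Q, df) {
  if (!is.finite(Q) || Q < 0) stop("Q must be non-negative")
  if (!is.finite(df) || df < 0 || df != round(df))
    stop("df must be a non-negative integer")
  if (df == 0) return(1)
  stats::pchisq(Q, df = df, lower.tail = FALSE)
}

#' Degrees of freedom of the network Q statistics
#'
#' Computes, from the network structure alone, the degrees of freedom of
#' the network Q decomposition: with \eqn{N_s} arms per study, \eqn{N_d}
#' treatments per design and \eqn{T} basic parameters,
#' \deqn{df^{net} = \sum_s (N_s - 1) - T, \quad
#'       df^{inc} = \sum_d (N_d - 1) - T, \quad
#'       df^{het} = df^{net} - df^{inc},}
#' and per design \eqn{df_d^{het} = \sum_{s \in d}(N_s - 1) - N_d + 1}.
#' \eqn{df^{inc} = 0} means inconsistency is unassessable (no loops).
#'
#' @param net a \code{network_data} object.
#' @return A list with \code{df_net}, \code{df_het}, \code{df_inc} and the
#'   per-design vector \code{df_het_design}.
#' @export
q_dof <- function(net) {
  stopifnot(inherits(net, "network_data"))
  n_study_contrasts <- sum(vapply(net$studies,
                                  function(s) length(s$y), integer(1)))
  n_design_contrasts <- sum(vapply(net$designs,
                                   function(d) length(d$treatments) - 1L,
                                   integer(1)))
  per <- vapply(net$designs, function(d) {
    sum(vapply(d$studies, function(s) length(s$y), integer(1))) -
      (length(d$treatments) - 1L)
  }, integer(1))
  list(df_net = n_study_contrasts - net$T,
       df_het = n_study_contrasts - n_design_contrasts,
       df_inc = n_design_contrasts - net$T,
       df_het_design = per)
}

#' Q decomposition of a network fit
#'
#' Extracts the decomposition of the network Cochran Q statistic,
#' \eqn{Q^{net} = Q^{het} + Q^{inc}}: overall heterogeneity in the network,
#' heterogeneity within designs (summed over designs), and inconsistency
#' between designs, each with degrees of freedom and chi-squared p-value.
#' Per-design heterogeneity statistics and the per-design inconsistency
#' summands \eqn{Q_{d'}^{inc}} (which sum to \eqn{Q^{inc}}) are attached.
#'
#' @param fit a \code{netgls} fit.
#' @return An object of class \code{q_decomposition}.
#' @export
q_decomposition <- function(fit) {
  stopifnot(inherits(fit, "netgls"))
  structure(fit$Q, class = "q_decomposition")
}

#' @export
print.q_decomposition <- function(x, ...) {
  tab <- data.frame(Q = c(x$Q_net, x$Q_het, x$Q_inc),
                    df = c(x$df_net, x$df_het, x$df_inc),
                    p = c(x$p_net, x$p_het, x$p_inc),
                    row.names = c("Q_net (total)",
                                  "Q_het (within designs)",
                                  "Q_inc (between designs)"))
  cat("Decomposition of the network Q statistic:\n")
  print(format_q_table(tab))
  het <- x$per_design_het
  het_df <- vapply(het, `[[`, integer(1), "df")
  if (any(het_df > 0)) {
    cat("\nHeterogeneity within designs (multi-study designs):\n")
    keep <- het_df > 0
    tab2 <- data.frame(Q = vapply(het[keep], `[[`, numeric(1), "Q"),
                       df = het_df[keep],
                       p = vapply(het[keep], `[[`, numeric(1), "p"),
                       row.names = names(het)[keep])
    print(format_q_table(tab2))
  }
  if (x$df_inc == 0)
    cat("\nNote: inconsistency unassessable (no loops), df_inc = 0\n")
  invisible(x)
}

format_q_table <- function(tab) {
  data.frame(Q = sprintf("%.2f", tab$Q), df = tab$df,
             p = sprintf("%.3f", tab$p), row.names = rownames(tab))
}
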