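#' Pool all studies of one design (first stage)
#'
#' Inverse-variance pooling of all studies sharing a design into the direct
#' estimate of that design:
#' \deqn{\hat\theta_d^{dir} = (\sum_s V_s^{-1})^{-1} \sum_s V_s^{-1} Y_s,
#'       \qquad V_d^{dir} = (\sum_s V_s^{-1})^{-1},}
#' where the sums run over the studies of design \eqn{d}. For multi-arm
#' designs these are matrix-weighted means of the per-study contrast
#' vectors. A single-study design returns that study's values unchanged.
#'
#' @param group a design group, i.e. one element of
#'   \code{network_data$designs}.
#' @return A list with \code{design}, \code{theta_dir} (named vector of
#'   pooled contrasts versus the design reference) and \code{V_dir}
#'   (covariance of the pooled vector).
#' @export
pool_design <- function(group) {
  stopifnot(length(group$studies) >= 1L)
  k <- length(group$treatments) - 1L
  A <- matrix(0, k, k)
  b <- numeric(k)
  for (s in group$studies) {
    Vinv <- solve(s$cov)
    A <- A + Vinv
    b <- b + Vinv %*% s$y
  }
  A <- (A + t(A)) / 2
  V_dir <- solve(A)
  V_dir <- (V_dir + t(V_dir)) / 2
  theta <- drop(V_dir %*% b)
  nonref <- group$treatments[-1]
  names(theta) <- nonref
  dimnames(V_dir) <- list(nonref, nonref)
  list(design = group$design, theta_dir = theta, V_dir = V_dir)
}

#' Within-design heterogeneity statistic
#'
#' Cochran-type Q statistic for heterogeneity among the studies of one
#' design,
#' \deqn{Q_d^{het} = \sum_{s} (Y_s - \hat\theta_d^{dir})' V_s^{-1}
#'       (Y_s - \hat\theta_d^{dir}),}
#' chi-squared with \eqn{\sum_s (N_s - 1) - N_d + 1} degrees of freedom
#' under homogeneity. A single-study design has zero degrees of freedom and
#' p-value 1.
#'
#' @param group a design group (element of \code{network_data$designs}).
#' @param direct the pooled direct estimate from [pool_design()]; computed
#'   if omitted.
#' @return A list with \code{Q}, \code{df} and \code{p}.
#' @export
q_het_design <- function(group, direct = NULL) {
  if (is.null(direct)) direct <- pool_design(group)
  Q <- 0
  for (s in group$studies) {
    r <- s$y - direct$theta_dir[names(s$y)]
    Q <- Q + drop(crossprod(r, solve(s$cov, r)))
  }
  n_contrasts <- sum(vapply(group$studies,
                            function(s) length(s$y), integer(1)))
  df <- n_contrasts - (length(group$treatments) - 1L)
  list(Q = max(Q, 0), df = df, p = chi2_pvalue(max(Q, 0), df))
}

#' All direct estimates of a network
#'
#' Applies [pool_design()] to every design of the network.
#'
#' @param net a \code{network_data} object.
#' @return A named list of direct estimates, in design order.
#' @export
direct_estimates <- function(net) {
  stopifnot(inherits(net, "network_data"))
  lapply(net$designs, pool_design)
}
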