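#' Aggregated design matrix of the consistency model
#'
#' Builds the second-stage (design-level) linear model: one row per design
#' contrast over the \eqn{T} basic parameters, which are the contrasts of
#' every non-reference treatment versus the network reference (the
#' lexicographically smallest treatment). A design contributes
#' \eqn{N_d - 1} rows; each row carries +1 in the column of its
#' non-reference treatment and -1 in the column of the design reference
#' (omitted when the design reference is the network reference).
#'
#' @param net a \code{network_data} object.
#' @param directs direct estimates from [direct_estimates()]; computed if
#'   omitted.
#' @return A list with the design matrix \code{Xa} (rows labelled by design
#'   contrast, multi-arm rows suffixed \code{*}), the stacked direct
#'   estimate \code{theta_dir}, the block-diagonal covariance \code{Va} and
#'   its blocks, \code{row_design} mapping rows to designs, and the
#'   constituent \code{directs}.
#' @export
build_design_matrix <- function(net, directs = NULL) {
  stopifnot(inherits(net, "network_data"))
  if (is.null(directs)) directs <- direct_estimates(net)
  basic <- net$treatments[-1]
  rows <- list(); labels <- character(0); row_design <- character(0)
  theta_dir <- numeric(0)
  blocks <- list()
  for (d in net$designs) {
    ref <- d$reference
    nonref <- d$treatments[-1]
    multi <- length(d$treatments) > 2L
    for (t in nonref) {
      r <- stats::setNames(numeric(length(basic)), basic)
      r[t] <- 1
      if (ref != net$reference) r[ref] <- -1
      rows[[length(rows) + 1L]] <- r
      labels <- c(labels,
                  if (multi) paste0(ref, ":", t, "*") else d$design)
      row_design <- c(row_design, d$design)
    }
    dir <- directs[[d$design]]
    theta_dir <- c(theta_dir, dir$theta_dir)
    blocks[[d$design]] <- dir$V_dir
  }
  Xa <- do.call(rbind, rows)
  dimnames(Xa) <- list(labels, basic)
  names(theta_dir) <- labels
  Va <- matrix(0, nrow(Xa), nrow(Xa), dimnames = list(labels, labels))
  i <- 1L
  for (d in names(blocks)) {
    k <- nrow(blocks[[d]])
    Va[i:(i + k - 1L), i:(i + k - 1L)] <- blocks[[d]]
    i <- i + k
  }
  list(Xa = Xa, theta_dir = theta_dir, Va = Va, Va_blocks = blocks,
       row_design = row_design, row_labels = labels, directs = directs)
}

#' Fit the fixed-effects consistency model of a treatment network
#'
#' Two-stage generalized least squares analysis of a network of treatment
#' comparisons. The first stage pools the studies of each design (each set
#' of treatments compared together) by inverse-variance weighting into
#' direct estimates with known covariance. The second stage fits the
#' consistency model by GLS (the Aitken estimator),
#' \deqn{\hat\theta^{net} = (X_a' V_a^{-1} X_a)^{-1} X_a' V_a^{-1}
#'       \hat\theta^{dir},}
#' estimating the \eqn{T} basic parameters (contrasts versus the network
#' reference). The fit carries the design-level hat matrix
#' \deqn{H = X_a (X_a' V_a^{-1} X_a)^{-1} X_a' V_a^{-1},}
#' whose row \eqn{d'} gives the linear weight of every direct estimate in
#' the network estimate of \eqn{d'}, and the decomposition of the network
#' Cochran Q statistic into within-design heterogeneity and between-design
#' inconsistency, \eqn{Q^{net} = Q^{het} + Q^{inc}}.
#'
#' @param data a contrast-level data frame (columns \code{study, treat1,
#'   treat2, effect, se}) or a \code{network_data} object from
#'   [parse_contrasts()].
#' @param arm_vars optional arm-variance table for multi-arm studies (see
#'   [parse_contrasts()]); ignored when \code{data} is already parsed.
#' @return An object of class \code{netgls} with components including
#'   \code{theta} (basic parameter estimates), \code{vcov}, \code{H},
#'   \code{fitted}, \code{resid} (design-level residuals
#'   \eqn{\hat\theta^{dir} - X_a\hat\theta^{net}}), and \code{Q} (the full
#'   Q decomposition, see [q_decomposition()]).
#' @examples
#' fit <- netgls(make_scenario("fig1_a"))
#' fit
#' coef(fit)
#' hatvalues(fit)
#' @export
netgls <- function(data, arm_vars = NULL) {
  cl <- match.call()
  net <- if (inherits(data, "network_data")) data else
    parse_contrasts(data, arm_vars)
  directs <- direct_estimates(net)
  model <- build_design_matrix(net, directs)
  fit <- fit_aggregated(model)
  Q <- q_decompose(net, model, fit, directs)
  structure(c(list(call = cl, net = net, directs = directs, model = model,
                   Q = Q),
              fit),
            class = "netgls")
}

# GLS core on the aggregated model. Separated so the detaching machinery
# can reuse it with an extended design matrix.
fit_aggregated <- function(model) {
  Xa <- model$Xa
  T_par <- ncol(Xa)
  Vainv <- block_inverse(model$Va_blocks, rownames(Xa))
  A <- crossprod(Xa, Vainv %*% Xa)
  A <- (A + t(A)) / 2
  if (qr(A)$rank < T_par)
    stop("aggregated design matrix is rank deficient; ",
         "the treatment network is not connected")
  cov_net <- solve(A)
  cov_net <- (cov_net + t(cov_net)) / 2
  theta <- drop(cov_net %*% crossprod(Xa, Vainv %*% model$theta_dir))
  names(theta) <- colnames(Xa)
  H <- Xa %*% cov_net %*% crossprod(Xa, Vainv)
  dimnames(H) <- list(rownames(Xa), rownames(Xa))
  fitted <- drop(Xa %*% theta)
  names(fitted) <- rownames(Xa)
  list(theta = theta, vcov = cov_net, H = H, fitted = fitted,
       resid = model$theta_dir - fitted, Vainv = Vainv)
}

block_inverse <- function(blocks, labels) {
  n <- sum(vapply(blocks, nrow, integer(1)))
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- 1L
  for (b in blocks) {
    k <- nrow(b)
    Binv <- solve(b)
    M[i:(i + k - 1L), i:(i + k - 1L)] <- (Binv + t(Binv)) / 2
    i <- i + k
  }
  M
}

# Full Q decomposition: Q_net from study-level residuals, Q_het from the
# first stage, Q_inc from the design-level residuals; the three are
# computed independently so their additivity is a genuine check.
q_decompose <- function(net, model, fit, directs) {
  per_het <- lapply(net$designs, function(d)
    q_het_design(d, directs[[d$design]]))
  Q_het <- sum(vapply(per_het, `[[`, numeric(1), "Q"))
  df_het <- sum(vapply(per_het, `[[`, integer(1), "df"))

  per_inc <- numeric(net$D)
  names(per_inc) <- names(net$designs)
  for (d in names(net$designs)) {
    idx <- which(model$row_design == d)
    r <- fit$resid[idx]
    per_inc[d] <- drop(crossprod(r, solve(model$Va_blocks[[d]], r)))
  }
  Q_inc <- sum(per_inc)
  df_inc <- nrow(model$Xa) - net$T

  Q_net <- 0
  for (d in names(net$designs)) {
    idx <- which(model$row_design == d)
    fit_d <- fit$fitted[idx]
    names(fit_d) <- net$designs[[d]]$treatments[-1]
    for (s in net$designs[[d]]$studies) {
      r <- s$y - fit_d[names(s$y)]
      Q_net <- Q_net + drop(crossprod(r, solve(s$cov, r)))
    }
  }
  df_net <- sum(vapply(net$studies, function(s) length(s$y), integer(1))) -
    net$T

  list(Q_net = Q_net, Q_het = Q_het, Q_inc = Q_inc,
       df_net = df_net, df_het = df_het, df_inc = df_inc,
       p_net = chi2_pvalue(Q_net, df_net),
       p_het = chi2_pvalue(Q_het, df_het),
       p_inc = chi2_pvalue(Q_inc, df_inc),
       per_design_het = per_het, per_design_inc = per_inc)
}

#' Design-level hat matrix
#'
#' Returns the hat matrix of the aggregated GLS fit, whose entry
#' \eqn{(d', d)} is the linear coefficient of the direct estimate of design
#' \eqn{d} in the network estimate of the contrast of design \eqn{d'}.
#' Entries lie in \eqn{[-1, 1]}; the diagonal entry is the weight of a
#' design's own direct evidence in its network estimate, and the trace
#' equals the number of basic parameters \eqn{T}.
#'
#' @param fit a \code{netgls} fit.
#' @param percent if \code{TRUE}, return integer percentages (rounded half
#'   away from zero) for display; raw values otherwise.
#' @return A labelled square matrix, one row/column per design contrast.
#' @export
hat_matrix <- function(fit, percent = FALSE) {
  stopifnot(inherits(fit, "netgls"))
  H <- fit$H
  if (percent) {
    H[] <- sign(H) * floor(abs(H) * 100 + 0.5)
  }
  H
}

#' Split a design's hat-matrix weight over its studies
#'
#' For a two-arm design, the diagonal hat-matrix entry (the weight of the
#' design's direct evidence in its own network estimate) is split over the
#' member studies in proportion to their inverse variances, so the shares
#' sum to the design's entry.
#'
#' @param fit a \code{netgls} fit.
#' @param design a design label.
#' @return A named vector of per-study shares.
#' @export
study_contributions <- function(fit, design) {
  stopifnot(inherits(fit, "netgls"))
  grp <- fit$net$designs[[design]]
  if (is.null(grp)) stop("unknown design: ", design)
  if (length(grp$treatments) > 2L)
    stop("study-level contribution split is only defined for two-arm ",
         "designs")
  w <- vapply(grp$studies, function(s) 1 / s$cov[1, 1], numeric(1))
  shares <- fit$H[design, design] * w / sum(w)
  names(shares) <- vapply(grp$studies, `[[`, character(1), "study")
  shares
}
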