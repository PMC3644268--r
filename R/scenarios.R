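#' Illustrative network scenarios
#'
#' Builds the contrast table of one of the illustrative six-treatment
#' networks used throughout: one single-study design per edge, unit
#' variances, all effects zero except a perturbation \code{delta} on one
#' design. The named scenarios are
#' \describe{
#'   \item{fig1_a}{the eight-design network with edges 1:2, 1:3, 1:6,
#'     2:3, 3:4, 4:5, 4:6, 5:6 (two triangles joined by two bridges of a
#'     four-cycle); default perturbation on 1:2.}
#'   \item{fig3_b, fig3_c}{the same network, perturbed on 1:6 resp. 1:3.}
#'   \item{fig3_d}{the single six-cycle 1:2, 2:3, 3:4, 4:5, 5:6, 1:6;
#'     default perturbation on 1:2.}
#'   \item{fig3_e}{the complete network of all 15 pairs; default
#'     perturbation on 1:2.}
#'   \item{triangle}{three treatments A, B, C with all three pairs;
#'     default perturbation on A:B.}
#'   \item{random}{a random connected six-treatment network (spanning
#'     tree plus three extra edges) with the perturbation on a random
#'     edge; requires \code{seed}.}
#' }
#'
#' @param name scenario name.
#' @param perturb design label carrying the perturbation; default as
#'   listed above.
#' @param delta the perturbation, in units of the (unit) standard error of
#'   a direct estimate; default 5.
#' @param seed integer seed, used by the \code{random} scenario.
#' @return A contrast-level data frame suitable for [netgls()].
#' @examples
#' fit <- netgls(make_scenario("fig1_a"))
#' q_decomposition(fit)
#' @export
make_scenario <- function(name = c("fig1_a", "fig3_b", "fig3_c", "fig3_d",
                                   "fig3_e", "triangle", "random"),
                          perturb = NULL, delta = 5, seed = NULL) {
  name <- match.arg(name)
  if (!is.finite(delta)) stop("delta must be finite")
  two_tri <- c("1:2", "1:3", "1:6", "2:3", "3:4", "4:5", "4:6", "5:6")
  cyc6 <- c("1:2", "1:6", "2:3", "3:4", "4:5", "5:6")
  full6 <- apply(utils::combn(as.character(1:6), 2), 2, paste,
                 collapse = ":")
  spec <- switch(name,
    fig1_a = list(edges = two_tri, default = "1:2"),
    fig3_b = list(edges = two_tri, default = "1:6"),
    fig3_c = list(edges = two_tri, default = "1:3"),
    fig3_d = list(edges = cyc6, default = "1:2"),
    fig3_e = list(edges = full6, default = "1:2"),
    triangle = list(edges = c("A:B", "A:C", "B:C"), default = "A:B"),
    random = {
      if (is.null(seed)) stop("the random scenario needs a seed")
      set.seed(seed)
      edges <- random_connected_edges(6, extra = 3)
      list(edges = edges, default = sample(edges, 1))
    })
  if (is.null(perturb)) perturb <- spec$default
  if (!perturb %in% spec$edges)
    stop("perturbed design '", perturb, "' is not an edge of scenario ",
         name)
  pairs <- strsplit(spec$edges, ":", fixed = TRUE)
  data.frame(study = paste0("s_", gsub(":", "_", spec$edges)),
             treat1 = vapply(pairs, `[`, character(1), 2),
             treat2 = vapply(pairs, `[`, character(1), 1),
             effect = ifelse(spec$edges == perturb, delta, 0),
             se = 1,
             stringsAsFactors = FALSE)
}

random_connected_edges <- function(n, extra = 2) {
  trts <- as.character(seq_len(n))
  perm <- sample(trts)
  tree <- vapply(2:n, function(i) {
    design_id(c(perm[i], perm[sample.int(i - 1, 1)]))
  }, character(1))
  all_pairs <- apply(utils::combn(trts, 2), 2, paste, collapse = ":")
  rest <- setdiff(all_pairs, tree)
  sort(c(tree, sample(rest, min(extra, length(rest)))))
}

#' Simulate study-level network data
#'
#' Draws study effects for a given set of designs under the consistency
#' model with optional between-study heterogeneity: for every study of
#' design \eqn{d}, the contrast vector is
#' \eqn{Y_s \sim N(X_d \theta + u_s, V_s)} where \eqn{u_s} are independent
#' \eqn{N(0, het\_sd^2)} per-contrast study shifts and \eqn{V_s} is built
#' from unit arm variances (so a two-arm study has variance 2 and a
#' multi-arm study the corresponding correlated block).
#'
#' @param designs character vector of design labels, each a ":"-joined
#'   treatment set (two or more treatments); must form a connected
#'   network.
#' @param theta named vector of true basic parameters (contrasts of each
#'   non-reference treatment versus the lexicographically smallest
#'   treatment); defaults to all zero.
#' @param het_sd between-study heterogeneity standard deviation (>= 0).
#' @param n_studies number of studies per design; scalar or one value per
#'   design.
#' @param seed optional integer seed.
#' @return A list with \code{data} (contrast table) and \code{arm_vars}
#'   (arm-variance table, or \code{NULL} without multi-arm designs), ready
#'   for [netgls()].
#' @examples
#' sim <- simulate_network(c("A:B", "A:C", "B:C"), het_sd = 0.2,
#'                         n_studies = 3, seed = 1)
#' fit <- netgls(sim$data, sim$arm_vars)
#' @export
simulate_network <- function(designs, theta = NULL, het_sd = 0,
                             n_studies = 1, seed = NULL) {
  stopifnot(het_sd >= 0, all(n_studies >= 1))
  if (anyDuplicated(designs)) stop("duplicate design labels")
  if (!is.null(seed)) set.seed(seed)
  n_studies <- rep_len(n_studies, length(designs))
  ord <- order(designs)
  designs <- designs[ord]
  n_studies <- n_studies[ord]
  trt_sets <- lapply(strsplit(designs, ":", fixed = TRUE), sort)
  treatments <- sort(unique(unlist(trt_sets)))
  ref <- treatments[1]
  if (is.null(theta)) theta <- stats::setNames(numeric(length(treatments) - 1),
                                               treatments[-1])
  if (is.null(names(theta)) || !all(treatments[-1] %in% names(theta)))
    stop("theta must be named with every non-reference treatment")
  full <- c(stats::setNames(0, ref), theta[treatments[-1]])

  check_sim_connected(trt_sets, treatments)

  rows <- list(); av_rows <- list()
  for (i in seq_along(designs)) {
    trts <- trt_sets[[i]]
    d_ref <- trts[1]; nonref <- trts[-1]
    k <- length(nonref)
    mu <- full[nonref] - full[d_ref]
    V <- matrix(1, k, k); diag(V) <- 2           # unit arm variances
    L <- t(chol(V))
    for (s in seq_len(n_studies[i])) {
      id <- sprintf("%s_s%02d", gsub(":", "_", designs[i]), s)
      u <- stats::rnorm(k, 0, het_sd)
      y <- mu + u + drop(L %*% stats::rnorm(k))
      rows[[length(rows) + 1L]] <- data.frame(
        study = id, treat1 = nonref, treat2 = d_ref, effect = unname(y),
        se = sqrt(2), stringsAsFactors = FALSE)
      if (k > 1L)
        av_rows[[length(av_rows) + 1L]] <- data.frame(
          study = id, treatment = trts, var = 1, stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       arm_vars = if (length(av_rows) > 0)
         do.call(rbind, c(av_rows, list(make.row.names = FALSE)))
       else NULL)
}

check_sim_connected <- function(trt_sets, treatments) {
  edges <- do.call(rbind, lapply(trt_sets, function(t) {
    p <- utils::combn(t, 2)
    data.frame(from = p[1, ], to = p[2, ], stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = treatments)
  if (igraph::components(g)$no > 1L)
    stop("simulated topology is disconnected")
  invisible(TRUE)
}
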