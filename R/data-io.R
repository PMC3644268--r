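#' Read a contrast-level data file
#'
#' Reads a delimited text file of contrast-level study results with columns
#' \code{study, treat1, treat2, effect, se}. The effect is the estimated
#' treatment effect of \code{treat1} relative to \code{treat2} (e.g. a log
#' odds ratio or a mean difference) and \code{se} its standard error.
#' Files ending in \code{.tsv} or \code{.tab} are read as tab-separated,
#' anything else as comma-separated.
#'
#' @param file path to the contrast table.
#' @return A data frame with character treatment/study columns.
#' @seealso [parse_contrasts()] to assemble a network from the table.
#' @export
read_contrast_data <- function(file) {
  sep <- if (grepl("\\.(tsv|tab)$", file, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  dat
}

#' Read an arm-level variance file
#'
#' Reads a delimited file with columns \code{study, treatment, var} giving
#' the variance of the estimated outcome in each arm of multi-arm studies,
#' from which per-study covariance blocks are assembled.
#'
#' @param file path to the arm-variance table.
#' @return A data frame.
#' @export
read_arm_variances <- function(file) {
  sep <- if (grepl("\\.(tsv|tab)$", file, ignore.case = TRUE)) "\t" else ","
  utils::read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

design_id <- function(treatments) paste(sort(treatments), collapse = ":")

#' Assemble a treatment network from contrast-level data
#'
#' Groups contrast rows into studies, re-orients every contrast to the
#' design-specific reference treatment (the lexicographically smallest
#' treatment of the design), assembles per-study covariance blocks, groups
#' studies into designs (sets of treatments compared together) and checks
#' that the network of treatments is connected.
#'
#' For a two-arm study the covariance block is simply \code{se^2}. For a
#' study with three or more arms the block is built, in order of preference,
#' from (i) arm-level variances supplied via \code{arm_vars}, using
#' \eqn{Var(Y_{0:i}) = v_0 + v_i} and \eqn{Cov(Y_{0:i}, Y_{0:j}) = v_0}
#' for the design reference arm 0, or (ii) the complete set of
#' \eqn{n(n-1)/2} pairwise standard errors, solving \eqn{se_{ab}^2 = v_a +
#' v_b} for the arm variances by least squares. A multi-arm study providing
#' neither is rejected, since the pairwise correlations cannot be recovered.
#'
#' @param data data frame with columns \code{study, treat1, treat2, effect,
#'   se}; \code{effect} is treat1 minus treat2.
#' @param arm_vars optional data frame with columns \code{study, treatment,
#'   var} for multi-arm studies.
#' @return An object of class \code{network_data}: a list with components
#'   \code{treatments} (sorted labels; the first is the network reference),
#'   \code{studies} (per-study records with contrast vector \code{y} and
#'   covariance block \code{cov}), \code{designs}, and the counts \code{S},
#'   \code{D}, \code{T}.
#' @examples
#' dat <- data.frame(study = c("s1", "s2", "s3", "s4"),
#'                   treat1 = c("B", "B", "C", "C"),
#'                   treat2 = c("A", "A", "A", "B"),
#'                   effect = c(0.5, 0.7, 0.2, -0.4),
#'                   se = 1)
#' net <- parse_contrasts(dat)
#' net
#' @export
parse_contrasts <- function(data, arm_vars = NULL) {
  required <- c("study", "treat1", "treat2", "effect", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L)
    stop("input is missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)
  for (col in c("study", "treat1", "treat2"))
    data[[col]] <- trimws(as.character(data[[col]]))
  data$effect <- as.numeric(data$effect)
  data$se <- as.numeric(data$se)
  if (any(!is.finite(data$effect)) || any(!is.finite(data$se)))
    stop("non-finite effect or standard error in input")
  if (any(data$se <= 0))
    stop("standard errors must be strictly positive")
  if (any(data$treat1 == data$treat2))
    stop("self-comparison (treat1 == treat2) in input")

  pair_key <- paste(data$study,
                    pmin(data$treat1, data$treat2),
                    pmax(data$treat1, data$treat2), sep = "\r")
  if (anyDuplicated(pair_key))
    stop("duplicate (study, treatment pair) rows: ",
         paste(unique(data$study[duplicated(pair_key)]), collapse = ", "))

  if (!is.null(arm_vars)) {
    av_required <- c("study", "treatment", "var")
    if (length(setdiff(av_required, names(arm_vars))) > 0L)
      stop("arm variance table needs columns: study, treatment, var")
    arm_vars <- as.data.frame(arm_vars)
    arm_vars$study <- trimws(as.character(arm_vars$study))
    arm_vars$treatment <- trimws(as.character(arm_vars$treatment))
    arm_vars$var <- as.numeric(arm_vars$var)
    if (any(!is.finite(arm_vars$var)) || any(arm_vars$var <= 0))
      stop("arm variances must be positive and finite")
  }

  studies <- lapply(split(data, data$study), function(rows) {
    build_study(rows, arm_vars)
  })
  studies <- studies[order(names(studies))]

  design_of <- vapply(studies, function(s) s$design, character(1))
  designs <- lapply(split(names(studies), design_of), function(ids) {
    trts <- studies[[ids[1]]]$treatments
    list(design = design_id(trts), treatments = trts, reference = trts[1],
         studies = studies[ids])
  })
  designs <- designs[order(names(designs))]

  treatments <- sort(unique(unlist(lapply(studies, `[[`, "treatments"))))
  check_connected(designs, treatments)

  structure(list(treatments = treatments,
                 reference = treatments[1],
                 studies = studies,
                 designs = designs,
                 S = length(studies),
                 D = length(designs),
                 T = length(treatments) - 1L),
            class = "network_data")
}

# One study: orient all rows to the design reference and build y and cov.
build_study <- function(rows, arm_vars) {
  trts <- sort(unique(c(rows$treat1, rows$treat2)))
  ref <- trts[1]
  nonref <- trts[-1]
  n_arm <- length(trts)
  n_con <- n_arm - 1L

  # Each input row states effect(treat1) - effect(treat2); express it in the
  # basis of the n-1 contrasts versus the design reference and solve.
  C <- matrix(0, nrow(rows), n_con, dimnames = list(NULL, nonref))
  for (i in seq_len(nrow(rows))) {
    if (rows$treat1[i] != ref) C[i, rows$treat1[i]] <- 1
    if (rows$treat2[i] != ref) C[i, rows$treat2[i]] <- -1
  }
  qrC <- qr(C)
  if (qrC$rank < n_con)
    stop("study '", rows$study[1],
         "': contrast rows do not determine all arms (inconsistent or ",
         "incomplete treatment set)")
  y <- drop(qr.coef(qrC, rows$effect))
  names(y) <- nonref

  if (n_arm == 2L) {
    cov <- matrix(rows$se^2, 1, 1, dimnames = list(nonref, nonref))
  } else {
    av <- NULL
    if (!is.null(arm_vars)) {
      av_rows <- arm_vars[arm_vars$study == rows$study[1], , drop = FALSE]
      if (nrow(av_rows) > 0L) {
        if (!setequal(av_rows$treatment, trts))
          stop("study '", rows$study[1],
               "': arm variances must be given for all of: ",
               paste(trts, collapse = ", "))
        av <- av_rows$var[match(trts, av_rows$treatment)]
        names(av) <- trts
      }
    }
    if (is.null(av)) {
      av <- solve_arm_variances(rows, trts)
      if (is.null(av))
        stop("study '", rows$study[1], "': multi-arm study needs arm ",
             "variances (or all pairwise standard errors) to build its ",
             "covariance block")
    }
    cov <- matrix(av[ref], n_con, n_con, dimnames = list(nonref, nonref))
    diag(cov) <- av[ref] + av[nonref]
  }

  list(study = rows$study[1], design = design_id(trts), treatments = trts,
       reference = ref, y = y, cov = cov)
}

# Recover arm variances from a complete set of pairwise SEs:
# se(a,b)^2 = v_a + v_b, solved by least squares. Returns NULL when the
# pairwise set is incomplete, errors when a solved variance is <= 0.
solve_arm_variances <- function(rows, trts) {
  n <- length(trts)
  if (nrow(rows) < n * (n - 1) / 2) return(NULL)
  A <- matrix(0, nrow(rows), n, dimnames = list(NULL, trts))
  for (i in seq_len(nrow(rows))) {
    A[i, rows$treat1[i]] <- 1
    A[i, rows$treat2[i]] <- 1
  }
  if (qr(A)$rank < n) return(NULL)
  v <- drop(qr.coef(qr(A), rows$se^2))
  names(v) <- trts
  if (any(v <= 0))
    stop("study '", rows$study[1], "': pairwise standard errors imply a ",
         "non-positive arm variance; supply arm variances explicitly")
  v
}

check_connected <- function(designs, treatments) {
  edges <- design_edges(designs)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = treatments)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    groups <- split(names(comp$membership), comp$membership)
    stop("treatment network is disconnected; components: ",
         paste(vapply(groups, paste, character(1), collapse = ","),
               collapse = " | "))
  }
  invisible(TRUE)
}

# All within-design treatment pairs, one row per design x pair.
design_edges <- function(designs) {
  rows <- lapply(designs, function(d) {
    pairs <- utils::combn(d$treatments, 2)
    data.frame(from = pairs[1, ], to = pairs[2, ], design = d$design,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Treatment graph of a network
#'
#' Builds the undirected multigraph with treatments as nodes and one edge,
#' tagged with its design label, for every treatment pair compared within
#' a design. Multi-arm designs contribute an edge for each of their pairs.
#'
#' @param net a \code{network_data} object.
#' @return An \code{igraph} graph with edge attribute \code{design}.
#' @export
design_graph <- function(net) {
  stopifnot(inherits(net, "network_data"))
  edges <- design_edges(net$designs)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$treatments)
  igraph::E(g)$design <- edges$design
  g
}

#' @export
print.network_data <- function(x, ...) {
  cat("Treatment network:", x$S, "studies,", x$D, "designs,",
      length(x$treatments), "treatments\n")
  cat("Treatments:", paste(x$treatments, collapse = ", "),
      "(reference:", paste0(x$reference, ")"), "\n")
  n_multi <- sum(vapply(x$studies,
                        function(s) length(s$treatments) > 2L, logical(1)))
  if (n_multi > 0) cat("Multi-arm studies:", n_multi, "\n")
  invisible(x)
}

#' Flatten a network back to a contrast table
#'
#' Returns the canonical contrast-level table of a network: one row per
#' study contrast, oriented as non-reference treatment versus the design
#' reference. For multi-arm studies the off-diagonal covariances are not
#' representable in this table; re-parsing such data needs the arm
#' variances from [arm_variances()] as well.
#'
#' @param x a \code{network_data} object.
#' @param ... unused.
#' @return A data frame with columns \code{study, treat1, treat2, effect, se}.
#' @export
as.data.frame.network_data <- function(x, ...) {
  rows <- lapply(x$studies, function(s) {
    data.frame(study = s$study,
               treat1 = names(s$y),
               treat2 = s$reference,
               effect = unname(s$y),
               se = sqrt(diag(s$cov)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Arm variances of multi-arm studies
#'
#' Recovers the arm-level variances underlying the covariance blocks of all
#' multi-arm studies in a network (the inverse of the construction used by
#' [parse_contrasts()]). Errors if a block was not built from arm variances
#' (unequal off-diagonal entries).
#'
#' @param net a \code{network_data} object.
#' @return A data frame with columns \code{study, treatment, var}, or
#'   \code{NULL} if the network has no multi-arm study.
#' @export
arm_variances <- function(net) {
  stopifnot(inherits(net, "network_data"))
  multi <- Filter(function(s) length(s$treatments) > 2L, net$studies)
  if (length(multi) == 0L) return(NULL)
  rows <- lapply(multi, function(s) {
    off <- s$cov[upper.tri(s$cov)]
    if (diff(range(off)) > 1e-10 * max(abs(off), 1))
      stop("study '", s$study, "': covariance block is not arm-variance ",
           "decomposable")
    v_ref <- mean(off)
    v <- c(v_ref, diag(s$cov) - v_ref)
    data.frame(study = s$study, treatment = s$treatments, var = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
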