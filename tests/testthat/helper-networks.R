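# Shared fixtures and independent oracles, all built in code.

scenario_fit <- function(name, ...) netgls(make_scenario(name, ...))

# The three-treatment worked example: two studies on A0:A1, one on A0:A2,
# one on A1:A2.
three_treatment_rows <- function(effects = c(0.5, 0.7, 0.2, -0.4),
                                 ses = c(1, 1, 1, 1)) {
  data.frame(study = c("s1", "s2", "s3", "s4"),
             treat1 = c("A1", "A1", "A2", "A2"),
             treat2 = c("A0", "A0", "A0", "A1"),
             effect = effects, se = ses, stringsAsFactors = FALSE)
}

# An eight-treatment network containing a pendant design (6:7 introduces
# treatment 7 seen nowhere else) and a bridge design (3:4).
pendant_bridge_rows <- function() {
  edges <- c("1:2", "1:3", "2:3", "3:4", "4:5", "4:6", "5:6", "6:7",
             "4:8", "6:8")
  pairs <- strsplit(edges, ":")
  data.frame(study = paste0("s", seq_along(edges)),
             treat1 = vapply(pairs, `[`, character(1), 2),
             treat2 = vapply(pairs, `[`, character(1), 1),
             effect = 0, se = 1, stringsAsFactors = FALSE)
}

# A star network (no loops): inconsistency unassessable.
star_rows <- function(k = 4) {
  data.frame(study = paste0("s", seq_len(k)),
             treat1 = LETTERS[seq_len(k) + 1], treat2 = "A",
             effect = 0, se = 1, stringsAsFactors = FALSE)
}

# Unit-variance network from an explicit edge list.
edges_to_rows <- function(edges, effects = 0) {
  pairs <- strsplit(edges, ":")
  data.frame(study = paste0("s", seq_along(edges)),
             treat1 = vapply(pairs, `[`, character(1), 2),
             treat2 = vapply(pairs, `[`, character(1), 1),
             effect = rep_len(effects, length(edges)), se = 1,
             stringsAsFactors = FALSE)
}

# Effective resistance between two nodes of a graph with unit resistors,
# via the Moore-Penrose inverse of the Laplacian. Inf when disconnected.
effective_resistance <- function(edges, a, b) {
  verts <- sort(unique(unlist(strsplit(edges, ":"))))
  if (!(a %in% verts) || !(b %in% verts)) return(Inf)
  n <- length(verts)
  L <- matrix(0, n, n, dimnames = list(verts, verts))
  for (e in strsplit(edges, ":")) {
    L[e[1], e[2]] <- L[e[1], e[2]] - 1
    L[e[2], e[1]] <- L[e[2], e[1]] - 1
  }
  diag(L) <- -rowSums(L)
  # resistance is finite only within one component
  g <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(strsplit(edges, ":"),
                          function(e) data.frame(from = e[1], to = e[2]))),
    directed = FALSE, vertices = verts)
  comp <- igraph::components(g)$membership
  if (comp[a] != comp[b]) return(Inf)
  Lp <- MASS::ginv(L)
  ia <- match(a, verts); ib <- match(b, verts)
  Lp[ia, ia] + Lp[ib, ib] - 2 * Lp[ia, ib]
}

# All connected edge subsets of K5 with at most max_edges edges.
connected_edge_subsets <- function(max_edges = 5) {
  all_edges <- apply(utils::combn(as.character(1:5), 2), 2, paste,
                     collapse = ":")
  out <- list()
  for (k in seq_len(max_edges)) {
    sets <- utils::combn(all_edges, k, simplify = FALSE)
    for (s in sets) {
      verts <- sort(unique(unlist(strsplit(s, ":"))))
      el <- do.call(rbind, lapply(strsplit(s, ":"),
                                  function(e) data.frame(from = e[1],
                                                         to = e[2])))
      g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = verts)
      if (igraph::components(g)$no == 1L) out[[length(out) + 1L]] <- s
    }
  }
  out
}

# Random heterogeneous + inconsistent network simulations for property
# tests: a six-treatment topology with one three-arm design.
random_mixed_sim <- function(seed, het_sd = 0.4) {
  set.seed(seed)
  designs <- c("A:B", "A:C", "B:C", "B:D", "C:D", "A:B:C")
  theta <- stats::setNames(stats::rnorm(3, 0, 1), c("B", "C", "D"))
  simulate_network(designs, theta = theta, het_sd = het_sd,
                   n_studies = c(3, 2, 2, 1, 2, 2))
}

# One-stage GLS oracle computed straight from the study-level model.
one_stage_oracle <- function(net) {
  basic <- net$treatments[-1]
  rows <- list(); y <- numeric(0); blocks <- list()
  for (s in net$studies) {
    for (t in names(s$y)) {
      r <- stats::setNames(numeric(length(basic)), basic)
      r[t] <- 1
      if (s$reference != net$reference) r[s$reference] <- -1
      rows[[length(rows) + 1L]] <- r
    }
    y <- c(y, s$y)
    blocks[[length(blocks) + 1L]] <- s$cov
  }
  X <- do.call(rbind, rows)
  n <- length(y)
  Vinv <- matrix(0, n, n)
  i <- 1L
  for (b in blocks) {
    k <- nrow(b)
    Vinv[i:(i + k - 1L), i:(i + k - 1L)] <- solve(b)
    i <- i + k
  }
  A <- crossprod(X, Vinv %*% X)
  covb <- solve(A)
  list(theta = drop(covb %*% crossprod(X, Vinv %*% y)),
       vcov = covb)
}

# Q_inc recomputed by the package's aggregated GLS for an arbitrary vector
# of direct estimates on a fixed unit-variance structure.
qinc_on_structure <- function(model, theta_dir) {
  m <- model
  m$theta_dir[] <- theta_dir
  f <- netqdiag:::fit_aggregated(m)
  Q <- 0
  for (d in names(m$Va_blocks)) {
    idx <- which(m$row_design == d)
    r <- f$resid[idx]
    Q <- Q + drop(crossprod(r, solve(m$Va_blocks[[d]], r)))
  }
  Q
}
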