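test_that("the aggregated design matrix encodes contrasts vs the reference", {
  net <- parse_contrasts(three_treatment_rows())
  m <- build_design_matrix(net)
  expect_equal(unname(m$Xa),
               matrix(c(1, 0, -1,
                        0, 1, 1), ncol = 2),
               tolerance = 0)
  expect_equal(rownames(m$Xa), c("A0:A1", "A0:A2", "A1:A2"))

  # adding a three-arm design appends one row per non-reference arm
  rows <- rbind(three_treatment_rows(),
                data.frame(study = "t1", treat1 = c("A1", "A2"),
                           treat2 = "A0", effect = 0, se = sqrt(2)))
  av <- data.frame(study = "t1", treatment = c("A0", "A1", "A2"), var = 1)
  m2 <- build_design_matrix(parse_contrasts(rows, av))
  expect_equal(nrow(m2$Xa), 5L)
  idx <- which(m2$row_design == "A0:A1:A2")
  expect_equal(unname(m2$Xa[idx, ]), rbind(c(1, 0), c(0, 1)))
  expect_equal(rownames(m2$Xa)[idx], c("A0:A1*", "A0:A2*"))

  single <- parse_contrasts(data.frame(study = "s", treat1 = "B",
                                       treat2 = "A", effect = 0, se = 1))
  expect_equal(unname(build_design_matrix(single)$Xa),
               matrix(1, 1, 1))
})

test_that("GLS reproduces hand-solved and exactly consistent networks", {
  # triangle with a unit perturbation: minimize (1-a)^2 + b^2 + (b-a)^2
  tri <- netgls(make_scenario("triangle", delta = 1))
  expect_equal(unname(coef(tri)), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(fitted(tri)), c(2 / 3, 1 / 3, -1 / 3),
               tolerance = 1e-12)

  # consistent direct estimates are reproduced exactly
  theta <- c(B = 0.4, C = -0.2, D = 1.1)
  sim <- simulate_network(c("A:B", "A:C", "B:C", "B:D"), theta = theta,
                          het_sd = 0, n_studies = 1, seed = 3)
  dat <- sim$data
  # overwrite the sampled effects with exactly consistent values
  full <- c(A = 0, theta)
  dat$effect <- full[dat$treat1] - full[dat$treat2]
  fit <- netgls(dat)
  expect_equal(coef(fit), theta, tolerance = 1e-10)
  expect_equal(fit$Q$Q_inc, 0, tolerance = 1e-10)
})

test_that("estimates agree with an independent multivariate GLS fitter", {
  skip_if_not_installed("metafor")
  sim <- random_mixed_sim(seed = 21)
  net <- parse_contrasts(sim$data, sim$arm_vars)
  fit <- netgls(net)

  # study-level fixed-effects GLS via metafor on the same model
  basic <- net$treatments[-1]
  X <- NULL; y <- NULL; Vfull <- NULL
  for (s in net$studies) {
    for (t in names(s$y)) {
      r <- stats::setNames(numeric(length(basic)), basic)
      r[t] <- 1
      if (s$reference != net$reference) r[s$reference] <- -1
      X <- rbind(X, r)
    }
    y <- c(y, s$y)
    Vfull <- if (is.null(Vfull)) s$cov else
      rbind(cbind(Vfull, matrix(0, nrow(Vfull), nrow(s$cov))),
            cbind(matrix(0, nrow(s$cov), ncol(Vfull)), s$cov))
  }
  rma <- metafor::rma.mv(y, V = Vfull, mods = ~ X - 1, method = "FE")
  expect_equal(unname(coef(fit)), unname(coef(rma)), tolerance = 1e-6)
  expect_equal(unname(vcov(fit)), unname(vcov(rma)), tolerance = 1e-6)
})

test_that("one-stage and two-stage estimation are equivalent", {
  for (seed in c(2, 13)) {
    sim <- random_mixed_sim(seed = seed)
    net <- parse_contrasts(sim$data, sim$arm_vars)
    fit <- netgls(net)
    oracle <- one_stage_oracle(net)
    expect_equal(unname(coef(fit)), unname(oracle$theta),
                 tolerance = 1e-8)
    expect_equal(unname(vcov(fit)), unname(oracle$vcov),
                 tolerance = 1e-8)
  }
})

test_that("the hat matrix is a projection with the documented bounds", {
  for (fit in list(scenario_fit("fig1_a"),
                   netgls(random_mixed_sim(seed = 9)$data,
                          random_mixed_sim(seed = 9)$arm_vars))) {
    H <- hat_matrix(fit)
    expect_equal(H %*% H, H, tolerance = 1e-8)
    expect_equal(sum(diag(H)), fit$net$T, tolerance = 1e-8)
    expect_equal(H %*% fit$model$Xa, fit$model$Xa, tolerance = 1e-8)
    expect_true(all(diag(H) >= -1e-10 & diag(H) <= 1 + 1e-10))
    expect_true(all(H >= -1 - 1e-10 & H <= 1 + 1e-10))
  }
  # an isolated single comparison is fully self-driven
  single <- netgls(data.frame(study = "s", treat1 = "B", treat2 = "A",
                              effect = 0.3, se = 0.5))
  expect_equal(unname(hat_matrix(single)), matrix(1, 1, 1))
})

test_that("hat diagonals match the effective-resistance oracle", {
  skip_if_not_installed("MASS")
  subsets <- connected_edge_subsets(5)
  expect_gt(length(subsets), 100)
  for (edges in subsets) {
    fit <- netgls(edges_to_rows(edges))
    h <- diag(hat_matrix(fit))
    for (i in seq_along(edges)) {
      ab <- strsplit(edges[i], ":")[[1]]
      R_ind <- effective_resistance(edges[-i], ab[1], ab[2])
      expected <- 1 / (1 + 1 / R_ind)   # direct weight vs indirect path
      expect_equal(unname(h[i]), expected, tolerance = 1e-8)
    }
  }
})

test_that("network contrasts do not depend on the reference labelling", {
  rows <- make_scenario("fig1_a")
  relab <- function(x) chartr("123456", "614325", x)
  rows2 <- rows
  rows2$treat1 <- relab(rows2$treat1)
  rows2$treat2 <- relab(rows2$treat2)
  f1 <- netgls(rows)
  f2 <- netgls(rows2)
  re1 <- relative_effects(f1)
  re2 <- relative_effects(f2)
  for (a in f1$net$treatments) for (b in f1$net$treatments) {
    expect_equal(re2$estimate[relab(a), relab(b)], re1$estimate[a, b],
                 tolerance = 1e-10)
    expect_equal(re2$se[relab(a), relab(b)], re1$se[a, b],
                 tolerance = 1e-10)
  }
})

test_that("a design's hat weight splits over studies by inverse variance", {
  rows <- rbind(make_scenario("fig1_a"),
                data.frame(study = "extra", treat1 = "2", treat2 = "1",
                           effect = 0, se = sqrt(1 / 3)))
  fit <- netgls(rows)
  shares <- study_contributions(fit, "1:2")
  expect_equal(sum(shares), unname(fit$H["1:2", "1:2"]))
  # weights 1 and 3: shares split 1/4 vs 3/4
  expect_equal(unname(shares["extra"] / sum(shares)), 0.75)

  single <- study_contributions(fit, "1:3")
  expect_equal(unname(single), unname(fit$H["1:3", "1:3"]))

  multi <- random_mixed_sim(seed = 4)
  mfit <- netgls(multi$data, multi$arm_vars)
  expect_error(study_contributions(mfit, "A:B:C"), "two-arm")
})

test_that("percent formatting rounds half away from zero", {
  fit <- scenario_fit("fig1_a")
  Hp <- hat_matrix(fit, percent = TRUE)
  expect_equal(unname(diag(Hp)), c(63, 53, 70, 63, 70, 63, 53, 63))
  expect_true(all(Hp == round(Hp)))
})
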