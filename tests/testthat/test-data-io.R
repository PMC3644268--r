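test_that("contrast tables parse into studies, designs and counts", {
  net <- parse_contrasts(three_treatment_rows())
  expect_s3_class(net, "network_data")
  expect_equal(net$S, 4L)
  expect_equal(net$D, 3L)
  expect_equal(net$T, 2L)
  expect_equal(net$treatments, c("A0", "A1", "A2"))
  expect_equal(sort(names(net$designs)), c("A0:A1", "A0:A2", "A1:A2"))
  expect_equal(length(net$designs[["A0:A1"]]$studies), 2L)

  minimal <- parse_contrasts(data.frame(study = "s1", treat1 = "A",
                                        treat2 = "B", effect = 0, se = 1))
  expect_equal(minimal$S, 1L)
  expect_equal(minimal$D, 1L)
  s <- minimal$studies[["s1"]]
  # reoriented to the design reference A: contrast is B vs A
  expect_equal(unname(s$y), 0)
  expect_equal(unname(s$cov), matrix(1, 1, 1))
  expect_equal(s$reference, "A")
})

test_that("multi-arm covariance blocks follow the arm-difference algebra", {
  rows <- data.frame(study = "t1", treat1 = c("B", "C"), treat2 = "A",
                     effect = c(0.3, 0.6), se = sqrt(2))
  av <- data.frame(study = "t1", treatment = c("A", "B", "C"), var = 1)
  net <- parse_contrasts(rows, av)
  blk <- net$studies[["t1"]]$cov
  expect_equal(unname(blk), matrix(c(2, 1, 1, 2), 2))
  expect_true(all(eigen(blk, symmetric = TRUE)$values > 0))

  # same block recovered from the complete set of pairwise SEs
  rows2 <- data.frame(study = "t1",
                      treat1 = c("B", "C", "C"), treat2 = c("A", "A", "B"),
                      effect = c(0.3, 0.6, 0.3), se = sqrt(2))
  net2 <- parse_contrasts(rows2)
  expect_equal(net2$studies[["t1"]]$cov, blk)

  # positive definiteness holds for any positive arm variances
  av3 <- data.frame(study = "t1", treatment = c("A", "B", "C"),
                    var = c(0.3, 1.7, 0.02))
  net3 <- parse_contrasts(rows, av3)
  expect_true(all(eigen(net3$studies[["t1"]]$cov)$values > 0))
})

test_that("malformed inputs are rejected with informative errors", {
  disc <- data.frame(study = c("s1", "s2"), treat1 = c("B", "D"),
                     treat2 = c("A", "C"), effect = 0, se = 1)
  expect_error(parse_contrasts(disc), "disconnected")

  dup <- rbind(three_treatment_rows(),
               data.frame(study = "s1", treat1 = "A0", treat2 = "A1",
                          effect = 0.1, se = 1))
  expect_error(parse_contrasts(dup), "duplicate")

  underspec <- data.frame(study = "t1", treat1 = c("B", "C"),
                          treat2 = "A", effect = 0, se = 1)
  expect_error(parse_contrasts(underspec), "arm variances")

  # pairwise SEs implying a negative arm variance
  bad <- data.frame(study = "t1",
                    treat1 = c("B", "C", "C"), treat2 = c("A", "A", "B"),
                    effect = 0, se = sqrt(c(1, 1, 4)))
  expect_error(parse_contrasts(bad), "non-positive arm variance")

  expect_error(parse_contrasts(data.frame(study = "s", treat1 = "A",
                                          treat2 = "B", effect = 0,
                                          se = -1)),
               "positive")
})

test_that("swapping treat1/treat2 with negated effect changes nothing", {
  rows <- three_treatment_rows()
  flipped <- rows
  flipped[2, c("treat1", "treat2")] <- rows[2, c("treat2", "treat1")]
  flipped$effect[2] <- -rows$effect[2]
  f1 <- netgls(rows)
  f2 <- netgls(flipped)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$Q$Q_net, f2$Q$Q_net)
  expect_equal(f1$Q$Q_inc, f2$Q$Q_inc)
})

test_that("networks round-trip through the contrast table", {
  sim <- random_mixed_sim(seed = 11)
  net <- parse_contrasts(sim$data, sim$arm_vars)
  back <- parse_contrasts(as.data.frame(net), arm_variances(net))
  expect_equal(names(back$studies), names(net$studies))
  for (id in names(net$studies)) {
    expect_equal(back$studies[[id]]$y, net$studies[[id]]$y)
    expect_equal(back$studies[[id]]$cov, net$studies[[id]]$cov)
  }
})

test_that("the design graph carries one tagged edge per design pair", {
  g <- design_graph(parse_contrasts(make_scenario("fig1_a")))
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 8)

  tri <- parse_contrasts(
    data.frame(study = "t1", treat1 = c("B", "C"), treat2 = "A",
               effect = 0, se = sqrt(2)),
    data.frame(study = "t1", treatment = c("A", "B", "C"), var = 1))
  gt <- design_graph(tri)
  expect_equal(igraph::ecount(gt), 3)
  expect_equal(unique(igraph::E(gt)$design), "A:B:C")

  single <- design_graph(parse_contrasts(
    data.frame(study = "s", treat1 = "B", treat2 = "A", effect = 0,
               se = 1)))
  expect_equal(igraph::vcount(single), 2)
  expect_equal(igraph::ecount(single), 1)
})
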