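test_that("edge weights count shared segment clusters", {
  inc <- rbind(S1 = c(1, 1, 1, 0), S2 = c(1, 1, 1, 1), S3 = c(0, 0, 0, 0))
  colnames(inc) <- sprintf("G%d", 1:4)
  meta <- data.frame(sample_id = rownames(inc), disease = "healthy",
                     continent = "Europe")
  net <- build_sharing_network(inc, meta)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_equal(net$density, 1 / 3)
  ## disjoint carriage: empty edge set
  inc2 <- rbind(S1 = c(1, 0), S2 = c(0, 1))
  colnames(inc2) <- c("G1", "G2")
  net2 <- build_sharing_network(inc2, meta[1:2, ])
  expect_equal(nrow(net2$edges), 0)
  expect_equal(net2$density, 0)
  ## metadata must cover all samples
  expect_error(build_sharing_network(inc, meta[1:2, ]), "S3")
})

test_that("edge weights equal incidence row dot products (brute force)", {
  mk <- make_incidence(30, 40, density = 0.3, seed = 21)
  net <- build_sharing_network(mk$incidence, mk$metadata)
  for (e in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[e],
                 sum(mk$incidence[net$edges$sample_a[e], ] *
                       mk$incidence[net$edges$sample_b[e], ]))
  }
})

test_that("checkerboard permutation conserves every row and column sum", {
  for (seed in 1:5) {
    mk <- make_incidence(50, 80, density = 0.25, seed = seed)
    perm <- permute_incidence(mk$incidence, seed = seed)
    expect_identical(rowSums(perm), rowSums(mk$incidence))
    expect_identical(colSums(perm), colSums(mk$incidence))
    expect_gt(attr(perm, "successes"), 0)
    expect_gt(sum(perm != mk$incidence), 0)  # actually randomized
  }
})

test_that("an all-ones incidence admits no swap and is returned flagged", {
  inc <- matrix(1L, 4, 4, dimnames = list(paste0("S", 1:4), paste0("G", 1:4)))
  perm <- permute_incidence(inc, seed = 1)
  expect_true(all(perm == inc))
  expect_true(attr(perm, "no_swap"))
})

test_that("the two-state chain on a 2x2 identity visits both states equally", {
  inc <- diag(2)
  dimnames(inc) <- list(c("S1", "S2"), c("G1", "G2"))
  storage.mode(inc) <- "integer"
  flipped <- 0
  for (seed in 1:2000) {
    perm <- permute_incidence(inc, seed = seed)
    if (perm[1, 1] == 0) flipped <- flipped + 1
  }
  expect_lt(abs(flipped / 2000 - 0.5), 0.05)
})

test_that("group connectivity p-values respect the empirical floor and ceiling", {
  mk <- make_incidence(40, 60, density = 0.2, seed = 31)
  ens <- null_ensemble(mk$incidence, mk$metadata, n_perm = 99, seed = 3)
  net <- build_sharing_network(mk$incidence, mk$metadata)
  gt <- group_connectivity_test(net, ens)
  expect_true(all(gt$p >= 1 / 100))
  expect_true(all(gt$p <= 1))
})

test_that("planted within-group enrichment drives the group test to the p floor", {
  base_cfg <- sim_config(n_samples = 150, Nm = 300, d = 1e-3, seed = 401)
  sim0 <- simulate_segment_incidence(base_cfg, n_entities = 200)
  f0 <- colMeans(sim0$incidence)
  planted <- names(f0)[f0 > 0.1 & f0 < 0.4][1:8]
  cfg <- sim_config(n_samples = 150, Nm = 300, d = 1e-3, seed = 401,
                    planted_selection = data.frame(segment_id = planted,
                                                   disease = "IBD",
                                                   boost = 10))
  sim <- simulate_segment_incidence(cfg, n_entities = 200)
  ens <- null_ensemble(sim$incidence, sim$metadata, n_perm = 200, seed = 4,
                       geography = FALSE, segments = FALSE,
                       edges = data.frame(sample_a = character(),
                                          sample_b = character()))
  net <- build_sharing_network(sim$incidence, sim$metadata)
  gt <- group_connectivity_test(net, ens)
  expect_equal(gt$p[gt$disease == "IBD"], 1 / 201)
})

test_that("two samples forced to share many clusters form a significant edge", {
  mk <- make_incidence(40, 200, density = 0.05, seed = 41)
  inc <- mk$incidence
  inc["S001", 1:50] <- 1L
  inc["S002", 1:50] <- 1L
  meta <- mk$metadata
  meta$disease <- "healthy"  # one group so the pair is a same-disease edge
  ## the p floor 1 / (n_perm + 1) must clear the FDR threshold after
  ## correction across all same-disease edges, hence the large ensemble
  ens <- null_ensemble(inc, meta, n_perm = 10000, seed = 6,
                       geography = FALSE, segments = FALSE)
  net <- build_sharing_network(inc, meta)
  es <- edge_significance(net, ens)
  target <- es[es$sample_a == "S001" & es$sample_b == "S002", ]
  expect_true(target$significant)
  expect_lt(target$q, 0.05)
})

test_that("edge significance stays near its nominal rate on null data", {
  mk <- make_incidence(35, 120, density = 0.25, seed = 51)
  ens <- null_ensemble(mk$incidence, mk$metadata, n_perm = 200, seed = 7,
                       geography = FALSE, segments = FALSE)
  net <- build_sharing_network(mk$incidence, mk$metadata)
  es <- edge_significance(net, ens)
  expect_lte(mean(es$significant), 0.05)
})

test_that("segments carried once in a group are never significant", {
  mk <- make_incidence(30, 50, density = 0.15, seed = 61)
  inc <- mk$incidence
  inc[, "G001"] <- 0L
  inc["S001", "G001"] <- 1L
  ens <- null_ensemble(inc, mk$metadata, n_perm = 100, seed = 8,
                       geography = FALSE)
  ss <- segment_significance(inc, ens)
  g1 <- ss[ss$segment == "G001", ]
  expect_true(all(g1$observed == 0))
  expect_true(all(!g1$significant))
  expect_true(all(g1$p == 1))
})

test_that("per-capita strength ratios match the worked example", {
  ## node n1: one same-disease partner with weight 3, two other-disease
  ## partners with weights 1 and 2 -> (3/1) / (3/2) = 2
  inc <- rbind(
    n1 = c(rep(1, 3), rep(1, 1), rep(1, 2), 0),
    n2 = c(rep(1, 3), 0, 0, 0, 0),
    m1 = c(0, 0, 0, 1, 0, 0, 1),
    m2 = c(0, 0, 0, 0, 1, 1, 1))
  colnames(inc) <- sprintf("G%d", 1:7)
  meta <- data.frame(sample_id = rownames(inc),
                     disease = c("IBD", "IBD", "healthy", "healthy"),
                     continent = "Europe")
  net <- build_sharing_network(inc, meta)
  sr <- strength_ratio(net, mode = "per_capita")
  expect_equal(sr$per_node$ratio[sr$per_node$sample_id == "n1"], 2.0)
  raw <- strength_ratio(net, mode = "raw")
  expect_equal(raw$per_node$ratio[raw$per_node$sample_id == "n1"], 1.0)
})

test_that("strength ratios need at least two disease groups", {
  inc <- rbind(S1 = c(1, 1), S2 = c(1, 0))
  colnames(inc) <- c("G1", "G2")
  meta <- data.frame(sample_id = c("S1", "S2"), disease = "IBD",
                     continent = "Europe")
  net <- build_sharing_network(inc, meta)
  expect_error(strength_ratio(net), "two disease groups")
})

test_that("label-shuffled networks have median strength ratio near one", {
  set.seed(71)
  meds <- replicate(30, {
    mk <- make_incidence(60, 80, density = 0.3,
                         seed = sample.int(1e6, 1))
    net <- build_sharing_network(mk$incidence, mk$metadata)
    sr <- suppressWarnings(strength_ratio(net))
    median(sr$per_node$ratio[is.finite(sr$per_node$ratio)])
  })
  expect_lt(abs(median(meds) - 1), 0.05)
})

test_that("cross-continental fractions count significant same-disease edges", {
  mk <- make_incidence(20, 30, density = 0.4, seed = 81)
  net <- build_sharing_network(mk$incidence, mk$metadata)
  ens <- null_ensemble(mk$incidence, mk$metadata, n_perm = 50, seed = 9,
                       geography = FALSE, segments = FALSE)
  es <- edge_significance(net, ens)
  ## none significant -> all fractions zero (where cross edges exist)
  es$significant <- FALSE
  cc0 <- cross_continental_summary(net, es)
  expect_true(all(cc0$fraction[cc0$n_cross > 0] == 0))
  ## all significant -> fraction one
  es$significant <- TRUE
  cc1 <- cross_continental_summary(net, es)
  expect_true(all(cc1$fraction[cc1$n_cross > 0] == 1))
  ## planted at a known fraction: flag exactly half of the cross edges
  cont <- setNames(net$metadata$continent, net$metadata$sample_id)
  cross_idx <- which(cont[es$sample_a] != cont[es$sample_b] &
                       es$disease == "healthy")
  if (length(cross_idx) >= 2) {
    es$significant <- FALSE
    half <- cross_idx[seq_len(floor(length(cross_idx) / 2))]
    es$significant[half] <- TRUE
    cc <- cross_continental_summary(net, es)
    expect_equal(cc$fraction[cc$disease == "healthy"],
                 length(half) / length(cross_idx))
  }
})

test_that("obesity is excluded from geography-resolved groups by default", {
  mk <- make_incidence(60, 40, density = 0.2, seed = 91)
  ens <- null_ensemble(mk$incidence, mk$metadata, n_perm = 20, seed = 10,
                       segments = FALSE)
  geo <- ens$defs[!is.na(ens$defs$cont_a), ]
  expect_false("obese" %in% geo$disease)
  expect_true("obese" %in% ens$defs$disease)  # still in the pooled stats
})
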