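test_that("deduplication keeps the larger plasmid of qualifying pairs", {
  ## single plasmid, no matches
  res <- dedup_plasmids(c(A = 1000),
                        data.frame(a = character(), b = character(),
                                   identity = numeric(),
                                   aligned_length = numeric()))
  expect_equal(res$representatives, "A")

  ## A (10 kb) absorbs B (9 kb) at 0.96 identity over 9.6 kb; C unrelated
  lengths <- c(A = 10000, B = 9000, C = 5000)
  matches <- data.frame(a = "A", b = "B", identity = 0.96,
                        aligned_length = 9600)
  res <- dedup_plasmids(lengths, matches)
  expect_setequal(res$representatives, c("A", "C"))
  expect_equal(unname(res$map[["B"]]), "A")

  ## exhaustive check: survivors have no qualifying pair among themselves
  surv <- res$representatives
  for (i in surv) for (j in surv) {
    if (i == j) next
    hit <- matches[(matches$a == i & matches$b == j) |
                     (matches$a == j & matches$b == i), ]
    if (nrow(hit)) {
      expect_false(hit$identity > 0.95 &
                     hit$aligned_length >= 0.95 * max(lengths[i], lengths[j]))
    }
  }
})

test_that("identity exactly at the threshold does not merge (rule is strictly above)", {
  res <- dedup_plasmids(c(A = 10000, B = 9000),
                        data.frame(a = "A", b = "B", identity = 0.95,
                                   aligned_length = 9800))
  expect_setequal(res$representatives, c("A", "B"))
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(42)
  for (trial in 1:5) {
    n <- 12
    ids <- sprintf("P%02d", 1:n)
    lengths <- setNames(sample(1000:20000, n), ids)
    pairs <- t(combn(ids, 2))
    take <- runif(nrow(pairs)) < 0.3
    matches <- data.frame(a = pairs[take, 1], b = pairs[take, 2],
                          identity = runif(sum(take), 0.9, 1),
                          aligned_length = runif(sum(take), 0.8, 1) *
                            pmax(lengths[pairs[take, 1]],
                                 lengths[pairs[take, 2]]))
    r1 <- dedup_plasmids(lengths, matches)
    ## idempotence: running again on survivors changes nothing
    keep <- matches$a %in% r1$representatives &
      matches$b %in% r1$representatives
    r2 <- dedup_plasmids(lengths[r1$representatives],
                         matches[keep, , drop = FALSE])
    expect_setequal(r2$representatives, r1$representatives)
    ## order invariance: permuting the match rows gives the same survivors
    perm <- sample(nrow(matches))
    r3 <- dedup_plasmids(lengths, matches[perm, , drop = FALSE])
    expect_setequal(r3$representatives, r1$representatives)
  }
})

test_that("self-matches are ignored with a warning", {
  expect_warning(
    res <- dedup_plasmids(c(A = 1000, B = 900),
                          data.frame(a = "A", b = "A", identity = 1,
                                     aligned_length = 1000)),
    "self-match")
  expect_setequal(res$representatives, c("A", "B"))
})

test_that("presence calling applies the coverage threshold inclusively", {
  counts <- matrix(c(10, 10, 10, 0), 1, 4,
                   dimnames = list("S1", c("P1", "P2", "P3", "P4")))
  coverage <- matrix(c(1.0, 0.699, 0.70, 1.0), 1, 4)
  ab <- make_abund(counts, coverage, 100)
  pres <- call_presence(ab)
  expect_true(pres[1, "P1"])    # full coverage, positive abundance
  expect_false(pres[1, "P2"])   # 0.699 below the threshold
  expect_true(pres[1, "P3"])    # exactly 0.70 is present
  expect_false(pres[1, "P4"])   # covered but zero abundance
})

test_that("missing coverage is treated as zero with a warning", {
  counts <- matrix(c(5, 5), 1, 2, dimnames = list("S1", c("P1", "P2")))
  coverage <- matrix(c(NA, 0.9), 1, 2)
  ab <- abundance_matrix(counts, matrix(c(0.9, 0.9), 1, 2), 10)
  ab$coverage[1, 1] <- NA
  expect_warning(pres <- call_presence(ab), "missing coverage")
  expect_false(pres[1, "P1"])
})

test_that("the depth cutoff is 1% of the lowest present abundance in the shallowest sample", {
  counts <- rbind(S1 = c(P1 = 50, P2 = 200, P3 = 0.4),
                  S2 = c(P1 = 80, P2 = 0.3, P3 = 90))
  ab <- make_abund(counts, matrix(1, 2, 3), read_depth = c(100, 1e6))
  pres <- call_presence(ab)
  dc <- apply_depth_cutoff(ab, pres)
  ## shallowest sample is S1; lowest present abundance there is 0.4 -> 0.004
  expect_equal(dc$cutoff, 0.004)
  expect_equal(dc$shallowest_sample, "S1")
  expect_true(all(dc$presence == pres))  # everything above the cutoff

  ## a cell below a larger cutoff becomes absent
  counts2 <- rbind(S1 = c(P1 = 50, P2 = 200),
                   S2 = c(P1 = 0.4, P2 = 90))
  ab2 <- make_abund(counts2, matrix(1, 2, 2), read_depth = c(100, 1e6))
  pres2 <- call_presence(ab2)
  dc2 <- apply_depth_cutoff(ab2, pres2)
  expect_equal(dc2$cutoff, 0.5)          # 1% of 50
  expect_false(dc2$presence["S2", "P1"]) # 0.4 < 0.5 masked
  expect_true(dc2$presence["S2", "P2"])
})

test_that("an empty shallowest sample aborts with advice", {
  counts <- rbind(S1 = c(P1 = 0, P2 = 0), S2 = c(P1 = 10, P2 = 10))
  ab <- make_abund(counts, matrix(1, 2, 2), read_depth = c(10, 1e5))
  pres <- call_presence(ab)
  expect_error(apply_depth_cutoff(ab, pres), "relax the presence filter")
})

test_that("filtering is monotone: tightening thresholds never adds presences", {
  set.seed(77)
  counts <- matrix(rpois(300, 5), 15, 20,
                   dimnames = list(sprintf("S%02d", 1:15),
                                   sprintf("P%02d", 1:20)))
  coverage <- matrix(runif(300), 15, 20)
  ab <- make_abund(counts, coverage, sample(50:500, 15))
  p1 <- call_presence(ab, min_cov = 0.5)
  p2 <- call_presence(ab, min_cov = 0.8)
  expect_true(all(p1 | !p2))  # p2 subset of p1
  dc <- apply_depth_cutoff(ab, p1)
  expect_true(all(p1 | !dc$presence))
})

test_that("richness ratios divide plasmid by species richness", {
  pres <- matrix(TRUE, 1, 10, dimnames = list("S1", sprintf("P%02d", 1:10)))
  taxa <- matrix(1, 1, 5, dimnames = list("S1", sprintf("sp%d", 1:5)))
  meta <- data.frame(sample_id = "S1", disease = "healthy")
  rr <- richness_ratio(pres, taxa, meta)
  expect_equal(rr$per_sample$ratio, 2.0)
  expect_equal(rr$per_sample$plasmid_richness, 10)
})

test_that("a shifted group is detected and zero-species samples are excluded", {
  set.seed(5)
  n <- 100
  pres <- matrix(runif(2 * n * 40) < 0.5, 2 * n, 40,
                 dimnames = list(sprintf("S%03d", 1:(2 * n)), NULL))
  colnames(pres) <- sprintf("P%02d", 1:40)
  taxa <- matrix(1L, 2 * n, 20,
                 dimnames = list(rownames(pres), sprintf("sp%d", 1:20)))
  ## group B carries ~50% more plasmids
  pres[(n + 1):(2 * n), ] <- runif(n * 40) < 0.75
  meta <- data.frame(sample_id = rownames(pres),
                     disease = rep(c("healthy", "IBD"), each = n))
  rr <- richness_ratio(pres, taxa, meta)
  expect_lt(rr$tests$q[1], 0.05)
  ## zero species richness excluded with warning
  taxa[1, ] <- 0L
  expect_warning(rr2 <- richness_ratio(pres, taxa, meta), "zero species")
  expect_true(is.na(rr2$per_sample$ratio[rr2$per_sample$sample_id == "S001"]))
})

test_that("the length trough falls between bimodal peaks and is absent for unimodal data", {
  set.seed(19)
  lengths <- c(rlnorm(800, log(3000), 0.3), rlnorm(200, log(30000), 0.3))
  trough <- length_trough(lengths)
  expect_gt(trough, 3000)
  expect_lt(trough, 30000)
  expect_true(is.na(length_trough(rlnorm(500, log(5000), 0.3))))
  ## symmetric construction: trough near the geometric midpoint
  sym <- c(rlnorm(500, log(2000), 0.25), rlnorm(500, log(20000), 0.25))
  tr <- length_trough(sym)
  mid <- sqrt(2000 * 20000)
  expect_lt(abs(log10(tr) - log10(mid)), 0.25)
  expect_error(length_trough(c(1, 2, 3)), "at least 10")
})
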