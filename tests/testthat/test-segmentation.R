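test_that("doubling concatenates a sequence with itself", {
  expect_equal(unname(doubled_sequence(c(x = "ACGT"))), "ACGTACGT")
})

test_that("two identical plasmids give one full-length hit", {
  set.seed(101)
  s <- random_dna(1500)
  for (eng in c("seed", "dp")) {
    hits <- find_shared_segments(c(A = s, B = s), engine = eng)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$length, 1500)
    expect_equal(hits$identity, 1.0)
  }
})

test_that("the length threshold is exact: 999 bp is rejected, 1000 bp accepted", {
  set.seed(102)
  block999 <- random_dna(999)
  block1000 <- random_dna(1000)
  ## non-matching flanks (A-runs vs C-runs) so the optimal local alignment
  ## cannot extend a single base past the planted block
  mk <- function(block) {
    a <- random_dna(3000); b <- random_dna(3000)
    substr(a, 471, 500) <- strrep("A", 30)
    substr(a, 501, 500 + nchar(block)) <- block
    substr(a, 501 + nchar(block), 530 + nchar(block)) <- strrep("A", 30)
    substr(b, 1171, 1200) <- strrep("C", 30)
    substr(b, 1201, 1200 + nchar(block)) <- block
    substr(b, 1201 + nchar(block), 1230 + nchar(block)) <- strrep("C", 30)
    c(A = a, B = b)
  }
  expect_equal(nrow(find_shared_segments(mk(block999))), 0)
  h <- find_shared_segments(mk(block1000))
  expect_equal(nrow(h), 1)
  expect_gte(h$length, 1000)
})

test_that("a mutated block is found with identity close to the planted value", {
  set.seed(103)
  block <- random_dna(1200)
  a <- random_dna(4000); b <- random_dna(3500)
  substr(a, 1001, 2200) <- mutate_dna(block, 0.075)
  substr(b, 501, 1700) <- mutate_dna(block, 0.075)
  hits <- find_shared_segments(c(A = a, B = b))
  expect_equal(nrow(hits), 1)
  expect_lt(abs(hits$identity - 0.85), 0.02)
  oracle <- sw_oracle(a, b)
  expect_lt(abs(hits$identity - oracle$identity), 0.02)
  expect_lt(abs(hits$length - oracle$length) / oracle$length, 0.1)
})

test_that("origin-spanning blocks are recovered through the doubling trick", {
  set.seed(104)
  block <- random_dna(1000)
  La <- 3000
  a <- random_dna(La); b <- random_dna(3000)
  ## place block across the origin of A: last 200 bp then first 800 bp
  substr(a, La - 199, La) <- substr(block, 1, 200)
  substr(a, 1, 800) <- substr(block, 201, 1000)
  substr(b, 901, 1900) <- block
  hits <- find_shared_segments(c(A = a, B = b))
  expect_equal(nrow(hits), 1)
  ## full block found (random flanks can extend the alignment by a base
  ## or two, hence the small slack)
  expect_gte(hits$length, 1000)
  expect_lte(hits$length, 1010)
  ## reported as an origin-spanning interval on circular coordinates
  expect_lt(abs(hits$start_a - (La - 200)), 5)
  expect_lt(abs(hits$end_a - (La + 800)), 5)
  expect_gt(hits$end_a, La)

  ## a plain linear comparison of the undoubled sequences cannot reach
  ## 1000 contiguous bases: the two fragments are 200 and 800 bp
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -4, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 8, gapExtension = 4)
  expect_lt(Biostrings::nchar(aln), 1000)
})

test_that("doubling duplicates collapse to a single hit per shared block", {
  set.seed(105)
  block <- random_dna(1500)
  a <- random_dna(4000); b <- random_dna(4000)
  substr(a, 1001, 2500) <- block
  substr(b, 2001, 3500) <- block
  hits <- find_shared_segments(c(A = a, B = b))
  expect_equal(nrow(hits), 1)
})

test_that("rotating a plasmid's origin leaves segment calls unchanged", {
  set.seed(106)
  cfg <- sim_config(n_plasmids = 10, seed = 206)
  gen <- generate_plasmid_sequences(cfg)
  h0 <- find_shared_segments(gen$sequences)
  seqs_rot <- gen$sequences
  for (i in seq_along(seqs_rot)) {
    seqs_rot[[i]] <- rotate_dna(seqs_rot[[i]], 137 * i)
  }
  h1 <- find_shared_segments(seqs_rot)
  key <- function(h) {
    k <- data.frame(a = pmin(h$plasmid_a, h$plasmid_b),
                    b = pmax(h$plasmid_a, h$plasmid_b))
    k <- k[order(k$a, k$b), ]
    paste(k$a, k$b)
  }
  expect_equal(key(h1), key(h0))
  o0 <- order(h0$plasmid_a, h0$plasmid_b)
  o1 <- order(h1$plasmid_a, h1$plasmid_b)
  expect_equal(h1$length[o1], h0$length[o0], tolerance = 0.02)
  expect_equal(h1$identity[o1], h0$identity[o0], tolerance = 0.02)
})

test_that("the seed engine agrees with full dynamic programming on small instances", {
  set.seed(107)
  cfg <- sim_config(n_plasmids = 8, length_modes = c(2500, 4000),
                    length_sdlog = c(0.1, 0.1), seed = 207)
  blocks <- data.frame(block_id = c("B1", "B2"), length = c(1100, 1600),
                       identity = c(0.9, 1), n_carriers = 2,
                       origin_spanning = c(FALSE, TRUE))
  gen <- generate_plasmid_sequences(cfg, blocks)
  hs <- find_shared_segments(gen$sequences, engine = "seed")
  hd <- find_shared_segments(gen$sequences, engine = "dp")
  keyify <- function(h) sort(paste(pmin(h$plasmid_a, h$plasmid_b),
                                   pmax(h$plasmid_a, h$plasmid_b)))
  expect_equal(keyify(hs), keyify(hd))
  os <- order(hs$plasmid_a, hs$plasmid_b)
  od <- order(hd$plasmid_a, hd$plasmid_b)
  expect_equal(hs$identity[os], hd$identity[od], tolerance = 0.02)
})

test_that("non-ACGT input is rejected with a position report", {
  expect_error(find_shared_segments(c(A = "ACGTNACGT", B = "ACGT")),
               "position 5")
})

test_that("empty input yields an empty hit table", {
  h <- find_shared_segments(setNames(character(), character()))
  expect_equal(nrow(h), 0)
})

test_that("hits are dropped unless their plasmids occur in at least two samples", {
  set.seed(108)
  s <- random_dna(2000)
  plasmids <- c(A = s, B = s)
  pres1 <- matrix(c(TRUE, TRUE), 1, 2,
                  dimnames = list("S1", c("A", "B")))
  expect_equal(nrow(find_shared_segments(plasmids, presence = pres1)), 0)
  pres2 <- rbind(S1 = c(A = TRUE, B = FALSE), S2 = c(A = FALSE, B = TRUE))
  expect_equal(nrow(find_shared_segments(plasmids, presence = pres2)), 1)
})

test_that("segments cluster by identity with mutual coverage required", {
  set.seed(109)
  base <- random_dna(2000)
  a <- random_dna(5000); b <- random_dna(5000)
  c_ <- random_dna(5000); d_ <- random_dna(5000)
  substr(a, 1001, 3000) <- base
  substr(b, 501, 2500) <- mutate_dna(base, 0.075)   # ~85% to A's copy
  other <- random_dna(1400)
  substr(c_, 2001, 3400) <- other
  substr(d_, 101, 1500) <- other
  plas <- c(A = a, B = b, C = c_, D = d_)
  hits <- find_shared_segments(plas)
  cl <- cluster_segments(hits, plas)
  expect_equal(length(cl$representatives), 2)
  byc <- split(cl$members$plasmid_id, cl$members$cluster_id)
  sets <- lapply(byc, function(x) sort(unique(x)))
  expect_true(list(c("A", "B")) %in% sets || any(vapply(sets, identical, TRUE, y = c("A", "B"))))
  expect_true(any(vapply(sets, identical, TRUE, y = c("C", "D"))))

  ## coverage failure: a fragment covering only 80% at high identity
  ## founds its own cluster
  frag <- substr(base, 1, 1600)  # 80% of 2000
  e_ <- random_dna(5000); f_ <- random_dna(5000)
  substr(e_, 1001, 2600) <- frag
  substr(f_, 2001, 3600) <- frag
  plas2 <- c(A = a, B = b, E = e_, F = f_)
  hits2 <- find_shared_segments(plas2)
  cl2 <- cluster_segments(hits2, plas2)
  expect_equal(length(cl2$representatives), 2)
})

test_that("single segments form singleton clusters", {
  set.seed(110)
  s <- random_dna(1800)
  plas <- c(A = s, B = s)
  cl <- cluster_segments(find_shared_segments(plas), plas)
  expect_equal(length(cl$representatives), 1)
})

test_that("segment incidence follows member-plasmid presence and drops singletons", {
  set.seed(111)
  s <- random_dna(2000)
  plas <- c(P1 = s, P2 = s)
  hits <- find_shared_segments(plas)
  cl <- cluster_segments(hits, plas)
  pres <- rbind(S1 = c(P1 = FALSE, P2 = TRUE),
                S2 = c(P1 = TRUE, P2 = FALSE),
                S3 = c(P1 = FALSE, P2 = FALSE))
  inc <- segment_incidence(cl, pres)
  expect_equal(ncol(inc), 1)
  expect_equal(unname(inc[, 1]), c(TRUE, TRUE, FALSE))  # S1 via P2 alone
  ## carried by one sample only -> dropped
  pres1 <- rbind(S1 = c(P1 = TRUE, P2 = TRUE),
                 S2 = c(P1 = FALSE, P2 = FALSE))
  expect_equal(ncol(segment_incidence(cl, pres1)), 0)
  ## orphan plasmid id -> error listing it
  pres_bad <- pres[, 1, drop = FALSE]
  expect_error(segment_incidence(cl, pres_bad), "P2")
})

test_that("ground-truth incidence round-trips through clustering", {
  cfg <- sim_config(n_plasmids = 16, n_samples = 25, seed = 209)
  gen <- generate_plasmid_sequences(cfg)
  pool <- source_pool(16, seed = 209, ids = gen$plasmids$plasmid_id)
  ab <- simulate_neutral_abundances(pool, cfg)
  pres <- call_presence(ab)
  hits <- find_shared_segments(gen$sequences, presence = pres)
  cl <- cluster_segments(hits, gen$sequences)
  inc <- segment_incidence(cl, pres)
  ## every emitted cluster's carriers match the union of its member
  ## plasmids' presence
  for (cid in colnames(inc)) {
    pls <- unique(cl$members$plasmid_id[cl$members$cluster_id == cid])
    expect_equal(unname(inc[, cid]),
                 unname(rowSums(pres[, pls, drop = FALSE]) > 0))
  }
})
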