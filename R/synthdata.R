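## Synthetic-data generator: Sloan-type neutral local communities drawn from
## a heavy-tailed regional pool, planted non-neutral segments, plasmid
## sequences carrying shared blocks, and sample metadata. Every generator is
## deterministic under its seed and the emitted ground truth lets downstream
## stages be validated end-to-end.

#' Regional source pool of entity abundances
#'
#' Entities (plasmids or segment clusters) get relative abundances drawn from
#' a renormalized log-normal, the heavy-tailed shape typical of plasmidome
#' abundance distributions.
#'
#' @param n_entities number of entities in the pool.
#' @param sigma log-normal shape parameter (sd of log abundance).
#' @param seed integer seed.
#' @param ids optional entity identifiers (default `E0001`, ...).
#' @return list with `entity_ids`, `p` (simplex weights summing to 1) and
#'   `seed`.
#' @export
source_pool <- function(n_entities, sigma = 2, seed = 1, ids = NULL) {
  .assert(n_entities >= 1, "need at least one entity")
  set.seed(seed)
  p <- rlnorm(n_entities, meanlog = 0, sdlog = sigma)
  p <- p / sum(p)
  ids <- ids %||% sprintf("E%04d", seq_len(n_entities))
  .assert(length(ids) == n_entities, "ids length mismatch")
  list(entity_ids = ids, p = p, seed = seed)
}

#' Simulation configuration
#'
#' Central place for every knob of the synthetic study. Defaults reflect the
#' study conditions: disease-group proportions follow the cohort's group
#' sizes (1548 healthy, 339 IBD, 1035 GRD, 545 obese of 3467), the
#' mobilizable fraction the 1027 / 11,086 lifestyle split, and per-sample
#' read depths emulate heterogeneous sequencing effort at desk scale.
#'
#' @param n_samples number of local communities (stool samples).
#' @param Nm metacommunity size times immigration rate of the neutral model.
#' @param d detection limit: minimum relative abundance at which an entity is
#'   called present.
#' @param read_depth_range integer pair; per-sample depth is drawn uniformly
#'   in this range.
#' @param disease_proportions named fractions summing to 1.
#' @param continent_proportions named fractions summing to 1.
#' @param planted_selection optional data.frame with columns `segment_id`,
#'   `disease`, `boost` describing non-neutral segments to plant.
#' @param lifestyle_fraction fraction of plasmids that are mobilizable.
#' @param n_plasmids,n_species entity counts for sequence-level simulation
#'   and taxa profiles.
#' @param length_modes,length_sdlog,length_weights two-component log-normal
#'   length mixture (bp modes, log-sd, mixture weights).
#' @param amr_prob named probabilities of carrying any AMR gene per
#'   lifestyle; defaults give a mobilizable/non-mobilizable odds ratio near
#'   the reported 6.14.
#' @param seed master seed; each generator derives its own stream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300,
                       Nm = 500,
                       d = 1e-3,
                       read_depth_range = c(2e4, 8.6e5),
                       disease_proportions = c(healthy = 1548, IBD = 339,
                                               GRD = 1035, obese = 545) / 3467,
                       continent_proportions = c(Europe = 0.4,
                                                 `North America` = 0.3,
                                                 Asia = 0.2,
                                                 `South America` = 0.1),
                       planted_selection = NULL,
                       lifestyle_fraction = 1027 / 11086,
                       n_plasmids = 40,
                       n_species = 150,
                       length_modes = c(3000, 30000),
                       length_sdlog = c(0.35, 0.35),
                       length_weights = c(0.8, 0.2),
                       amr_prob = c(mobilizable = 0.4, non_mobilizable = 0.098),
                       seed = 1) {
  .assert(Nm > 0, "Nm must be positive")
  .assert(d > 0 && d < 1, "detection limit d must be in (0, 1)")
  .assert(abs(sum(disease_proportions) - 1) < 1e-8,
          "disease proportions must sum to 1")
  .assert(abs(sum(continent_proportions) - 1) < 1e-8,
          "continent proportions must sum to 1")
  .assert(length(read_depth_range) == 2 && all(read_depth_range >= 1) &&
            read_depth_range[1] <= read_depth_range[2],
          "read_depth_range must be an increasing positive pair")
  .assert(lifestyle_fraction >= 0 && lifestyle_fraction <= 1,
          "lifestyle_fraction must be in [0, 1]")
  if (!is.null(planted_selection)) {
    .assert(all(c("segment_id", "disease", "boost") %in% names(planted_selection)),
            "planted_selection needs columns segment_id, disease, boost")
    .assert(all(planted_selection$boost >= 1), "boost factors must be >= 1")
    .assert(all(planted_selection$disease %in% names(disease_proportions)),
            "planted_selection refers to unknown disease labels")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate neutral local communities from a source pool
#'
#' The generative counterpart of the Sloan neutral community model: each
#' sample's relative abundance of entity i is drawn from
#' `Beta(Nm * p_i, Nm * (1 - p_i))`, renormalized across entities, and then
#' observed through multinomial read sampling at the sample's depth.
#' Detection applies the configured limit `d` to count-derived relative
#' abundances.
#'
#' @param pool a [source_pool()].
#' @param cfg a [sim_config()].
#' @return a [abundance_matrix()] with an additional attribute `detection`
#'   (logical samples x entities matrix: relative abundance `>= d`).
#' @export
simulate_neutral_abundances <- function(pool, cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  .assert(abs(sum(pool$p) - 1) < 1e-9 && all(pool$p > 0),
          "pool weights must be positive and sum to 1")
  a <- cfg$Nm * pool$p
  b <- cfg$Nm * (1 - pool$p)
  if (any(pmin(a, b) < 1e-8)) {
    stop("Beta shape underflow: Nm * p (or Nm * (1 - p)) below 1e-8 for ",
         sum(pmin(a, b) < 1e-8), " entities; increase Nm or trim the pool",
         call. = FALSE)
  }
  n_ent <- length(pool$p)
  set.seed(cfg$seed)
  depth <- round(runif(cfg$n_samples, cfg$read_depth_range[1],
                       cfg$read_depth_range[2]))
  counts <- matrix(0, cfg$n_samples, n_ent,
                   dimnames = list(sprintf("S%04d", seq_len(cfg$n_samples)),
                                   pool$entity_ids))
  for (s in seq_len(cfg$n_samples)) {
    x <- rbeta(n_ent, a, b)
    x <- x / sum(x)
    counts[s, ] <- rmultinom(1, depth[s], x)[, 1]
  }
  rel <- counts / depth
  detect <- rel >= cfg$d
  ## coverage fractions: detected plasmids get near-complete mapping
  ## coverage, undetected ones patchy sub-threshold coverage
  cov <- matrix(runif(length(counts), 0, 0.7 - 1e-9), nrow(counts), ncol(counts))
  cov[detect] <- runif(sum(detect), 0.8, 1)
  dimnames(cov) <- dimnames(counts)
  out <- abundance_matrix(counts, cov, depth)
  attr(out, "detection") <- detect
  out
}

#' Generate sample metadata
#'
#' Disease and continent labels drawn independently at the configured
#' proportions; deterministic under the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `sample_id`, `disease`, `continent`.
#' @export
generate_metadata <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  set.seed(cfg$seed + 1L)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(cfg$n_samples)),
    disease = sample(names(cfg$disease_proportions), cfg$n_samples,
                     replace = TRUE, prob = cfg$disease_proportions),
    continent = sample(names(cfg$continent_proportions), cfg$n_samples,
                       replace = TRUE, prob = cfg$continent_proportions),
    stringsAsFactors = FALSE)
}

## substitute bases at i.i.d. rate, always to a different base
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit], function(ch)
      alt[[ch]][sample.int(3, 1)], "")
  }
  paste(chars, collapse = "")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

#' Generate circular plasmid sequences with planted shared blocks
#'
#' Plasmid lengths follow a two-component log-normal mixture (bimodal, modes
#' near 3 kb and 30 kb). Shared segment blocks are copied across designated
#' carrier plasmids with i.i.d. point substitutions tuned so two copies
#' diverge to the target pairwise identity; blocks flagged origin-spanning
#' straddle the linearization origin of their first carrier. Lifestyle
#' labels, mobility-gene intervals, pathway labels and AMR flags are
#' assigned per configuration.
#'
#' @param cfg a [sim_config()].
#' @param blocks optional data.frame with columns `block_id`, `length`,
#'   `identity`, `n_carriers`, `origin_spanning`; by default six blocks of
#'   1200-2500 bp at identities 0.85-1 are planted.
#' @return list with `sequences` (named character vector of circular plasmid
#'   sequences), `plasmids` (id, length, lifestyle), `annotations` (per
#'   plasmid: lifestyle, length, amr_count, pathways, mobility intervals as
#'   0-based half-open `start-end` pairs separated by `;`), and
#'   `truth_blocks` (planted member intervals, 0-based half-open on circular
#'   coordinates, `end` may exceed the plasmid length when the block wraps).
#' @export
generate_plasmid_sequences <- function(cfg, blocks = NULL) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  set.seed(cfg$seed + 2L)
  n <- cfg$n_plasmids
  ids <- sprintf("P%03d", seq_len(n))
  comp <- sample(seq_along(cfg$length_weights), n, TRUE, cfg$length_weights)
  mu <- log(cfg$length_modes) + cfg$length_sdlog^2  # log-normal mode = modes
  len <- round(rlnorm(n, mu[comp], cfg$length_sdlog[comp]))
  seqs <- vapply(len, .random_dna, "")
  names(seqs) <- ids

  if (is.null(blocks)) {
    ## scale the default planting with the plasmid count so every block
    ## finds non-overlapping hosts (small plasmids fit only one block)
    nb <- max(2L, min(6L, n %/% 3L))
    max_car <- max(2L, min(4L, n %/% 5L))
    blocks <- data.frame(
      block_id = sprintf("B%02d", seq_len(nb)),
      length = round(runif(nb, 1200, 2500)),
      identity = runif(nb, 0.85, 1),
      n_carriers = sample(rep(2:max_car, 2), nb, TRUE),
      origin_spanning = rep(c(TRUE, FALSE), length.out = nb))
  }
  truth <- list()
  ## occupied circular intervals per plasmid so planted blocks never
  ## overwrite each other (which would corrupt the ground truth)
  occupied <- lapply(seq_len(n), function(i) NULL)
  free_at <- function(pi, start0, end0) {
    occ <- occupied[[pi]]
    if (is.null(occ)) return(TRUE)
    all(vapply(seq_len(nrow(occ)), function(r)
      .circ_overlap(start0, end0, occ[r, 1], occ[r, 2], len[pi]) == 0, TRUE))
  }
  place <- function(pi, blen, spanning) {
    L <- len[pi]
    if (spanning) {
      start0 <- L - floor(blen / 2)
      if (free_at(pi, start0, start0 + blen)) return(start0)
      return(NA_integer_)
    }
    for (try in 1:50) {
      start0 <- sample.int(L - blen, 1) - 1L
      if (free_at(pi, start0, start0 + blen)) return(start0)
    }
    NA_integer_
  }
  for (bi in seq_len(nrow(blocks))) {
    blen <- blocks$length[bi]
    hosts_ok <- which(len > blen + 200)
    if ("carriers" %in% names(blocks)) {
      carriers <- strsplit(blocks$carriers[bi], ",")[[1]]
      carriers <- match(carriers, ids)
    } else {
      .assert(length(hosts_ok) >= blocks$n_carriers[bi],
              sprintf("block %s (%d bp) longer than available host plasmids",
                      blocks$block_id[bi], blen))
      carriers <- sample(hosts_ok, blocks$n_carriers[bi])
    }
    if (any(len[carriers] < blen)) {
      stop("requested block ", blocks$block_id[bi],
           " is longer than a designated host plasmid", call. = FALSE)
    }
    base_block <- .random_dna(blen)
    rate <- (1 - blocks$identity[bi]) / 2  # divergence split across copies
    for (k in seq_along(carriers)) {
      pi <- carriers[k]
      L <- len[pi]
      copy <- .mutate_seq(base_block, rate)
      spanning <- isTRUE(blocks$origin_spanning[bi]) && k == 1L
      start0 <- place(pi, blen, spanning)
      if (is.na(start0) && spanning) start0 <- place(pi, blen, FALSE)
      if (is.na(start0)) {
        ## no free slot on this host; fall back to another eligible one
        alts <- setdiff(hosts_ok, carriers)
        for (alt in alts[sample.int(length(alts))]) {
          start0 <- place(alt, blen, FALSE)
          if (!is.na(start0)) { pi <- alt; L <- len[pi]; break }
        }
      }
      .assert(!is.na(start0),
              sprintf("could not place block %s without overlap",
                      blocks$block_id[bi]))
      occupied[[pi]] <- rbind(occupied[[pi]], c(start0, start0 + blen))
      end0 <- start0 + blen
      s <- seqs[[pi]]
      if (end0 <= L) {
        substr(s, start0 + 1, end0) <- copy
      } else {
        head_len <- L - start0
        substr(s, start0 + 1, L) <- substr(copy, 1, head_len)
        substr(s, 1, end0 - L) <- substr(copy, head_len + 1, blen)
      }
      seqs[[pi]] <- s
      truth[[length(truth) + 1L]] <- data.frame(
        block_id = blocks$block_id[bi], plasmid_id = ids[pi],
        start = start0, end = end0, identity = blocks$identity[bi],
        origin_spanning = end0 > L)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(block_id = character(), plasmid_id = character(),
               start = integer(), end = integer(), identity = numeric(),
               origin_spanning = logical())

  lifestyle <- ifelse(runif(n) < cfg$lifestyle_fraction,
                      "mobilizable", "non_mobilizable")
  mob_iv <- character(n)
  for (i in which(lifestyle == "mobilizable")) {
    k <- sample(1:2, 1)
    ivs <- character(k)
    for (j in seq_len(k)) {
      w <- min(round(runif(1, 400, 1500)), len[i] - 1)
      s0 <- sample.int(len[i] - w, 1) - 1L
      ivs[j] <- sprintf("%d-%d", s0, s0 + w)
    }
    mob_iv[i] <- paste(ivs, collapse = ";")
  }
  vocab <- c("beta-Lactam resistance", "ABC transporters",
             "Metabolic pathways", "Homologous recombination",
             "Mismatch repair", "Biosynthesis of secondary metabolites",
             "Microbial metabolism in diverse environments",
             "Vibrio cholerae infection", "Two-component system",
             "Quorum sensing")
  pathways <- vapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) "" else paste(sample(vocab, k), collapse = ";")
  }, "")
  p_amr <- unname(cfg$amr_prob[ifelse(lifestyle == "mobilizable",
                                      "mobilizable", "non_mobilizable")])
  amr <- ifelse(runif(n) < p_amr, rpois(n, 1.5) + 1L, 0L)

  list(
    sequences = seqs,
    plasmids = data.frame(plasmid_id = ids, length = len,
                          lifestyle = lifestyle, stringsAsFactors = FALSE),
    annotations = data.frame(plasmid_id = ids, lifestyle = lifestyle,
                             length = len, amr_count = amr,
                             pathways = pathways,
                             mobility_intervals = mob_iv,
                             stringsAsFactors = FALSE),
    truth_blocks = truth)
}

#' Plant non-neutral (selected) segments into an incidence matrix
#'
#' Raises the carriage probability of chosen segments within a target
#' disease group: a segment with overall carriage frequency `q` gets target
#' frequency `min(1, boost * q)` inside the group, achieved by upgrading
#' absent cells with probability `(target - q) / (1 - q)`. Cells outside the
#' target group, and all cells when `boost = 1`, are untouched.
#'
#' @param incidence logical/0-1 matrix, samples x segments.
#' @param metadata data.frame with `sample_id` and `disease` covering the
#'   incidence rows.
#' @param planted data.frame with `segment_id`, `disease`, `boost`.
#' @param seed integer seed.
#' @return list with the modified `incidence` and a `truth` table recording
#'   per planted segment the group, boost, and achieved carrier count.
#' @export
plant_selection <- function(incidence, metadata, planted, seed = 1) {
  .assert(all(planted$segment_id %in% colnames(incidence)),
          "planted segment ids missing from incidence")
  .assert(all(planted$boost >= 1), "boost factors must be >= 1")
  .assert(all(metadata$sample_id == rownames(incidence)),
          "metadata rows must match incidence rows")
  unknown <- setdiff(planted$disease, unique(metadata$disease))
  if (length(unknown)) {
    stop("unknown disease label(s) in planted_selection: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  inc <- incidence * 1L
  truth <- planted
  truth$achieved_carriers <- NA_integer_
  for (i in seq_len(nrow(planted))) {
    seg <- planted$segment_id[i]
    boost <- planted$boost[i]
    if (boost == 1) {
      truth$achieved_carriers[i] <- sum(inc[metadata$disease == planted$disease[i], seg])
      next
    }
    q0 <- mean(inc[, seg])
    q1 <- min(1, boost * q0)
    rows <- which(metadata$disease == planted$disease[i])
    if (q0 < 1) {
      flip_p <- (q1 - q0) / (1 - q0)
      zeros <- rows[inc[rows, seg] == 0]
      inc[zeros[runif(length(zeros)) < flip_p], seg] <- 1L
    }
    truth$achieved_carriers[i] <- sum(inc[rows, seg])
  }
  list(incidence = inc, truth = truth)
}

#' Simulate a segment-level incidence study
#'
#' Convenience wrapper for network / selection experiments that work at the
#' sample x segment level: draws a heavy-tailed segment pool, simulates
#' neutral carriage, generates metadata, and optionally plants selected
#' segments from `cfg$planted_selection`.
#'
#' @param cfg a [sim_config()]; `n_entities` segments are simulated.
#' @param n_entities number of segment clusters.
#' @return list with `abund` (abundance object), `incidence` (0/1 matrix
#'   after any planting), `metadata`, `pool`, and `truth` (NULL when nothing
#'   was planted).
#' @export
simulate_segment_incidence <- function(cfg, n_entities = 500) {
  pool <- source_pool(n_entities, seed = cfg$seed,
                      ids = sprintf("SEG%04d", seq_len(n_entities)))
  abund <- simulate_neutral_abundances(pool, cfg)
  meta <- generate_metadata(cfg)
  inc <- attr(abund, "detection") * 1L
  truth <- NULL
  if (!is.null(cfg$planted_selection)) {
    pl <- plant_selection(inc, meta, cfg$planted_selection,
                          seed = cfg$seed + 3L)
    inc <- pl$incidence
    truth <- pl$truth
    ## keep abundance consistent with the upgraded cells: newly present
    ## cells get a just-detectable count so occurrence outruns abundance
    newly <- which(inc == 1L & abund$counts == 0, arr.ind = TRUE)
    if (nrow(newly)) {
      abund$counts[newly] <- ceiling(cfg$d * abund$read_depth[newly[, 1]])
      abund$coverage[newly] <- runif(nrow(newly), 0.8, 1)
    }
  }
  list(abund = abund, incidence = inc, metadata = meta, pool = pool,
       truth = truth)
}

#' Simulate a complete plasmidome study and optionally write its files
#'
#' Runs every generator under one configuration: plasmid sequences with
#' shared blocks and annotations, neutral per-sample plasmid abundances,
#' sample metadata, and simple per-sample taxa profiles. When `outdir` is
#' given, writes `plasmids.fasta`, `abundance.tsv`, `coverage.tsv`,
#' `metadata.tsv`, `annotations.tsv`, `taxa.tsv` and `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory.
#' @return list with all generated components and the ground truth.
#' @export
simulate_dataset <- function(cfg, outdir = NULL) {
  gen <- generate_plasmid_sequences(cfg)
  pool <- source_pool(cfg$n_plasmids, seed = cfg$seed,
                      ids = gen$plasmids$plasmid_id)
  abund <- simulate_neutral_abundances(pool, cfg)
  meta <- generate_metadata(cfg)
  set.seed(cfg$seed + 4L)
  prevalence <- rbeta(cfg$n_species, 2, 3)
  taxa <- matrix(rbinom(cfg$n_samples * cfg$n_species, 1,
                        rep(prevalence, each = cfg$n_samples)),
                 cfg$n_samples, cfg$n_species,
                 dimnames = list(meta$sample_id,
                                 sprintf("sp%04d", seq_len(cfg$n_species))))
  truth <- list(
    pool = data.frame(entity_id = pool$entity_ids, p = pool$p),
    blocks = gen$truth_blocks,
    lifestyle = gen$plasmids[, c("plasmid_id", "lifestyle")],
    config = list(Nm = cfg$Nm, d = cfg$d, seed = cfg$seed,
                  n_samples = cfg$n_samples))
  out <- list(sequences = gen$sequences, plasmids = gen$plasmids,
              annotations = gen$annotations, abund = abund,
              metadata = meta, taxa = taxa, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    dna <- Biostrings::DNAStringSet(gen$sequences)
    names(dna) <- paste0(names(gen$sequences), " circular=true")
    Biostrings::writeXStringSet(dna, file.path(outdir, "plasmids.fasta"))
    write_matrix_tsv(abund$counts, file.path(outdir, "abundance.tsv"))
    write_matrix_tsv(abund$coverage, file.path(outdir, "coverage.tsv"))
    write_tsv0(meta, file.path(outdir, "metadata.tsv"))
    write_tsv0(gen$annotations, file.path(outdir, "annotations.tsv"))
    write_matrix_tsv(taxa, file.path(outdir, "taxa.tsv"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  out
}
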