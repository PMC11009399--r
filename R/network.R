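## Sample-sample segment-sharing network and its degree-preserving
## permutation null. Two samples are connected when they carry at least one
## common segment cluster; the edge weight is the number of shared
## clusters. Significance of group connectivity, single edges, and single
## segments is assessed against an ensemble of incidence matrices rewired
## by checkerboard swaps, which conserve every sample degree and segment
## prevalence exactly.

#' Build the segment-sharing network
#'
#' Edge weights are pairwise co-carriage counts (the dot product of the two
#' samples' incidence rows); the reported density is the fraction of
#' possible sample pairs connected by at least one shared segment.
#'
#' @param incidence logical/0-1 samples x segments matrix.
#' @param metadata data.frame with `sample_id`, `disease`, `continent`
#'   covering every incidence row.
#' @return object of class `sharing_network` with the weighted `graph`
#'   (igraph), an `edges` data.frame, the `incidence`, `metadata`, and
#'   `density`.
#' @export
build_sharing_network <- function(incidence, metadata) {
  missing <- setdiff(rownames(incidence), metadata$sample_id)
  if (length(missing)) {
    stop("metadata is missing samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- metadata[match(rownames(incidence), metadata$sample_id), ]
  inc <- (incidence > 0) * 1L
  w <- tcrossprod(inc)
  diag(w) <- 0
  ut <- which(upper.tri(w) & w >= 1, arr.ind = TRUE)
  edges <- data.frame(sample_a = rownames(w)[ut[, 1]],
                      sample_b = colnames(w)[ut[, 2]],
                      weight = w[ut])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(inc), disease = meta$disease,
                          continent = meta$continent))
  n <- nrow(inc)
  structure(list(graph = g, edges = edges, incidence = inc, metadata = meta,
                 weights = w, n_samples = n,
                 density = nrow(edges) / choose(n, 2)),
            class = "sharing_network")
}

#' @export
print.sharing_network <- function(x, ...) {
  cat(sprintf("sharing_network: %d samples, %d edges (density %.1f%% of %s pairs)\n",
              x$n_samples, nrow(x$edges), 100 * x$density,
              format(choose(x$n_samples, 2), big.mark = ",")))
  invisible(x)
}

#' Degree-preserving permutation of an incidence matrix
#'
#' Randomizes a bipartite 0/1 matrix by repeated checkerboard swaps
#' (`[[1,0],[0,1]] <-> [[0,1],[1,0]]`), which leave every row and column sum
#' unchanged. The default number of proposals is 10 times the number of
#' 1-cells.
#'
#' @param incidence 0/1 matrix.
#' @param seed integer seed of the swap chain.
#' @param n_swaps number of swap proposals, or `"auto"`.
#' @return the permuted matrix with attributes `successes` (accepted swaps)
#'   and `no_swap` (TRUE when no swap was possible, e.g. an all-ones
#'   matrix, and the original is returned unchanged).
#' @export
permute_incidence <- function(incidence, seed = 1, n_swaps = "auto") {
  inc <- (incidence > 0) * 1L
  ones <- sum(inc)
  if (identical(n_swaps, "auto")) n_swaps <- 10 * ones
  res <- cpp_rewire(inc, as.double(n_swaps), as.double(seed))
  out <- res$incidence
  attr(out, "successes") <- res$successes
  attr(out, "no_swap") <- res$successes == 0
  out
}

## Enumerate group statistics: per disease the pooled within-disease
## connectivity, and (for diseases not excluded from geography analyses)
## within-continent and cross-continent-pair connectivity.
.group_defs <- function(meta, geography = TRUE, exclude_geo = "obese") {
  diseases <- sort(unique(meta$disease))
  conts <- sort(unique(meta$continent))
  defs <- data.frame(disease = diseases, cont_a = NA_character_,
                     cont_b = NA_character_)
  if (geography && length(conts) > 1) {
    for (dz in setdiff(diseases, exclude_geo)) {
      cc <- combn(conts, 2)
      defs <- rbind(defs,
                    data.frame(disease = dz, cont_a = conts, cont_b = conts),
                    data.frame(disease = dz, cont_a = cc[1, ],
                               cont_b = cc[2, ]))
    }
  }
  ## keep groups with at least 2 qualifying samples (or 1 per side of a pair)
  keep <- vapply(seq_len(nrow(defs)), function(i) {
    dz <- defs$disease[i]
    if (is.na(defs$cont_a[i])) sum(meta$disease == dz) >= 2
    else if (defs$cont_a[i] == defs$cont_b[i])
      sum(meta$disease == dz & meta$continent == defs$cont_a[i]) >= 2
    else sum(meta$disease == dz & meta$continent == defs$cont_a[i]) >= 1 &&
      sum(meta$disease == dz & meta$continent == defs$cont_b[i]) >= 1
  }, TRUE)
  defs[keep, , drop = FALSE]
}

#' Build a permutation null ensemble over an incidence matrix
#'
#' Runs `n_perm` independent checkerboard-swap chains from the original
#' incidence (each chain 10 x the number of 1-cells proposals by default)
#' and records, for each permuted matrix, the statistics needed by the
#' significance tests: total within-group edge weight for every disease (and
#' disease x continent block / continent pair), per-edge co-carriage counts
#' for observed same-disease edges, and per-(segment, disease) carrier-pair
#' counts.
#'
#' @param incidence 0/1 samples x segments matrix.
#' @param metadata data.frame with `sample_id`, `disease`, `continent`.
#' @param n_perm number of permutations (study design: 10,000; desk-scale
#'   default 1000).
#' @param seed integer seed; chains are seeded independently per member.
#' @param swap_mult proposals per chain as a multiple of the 1-cell count.
#' @param edges optional data.frame of sample pairs (`sample_a`,
#'   `sample_b`) whose null weights should be tracked; defaults to all
#'   same-disease pairs connected in the observed network.
#' @param segments track per-(segment, disease) null statistics?
#' @param geography include continent-resolved group statistics?
#' @param exclude_geo disease labels excluded from geography statistics
#'   (study design: obesity, restricted to one continent).
#' @return object of class `null_ensemble`.
#' @export
null_ensemble <- function(incidence, metadata, n_perm = 1000, seed = 1,
                          swap_mult = 10, edges = NULL, segments = TRUE,
                          geography = TRUE, exclude_geo = "obese") {
  meta <- metadata[match(rownames(incidence), metadata$sample_id), ]
  .assert(!anyNA(meta$sample_id), "metadata must cover all incidence rows")
  inc <- (incidence > 0) * 1L
  diseases <- sort(unique(meta$disease))
  conts <- sort(unique(meta$continent))
  block <- interaction(factor(meta$disease, diseases),
                       factor(meta$continent, conts), drop = TRUE)
  block_levels <- levels(block)
  bl_dz <- match(sub("\\..*$", "", block_levels), diseases) - 1L
  bl_ct <- match(sub("^.*\\.", "", block_levels), conts) - 1L

  defs <- .group_defs(meta, geography, exclude_geo)
  stat_dz <- match(defs$disease, diseases) - 1L
  stat_c1 <- ifelse(is.na(defs$cont_a), -1L, match(defs$cont_a, conts) - 1L)
  stat_c2 <- ifelse(is.na(defs$cont_b), -1L, match(defs$cont_b, conts) - 1L)

  if (is.null(edges)) {
    w <- tcrossprod(inc)
    diag(w) <- 0
    same <- outer(meta$disease, meta$disease, "==")
    ut <- which(upper.tri(w) & w >= 1 & same, arr.ind = TRUE)
    edges <- data.frame(sample_a = rownames(inc)[ut[, 1]],
                        sample_b = rownames(inc)[ut[, 2]])
  }
  e1 <- match(edges$sample_a, rownames(inc)) - 1L
  e2 <- match(edges$sample_b, rownames(inc)) - 1L
  .assert(!anyNA(e1) && !anyNA(e2), "edge samples missing from incidence")

  res <- cpp_null_ensemble(inc, as.integer(block) - 1L, bl_dz, bl_ct,
                           stat_dz, stat_c1, stat_c2, e1, e2,
                           as.integer(n_perm), swap_mult * sum(inc),
                           as.double(seed), isTRUE(segments),
                           length(diseases))
  if (isTRUE(segments)) {
    rownames(res$seg_obs) <- rownames(res$seg_exceed) <- colnames(inc)
    colnames(res$seg_obs) <- colnames(res$seg_exceed) <- diseases
  }
  structure(list(
    defs = defs, group_obs = as.numeric(res$group_obs),
    group_null = res$group_null,
    edges = cbind(edges,
                  disease = meta$disease[e1 + 1L],
                  observed = as.numeric(res$edge_obs),
                  exceed = as.integer(res$edge_exceed)),
    seg_obs = res$seg_obs, seg_exceed = res$seg_exceed,
    diseases = diseases, n_perm = n_perm, seed = seed,
    swap_successes = as.numeric(res$successes),
    incidence_dim = dim(inc)),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d permutations of a %d x %d incidence\n",
              x$n_perm, x$incidence_dim[1], x$incidence_dim[2]))
  cat(sprintf("  mean accepted swaps per chain: %.0f\n",
              mean(x$swap_successes)))
  invisible(x)
}

#' Group connectivity against the permutation null
#'
#' The statistic per group is the total edge weight among qualifying sample
#' pairs (same disease, optionally restricted to a continent or a continent
#' pair). Empirical p-values use the `(1 + b) / (1 + n_perm)` convention and
#' are Benjamini-Hochberg corrected across groups.
#'
#' @param net a [build_sharing_network()] (used for consistency checks).
#' @param ensemble a [null_ensemble()] built on the same incidence.
#' @return data.frame: group definition, observed statistic, null mean,
#'   empirical `p`, FDR `q`.
#' @export
group_connectivity_test <- function(net, ensemble) {
  .assert(inherits(ensemble, "null_ensemble"), "need a null_ensemble")
  .assert(identical(dim(net$incidence), ensemble$incidence_dim),
          "ensemble was built on a different incidence")
  defs <- ensemble$defs
  b <- vapply(seq_len(nrow(defs)), function(i)
    sum(ensemble$group_null[, i] >= ensemble$group_obs[i]), 0L)
  out <- data.frame(defs,
                    observed = ensemble$group_obs,
                    null_mean = colMeans(ensemble$group_null),
                    p = (1 + b) / (1 + ensemble$n_perm))
  out$q <- bh_adjust(out$p)
  out
}

#' Per-edge significance within disease states
#'
#' Compares each observed same-disease edge weight with its weights across
#' the permuted networks; Benjamini-Hochberg correction is applied within
#' each disease state.
#'
#' @inheritParams group_connectivity_test
#' @param alpha FDR threshold for the `significant` flag (study design
#'   0.05).
#' @return data.frame: sample pair, disease, observed weight, `p`, `q`,
#'   `significant`.
#' @export
edge_significance <- function(net, ensemble, alpha = 0.05) {
  ed <- ensemble$edges
  ed$p <- (1 + ed$exceed) / (1 + ensemble$n_perm)
  ed$q <- NA_real_
  for (dz in unique(ed$disease)) {
    idx <- ed$disease == dz
    ed$q[idx] <- bh_adjust(ed$p[idx])
  }
  ed$significant <- ed$q <= alpha
  ed
}

#' Per-segment significance within disease states
#'
#' The statistic per (segment, disease) is the number of within-disease
#' carrier pairs `C(k, 2)`; segments carried by fewer than two group members
#' have statistic 0 and are never significant. FDR correction is applied per
#' disease; the selected fraction per disease is reported as an attribute.
#'
#' @param incidence the incidence matrix the ensemble was built on.
#' @param ensemble a [null_ensemble()] built with `segments = TRUE`.
#' @param metadata sample metadata (unused beyond validation; the ensemble
#'   already carries the grouping).
#' @param alpha FDR threshold for the `significant` flag.
#' @return long data.frame: segment, disease, observed statistic, `p`, `q`,
#'   `significant`; attribute `selected_fraction` is the per-disease share
#'   of segments flagged.
#' @export
segment_significance <- function(incidence, ensemble, metadata = NULL,
                                 alpha = 0.05) {
  .assert(nrow(ensemble$seg_obs) > 0,
          "ensemble was built without segment statistics")
  segs <- rownames(ensemble$seg_obs)
  out <- do.call(rbind, lapply(ensemble$diseases, function(dz) {
    obs <- ensemble$seg_obs[, dz]
    p <- (1 + ensemble$seg_exceed[, dz]) / (1 + ensemble$n_perm)
    p[obs == 0] <- 1
    data.frame(segment = segs, disease = dz, observed = obs, p = p,
               q = bh_adjust(p), row.names = NULL)
  }))
  out$significant <- out$q <= alpha & out$observed > 0
  attr(out, "selected_fraction") <-
    tapply(out$significant, out$disease, mean)
  out
}

#' Within- versus between-disease connection strength
#'
#' A node's within-disease strength is the summed weight of its edges to
#' same-disease nodes, its between-disease strength the summed weight to
#' all other nodes. Mode `"per_capita"` (default) divides each strength by
#' the number of potential partners of that kind before forming the ratio,
#' removing group-size imbalance; `"raw"` uses plain sums. Ratios are
#' compared between disease groups by pairwise two-sided Wilcoxon rank-sum
#' tests with Benjamini-Hochberg correction. Nodes with zero
#' between-strength have infinite ratio; they are reported but excluded
#' from the tests.
#'
#' @param net a [build_sharing_network()].
#' @param mode `"per_capita"` or `"raw"`.
#' @return list with `per_node` (sample, disease, strengths, ratio),
#'   `group_medians`, `tests`, and `n_infinite`.
#' @export
strength_ratio <- function(net, mode = c("per_capita", "raw")) {
  mode <- match.arg(mode)
  meta <- net$metadata
  .assert(length(unique(meta$disease)) >= 2,
          "strength ratios need at least two disease groups")
  w <- net$weights
  same <- outer(meta$disease, meta$disease, "==")
  diag(same) <- FALSE
  within <- rowSums(w * same)
  between <- rowSums(w * !same)  # diagonal of w is zero
  n_same <- rowSums(same)
  n_other <- nrow(w) - 1 - n_same
  if (mode == "per_capita") {
    within <- within / pmax(n_same, 1)
    between <- between / pmax(n_other, 1)
  }
  ratio <- ifelse(between > 0, within / between, Inf)
  per_node <- data.frame(sample_id = rownames(w), disease = meta$disease,
                         within_strength = within,
                         between_strength = between, ratio = ratio,
                         row.names = NULL)
  finite <- per_node[is.finite(per_node$ratio), ]
  groups <- sort(unique(finite$disease))
  tests <- NULL
  if (length(groups) >= 2) {
    pairs <- combn(groups, 2)
    tests <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                        p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      tests$p[i] <- suppressWarnings(wilcox.test(
        finite$ratio[finite$disease == pairs[1, i]],
        finite$ratio[finite$disease == pairs[2, i]])$p.value)
    }
    tests$q <- bh_adjust(tests$p)
  }
  list(per_node = per_node,
       group_medians = tapply(finite$ratio, finite$disease, median),
       tests = tests,
       n_infinite = sum(!is.finite(per_node$ratio)))
}

#' Fraction of cross-continental edges that are significant, per disease
#'
#' @param net a [build_sharing_network()].
#' @param sig_edges result of [edge_significance()].
#' @return data.frame: disease, number of cross-continental same-disease
#'   edges, number significant, `fraction` (NA when a disease has no
#'   cross-continental edge).
#' @export
cross_continental_summary <- function(net, sig_edges) {
  meta <- net$metadata
  cont <- setNames(meta$continent, meta$sample_id)
  cross <- cont[sig_edges$sample_a] != cont[sig_edges$sample_b]
  ed <- sig_edges[cross, , drop = FALSE]
  diseases <- sort(unique(sig_edges$disease))
  out <- data.frame(disease = diseases, n_cross = 0L, n_significant = 0L,
                    fraction = NA_real_)
  for (i in seq_along(diseases)) {
    sub <- ed[ed$disease == diseases[i], , drop = FALSE]
    out$n_cross[i] <- nrow(sub)
    out$n_significant[i] <- sum(sub$significant)
    if (nrow(sub) > 0) out$fraction[i] <- out$n_significant[i] / nrow(sub)
  }
  out
}
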