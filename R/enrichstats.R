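## Enrichment and comparative statistics for selected / significant entity
## sets and plasmid lifestyles: upper-tail hypergeometric pathway
## enrichment with gene-ratio filtering, 2x2 odds ratios with Fisher's
## exact test, two-sample Kolmogorov-Smirnov comparisons of AMR gene
## counts, lifestyle proportions per disease state, and the
## mobility-adjusted length comparison.

## parse "start-end;start-end" 0-based half-open interval strings
.parse_intervals <- function(s) {
  if (is.na(s) || s == "") return(cbind(start = integer(), end = integer()))
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  cbind(start = as.integer(vapply(parts, `[`, "", 1)),
        end = as.integer(vapply(parts, `[`, "", 2)))
}

.split_terms <- function(s) {
  if (is.na(s) || s == "") character() else strsplit(s, ";")[[1]]
}

#' Hypergeometric term enrichment of a selected entity set
#'
#' For each annotation term, tests whether the term is over-represented
#' among selected entities relative to the background by the upper-tail
#' hypergeometric probability `P(X >= k)`, with Benjamini-Hochberg
#' correction across terms. Results carry the gene ratio `k / n` (fraction
#' of selected entities annotated with the term); the `passes` flag applies
#' the study-style filter gene ratio strictly above `min_gene_ratio` and
#' `q <= q_max`. Entities without annotations stay in the background count.
#'
#' @param selected character vector of selected entity ids (subset of
#'   `background`).
#' @param background character vector of background entity ids.
#' @param annotations data.frame with `entity_id` and `pathways`
#'   (`;`-separated term labels, possibly empty).
#' @param min_gene_ratio gene-ratio filter (default 0.1).
#' @param q_max FDR threshold for the filter (0.01 or 0.0001 depending on
#'   the analysis).
#' @return data.frame: term, k, n, K, N, gene_ratio, odds_ratio, p, q,
#'   passes.
#' @export
hypergeom_enrich <- function(selected, background, annotations,
                             min_gene_ratio = 0.1, q_max = 0.01) {
  .assert(all(selected %in% background),
          "selected entities must be a subset of the background")
  ann <- annotations[annotations$entity_id %in% background, ]
  terms_by_entity <- lapply(ann$pathways, .split_terms)
  names(terms_by_entity) <- ann$entity_id
  long <- data.frame(
    entity_id = rep(ann$entity_id, lengths(terms_by_entity)),
    term = unlist(terms_by_entity, use.names = FALSE))
  if (nrow(long) == 0) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), gene_ratio = numeric(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      passes = logical()))
  }
  N <- length(background)
  n <- length(selected)
  terms <- sort(unique(long$term))
  K <- table(factor(long$term[!duplicated(paste(long$entity_id, long$term))],
                    terms))
  sel_long <- long[long$entity_id %in% selected, ]
  k <- table(factor(sel_long$term[!duplicated(paste(sel_long$entity_id,
                                                    sel_long$term))], terms))
  k <- as.integer(k); K <- as.integer(K)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  or <- (k * (N - K - n + k)) / pmax((K - k) * (n - k), 0)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    gene_ratio = k / n, odds_ratio = or, p = p,
                    q = bh_adjust(p))
  out$passes <- out$gene_ratio > min_gene_ratio & out$q <= q_max
  out[order(out$p), ]
}

#' Odds ratio and Fisher's exact test for a 2x2 table
#'
#' The sample odds ratio `(a d) / (b c)` with the Haldane-Anscombe +0.5
#' correction when any cell is zero, and the exact two-sided Fisher
#' p-value.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = condition,
#'   columns = outcome (`a` = condition 1 & outcome 1).
#' @return list with `odds_ratio` and `p`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  .assert(all(cells >= 0) && all(cells == round(cells)),
          "cell counts must be non-negative integers")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    warning("a margin of the 2x2 table is zero; odds ratio undefined")
    return(list(odds_ratio = NA_real_, p = NA_real_))
  }
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
  list(odds_ratio = or, p = ft$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param counts_a,counts_b numeric samples (e.g. AMR gene counts per
#'   plasmid in two lifestyles).
#' @param exact passed to [stats::ks.test()]; `NULL` lets it choose.
#' @return list with the statistic `D` and `p`.
#' @export
ks_compare <- function(counts_a, counts_b, exact = NULL) {
  .assert(length(counts_a) >= 1 && length(counts_b) >= 1,
          "both samples need at least one observation")
  kt <- suppressWarnings(ks.test(counts_a, counts_b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Mobilizable fraction per disease state with pairwise tests
#'
#' Counts present (sample, plasmid) observations per disease state and the
#' fraction of those that involve mobilizable plasmids, with Wilson 95%
#' confidence intervals and pairwise chi-square tests (Benjamini-Hochberg
#' corrected).
#'
#' @param presence logical samples x plasmids matrix.
#' @param annotations data.frame with `plasmid_id` and `lifestyle`
#'   (`mobilizable` / `non_mobilizable`).
#' @param metadata data.frame with `sample_id` and `disease`.
#' @return list with `fractions` (disease, n_obs, n_mobilizable, fraction,
#'   ci bounds) and `tests` (pairwise chi-square with `q`).
#' @export
lifestyle_proportion_tests <- function(presence, annotations, metadata) {
  meta <- metadata[match(rownames(presence), metadata$sample_id), ]
  life <- setNames(annotations$lifestyle, annotations$plasmid_id)
  .assert(all(colnames(presence) %in% names(life)),
          "annotations must cover every plasmid in presence")
  mob <- life[colnames(presence)] == "mobilizable"
  diseases <- sort(unique(meta$disease))
  fr <- data.frame(disease = diseases, n_obs = 0L, n_mobilizable = 0L)
  for (i in seq_along(diseases)) {
    sub <- presence[meta$disease == diseases[i], , drop = FALSE]
    fr$n_obs[i] <- sum(sub)
    fr$n_mobilizable[i] <- sum(sub[, mob, drop = FALSE])
  }
  keep <- fr$n_obs > 0
  if (any(!keep)) message("skipping group(s) with zero observations: ",
                          paste(fr$disease[!keep], collapse = ", "))
  fr <- fr[keep, , drop = FALSE]
  fr$fraction <- fr$n_mobilizable / fr$n_obs
  ci <- wilson_ci(fr$fraction, fr$n_obs)
  fr$ci_lower <- ci[, "lower"]; fr$ci_upper <- ci[, "upper"]
  tests <- NULL
  if (nrow(fr) >= 2) {
    pairs <- combn(fr$disease, 2)
    tests <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                        p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      ia <- fr$disease == pairs[1, i]; ib <- fr$disease == pairs[2, i]
      tab <- rbind(c(fr$n_mobilizable[ia], fr$n_obs[ia] - fr$n_mobilizable[ia]),
                   c(fr$n_mobilizable[ib], fr$n_obs[ib] - fr$n_mobilizable[ib]))
      tests$p[i] <- suppressWarnings(chisq.test(tab)$p.value)
    }
    tests$q <- bh_adjust(tests$p)
  }
  list(fractions = fr, tests = tests)
}

#' Compare plasmid lengths between lifestyles after removing mobility genes
#'
#' The adjusted length subtracts the union of a plasmid's mobility-gene
#' intervals (overlapping intervals are merged before summation) from its
#' total length, so the comparison is not driven by the large mobility
#' backbone itself. Lifestyles are compared by a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param annotations data.frame with `plasmid_id`, `lifestyle`, `length`
#'   and `mobility_intervals` (0-based half-open `start-end` pairs,
#'   `;`-separated, empty for none).
#' @return list with `per_plasmid` (adjusted lengths), group means, and the
#'   Wilcoxon `p`.
#' @export
adjusted_length_compare <- function(annotations) {
  adj <- vapply(seq_len(nrow(annotations)), function(i) {
    iv <- .parse_intervals(annotations$mobility_intervals[i])
    covered <- merged_interval_length(iv[, "start"], iv[, "end"])
    if (nrow(iv) > 1 && covered < sum(iv[, "end"] - iv[, "start"])) {
      message("overlapping mobility intervals merged for ",
              annotations$plasmid_id[i])
    }
    annotations$length[i] - covered
  }, 0)
  per <- data.frame(plasmid_id = annotations$plasmid_id,
                    lifestyle = annotations$lifestyle,
                    length = annotations$length, adjusted_length = adj)
  mobs <- per$adjusted_length[per$lifestyle == "mobilizable"]
  nons <- per$adjusted_length[per$lifestyle == "non_mobilizable"]
  p <- if (length(mobs) && length(nons))
    wilcox.test(mobs, nons, alternative = "two.sided")$p.value else NA_real_
  list(per_plasmid = per,
       mean_mobilizable = if (length(mobs)) mean(mobs) else NA_real_,
       mean_non_mobilizable = if (length(nons)) mean(nons) else NA_real_,
       p = p)
}
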