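## Plasmid deduplication, presence calling, depth filtering and richness
## statistics. Thresholds follow the study design: presence needs read
## coverage of at least 70% of the plasmid length (inclusive), duplicates
## are plasmid pairs with identity strictly above 95% over at least 95% of
## the larger plasmid, and the depth cutoff is 1% of the lowest present
## abundance in the sample with the lowest read depth.

#' Deduplicate plasmids from pairwise match evidence
#'
#' Keeps the larger of any two plasmids whose identity is strictly above
#' `min_id` and whose aligned length covers at least `min_cov` of the larger
#' plasmid. Candidate merges are processed in decreasing order of the larger
#' member's length (ties broken by lexicographic id) so transitive chains
#' resolve deterministically and independently of input order.
#'
#' @param lengths named numeric vector of plasmid lengths (bp).
#' @param matches data.frame with columns `a`, `b`, `identity` (fraction in
#'   `[0, 1]`) and `aligned_length` (bp). Symmetric duplicates are allowed;
#'   self-matches are dropped with a warning.
#' @param min_id identity threshold, exclusive (default 0.95: "above 95%").
#' @param min_cov fraction of the larger plasmid that must be covered,
#'   inclusive (default 0.95).
#' @return list with `representatives` (surviving ids) and `map` (named
#'   character vector member -> representative, identity for survivors).
#' @export
dedup_plasmids <- function(lengths, matches, min_id = 0.95, min_cov = 0.95) {
  .assert(!is.null(names(lengths)), "`lengths` must be named by plasmid id")
  ids <- names(lengths)
  if (nrow(matches) == 0) {
    return(list(representatives = ids, map = setNames(ids, ids)))
  }
  .assert(all(matches$identity >= 0 & matches$identity <= 1),
          "identities must be fractions in [0, 1]")
  .assert(all(c(matches$a, matches$b) %in% ids),
          "matches refer to unknown plasmid ids")
  self <- matches$a == matches$b
  if (any(self)) {
    warning(sum(self), " self-match(es) ignored")
    matches <- matches[!self, , drop = FALSE]
  }
  if (nrow(matches) == 0) {
    return(list(representatives = ids, map = setNames(ids, ids)))
  }
  ## orient each pair as (larger, smaller); length ties by lexicographic id
  la <- lengths[matches$a]; lb <- lengths[matches$b]
  a_larger <- la > lb | (la == lb & matches$a < matches$b)
  big <- ifelse(a_larger, matches$a, matches$b)
  small <- ifelse(a_larger, matches$b, matches$a)
  keep <- matches$identity > min_id &
    matches$aligned_length >= min_cov * lengths[big]
  big <- big[keep]; small <- small[keep]
  o <- order(-lengths[big], big, small)
  big <- big[o]; small <- small[o]
  killer <- setNames(rep(NA_character_, length(ids)), ids)
  alive <- setNames(rep(TRUE, length(ids)), ids)
  for (i in seq_along(big)) {
    if (alive[[big[i]]] && alive[[small[i]]]) {
      alive[[small[i]]] <- FALSE
      killer[[small[i]]] <- big[i]
    }
  }
  map <- setNames(ids, ids)
  for (id in ids[!alive]) {
    rep_id <- killer[[id]]
    while (!alive[[rep_id]]) rep_id <- killer[[rep_id]]
    map[[id]] <- rep_id
  }
  list(representatives = ids[alive], map = map)
}

#' Call plasmid presence from read coverage
#'
#' A plasmid is present in a sample when reads cover at least `min_cov` of
#' its length (inclusive boundary) and its abundance is positive.
#'
#' @param abund a [abundance_matrix()].
#' @param min_cov minimum coverage fraction (default 0.70).
#' @return logical matrix, samples x plasmids.
#' @export
call_presence <- function(abund, min_cov = 0.70) {
  .assert(inherits(abund, "plasmid_abundance"), "need a plasmid_abundance")
  cov <- abund$coverage
  if (anyNA(cov)) {
    warning(sum(is.na(cov)), " missing coverage cells treated as 0")
    cov[is.na(cov)] <- 0
  }
  pres <- cov >= min_cov & abund$counts > 0
  dimnames(pres) <- dimnames(abund$counts)
  pres
}

#' Apply the read-depth abundance cutoff
#'
#' The cutoff is 1% (configurable) of the lowest abundance among plasmids
#' called present in the sample with the lowest read depth. Any cell whose
#' abundance falls below the cutoff is set absent; plasmids absent from
#' every sample afterwards are reported as dropped.
#'
#' @param abund a [abundance_matrix()].
#' @param presence logical matrix from [call_presence()].
#' @param frac fraction of the reference abundance (default 0.01).
#' @return list with the masked `presence` matrix, the `cutoff` value, the
#'   id of the shallowest sample, and `dropped` plasmid ids.
#' @export
apply_depth_cutoff <- function(abund, presence, frac = 0.01) {
  .assert(identical(dim(presence), dim(abund$counts)),
          "presence and abundance dimensions differ")
  shallow <- which.min(abund$read_depth)
  present_ab <- abund$counts[shallow, presence[shallow, ]]
  present_ab <- present_ab[present_ab > 0]
  if (length(present_ab) == 0) {
    stop("the lowest-depth sample (", rownames(abund$counts)[shallow],
         ") has no present plasmid; relax the presence filter before ",
         "applying the depth cutoff", call. = FALSE)
  }
  cutoff <- frac * min(present_ab)
  masked <- presence & abund$counts >= cutoff
  dropped <- colnames(presence)[colSums(masked) == 0 & colSums(presence) > 0]
  list(presence = masked, cutoff = cutoff,
       shallowest_sample = rownames(abund$counts)[shallow], dropped = dropped)
}

#' Plasmid-to-species richness ratios and group comparison
#'
#' Per sample, richness is the count of present entities; the ratio divides
#' plasmid richness by species richness. Disease groups are compared by
#' pairwise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
#' correction.
#'
#' @param presence logical samples x plasmids matrix.
#' @param taxa_profiles samples x species matrix; any positive value counts
#'   as species presence.
#' @param metadata data.frame with `sample_id` and `disease`.
#' @return list with `per_sample` (sample_id, disease, plasmid_richness,
#'   species_richness, ratio) and `tests` (group pair, W, p, q).
#' @export
richness_ratio <- function(presence, taxa_profiles, metadata) {
  common <- intersect(rownames(presence), rownames(taxa_profiles))
  .assert(length(common) > 0, "no samples shared between presence and taxa")
  meta <- metadata[match(common, metadata$sample_id), ]
  pr <- rowSums(presence[common, , drop = FALSE])
  sr <- rowSums(taxa_profiles[common, , drop = FALSE] > 0)
  per_sample <- data.frame(sample_id = common, disease = meta$disease,
                           plasmid_richness = pr, species_richness = sr,
                           ratio = ifelse(sr > 0, pr / sr, NA_real_),
                           row.names = NULL)
  if (any(sr == 0)) {
    warning(sum(sr == 0), " sample(s) with zero species richness excluded ",
            "from ratio tests")
  }
  ok <- per_sample[!is.na(per_sample$ratio), ]
  groups <- sort(unique(ok$disease))
  tests <- NULL
  if (length(groups) >= 2) {
    pairs <- combn(groups, 2)
    tests <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                        W = NA_real_, p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      wt <- wilcox.test(ok$ratio[ok$disease == pairs[1, i]],
                        ok$ratio[ok$disease == pairs[2, i]],
                        alternative = "two.sided", exact = NULL)
      tests$W[i] <- unname(wt$statistic)
      tests$p[i] <- wt$p.value
    }
    tests$q <- bh_adjust(tests$p)
  }
  list(per_sample = per_sample, tests = tests)
}

#' Locate the trough of a bimodal length distribution
#'
#' Fits a Gaussian kernel density on log10 length and returns the abscissa
#' (in bp) of the minimum between the two largest local maxima, or `NA` when
#' the density is unimodal.
#'
#' @param lengths positive numeric vector of plasmid lengths (bp), at least
#'   10 observations.
#' @param ... passed to [stats::density()].
#' @return trough position in bp, or `NA_real_` for unimodal input.
#' @export
length_trough <- function(lengths, ...) {
  .assert(length(lengths) >= 10, "need at least 10 length observations")
  .assert(all(lengths > 0), "lengths must be positive")
  dd <- density(log10(lengths), ...)
  y <- dd$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) return(NA_real_)
  top2 <- sort(is_max[order(-y[is_max])][1:2])
  between <- seq(top2[1], top2[2])
  10^dd$x[between[which.min(y[between])]]
}
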