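## Shared-segment extraction from circular plasmids. Plasmid sequences are
## duplicated (seq + seq) so a homologous block that straddles the
## arbitrary linearization origin stays contiguous; hits are then reduced
## back to circular coordinates and offset duplicates created by the
## doubling are collapsed. The default engine seeds candidate regions with
## exact k-mer matches, chains colinear seeds by diagonal, and verifies
## each region with a windowed Smith-Waterman alignment; a full
## dynamic-programming mode over whole doubled sequences is available for
## validation on small instances. A segment is a local alignment of at
## least `min_len` bp at `min_id` identity (matches / alignment columns)
## between two distinct plasmids occurring in at least two samples.

.as_seq_vector <- function(plasmids) {
  if (inherits(plasmids, "DNAStringSet")) plasmids <- as.character(plasmids)
  .assert(is.character(plasmids) && !is.null(names(plasmids)),
          "plasmids must be a named character vector or DNAStringSet")
  toupper(plasmids)
}

.check_acgt <- function(seqs) {
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    off <- which(bad > 0)
    stop("non-ACGT character(s): ",
         paste(sprintf("%s at position %d", names(seqs)[off], bad[off]),
               collapse = "; "), call. = FALSE)
  }
}

## scoring: match 2, mismatch -4, gap open 8, gap extend 4. Random DNA
## then has strongly negative score drift even with gaps, so local
## alignments never extend past true homology, while 80%-identity blocks
## still score positively (0.8 * 2 - 0.2 * 4 = 0.8 per column).
.nuc_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                           baseOnly = TRUE)
}

.local_align <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = .nuc_mat(),
                                gapOpening = 8, gapExtension = 4)
}

#' Double a circular sequence
#'
#' Concatenates each sequence with itself so any block spanning the
#' linearization origin appears contiguously; downstream coordinates are
#' reduced modulo the original length.
#'
#' @param x named character vector or `DNAStringSet` of circular sequences.
#' @return character vector of doubled sequences (length 2L each).
#' @export
doubled_sequence <- function(x) {
  s <- .as_seq_vector(x)
  setNames(paste0(s, s), names(s))
}

## overlap (bp) of two circular intervals given as 0-based half-open
## (start, end) with end <= start + L; computed on the doubled line
.circ_overlap <- function(s1, e1, s2, e2, L) {
  ov <- function(a1, b1, a2, b2) max(0, min(b1, b2) - max(a1, a2))
  max(ov(s1, e1, s2, e2), ov(s1, e1, s2 + L, e2 + L),
      ov(s1 + L, e1 + L, s2, e2))
}

.empty_hits <- function() {
  structure(data.frame(plasmid_a = character(), plasmid_b = character(),
                       start_a = integer(), end_a = integer(),
                       start_b = integer(), end_b = integer(),
                       length = integer(), identity = numeric()),
            class = c("segment_hits", "data.frame"))
}

## align a doubled-coordinate window pair; returns a one-row hit df or
## NULL. When the optimal local alignment touches a window edge the true
## homology may continue past it (typical for blocks straddling the
## linearization origin, where the seed chain stops at the doubling
## boundary), so the touched edges are pushed out and the window realigned.
.window_hit <- function(ida, idb, da, db, La, Lb, wa1, wa2, wb1, wb2,
                        min_len, min_id, expand = 1000L, max_expand = 8L) {
  for (iter in seq_len(max_expand)) {
    sa_str <- substr(da, wa1, wa2)
    sb_str <- substr(db, wb1, wb2)
    aln <- .local_align(sa_str, sb_str)
    cols <- Biostrings::nchar(aln)
    if (cols == 0) return(NULL)
    pa0 <- Biostrings::pattern(aln); pb0 <- Biostrings::subject(aln)
    grew <- FALSE
    if (Biostrings::start(pa0) <= 3 && wa1 > 1) {
      wa1 <- max(1L, wa1 - expand); grew <- TRUE
    }
    if (Biostrings::end(pa0) >= nchar(sa_str) - 2 && wa2 < 2L * La) {
      wa2 <- min(2L * La, wa2 + expand); grew <- TRUE
    }
    if (Biostrings::start(pb0) <= 3 && wb1 > 1) {
      wb1 <- max(1L, wb1 - expand); grew <- TRUE
    }
    if (Biostrings::end(pb0) >= nchar(sb_str) - 2 && wb2 < 2L * Lb) {
      wb2 <- min(2L * Lb, wb2 + expand); grew <- TRUE
    }
    if (!grew) break
    if (as.double(wa2 - wa1 + 1) * (wb2 - wb1 + 1) > 2e9) break
  }
  id <- Biostrings::nmatch(aln) / cols
  len <- min(cols, La, Lb)  # a hit cannot exceed a full circular plasmid
  if (len < min_len || id < min_id) return(NULL)
  pa <- Biostrings::pattern(aln); pb <- Biostrings::subject(aln)
  sa <- (wa1 + Biostrings::start(pa) - 2L) %% La
  sb <- (wb1 + Biostrings::start(pb) - 2L) %% Lb
  data.frame(plasmid_a = ida, plasmid_b = idb,
             start_a = sa, end_a = sa + min(Biostrings::width(pa), La),
             start_b = sb, end_b = sb + min(Biostrings::width(pb), Lb),
             length = len, identity = id)
}

## collapse doubling duplicates / merge overlapping hits per plasmid pair:
## reciprocal circular overlap > 50% on both plasmids keeps the longer
## (then higher-identity) hit, so a truncated duplicate of a block never
## shadows its full-length alignment
.merge_pair_hits <- function(hits, La, Lb) {
  if (nrow(hits) <= 1) return(hits)
  o <- order(-hits$length, -hits$identity)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(hits))) {
      if (!keep[j]) next
      ova <- .circ_overlap(hits$start_a[i], hits$end_a[i],
                           hits$start_a[j], hits$end_a[j], La)
      ovb <- .circ_overlap(hits$start_b[i], hits$end_b[i],
                           hits$start_b[j], hits$end_b[j], Lb)
      la_i <- hits$end_a[i] - hits$start_a[i]
      la_j <- hits$end_a[j] - hits$start_a[j]
      lb_i <- hits$end_b[i] - hits$start_b[i]
      lb_j <- hits$end_b[j] - hits$start_b[j]
      if (ova > 0.5 * min(la_i, la_j) && ovb > 0.5 * min(lb_i, lb_j)) {
        keep[j] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Find shared segments between circular plasmids
#'
#' All-vs-all search for local alignments of at least `min_len` bp at
#' `min_id` identity between distinct plasmids, on doubled sequences so
#' origin-spanning blocks are found; duplicate hits produced by the
#' doubling are collapsed and hits overlapping reciprocally by more than
#' 50% are merged keeping the higher identity. When a presence matrix is
#' supplied, only hits whose carrying plasmids occur in at least two
#' samples are retained.
#'
#' @param plasmids named character vector or `DNAStringSet` of circular
#'   plasmid sequences (ACGT only).
#' @param min_len minimum aligned length in bp (study design 1000; the
#'   supplementary variants use 500).
#' @param min_id minimum identity, matches / alignment columns (0.80; the
#'   variants use 0.90 / 0.95).
#' @param engine `"seed"` (default; exact k-mer seeding with windowed
#'   Smith-Waterman extension) or `"dp"` (full dynamic programming over
#'   whole doubled sequences; one best hit per pair, small inputs only).
#' @param presence optional logical samples x plasmids matrix used for the
#'   at-least-two-samples rule.
#' @param k seed k-mer length.
#' @param band diagonal tolerance when chaining seeds.
#' @param seed_gap maximum gap (bp) between chained seeds.
#' @param margin window margin (bp) added around the chained seed span.
#' @param max_kmer_hits k-mers occurring more often than this are skipped
#'   as repetitive.
#' @return data.frame of class `segment_hits`: plasmid pair, 0-based
#'   half-open intervals on circular coordinates (`end` may exceed the
#'   plasmid length when the segment wraps the origin), aligned `length`
#'   (columns) and `identity`.
#' @export
find_shared_segments <- function(plasmids, min_len = 1000, min_id = 0.80,
                                 engine = c("seed", "dp"), presence = NULL,
                                 k = 16, band = 64, seed_gap = 512,
                                 margin = 300, max_kmer_hits = 64) {
  engine <- match.arg(engine)
  seqs <- .as_seq_vector(plasmids)
  if (length(seqs) == 0) return(.empty_hits())
  .check_acgt(seqs)
  L <- nchar(seqs)
  doubled <- doubled_sequence(seqs)
  ids <- names(seqs)

  pair_windows <- list()
  if (engine == "seed") {
    starts <- lapply(L, seq_len)
    kmers <- unlist(lapply(seq_along(seqs), function(i)
      substring(doubled[[i]], starts[[i]], starts[[i]] + k - 1L)))
    pidx <- rep(seq_along(seqs), L)
    pos <- unlist(starts)
    o <- order(kmers, method = "radix")
    r <- rle(kmers[o])
    grp_end <- cumsum(r$lengths)
    grp_start <- grp_end - r$lengths + 1L
    multi <- which(r$lengths >= 2L & r$lengths <= max_kmer_hits)
    acc <- vector("list", length(multi)); nacc <- 0L
    for (g in multi) {
      idx <- o[grp_start[g]:grp_end[g]]
      ps <- pidx[idx]
      if (length(unique(ps)) < 2) next
      pp <- pos[idx]
      u <- which(outer(ps, ps, "<"), arr.ind = TRUE)
      nacc <- nacc + 1L
      acc[[nacc]] <- cbind(a = ps[u[, 1]], b = ps[u[, 2]],
                           pa = pp[u[, 1]], pb = pp[u[, 2]])
    }
    if (nacc == 0L) return(.empty_hits())
    seeds <- do.call(rbind, acc[seq_len(nacc)])
    pair_key <- paste(seeds[, "a"], seeds[, "b"])
    for (key in unique(pair_key)) {
      sub <- seeds[pair_key == key, , drop = FALSE]
      i <- sub[1, "a"]; j <- sub[1, "b"]
      ## a block wrapping a linearization origin splits its seed chain
      ## across the doubling boundary; +L shifted seed copies put the two
      ## parts back on one diagonal (duplicate windows are collapsed later)
      sub <- rbind(sub,
                   cbind(a = sub[, "a"], b = sub[, "b"],
                         pa = sub[, "pa"] + L[i], pb = sub[, "pb"]),
                   cbind(a = sub[, "a"], b = sub[, "b"],
                         pa = sub[, "pa"], pb = sub[, "pb"] + L[j]),
                   cbind(a = sub[, "a"], b = sub[, "b"],
                         pa = sub[, "pa"] + L[i], pb = sub[, "pb"] + L[j]))
      dg <- sub[, "pa"] - sub[, "pb"]
      od <- order(dg, sub[, "pa"])
      sub <- sub[od, , drop = FALSE]; dg <- dg[od]
      dcl <- cumsum(c(1L, diff(dg) > band))
      for (d in unique(dcl)) {
        blk <- sub[dcl == d, , drop = FALSE]
        blk <- blk[order(blk[, "pa"]), , drop = FALSE]
        gcl <- cumsum(c(1L, diff(blk[, "pa"]) > seed_gap))
        for (gg in unique(gcl)) {
          ch <- blk[gcl == gg, , drop = FALSE]
          span <- max(ch[, "pa"]) + k - min(ch[, "pa"])
          if (nrow(ch) < 2L || span < min_len / 2) next
          pair_windows[[length(pair_windows) + 1L]] <- list(
            i = i, j = j,
            wa = c(max(1L, min(ch[, "pa"]) - margin),
                   min(2L * L[i], max(ch[, "pa"]) + k - 1L + margin)),
            wb = c(max(1L, min(ch[, "pb"]) - margin),
                   min(2L * L[j], max(ch[, "pb"]) + k - 1L + margin)))
        }
      }
    }
  } else {
    if (length(seqs) > 1) {
      for (i in seq_len(length(seqs) - 1)) {
        for (j in seq(i + 1, length(seqs))) {
          .assert(4 * as.double(L[i]) * L[j] < 2^31,
                  "sequences too long for the full-DP engine; use engine = 'seed'")
          pair_windows[[length(pair_windows) + 1L]] <- list(
            i = i, j = j, wa = c(1L, 2L * L[i]), wb = c(1L, 2L * L[j]))
        }
      }
    }
  }

  if (length(pair_windows) == 0) return(.empty_hits())
  ## collapse windows that are +L shifted images of one another before
  ## aligning (coarse mod-L key; surviving duplicates merge after scoring)
  wkey <- vapply(pair_windows, function(pw) {
    paste(pw$i, pw$j,
          ((pw$wa[1] - 1) %% L[pw$i]) %/% 64, ((pw$wb[1] - 1) %% L[pw$j]) %/% 64,
          (pw$wa[2] - pw$wa[1]) %/% 64, (pw$wb[2] - pw$wb[1]) %/% 64)
  }, "")
  pair_windows <- pair_windows[!duplicated(wkey)]
  hits <- lapply(pair_windows, function(pw) {
    .window_hit(ids[pw$i], ids[pw$j], doubled[[pw$i]], doubled[[pw$j]],
                L[pw$i], L[pw$j], pw$wa[1], pw$wa[2], pw$wb[1], pw$wb[2],
                min_len, min_id)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits) || nrow(hits) == 0) return(.empty_hits())

  merged <- lapply(split(hits, paste(hits$plasmid_a, hits$plasmid_b)),
                   function(h) .merge_pair_hits(h, L[h$plasmid_a[1]],
                                                L[h$plasmid_b[1]]))
  hits <- do.call(rbind, merged)
  rownames(hits) <- NULL

  if (!is.null(presence)) {
    .assert(all(c(hits$plasmid_a, hits$plasmid_b) %in% colnames(presence)),
            "presence matrix must cover all plasmids with hits")
    n_samp <- vapply(seq_len(nrow(hits)), function(i)
      sum(presence[, hits$plasmid_a[i]] | presence[, hits$plasmid_b[i]]), 0)
    hits <- hits[n_samp >= 2, , drop = FALSE]
  }
  structure(hits, class = c("segment_hits", "data.frame"))
}

#' Cluster extracted segments by identity and mutual coverage
#'
#' Greedy longest-first clustering in the CD-HIT style: segment instances
#' (both sides of every hit, deduplicated per plasmid at >50% reciprocal
#' overlap) are sorted by decreasing length; each joins the first cluster
#' whose representative aligns at `min_id` identity covering at least
#' `mutual_cov` of BOTH sequences, otherwise it founds a new cluster.
#'
#' @param hits a [find_shared_segments()] result.
#' @param plasmids the plasmid sequences the hits refer to.
#' @param min_id identity threshold (0.80).
#' @param mutual_cov coverage threshold applied to both lengths (0.90).
#' @return object of class `segment_clusters`: `members` (cluster_id,
#'   plasmid_id, start, end, identity to the representative),
#'   `representatives` (named character vector of representative
#'   sequences).
#' @export
cluster_segments <- function(hits, plasmids, min_id = 0.80,
                             mutual_cov = 0.90) {
  seqs <- .as_seq_vector(plasmids)
  doubled <- doubled_sequence(seqs)
  L <- nchar(seqs)
  if (nrow(hits) == 0) {
    return(structure(list(members = data.frame(), representatives = character()),
                     class = "segment_clusters"))
  }
  inst <- rbind(
    data.frame(plasmid_id = hits$plasmid_a, start = hits$start_a,
               end = hits$end_a),
    data.frame(plasmid_id = hits$plasmid_b, start = hits$start_b,
               end = hits$end_b))
  inst$len <- inst$end - inst$start
  inst <- inst[order(-inst$len), ]
  keep <- rep(TRUE, nrow(inst))
  for (i in seq_len(nrow(inst) - 1)) {
    if (!keep[i]) next
    for (j in seq(i + 1, nrow(inst))) {
      if (!keep[j] || inst$plasmid_id[j] != inst$plasmid_id[i]) next
      ov <- .circ_overlap(inst$start[i], inst$end[i], inst$start[j],
                          inst$end[j], L[inst$plasmid_id[i]])
      if (ov > 0.5 * min(inst$len[i], inst$len[j])) keep[j] <- FALSE
    }
  }
  inst <- inst[keep, , drop = FALSE]
  inst$seq <- vapply(seq_len(nrow(inst)), function(i)
    substr(doubled[[inst$plasmid_id[i]]], inst$start[i] + 1L, inst$end[i]),
    "")

  rep_seq <- character()
  members <- vector("list", nrow(inst))
  for (i in seq_len(nrow(inst))) {
    assigned <- NA_integer_; ident <- NA_real_
    for (ci in seq_along(rep_seq)) {
      aln <- .local_align(inst$seq[i], rep_seq[[ci]])
      cols <- Biostrings::nchar(aln)
      if (cols == 0) next
      id <- Biostrings::nmatch(aln) / cols
      wa <- Biostrings::width(Biostrings::pattern(aln))
      wb <- Biostrings::width(Biostrings::subject(aln))
      if (id >= min_id && wa >= mutual_cov * inst$len[i] &&
          wb >= mutual_cov * nchar(rep_seq[[ci]])) {
        assigned <- ci; ident <- id
        break
      }
    }
    if (is.na(assigned)) {
      rep_seq <- c(rep_seq, inst$seq[i])
      assigned <- length(rep_seq); ident <- 1.0
    }
    members[[i]] <- data.frame(cluster_id = assigned,
                               plasmid_id = inst$plasmid_id[i],
                               start = inst$start[i], end = inst$end[i],
                               identity = ident)
  }
  members <- do.call(rbind, members)
  members$cluster_id <- sprintf("SEG%04d", members$cluster_id)
  names(rep_seq) <- sprintf("SEG%04d", seq_along(rep_seq))
  structure(list(members = members, representatives = rep_seq),
            class = "segment_clusters")
}

#' @export
print.segment_clusters <- function(x, ...) {
  cat(sprintf("segment_clusters: %d clusters, %d member intervals\n",
              length(x$representatives), nrow(x$members)))
  invisible(x)
}

#' Sample x segment-cluster incidence
#'
#' A sample carries a cluster when it carries at least one member plasmid;
#' clusters carried by fewer than two samples are dropped (a shared segment
#' must repeat across samples).
#'
#' @param clusters a [cluster_segments()] result.
#' @param presence logical samples x plasmids matrix.
#' @return logical samples x clusters matrix.
#' @export
segment_incidence <- function(clusters, presence) {
  members <- clusters$members
  orphan <- setdiff(unique(members$plasmid_id), colnames(presence))
  if (length(orphan)) {
    stop("plasmid id(s) missing from presence matrix: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  cl_ids <- names(clusters$representatives)
  inc <- matrix(FALSE, nrow(presence), length(cl_ids),
                dimnames = list(rownames(presence), cl_ids))
  for (cl in cl_ids) {
    pls <- unique(members$plasmid_id[members$cluster_id == cl])
    inc[, cl] <- rowSums(presence[, pls, drop = FALSE]) > 0
  }
  inc[, colSums(inc) >= 2, drop = FALSE]
}
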