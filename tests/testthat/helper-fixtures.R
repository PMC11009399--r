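## Shared fixtures, built in code at test time.

## small abundance object with full control over the three tables
make_abund <- function(counts, coverage = NULL, read_depth = NULL) {
  if (is.null(coverage)) coverage <- (counts > 0) * 1
  if (is.null(read_depth)) read_depth <- pmax(rowSums(counts), 1)
  abundance_matrix(counts, coverage, read_depth)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## substitute bases at the given rate, always to a different base
mutate_dna <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  chars[hit] <- vapply(chars[hit], function(ch) alt[[ch]][sample.int(3, 1)], "")
  paste(chars, collapse = "")
}

## rotate a circular sequence so its origin moves by `by` bases
rotate_dna <- function(s, by) {
  n <- nchar(s)
  by <- by %% n
  if (by == 0) return(s)
  paste0(substr(s, by + 1, n), substr(s, 1, by))
}

## independent Smith-Waterman oracle for one circular pair: best local
## alignment of the (undoubled) query against the doubled subject, taken
## over two query rotations so an origin-spanning block is contiguous in
## at least one of them. Keeping the query single-copy prevents the
## alignment from chaining two periodic images of the same block, which a
## doubled-by-doubled comparison would allow.
sw_oracle <- function(seq_a, seq_b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  best <- NULL
  for (rot in c(0, floor(nchar(seq_a) / 2))) {
    aln <- Biostrings::pairwiseAlignment(
      rotate_dna(seq_a, rot), paste0(seq_b, seq_b), type = "local",
      substitutionMatrix = mat, gapOpening = 8, gapExtension = 4)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
      best <- aln
    }
  }
  cols <- Biostrings::nchar(best)
  list(length = min(cols, nchar(seq_a), nchar(seq_b)),
       identity = Biostrings::nmatch(best) / cols)
}

## random incidence matrix with labelled metadata
make_incidence <- function(n_samples, n_segments, density = 0.2, seed = 1) {
  set.seed(seed)
  inc <- matrix(rbinom(n_samples * n_segments, 1, density),
                n_samples, n_segments,
                dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                sprintf("G%03d", seq_len(n_segments))))
  meta <- data.frame(
    sample_id = rownames(inc),
    disease = sample(c("healthy", "IBD", "GRD", "obese"), n_samples, TRUE),
    continent = sample(c("Europe", "Asia"), n_samples, TRUE))
  list(incidence = inc, metadata = meta)
}
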