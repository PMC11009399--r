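## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param phat observed (or predicted) proportion(s).
#' @param n number of trials.
#' @param conf confidence level.
#' @return matrix with columns `lower` and `upper`.
#' @keywords internal
wilson_ci <- function(phat, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

## TSV conventions: tab separated, header row, no quoting, no row names.
write_tsv0 <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv0 <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## Matrix <-> long TSV (sample rows, entity columns, first column sample_id)
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv0(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv0(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Construct a per-sample plasmid abundance container
#'
#' Bundles the three per-dataset tables every downstream stage consumes: an
#' abundance matrix (read-derived abundance values, samples in rows, plasmids
#' in columns), the matching read-coverage fractions, and per-sample read
#' depths.
#'
#' @param counts numeric matrix of abundances (samples x plasmids),
#'   non-negative. Row and column names are required and become sample and
#'   plasmid identifiers.
#' @param coverage numeric matrix in `[0, 1]`, same dimensions as `counts`:
#'   fraction of each plasmid's length covered by reads in each sample.
#' @param read_depth positive integer vector, one per sample (total reads).
#' @return an object of class `plasmid_abundance`.
#' @export
abundance_matrix <- function(counts, coverage, read_depth) {
  .assert(is.matrix(counts) && !is.null(rownames(counts)) && !is.null(colnames(counts)),
          "`counts` must be a matrix with sample rownames and plasmid colnames")
  .assert(all(counts >= 0), "abundances must be non-negative")
  .assert(identical(dim(counts), dim(coverage)),
          "`coverage` must have the same dimensions as `counts`")
  .assert(all(coverage >= 0 & coverage <= 1), "coverage fractions must be in [0, 1]")
  .assert(length(read_depth) == nrow(counts), "one read depth per sample required")
  .assert(all(read_depth > 0), "read depths must be positive")
  dimnames(coverage) <- dimnames(counts)
  structure(
    list(counts = counts, coverage = coverage,
         read_depth = setNames(as.numeric(read_depth), rownames(counts)),
         sample_ids = rownames(counts), plasmid_ids = colnames(counts)),
    class = "plasmid_abundance")
}

#' @export
print.plasmid_abundance <- function(x, ...) {
  cat(sprintf("plasmid_abundance: %d samples x %d plasmids\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  read depth: %s - %s\n", format(min(x$read_depth), big.mark = ","),
              format(max(x$read_depth), big.mark = ",")))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' Normalizes each sample's abundance row to sum to one. Samples whose row is
#' all zero stay zero.
#'
#' @param abund a [abundance_matrix()] object or a plain matrix.
#' @return numeric matrix of the same shape, rows summing to 1 (or 0).
#' @export
relative_abundance <- function(abund) {
  m <- if (inherits(abund, "plasmid_abundance")) abund$counts else abund
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

## Benjamini-Hochberg wrapper kept for readability at call sites
bh_adjust <- function(p) p.adjust(p, method = "BH")

## Merge 0-based half-open intervals; returns total covered length.
merged_interval_length <- function(starts, ends) {
  if (length(starts) == 0) return(0)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] <= cur_e) {
        cur_e <- max(cur_e, ends[i])
      } else {
        tot <- tot + (cur_e - cur_s)
        cur_s <- starts[i]; cur_e <- ends[i]
      }
    }
  }
  tot + (cur_e - cur_s)
}
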