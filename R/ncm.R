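## Sloan neutral community model: occurrence frequency of an entity across
## local communities is predicted from its mean relative abundance p via the
## beta approximation valid for large prokaryotic populations,
##   f_pred(p) = 1 - I_d(Nm * p, Nm * (1 - p)),
## where I is the regularized incomplete beta function, d the detection
## limit and Nm the metacommunity size times immigration rate. Entities
## occurring far above the fitted curve at high prevalence are flagged as
## under positive selection.

#' Occurrence statistics for the neutral model
#'
#' For each entity, computes the mean sample-normalized relative abundance
#' `p` and the occurrence frequency `f` (fraction of samples in which the
#' entity is present). Entities present nowhere are excluded with a warning.
#'
#' @param abund a [abundance_matrix()] (or plain abundance matrix); relative
#'   abundances are computed per sample.
#' @param presence logical samples x entities matrix defining occurrence.
#' @param entities optional subset of entity ids.
#' @return list of class `occurrence_stats` with `entity_ids`, `p`, `f` and
#'   `n_samples`.
#' @export
occurrence_stats <- function(abund, presence, entities = NULL) {
  rel <- relative_abundance(abund)
  .assert(identical(dim(rel), dim(presence)),
          "abundance and presence dimensions differ")
  entities <- entities %||% colnames(rel)
  .assert(all(entities %in% colnames(rel)) && all(entities %in% colnames(presence)),
          "entities missing from abundance or presence matrix")
  p <- colMeans(rel[, entities, drop = FALSE])
  f <- colMeans(presence[, entities, drop = FALSE])
  absent <- f == 0
  if (any(absent)) {
    warning(sum(absent), " entity(ies) absent from every sample excluded")
    p <- p[!absent]; f <- f[!absent]; entities <- entities[!absent]
  }
  structure(list(entity_ids = entities, p = unname(p), f = unname(f),
                 n_samples = nrow(rel)),
            class = "occurrence_stats")
}

#' Predicted occurrence frequency under the neutral model
#'
#' @param p mean relative abundance(s), in `(0, 1)`; values outside are
#'   clipped to `[1e-12, 1 - 1e-12]` with a warning.
#' @param Nm metacommunity size times immigration.
#' @param d detection limit (relative abundance), in `(0, 1)`.
#' @return expected occurrence frequency `1 - I_d(Nm p, Nm (1 - p))`.
#' @export
predict_freq <- function(p, Nm, d) {
  .assert(Nm > 0, "Nm must be positive")
  .assert(d > 0 && d < 1, "detection limit d must be in (0, 1)")
  eps <- 1e-12
  if (any(p <= 0 | p >= 1)) {
    warning("abundances outside (0, 1) clipped")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

#' Fit the neutral community model
#'
#' Finds the `Nm` minimizing the sum of squared differences between observed
#' and predicted occurrence frequencies by bounded one-dimensional least
#' squares on a log10(Nm) scale. Goodness of fit is the ordinary
#' `R^2 = 1 - SSres / SStot` about the mean frequency; per-entity 95%
#' confidence bands around the fitted curve use Wilson score bounds at the
#' number of samples.
#'
#' @param stats an [occurrence_stats()].
#' @param d detection limit; defaults to the minimum positive `p` in
#'   `stats` when not supplied (occupancy convention: smallest observable
#'   relative abundance).
#' @param interval log10(Nm) search bounds.
#' @return object of class `ncm_fit`: `Nm`, `d`, `R2`, `n_samples`, and a
#'   per-entity data.frame `table` (entity_id, p, f, f_pred, residual,
#'   ci_lower, ci_upper).
#' @export
fit_ncm <- function(stats, d = NULL, interval = c(-2, 12)) {
  .assert(inherits(stats, "occurrence_stats"), "need occurrence_stats")
  d <- d %||% min(stats$p[stats$p > 0])
  .assert(d > 0 && d < 1, "detection limit d must be in (0, 1)")
  p <- pmin(pmax(stats$p, 1e-12), 1 - 1e-12)
  f <- stats$f
  sse <- function(log10_nm) {
    sum((f - predict_freq(p, 10^log10_nm, d))^2)
  }
  opt <- optimize(sse, interval = interval, tol = 1e-7)
  if (!is.finite(opt$objective)) {
    prof <- vapply(seq(interval[1], interval[2], length.out = 50), sse, 0)
    stop("NCM fit did not converge; SSE profile: ",
         paste(signif(prof, 3), collapse = ", "), call. = FALSE)
  }
  Nm <- 10^opt$minimum
  f_pred <- predict_freq(p, Nm, d)
  ss_tot <- sum((f - mean(f))^2)
  R2 <- if (ss_tot == 0) {
    warning("all observed frequencies identical; R^2 undefined")
    NA_real_
  } else 1 - opt$objective / ss_tot
  ci <- wilson_ci(f_pred, stats$n_samples)
  structure(list(
    Nm = Nm, d = d, R2 = R2, n_samples = stats$n_samples,
    sse = opt$objective,
    table = data.frame(entity_id = stats$entity_ids, p = stats$p, f = f,
                       f_pred = f_pred, residual = f - f_pred,
                       ci_lower = ci[, "lower"], ci_upper = ci[, "upper"],
                       row.names = NULL)),
    class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Neutral community model fit (%d entities, %d samples)\n",
              nrow(x$table), x$n_samples))
  cat(sprintf("  Nm = %.4g   detection limit d = %.3g   R^2 = %.3f\n",
              x$Nm, x$d, x$R2))
  invisible(x)
}

#' Compare neutrality of two groups by subsampled refits
#'
#' Corrects for unequal group sizes when comparing goodness of fit: the
#' larger group is repeatedly subsampled (without replacement) to the size
#' of the smaller group, the model refit, and the empirical p-value is the
#' fraction of subsample `R^2` values at least as large as the small group's
#' `R^2` (with the usual +1 correction so p is never 0).
#'
#' @param stats_big,stats_small [occurrence_stats()] for the two groups;
#'   `stats_big` must contain more entities.
#' @param d detection limit shared by both fits.
#' @param n_iter number of subsample iterations (study design: 1000).
#' @param seed integer seed.
#' @return list with `p`, the small group's `R2_small`, the vector of
#'   subsample `R2`, and `n_degenerate` (redrawn iterations with all-equal
#'   frequencies).
#' @export
subsample_compare <- function(stats_big, stats_small, d, n_iter = 1000,
                              seed = 1) {
  nb <- length(stats_big$entity_ids)
  ns <- length(stats_small$entity_ids)
  .assert(nb > ns, "the first group must be larger than the second")
  fit_small <- fit_ncm(stats_small, d = d)
  set.seed(seed)
  r2 <- numeric(n_iter)
  n_degenerate <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      idx <- sample.int(nb, ns)
      if (length(unique(stats_big$f[idx])) > 1) break
      n_degenerate <- n_degenerate + 1L
    }
    sub <- structure(list(entity_ids = stats_big$entity_ids[idx],
                          p = stats_big$p[idx], f = stats_big$f[idx],
                          n_samples = stats_big$n_samples),
                     class = "occurrence_stats")
    r2[i] <- suppressWarnings(fit_ncm(sub, d = d)$R2)
  }
  list(p = (1 + sum(r2 >= fit_small$R2, na.rm = TRUE)) / (1 + n_iter),
       R2_small = fit_small$R2, R2_subsamples = r2,
       n_degenerate = n_degenerate)
}

#' Flag entities deviating from the neutral fit (under selection)
#'
#' Two rules are provided. `"quantile"` (default): entities in both the top
#' 5% of occurrence frequencies and the top 5% of deviations above the fit
#' (deviation measured on the frequency axis). `"ci"`: entities with
#' frequency above 0.95 and above the upper 95% confidence band of the
#' fitted curve.
#'
#' @param fit an [fit_ncm()] result.
#' @param pct quantile percentage for rule `"quantile"` (default 95).
#' @param rule `"quantile"` or `"ci"`.
#' @return character vector of selected entity ids.
#' @export
select_deviant <- function(fit, pct = 95, rule = c("quantile", "ci")) {
  rule <- match.arg(rule)
  tb <- fit$table
  if (rule == "quantile") {
    qf <- quantile(tb$f, pct / 100)
    qr <- quantile(tb$residual, pct / 100)
    tb$entity_id[tb$f >= qf & tb$residual >= qr]
  } else {
    tb$entity_id[tb$f > 0.95 & tb$f > tb$ci_upper]
  }
}

#' Plot a neutral model fit
#'
#' Occurrence frequency against log10 mean relative abundance with the
#' fitted curve and its 95% band; requires ggplot2.
#'
#' @param fit an [fit_ncm()] result.
#' @param selected optional ids to highlight.
#' @return a ggplot object.
#' @export
plot_ncm_fit <- function(fit, selected = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tb <- fit$table
  tb$selected <- tb$entity_id %in% (selected %||% character())
  o <- order(tb$p)
  ggplot2::ggplot(tb, ggplot2::aes(x = log10(p), y = f)) +
    ggplot2::geom_point(ggplot2::aes(colour = selected), size = 0.8,
                        show.legend = !is.null(selected)) +
    ggplot2::geom_line(data = tb[o, ], ggplot2::aes(y = f_pred)) +
    ggplot2::geom_line(data = tb[o, ], ggplot2::aes(y = ci_lower),
                       linetype = "dashed") +
    ggplot2::geom_line(data = tb[o, ], ggplot2::aes(y = ci_upper),
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  title = sprintf("NCM fit: Nm = %.3g, R^2 = %.2f",
                                  fit$Nm, fit$R2))
}
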