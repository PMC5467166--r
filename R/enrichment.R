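#' Gene-set overlap enrichment (Fisher / hypergeometric)
#'
#' Cross-tabulates membership of `set` and `target` within `universe` and
#' tests over-representation. Ids outside the universe are dropped with a
#' warning (annotation mismatches between platforms are the norm). The 2x2
#' counts are `a` (in set and in target), `b` (in set only), `c` (in target
#' only) and `d` (neither).
#'
#' One-sided p is the exact hypergeometric upper tail `P[X >= a]`; two-sided
#' p sums all tables with probability at most that of the observed one
#' (via [stats::fisher.test()]).
#'
#' @param set,target,universe Character vectors of gene ids.
#' @param sided `"one"` (default) or `"two"`.
#' @return One-row data frame of class `enrichment_result`: counts `a,b,c,d`,
#'   `odds_ratio`, `fold_enrichment` (observed / expected overlap, expected =
#'   (a+b)(a+c)/N), `capture_fraction` (a / (a+b)), `p`, `q` (NA until
#'   [bh_adjust()] is applied across results), `sided`.
#' @export
fisher_enrichment <- function(set, target, universe, sided = c("one", "two")) {
  sided <- match.arg(sided)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  dropped <- length(setdiff(set, universe)) + length(setdiff(target, universe))
  if (dropped > 0L) {
    warning(dropped, " id(s) outside the universe were dropped")
  }
  set <- unique(intersect(set, universe))
  target <- unique(intersect(target, universe))
  if (!length(set)) stop("set is empty after intersecting with the universe")
  a <- length(intersect(set, target))
  b <- length(set) - a
  c_ <- length(target) - a
  d <- length(universe) - a - b - c_
  N <- length(universe)
  expected <- (a + b) * (a + c_) / N
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
  p <- if (sided == "one") {
    stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
  } else {
    stats::fisher.test(tab)$p.value
  }
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  if (a == 0 && (b == 0 || c_ == 0)) or <- NaN
  out <- data.frame(a = a, b = b, c = c_, d = d,
                    odds_ratio = or,
                    fold_enrichment = if (expected > 0) a / expected else NA_real_,
                    capture_fraction = a / (a + b),
                    p = p, q = NA_real_, sided = sided, row.names = NULL)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, order
#' preserving), for vectors of p-values in (0, 1].
#'
#' @param p_values Numeric vector of p-values.
#' @return Vector of q-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0L))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare intramodular connectivity between a gene set and its background
#'
#' Reports the ratio of mean `k_in` in the set to the background mean, with a
#' one-sided Fisher exact test on the 2x2 table of set membership against
#' `k_in` above the pooled median. A rank-sum (Wilcoxon) alternative is
#' exposed because dichotomizing a continuous connectivity is one reading of
#' a "Fisher test" on connectivity, not the only one.
#'
#' @param k_in Named numeric vector of intramodular connectivities.
#' @param set Character vector of gene ids (the focal set).
#' @param background Character vector of gene ids; may include the set (the
#'   set is removed from the comparison group internally).
#' @param method `"median_fisher"` (default) or `"ranksum"`.
#' @return List with `mean_ratio`, `p`, `method`, and the component means.
#' @export
connectivity_set_comparison <- function(k_in, set, background,
                                        method = c("median_fisher", "ranksum")) {
  method <- match.arg(method)
  if (is.null(names(k_in))) stop("k_in must be named by gene id")
  set <- intersect(set, names(k_in))
  background <- intersect(background, names(k_in))
  rest <- setdiff(background, set)
  if (!length(set) || !length(background)) stop("set or background is empty")
  ks <- k_in[set]
  kb <- k_in[background]
  kr <- k_in[rest]
  mean_ratio <- mean(ks) / mean(kb)
  if (!length(rest)) {
    warning("background contains no genes outside the set; no test performed")
    return(list(mean_ratio = mean_ratio, p = NA_real_, method = method,
                mean_set = mean(ks), mean_background = mean(kb)))
  }
  if (method == "median_fisher") {
    med <- stats::median(c(ks, kr))
    tab <- matrix(c(sum(ks > med), sum(ks <= med),
                    sum(kr > med), sum(kr <= med)), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  } else {
    p <- stats::wilcox.test(ks, kr, alternative = "greater", exact = FALSE)$p.value
  }
  list(mean_ratio = mean_ratio, p = p, method = method,
       mean_set = mean(ks), mean_background = mean(kb))
}

#' Resampling-based region enrichment
#'
#' Tests whether an observed hit proportion (e.g. motif matches in promoters
#' of a gene set) exceeds the proportion seen in resampled random regions.
#' The random sets are pooled into a single background proportion and a
#' one-tailed Fisher exact test is applied to observed vs pooled counts.
#' A per-resample empirical p (`p_empirical`: add-one-smoothed fraction of
#' random sets with a hit proportion at least the observed one) is also
#' returned for users who prefer not to pool.
#'
#' @param observed_hits,observed_total Hit count and total for the observed
#'   regions.
#' @param random_hits,random_totals Equal-length vectors of hit counts and
#'   totals for the resampled region sets (at least one set).
#' @return One-row data frame of class `enrichment_result` (counts are the
#'   pooled 2x2), plus columns `fold_enrichment`, `p`, `p_empirical`.
#' @export
resampling_region_enrichment <- function(observed_hits, observed_total,
                                         random_hits, random_totals) {
  if (length(random_hits) != length(random_totals) || !length(random_hits)) {
    stop("random_hits and random_totals must be equal-length, non-empty")
  }
  if (observed_total <= 0 || any(random_totals <= 0)) stop("totals must be positive")
  if (observed_hits > observed_total || any(random_hits > random_totals)) {
    stop("hits cannot exceed totals")
  }
  pooled_hits <- sum(random_hits)
  pooled_total <- sum(random_totals)
  tab <- matrix(c(observed_hits, observed_total - observed_hits,
                  pooled_hits, pooled_total - pooled_hits), 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  obs_prop <- observed_hits / observed_total
  pooled_prop <- pooled_hits / pooled_total
  p_emp <- (1 + sum(random_hits / random_totals >= obs_prop)) /
    (length(random_hits) + 1)
  out <- data.frame(a = observed_hits, b = observed_total - observed_hits,
                    c = pooled_hits, d = pooled_total - pooled_hits,
                    odds_ratio = (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], 1),
                    fold_enrichment = if (pooled_prop > 0) obs_prop / pooled_prop else Inf,
                    capture_fraction = obs_prop,
                    p = p, q = NA_real_, sided = "one",
                    p_empirical = p_emp, row.names = NULL)
  class(out) <- c("enrichment_result", class(out))
  out
}
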