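#' Differential-expression thresholds
#'
#' The cutoff set defining the two reported gene lists: the broad DE count
#' (raw p below `alpha_list`) and the high-confidence subset (Bonferroni
#' p at or below `subset_p` and fold change above `subset_fold`). Genes with
#' fewer than `min_total_count` summed reads across the two conditions are
#' excluded from testing and from the Bonferroni denominator.
#'
#' @param alpha_list Raw-p cutoff for the DE list (default 0.05).
#' @param subset_p Corrected-p cutoff for the subset (default 0.01).
#' @param subset_fold Minimum fold change for the subset (default 2).
#' @param min_total_count Minimum `x1 + x2` to test a gene (default 10).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(alpha_list = 0.05, subset_p = 0.01,
                          subset_fold = 2, min_total_count = 10) {
  if (alpha_list <= 0 || alpha_list > 1) stop("alpha_list must be in (0, 1]")
  if (subset_p <= 0 || subset_p > 1) stop("subset_p must be in (0, 1]")
  if (subset_fold < 1) stop("subset_fold must be >= 1")
  if (min_total_count < 1) stop("min_total_count must be >= 1")
  structure(list(alpha_list = alpha_list, subset_p = subset_p,
                 subset_fold = subset_fold,
                 min_total_count = min_total_count),
            class = "de_thresholds")
}

#' Aggregate pooled counts to condition level
#'
#' Sums each gene's counts over a condition's pools (`x = sum of pool
#' counts`) and sums the pools' library totals (`N`), yielding the
#' condition-level read proportions `x/N` the pooled z-test compares.
#'
#' @param counts A [count_matrix()].
#' @param condition_pair Character vector of two condition labels; the
#'   first is the reference for direction calls.
#' @return A list: `genes`, `x1`, `x2` (per-gene summed counts), `N1`, `N2`
#'   (summed library totals), `q1`, `q2` (pool counts per condition),
#'   `conditions`.
#' @export
aggregate_condition <- function(counts, condition_pair) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(condition_pair) != 2L) stop("condition_pair must name two conditions")
  avail <- unique(counts$map$condition)
  unknown <- setdiff(condition_pair, avail)
  if (length(unknown)) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  }
  pools1 <- counts$map$pool[counts$map$condition == condition_pair[1]]
  pools2 <- counts$map$pool[counts$map$condition == condition_pair[2]]
  list(genes = rownames(counts$counts),
       x1 = rowSums(counts$counts[, pools1, drop = FALSE]),
       x2 = rowSums(counts$counts[, pools2, drop = FALSE]),
       N1 = sum(counts$totals[pools1]),
       N2 = sum(counts$totals[pools2]),
       q1 = length(pools1), q2 = length(pools2),
       conditions = condition_pair)
}

#' Pooled z statistic for two count proportions
#'
#' Compares per-gene read proportions `x1/N1` and `x2/N2` between two
#' conditions with the pooled-library variance term `1/(4N)` per condition.
#' The default `sqrt` variant applies the variance-stabilizing square-root
#' transform to the proportions, for which `1/(4N)` is the first-order
#' variance under Poisson sampling:
#' `Z = (sqrt(x1/N1) - sqrt(x2/N2)) / sqrt(1/(4 N1) + 1/(4 N2))`.
#' The `raw` variant uses untransformed proportions in the numerator with
#' the same denominator; at transcript-scale proportions it is far more
#' conservative.
#'
#' @param x1,x2 Summed read counts per condition (vectorized).
#' @param N1,N2 Summed library totals per condition.
#' @param variant `"sqrt"` (default) or `"raw"`.
#' @return Numeric vector of z statistics, finite for all valid inputs
#'   (including zero counts).
#' @examples
#' pooled_z(100, 1e4, 50, 1e4)           # ~ 4.142
#' pooled_z(10, 1000, 20, 2000)          # equal proportions -> 0
#' @export
pooled_z <- function(x1, N1, x2, N2, variant = c("sqrt", "raw")) {
  variant <- match.arg(variant)
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals N must be > 0")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > N1) || any(x2 > N2)) {
    stop("counts must satisfy 0 <= x <= N")
  }
  denom <- sqrt(1 / (4 * N1) + 1 / (4 * N2))
  num <- switch(variant,
                sqrt = sqrt(x1 / N1) - sqrt(x2 / N2),
                raw = x1 / N1 - x2 / N2)
  num / denom
}

#' Two-sided normal p-value
#'
#' `p = 2 Phi(Z)` for `Z < 0`, else `2 (1 - Phi(Z))`, with `Phi` the
#' standard normal CDF. Exactly symmetric in the sign of `Z`.
#'
#' @param z Finite numeric vector of z statistics.
#' @return p-values in (0, 1].
#' @export
two_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  p <- ifelse(z < 0, 2 * pnorm(z), 2 * pnorm(z, lower.tail = FALSE))
  # extreme |z| underflows the normal tail to 0; keep p in (0, 1]
  pmax(p, .Machine$double.xmin)
}

#' Bonferroni correction
#'
#' Family-wise error control: `p_bonf = min(1, n_tests * p_raw)`.
#'
#' @param p_raw Raw p-values in (0, 1].
#' @param n_tests Number of tests in the family (>= 1).
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni <- function(p_raw, n_tests) {
  n_tests <- as.integer(n_tests)
  if (is.na(n_tests) || n_tests < 1L) stop("n_tests must be >= 1")
  if (any(p_raw <= 0) || any(p_raw > 1)) stop("p_raw must be in (0, 1]")
  pmin(1, n_tests * p_raw)
}

#' Fold change and regulation direction
#'
#' Ratio of pseudocount-stabilized per-condition rates
#' `r_i = (x_i + c) / N_i`, reported as `max(r1, r2) / min(r1, r2)` (always
#' >= 1) with direction `up` when condition 1 has the higher rate, `down`
#' when lower, `none` when equal. With `pseudocount = 0` and both counts
#' zero the fold is undefined; such genes get `fold = NA` and direction
#' `"untestable"` rather than propagating NaN.
#'
#' @param x1,x2,N1,N2 As in [pooled_z()].
#' @param pseudocount Non-negative stabilizer added to each count
#'   (default 0.5).
#' @return Data frame with columns `fold`, `direction`.
#' @examples
#' fold_change(0, 1e6, 49, 1e6)  # fold 99, direction "down"
#' @export
fold_change <- function(x1, N1, x2, N2, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals N must be > 0")
  r1 <- (x1 + pseudocount) / N1
  r2 <- (x2 + pseudocount) / N2
  untestable <- r1 == 0 & r2 == 0
  fold <- pmax(r1, r2) / pmin(r1, r2)
  direction <- ifelse(r1 > r2, "up", ifelse(r1 < r2, "down", "none"))
  fold[untestable] <- NA_real_
  direction[untestable] <- "untestable"
  data.frame(fold = fold, direction = direction, stringsAsFactors = FALSE)
}

#' Run the pooled-z differential expression analysis
#'
#' Full per-gene pipeline for one condition pair: condition aggregation,
#' low-count filter, pooled z statistic, two-sided p, Bonferroni correction
#' over the genes actually tested, fold change with direction (relative to
#' the first condition), counts-per-million normalized abundances, and the
#' two list flags (`flag_p05`: raw p below `alpha_list`; `flag_subset`:
#' Bonferroni p at or below `subset_p` and fold above `subset_fold`).
#'
#' @param counts A [count_matrix()].
#' @param condition_pair Two condition labels, reference first.
#' @param thresholds A [de_thresholds()].
#' @param variant z-statistic variant, see [pooled_z()].
#' @param pseudocount Passed to [fold_change()].
#' @return A data frame sorted by raw p (ties broken by gene id) with
#'   columns gene, x1, N1, x2, N2, cpm1, cpm2, Z, p_raw, p_bonf, fold,
#'   direction, flag_p05, flag_subset; attribute `n_tested` gives the
#'   Bonferroni family size and attribute `status` is `"ok"` or
#'   `"no_testable_genes"` (then the frame has zero rows).
#' @export
run_de <- function(counts, condition_pair, thresholds = de_thresholds(),
                   variant = c("sqrt", "raw"), pseudocount = 0.5) {
  variant <- match.arg(variant)
  stopifnot(inherits(thresholds, "de_thresholds"))
  agg <- aggregate_condition(counts, condition_pair)

  keep <- (agg$x1 + agg$x2) >= thresholds$min_total_count
  empty_cols <- data.frame(
    gene = character(), x1 = numeric(), N1 = numeric(), x2 = numeric(),
    N2 = numeric(), cpm1 = numeric(), cpm2 = numeric(), Z = numeric(),
    p_raw = numeric(), p_bonf = numeric(), fold = numeric(),
    direction = character(), flag_p05 = logical(), flag_subset = logical(),
    stringsAsFactors = FALSE)
  if (!any(keep)) {
    attr(empty_cols, "n_tested") <- 0L
    attr(empty_cols, "status") <- "no_testable_genes"
    return(empty_cols)
  }

  x1 <- agg$x1[keep]; x2 <- agg$x2[keep]
  n_tested <- sum(keep)
  z <- pooled_z(x1, agg$N1, x2, agg$N2, variant)
  p_raw <- two_sided_p(z)
  p_bonf <- bonferroni(p_raw, n_tested)
  fc <- fold_change(x1, agg$N1, x2, agg$N2, pseudocount)

  res <- data.frame(
    gene = agg$genes[keep],
    x1 = x1, N1 = agg$N1, x2 = x2, N2 = agg$N2,
    cpm1 = 1e6 * x1 / agg$N1, cpm2 = 1e6 * x2 / agg$N2,
    Z = z, p_raw = p_raw, p_bonf = p_bonf,
    fold = fc$fold, direction = fc$direction,
    stringsAsFactors = FALSE)
  res$flag_p05 <- res$p_raw < thresholds$alpha_list
  res$flag_subset <- res$p_bonf <= thresholds$subset_p &
    !is.na(res$fold) & res$fold > thresholds$subset_fold
  res <- res[order(res$p_raw, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "status") <- "ok"
  attr(res, "conditions") <- condition_pair
  res
}

#' Extract the up/down high-fold gene lists from a DE table
#'
#' Convenience accessor for the lists that feed enrichment: genes in the
#' Bonferroni `subset_p` / `subset_fold` subset, split by direction relative
#' to the first condition.
#'
#' @param de_table Result of [run_de()].
#' @return List with character vectors `up` and `down`.
#' @export
de_gene_lists <- function(de_table) {
  sub <- de_table[de_table$flag_subset, , drop = FALSE]
  list(up = sub$gene[sub$direction == "up"],
       down = sub$gene[sub$direction == "down"])
}
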