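#' Fit a fixed-effects model to a phenotype response
#'
#' Ordinary least squares with one or two categorical factors, the workhorse
#' behind the carcass-trait and shear-force tables. Factors are coded
#' sum-to-zero so the reported F tests are marginal (type III), which is the
#' appropriate test under the study's unequal group sizes (6/5/5 animals).
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of one or two factor column names.
#' @param include_interaction Add the two-factor interaction term
#'   (two-factor models only).
#' @return An object of class `carcass_fit` wrapping the `lm` fit with
#'   factor metadata; `anova_table()` extracts the marginal F table.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 6), g = c("a", "a", "a", "b", "b"))
#' fit <- fit_carcass_model(d, "y", "g")
#' anova_table(fit)
#' @export
fit_carcass_model <- function(data, response, factors,
                              include_interaction = FALSE) {
  if (!length(factors) %in% 1:2) stop("factors must name one or two columns")
  missing <- setdiff(c(response, factors), names(data))
  if (length(missing)) stop("column(s) not in data: ", paste(missing, collapse = ", "))
  if (include_interaction && length(factors) != 2L) {
    stop("an interaction needs two factors")
  }
  data <- data[, c(response, factors), drop = FALSE]
  data <- data[complete.cases(data), , drop = FALSE]
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L) stop("factor '", f, "' needs >= 2 observed levels")
  }

  op <- paste(factors, collapse = if (include_interaction) " * " else " + ")
  fml <- stats::as.formula(paste(response, "~", op))
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- lm(fml, data = data, contrasts = contr)

  if (fit$df.residual < 1L) stop("model leaves no residual degrees of freedom")
  if (any(is.na(coef(fit)))) {
    stop("singular design: aliased coefficients ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  structure(list(lm = fit, response = response, factors = factors,
                 include_interaction = include_interaction, data = data),
            class = "carcass_fit")
}

#' Marginal (type III) ANOVA table of a carcass fit
#'
#' @param fit A [fit_carcass_model()] result.
#' @return Data frame with one row per model term: term, df, sum_sq, F, p.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "carcass_fit"))
  a <- car::Anova(fit$lm, type = "III")
  a <- as.data.frame(a)
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  data.frame(term = rownames(a)[keep],
             df = a$Df[keep],
             sum_sq = a[keep, "Sum Sq"],
             F = a[keep, "F value"],
             p = a[keep, "Pr(>F)"],
             stringsAsFactors = FALSE)
}

#' Least-squares means for a factor
#'
#' Model-based marginal means: the model prediction for each level of
#' `factor`, averaged with equal weight over the other factor's levels —
#' not observation-weighted, which is what distinguishes LS means from raw
#' group means under unequal cell sizes. For a one-way model the LS mean
#' equals the group arithmetic mean.
#'
#' @param fit A [fit_carcass_model()] result.
#' @param factor Name of the factor to summarize.
#' @return An object of class `lsmeans_table`: data frame with columns
#'   level, lsmean, se, df, carrying the underlying `emmGrid` as attribute
#'   `grid` for downstream pairwise contrasts.
#' @export
ls_means <- function(fit, factor) {
  stopifnot(inherits(fit, "carcass_fit"))
  if (!factor %in% fit$factors) {
    stop("factor '", factor, "' is not in the model (factors: ",
         paste(fit$factors, collapse = ", "), ")")
  }
  emm <- emmeans::emmeans(fit$lm, specs = factor)
  s <- as.data.frame(summary(emm))
  out <- data.frame(level = as.character(s[[factor]]),
                    lsmean = s$emmean, se = s$SE, df = s$df,
                    stringsAsFactors = FALSE)
  structure(out, class = c("lsmeans_table", "data.frame"),
            grid = emm, factor = factor)
}

#' Compact letter display from pairwise LS-mean comparisons
#'
#' Pairwise t-tests on all LS-mean differences (unadjusted by default,
#' matching the PDIFF convention behind published superscripts; Tukey
#' available via `adjust`), rendered as letters by insert-and-absorb:
#' levels sharing a letter are not significantly different at `alpha`.
#' Levels are ordered by descending LS mean and the highest mean takes
#' letter `a`.
#'
#' @param lsm A [ls_means()] table.
#' @param alpha Significance level for pairwise differences (default 0.05).
#' @param adjust Multiplicity adjustment for the pairwise p-values
#'   (`"none"`, the default, or `"tukey"`).
#' @return Data frame level, lsmean, se, letters (ordered by descending
#'   LS mean); attribute `pairwise` holds the contrast table.
#' @export
pairwise_letters <- function(lsm, alpha = 0.05, adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(lsm, "lsmeans_table"))
  grid <- attr(lsm, "grid")
  ord <- order(-lsm$lsmean, lsm$level)
  levels_sorted <- lsm$level[ord]

  if (nrow(lsm) < 2L) stop("letter display needs >= 2 levels")
  ctr <- as.data.frame(summary(emmeans::contrast(grid, method = "pairwise",
                                                 adjust = adjust)))
  # contrast labels are "lvl1 - lvl2"; numeric-like levels get the factor
  # name prepended (e.g. "aging_day1 - aging_day3") — strip both decorations
  clean <- function(s) {
    s <- trimws(gsub("^\\(|\\)$", "", trimws(s)))
    if (s %in% levels_sorted) return(s)
    sub(paste0("^", attr(lsm, "factor")), "", s)
  }
  pair_lv <- strsplit(as.character(ctr$contrast), " - ", fixed = TRUE)
  pairs <- do.call(rbind, lapply(seq_along(pair_lv), function(i) {
    data.frame(a = clean(pair_lv[[i]][1]), b = clean(pair_lv[[i]][2]),
               p = ctr$p.value[i], stringsAsFactors = FALSE)
  }))
  bad <- setdiff(unique(c(pairs$a, pairs$b)), levels_sorted)
  if (length(bad)) stop("could not match contrast label(s) to levels: ",
                        paste(bad, collapse = ", "))

  sig <- matrix(FALSE, nrow(lsm), nrow(lsm),
                dimnames = list(levels_sorted, levels_sorted))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$p[i] <= alpha) {
      sig[pairs$a[i], pairs$b[i]] <- TRUE
      sig[pairs$b[i], pairs$a[i]] <- TRUE
    }
  }
  letters_vec <- cld_insert_absorb(levels_sorted, sig)

  out <- data.frame(level = levels_sorted,
                    lsmean = lsm$lsmean[ord], se = lsm$se[ord],
                    letters = letters_vec[levels_sorted],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pairwise") <- pairs
  attr(out, "alpha") <- alpha
  out
}

# Insert-and-absorb compact letter display (Piepho-style). `levels_sorted`
# is ordered by descending mean; `sig` is a symmetric logical matrix of
# significant pairwise differences over those levels. Returns a named
# character vector of letter strings; levels share a letter iff they sit in
# a common non-significance class.
cld_insert_absorb <- function(levels_sorted, sig) {
  cols <- list(levels_sorted)  # start: one class holding every level
  for (a in levels_sorted) {
    for (b in levels_sorted) {
      if (a >= b || !sig[a, b]) next
      k <- 1L
      while (k <= length(cols)) {
        cl <- cols[[k]]
        if (a %in% cl && b %in% cl) {
          # split the violating class into two, dropping one level each
          cols[[k]] <- setdiff(cl, a)
          cols[[length(cols) + 1L]] <- setdiff(cl, b)
          # absorb: delete any class contained in another
          keep <- rep(TRUE, length(cols))
          for (i in seq_along(cols)) {
            for (j in seq_along(cols)) {
              if (i != j && keep[j] &&
                  all(cols[[i]] %in% cols[[j]]) &&
                  (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
                keep[i] <- FALSE
                break
              }
            }
          }
          cols <- cols[keep]
          k <- 0L  # rescan from the start after a split
        }
        k <- k + 1L
      }
    }
  }
  # order classes by the position of their top (highest-mean) member so the
  # highest mean gets 'a'
  first_pos <- vapply(cols, function(cl) min(match(cl, levels_sorted)), 0)
  cols <- cols[order(first_pos)]
  out <- setNames(rep("", length(levels_sorted)), levels_sorted)
  for (i in seq_along(cols)) {
    for (lv in cols[[i]]) out[lv] <- paste0(out[lv], letters[i])
  }
  out
}

#' Screen for a grade x aging interaction
#'
#' Fits the two-factor model with interaction, reports the interaction's
#' marginal F and p, and records the modeling decision: if the interaction
#' is not significant at `alpha` the downstream analysis proceeds with
#' main-effects models (as the study did), otherwise the interaction is
#' kept.
#'
#' @param data,response Passed to [fit_carcass_model()].
#' @param factor_a,factor_b The two factor column names.
#' @param alpha Decision level (default 0.05).
#' @return List with `F`, `p`, `df`, `decision` (`"main_effects"` or
#'   `"keep_interaction"`), and the fitted `carcass_fit`.
#' @export
interaction_screen <- function(data, response, factor_a, factor_b,
                               alpha = 0.05) {
  fit <- fit_carcass_model(data, response, c(factor_a, factor_b),
                           include_interaction = TRUE)
  at <- anova_table(fit)
  ia <- at[grepl(":", at$term, fixed = TRUE), , drop = FALSE]
  if (nrow(ia) != 1L) stop("interaction term not found in ANOVA table")
  list(F = ia$F, p = ia$p, df = ia$df,
       decision = if (ia$p >= alpha) "main_effects" else "keep_interaction",
       fit = fit)
}
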