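#' Read a GMT gene-set collection
#'
#' Parses the standard tab-separated GMT format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are collapsed; case is preserved.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: list with `terms`
#'   (named list of character vectors, in file order) and `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    name <- fields[1]
    if (name %in% names(terms)) stop("duplicate term name in GMT: ", name)
    terms[[name]] <- unique(fields[-(1:2)])
    descriptions[[name]] <- fields[2]
  }
  structure(list(terms = terms, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$terms), "terms,",
      length(unique(unlist(x$terms))), "distinct genes\n")
  invisible(x)
}

#' Hypergeometric over-representation p-value (Fisher / EASE)
#'
#' One-tailed enrichment p for observing `k` or more list genes in a set of
#' `K` background members, with a list of size `n` drawn from a background
#' of `M` genes: `p = P(X >= k)` for `X ~ Hypergeometric(M, K, n)`, computed
#' exactly. The `ease` mode is the conservative modified Fisher score that
#' discounts one gene from the observed overlap (`k` replaced by
#' `max(k - 1, 0)`), so an overlap of a single gene is never significant.
#'
#' @param k Overlap count (list genes in the set).
#' @param n List size. @param K Set size in background. @param M Background
#'   size.
#' @param mode `"fisher"` or `"ease"`.
#' @return p-value in (0, 1].
#' @examples
#' ease_p(2, 2, 5, 10, mode = "fisher")  # 10/45
#' ease_p(2, 2, 5, 10, mode = "ease")    # 35/45
#' @export
ease_p <- function(k, n, K, M, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  if (K > M || n > M) stop("set size K and list size n must not exceed background M")
  if (k < 0 || k > min(n, K)) stop("overlap k must satisfy 0 <= k <= min(n, K)")
  k_eff <- if (mode == "ease") pmax(k - 1, 0) else k
  # P(X >= k_eff); phyper's upper tail is strict, hence k_eff - 1
  phyper(k_eff - 1, K, M - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of a DE gene list
#'
#' Tests every term of a collection for over-representation in `gene_list`
#' against the background universe (by default all genes in the
#' collection's union; in the pipeline, all genes tested for DE). List
#' genes outside the background are dropped with a warning, duplicates are
#' counted once, and terms with fewer than two background members are
#' skipped with a warning. No correction across terms is applied: the
#' reported p is the raw enrichment p, flagged at `cutoff`.
#'
#' @param gene_list Character vector of query genes.
#' @param collection A [read_gmt()] collection.
#' @param background Character vector defining the gene universe.
#' @param cutoff Enrichment flag cutoff on raw p (default 0.1).
#' @param mode `"fisher"` or `"ease"`, see [ease_p()].
#' @return Data frame sorted by p then term: columns term, k (overlap), n
#'   (list size in background), K (set size in background), M (background
#'   size), p, enriched; attribute `status` is `"ok"` or `"empty_list"`.
#' @export
enrich <- function(gene_list, collection, background = NULL, cutoff = 0.1,
                   mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(background)) background <- unique(unlist(collection$terms))
  background <- unique(as.character(background))
  M <- length(background)

  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background were dropped")
    gene_list <- intersect(gene_list, background)
  }
  n <- length(gene_list)

  empty <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), M = integer(), p = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "status") <- "empty_list"
    return(empty)
  }

  rows <- lapply(names(collection$terms), function(term) {
    members <- intersect(collection$terms[[term]], background)
    K <- length(members)
    if (K < 2L) {
      warning("term '", term, "' has < 2 background members; skipped")
      return(NULL)
    }
    k <- length(intersect(gene_list, members))
    data.frame(term = term, k = k, n = n, K = K, M = M,
               p = ease_p(k, n, K, M, mode), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    attr(empty, "status") <- "ok"
    return(empty)
  }
  res$enriched <- res$p < cutoff
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "status") <- "ok"
  res
}
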