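#' Pooled count matrix container
#'
#' Integer gene counts for pooled sequencing libraries together with the
#' pool-to-condition map and per-pool library totals (total aligned reads,
#' taken as the column sums unless supplied).
#'
#' @param counts Integer matrix, genes x pools, with unique rownames (gene
#'   ids) and colnames (pool ids).
#' @param map Data frame with columns `pool`, `condition` covering every
#'   column of `counts`.
#' @param totals Optional named per-pool library totals; defaults to column
#'   sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, map, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene rownames")
  }
  if (is.null(colnames(counts))) stop("counts must have pool colnames")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!all(c("pool", "condition") %in% names(map))) {
    stop("map must have columns 'pool' and 'condition'")
  }
  map <- data.frame(pool = as.character(map$pool),
                    condition = as.character(map$condition),
                    stringsAsFactors = FALSE)
  missing <- setdiff(colnames(counts), map$pool)
  if (length(missing)) stop("pool(s) missing from condition map: ",
                            paste(missing, collapse = ", "))
  map <- map[match(colnames(counts), map$pool), , drop = FALSE]
  rownames(map) <- NULL
  if (is.null(totals)) {
    totals <- colSums(counts)
  } else {
    totals <- totals[colnames(counts)]
    if (any(is.na(totals)) || any(totals <= 0)) stop("totals must be positive for every pool")
  }
  structure(list(counts = counts, map = map, totals = totals),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "pools\n")
  cat("conditions:", paste(unique(x$map$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate per-animal gene counts
#'
#' Draws a gene x animal count matrix from a negative-binomial model
#' (`var = mu + dispersion * mu^2`; `dispersion = 0` is exact Poisson). A
#' random subset of `de_fraction * n_genes` genes is spiked: in grade *g*
#' their baseline mean is multiplied by `effect_folds[g]`. Each grade's
#' per-gene means are then rescaled so the expected per-animal library total
#' equals `library_depth` — a fixed sequencing depth means spiked genes
#' claim a larger share of reads rather than adding reads.
#'
#' @param config A [count_sim_config()].
#' @param design A [design_spec()]; its grades must all appear in
#'   `config$effect_folds`.
#' @param seed Integer seed.
#' @return A list: `counts` (integer matrix genes x animals), `animals`
#'   (data frame animal_id, grade), `spiked` (character vector of spiked
#'   gene ids — the ground-truth DE set), `mean_matrix` (expected counts,
#'   genes x grades).
#' @export
simulate_animal_counts <- function(config, design, seed) {
  stopifnot(inherits(config, "count_sim_config"), inherits(design, "design_spec"))
  missing <- setdiff(design$grades, names(config$effect_folds))
  if (length(missing)) stop("effect_folds missing grade(s): ",
                            paste(missing, collapse = ", "))

  genes <- gene_ids(config$n_genes)
  with_rng(seed, {
    spiked <- if (config$n_spiked > 0L) {
      sort(sample(genes, config$n_spiked))
    } else character(0)

    fold_mat <- matrix(1, config$n_genes, length(design$grades),
                       dimnames = list(genes, design$grades))
    for (g in design$grades) {
      fold_mat[spiked, g] <- config$effect_folds[[g]]
    }
    mean_mat <- config$baseline_mean * fold_mat
    # per-grade depth normalization: expected animal total = library_depth
    mean_mat <- sweep(mean_mat, 2, colSums(mean_mat), "/") * config$library_depth

    animals <- do.call(rbind, lapply(design$grades, function(g) {
      data.frame(animal_id = animal_ids(design, g), grade = g,
                 stringsAsFactors = FALSE)
    }))
    counts <- matrix(0L, config$n_genes, nrow(animals),
                     dimnames = list(genes, animals$animal_id))
    for (j in seq_len(nrow(animals))) {
      mu <- mean_mat[, animals$grade[j]]
      counts[, j] <- if (config$dispersion == 0) {
        rpois(config$n_genes, mu)
      } else {
        rnbinom(config$n_genes, size = 1 / config$dispersion, mu = mu)
      }
    }
    list(counts = counts, animals = animals, spiked = spiked,
         mean_matrix = mean_mat)
  })
}

#' Randomly allocate each grade's animals to pools
#'
#' Balanced random split: within a grade the animals are shuffled and dealt
#' into `pools_per_grade` pools whose sizes differ by at most one (the study
#' split 6 Choice animals 3/3 and the 5 Select and 5 Standard animals 3/2).
#'
#' @param design A [design_spec()].
#' @param seed Integer seed.
#' @return A `pool_assignment`: named list mapping pool id (e.g.
#'   `"Choice_P1"`) to a list with `grade` and `animal_ids`.
#' @export
assign_pools <- function(design, seed) {
  stopifnot(inherits(design, "design_spec"))
  with_rng(seed, {
    out <- list()
    for (g in design$grades) {
      ids <- sample(animal_ids(design, g))
      k <- design$pools_per_grade
      # deal sizes differing by at most one, larger pools first
      sizes <- rep(length(ids) %/% k, k) + (seq_len(k) <= length(ids) %% k)
      idx <- split(seq_along(ids), rep(seq_len(k), sizes))
      for (p in seq_len(k)) {
        out[[paste0(g, "_P", p)]] <- list(grade = g,
                                          animal_ids = sort(ids[idx[[p]]]))
      }
    }
    structure(out, class = "pool_assignment")
  })
}

#' Sum animal libraries into pooled libraries
#'
#' Forms each pool's count vector as the sum of its member animals' counts,
#' optionally downsampled to a common target depth by multinomial draws on
#' the pooled gene proportions (emulating resequencing the pooled material
#' at fixed depth).
#'
#' @param animal_counts Result of [simulate_animal_counts()], or any integer
#'   matrix genes x animals.
#' @param assignment A `pool_assignment` from [assign_pools()].
#' @param target_depth Optional common library total per pool; must not
#'   exceed any pool's summed total.
#' @param seed Integer seed (used only when downsampling).
#' @return A [count_matrix()] whose conditions are the grades.
#' @export
form_pool_libraries <- function(animal_counts, assignment, target_depth = NULL,
                                seed = 0L) {
  counts <- if (is.list(animal_counts)) animal_counts$counts else animal_counts
  stopifnot(inherits(assignment, "pool_assignment"))
  needed <- unlist(lapply(assignment, `[[`, "animal_ids"))
  missing <- setdiff(needed, colnames(counts))
  if (length(missing)) stop("assigned animal(s) absent from count matrix: ",
                            paste(missing, collapse = ", "))

  pooled <- vapply(assignment, function(p) {
    rowSums(counts[, p$animal_ids, drop = FALSE])
  }, numeric(nrow(counts)))
  storage.mode(pooled) <- "integer"

  if (!is.null(target_depth)) {
    target_depth <- as.numeric(target_depth)
    short <- colSums(pooled) < target_depth
    if (any(short)) {
      stop("target_depth exceeds summed total of pool(s): ",
           paste(colnames(pooled)[short], collapse = ", "))
    }
    pooled <- with_rng(seed, {
      apply(pooled, 2, function(x) {
        as.integer(rmultinom(1, size = target_depth, prob = x))
      })
    })
    rownames(pooled) <- rownames(counts)
  }

  map <- data.frame(pool = names(assignment),
                    condition = vapply(assignment, `[[`, "", "grade"),
                    stringsAsFactors = FALSE)
  count_matrix(pooled, map)
}
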