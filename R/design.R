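#' Study design for the pooled-library experiment
#'
#' Describes the animal cohort and pooling layout: an ordered set of quality
#' grades, the number of animals per grade, and how many sequencing pools
#' each grade's animal libraries are split into. The default reproduces the
#' study cohort: 16 steers (6 Choice, 5 Select, 5 Standard) with two pools
#' per grade serving as biological replicates.
#'
#' @param grades Character vector of condition labels, ordered (reference
#'   grade first for count simulation).
#' @param animals_per_grade Named integer vector, one positive entry per
#'   grade.
#' @param pools_per_grade Number of pools each grade's animals are randomly
#'   split into (default 2).
#' @return An object of class `design_spec`.
#' @examples
#' design_spec()
#' design_spec(grades = c("A", "B"), animals_per_grade = c(A = 4, B = 4))
#' @export
design_spec <- function(grades = c("Standard", "Select", "Choice"),
                        animals_per_grade = c(Standard = 5, Select = 5, Choice = 6),
                        pools_per_grade = 2L) {
  grades <- as.character(grades)
  if (anyDuplicated(grades)) stop("grade labels must be unique")
  if (is.null(names(animals_per_grade)) ||
      !setequal(names(animals_per_grade), grades)) {
    stop("animals_per_grade must be named by the grades: ",
         paste(grades, collapse = ", "))
  }
  animals_per_grade <- animals_per_grade[grades]
  n <- as.integer(animals_per_grade)
  if (any(is.na(n)) || any(n < 1L)) stop("animals_per_grade must be positive integers")
  pools_per_grade <- as.integer(pools_per_grade)
  if (pools_per_grade < 1L) stop("pools_per_grade must be >= 1")
  if (any(n < pools_per_grade)) {
    bad <- grades[n < pools_per_grade]
    stop("grade(s) with fewer animals than pools: ", paste(bad, collapse = ", "))
  }
  structure(
    list(grades = grades,
         animals_per_grade = setNames(n, grades),
         pools_per_grade = pools_per_grade),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", sum(x$animals_per_grade), "animals;",
      x$pools_per_grade, "pool(s) per grade\n")
  for (g in x$grades) cat("  ", g, ": ", x$animals_per_grade[[g]], " animals\n", sep = "")
  invisible(x)
}

# animal ids of one grade, e.g. "Choice_1" .. "Choice_6"
animal_ids <- function(design, grade) {
  paste(grade, seq_len(design$animals_per_grade[[grade]]), sep = "_")
}

#' Configuration for the per-animal count simulator
#'
#' Parameters of the negative-binomial gene-count model used to emulate
#' individual animal libraries before pooling. Counts for gene *i* in an
#' animal of grade *g* are drawn with mean
#' `baseline_mean[i] * fold(g, i) * s_g`, where `s_g` rescales each grade's
#' expected per-animal total to `library_depth` (sequencing yields a fixed
#' depth, so spiking genes up reallocates proportions rather than adding
#' reads), and variance `mu + dispersion * mu^2` (`dispersion = 0` is exact
#' Poisson).
#'
#' @param n_genes Number of genes.
#' @param baseline_mean Per-gene expected count at reference depth; scalar
#'   (recycled) or length `n_genes`.
#' @param dispersion Overdispersion alpha >= 0 in `var = mu + alpha mu^2`.
#' @param de_fraction Fraction of genes carrying a grade effect, in [0, 1);
#'   `de_fraction * n_genes` must be a whole number.
#' @param effect_folds Named positive fold multipliers per grade applied to
#'   the spiked genes; the reference grade must have fold 1.
#' @param library_depth Expected reads per animal library.
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 200L,
                             baseline_mean = 100,
                             dispersion = 0.05,
                             de_fraction = 0.05,
                             effect_folds = c(Standard = 1, Select = 2, Choice = 4),
                             library_depth = 1e6) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be positive")
  if (!length(baseline_mean) %in% c(1L, n_genes)) {
    stop("baseline_mean must be scalar or length n_genes")
  }
  if (any(baseline_mean <= 0)) stop("baseline_mean must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0, 1)")
  n_spiked <- de_fraction * n_genes
  if (abs(n_spiked - round(n_spiked)) > 1e-8) {
    stop("de_fraction * n_genes must be a whole number of spiked genes")
  }
  if (any(effect_folds <= 0)) stop("fold multipliers must be > 0")
  if (library_depth < 1) stop("library_depth must be positive")
  structure(
    list(n_genes = n_genes,
         baseline_mean = rep_len(as.numeric(baseline_mean), n_genes),
         dispersion = as.numeric(dispersion),
         de_fraction = as.numeric(de_fraction),
         n_spiked = as.integer(round(n_spiked)),
         effect_folds = effect_folds,
         library_depth = as.numeric(library_depth)),
    class = "count_sim_config"
  )
}

# stable zero-padded gene ids g000001...
gene_ids <- function(n) sprintf("g%06d", seq_len(n))
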