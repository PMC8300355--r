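#' Read a phenotype calibration file
#'
#' Loads the plain-text (YAML) calibration mirroring the published
#' main-effect tables: per-grade shear-force means and SDs, per-aging-day
#' shear means, and per-grade (mean, SD) pairs for the non-aged carcass
#' traits (hot carcass weight, fat depth, ribeye area, KPH, yield grade,
#' marbling score). The file shipped with the package carries the study's
#' printed values.
#'
#' @param path Path to a calibration YAML; defaults to the shipped file.
#' @return A list with components `grades`, `aging_days`, `shear`, `traits`.
#' @export
read_calibration <- function(path = system.file("extdata", "carcass_calibration.yaml",
                                                package = "gradexpr")) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  cal <- yaml::read_yaml(path)
  needed <- c("grades", "aging_days", "shear", "traits")
  missing <- setdiff(needed, names(cal))
  if (length(missing)) stop("calibration file lacks field(s): ",
                            paste(missing, collapse = ", "))
  cal$aging_days <- as.integer(cal$aging_days)
  cal
}

#' Calibrate the additive phenotype model
#'
#' Turns published marginal means into an additive simulation model for
#' Warner-Bratzler shear force,
#' `shear(animal, day) = grand_mean + grade_effect + aging_effect + noise`,
#' plus independent per-grade normal draws for the non-aged carcass traits.
#' The grand mean is the unweighted mean of the aging-day means; grade and
#' aging effects are deviations of the respective marginal means from it.
#' Because the two published margins are rounded independently, the grade
#' effects are allowed a small non-zero sum; calibration fails if the two
#' implied grand means disagree by more than 0.1 N.
#'
#' @param calibration A calibration list as returned by [read_calibration()].
#' @return An object of class `phenotype_model` with fields `grand_mean`,
#'   `grade_effects`, `aging_effects`, `residual_sd` (per grade, N),
#'   `trait_params`, `grades`, `aging_days`.
#' @examples
#' m <- calibrate_phenotype_model()
#' m$grand_mean  # unweighted mean of the five aging-day shear means
#' @export
calibrate_phenotype_model <- function(calibration = read_calibration()) {
  grades <- calibration$grades
  days <- calibration$aging_days
  shear <- calibration$shear

  gm <- unlist(shear$grade_means)
  gs <- unlist(shear$grade_sds)
  am <- unlist(shear$aging_means)
  miss_g <- setdiff(grades, names(gm))
  if (length(miss_g)) stop("shear grade mean missing for grade: ",
                           paste(miss_g, collapse = ", "))
  miss_d <- setdiff(as.character(days), names(am))
  if (length(miss_d)) stop("shear aging mean missing for day: ",
                           paste(miss_d, collapse = ", "))
  if (any(gs[grades] <= 0)) stop("shear residual SDs must be > 0")

  grand_mean <- mean(am[as.character(days)])
  aging_effects <- am[as.character(days)] - grand_mean
  grade_effects <- gm[grades] - grand_mean

  # consistency of the two printed margins: both estimate the same grand mean
  drift <- abs(mean(gm[grades]) - grand_mean)
  if (drift > 0.1) {
    stop(sprintf(
      "grade-margin and aging-margin grand means disagree by %.3f N (> 0.1)", drift))
  }

  trait_params <- lapply(calibration$traits, function(tr) {
    mu <- unlist(tr$mean)[grades]
    sd <- unlist(tr$sd)[grades]
    if (any(is.na(mu)) || any(is.na(sd))) {
      stop("trait table missing a grade among: ", paste(grades, collapse = ", "))
    }
    if (any(sd <= 0)) stop("trait SDs must be > 0")
    list(mean = mu, sd = sd)
  })

  structure(
    list(grand_mean = grand_mean,
         grade_effects = grade_effects,
         aging_effects = aging_effects,
         residual_sd = gs[grades],
         trait_params = trait_params,
         grades = grades,
         aging_days = days),
    class = "phenotype_model"
  )
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("Additive phenotype model\n")
  cat(sprintf("  grand mean shear: %.2f N\n", x$grand_mean))
  cat("  grade effects (N):",
      paste(sprintf("%s %+0.2f", names(x$grade_effects), x$grade_effects),
            collapse = ", "), "\n")
  cat("  aging effects (N):",
      paste(sprintf("d%s %+0.2f", names(x$aging_effects), x$aging_effects),
            collapse = ", "), "\n")
  cat("  traits:", paste(names(x$trait_params), collapse = ", "), "\n")
  invisible(x)
}
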