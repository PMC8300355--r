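#' Simulate carcass and shear-force phenotypes
#'
#' Draws per-animal records from a calibrated [phenotype
#' model][calibrate_phenotype_model]: shear force follows the additive
#' grade + aging-day model with per-grade residual noise; each non-aged
#' carcass trait is an independent normal draw per animal with its grade's
#' mean and SD, truncated below at a trait-specific floor (0 for physical
#' quantities, 100 for the marbling score, whose scale bottoms out below
#' "Traces"). The same seed always yields the same tables.
#'
#' @param model A `phenotype_model`.
#' @param design A [design_spec()]; grades must match the model's.
#' @param n_steaks_per_cell Shear records per animal x aging-day cell
#'   (default 1, one averaged steak measurement per cell).
#' @param seed Integer seed governing all draws.
#' @return A list with `shear` (data frame: animal_id, grade, aging_day,
#'   shear_n) and `carcass` (data frame: animal_id, grade, one column per
#'   trait).
#' @examples
#' m <- calibrate_phenotype_model()
#' ph <- simulate_phenotypes(m, design_spec(), seed = 1)
#' head(ph$shear)
#' @export
simulate_phenotypes <- function(model, design, n_steaks_per_cell = 1L, seed) {
  stopifnot(inherits(model, "phenotype_model"), inherits(design, "design_spec"))
  if (!setequal(design$grades, model$grades)) {
    stop("design grades do not match the calibrated model's grades")
  }
  n_steaks_per_cell <- as.integer(n_steaks_per_cell)
  if (n_steaks_per_cell < 1L) stop("n_steaks_per_cell must be positive")

  trait_floor <- function(trait) if (trait == "marbling") 100 else 0

  with_rng(seed, {
    shear_rows <- list()
    carcass_rows <- list()
    for (g in design$grades) {
      ids <- animal_ids(design, g)
      n_a <- length(ids)

      cells <- expand.grid(animal_id = ids,
                           aging_day = model$aging_days,
                           rep = seq_len(n_steaks_per_cell),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mu <- model$grand_mean + model$grade_effects[[g]] +
        model$aging_effects[as.character(cells$aging_day)]
      shear_rows[[g]] <- data.frame(
        animal_id = cells$animal_id,
        grade = g,
        aging_day = cells$aging_day,
        shear_n = as.numeric(mu) + rnorm(nrow(cells), 0, model$residual_sd[[g]]),
        stringsAsFactors = FALSE
      )

      traits <- lapply(names(model$trait_params), function(tr) {
        p <- model$trait_params[[tr]]
        pmax(rnorm(n_a, p$mean[[g]], p$sd[[g]]), trait_floor(tr))
      })
      names(traits) <- names(model$trait_params)
      carcass_rows[[g]] <- data.frame(animal_id = ids, grade = g,
                                      traits, stringsAsFactors = FALSE)
    }
    shear <- do.call(rbind, shear_rows)
    carcass <- do.call(rbind, carcass_rows)
    rownames(shear) <- rownames(carcass) <- NULL
    shear$grade <- factor(shear$grade, levels = design$grades)
    carcass$grade <- factor(carcass$grade, levels = design$grades)
    list(shear = shear, carcass = carcass)
  })
}
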