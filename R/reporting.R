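## Scenario grids and curve export.

#' Carrier-probability grids over scenario parameters
#'
#' Evaluates carrier probabilities over a Cartesian grid of scenario
#' parameters for one of the example families: `"single_case"` (one
#' affected woman; grid over diagnosis age and her ER status),
#' `"mother_daughter"` (affected mother and daughter; grid over both
#' diagnosis ages and the mother's ER status) or `"tested_negative"`
#' (the mother-daughter family with a mutation-negative proband).
#'
#' @param model A `brca_risk_model`.
#' @param scenario Scenario name.
#' @param proband_ages Vector of proband diagnosis ages.
#' @param relative_ages Vector of the mother's diagnosis ages (ignored
#'   for `"single_case"`).
#' @param er_states ER states for the scenario's varying tumour
#'   (`"untested"`, `"negative"`, `"positive"`).
#' @return A data frame of class `scenario_grid` with one row per cell
#'   and columns `p_noncarrier`, `p_brca1`, `p_brca2`.
#' @export
generate_probability_grid <- function(model,
                                      scenario = c("single_case", "mother_daughter",
                                                   "tested_negative"),
                                      proband_ages,
                                      relative_ages = NULL,
                                      er_states = c("untested", "negative", "positive")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(model, "brca_risk_model"))
  if (!length(proband_ages) || !length(er_states) ||
      (scenario != "single_case" && !length(relative_ages))) {
    stop("empty scenario parameter range", call. = FALSE)
  }
  cells <- if (scenario == "single_case") {
    expand.grid(proband_age = proband_ages, er = er_states,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(proband_age = proband_ages, mother_age = relative_ages,
                mother_er = er_states, stringsAsFactors = FALSE)
  }
  post <- t(vapply(seq_len(nrow(cells)), function(i) {
    ped <- switch(scenario,
      single_case = ped_single_case(cells$proband_age[i], er = cells$er[i]),
      mother_daughter = ped_mother_daughter(cells$proband_age[i],
                                            cells$mother_age[i],
                                            mother_er = cells$mother_er[i]),
      tested_negative = ped_proband_tested_negative(cells$proband_age[i],
                                                    cells$mother_age[i],
                                                    mother_er = cells$mother_er[i]))
    unclass(predict(model, ped, target = "proband"))
  }, numeric(3)))
  colnames(post) <- c("p_noncarrier", "p_brca1", "p_brca2")
  out <- cbind(cells, as.data.frame(post))
  class(out) <- c("scenario_grid", "data.frame")
  out
}

#' Export per-age hazard and cumulative-risk curves
#'
#' Tabulates, for each requested genotype and end-point class, the
#' polygene-averaged (survivor-weighted) hazard per 100,000 and the
#' polygene-averaged cumulative risk at every age, optionally writing
#' the table as CSV.
#'
#' @param model A `brca_risk_model`.
#' @param genotypes Genotypes to include.
#' @param classes End-point classes (see [cumulative_risk()]).
#' @param cohort Cohort label (default: first).
#' @param scenario CK assay scenario, for CK classes.
#' @param path Optional CSV output path.
#' @return A data frame with columns `cohort`, `genotype`, `endpoint`,
#'   `age`, `hazard_per_100k`, `cumulative_risk`.
#' @export
export_risk_curves <- function(model, genotypes = GENOTYPES,
                               classes = c("total", "er_neg", "er_pos"),
                               cohort = NULL, scenario = NULL, path = NULL) {
  stopifnot(inherits(model, "brca_risk_model"))
  ep <- model$endpoints
  if (is.null(cohort)) cohort <- names(ep$cohorts)[1]
  ch <- get_cohort(ep, cohort)
  rows <- list()
  for (g in genotypes) {
    for (cl in classes) {
      share <- endpoint_share(ep, g, cl, scenario, cohort)
      cum <- vapply(AGES + 1, function(a) cumulative_risk(ep, g, cl, a, cohort,
                                                          scenario),
                    numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, genotype = g, endpoint = cl, age = AGES,
        hazard_per_100k = ch$lambda_bar[, g] * share * 1e5,
        cumulative_risk = cum, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
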