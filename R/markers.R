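## Tumour marker proportion tables (ER / TN / basal cytokeratins).

ER_BANDS <- c(0, 30, 40, 50, 60, 70)  # right-open; <30, 30-39, ..., >=70

CK_SCENARIOS <- c("both_ck", "ck56_only", "ck14_only")

#' Built-in tumour marker proportion tables
#'
#' Returns the marker proportion tables embedded in the package, derived
#' from a consortium series of BRCA1/BRCA2 carrier tumours and unselected
#' control tumours:
#'
#' * `er_negative_given_case`: proportion of incident breast cancers that
#'   are ER-negative, by 10-year age band. A full band table is carried
#'   for BRCA1 (the oldest band is extrapolated from 60-69). The BRCA2
#'   row of the source table is retained for reference but, because the
#'   BRCA2 ER distribution is indistinguishable from the general
#'   population, BRCA2 and noncarrier proportions are by default taken
#'   from the population ER-negative curve of the model configuration.
#' * `tn_given_er_negative`: proportion of ER-negative cancers that are
#'   triple-negative (ER-, PR-, HER2-), age-constant, per genotype.
#' * `ck_class_given_tn`: cytokeratin class distribution among TN
#'   tumours, age-constant, for three assay scenarios: both CK5/6 and
#'   CK14 tested (classes `both_pos`, `one_pos`, `neither`), only CK5/6
#'   tested, only CK14 tested (classes `pos`, `neg`). Sparse BRCA2 CK
#'   data are replaced by the control values except for the CK14-only
#'   row, which was estimated directly.
#'
#' Control ("unselected cases") values double as the population-level
#' proportions when noncarrier proportions are solved from the population
#' constraint.
#'
#' @return An object of class `marker_tables`.
#' @examples
#' tabs <- builtin_marker_tables()
#' marker_proportion(tabs, "BRCA1", 45, "er_neg")   # 0.86
#' @export
builtin_marker_tables <- function() {
  er_b1 <- c(0.93, 0.91, 0.86, 0.89, 0.83, 0.83)
  er_b2 <- c(0.44, 0.26, 0.47, 0.14, 0.20, 0.15)  # sparse; unused by default
  names(er_b1) <- names(er_b2) <-
    c("<30", "30-39", "40-49", "50-59", "60-69", ">=70")

  tn <- c(noncarrier = 0.53, BRCA1 = 0.90, BRCA2 = 0.86)

  ck <- list(
    both_ck = rbind(
      both_pos = c(noncarrier = 0.14, BRCA1 = 0.49, BRCA2 = 0.14),
      one_pos  = c(noncarrier = 0.24, BRCA1 = 0.30, BRCA2 = 0.24),
      neither  = c(noncarrier = 0.62, BRCA1 = 0.21, BRCA2 = 0.62)
    ),
    ck56_only = rbind(
      pos = c(noncarrier = 0.26, BRCA1 = 0.64, BRCA2 = 0.26),
      neg = c(noncarrier = 0.74, BRCA1 = 0.36, BRCA2 = 0.74)
    ),
    ck14_only = rbind(
      pos = c(noncarrier = 0.27, BRCA1 = 0.63, BRCA2 = 0.50),
      neg = c(noncarrier = 0.73, BRCA1 = 0.37, BRCA2 = 0.50)
    )
  )

  structure(list(
    er_negative_given_case = list(BRCA1 = er_b1, BRCA2 = er_b2),
    er_band_extrapolated = list(BRCA1 = c(rep(FALSE, 5), TRUE)),
    tn_given_er_negative = tn,
    ck_class_given_tn = ck
  ), class = "marker_tables")
}

er_band_index <- function(age) findInterval(age, ER_BANDS)

# Yearly ER-negative proportion curve for a genotype. BRCA2 and
# noncarriers delegate to the population curve unless the configuration
# opts into the (sparse) BRCA2 band table.
er_curve_for_genotype <- function(tables, genotype, population_er,
                                  use_table1_brca2 = FALSE) {
  if (genotype == "BRCA1" || (genotype == "BRCA2" && use_table1_brca2)) {
    unname(tables$er_negative_given_case[[genotype]][er_band_index(AGES)])
  } else {
    if (is.null(population_er)) {
      stop("population ER-negative curve required for genotype ", genotype,
           call. = FALSE)
    }
    population_er
  }
}

#' Look up a marker proportion
#'
#' Evaluates one conditional marker proportion for a genotype at a given
#' age: ER status uses the 10-year age-band tables (or the population
#' curve), TN and cytokeratin proportions are age-constant.
#'
#' @param tables A `marker_tables` object, from [builtin_marker_tables()].
#' @param genotype One of `"noncarrier"`, `"BRCA1"`, `"BRCA2"`.
#' @param age Age at diagnosis in years (0-79).
#' @param query One of `"er_neg"`, `"er_pos"` (proportion of cases),
#'   `"tn"`, `"non_tn"` (proportion of ER-negative cases), or a
#'   cytokeratin class: `"both_pos"`, `"one_pos"`, `"neither"` (scenario
#'   `"both_ck"`), `"pos"`, `"neg"` (scenarios `"ck56_only"`,
#'   `"ck14_only"`).
#' @param scenario Cytokeratin assay scenario; required for CK queries.
#' @param population_er Optional yearly population ER-negative proportion
#'   curve (length 80), required for ER queries on BRCA2/noncarriers.
#' @param use_table1_brca2 Use the sparse BRCA2 ER band table instead of
#'   the population curve.
#' @return A probability.
#' @export
marker_proportion <- function(tables, genotype, age, query,
                              scenario = NULL, population_er = NULL,
                              use_table1_brca2 = FALSE) {
  stopifnot(inherits(tables, "marker_tables"))
  if (!genotype %in% GENOTYPES) stop("unknown genotype: ", genotype, call. = FALSE)
  if (age < 0 || age > MAX_AGE) stop("age must be in 0-", MAX_AGE, call. = FALSE)

  if (query %in% c("er_neg", "er_pos")) {
    crv <- er_curve_for_genotype(tables, genotype, population_er, use_table1_brca2)
    p <- unname(crv[age + 1L])
    return(if (query == "er_neg") p else 1 - p)
  }
  if (query %in% c("tn", "non_tn")) {
    p <- tables$tn_given_er_negative[[genotype]]
    return(if (query == "tn") p else 1 - p)
  }
  if (is.null(scenario) || !scenario %in% CK_SCENARIOS) {
    stop("unknown or missing cytokeratin scenario: ",
         if (is.null(scenario)) "<none>" else scenario, call. = FALSE)
  }
  tab <- tables$ck_class_given_tn[[scenario]]
  if (!query %in% rownames(tab)) {
    stop(sprintf("unknown class '%s' for scenario '%s'", query, scenario),
         call. = FALSE)
  }
  tab[query, genotype]
}
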