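## Pedigree data model, CSV dialect, validation, example families and
## forward simulation.

PED_COLS <- c("id", "sex", "father", "mother", "birth_year",
              "observation_age", "breast_cancer_age", "ovarian_cancer_age",
              "er", "pr", "her2", "ck56", "ck14", "genetic_test")
MARKER_COLS <- c("er", "pr", "her2", "ck56", "ck14")
TEST_STATES <- c("none", "negative", "brca1_positive", "brca2_positive")

ped_fail <- function(msg) stop("pedigree: ", msg, call. = FALSE)

#' Construct a pedigree from a data frame
#'
#' Normalises and structurally validates a pedigree table (one row per
#' individual; columns `id`, `sex` (`F`/`M`), `father`, `mother`,
#' `birth_year`, `observation_age`, `breast_cancer_age`,
#' `ovarian_cancer_age`, marker columns `er`, `pr`, `her2`, `ck56`,
#' `ck14` (`positive`/`negative`/`untested`), `genetic_test` (`none`,
#' `negative`, `brca1_positive`, `brca2_positive`)). Missing columns are
#' filled with their neutral values. When only one parent of an
#' individual is listed, the missing spouse is auto-created as an
#' unobserved founder censored at age 0 (which conveys no information).
#' Structural problems (unknown parent ids, relationship cycles,
#' parent-sex inconsistencies) are errors; phenotype-level issues are
#' reported by [validate_pedigree()].
#'
#' @param df A data frame.
#' @return An object of class `bp_pedigree` (a data frame).
#' @export
as_pedigree <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) ped_fail("empty pedigree")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in PED_COLS) {
    if (!cc %in% names(df)) {
      df[[cc]] <- switch(cc,
        father = , mother = NA_character_,
        birth_year = NA_real_,
        observation_age = 0,
        breast_cancer_age = , ovarian_cancer_age = NA_real_,
        er = , pr = , her2 = , ck56 = , ck14 = "untested",
        genetic_test = "none",
        ped_fail(sprintf("missing required column '%s'", cc)))
    }
  }
  df <- df[PED_COLS]
  df$id <- as.character(df$id)
  if (anyNA(df$id) || any(df$id == "")) ped_fail("missing individual id")
  if (anyDuplicated(df$id)) ped_fail(sprintf("duplicate id '%s'", df$id[duplicated(df$id)][1]))
  df$sex <- toupper(as.character(df$sex))
  if (!all(df$sex %in% c("F", "M"))) ped_fail("sex must be 'F' or 'M'")
  for (cc in c("father", "mother")) {
    v <- as.character(df[[cc]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[cc]] <- v
  }
  for (cc in c("birth_year", "observation_age", "breast_cancer_age",
               "ovarian_cancer_age")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df$observation_age[is.na(df$observation_age)] <- 0
  for (cc in MARKER_COLS) {
    v <- as.character(df[[cc]])
    v[is.na(v) | v == ""] <- "untested"
    if (!all(v %in% c("positive", "negative", "untested"))) {
      ped_fail(sprintf("invalid %s marker state '%s'", cc,
                       setdiff(v, c("positive", "negative", "untested"))[1]))
    }
    df[[cc]] <- v
  }
  v <- as.character(df$genetic_test)
  v[is.na(v) | v == ""] <- "none"
  if (!all(v %in% TEST_STATES)) {
    ped_fail(sprintf("invalid genetic_test state '%s'", setdiff(v, TEST_STATES)[1]))
  }
  df$genetic_test <- v

  # auto-create the missing spouse of a single listed parent
  n0 <- nrow(df)
  for (i in seq_len(n0)) {
    has_f <- !is.na(df$father[i]); has_m <- !is.na(df$mother[i])
    if (has_f != has_m) {
      new_id <- make.unique(c(df$id, paste0(df$id[i], if (has_f) "_mother" else "_father")))[nrow(df) + 1L]
      spouse <- df[i, ]
      spouse$id <- new_id
      spouse$sex <- if (has_f) "F" else "M"
      spouse$father <- spouse$mother <- NA_character_
      spouse$birth_year <- df$birth_year[i]
      spouse$observation_age <- 0
      spouse$breast_cancer_age <- spouse$ovarian_cancer_age <- NA_real_
      spouse[MARKER_COLS] <- "untested"
      spouse$genetic_test <- "none"
      df <- rbind(df, spouse)
      if (has_f) df$mother[i] <- new_id else df$father[i] <- new_id
    }
  }

  for (cc in c("father", "mother")) {
    ref <- df[[cc]]
    bad <- !is.na(ref) & !ref %in% df$id
    if (any(bad)) ped_fail(sprintf("unknown parent id '%s'", ref[bad][1]))
  }
  fa <- match(df$father, df$id); mo <- match(df$mother, df$id)
  if (any(df$sex[fa[!is.na(fa)]] != "M")) ped_fail("father is not male")
  if (any(df$sex[mo[!is.na(mo)]] != "F")) ped_fail("mother is not female")

  # cycle check: parent relation must admit a topological order
  n <- nrow(df)
  remaining <- rep(TRUE, n)
  repeat {
    free <- which(remaining &
                    (is.na(fa) | !remaining[ifelse(is.na(fa), 1L, fa)]) &
                    (is.na(mo) | !remaining[ifelse(is.na(mo), 1L, mo)]))
    if (!length(free)) break
    remaining[free] <- FALSE
  }
  if (any(remaining)) {
    ped_fail(sprintf("relationship cycle involving '%s'", df$id[remaining][1]))
  }

  rownames(df) <- NULL
  class(df) <- c("bp_pedigree", "data.frame")
  df
}

#' Read a pedigree CSV file
#'
#' Reads the documented pedigree CSV dialect (UTF-8, one row per
#' individual, header as in [as_pedigree()]; empty cells mean
#' absent/untested) and returns a validated pedigree.
#'
#' @param path Path to a CSV file.
#' @return A `bp_pedigree` object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) ped_fail(paste0("file not found: ", path))
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) ped_fail("empty pedigree file")
  as_pedigree(df)
}

#' Write a pedigree CSV file
#'
#' Emits the same CSV dialect read by [read_pedigree()], so
#' read-write-read round-trips.
#'
#' @param ped A `bp_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "bp_pedigree"))
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "")
  invisible(path)
}

# ids of all ancestors of an individual (by row index)
ancestor_set <- function(ped, i) {
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  seen <- integer(0); stack <- c(fa[i], mo[i])
  while (length(stack)) {
    j <- stack[1]; stack <- stack[-1]
    if (is.na(j) || j %in% seen) next
    seen <- c(seen, j)
    stack <- c(stack, fa[j], mo[j])
  }
  seen
}

#' Validate a pedigree against the phenotype model
#'
#' Reports (without stopping) every way a structurally well-formed
#' pedigree violates the phenotype model: cancer ages beyond the
#' observation age, marker states without a breast cancer diagnosis,
#' internally inconsistent marker panels (e.g. cytokeratin status
#' without an established triple-negative tumour), male breast or
#' ovarian cancer (out of model), and consanguineous matings (loops,
#' which the exact likelihood does not support).
#'
#' @param ped A `bp_pedigree`.
#' @return A character vector of issues (empty when the pedigree is valid).
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "bp_pedigree"))
  issues <- character(0)
  add <- function(...) issues <<- c(issues, sprintf(...))
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    bc <- ped$breast_cancer_age[i]; oc <- ped$ovarian_cancer_age[i]
    obs <- ped$observation_age[i]
    if (!is.na(bc) && bc > obs) add("%s: breast cancer age %g exceeds observation age %g", id, bc, obs)
    if (!is.na(oc) && oc > obs) add("%s: ovarian cancer age %g exceeds observation age %g", id, oc, obs)
    if (!is.na(bc) && (bc < 0 || bc > MAX_AGE)) add("%s: breast cancer age %g outside model ages 0-%d", id, bc, MAX_AGE)
    if (!is.na(oc) && (oc < 0 || oc > MAX_AGE)) add("%s: ovarian cancer age %g outside model ages 0-%d", id, oc, MAX_AGE)
    panel_recorded <- any(unlist(ped[i, MARKER_COLS]) != "untested")
    if (panel_recorded && is.na(bc)) add("%s: tumour markers recorded without a breast cancer diagnosis", id)
    if (!is.na(bc)) {
      cls <- tryCatch(classify_panel(as.list(ped[i, MARKER_COLS])),
                      error = function(e) conditionMessage(e))
      if (is.character(cls)) add("%s: %s", id, cls)
    }
    if (ped$sex[i] == "M") {
      if (!is.na(bc)) add("%s: male breast cancer is outside the model", id)
      if (!is.na(oc)) add("%s: ovarian cancer recorded for a male", id)
    }
  }
  # consanguineous matings create loops
  mates <- unique(stats::na.omit(data.frame(f = ped$father, m = ped$mother,
                                            stringsAsFactors = FALSE)))
  for (k in seq_len(nrow(mates))) {
    fi <- match(mates$f[k], ped$id); mi <- match(mates$m[k], ped$id)
    shared <- intersect(c(fi, ancestor_set(ped, fi)), c(mi, ancestor_set(ped, mi)))
    if (length(shared)) add("inbreeding loop: mates %s and %s are related", mates$f[k], mates$m[k])
  }
  issues
}

#' Example pedigree builders
#'
#' Programmatic builders for the scenario families used throughout the
#' package: a single affected woman, the affected mother / affected
#' daughter family, and the variant where the proband's mutation search
#' was negative. Returned as a named list of functions; see
#' [ped_single_case()], [ped_mother_daughter()] and
#' [ped_proband_tested_negative()].
#'
#' @return A named list of builder functions.
#' @export
example_pedigrees <- function() {
  list(single_case = ped_single_case,
       mother_daughter = ped_mother_daughter,
       tested_negative = ped_proband_tested_negative)
}

#' Single affected woman
#'
#' One woman diagnosed with breast cancer at `diagnosis_age`, with no
#' informative relatives and follow-up ending at diagnosis.
#'
#' @param diagnosis_age Age at breast cancer diagnosis.
#' @param er,pr,her2,ck56,ck14 Marker panel states
#'   (`positive`/`negative`/`untested`).
#' @param birth_year Birth year (assigns the cohort).
#' @param genetic_test Genetic test result.
#' @return A `bp_pedigree` with the proband id `"proband"`.
#' @export
ped_single_case <- function(diagnosis_age, er = "untested", pr = "untested",
                            her2 = "untested", ck56 = "untested",
                            ck14 = "untested", birth_year = 1960,
                            genetic_test = "none") {
  as_pedigree(data.frame(
    id = "proband", sex = "F", father = NA, mother = NA,
    birth_year = birth_year, observation_age = diagnosis_age,
    breast_cancer_age = diagnosis_age, ovarian_cancer_age = NA,
    er = er, pr = pr, her2 = her2, ck56 = ck56, ck14 = ck14,
    genetic_test = genetic_test, stringsAsFactors = FALSE))
}

#' Affected mother and affected daughter
#'
#' The two-affected-women scenario family: a proband daughter diagnosed
#' at `proband_age` and her mother diagnosed at `mother_age`, linked by
#' an uninformative father; follow-up for each woman ends at her
#' diagnosis.
#'
#' @param proband_age,mother_age Ages at breast cancer diagnosis.
#' @param proband_er,mother_er ER status of each tumour
#'   (`positive`/`negative`/`untested`).
#' @param proband_test Proband's genetic test result.
#' @param birth_year_proband,birth_year_mother Birth years.
#' @return A `bp_pedigree`; the proband id is `"proband"`.
#' @export
ped_mother_daughter <- function(proband_age, mother_age,
                                proband_er = "untested",
                                mother_er = "untested",
                                proband_test = "none",
                                birth_year_proband = 1960,
                                birth_year_mother = 1935) {
  as_pedigree(data.frame(
    id = c("proband", "mother", "father"),
    sex = c("F", "F", "M"),
    father = c("father", NA, NA),
    mother = c("mother", NA, NA),
    birth_year = c(birth_year_proband, birth_year_mother, birth_year_mother),
    observation_age = c(proband_age, mother_age, 0),
    breast_cancer_age = c(proband_age, mother_age, NA),
    ovarian_cancer_age = NA,
    er = c(proband_er, mother_er, "untested"),
    pr = "untested", her2 = "untested", ck56 = "untested", ck14 = "untested",
    genetic_test = c(proband_test, "none", "none"),
    stringsAsFactors = FALSE))
}

#' Mother-daughter family with a mutation-negative proband
#'
#' As [ped_mother_daughter()], but the proband has been screened for
#' BRCA1/BRCA2 mutations with a negative result; the reduced test
#' sensitivities leave a residual carrier probability.
#'
#' @inheritParams ped_mother_daughter
#' @return A `bp_pedigree`.
#' @export
ped_proband_tested_negative <- function(proband_age, mother_age,
                                        proband_er = "untested",
                                        mother_er = "untested", ...) {
  ped_mother_daughter(proband_age, mother_age, proband_er, mother_er,
                      proband_test = "negative", ...)
}
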