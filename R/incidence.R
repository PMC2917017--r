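## Genotype- and subtype-specific incidence construction.
##
## Breast cancer hazard for an individual with major genotype g and
## polygene level l at age t:  lambda_{g,l}(t) = base_g(t) * exp(sd(t) z_l).
## base_g(t) is solved yearly so that (i) the polygene-average hazard among
## unaffected carriers equals the configured carrier incidence curve and
## (ii) the mixture over genotypes and polygenes among unaffected women
## equals the configured population incidence. Subtype end points are then
## carved out of the total hazard by age-specific proportions, with the
## noncarrier proportion closed so that the population mixture reproduces
## the population subtype incidence at every age.

ENDPOINT_CLASSES <- c("total", "er_pos", "er_neg", "er_neg_tn", "er_neg_nontn")

#' Constrain per-genotype total hazards to carrier and population curves
#'
#' Runs the yearly forward pass that (a) tracks the joint distribution of
#' (major genotype, polygene level) among women still alive and free of
#' breast and ovarian cancer, (b) rescales each carrier genotype's
#' baseline so the polygene-average hazard among its unaffected carriers
#' equals the configured carrier incidence, and (c) solves the noncarrier
#' average hazard from the population incidence mixture. Ovarian hazards
#' (no polygene) are closed against the population ovarian curve in the
#' same way.
#'
#' @param config A `bp_config` object.
#' @return An object of class `bp_hazards`: per cohort, the average
#'   (`lambda_bar`) and per-level baseline (`base`) breast hazards, the
#'   polygene multipliers (`mult`), ovarian hazards (`ovarian`) and the
#'   joint survivor distribution (`pi_joint`, ages x genotypes x levels).
#' @export
constrain_total_hazards <- function(config) {
  stopifnot(inherits(config, "bp_config"))
  pm <- polygenic_model(config$n_polygenic_loci, config$polygenic_sd)
  mult <- polygene_multiplier_matrix(pm)     # ages x levels
  nlev <- length(pm$levels)
  f <- config$carrier_frequency
  prior <- outer(c(1 - sum(f), f["BRCA1"], f["BRCA2"]), pm$founder_probabilities)
  dimnames(prior) <- list(GENOTYPES, NULL)
  breast_only <- identical(config$survival_weighting, "breast")

  cohorts <- list()
  for (lab in config$cohorts$label) {
    cur <- config$incidence[[lab]]
    lam_bar <- matrix(0, length(AGES), 3, dimnames = list(NULL, GENOTYPES))
    lam_bar[, "BRCA1"] <- cur$brca1_breast
    lam_bar[, "BRCA2"] <- cur$brca2_breast
    base <- matrix(0, length(AGES), 3, dimnames = list(NULL, GENOTYPES))
    ovarian <- matrix(0, length(AGES), 3, dimnames = list(NULL, GENOTYPES))
    ovarian[, "BRCA1"] <- cur$brca1_ovarian
    ovarian[, "BRCA2"] <- cur$brca2_ovarian
    pi_joint <- array(0, dim = c(length(AGES), 3, nlev),
                      dimnames = list(NULL, GENOTYPES, NULL))

    w <- prior
    for (i in seq_along(AGES)) {
      w <- w / sum(w)
      pi_joint[i, , ] <- w
      pig <- rowSums(w)

      # carrier baselines: survivor-weighted polygene average = target
      for (g in c("BRCA1", "BRCA2")) {
        tgt <- lam_bar[i, g]
        if (tgt > 0) {
          cond <- if (pig[g] > 0) w[g, ] / pig[g] else pm$founder_probabilities
          base[i, g] <- tgt / sum(cond * mult[i, ])
        }
      }

      # noncarrier average solved from the population mixture
      pop <- cur$population_breast[i]
      rest <- pig["BRCA1"] * lam_bar[i, "BRCA1"] + pig["BRCA2"] * lam_bar[i, "BRCA2"]
      nc_bar <- (pop - rest) / pig["noncarrier"]
      if (nc_bar < -1e-12) {
        stop(sprintf(
          "cohort %s, age %d: carrier breast cancer burden exceeds the population incidence",
          lab, AGES[i]), call. = FALSE)
      }
      nc_bar <- max(nc_bar, 0)
      lam_bar[i, "noncarrier"] <- nc_bar
      if (nc_bar > 0) {
        cond <- w["noncarrier", ] / pig["noncarrier"]
        base[i, "noncarrier"] <- nc_bar / sum(cond * mult[i, ])
      }

      # noncarrier ovarian hazard from the population ovarian curve
      ov_rest <- pig["BRCA1"] * ovarian[i, "BRCA1"] + pig["BRCA2"] * ovarian[i, "BRCA2"]
      ov_nc <- (cur$population_ovarian[i] - ov_rest) / pig["noncarrier"]
      if (ov_nc < -1e-12) {
        stop(sprintf(
          "cohort %s, age %d: carrier ovarian burden exceeds the population incidence",
          lab, AGES[i]), call. = FALSE)
      }
      ovarian[i, "noncarrier"] <- max(ov_nc, 0)

      lam <- base[i, ] %o% rep(1, nlev) * rep(1, 3) %o% mult[i, ]
      atr <- lam
      if (!breast_only) atr <- atr + ovarian[i, ]
      w <- w * exp(-atr)
      if (sum(w) <= 0) {
        stop(sprintf("cohort %s, age %d: degenerate hazards exhaust the population",
                     lab, AGES[i]), call. = FALSE)
      }
    }
    cohorts[[lab]] <- list(lambda_bar = lam_bar, base = base, mult = mult,
                           ovarian = ovarian, pi_joint = pi_joint,
                           population_breast = cur$population_breast,
                           population_ovarian = cur$population_ovarian)
  }
  structure(list(cohorts = cohorts, pm = pm, config = config),
            class = "bp_hazards")
}

#' Joint genotype/polygene distribution among unaffected women
#'
#' Forward recursion from the founder priors: each year the joint mass is
#' multiplied by the probability of remaining free of breast and ovarian
#' cancer under the per-state hazards, then renormalised. Returns the
#' conditional distribution among women alive and cancer-free at the
#' start of each year of age.
#'
#' @param config A `bp_config`.
#' @param hazards A `bp_hazards` from [constrain_total_hazards()].
#' @param cohort Cohort label; defaults to the first cohort.
#' @return A 3-d array (ages 0-79 x genotype x polygene level).
#' @export
genotype_distribution_among_unaffected <- function(config, hazards,
                                                   cohort = NULL) {
  stopifnot(inherits(hazards, "bp_hazards"))
  ch <- get_cohort(hazards, cohort)
  nlev <- ncol(ch$mult)
  f <- config$carrier_frequency
  w <- outer(c(1 - sum(f), f["BRCA1"], f["BRCA2"]), hazards$pm$founder_probabilities)
  dimnames(w) <- list(GENOTYPES, NULL)
  breast_only <- identical(config$survival_weighting, "breast")
  out <- array(0, dim = c(length(AGES), 3, nlev),
               dimnames = list(NULL, GENOTYPES, NULL))
  for (i in seq_along(AGES)) {
    s <- sum(w)
    if (s <= 0) stop("zero total mass in survivor recursion at age ", AGES[i],
                     call. = FALSE)
    w <- w / s
    out[i, , ] <- w
    lam <- ch$base[i, ] %o% rep(1, nlev) * rep(1, 3) %o% ch$mult[i, ]
    atr <- lam
    if (!breast_only) atr <- atr + ch$ovarian[i, ]
    w <- w * exp(-atr)
  }
  out
}

get_cohort <- function(hazards, cohort = NULL) {
  if (is.null(cohort)) cohort <- names(hazards$cohorts)[1]
  ch <- hazards$cohorts[[cohort]]
  if (is.null(ch)) stop("unknown cohort: ", cohort, call. = FALSE)
  ch
}

split_fail <- function(lab, age, endpoint, value) {
  stop(sprintf(
    "cohort %s, age %d, end point %s: implied noncarrier hazard share %.4g outside [0, 1]",
    lab, age, endpoint, value), call. = FALSE)
}

# Solve the noncarrier proportion at one layer of the subtype hierarchy
# from the population constraint: pop = sum_g caseweight_g * p_g.
close_layer <- function(p_pop, wcase, p_b1, p_b2, lab, endpoint) {
  p_nc <- (p_pop - wcase[, "BRCA1"] * p_b1 - wcase[, "BRCA2"] * p_b2) /
    wcase[, "noncarrier"]
  p_nc[wcase[, "noncarrier"] == 0] <- p_pop[wcase[, "noncarrier"] == 0]
  bad <- which(p_nc < -1e-12 | p_nc > 1 + 1e-12)
  if (length(bad)) split_fail(lab, AGES[bad[1]], endpoint, p_nc[bad[1]])
  pmin(pmax(p_nc, 0), 1)
}

#' Split constrained total hazards into tumour-subtype end points
#'
#' Carves the total breast cancer hazard of each (genotype, polygene
#' level) into the subtype end-point hierarchy ER+/ER-, TN/non-TN within
#' ER-, and cytokeratin classes within TN (per assay scenario). Carrier
#' proportions come from the marker tables (BRCA1 ER from the age-band
#' table; BRCA2 ER from the population curve; TN/CK age-constant);
#' noncarrier proportions are solved at each layer so that the
#' case-weighted population mixture reproduces the population subtype
#' incidence at every age. All layers inherit the genotype's polygene
#' scaling, so end-point hazards sum exactly to the total at every grid
#' point.
#'
#' @param hazards A `bp_hazards` from [constrain_total_hazards()].
#' @param tables A `marker_tables` object.
#' @param config The `bp_config` used to build `hazards`.
#' @return An object of class `bp_endpoints` (extends `bp_hazards` with
#'   per-cohort share curves `q` (ER-), `r` (TN | ER-) and `ck`
#'   (class | TN, per scenario)).
#' @export
split_endpoints <- function(hazards, tables, config) {
  stopifnot(inherits(hazards, "bp_hazards"), inherits(tables, "marker_tables"))
  q_pop <- config$population_er_negative
  for (lab in names(hazards$cohorts)) {
    ch <- hazards$cohorts[[lab]]
    pig <- apply(ch$pi_joint, c(1, 2), sum)     # ages x genotypes
    pop_model <- rowSums(pig * ch$lambda_bar)
    # distribution of genotype among incident cases at each age
    wcase <- pig * ch$lambda_bar / ifelse(pop_model > 0, pop_model, 1)
    nocase <- pop_model <= 0
    wcase[nocase, ] <- rep(c(1, 0, 0), each = sum(nocase))
    colnames(wcase) <- GENOTYPES

    q <- matrix(0, length(AGES), 3, dimnames = list(NULL, GENOTYPES))
    q[, "BRCA1"] <- er_curve_for_genotype(tables, "BRCA1", q_pop)
    q[, "BRCA2"] <- er_curve_for_genotype(tables, "BRCA2", q_pop,
                                          config$use_table1_brca2)
    q[, "noncarrier"] <- close_layer(q_pop, wcase, q[, "BRCA1"], q[, "BRCA2"],
                                     lab, "ER-negative")
    q[nocase, "noncarrier"] <- q_pop[nocase]

    # case weights among ER-negative cases
    vnum <- wcase * q
    vden <- rowSums(vnum)
    vcase <- vnum / ifelse(vden > 0, vden, 1)
    vcase[vden <= 0, ] <- rep(c(1, 0, 0), each = sum(vden <= 0))

    r_tab <- tables$tn_given_er_negative
    r <- matrix(0, length(AGES), 3, dimnames = list(NULL, GENOTYPES))
    r[, "BRCA1"] <- r_tab[["BRCA1"]]
    r[, "BRCA2"] <- r_tab[["BRCA2"]]
    r[, "noncarrier"] <- close_layer(rep(r_tab[["noncarrier"]], length(AGES)),
                                     vcase, r[, "BRCA1"], r[, "BRCA2"],
                                     lab, "TN")

    unum <- vcase * r
    uden <- rowSums(unum)
    ucase <- unum / ifelse(uden > 0, uden, 1)
    ucase[uden <= 0, ] <- rep(c(1, 0, 0), each = sum(uden <= 0))

    ck <- list()
    for (sc in CK_SCENARIOS) {
      tab <- tables$ck_class_given_tn[[sc]]
      cls <- rownames(tab)
      arr <- array(0, dim = c(length(AGES), length(cls), 3),
                   dimnames = list(NULL, cls, GENOTYPES))
      for (cl in cls) {
        arr[, cl, "BRCA1"] <- tab[cl, "BRCA1"]
        arr[, cl, "BRCA2"] <- tab[cl, "BRCA2"]
        arr[, cl, "noncarrier"] <- close_layer(
          rep(tab[cl, "noncarrier"], length(AGES)), ucase,
          arr[, cl, "BRCA1"], arr[, cl, "BRCA2"], lab,
          sprintf("CK %s/%s", sc, cl))
      }
      # renormalise the tiny closure rounding so classes partition exactly
      tot <- apply(arr[, , "noncarrier", drop = FALSE], 1, sum)
      ok <- tot > 0
      arr[ok, , "noncarrier"] <- arr[ok, , "noncarrier"] / tot[ok]
      ck[[sc]] <- arr
    }

    hazards$cohorts[[lab]]$q <- q
    hazards$cohorts[[lab]]$r <- r
    hazards$cohorts[[lab]]$ck <- ck
  }
  hazards$tables <- tables
  class(hazards) <- c("bp_endpoints", "bp_hazards")
  hazards
}

# Share of the total hazard belonging to an end-point class, as a vector
# over ages, for one genotype.
endpoint_share <- function(endpoints, genotype, class,
                           scenario = NULL, cohort = NULL) {
  ch <- get_cohort(endpoints, cohort)
  if (class == "total") return(rep(1, length(AGES)))
  q <- ch$q[, genotype]
  if (class == "er_pos") return(1 - q)
  if (class == "er_neg") return(q)
  r <- ch$r[, genotype]
  if (class == "er_neg_tn") return(q * r)
  if (class == "er_neg_nontn") return(q * (1 - r))
  if (!class %in% c("both_pos", "one_pos", "neither", "pos", "neg")) {
    stop("unknown end point class: ", class, call. = FALSE)
  }
  if (is.null(scenario)) stop("cytokeratin class requires a scenario", call. = FALSE)
  arr <- ch$ck[[scenario]]
  if (is.null(arr) || !class %in% dimnames(arr)[[2]]) {
    stop(sprintf("unknown end point class '%s' (scenario %s)", class,
                 if (is.null(scenario)) "<none>" else scenario), call. = FALSE)
  }
  q * r * arr[, class, genotype]
}

# Classify a marker panel into the finest observed end-point class.
# panel: named character vector/list with er, pr, her2, ck56, ck14 in
# {"positive","negative","untested"}.
classify_panel <- function(panel) {
  p <- lapply(c(er = "er", pr = "pr", her2 = "her2",
                ck56 = "ck56", ck14 = "ck14"),
              function(nm) {
                v <- panel[[nm]]
                if (is.null(v) || is.na(v)) v <- "untested"
                if (!v %in% c("positive", "negative", "untested")) {
                  stop(sprintf("invalid marker state '%s' for %s", v, nm),
                       call. = FALSE)
                }
                v
              })
  ck_recorded <- p$ck56 != "untested" || p$ck14 != "untested"

  if (p$er == "untested") {
    if (ck_recorded) stop("cytokeratin status recorded without an established TN tumour",
                          call. = FALSE)
    return(list(class = "total", scenario = NULL))
  }
  if (p$er == "positive") {
    if (ck_recorded) stop("cytokeratin status recorded on a non-TN tumour",
                          call. = FALSE)
    return(list(class = "er_pos", scenario = NULL))
  }
  # ER-negative
  tn <- if (p$pr == "positive" || p$her2 == "positive") "no"
        else if (p$pr == "negative" && p$her2 == "negative") "yes"
        else "unknown"
  if (tn == "no") {
    if (ck_recorded) stop("cytokeratin status recorded on a non-TN tumour",
                          call. = FALSE)
    return(list(class = "er_neg_nontn", scenario = NULL))
  }
  if (tn == "unknown") {
    if (ck_recorded) stop("cytokeratin status recorded without an established TN tumour",
                          call. = FALSE)
    return(list(class = "er_neg", scenario = NULL))
  }
  # TN established
  if (p$ck56 != "untested" && p$ck14 != "untested") {
    npos <- (p$ck56 == "positive") + (p$ck14 == "positive")
    cls <- c("neither", "one_pos", "both_pos")[npos + 1L]
    return(list(class = cls, scenario = "both_ck"))
  }
  if (p$ck56 != "untested") {
    return(list(class = if (p$ck56 == "positive") "pos" else "neg",
                scenario = "ck56_only"))
  }
  if (p$ck14 != "untested") {
    return(list(class = if (p$ck14 == "positive") "pos" else "neg",
                scenario = "ck14_only"))
  }
  list(class = "er_neg_tn", scenario = NULL)
}

#' Hazard of the finest end point observed on a marker panel
#'
#' Returns the age-specific hazard, for a given genotype and polygene
#' level, of developing a breast tumour with the observed marker panel,
#' marginalising every untested deeper layer: with no markers tested this
#' is the total breast cancer hazard; with only ER- observed it is the
#' ER-negative hazard (sum of all ER-negative sub-end points); and so on
#' down to cytokeratin classes under the relevant assay scenario.
#'
#' @param endpoints A `bp_endpoints` object.
#' @param genotype One of `"noncarrier"`, `"BRCA1"`, `"BRCA2"`.
#' @param level Polygene level (0..2N).
#' @param age Age in years (0-79).
#' @param panel Named list/vector with entries `er`, `pr`, `her2`,
#'   `ck56`, `ck14`, each `"positive"`, `"negative"` or `"untested"`.
#' @param cohort Cohort label (default: first).
#' @return A hazard (events per person-year).
#' @export
endpoint_hazard_for_panel <- function(endpoints, genotype, level, age, panel,
                                      cohort = NULL) {
  stopifnot(inherits(endpoints, "bp_endpoints"))
  cl <- classify_panel(panel)
  ch <- get_cohort(endpoints, cohort)
  i <- age + 1L
  lam <- ch$base[i, genotype] * ch$mult[i, level + 1L]
  share <- endpoint_share(endpoints, genotype, cl$class, cl$scenario, cohort)
  unname(lam * share[i])
}

#' Cumulative risk of a subtype end point
#'
#' Polygene-averaged cause-specific cumulative incidence of the given end
#' point by `to_age` for a random individual of the given genotype:
#' `E_level[ sum_t S_level(t) (1 - exp(-lambda_level(t))) share(t) ]`,
#' where `S` is survival under the total breast cancer hazard. Competing
#' non-breast mortality is not modelled, and sub-class risks are
#' first-cancer cause-specific, so ER- and ER+ risks sum exactly to the
#' total breast cancer risk.
#'
#' @param endpoints A `bp_endpoints` object.
#' @param genotype One of `"noncarrier"`, `"BRCA1"`, `"BRCA2"`.
#' @param class End-point class: `"total"`, `"er_pos"`, `"er_neg"`,
#'   `"er_neg_tn"`, `"er_neg_nontn"`, or a CK class with `scenario`.
#' @param to_age Risk horizon in years (0-80): risk of an event before
#'   this age.
#' @param cohort Cohort label (default: first).
#' @param scenario CK assay scenario for CK classes.
#' @return A probability.
#' @export
cumulative_risk <- function(endpoints, genotype, class, to_age,
                            cohort = NULL, scenario = NULL) {
  stopifnot(inherits(endpoints, "bp_endpoints"))
  if (to_age < 0 || to_age > MAX_AGE + 1L) {
    stop("to_age must be in 0-", MAX_AGE + 1L, call. = FALSE)
  }
  if (to_age == 0) return(0)
  ch <- get_cohort(endpoints, cohort)
  share <- endpoint_share(endpoints, genotype, class, scenario, cohort)
  pl <- endpoints$pm$founder_probabilities
  idx <- seq_len(to_age)
  risk <- 0
  for (l in seq_along(pl)) {
    lam <- ch$base[idx, genotype] * ch$mult[idx, l]
    surv <- exp(-c(0, cumsum(lam)[-length(lam)]))
    risk <- risk + pl[l] * sum(surv * (1 - exp(-lam)) * share[idx])
  }
  risk
}
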