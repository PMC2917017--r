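test_that("an empty phenotype history contributes factor 1 in every state", {
  m <- toy_model(2)
  newborn <- as.list(ped_single_case(30)[1, ])
  newborn$breast_cancer_age <- NA; newborn$observation_age <- 0
  for (g in c("noncarrier", "BRCA1", "BRCA2")) {
    for (l in c(0, 2, 4)) {
      expect_equal(individual_penetrance(newborn, list(major = g, polygene_level = l),
                                         m$endpoints, m$config), 1)
    }
  }
})

test_that("affected-woman penetrance matches the closed-form product", {
  m <- toy_model(1)
  ch <- m$endpoints$cohorts$all
  ind <- as.list(ped_single_case(45, er = "negative", birth_year = 1950)[1, ])
  for (g in c("noncarrier", "BRCA1")) {
    for (l in 0:2) {
      surv <- exp(-sum(ch$base[1:45, g] * ch$mult[1:45, l + 1]) -
                    sum(ch$ovarian[1:45, g]))
      hazard <- unname(ch$base[46, g] * ch$mult[46, l + 1] * ch$q[46, g])
      expect_equal(
        individual_penetrance(ind, list(major = g, polygene_level = l),
                              m$endpoints, m$config),
        surv * hazard)
    }
  }
})

test_that("a negative mutation test leaves the one-minus-sensitivity factor", {
  m <- toy_model(2)   # default sensitivities 0.70 / 0.80
  ind <- list(id = "x", sex = "M", birth_year = 1950, observation_age = 0,
              breast_cancer_age = NA, ovarian_cancer_age = NA,
              er = "untested", pr = "untested", her2 = "untested",
              ck56 = "untested", ck14 = "untested", genetic_test = "negative")
  expect_equal(individual_penetrance(ind, list(major = "BRCA1", polygene_level = 2),
                                     m$endpoints, m$config), 0.30)
  expect_equal(individual_penetrance(ind, list(major = "BRCA2", polygene_level = 2),
                                     m$endpoints, m$config), 0.20)
  expect_equal(individual_penetrance(ind, list(major = "noncarrier", polygene_level = 2),
                                     m$endpoints, m$config), 1)
})

test_that("a pedigree with no phenotype information has likelihood 1", {
  m <- toy_model(2)
  ped <- as_pedigree(data.frame(id = "f0", sex = "F", father = NA, mother = NA,
                                birth_year = 1950, observation_age = 0))
  expect_equal(pedigree_loglikelihood(ped, m$endpoints, m$config), 0)
})

test_that("peeling equals exhaustive enumeration on small pedigrees", {
  set.seed(101)
  m <- toy_model(2)
  done <- 0
  while (done < 10) {
    ped <- random_pedigree(5)
    if (nrow(ped) > 4) next    # keep the exhaustive oracle fast here
    done <- done + 1
    a <- pedigree_loglikelihood(ped, m$endpoints, m$config)
    b <- bf_loglik(ped, m$endpoints, m$config)
    expect_lt(abs(a - b), 1e-10)
    tg <- sample(ped$id, 1)
    pa <- carrier_probabilities(ped, tg, m$endpoints, m$config)
    pb <- bf_posterior(ped, tg, m$endpoints, m$config)
    expect_lt(max(abs(unclass(pa) - pb)), 1e-10)
  }
})

test_that("the likelihood is invariant under row reordering", {
  set.seed(55)
  m <- toy_model(2)
  ped <- random_pedigree(5)
  ll <- pedigree_loglikelihood(ped, m$endpoints, m$config)
  for (k in 1:3) {
    perm <- as_pedigree(as.data.frame(ped)[sample(nrow(ped)), , drop = FALSE])
    expect_equal(pedigree_loglikelihood(perm, m$endpoints, m$config), ll)
  }
})

test_that("posteriors are normalised and honour perfect test specificity", {
  m <- toy_model(2)
  p <- carrier_probabilities(ped_mother_daughter(40, 60), "proband",
                             m$endpoints, m$config)
  expect_true(all(unclass(p) >= 0))
  expect_lt(abs(sum(unclass(p)) - 1), 1e-12)
  pedpos <- ped_single_case(40, genetic_test = "brca1_positive")
  ppos <- carrier_probabilities(pedpos, "proband", m$endpoints, m$config)
  expect_equal(unname(ppos[["BRCA1"]]), 1)
  expect_error(carrier_probabilities(pedpos, "nobody", m$endpoints, m$config),
               "unknown target")
})

test_that("inbreeding loops are rejected as unsupported structures", {
  m <- toy_model(2)
  df <- data.frame(
    id = c("gf", "gm", "s1", "s2", "k"), sex = c("M", "F", "M", "F", "F"),
    father = c(NA, NA, "gf", "gf", "s1"), mother = c(NA, NA, "gm", "gm", "s2"),
    birth_year = 1950, observation_age = c(0, 0, 0, 0, 20),
    stringsAsFactors = FALSE)
  expect_error(pedigree_loglikelihood(as_pedigree(df), m$endpoints, m$config),
               "unsupported pedigree structure")
})

test_that("informative markers shift the BRCA1 posterior in the expected direction", {
  m <- default_model()
  for (age in c(30, 50, 70)) {
    base <- predict(m, ped_single_case(age))[["BRCA1"]]
    up <- predict(m, ped_single_case(age, er = "negative"))[["BRCA1"]]
    dn <- predict(m, ped_single_case(age, er = "positive"))[["BRCA1"]]
    expect_gt(up, base)
    expect_lt(dn, base)
  }
})

test_that("untested panels reproduce the base no-pathology model exactly", {
  m <- toy_model(2)
  hz <- constrain_total_hazards(m$config)
  for (ped in list(ped_single_case(42), ped_mother_daughter(35, 55))) {
    a <- carrier_probabilities(ped, "proband", m$endpoints, m$config)
    b <- carrier_probabilities(ped, "proband", hz, m$config)
    expect_equal(unclass(a), unclass(b), tolerance = 0)
  }
  # but a marker panel needs the end-point hazards
  expect_error(
    carrier_probabilities(ped_single_case(42, er = "negative"), "proband",
                          hz, m$config),
    "no end-point hazards")
})

test_that("marker-marginalised posteriors reproduce the untested posterior", {
  m <- toy_model(2)
  pu <- ped_mother_daughter(40, 50)
  pn <- ped_mother_daughter(40, 50, proband_er = "negative")
  pp <- ped_mother_daughter(40, 50, proband_er = "positive")
  lln <- pedigree_loglikelihood(pn, m$endpoints, m$config)
  llp <- pedigree_loglikelihood(pp, m$endpoints, m$config)
  llu <- pedigree_loglikelihood(pu, m$endpoints, m$config)
  # ER-negative and ER-positive likelihoods partition the untested one
  expect_lt(abs(exp(lln) + exp(llp) - exp(llu)) / exp(llu), 1e-12)
  wn <- exp(lln - llu)
  post_u <- unclass(carrier_probabilities(pu, "proband", m$endpoints, m$config))
  post_n <- unclass(carrier_probabilities(pn, "proband", m$endpoints, m$config))
  post_p <- unclass(carrier_probabilities(pp, "proband", m$endpoints, m$config))
  expect_lt(max(abs(wn * post_n + (1 - wn) * post_p - post_u)), 1e-10)
})
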