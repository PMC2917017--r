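test_that("a single listed parent gets an auto-created uninformative spouse", {
  df <- data.frame(id = c("m", "d"), sex = c("F", "F"),
                   father = c(NA, NA), mother = c(NA, "m"),
                   birth_year = c(1940, 1965), observation_age = c(60, 40),
                   stringsAsFactors = FALSE)
  ped <- as_pedigree(df)
  expect_equal(nrow(ped), 3)
  added <- setdiff(ped$id, c("m", "d"))
  expect_equal(ped$sex[ped$id == added], "M")
  expect_equal(ped$observation_age[ped$id == added], 0)
  expect_equal(ped$father[ped$id == "d"], added)
  expect_length(validate_pedigree(ped), 0)
})

test_that("structural defects are rejected with clear errors", {
  base <- data.frame(id = c("a", "b"), sex = c("F", "F"),
                     father = NA, mother = c("b", "a"),
                     birth_year = 1950, observation_age = 40,
                     stringsAsFactors = FALSE)
  expect_error(as_pedigree(base), "cycle")
  expect_error(as_pedigree(data.frame(id = "x", sex = "F", father = NA,
                                      mother = "ghost", observation_age = 10)),
               "unknown parent")
  expect_error(as_pedigree(data.frame()), "empty")
  expect_error(as_pedigree(data.frame(id = c("a", "a"), sex = "F")), "duplicate")
  # parent sex inconsistency
  expect_error(as_pedigree(data.frame(
    id = c("p", "f", "m"), sex = c("F", "F", "F"),
    father = c("f", NA, NA), mother = c("m", NA, NA), observation_age = 1)),
    "father is not male")
})

test_that("empty or missing pedigree files are errors", {
  f <- tempfile(fileext = ".csv")
  writeLines("id,sex,father,mother", f)
  expect_error(read_pedigree(f), "empty")
  expect_error(read_pedigree(tempfile()), "not found")
})

test_that("pedigree CSV round-trips through write and read", {
  ped <- ped_mother_daughter(40, 50, mother_er = "negative")
  f <- tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  ped2 <- read_pedigree(f)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
  write_pedigree(ped2, f)
  expect_equal(as.data.frame(read_pedigree(f)), as.data.frame(ped2))
})

test_that("validation reports phenotype-model violations without stopping", {
  ped <- ped_single_case(45, er = "negative", ck56 = "positive")
  expect_match(validate_pedigree(ped), "established TN", all = FALSE)

  df <- as.data.frame(ped_mother_daughter(40, 50))
  df$breast_cancer_age[df$id == "father"] <- 30
  df$observation_age[df$id == "father"] <- 30
  issues <- validate_pedigree(as_pedigree(df))
  expect_match(issues, "male breast cancer", all = FALSE)

  df2 <- as.data.frame(ped_single_case(45))
  df2$breast_cancer_age <- 50
  expect_match(validate_pedigree(as_pedigree(df2)), "exceeds observation age",
               all = FALSE)

  # consanguineous mating is flagged as a loop
  df3 <- data.frame(
    id = c("gf", "gm", "s1", "s2", "k"), sex = c("M", "F", "M", "F", "F"),
    father = c(NA, NA, "gf", "gf", "s1"), mother = c(NA, NA, "gm", "gm", "s2"),
    birth_year = 1950, observation_age = c(0, 0, 0, 0, 20),
    stringsAsFactors = FALSE)
  expect_match(validate_pedigree(as_pedigree(df3)), "inbreeding loop", all = FALSE)

  expect_length(validate_pedigree(ped_mother_daughter(40, 50)), 0)
})

test_that("example builders produce the documented scenario families", {
  p1 <- ped_single_case(30)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$breast_cancer_age, 30)
  expect_true(all(unlist(p1[brcapath:::MARKER_COLS]) == "untested"))

  p2 <- ped_mother_daughter(40, 50, mother_er = "negative")
  expect_setequal(p2$id, c("proband", "mother", "father"))
  expect_equal(sum(!is.na(p2$breast_cancer_age)), 2)
  expect_equal(p2$er[p2$id == "mother"], "negative")
  expect_equal(p2$observation_age[p2$id == "father"], 0)

  p3 <- ped_proband_tested_negative(40, 50)
  expect_equal(p3$genetic_test[p3$id == "proband"], "negative")

  builders <- example_pedigrees()
  expect_named(builders, c("single_case", "mother_daughter", "tested_negative"))
  expect_equal(as.data.frame(builders$single_case(35)),
               as.data.frame(ped_single_case(35)))
})

test_that("simulation is reproducible and respects degenerate hazards", {
  m <- toy_model(2)
  skel <- data.frame(id = c("f", "mo", "d1", "d2"), sex = c("M", "F", "F", "F"),
                     father = c(NA, NA, "f", "f"), mother = c(NA, NA, "mo", "mo"),
                     birth_year = c(1940, 1945, 1970, 1972),
                     observation_age = c(70, 70, 50, 50))
  s1 <- simulate_pedigree(skel, m, seed = 11)
  s2 <- simulate_pedigree(skel, m, seed = 11)
  expect_equal(s1, s2)
  s3 <- simulate_pedigree(skel, m, seed = 12)
  expect_s3_class(s3, "bp_pedigree")
  expect_length(validate_pedigree(s1), 0)

  # zero hazards -> nobody affected
  lst <- list(
    carrier_frequency = list(brca1 = 0.2, brca2 = 0.1),
    n_polygenic_loci = 2,
    cohorts = list(list(label = "all", years = c(1900, 2100))),
    incidence = list(all = lapply(stats::setNames(nm = brcapath:::INCIDENCE_CURVES),
                                  function(nm) list(list(age = 0, rate = 0)))),
    population_er_negative = list(list(age = 0, prop = 0.4))
  )
  m0 <- brca_risk_model(build_model_config(lst))
  s0 <- simulate_pedigree(skel, m0, seed = 5)
  expect_true(all(is.na(s0$breast_cancer_age)))
  expect_true(all(is.na(s0$ovarian_cancer_age)))

  expect_error(simulate_pedigree(skel[, 1:3], m, seed = 1), "skeleton")
})

test_that("simulated transmission respects Mendelian carrier inheritance", {
  m <- toy_model(2)
  skel <- data.frame(id = c("f", "mo", "d"), sex = c("M", "F", "F"),
                     father = c(NA, NA, "f"), mother = c(NA, NA, "mo"),
                     birth_year = 1950, observation_age = c(0, 0, 0))
  # with both parents forced noncarriers, every child is a noncarrier
  for (seed in 1:5) {
    sim <- simulate_pedigree(skel, m, seed = seed,
                             founder_status = c(f = "noncarrier", mo = "noncarrier"))
    expect_equal(unname(attr(sim, "true_status")["d"]), "noncarrier")
  }
  # forced carrier parents transmit with frequency ~ 1/2 (heterozygotes)
  hits <- vapply(1:200, function(seed) {
    sim <- simulate_pedigree(skel, m, seed = 1000 + seed,
                             founder_status = c(f = "BRCA1", mo = "noncarrier"))
    attr(sim, "true_status")[["d"]] == "BRCA1"
  }, logical(1))
  expect_gt(mean(hits), 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(mean(hits), 0.5 + 3 * sqrt(0.25 / 200))
})
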