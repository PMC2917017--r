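# Fixtures built in code: small configurations, toy models and a random
# pedigree generator used across the suite.

# Compact configuration with simple curves; fast to constrain.
toy_config <- function(n_loci = 2, sd = 0.8, f1 = 0.002, f2 = 0.003,
                       rr1 = 20, rr2 = 10, sens = NULL,
                       survival_weighting = "breast+ovarian") {
  pop <- list(list(age = 0, rate = 0), list(age = 20, rate = 10),
              list(age = 30, rate = 50), list(age = 40, rate = 150),
              list(age = 50, rate = 220), list(age = 60, rate = 280),
              list(age = 70, rate = 320))
  scale_tab <- function(tab, k) lapply(tab, function(x) list(age = x$age, rate = x$rate * k))
  ov <- list(list(age = 0, rate = 0), list(age = 30, rate = 10),
             list(age = 50, rate = 30), list(age = 70, rate = 50))
  lst <- list(
    carrier_frequency = list(brca1 = f1, brca2 = f2),
    n_polygenic_loci = n_loci,
    polygenic_sd = list(list(age = 0, sd = sd)),
    cohorts = list(list(label = "all", years = c(1900, 2100))),
    incidence = list(all = list(
      population_breast = pop,
      population_ovarian = ov,
      brca1_breast = scale_tab(pop, rr1),
      brca2_breast = scale_tab(pop, rr2),
      brca1_ovarian = scale_tab(ov, 15),
      brca2_ovarian = scale_tab(ov, 4))),
    population_er_negative = list(list(age = 0, prop = 0.50),
                                  list(age = 40, prop = 0.40),
                                  list(age = 60, prop = 0.30))
  )
  if (!is.null(sens)) lst$test_sensitivity <- list(brca1 = sens[1], brca2 = sens[2])
  lst$survival_weighting <- survival_weighting
  build_model_config(lst)
}

toy_model <- local({
  cache <- list()
  function(n_loci = 2, ...) {
    key <- paste(n_loci, ..., sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- brca_risk_model(toy_config(n_loci = n_loci, ...))
    }
    cache[[key]]
  }
})

default_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- brca_risk_model(default_config())
    cache
  }
})

# ---- random pedigrees for the oracle checks --------------------------

random_panel <- function() {
  er <- sample(c("untested", "negative", "positive"), 1, prob = c(0.4, 0.35, 0.25))
  pan <- c(er = er, pr = "untested", her2 = "untested",
           ck56 = "untested", ck14 = "untested")
  if (er == "negative" && stats::runif(1) < 0.6) {
    if (stats::runif(1) < 0.7) {
      pan["pr"] <- pan["her2"] <- "negative"   # TN
      u <- stats::runif(1)
      if (u < 0.3) {
        pan["ck56"] <- sample(c("positive", "negative"), 1)
        pan["ck14"] <- sample(c("positive", "negative"), 1)
      } else if (u < 0.5) {
        pan["ck56"] <- sample(c("positive", "negative"), 1)
      } else if (u < 0.7) {
        pan["ck14"] <- sample(c("positive", "negative"), 1)
      }
    } else {
      pan["pr"] <- "positive"
    }
  }
  pan
}

random_phenotype_row <- function(id, sex, father = NA, mother = NA) {
  obs <- sample(25:75, 1)
  bc <- oc <- NA_real_
  pan <- c(er = "untested", pr = "untested", her2 = "untested",
           ck56 = "untested", ck14 = "untested")
  gt <- "none"
  if (sex == "F") {
    if (stats::runif(1) < 0.45) {
      bc <- sample(25:obs, 1)
      pan <- random_panel()
    }
    if (is.na(bc) && obs >= 30 && stats::runif(1) < 0.15) oc <- sample(30:obs, 1)
  }
  if (stats::runif(1) < 0.15) {
    gt <- sample(c("negative", "brca1_positive", "brca2_positive"), 1,
                 prob = c(0.6, 0.25, 0.15))
  }
  obs <- min(obs, bc, oc, na.rm = TRUE)
  data.frame(id = id, sex = sex, father = father, mother = mother,
             birth_year = 1950, observation_age = obs,
             breast_cancer_age = bc, ovarian_cancer_age = oc,
             er = pan["er"], pr = pan["pr"], her2 = pan["her2"],
             ck56 = pan["ck56"], ck14 = pan["ck14"],
             genetic_test = gt, stringsAsFactors = FALSE)
}

# Loop-free three-generation family with exactly six members.
random_pedigree6 <- function() {
  rows <- list(random_phenotype_row("fa", "M"),
               random_phenotype_row("mo", "F", "gf", "gm"),
               random_phenotype_row("gf", "M"),
               random_phenotype_row("gm", "F"),
               random_phenotype_row("c1", sample(c("F", "M"), 1), "fa", "mo"),
               random_phenotype_row("c2", sample(c("F", "M"), 1), "fa", "mo"))
  as_pedigree(do.call(rbind, rows))
}

# Loop-free random family of at most max_members members.
random_pedigree <- function(max_members = 6) {
  rows <- list(random_phenotype_row("fa", "M"), random_phenotype_row("mo", "F"))
  n_children <- sample(1:3, 1)
  for (k in seq_len(n_children)) {
    rows[[length(rows) + 1L]] <-
      random_phenotype_row(paste0("c", k), sample(c("F", "M"), 1), "fa", "mo")
  }
  if (length(rows) + 2 <= max_members && stats::runif(1) < 0.4) {
    rows[[length(rows) + 1L]] <- random_phenotype_row("gf", "M")
    rows[[length(rows) + 1L]] <- random_phenotype_row("gm", "F")
    rows[[2]]$father <- "gf"; rows[[2]]$mother <- "gm"
  }
  as_pedigree(do.call(rbind, rows))
}
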