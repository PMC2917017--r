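test_that("degenerate mixture: no carriers, no polygene -> noncarrier equals population", {
  cfg <- toy_config(f1 = 0, f2 = 0, sd = 0)
  hz <- constrain_total_hazards(cfg)
  ch <- hz$cohorts$all
  expect_equal(ch$lambda_bar[, "noncarrier"], cfg$incidence$all$population_breast)
  expect_equal(ch$base[, "noncarrier"], cfg$incidence$all$population_breast)
  expect_equal(ch$ovarian[, "noncarrier"], cfg$incidence$all$population_ovarian)
})

test_that("survivor-weighted mixtures reproduce the configured curves", {
  for (m in list(toy_model(2), default_model())) {
    cfg <- m$config
    lab <- names(m$endpoints$cohorts)[1]
    ch <- m$endpoints$cohorts[[lab]]
    pig <- apply(ch$pi_joint, c(1, 2), sum)
    pop <- cfg$incidence[[lab]]$population_breast
    mix <- rowSums(pig * ch$lambda_bar)
    nz <- pop > 0
    expect_lt(max(abs(mix[nz] - pop[nz]) / pop[nz]), 1e-8)
    # carrier polygene averages equal the configured carrier curves
    for (g in c("BRCA1", "BRCA2")) {
      tgt <- cfg$incidence[[lab]][[paste0(tolower(g), "_breast")]]
      cond <- ch$pi_joint[, g, ] / ifelse(pig[, g] > 0, pig[, g], 1)
      avg <- rowSums(cond * (ch$base[, g] * ch$mult))
      nzg <- tgt > 0
      expect_lt(max(abs(avg[nzg] - tgt[nzg]) / tgt[nzg]), 1e-8)
    }
    # ER-negative population incidence is reproduced as well
    wcase <- pig * ch$lambda_bar
    er_mix <- rowSums(wcase * ch$q)
    er_tgt <- pop * cfg$population_er_negative
    expect_lt(max(abs(er_mix[nz] - er_tgt[nz]) / pmax(er_tgt[nz], 1e-300)), 1e-8)
  }
})

test_that("excess carrier burden is a configuration error", {
  cfg <- toy_config(f1 = 0.5, f2 = 0.001, rr1 = 10)
  expect_error(constrain_total_hazards(cfg), "exceeds the population incidence")
})

test_that("end-point shares partition the total hazard at machine precision", {
  ep <- default_model()$endpoints
  for (g in c("noncarrier", "BRCA1", "BRCA2")) {
    q <- brcapath:::endpoint_share(ep, g, "er_neg")
    expect_equal(brcapath:::endpoint_share(ep, g, "er_pos") + q,
                 rep(1, 80))
    tn <- brcapath:::endpoint_share(ep, g, "er_neg_tn")
    expect_equal(tn + brcapath:::endpoint_share(ep, g, "er_neg_nontn"), q)
    for (sc in c("both_ck", "ck56_only", "ck14_only")) {
      cls <- dimnames(ep$cohorts[[1]]$ck[[sc]])[[2]]
      tot <- Reduce(`+`, lapply(cls, function(cl) {
        brcapath:::endpoint_share(ep, g, cl, scenario = sc)
      }))
      expect_equal(tot, tn, tolerance = 1e-12)
    }
  }
  # carrier shares at age 45 reproduce the table proportions
  expect_equal(unname(ep$cohorts[[1]]$q[46, "BRCA1"]), 0.86)
  expect_equal(unname(ep$cohorts[[1]]$r[46, "BRCA1"]), 0.90)
})

test_that("panel hazards marginalise untested layers correctly", {
  m <- default_model()
  ep <- m$endpoints
  ch <- ep$cohorts[[1]]
  untested <- c(er = "untested", pr = "untested", her2 = "untested",
                ck56 = "untested", ck14 = "untested")
  lam_tot <- unname(ch$base[46, "BRCA1"] * ch$mult[46, 3])
  expect_equal(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, untested), lam_tot)
  ern <- untested; ern["er"] <- "negative"
  expect_equal(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, ern),
               lam_tot * 0.86)
  tnp <- ern; tnp["pr"] <- tnp["her2"] <- "negative"; tnp["ck56"] <- "positive"
  expect_equal(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, tnp),
               lam_tot * 0.86 * 0.90 * 0.64)
  # the two sub-end points of a layer sum to the layer hazard
  tn_only <- ern; tn_only["pr"] <- tn_only["her2"] <- "negative"
  tnn <- tnp; tnn["ck56"] <- "negative"
  expect_equal(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, tnp) +
                 endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, tnn),
               endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, tn_only))
  bad <- untested; bad["er"] <- "positive"; bad["ck56"] <- "positive"
  expect_error(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, bad), "non-TN")
  bad2 <- ern; bad2["ck14"] <- "negative"
  expect_error(endpoint_hazard_for_panel(ep, "BRCA1", 2, 45, bad2),
               "established TN")
})

test_that("a zero marker proportion gives an identically zero end-point hazard", {
  tabs <- builtin_marker_tables()
  tabs$er_negative_given_case$BRCA1[] <- 0
  cfg <- toy_config()
  hz <- constrain_total_hazards(cfg)
  ep <- split_endpoints(hz, tabs, cfg)
  expect_equal(brcapath:::endpoint_share(ep, "BRCA1", "er_neg"), rep(0, 80))
})

test_that("cumulative risks are monotone, bounded and additive", {
  ep <- default_model()$endpoints
  for (g in c("BRCA1", "noncarrier")) {
    risks <- vapply(0:80, function(a) cumulative_risk(ep, g, "total", a),
                    numeric(1))
    expect_equal(risks[1], 0)
    expect_true(all(diff(risks) >= 0))
    expect_true(all(risks <= 1))
    ern <- vapply(0:80, function(a) cumulative_risk(ep, g, "er_neg", a), numeric(1))
    erp <- vapply(0:80, function(a) cumulative_risk(ep, g, "er_pos", a), numeric(1))
    expect_equal(ern + erp, risks, tolerance = 1e-12)
  }
  expect_error(cumulative_risk(ep, "BRCA1", "nope", 70), "unknown end point")
})

test_that("survivor distribution starts at the founder prior and depletes carriers", {
  m <- toy_model(2)
  pj <- genotype_distribution_among_unaffected(m$config, m$endpoints)
  f <- m$config$carrier_frequency
  prior <- outer(c(1 - sum(f), f["BRCA1"], f["BRCA2"]),
                 m$endpoints$pm$founder_probabilities)
  expect_equal(unname(pj[1, , ]), unname(prior))
  expect_equal(pj, m$endpoints$cohorts$all$pi_joint)
  # carrier hazards exceed noncarrier hazards at all ages (rr 20 / 10),
  # so the carrier share among unaffected women must fall with age
  b1_share <- apply(pj[, "BRCA1", , drop = FALSE], 1, sum)
  adult <- 21:80   # hazards are zero before age 20
  expect_true(all(diff(b1_share[adult]) < 0))
})

test_that("zero hazards leave the survivor distribution constant", {
  lst <- list(
    carrier_frequency = list(brca1 = 0.01, brca2 = 0.01),
    n_polygenic_loci = 2,
    polygenic_sd = list(list(age = 0, sd = 1)),
    cohorts = list(list(label = "all", years = c(1900, 2100))),
    incidence = list(all = lapply(stats::setNames(nm = brcapath:::INCIDENCE_CURVES),
                                  function(nm) list(list(age = 0, rate = 0)))),
    population_er_negative = list(list(age = 0, prop = 0.4))
  )
  cfg <- build_model_config(lst)
  hz <- constrain_total_hazards(cfg)
  pj <- genotype_distribution_among_unaffected(cfg, hz)
  for (i in c(2, 40, 80)) expect_equal(pj[i, , ], pj[1, , ])
})
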