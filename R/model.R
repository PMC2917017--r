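## The fitted-model-style front end: one constructor returning a classed
## object, with the usual methods.

#' Build a pathology-aware BRCA risk model
#'
#' Constructs the full risk engine for one parameter configuration:
#' solves the per-(genotype, polygene level) total breast cancer hazards
#' against the configured carrier and population incidence curves
#' ([constrain_total_hazards()]) and splits them into tumour-subtype end
#' points using the marker proportion tables ([split_endpoints()]). The
#' returned object is the single entry point for prediction
#' ([predict.brca_risk_model()]), risk curves ([export_risk_curves()],
#' [plot.brca_risk_model()]), scenario grids
#' ([generate_probability_grid()]) and simulation
#' ([simulate.brca_risk_model()]).
#'
#' @param config A `bp_config`, from [load_model_config()] or
#'   [default_config()].
#' @param tables Marker proportion tables; defaults to
#'   [builtin_marker_tables()].
#' @return An object of class `brca_risk_model`.
#' @examples
#' m <- brca_risk_model()
#' predict(m, ped_single_case(30, er = "negative"), target = "proband")
#' @export
brca_risk_model <- function(config = default_config(),
                            tables = builtin_marker_tables()) {
  stopifnot(inherits(config, "bp_config"), inherits(tables, "marker_tables"))
  hazards <- constrain_total_hazards(config)
  endpoints <- split_endpoints(hazards, tables, config)
  structure(list(config = config, tables = tables, endpoints = endpoints),
            class = "brca_risk_model")
}

#' @export
print.brca_risk_model <- function(x, ...) {
  cat("Pathology-aware BRCA pedigree risk model\n")
  print(x$config)
  cat(sprintf("  subtype end points: ER +/-, TN within ER-, CK classes within TN\n"))
  invisible(x)
}

#' @export
coef.brca_risk_model <- function(object, ...) {
  cf <- object$config
  c(carrier_frequency_brca1 = unname(cf$carrier_frequency["BRCA1"]),
    carrier_frequency_brca2 = unname(cf$carrier_frequency["BRCA2"]),
    n_polygenic_loci = cf$n_polygenic_loci,
    polygenic_sd_age20 = cf$polygenic_sd[21],
    polygenic_sd_age70 = cf$polygenic_sd[71],
    test_sensitivity_brca1 = unname(cf$test_sensitivity["BRCA1"]),
    test_sensitivity_brca2 = unname(cf$test_sensitivity["BRCA2"]))
}

#' Summarise a BRCA risk model
#'
#' Tabulates polygene-averaged cumulative risks by age 70 for the main
#' subtype end points and each major genotype.
#'
#' @param object A `brca_risk_model`.
#' @param to_age Risk horizon (default 70).
#' @param cohort Cohort label (default: first).
#' @param ... Unused.
#' @export
summary.brca_risk_model <- function(object, to_age = 70, cohort = NULL, ...) {
  classes <- c("total", "er_neg", "er_pos", "er_neg_tn", "er_neg_nontn")
  risks <- sapply(GENOTYPES, function(g) {
    vapply(classes, function(cl) {
      cumulative_risk(object$endpoints, g, cl, to_age, cohort)
    }, numeric(1))
  })
  structure(list(to_age = to_age, risks = risks, coef = coef(object)),
            class = "summary.brca_risk_model")
}

#' @export
print.summary.brca_risk_model <- function(x, ...) {
  cat(sprintf("Cumulative risk by age %d (polygene-averaged):\n", x$to_age))
  print(round(x$risks, 4))
  cat("\nParameters:\n")
  print(round(x$coef, 5))
  invisible(x)
}

#' Predict carrier probabilities from a pedigree
#'
#' @param object A `brca_risk_model`.
#' @param pedigree A `bp_pedigree`.
#' @param target Id(s) of the individual(s) of interest (default
#'   `"proband"` if present, otherwise the first individual).
#' @param ... Unused.
#' @return For one target, a `carrier_posterior`; for several, a data
#'   frame with one row per target.
#' @export
predict.brca_risk_model <- function(object, pedigree, target = NULL, ...) {
  stopifnot(inherits(pedigree, "bp_pedigree"))
  if (is.null(target)) {
    target <- if ("proband" %in% pedigree$id) "proband" else pedigree$id[1]
  }
  if (length(target) == 1L) {
    return(carrier_probabilities(pedigree, target, object$endpoints, object$config))
  }
  res <- t(vapply(target, function(tg) {
    unclass(carrier_probabilities(pedigree, tg, object$endpoints, object$config))
  }, numeric(3)))
  data.frame(id = target, res, row.names = NULL)
}

#' Plot model incidence or cumulative-risk curves
#'
#' Base-graphics curves of the polygene-averaged ER-negative,
#' ER-positive and total breast cancer incidence (per 100,000) or
#' cumulative risk for one genotype.
#'
#' @param x A `brca_risk_model`.
#' @param genotype Major genotype to plot.
#' @param what `"incidence"` or `"cumulative"`.
#' @param cohort Cohort label (default: first).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.brca_risk_model <- function(x, genotype = "BRCA1",
                                 what = c("incidence", "cumulative"),
                                 cohort = NULL, ...) {
  what <- match.arg(what)
  ep <- x$endpoints
  ch <- get_cohort(ep, cohort)
  if (what == "incidence") {
    q <- ch$q[, genotype]
    y <- cbind(total = ch$lambda_bar[, genotype],
               er_neg = ch$lambda_bar[, genotype] * q,
               er_pos = ch$lambda_bar[, genotype] * (1 - q)) * 1e5
    ylab <- "incidence per 100,000"
  } else {
    y <- sapply(c("total", "er_neg", "er_pos"), function(cl) {
      vapply(AGES + 1, function(a) cumulative_risk(ep, genotype, cl, a, cohort),
             numeric(1))
    })
    ylab <- "cumulative risk"
  }
  graphics::matplot(AGES, y, type = "l", lty = 1:3, col = c(1, 2, 4),
                    xlab = "age (years)", ylab = ylab,
                    main = sprintf("%s (%s)", genotype, what), ...)
  graphics::legend("topleft", legend = c("all breast", "ER-negative", "ER-positive"),
                   lty = 1:3, col = c(1, 2, 4), bty = "n")
  invisible(x)
}

#' Simulate pedigrees from the model
#'
#' @param object A `brca_risk_model`.
#' @param nsim Number of replicate pedigrees.
#' @param seed Integer seed (replicate `i` uses `seed + i - 1`).
#' @param skeleton Pedigree skeleton; see [simulate_pedigree()].
#' @param ... Passed to [simulate_pedigree()].
#' @return A list of `bp_pedigree` objects (a single pedigree if
#'   `nsim = 1`).
#' @export
simulate.brca_risk_model <- function(object, nsim = 1, seed = 1L,
                                     skeleton, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_pedigree(skeleton, object, seed = seed + i - 1L, ...)
  })
  if (nsim == 1) out[[1]] else out
}
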