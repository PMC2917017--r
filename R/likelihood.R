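## Exact pedigree likelihood over the joint (major genotype x polygene
## level) state space, by variable elimination over the family factor
## graph (Elston-Stewart peeling generalised to an arbitrary loop-free
## elimination order), and Bayesian carrier posteriors.

# ---- state space -----------------------------------------------------

# states are (major genotype 1..6) x (level 0..2N); index
# s = (g - 1) * nlev + l + 1
state_space <- function(n_loci) {
  nlev <- 2L * n_loci + 1L
  list(nlev = nlev, S = 6L * nlev,
       status = rep(unname(MAJOR_STATUS[MAJOR_GENOTYPES]), each = nlev),
       level = rep(0:(nlev - 1L), times = 6L))
}

# joint founder prior over states
state_founder_prior <- function(config, pm) {
  as.vector(t(outer(major_founder_prior(config$carrier_frequency),
                    pm$founder_probabilities)))
}

# joint transmission array T[child, father, mother] over states
state_transmission_array <- function(n_loci) {
  M <- major_transmission_array()
  H <- polygene_transmission_array(n_loci)
  nlev <- 2L * n_loci + 1L
  S <- 6L * nlev
  T_ <- array(0, dim = c(S, S, S))
  for (gf in 1:6) for (gm in 1:6) {
    Mv <- M[, gf, gm]
    gnz <- which(Mv > 0)
    for (lf in 1:nlev) for (lm in 1:nlev) {
      Hv <- H[, lf, lm]
      sf <- (gf - 1L) * nlev + lf
      sm <- (gm - 1L) * nlev + lm
      blk <- outer(Hv, Mv[gnz])          # nlev x |gnz|
      idx <- rep((gnz - 1L) * nlev, each = nlev) + rep(1:nlev, length(gnz))
      T_[idx, sf, sm] <- as.vector(blk)
    }
  }
  T_
}

# ---- penetrance ------------------------------------------------------

# Penetrance factors for one individual as a (3 statuses x nlev levels)
# matrix; statuses ordered as GENOTYPES.
penetrance_matrix <- function(ind, hazards, config, cohort = NULL) {
  ch <- get_cohort(hazards, cohort)
  nlev <- ncol(ch$mult)
  out <- matrix(1, 3, nlev, dimnames = list(GENOTYPES, NULL))

  bc <- ind$breast_cancer_age; oc <- ind$ovarian_cancer_age
  obs <- ind$observation_age
  t_end <- min(bc, oc, obs, na.rm = TRUE)
  t_end <- min(t_end, MAX_AGE + 1L)

  if (ind$sex == "F" && t_end > 0) {
    idx <- seq_len(t_end)
    for (g in GENOTYPES) {
      lam <- ch$base[idx, g] * ch$mult[idx, , drop = FALSE]   # ages x levels
      out[g, ] <- out[g, ] * exp(-colSums(lam))
      out[g, ] <- out[g, ] * exp(-sum(ch$ovarian[idx, g]))
    }
  }
  if (ind$sex == "F" && !is.na(bc) && bc <= t_end && bc <= MAX_AGE) {
    if (inherits(hazards, "bp_endpoints")) {
      cl <- classify_panel(as.list(ind[MARKER_COLS]))
      for (g in GENOTYPES) {
        share <- endpoint_share(hazards, g, cl$class, cl$scenario,
                                cohort %||% names(hazards$cohorts)[1])
        out[g, ] <- out[g, ] * ch$base[bc + 1L, g] * ch$mult[bc + 1L, ] * share[bc + 1L]
      }
    } else {
      if (any(unlist(ind[MARKER_COLS]) != "untested")) {
        stop("marker panel present but no end-point hazards supplied", call. = FALSE)
      }
      for (g in GENOTYPES) {
        out[g, ] <- out[g, ] * ch$base[bc + 1L, g] * ch$mult[bc + 1L, ]
      }
    }
  }
  if (ind$sex == "F" && !is.na(oc) && oc <= t_end && oc <= MAX_AGE) {
    out <- out * ch$ovarian[oc + 1L, ]
  }

  tf <- switch(ind$genetic_test,
    none = c(1, 1, 1),
    negative = c(1, 1 - config$test_sensitivity[["BRCA1"]],
                 1 - config$test_sensitivity[["BRCA2"]]),
    brca1_positive = c(0, config$test_sensitivity[["BRCA1"]], 0),
    brca2_positive = c(0, 0, config$test_sensitivity[["BRCA2"]]))
  out * tf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Penetrance factor for one individual and one genetic state
#'
#' The likelihood contribution of a single individual's phenotype record
#' (censoring, cancer diagnoses with marker panels, genetic test result)
#' conditional on a joint genetic state: survival to the end of follow-up
#' under the state's total breast and ovarian hazards, times the observed
#' end-point hazard at each diagnosis, times the test-result factor
#' (sensitivity < 1, specificity 1). Males contribute genetic-test
#' factors only.
#'
#' @param ind A single-row `bp_pedigree` (or a list with the same fields).
#' @param state List with `major` (`"noncarrier"`/`"BRCA1"`/`"BRCA2"`)
#'   and `polygene_level` (0..2N).
#' @param hazards A `bp_endpoints` (or `bp_hazards` for the base model).
#' @param config The model configuration.
#' @param cohort Cohort label (default: from the individual's birth year).
#' @return A nonnegative likelihood factor.
#' @export
individual_penetrance <- function(ind, state, hazards, config, cohort = NULL) {
  if (inherits(ind, "data.frame")) ind <- as.list(ind[1, ])
  if (is.null(cohort) && !is.na(ind$birth_year %||% NA)) {
    cohort <- cohort_for_birth_year(config, ind$birth_year)
  }
  pm <- penetrance_matrix(ind, hazards, config, cohort)
  unname(pm[state$major, state$polygene_level + 1L])
}

# ---- factor algebra --------------------------------------------------

# A factor is list(vars = <row indices>, tab = numeric array with one
# dim of size S per var, in vars order).

expand_factor_tab <- function(f, u, S) {
  ku <- length(u); kf <- length(f$vars)
  if (kf == ku && all(f$vars == u)) return(f$tab)
  extra <- setdiff(u, f$vars)
  cur <- c(f$vars, extra)
  tab <- array(f$tab, dim = rep(S, ku))   # recycles over trailing dims
  aperm(tab, match(u, cur))
}

factor_product <- function(f1, f2, S) {
  u <- union(f1$vars, f2$vars)
  list(vars = u, tab = expand_factor_tab(f1, u, S) * expand_factor_tab(f2, u, S))
}

factor_marginalize <- function(f, v, S) {
  k <- length(f$vars)
  pos <- match(v, f$vars)
  others <- f$vars[-pos]
  tab <- aperm(array(f$tab, dim = rep(S, k)), c(pos, seq_len(k)[-pos]))
  dim(tab) <- c(S, S^(k - 1L))
  out <- colSums(tab)
  if (length(others)) dim(out) <- rep(S, length(others))
  list(vars = others, tab = out)
}

# build the factor list for a pedigree
pedigree_factors <- function(ped, hazards, config) {
  n <- nrow(ped)
  pm <- hazards$pm
  ss <- state_space(pm$n_loci)
  prior <- state_founder_prior(config, pm)
  T_ <- state_transmission_array(pm$n_loci)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)

  factors <- list()
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      factors[[length(factors) + 1L]] <- list(vars = i, tab = prior)
    } else {
      factors[[length(factors) + 1L]] <- list(vars = c(i, fa[i], mo[i]), tab = T_)
    }
    cohort <- if (is.na(ped$birth_year[i])) NULL else
      cohort_for_birth_year(config, ped$birth_year[i])
    pen <- penetrance_matrix(as.list(ped[i, ]), hazards, config, cohort)
    # map (status x level) onto the 6-genotype state vector
    psi <- pen[match(MAJOR_STATUS[MAJOR_GENOTYPES], GENOTYPES), , drop = FALSE]
    factors[[length(factors) + 1L]] <- list(vars = i, tab = as.vector(t(psi)))
  }
  list(factors = factors, S = ss$S, ss = ss)
}

# eliminate all variables except `keep`; returns list(factors, logscale)
run_elimination <- function(factors, S, n, keep = integer(0)) {
  logscale <- 0
  todo <- setdiff(seq_len(n), keep)
  while (length(todo)) {
    # greedy: eliminate the variable with the smallest resulting scope
    cost <- vapply(todo, function(v) {
      sc <- unique(unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars)))
      length(setdiff(sc, v))
    }, numeric(1))
    v <- todo[which.min(cost)]
    todo <- setdiff(todo, v)
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    fs <- factors[inv]
    factors <- factors[!inv]
    prod <- fs[[1]]
    for (f in fs[-1]) prod <- factor_product(prod, f, S)
    marg <- factor_marginalize(prod, v, S)
    m <- max(marg$tab)
    if (m <= 0) {
      # zero likelihood: impossible observations under the model
      return(list(factors = list(list(vars = integer(0), tab = 0)),
                  logscale = logscale))
    }
    marg$tab <- marg$tab / m
    logscale <- logscale + log(m)
    factors[[length(factors) + 1L]] <- marg
  }
  list(factors = factors, logscale = logscale)
}

check_pedigree_for_likelihood <- function(ped) {
  issues <- validate_pedigree(ped)
  loops <- grepl("^inbreeding loop", issues)
  if (any(loops)) {
    stop("unsupported pedigree structure: ", paste(issues[loops], collapse = "; "),
         call. = FALSE)
  }
  if (length(issues)) {
    stop("invalid pedigree: ", paste(issues, collapse = "; "), call. = FALSE)
  }
}

#' Exact pedigree log-likelihood
#'
#' Sums, over all joint assignments of major genotypes and polygene
#' levels to every pedigree member, the product of founder priors,
#' Mendelian/hypergeometric transmission probabilities and individual
#' penetrance factors. The sum is computed exactly by peeling (factor
#' elimination); pedigrees with inbreeding loops are rejected.
#'
#' @param ped A `bp_pedigree`.
#' @param hazards A `bp_endpoints` (or `bp_hazards` for the base model
#'   without subtype end points).
#' @param config The model configuration.
#' @return The log-likelihood (a scalar; 0 for a pedigree with no
#'   phenotype information).
#' @export
pedigree_loglikelihood <- function(ped, hazards, config) {
  stopifnot(inherits(ped, "bp_pedigree"), inherits(hazards, "bp_hazards"))
  check_pedigree_for_likelihood(ped)
  fg <- pedigree_factors(ped, hazards, config)
  res <- run_elimination(fg$factors, fg$S, nrow(ped))
  val <- prod(vapply(res$factors, function(f) as.numeric(f$tab[1]), numeric(1)))
  if (val <= 0) return(-Inf)
  res$logscale + log(val)
}

#' Carrier probabilities for a pedigree member
#'
#' Posterior probabilities that the target individual is a noncarrier, a
#' BRCA1 mutation carrier or a BRCA2 mutation carrier, given the whole
#' family's phenotypes, marker panels and test results: the pedigree
#' likelihood with the target's major genotype clamped to each class
#' (polygene marginalised), normalised over classes.
#'
#' @param ped A `bp_pedigree`.
#' @param target Id of the individual of interest.
#' @param hazards A `bp_endpoints` (or `bp_hazards` for the base model).
#' @param config The model configuration.
#' @return An object of class `carrier_posterior`: named numeric vector
#'   `(noncarrier, BRCA1, BRCA2)` summing to 1.
#' @export
carrier_probabilities <- function(ped, target, hazards, config) {
  stopifnot(inherits(ped, "bp_pedigree"), inherits(hazards, "bp_hazards"))
  ti <- match(as.character(target), ped$id)
  if (is.na(ti)) stop("unknown target id: ", target, call. = FALSE)
  check_pedigree_for_likelihood(ped)
  fg <- pedigree_factors(ped, hazards, config)
  res <- run_elimination(fg$factors, fg$S, nrow(ped), keep = ti)
  marg <- rep(1, fg$S)
  for (f in res$factors) {
    marg <- marg * (if (length(f$vars)) f$tab else as.numeric(f$tab))
  }
  tot <- sum(marg)
  if (tot <= 0) stop("zero pedigree likelihood: observations impossible under the model",
                     call. = FALSE)
  post <- vapply(GENOTYPES, function(g) sum(marg[fg$ss$status == g]) / tot,
                 numeric(1))
  structure(post, class = "carrier_posterior", target = as.character(target))
}

#' @export
print.carrier_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Carrier probabilities for '%s'\n", attr(x, "target")))
  v <- unclass(x)
  cat(sprintf("  noncarrier: %.*f\n  BRCA1:      %.*f\n  BRCA2:      %.*f\n",
              digits, v["noncarrier"], digits, v["BRCA1"], digits, v["BRCA2"]))
  invisible(x)
}
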