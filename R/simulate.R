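## Forward pedigree simulator: the generative mirror of the risk model.

# one random allele from a genotype code
sample_allele <- function(geno) {
  al <- MAJOR_ALLELES[[geno]]
  al[sample.int(2L, 1L)]
}

pair_code <- function(a, b) {
  switch(paste0(sort(c(a, b), method = "radix"), collapse = ""),
         ww = "ww", `1w` = "w1", `2w` = "w2",
         `11` = "11", `12` = "12", `22` = "22")
}

#' Simulate phenotypes on a pedigree skeleton
#'
#' Draws founder genotypes from the configured priors, transmits the
#' major locus Mendelianly and the polygene hypergeometrically, samples
#' ages at first breast/ovarian cancer from the per-(genotype, level)
#' yearly hazards, and labels breast tumours with marker panels drawn
#' from the model's subtype proportions. Follow-up ends at the first
#' cancer or at the skeleton's observation age, whichever is earlier.
#'
#' @param skeleton Data frame with columns `id`, `sex`, `father`,
#'   `mother`, `birth_year`, `observation_age` (unrelated individuals are
#'   allowed: the skeleton may be a forest).
#' @param model A [brca_risk_model()] object.
#' @param seed Integer seed; the same seed reproduces the same pedigree.
#' @param markers_tested Which markers are assayed on each simulated
#'   breast tumour (subset of `er`, `pr`, `her2`, `ck56`, `ck14`).
#'   Cytokeratins are only assayed on triple-negative tumours.
#' @param founder_status Optional named character vector (id ->
#'   `"noncarrier"`/`"BRCA1"`/`"BRCA2"`) clamping founder carrier
#'   status; carriers are made heterozygotes.
#' @return A `bp_pedigree` with simulated phenotypes. The true simulated
#'   states are attached as attributes `"true_status"` (carrier status)
#'   and `"true_level"` (polygene level), named by id.
#' @export
simulate_pedigree <- function(skeleton, model, seed = 1L,
                              markers_tested = c("er", "pr", "her2", "ck56", "ck14"),
                              founder_status = NULL) {
  stopifnot(inherits(model, "brca_risk_model"))
  need <- c("id", "sex", "father", "mother", "birth_year", "observation_age")
  if (!all(need %in% names(skeleton))) {
    stop("invalid skeleton: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sk <- as.data.frame(skeleton, stringsAsFactors = FALSE)
  sk$id <- as.character(sk$id)
  for (cc in c("father", "mother")) {
    v <- as.character(sk[[cc]]); v[!is.na(v) & v == ""] <- NA_character_
    sk[[cc]] <- v
  }
  n <- nrow(sk)
  set.seed(seed)
  config <- model$config
  endpoints <- model$endpoints
  n_loci <- endpoints$pm$n_loci

  fa <- match(sk$father, sk$id); mo <- match(sk$mother, sk$id)
  if (any(!is.na(sk$father) & is.na(fa)) || any(!is.na(sk$mother) & is.na(mo))) {
    stop("invalid skeleton: unknown parent id", call. = FALSE)
  }

  # topological order, founders first
  ord <- integer(0); placed <- rep(FALSE, n)
  while (length(ord) < n) {
    fa_ok <- is.na(fa) | placed[replace(fa, is.na(fa), 1L)]
    mo_ok <- is.na(mo) | placed[replace(mo, is.na(mo), 1L)]
    free <- which(!placed & fa_ok & mo_ok)
    if (!length(free)) stop("invalid skeleton: relationship cycle", call. = FALSE)
    ord <- c(ord, free); placed[free] <- TRUE
  }

  prior <- major_founder_prior(config$carrier_frequency)
  geno <- character(n); level <- integer(n)
  for (i in ord) {
    if (is.na(fa[i])) {
      forced <- founder_status[[sk$id[i]]]
      geno[i] <- if (!is.null(forced)) {
        switch(forced, noncarrier = "ww", BRCA1 = "w1", BRCA2 = "w2",
               stop("invalid founder status: ", forced, call. = FALSE))
      } else {
        sample(MAJOR_GENOTYPES, 1L, prob = prior)
      }
      level[i] <- stats::rbinom(1L, 2L * n_loci, 0.5)
    } else {
      geno[i] <- pair_code(sample_allele(geno[fa[i]]), sample_allele(geno[mo[i]]))
      level[i] <- stats::rhyper(1L, level[fa[i]], 2L * n_loci - level[fa[i]], n_loci) +
        stats::rhyper(1L, level[mo[i]], 2L * n_loci - level[mo[i]], n_loci)
    }
  }
  status <- unname(MAJOR_STATUS[geno])

  out <- data.frame(id = sk$id, sex = toupper(sk$sex), father = sk$father,
                    mother = sk$mother, birth_year = sk$birth_year,
                    observation_age = sk$observation_age,
                    breast_cancer_age = NA_real_, ovarian_cancer_age = NA_real_,
                    er = "untested", pr = "untested", her2 = "untested",
                    ck56 = "untested", ck14 = "untested",
                    genetic_test = "none", stringsAsFactors = FALSE)

  females <- which(out$sex == "F")
  if (length(females)) {
    cohorts <- vapply(females, function(i) {
      by <- sk$birth_year[i]
      if (is.na(by)) names(endpoints$cohorts)[1] else cohort_for_birth_year(config, by)
    }, character(1))
    for (lab in unique(cohorts)) {
      ch <- endpoints$cohorts[[lab]]
      sel <- females[cohorts == lab]
      gidx <- status[sel]
      lam <- ch$base[, gidx, drop = FALSE] *
        ch$mult[, level[sel] + 1L, drop = FALSE]          # ages x individuals
      ov <- ch$ovarian[, gidx, drop = FALSE]
      pb <- 1 - exp(-lam); po <- 1 - exp(-ov)
      ub <- matrix(stats::runif(length(pb)), nrow(pb))
      uo <- matrix(stats::runif(length(po)), nrow(po))
      for (k in seq_along(sel)) {
        i <- sel[k]
        horizon <- min(out$observation_age[i], MAX_AGE + 1L)
        if (horizon <= 0) next
        ages <- seq_len(horizon)                      # rows for ages 0..horizon-1
        b_age <- which(ub[ages, k] < pb[ages, k])[1] - 1L
        o_age <- which(uo[ages, k] < po[ages, k])[1] - 1L
        first <- suppressWarnings(min(b_age, o_age, na.rm = TRUE))
        if (!is.finite(first)) next
        out$observation_age[i] <- first
        if (!is.na(b_age) && b_age == first) {
          out$breast_cancer_age[i] <- b_age
          pan <- simulate_panel(endpoints, lab, status[i], b_age, markers_tested)
          out[i, MARKER_COLS] <- pan
        }
        if (!is.na(o_age) && o_age == first) out$ovarian_cancer_age[i] <- o_age
      }
    }
  }

  ped <- as_pedigree(out)
  attr(ped, "true_status") <- stats::setNames(status, sk$id)
  attr(ped, "true_level") <- stats::setNames(level, sk$id)
  ped
}

# draw a marker panel for one simulated breast tumour
simulate_panel <- function(endpoints, cohort, genotype, age, markers_tested) {
  pan <- c(er = "untested", pr = "untested", her2 = "untested",
           ck56 = "untested", ck14 = "untested")
  if (!"er" %in% markers_tested) return(pan)
  ch <- endpoints$cohorts[[cohort]]
  i <- age + 1L
  er_neg <- stats::runif(1) < ch$q[i, genotype]
  pan["er"] <- if (er_neg) "negative" else "positive"
  if (!er_neg) return(pan)
  if (!all(c("pr", "her2") %in% markers_tested)) return(pan)
  tn <- stats::runif(1) < ch$r[i, genotype]
  if (!tn) {
    # not triple-negative: at least one of PR/HER2 positive
    combo <- sample(3L, 1L)
    pan["pr"] <- c("positive", "negative", "positive")[combo]
    pan["her2"] <- c("negative", "positive", "positive")[combo]
    return(pan)
  }
  pan["pr"] <- pan["her2"] <- "negative"
  ck_t <- intersect(c("ck56", "ck14"), markers_tested)
  if (length(ck_t) == 2L) {
    cls <- sample(dimnames(ch$ck$both_ck)[[2]], 1L,
                  prob = ch$ck$both_ck[i, , genotype])
    if (cls == "both_pos") pan[c("ck56", "ck14")] <- "positive"
    else if (cls == "neither") pan[c("ck56", "ck14")] <- "negative"
    else {
      which_pos <- sample(c("ck56", "ck14"), 1L)
      pan[c("ck56", "ck14")] <- "negative"
      pan[which_pos] <- "positive"
    }
  } else if (length(ck_t) == 1L) {
    sc <- if (ck_t == "ck56") "ck56_only" else "ck14_only"
    pos <- stats::runif(1) < ch$ck[[sc]][i, "pos", genotype]
    pan[ck_t] <- if (pos) "positive" else "negative"
  }
  pan
}
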