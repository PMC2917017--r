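# Independent brute-force oracle for the pedigree likelihood: exhaustive
# enumeration of all joint (major genotype x polygene level) assignments
# by vectorised index arithmetic. Shares nothing with the peeling code
# path beyond the per-individual penetrance/prior/transmission tables.

bf_state_tables <- function(ped, hazards, config) {
  n_loci <- hazards$pm$n_loci
  nlev <- 2L * n_loci + 1L
  S <- 6L * nlev
  # per-state prior for founders
  geno_prior <- brcapath:::major_founder_prior(config$carrier_frequency)
  prior <- as.vector(t(outer(geno_prior, hazards$pm$founder_probabilities)))
  # transmission as a flat vector indexed by child + S*(father-1) + S^2*(mother-1)
  M <- brcapath:::major_transmission_array()
  H <- brcapath:::polygene_transmission_array(n_loci)
  T_ <- array(0, dim = c(S, S, S))
  for (gc_ in 1:6) for (gf in 1:6) for (gm in 1:6) {
    if (M[gc_, gf, gm] == 0) next
    for (lf in 1:nlev) for (lm in 1:nlev) {
      ic <- (gc_ - 1L) * nlev + (1:nlev)
      T_[ic, (gf - 1L) * nlev + lf, (gm - 1L) * nlev + lm] <-
        T_[ic, (gf - 1L) * nlev + lf, (gm - 1L) * nlev + lm] +
        M[gc_, gf, gm] * H[, lf, lm]
    }
  }
  status <- rep(unname(brcapath:::MAJOR_STATUS[brcapath:::MAJOR_GENOTYPES]),
                each = nlev)
  # penetrance vector per state: status row repeated over levels
  pens <- lapply(seq_len(nrow(ped)), function(i) {
    cohort <- if (is.na(ped$birth_year[i])) NULL else
      brcapath:::cohort_for_birth_year(config, ped$birth_year[i])
    pm <- brcapath:::penetrance_matrix(as.list(ped[i, ]), hazards, config, cohort)
    vec <- numeric(S)
    for (s in seq_len(S)) {
      g <- status[s]; l <- (s - 1L) %% nlev
      vec[s] <- pm[g, l + 1L]
    }
    vec
  })
  list(S = S, prior = prior, Tflat = as.vector(T_), pens = pens)
}

# joint likelihood over all S^n state assignments (vectorised)
bf_joint <- function(ped, hazards, config) {
  tabs <- bf_state_tables(ped, hazards, config)
  S <- tabs$S
  n <- nrow(ped)
  total <- S^n
  stopifnot(total <= 4e7)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  idx <- 0:(as.integer(total) - 1L)
  states <- lapply(seq_len(n), function(j) (idx %/% as.integer(S^(j - 1))) %% S + 1L)
  rm(idx)
  L <- rep(1, total)
  for (j in seq_len(n)) {
    sj <- states[[j]]
    L <- L * tabs$pens[[j]][sj]
    if (is.na(fa[j])) {
      L <- L * tabs$prior[sj]
    } else {
      lin <- sj + S * (states[[fa[j]]] - 1L) + S * S * (states[[mo[j]]] - 1L)
      L <- L * tabs$Tflat[lin]
    }
  }
  list(L = L, states = states, S = S)
}

bf_loglik <- function(ped, hazards, config) {
  log(sum(bf_joint(ped, hazards, config)$L))
}

# posterior for a target by brute force
bf_posterior <- function(ped, target, hazards, config) {
  jt <- bf_joint(ped, hazards, config)
  ti <- match(target, ped$id)
  nlev <- jt$S / 6L
  status <- rep(unname(brcapath:::MAJOR_STATUS[brcapath:::MAJOR_GENOTYPES]),
                each = nlev)
  st <- status[jt$states[[ti]]]
  out <- c(noncarrier = sum(jt$L[st == "noncarrier"]),
           BRCA1 = sum(jt$L[st == "BRCA1"]),
           BRCA2 = sum(jt$L[st == "BRCA2"]))
  out / sum(out)
}
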