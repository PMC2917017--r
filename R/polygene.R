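## Hypergeometric polygenic model: discrete approximation to a normal
## polygenic log-hazard component with age-dependent standard deviation.

#' Construct a polygenic model
#'
#' The polygenic log relative risk is approximated by a standardized
#' binomial allele count over `2 * n_loci` biallelic loci: an individual
#' at level `l` (0..2N) carries standardized value `z = (l - N) /
#' sqrt(N/2)`, which has mean 0 and variance 1 under the founder
#' distribution, and multiplies the breast cancer hazard at age `t` by
#' `exp(sd(t) * z)`. Transmission follows the hypergeometric rule: each
#' parent passes on a hypergeometric sample of N of its 2N alleles, which
#' preserves the founder distribution under random mating.
#'
#' @param n_loci Number of polygenic loci N (default 3, i.e. 7 levels).
#' @param sd_schedule Yearly standard deviation of the polygenic
#'   log-hazard, a numeric vector of length 80 (ages 0-79), or a single
#'   number recycled over ages.
#' @return An object of class `polygenic_model`.
#' @examples
#' pm <- polygenic_model(2, 1.0)
#' founder_distribution(2)
#' @export
polygenic_model <- function(n_loci = 3L, sd_schedule = 0) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("n_loci must be >= 1", call. = FALSE)
  if (length(sd_schedule) == 1L) sd_schedule <- rep(sd_schedule, length(AGES))
  if (length(sd_schedule) != length(AGES) || any(sd_schedule < 0) || anyNA(sd_schedule)) {
    stop("sd_schedule must be a nonnegative vector over ages 0-", MAX_AGE,
         call. = FALSE)
  }
  structure(list(
    n_loci = n_loci,
    levels = 0:(2L * n_loci),
    founder_probabilities = founder_distribution(n_loci),
    sd_schedule = sd_schedule
  ), class = "polygenic_model")
}

#' Founder distribution of polygene levels
#'
#' Binomial(2N, 1/2) masses over levels 0..2N: the allele-count
#' distribution of an individual with unrelated parents.
#'
#' @param n_loci Number of polygenic loci N.
#' @return Numeric vector of length 2N + 1 summing to 1.
#' @export
founder_distribution <- function(n_loci) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) stop("n_loci must be >= 1", call. = FALSE)
  stats::dbinom(0:(2L * n_loci), size = 2L * n_loci, prob = 0.5)
}

#' Polygene transmission distribution
#'
#' Distribution of a child's polygene level given both parental levels:
#' the child receives `K_f + K_m`, where `K_p` is a hypergeometric draw
#' of N alleles from the 2N alleles of parent `p`, of which
#' `parent_level` are positive.
#'
#' @param father_level,mother_level Parental levels in 0..2N.
#' @param n_loci Number of polygenic loci N.
#' @return Numeric vector of length 2N + 1 over child levels, summing to 1.
#' @export
transmission_distribution <- function(father_level, mother_level, n_loci) {
  n_loci <- as.integer(n_loci)
  two_n <- 2L * n_loci
  for (lv in c(father_level, mother_level)) {
    if (lv < 0 || lv > two_n || lv != round(lv)) {
      stop("invalid polygene level: ", lv, call. = FALSE)
    }
  }
  kf <- stats::dhyper(0:n_loci, m = father_level, n = two_n - father_level, k = n_loci)
  km <- stats::dhyper(0:n_loci, m = mother_level, n = two_n - mother_level, k = n_loci)
  # convolve the two parental contributions
  out <- numeric(two_n + 1L)
  for (i in 0:n_loci) {
    if (kf[i + 1L] > 0) {
      out[(i + 0:n_loci) + 1L] <- out[(i + 0:n_loci) + 1L] + kf[i + 1L] * km
    }
  }
  out
}

# Full transmission array T[child, father, mother], each dim 2N+1.
polygene_transmission_array <- function(n_loci) {
  s <- 2L * n_loci + 1L
  arr <- array(0, dim = c(s, s, s))
  for (f in 0:(s - 1L)) {
    for (m in 0:(s - 1L)) {
      arr[, f + 1L, m + 1L] <- transmission_distribution(f, m, n_loci)
    }
  }
  arr
}

#' Polygenic hazard multiplier
#'
#' Multiplicative effect on the breast cancer hazard of polygene level
#' `level` at a given age: `exp(sd(age) * (level - N) / sqrt(N/2))`.
#'
#' @param level Polygene level in 0..2N.
#' @param age Age in years (0-79).
#' @param model A `polygenic_model`.
#' @return A positive scale factor.
#' @export
polygene_multiplier <- function(level, age, model) {
  stopifnot(inherits(model, "polygenic_model"))
  n <- model$n_loci
  if (any(level < 0 | level > 2L * n)) stop("invalid polygene level", call. = FALSE)
  if (any(age < 0 | age > MAX_AGE)) {
    stop("polygenic sd undefined at age ", age[which(age < 0 | age > MAX_AGE)[1]],
         call. = FALSE)
  }
  z <- (level - n) / sqrt(n / 2)
  exp(model$sd_schedule[age + 1L] * z)
}

# Matrix of multipliers: ages (rows 0..79) x levels (cols 0..2N).
polygene_multiplier_matrix <- function(model) {
  z <- (model$levels - model$n_loci) / sqrt(model$n_loci / 2)
  exp(outer(model$sd_schedule, z))
}
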