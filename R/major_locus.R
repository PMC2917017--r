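## Major susceptibility locus: a single three-allele locus (wild type,
## BRCA1 allele "1", BRCA2 allele "2"). Carrier status is dominant, with
## the BRCA1 allele taking precedence in double heterozygotes; two
## independent rare loci would make double carriers negligible, so the
## single-locus collapse is used throughout.

MAJOR_GENOTYPES <- c("ww", "w1", "w2", "11", "12", "22")
MAJOR_ALLELES <- list(ww = c("w", "w"), w1 = c("w", "1"), w2 = c("w", "2"),
                      `11` = c("1", "1"), `12` = c("1", "2"), `22` = c("2", "2"))
MAJOR_STATUS <- c(ww = "noncarrier", w1 = "BRCA1", w2 = "BRCA2",
                  `11` = "BRCA1", `12` = "BRCA1", `22` = "BRCA2")

# Allele frequencies (w, 1, 2) reproducing the configured carrier
# frequencies under Hardy-Weinberg: P(any "1") = f1, P("2" without "1") = f2.
major_allele_freqs <- function(carrier_frequency) {
  f1 <- carrier_frequency[["BRCA1"]]; f2 <- carrier_frequency[["BRCA2"]]
  p0 <- sqrt(1 - f1 - f2)
  q1 <- 1 - sqrt(1 - f1)
  q2 <- sqrt(1 - f1) - p0
  c(w = p0, `1` = q1, `2` = q2)
}

major_founder_prior <- function(carrier_frequency) {
  q <- major_allele_freqs(carrier_frequency)
  p <- c(ww = q["w"]^2, w1 = 2 * q["w"] * q["1"], w2 = 2 * q["w"] * q["2"],
         `11` = q["1"]^2, `12` = 2 * q["1"] * q["2"], `22` = q["2"]^2)
  names(p) <- MAJOR_GENOTYPES
  p
}

# P(child genotype | father, mother): each parent passes one of its two
# alleles with probability 1/2.
major_transmission_array <- function() {
  arr <- array(0, dim = c(6, 6, 6),
               dimnames = list(MAJOR_GENOTYPES, MAJOR_GENOTYPES, MAJOR_GENOTYPES))
  code <- function(a, b) {
    pair <- paste0(sort(c(a, b), method = "radix"), collapse = "")
    switch(pair, ww = "ww", `1w` = "w1", `2w` = "w2",
           `11` = "11", `12` = "12", `22` = "22")
  }
  for (f in MAJOR_GENOTYPES) {
    for (m in MAJOR_GENOTYPES) {
      for (af in MAJOR_ALLELES[[f]]) {
        for (am in MAJOR_ALLELES[[m]]) {
          ch <- code(af, am)
          arr[ch, f, m] <- arr[ch, f, m] + 0.25
        }
      }
    }
  }
  arr
}
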