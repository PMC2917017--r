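# Synthetic default parameter set for brcapath.
#
# The genotype-specific total incidence curves, mutation frequencies and
# polygenic schedule of the original segregation analysis behind the
# published carrier/population curves are not shipped with this package;
# this file is a SYNTHETIC stand-in assembled once from field-standard
# values: rare-allele carrier frequencies of 2q for q = 0.00064 (BRCA1)
# and q = 0.00102 (BRCA2), an England-and-Wales-like population breast
# cancer incidence (~7% cumulative by age 70), early-onset BRCA1 and
# late-onset BRCA2 carrier incidence shapes, registry-like ovarian rates,
# and a polygenic log-hazard standard deviation declining with age.
# Rates are per 100,000 person-years; curves are age-band step functions
# expanded to single years on loading (right-open bands).
carrier_frequency:
  brca1: 0.00128
  brca2: 0.00204
n_polygenic_loci: 3
polygenic_sd:
  - {age: 0,  sd: 1.4}
  - {age: 30, sd: 1.3}
  - {age: 40, sd: 1.2}
  - {age: 50, sd: 1.1}
  - {age: 60, sd: 1.0}
  - {age: 70, sd: 0.9}
test_sensitivity:
  brca1: 0.70
  brca2: 0.80
survival_weighting: breast+ovarian
use_table1_brca2: false
cohorts:
  - label: "born1950plus"
    years: [1900, 2050]
incidence:
  born1950plus:
    population_breast:
      - {age: 0,  rate: 0}
      - {age: 20, rate: 1}
      - {age: 25, rate: 8}
      - {age: 30, rate: 25}
      - {age: 35, rate: 60}
      - {age: 40, rate: 120}
      - {age: 45, rate: 180}
      - {age: 50, rate: 220}
      - {age: 55, rate: 240}
      - {age: 60, rate: 265}
      - {age: 65, rate: 295}
      - {age: 70, rate: 320}
      - {age: 75, rate: 340}
    population_ovarian:
      - {age: 0,  rate: 0}
      - {age: 30, rate: 5}
      - {age: 40, rate: 15}
      - {age: 50, rate: 30}
      - {age: 60, rate: 45}
      - {age: 70, rate: 55}
    brca1_breast:
      - {age: 0,  rate: 0}
      - {age: 20, rate: 30}
      - {age: 25, rate: 300}
      - {age: 30, rate: 1000}
      - {age: 35, rate: 2200}
      - {age: 40, rate: 3000}
      - {age: 45, rate: 3400}
      - {age: 50, rate: 3100}
      - {age: 55, rate: 2700}
      - {age: 60, rate: 2400}
      - {age: 65, rate: 2200}
      - {age: 70, rate: 2100}
      - {age: 75, rate: 2000}
    brca2_breast:
      - {age: 0,  rate: 0}
      - {age: 20, rate: 10}
      - {age: 25, rate: 50}
      - {age: 30, rate: 280}
      - {age: 35, rate: 760}
      - {age: 40, rate: 1500}
      - {age: 45, rate: 2500}
      - {age: 50, rate: 3200}
      - {age: 55, rate: 3700}
      - {age: 60, rate: 4300}
      - {age: 65, rate: 4600}
      - {age: 70, rate: 4600}
      - {age: 75, rate: 4500}
    brca1_ovarian:
      - {age: 0,  rate: 0}
      - {age: 30, rate: 50}
      - {age: 40, rate: 600}
      - {age: 50, rate: 1500}
      - {age: 60, rate: 2200}
      - {age: 70, rate: 2400}
    brca2_ovarian:
      - {age: 0,  rate: 0}
      - {age: 30, rate: 10}
      - {age: 40, rate: 100}
      - {age: 50, rate: 500}
      - {age: 60, rate: 900}
      - {age: 70, rate: 1100}
# Proportion of incident breast cancers that are ER-negative in the
# general population, by 10-year age band (monotonically decreasing).
# The case-weighted aggregate under age 70 is ~0.356.
population_er_negative:
  - {age: 0,  prop: 0.50}
  - {age: 30, prop: 0.46}
  - {age: 40, prop: 0.42}
  - {age: 50, prop: 0.34}
  - {age: 60, prop: 0.29}
  - {age: 70, prop: 0.25}
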