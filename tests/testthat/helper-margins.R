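# Cohort of 7661 admissions built to the study's exclusion margins:
# 1468 readmissions-only (gap <= 30 d), 176 insufficient-labs-only
# (10/35 analytes measured), 33 both, and exactly 175 falls among the
# remaining 5984 included admissions.
make_margin_cohort <- function(seed = 1) {
  co <- simulate_cohort(sim_config(n = 7661, seed = seed, missing_prob = 0))
  adm <- co$admissions
  adm$readmission_gap_days <- NA_integer_
  adm$readmission_gap_days[1:1501] <- 15L          # 33 overlap + 1468 only
  lab_short <- adm$admission_id[c(1:33, 1502:1677)]  # 33 both + 176 only
  keep_analytes <- co$panel$analytes$analyte_id[1:10]
  labs <- co$labs
  labs <- labs[!(labs$admission_id %in% lab_short &
                   !(labs$analyte_id %in% keep_analytes)), ]
  adm$fell <- FALSE
  adm$fell[1678:1852] <- TRUE                      # 175 events, all included
  fall_cohort(adm, labs, co$deficits, co$icd10, panel = co$panel,
              provenance = "exclusion-margin fixture")
}
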