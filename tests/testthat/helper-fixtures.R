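# Small cohorts used across test files. Everything is generated in code at
# test time; sizes are kept small so the whole suite runs in minutes.

small_cohort <- function(seed = 7, n_roi = 10, n_sites = 3,
                         subjects_per_site = 10, autism_per_site = 5, ...) {
  simulate_cohort(sim_params(n_roi = n_roi, n_sites = n_sites,
                             subjects_per_site = subjects_per_site,
                             autism_per_site = autism_per_site,
                             seed = seed, ...))
}

# a hand-built phenotype frame with controlled missingness
toy_phenotypes <- function() {
  data.frame(
    subject_id = sprintf("s%02d", 1:6),
    site = rep(c("A", "B"), each = 3),
    diagnosis = rep(c("autism", "control"), 3),
    age = c(10, 20, 30, 12.5, 24, 48),
    gender = c("male", "female", "male", "male", "female", "male"),
    handedness = c("right", "left", "right", "ambidextrous", "right", "right"),
    eyes = c("open", "closed", "open", "unknown", "open", "open"),
    n_volumes_acquired = rep(150L, 6),
    n_volumes_retained = c(140L, 90L, 150L, 100L, 120L, NA),
    ados_social_comm = c(10, NA, 12, 1, NA, 0.5),
    adi_r_social = c(20, NA, 18, NA, NA, NA),
    adi_r_verbal = c(15, NA, 14, NA, NA, NA),
    verbal_iq = c(100, 110, NA, 115, 108, 120),
    performance_iq = c(105, 102, 98, 111, NA, 118),
    srs_total = c(95, 20, 88, 15, NA, 22),
    vineland_composite = c(70, 104, NA, 101, 98, 106),
    stringsAsFactors = FALSE)
}
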