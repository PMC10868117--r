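# Shared fixtures: a small hand-built bundle and compact simulation
# configs. Everything is constructed in code; no data files.

# Three-admission bundle at site_a with hand-placed lab values and codes.
# adm1: early adolescent, severe hypoglycemia (glucose min 1.5), coded.
# adm2: infant, mild-but-not-moderate anemia (hgb 100 vs cutoffs
#       110/90/70; infant range low 105 so also abnormal), not coded.
# adm3: middle childhood, all values mid-normal, spurious AKI code.
tiny_bundle <- function() {
  admissions <- data.frame(
    admission_id = c("a1", "a2", "a3"),
    patient_id = c("p1", "p1", "p2"),
    institution = "site_a",
    admit_date = as.Date(c("2019-01-01", "2019-03-01", "2020-06-15")),
    discharge_date = as.Date(c("2019-01-04", "2019-03-02", "2020-06-20")),
    age_at_admission = c(4700, 200, 3000),
    sex = c("female", "female", "male"),
    died_in_hospital = FALSE,
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    admission_id = c("a1", "a1", "a2", "a3", "a3"),
    analyte = c("glucose", "glucose", "hemoglobin", "glucose", "sodium"),
    value = c(1.5, 4.8, 100, 5.0, 140),
    unit = c("mmol/L", "mmol/L", "g/L", "mmol/L", "mmol/L"),
    collected_at = "2019-01-01T10:00:00",
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    admission_id = c("a1", "a3"),
    code = c("E16.2", "N17.9"),
    vocabulary = "ICD-10",
    stringsAsFactors = FALSE)
  unit_stays <- data.frame(
    admission_id = c("a1", "a1", "a2", "a3"),
    unit_id = c("u1", "u2", "u1", "u2"),
    stringsAsFactors = FALSE)
  cohort_bundle(admissions, measurements, diagnoses, unit_stays)
}

# Zero-random-effect, full-testing config: labels equal the latent
# strata exactly and the closed-form metrics are exact expectations.
oracle_config <- function(n_patients = 2000, coding_sens = c(0.2, 0.4, 0.6),
                          coding_fpr = 0.02, patient_sd = 0, seed = 7) {
  simulation_config(
    institutions = "site_a", n_patients = n_patients,
    admissions_lambda = 0.65, los_lambda = 1.8, test_prob_per_day = 1,
    patient_sd = patient_sd, unit_prev_sd = 0, unit_coding_sd = 0,
    coding_sens = coding_sens, coding_fpr = coding_fpr, seed = seed)
}

small_preset <- function(name, n_a = 600, n_b = 500) {
  scenario_presets(n_patients = c(site_a = n_a, site_b = n_b))[[name]]
}

bundle_paths <- function(dir) {
  list(admissions = file.path(dir, "admissions.csv"),
       measurements = file.path(dir, "measurements.csv"),
       diagnoses = file.path(dir, "diagnoses.csv"),
       unit_stays = file.path(dir, "unit_stays.csv"),
       reference_ranges = file.path(dir, "reference_ranges.csv"))
}

# Independent brute-force kappa: reconstruct the two raters' label
# vectors and compute observed/chance agreement from the vectors
# themselves (no cell arithmetic shared with cohen_kappa()).
kappa_brute <- function(tp, fp, fn, tn) {
  test <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  gold <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  po <- mean(test == gold)
  pe <- mean(test) * mean(gold) + mean(!test) * mean(!gold)
  (po - pe) / (1 - pe)
}
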