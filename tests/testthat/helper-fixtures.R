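# Shared fixtures built in code at test time.

write_cohort_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# A 10-row cohort file with two rows that fail hard validation: one unknown
# promoter variant, one malformed rank.
fixture_10row <- function() {
  write_cohort_file(c(
    "animal_id,sire_id,gender,birth_rank,rearing_rank,age_weaning,genotype_prom,genotype_coding,birth_weight,weaning_weight",
    "L001,S01,male,twin,twin,100,A1/A1,A3/B3,5.1,32.1",
    "L002,S01,female,single,single,95,A1/B1,A3/A3,5.6,30.2",
    "L003,S01,male,twin,twin,98,B1/B1,A3/C3,4.9,28.8",
    "L004,S01,female,twin,single,97,E1/A1,A3/A3,5.0,29.0",
    "L005,S02,male,single,single,92,A1/B1,A3/C3,5.8,33.0",
    "L006,S02,female,twin,twin,99,B1/B1,C3/C3,4.7,27.5",
    "L007,S02,male,quadruplet,twin,96,A1/A1,A3/A3,5.2,30.9",
    "L008,S02,female,twin,twin,94,A1/B1,B3/C3,5.3,29.9",
    "L009,S03,male,single,single,91,B1/D1,A3/A3,5.9,34.2",
    "L010,S03,female,triplet,triplet,101,A1/A1,A3/C3,4.3,26.4"))
}

# Default association dataset reused across assoc tests: one seeded cohort,
# phased, truth attached.  Built once per test run.
assoc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(sim_config(seed = 402))
      ph <- phase_cohort(co$records)
      cache <<- list(cohort = co, phasing = ph,
                     data = assoc_dataset(co$records, ph))
    }
    cache
  }
})

# Association data taken from the generator's hidden truth (no phasing):
# used where the property under test is the model, not the phasing.
truth_assoc_data <- function(cohort) {
  rec <- cohort$records
  m <- match(rec$animal_id, cohort$truth$animal_id)
  rec$diplotype <- cohort$truth$diplotype[m]
  rec
}
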