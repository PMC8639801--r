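# A hand-enumerated 25-visit fixture exercising every cohort rule:
# age and discharged-alive inclusion, window and location exclusions,
# transfer (day 0), day +30 inclusive and day +31 exclusive outcome
# boundaries, planned-readmission (chemotherapy code) skipping, and
# readmissions only via emergency-route visits.
#
# Expected enumeration (window 2017-01-01..2017-12-31, covered region R01):
#   excluded: v08, v09, v21 (age 64); v10 (died); v14, v15, v24 (discharge
#   outside window); v13, v22 (uncovered region R99)  -> 9 exclusions
#   index events (16): pA v01-v07, pC v11, v12, v23, pE v16-v18, pF v19,
#   v20, v25
#   outcome 1: v01 (ER +5), v03 (+30 boundary via v05, v04 on day 0 is a
#   transfer), v04 (+30 via v05), v11 (ER +7), v16 (+19 via v18; the +9
#   chemo visit v17 is planned and skipped), v17 (+10 via v18)
#   outcome 0: v02, v05 (next ER at +31), v06 (only a planned ER follows),
#   v07, v12, v18, v19, v20, v23, v25

cohort_fixture <- function() {
  persons <- rbind(
    fixture_person("pA", yob = 1940, gender = "male", location = "L_R01"),
    fixture_person("pB", yob = 1953, location = "L_R01"),
    fixture_person("pC", yob = 1935, location = "L_R01"),
    fixture_person("pD", yob = 1930, location = "L_R99"),
    fixture_person("pE", yob = 1945, location = "L_R01"),
    fixture_person("pF", yob = 1947, gender = "male", location = "L_R01"))

  V <- fixture_visit
  visits <- rbind(
    V("v01", "pA", "2017-02-01", los = 3),
    V("v02", "pA", "2017-02-09", los = 1, kind = "emergency"),
    V("v03", "pA", "2017-06-01", los = 2),
    V("v04", "pA", "2017-06-03", los = 0, kind = "emergency"),
    V("v05", "pA", "2017-07-03", los = 1, kind = "emergency"),
    V("v06", "pA", "2017-08-04", los = 1, kind = "emergency"),
    V("v07", "pA", "2017-08-15", los = 0, kind = "emergency"),
    V("v08", "pB", "2017-03-01", los = 2),
    V("v09", "pB", "2017-12-30", los = 0),
    V("v10", "pC", "2017-04-01", los = 5, alive = FALSE),
    V("v11", "pC", "2017-05-01", los = 2),
    V("v12", "pC", "2017-05-10", los = 1, kind = "emergency"),
    V("v13", "pD", "2017-07-01", los = 2),
    V("v14", "pE", "2016-12-20", los = 5),
    V("v15", "pE", "2017-12-28", los = 10),
    V("v16", "pE", "2017-09-01", los = 0),
    V("v17", "pE", "2017-09-10", los = 0, kind = "emergency"),
    V("v18", "pE", "2017-09-20", los = 1, kind = "emergency"),
    V("v19", "pF", "2017-11-01", los = 0),
    V("v20", "pF", "2017-03-15", los = 1, kind = "emergency"),
    V("v21", "pB", "2017-06-01", los = 1, kind = "emergency"),
    V("v22", "pD", "2017-08-01", los = 0, kind = "emergency"),
    V("v23", "pC", "2017-03-20", los = 1),
    V("v24", "pA", "2016-01-10", los = 3),
    V("v25", "pF", "2017-12-20", los = 1, kind = "emergency"))

  conditions <- rbind(
    fixture_condition("pA", "I50", "2017-02-01"),   # v01 principal
    fixture_condition("pA", "J44", "2017-06-01"),   # v03 principal
    fixture_condition("pA", "M16", "2017-07-03"),   # v05 principal
    fixture_condition("pA", "I21", "2015-03-01"),   # history: Charlson 1
    fixture_condition("pA", "Z511", "2017-08-15"),  # v07 chemo session
    fixture_condition("pC", "F03", "2017-05-01"),   # v11 principal
    fixture_condition("pC", "I63", "2017-03-20"),   # v23 principal
    fixture_condition("pC", "C78", "2016-06-01"),   # history: Charlson 6
    fixture_condition("pE", "K35", "2017-09-01"),   # v16 principal (other)
    fixture_condition("pE", "Z511", "2017-09-10"))  # v17 chemo session

  bundle <- cdm_bundle(persons = persons, visits = visits,
                       conditions = conditions, drugs = NULL,
                       locations = rbind(fixture_locations("R01"),
                                         fixture_locations("R99")),
                       site_id = "A")
  expected_outcome <- c(
    v01 = 1L, v02 = 0L, v03 = 1L, v04 = 1L, v05 = 0L, v06 = 0L, v07 = 0L,
    v11 = 1L, v12 = 0L, v16 = 1L, v17 = 1L, v18 = 0L, v19 = 0L, v20 = 0L,
    v23 = 0L, v25 = 0L)
  list(bundle = bundle,
       window = as.Date(c("2017-01-01", "2017-12-31")),
       expected_outcome = expected_outcome,
       expected_exclusions = c(kind = 0L, age = 3L, death = 1L,
                               window = 3L, location = 2L),
       expected_readmission_date = c(v01 = "2017-02-09", v03 = "2017-07-03",
                                     v04 = "2017-07-03", v11 = "2017-05-10",
                                     v16 = "2017-09-20", v17 = "2017-09-20"))
}
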