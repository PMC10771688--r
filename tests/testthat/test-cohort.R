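codes <- list(sud_diagnostic_codes = c("304", "305"),
              oat_drug_codes = c("MET-OAT"))

mk_visits <- function(client, dates, code = "304")
  data.frame(client_id = client, prescriber_id = "p1",
             date = as.Date(dates), diag_code = code,
             stringsAsFactors = FALSE)
empty_disp <- data.frame(client_id = character(0), prescriber_id = character(0),
                         date = as.Date(character(0)),
                         drug_code = character(0), stringsAsFactors = FALSE)
empty_acute <- data.frame(client_id = character(0),
                          date = as.Date(character(0)),
                          diag_code = character(0), stringsAsFactors = FALSE)
empty_pn <- data.frame(client_id = character(0), date = as.Date(character(0)),
                       sud_flag = logical(0), stringsAsFactors = FALSE)

test_that("two outpatient visits do not flag a client, three do", {
  two <- flag_sud_clients(empty_disp, mk_visits("c1", c("2019-01-01",
                                                        "2019-02-01")),
                          empty_acute, empty_pn, codes)
  expect_equal(nrow(two), 0L)
  three <- flag_sud_clients(empty_disp,
                            mk_visits("c1", c("2019-01-01", "2019-02-01",
                                              "2019-03-01")),
                            empty_acute, empty_pn, codes)
  expect_equal(three$pathway, "visit-count rule")
  expect_equal(three$first_indication_date, as.Date("2019-03-01"))
})

test_that("three visits on the same date count once", {
  same <- flag_sud_clients(empty_disp,
                           mk_visits("c1", rep("2019-01-01", 3L)),
                           empty_acute, empty_pn, codes)
  expect_equal(nrow(same), 0L)
})

test_that("one SUD-coded acute visit flags; a non-SUD code does not", {
  ac <- data.frame(client_id = "c1", date = as.Date("2018-06-01"),
                   diag_code = "305", stringsAsFactors = FALSE)
  f <- flag_sud_clients(empty_disp, NULL, ac, empty_pn, codes)
  expect_equal(f$pathway, "acute-care rule")
  ac$diag_code <- "250"
  expect_equal(nrow(flag_sud_clients(empty_disp, NULL, ac, empty_pn, codes)),
               0L)
})

test_that("OAT dispensation and perinatal record flag with earliest date winning", {
  disp <- data.frame(client_id = "c1", prescriber_id = "p1",
                     date = as.Date("2019-05-01"), drug_code = "MET-OAT",
                     stringsAsFactors = FALSE)
  pn <- data.frame(client_id = "c1", date = as.Date("2018-01-01"),
                   sud_flag = TRUE, stringsAsFactors = FALSE)
  f <- flag_sud_clients(disp, NULL, empty_acute, pn, codes)
  expect_equal(f$pathway, "perinatal record")
  expect_equal(f$first_indication_date, as.Date("2018-01-01"))
})

test_that("empty inputs give an empty flag table", {
  f <- flag_sud_clients(empty_disp, NULL, empty_acute, empty_pn, codes)
  expect_equal(nrow(f), 0L)
  expect_named(f, c("client_id", "sud_indicated", "first_indication_date",
                    "pathway"))
})

test_that("cohort requires a strictly prior indication", {
  flags <- data.frame(client_id = "c1", sud_indicated = TRUE,
                      first_indication_date = as.Date("2020-06-15"),
                      pathway = "acute-care rule", stringsAsFactors = FALSE)
  d <- data.frame(prescriber_id = "p1", client_id = "c1",
                  date = as.Date("2020-06-10"), stringsAsFactors = FALSE)
  expect_length(build_prescriber_cohort(d, flags), 0L)     # indication later
  d$date <- as.Date("2020-06-15")
  expect_length(build_prescriber_cohort(d, flags), 0L)     # same day
  d$date <- as.Date("2020-06-16")
  expect_equal(as.character(build_prescriber_cohort(d, flags)), "p1")
})

test_that("dispensations outside the study window never qualify", {
  flags <- data.frame(client_id = "c1", sud_indicated = TRUE,
                      first_indication_date = as.Date("2019-01-01"),
                      pathway = "OAT receipt", stringsAsFactors = FALSE)
  d <- data.frame(prescriber_id = "p1", client_id = "c1",
                  date = as.Date("2020-03-26"), stringsAsFactors = FALSE)
  expect_length(build_prescriber_cohort(d, flags), 0L)
  expect_error(build_prescriber_cohort(d, flags,
                                       as.Date(c("2021-01-01", "2020-01-01"))),
               "precedes")
})

test_that("adding records never removes a flag or a cohort member", {
  sim <- tiny_sim()
  d <- sim$data
  half <- d$dispensations[seq_len(nrow(d$dispensations) %/% 2L), ]
  f_half <- flag_sud_clients(half, d$visits, d$acute_visits, d$perinatal)
  f_full <- flag_sud_clients(d$dispensations, d$visits, d$acute_visits,
                             d$perinatal)
  expect_true(all(f_half$client_id %in% f_full$client_id))
  c_half <- build_prescriber_cohort(half, f_full)
  c_full <- build_prescriber_cohort(d$dispensations, f_full)
  expect_true(all(c_half %in% c_full))
})

test_that("cohort equals a brute-force recount over emitted records", {
  sim <- tiny_sim()
  d <- sim$data
  flags <- flag_sud_clients(d$dispensations, d$visits, d$acute_visits,
                            d$perinatal)
  cohort <- build_prescriber_cohort(d$dispensations, flags)
  ind <- stats::setNames(flags$first_indication_date, flags$client_id)
  dd <- d$dispensations
  in_win <- as.Date(dd$date) >= as.Date("2020-03-27") &
    as.Date(dd$date) <= as.Date("2021-08-31")
  manual <- sort(unique(dd$prescriber_id[
    in_win & !is.na(ind[dd$client_id]) & ind[dd$client_id] < as.Date(dd$date)]))
  expect_equal(as.character(cohort), manual)
  att <- attr(cohort, "attachments")
  expect_true(all(table(att$prescriber_id) >= 1L))
})

test_that("code sets load and validate from YAML", {
  cs <- load_code_sets()
  expect_true(length(cs$sud_diagnostic_codes) > 0L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("sud_diagnostic_codes: []\noat_drug_codes: [x]", bad)
  expect_error(load_code_sets(bad), "missing or empty")
})
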