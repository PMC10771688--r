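test_that("the 3-month gap rule fires at the first gap month", {
  # PSS only in June 2020 (month 4); July-September empty -> event July
  expect_equal(discontinuation_month(4L, n_months = 18L), 5L)
  # prescribing every month -> no event
  expect_true(is.na(discontinuation_month(4:18, n_months = 18L)))
  # PSS in June 2021 (month 16): only 2 observable empty months -> censored
  expect_true(is.na(discontinuation_month(16L, n_months = 18L)))
  # gap inside follow-up with later resumption does not block the event
  expect_equal(discontinuation_month(c(4L, 12L), n_months = 18L), 5L)
  expect_error(discontinuation_month(integer(0), 18L), "no PSS months")
})

test_that("discontinuation outcome is 1 only at the event month", {
  expect_equal(discontinuation_outcome(4L, month = 5L, n_months = 18L), 1L)
  expect_equal(discontinuation_outcome(4L, month = 4L, n_months = 18L), 0L)
  expect_error(discontinuation_outcome(4L, month = 3L, n_months = 18L),
               "precedes")
})

test_that("gap rule matches run-scanning enumeration over all 6-month patterns", {
  for (bits in 1:63) {
    months <- which(as.logical(bitwAnd(bits, 2^(0:5))))
    expect_equal(discontinuation_month(months, n_months = 6L),
                 oracle_discontinuation(months, n_months = 6L),
                 info = paste("pattern", bits))
  }
})

test_that("adoption outcome censors at the event", {
  expect_equal(adoption_outcome(5L, 3:6), c(0L, 0L, 1L, 0L))
  expect_equal(adoption_outcome(NA_integer_, 3L), 0L)
})

test_that("quartile machinery bins printed and empirical cuts correctly", {
  cuts <- quartile_cuts(mode = "printed", kind = "adoption",
                        variable = "caseload")
  expect_equal(as.character(apply_quartiles(c(2, 3, 6, 7, 13, 14), cuts)),
               c("Q1", "Q2", "Q2", "Q3", "Q3", "Q4"))
  ecuts <- quartile_cuts(mode = "printed", kind = "discontinuation",
                         variable = "experience")
  expect_equal(as.character(apply_quartiles(c(3.9, 4, 8.29, 8.3, 17.39, 17.4),
                                            ecuts, right = FALSE)),
               c("Q1", "Q2", "Q2", "Q3", "Q3", "Q4"))
})

test_that("empirical quartile bins are balanced on distinct values", {
  for (n in c(23L, 40L, 101L)) {
    x <- sample(seq_len(1000L), n)
    b <- table(apply_quartiles(x, quartile_cuts(x, "empirical")))
    expect_lte(max(b) - min(b), 1L)
    expect_equal(sum(b), n)
  }
})

test_that("case-mix aggregates match a brute-force recount", {
  study <- tiny_study()
  d <- study$data
  m <- 10L
  cm <- study$case_mix[[m]]
  mend <- month_end_date(m)
  dd <- d$dispensations
  dm <- month_index(dd$date)
  for (p in sample(study$cohort, 10L)) {
    cls <- unique(dd$client_id[dm == m & dd$prescriber_id == p &
                                 dd$client_id %in% study$flags$client_id])
    row <- cm[cm$prescriber_id == p, ]
    expect_equal(row$caseload, length(cls))
    if (length(cls) > 0L) {
      cl <- d$clients[match(cls, d$clients$client_id), ]
      expect_equal(row$pct_social_assistance,
                   100 * mean(cl$social_assistance_months > 0))
      expect_equal(row$pct_age40,
                   100 * mean(as.integer(format(mend, "%Y")) -
                                cl$birth_year >= 40L))
      benzo <- unique(dd$client_id[dd$med_class == "benzodiazepine" &
                                     dm >= m - 11L & dm <= m])
      expect_equal(row$pct_benzo, 100 * mean(cls %in% benzo))
      expect_equal(row$covid_client,
                   as.integer(any(!is.na(cl$covid_diagnosis_date) &
                                    cl$covid_diagnosis_date <= mend)))
    } else {
      expect_true(all(unlist(row[, c("pct_age40", "pct_benzo",
                                     "pct_social_assistance",
                                     "pct_overdose_12m")]) == 0))
    }
  }
})

test_that("adoption panel spans the documented risk window", {
  study <- tiny_study()
  p <- study$adoption_panel
  ad <- study$adoption
  # innovators contribute no rows
  innov <- ad$prescriber_id[ad$status == "innovator"]
  expect_false(any(p$prescriber_id %in% innov))
  # one row per prescriber-month, rows stop at the initiation month
  expect_equal(anyDuplicated(p[, c("prescriber_id", "month")]), 0L)
  early <- ad[ad$status == "early adopter", ]
  for (i in seq_len(nrow(early))) {
    rows <- p[p$prescriber_id == early$prescriber_id[i], ]
    expect_equal(rows$month, seq.int(3L, early$first_pss_month[i]))
    expect_equal(rows$outcome, as.integer(rows$month ==
                                            early$first_pss_month[i]))
  }
  # non-adopters carry zero outcomes through study end
  non <- ad$prescriber_id[ad$status == "non-adopter"]
  expect_true(all(p$outcome[p$prescriber_id %in% non] == 0L))
  # total row count equals the brute-force sum of months at risk
  expected <- sum(ifelse(is.na(ad$first_pss_month), 18L - 2L,
                         ifelse(ad$first_pss_month <= 2L, 0L,
                                ad$first_pss_month - 2L)))
  expect_equal(nrow(p), expected)
})

test_that("discontinuation panel runs from initiation to event or censoring", {
  study <- tiny_study()
  p <- study$discontinuation_panel
  expect_true(all(p$outcome %in% 0:1))
  expect_true(all(tapply(p$outcome, p$prescriber_id, sum) <= 1L))
  # outcome-1 rows are terminal rows at the recomputed event month
  ev_rows <- p[p$outcome == 1L, ]
  for (i in seq_len(nrow(ev_rows))) {
    id <- ev_rows$prescriber_id[i]
    expect_equal(ev_rows$month[i],
                 discontinuation_month(study$pss_months[[id]], 18L))
    expect_equal(max(p$month[p$prescriber_id == id]), ev_rows$month[i])
  }
})

test_that("month-m rows use only information through m-1", {
  study <- tiny_study()
  d <- study$data$dispensations
  for (m in c(5L, 9L, 14L)) {
    # recompute every lagged regressor after truncating the record stream at
    # the end of m-1; month-m rows must be unchanged
    trunc <- d[month_index(d$date) <= m - 1L, ]
    snap <- build_monthly_network(trunc, study$cohort, m - 1L)
    met <- node_metrics(snap)
    cls <- classify_dispensations(trunc)
    ad <- derive_adoption(cls, study$cohort)
    adopters <- ad$prescriber_id[!is.na(ad$first_pss_month)]
    e <- peer_exposure(snap, adopters)
    cm <- aggregate_case_mix(trunc, study$data$clients, study$flags,
                             study$cohort, m - 1L)
    rows <- study$adoption_panel[study$adoption_panel$month == m, ]
    expect_gt(nrow(rows), 0L)
    mi <- match(rows$prescriber_id, met$prescriber_id)
    expect_equal(rows$clustering, met$clustering[mi])
    expect_equal(rows$adjusted_strength, met$adjusted_strength[mi])
    expect_equal(rows$exposure, unname(e[rows$prescriber_id]))
    xi <- match(rows$prescriber_id, cm$prescriber_id)
    expect_equal(rows$caseload, cm$caseload[xi])
    expect_equal(rows$pct_social_assistance, cm$pct_social_assistance[xi])
  }
})

test_that("client-load inclusion thresholds drop low-caseload rows", {
  sim <- tiny_sim()
  s5 <- pss_study(sim$data, pss_config(min_sud_clients = 5L),
                  keep_snapshots = FALSE)
  expect_true(all(s5$adoption_panel$caseload >= 5L))
  expect_lt(nrow(s5$adoption_panel), nrow(tiny_study()$adoption_panel))
})
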