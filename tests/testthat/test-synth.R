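test_that("population counts and degenerate specialty mixes are honoured", {
  cfg <- sim_config(n_prescribers = 100L, n_clients = 200L, seed = 1L)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$prescribers), 100L)
  expect_equal(nrow(pop$clients), 200L)
  expect_true(all(pop$prescribers$region %in%
                    c("Interior", "Fraser", "Vancouver Coastal",
                      "Vancouver Island", "Northern", "Unknown")))

  mix <- c("general practice" = 1, "nurse practitioner" = 0,
           "psychiatry" = 0, "other" = 0, "unknown" = 0)
  pop1 <- simulate_population(sim_config(n_prescribers = 50L,
                                         n_clients = 50L,
                                         specialty_mix = mix, seed = 2L))
  expect_true(all(pop1$prescribers$specialty == "general practice"))
})

test_that("specialty frequencies are within 3 binomial SEs of the mix", {
  cfg <- sim_config(n_prescribers = 2000L, n_clients = 100L, seed = 7L)
  pop <- simulate_population(cfg)
  for (sp in names(cfg$specialty_mix)) {
    p <- cfg$specialty_mix[[sp]]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(pop$prescribers$specialty == sp) - p), 3 * se + 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(specialty_mix = c("general practice" = 0.5,
                                            "nurse practitioner" = 0.2,
                                            "psychiatry" = 0.2,
                                            "other" = 0.2,
                                            "unknown" = 0.2)),
               "probability vector")
  expect_error(sim_config(n_months = 3L), "3-month gap")
  expect_error(sim_config(n_innovator_seed = 10L, n_prescribers = 5L),
               "n_innovator_seed")
  expect_error(sim_config(sharing_rate = 0.5), "sharing_rate")
})

test_that("zero region mixing keeps the projected graph within regions", {
  cfg <- sim_config(n_prescribers = 60L, n_clients = 200L,
                    region_mixing = 0, seed = 3L)
  pop <- simulate_population(cfg)
  aff <- simulate_affiliation(pop, cfg)
  reg <- pop$prescribers$region
  names(reg) <- pop$prescribers$prescriber_id
  net <- build_monthly_network(aff$dispensations,
                               pop$prescribers$prescriber_id, cfg$n_months)
  expect_true(all(reg[net$edges$a] == reg[net$edges$b]))
})

test_that("one prescriber per client means an edgeless projection", {
  cfg <- sim_config(n_prescribers = 40L, n_clients = 120L,
                    sharing_rate = 1.0, seed = 4L)
  pop <- simulate_population(cfg)
  aff <- simulate_affiliation(pop, cfg)
  net <- build_monthly_network(aff$dispensations,
                               pop$prescribers$prescriber_id, cfg$n_months)
  expect_equal(nrow(net$edges), 0L)
})

test_that("clients see about sharing_rate - 1 additional prescribers", {
  cfg <- sim_config(seed = 3L)
  pop <- simulate_population(cfg)
  aff <- simulate_affiliation(pop, cfg)
  per_client <- tapply(aff$attachments$prescriber_id,
                       aff$attachments$client_id,
                       function(x) length(unique(x)))
  extra <- mean(per_client) - 1
  expect_lt(abs(extra - (cfg$sharing_rate - 1)),
            0.2 * (cfg$sharing_rate - 1))
})

test_that("every attachment surfaces in the dispensation stream", {
  sim <- tiny_sim()
  win <- sim$data$dispensations[
    as.Date(sim$data$dispensations$date) >= as.Date("2020-03-27"), ]
  seen <- unique(paste(win$prescriber_id, win$client_id))
  aff <- simulate_affiliation(simulate_population(sim$config), sim$config)
  expect_true(all(paste(aff$attachments$prescriber_id,
                        aff$attachments$client_id) %in% seen))
})

test_that("truth ledger is internally consistent", {
  truth <- tiny_sim()$truth
  cfg <- tiny_sim()$config
  has_both <- !is.na(truth$discontinuation_month)
  expect_true(all(truth$adoption_month[has_both] <
                    truth$discontinuation_month[has_both]))
  expect_true(all(truth$adoption_month[truth$seeds] %in%
                    cfg$innovation_months))
  expect_true(all(is.na(truth$cessation_month) |
                    truth$cessation_month > truth$adoption_month,
                  na.rm = TRUE))
})

test_that("PSS dispensations respect the truth ledger's activity spans", {
  sim <- tiny_sim()
  cls <- classify_dispensations(sim$data$dispensations)
  pss <- cls[cls$is_pss, ]
  m <- month_index(pss$date)
  ad <- sim$truth$adoption_month[pss$prescriber_id]
  ce <- sim$truth$cessation_month[pss$prescriber_id]
  expect_true(all(!is.na(ad)))
  expect_true(all(m >= ad))
  expect_true(all(is.na(ce) | m < ce))
})

test_that("a very negative intercept with zero exposure effect stops diffusion at the seeds", {
  cfg <- sim_config(n_prescribers = 60L, n_clients = 200L,
                    adopt_intercept = -30, adopt_beta_exposure = 0,
                    adopt_beta_caseload = 0, n_innovator_seed = 4L,
                    seed = 9L)
  sim <- simulate_pss_study(cfg)
  expect_equal(sum(!is.na(sim$truth$adoption_month)), 4L)
})

test_that("cumulative adoption is non-decreasing month over month", {
  truth <- tiny_sim()$truth
  ad <- truth$adoption_month
  cum <- vapply(1:18, function(m) sum(!is.na(ad) & ad <= m), integer(1L))
  expect_true(all(diff(cum) >= 0L))
})

test_that("identical seeds regenerate byte-identical study tables", {
  cfg <- sim_config(n_prescribers = 50L, n_clients = 180L,
                    n_innovator_seed = 3L, seed = 77L)
  s1 <- simulate_pss_study(cfg)
  s2 <- simulate_pss_study(cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$adoption_month, s2$truth$adoption_month)
})

test_that("study tables and truth survive a text round trip", {
  sim <- tiny_sim()
  dir <- withr::local_tempdir()
  write_study_data(sim, dir)
  back <- read_study_data(dir)
  for (nm in names(sim$data))
    expect_equal(back[[nm]], sim$data[[nm]], ignore_attr = TRUE)
  tr <- read_simulation_truth(file.path(dir, "simulation_truth.txt"))
  expect_equal(tr$true_coefficients, sim$truth$true_coefficients,
               tolerance = 1e-9)
  expect_identical(tr$adoption_month, sim$truth$adoption_month)
})
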