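test_that("drug costs reproduce hand arithmetic from the printed prices", {
  par <- uninflated_parameters()
  # first prucalopride cycle: 28-day pack plus one prescription fee
  expect_equal(drug_cost_per_cycle("prucalopride", "START_W1_4", 1, par),
               2.77 * 28 + 6.35)
  # later start cycles at the post-pack daily rate over 30.4 days
  expect_equal(drug_cost_per_cycle("prucalopride", "START_W5_8", 2, par),
               2.49 * 30.4 + 6.35)
  # year-1 maintenance: 130 treatment days spread over 9 cycles,
  # one fee per 28 treatment days; the annual total is conserved
  m1 <- drug_cost_per_cycle("prucalopride", "MAINTENANCE", 5, par)
  expect_equal(9 * m1, 130 * 2.49 + (130 / 28) * 6.35)
  # year 2+: the 220-day annual cap over 12 cycles
  m2 <- drug_cost_per_cycle("prucalopride", "MAINTENANCE", 15, par)
  expect_equal(12 * m2, 220 * 2.49 + (220 / 28) * 6.35)
  # laxative arm: weighted basket for any state
  expect_equal(drug_cost_per_cycle("laxative", "MAINTENANCE", 4, par),
               0.4538 * 30.4 + 6.35)
  expect_equal(drug_cost_per_cycle("laxative", "DROPOUT", 8, par),
               0.3938 * 30.4 + 6.35)
  # prucalopride-arm switch states buy laxatives, not prucalopride
  expect_equal(drug_cost_per_cycle("prucalopride", "SWITCH_W5_8", 3, par),
               0.3938 * 30.4 + 6.35)
  # 1.5 mg dose scenario prices the day at the mean of the 1 and 2 mg rates
  par15 <- par
  par15$analysis$dose <- "1.5mg"
  expect_equal(drug_cost_per_cycle("prucalopride", "START_W1_4", 1, par15),
               (2.77 + 1.95) / 2 * 28 + 6.35)
  expect_error(drug_cost_per_cycle("prucalopride", "NOWHERE", 1, par),
               "unknown state")
})

test_that("annual prucalopride spend never exceeds the cap", {
  par <- default_parameters()
  par$analysis$horizon_months <- 36
  b_after <- drug_cost_per_cycle("prucalopride", "MAINTENANCE", 15, par)
  cap_total <- 220 * 2.49 * 1.013 + (220 / 28) * 6.35
  expect_lte(12 * b_after, cap_total + 1e-9)
})

test_that("resource costs are the phase quantities times the tariffs", {
  par <- uninflated_parameters()
  # maintenance column, specialist at the DBC polyclinic tariff,
  # procedures at their configured (zero) prices
  expected <- 0.4 * 195.89 + 0.4 * 14 + 0.7 * 28 + 0.5 * 14 +
    0.2 * 10 + 0.3 * 27
  expect_equal(resource_cost_per_cycle("MAINTENANCE", par), expected)
  # zero profile costs nothing
  par0 <- par
  par0$resources$phases$maintenance[] <- 0
  expect_equal(resource_cost_per_cycle("MAINTENANCE", par0), 0)
  # linearity: doubling every tariff doubles the cost
  par2 <- par
  for (nm in setdiff(names(par2$costs$units), "costing_year"))
    par2$costs$units[[nm]] <- 2 * par2$costs$units[[nm]]
  expect_equal(resource_cost_per_cycle("MAINTENANCE", par2), 2 * expected)
  # configured procedure prices enter the sum
  parp <- par
  parp$costs$procedures[["colonoscopy"]] <- 100
  expect_equal(resource_cost_per_cycle("MAINTENANCE", parp),
               expected + 0.4 * 100)
})

test_that("complication costing matches hand arithmetic and scales", {
  par <- phase_mapped_parameters()
  # single complication, start weeks 1-4: monthly probability times the
  # consult and expected hospitalization cost of one event
  par$complications$items <- par$complications$items["hemorrhoids"]
  event <- 2.2 * 28 + 1.5 * 195.89 + 0.017 * 3102
  expect_equal(complication_cost_per_cycle("START_W1_4", par),
               0.19 * event)
  # weeks 5-12 column is a two-month period
  expect_equal(complication_cost_per_cycle("START_W5_8", par),
               (1 - 0.78^0.5) * event)
  # off switch removes the component everywhere
  par_off <- par
  par_off$analysis$include_complications <- FALSE
  for (s in health_states())
    expect_equal(complication_cost_per_cycle(s, par_off), 0)
  # near-linearity in the period probability for small probabilities
  par_eps <- par
  par_eps$complications$items$hemorrhoids$prob[["weeks1_4"]] <- 0.19 / 100
  expect_equal(complication_cost_per_cycle("START_W1_4", par_eps),
               0.19 / 100 * event, tolerance = 1e-3)
  # default map: no explicit complication costing outside the
  # failure/drop-out pathway
  pd <- uninflated_parameters()
  expect_equal(complication_cost_per_cycle("MAINTENANCE", pd), 0)
  expect_gt(complication_cost_per_cycle("DROPOUT", pd), 0)
})

test_that("length-of-stay hospital costing is anchored to the DBC tariff", {
  par <- phase_mapped_parameters()
  base <- complication_cost_per_cycle("DROPOUT", par)
  par_los <- par
  par_los$analysis$hospital_costing <- "los_daily"
  alt <- complication_cost_per_cycle("DROPOUT", par_los)
  # same order of magnitude; exact equality only at the mean stay
  expect_gt(alt, 0)
  expect_lt(abs(alt - base) / base, 0.35)
  # rescaling every stay leaves the anchored cost unchanged ...
  par2 <- par_los
  for (nm in names(par2$complications$items))
    par2$complications$items[[nm]]$los_days <-
      2 * par2$complications$items[[nm]]$los_days
  expect_equal(complication_cost_per_cycle("DROPOUT", par2), alt)
  # ... while shifting a single stay changes the complication mix
  par3 <- par_los
  par3$complications$items$rectal_prolapse$los_days <- 20
  expect_false(isTRUE(all.equal(
    complication_cost_per_cycle("DROPOUT", par3), alt)))
})

test_that("transport costs round-trip distances for face-to-face visits", {
  par <- uninflated_parameters()
  par$analysis$complication_states[] <- "none"  # isolate the phase part
  expected <- 2 * 0.20 * (0.4 * 7.0 + 0.7 * 1.1 + 0.2 * 1.1 + 0.3 * 1.7)
  expect_equal(transport_cost_per_cycle("MAINTENANCE", par), expected)
  # telephone-only contact costs nothing
  par0 <- par
  par0$resources$phases$maintenance[] <- 0
  par0$resources$phases$maintenance[["pcp_phone"]] <- 2
  expect_equal(transport_cost_per_cycle("MAINTENANCE", par0), 0)
  # exclusion scenario
  parx <- par
  parx$analysis$include_transport <- FALSE
  expect_equal(transport_cost_per_cycle("MAINTENANCE", parx), 0)
  # parking scenario adds the surcharge per visit
  park <- par
  park$analysis$include_parking <- TRUE
  expect_equal(transport_cost_per_cycle("MAINTENANCE", park),
               expected + (0.4 + 0.7 + 0.2 + 0.3) * 3.00)
})

test_that("indirect costs apply only to non-responders in the scenario", {
  par <- default_parameters()
  expect_equal(indirect_cost_per_cycle("START_W1_4", par), 0)  # flag off
  par$analysis$include_indirect <- TRUE
  expect_equal(indirect_cost_per_cycle("START_W1_4", par),
               0.87 * 0.12 * 2.4 * 8 * 26.99)
  expect_equal(indirect_cost_per_cycle("MAINTENANCE", par), 0)
  expect_equal(indirect_cost_per_cycle("SWITCH_MAINTENANCE", par), 0)
  expect_gt(indirect_cost_per_cycle("DROPOUT", par), 0)
})

test_that("failure work-up prices the after-failure practice pattern", {
  par <- uninflated_parameters()
  expect_equal(failure_workup_cost(par),
               0.282 * 195.89 + 0.049 * 3102)
  par$analysis$failure_workup <- "off"
  expect_equal(failure_workup_cost(par), 0)
})

test_that("cost profiles compose the components; flags only remove cost", {
  par <- default_parameters()
  res <- run_base_case(par)
  # switching any exclusion flag on can only lower an arm's total
  for (delta in list(c("include_complications", FALSE),
                     c("include_transport", FALSE))) {
    p2 <- par
    p2$analysis[[delta[[1]]]] <- as.logical(delta[[2]])
    r2 <- run_base_case(p2)
    expect_lte(r2$cost[1], res$cost[1])
    expect_lte(r2$cost[2], res$cost[2])
  }
  # indirect costs only add
  p3 <- par
  p3$analysis$include_indirect <- TRUE
  r3 <- run_base_case(p3)
  expect_gte(r3$cost[1], res$cost[1])
  # zeroed tariffs, prices and fees zero the non-drug components
  p0 <- par
  for (nm in setdiff(names(p0$costs$units), "costing_year"))
    p0$costs$units[[nm]] <- 0
  p0$costs$transport$cost_per_km <- 0
  prof <- build_cost_profiles(p0)
  expect_equal(unname(prof$fixed[, "resource"]), rep(0, 9))
  expect_equal(unname(prof$fixed[, "complication"]), rep(0, 9))
  expect_equal(unname(prof$fixed[, "transport"]), rep(0, 9))
  # ledger totals equal the sum of components
  costs <- accrue_costs(run_base_case(par, keep_traces = TRUE)$
                          traces$prucalopride, "prucalopride", par)
  expect_equal(sum(costs$component), costs$total, tolerance = 1e-9)
  expect_equal(sum(costs$ledger$cost), costs$total, tolerance = 1e-9)
})
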