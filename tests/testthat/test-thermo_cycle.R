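test_that("cycle components reproduce the published worked examples", {
  # wild type
  expect_equal(delta_g_gas(-2949799.37, -2949931.72), -132.35)
  expect_equal(delta_delta_g_sol(-122.04, -82.05), 39.99)
  expect_equal(reduction_free_energy(-132.35, 40.00), -92.35)
  expect_equal(round_half_up(redox_potential(-92.35, 1)), 4.00)
  expect_equal(reference_potential(4.00, 4.44), -0.44)
  # variant (sub-row inputs land within the printed rounding granularity)
  expect_equal(delta_g_gas(-2984537.94, -2984656.64), -118.70)
  expect_equal(delta_delta_g_sol(-88.45, -85.04), 3.41)
  expect_equal(reduction_free_energy(-118.69, 3.42), -115.27)
  expect_equal(round_half_up(redox_potential(-115.27, 1)), 5.00)
  expect_equal(reference_potential(5.00, 4.44), 0.56)

  expect_equal(delta_g_gas(-12.5, -12.5), 0)
  expect_equal(redox_potential(0, 1), 0)
  expect_error(redox_potential(-92.35, 0), "positive integer")
})

test_that("run_cycle composes the operations and validates its inputs", {
  recs <- read_energy_table(make_paper_energy_table())
  is_wt <- vapply(recs, function(r) r$system == "WT", TRUE)
  res <- run_cycle(recs[is_wt])
  expect_s3_class(res, "qmx_redox_result")
  expect_equal(res$dG_total, res$dG_gas + res$ddG_solv)  # exact additivity
  expect_equal(res$rounded$dG_gas, -132.35)
  # the published per-state rows carry 0.01 kcal/mol of print rounding
  # (their ddG_solv sums to 39.99 where the source tabulates 40.00), which
  # leaves E_calc one rounding quantum above the tabulated -0.44
  expect_equal(res$E_calc, 92.36 / 23.060548 - 4.44, tolerance = 1e-9)
  expect_equal(res$rounded$E_calc, -0.43)

  # antisymmetry under ox/red exchange
  ox <- recs[is_wt][[1]]; red <- recs[is_wt][[2]]
  swapped <- list(energy_record(ox$system, "red", ox$G_gas, ox$dG_solv),
                  energy_record(red$system, "ox", red$G_gas, red$dG_solv))
  res_sw <- run_cycle(swapped)
  expect_equal(res_sw$dG_total, -res$dG_total)
  expect_equal(res_sw$dE, -res$dE)

  expect_error(run_cycle(recs[is_wt][1]), "exactly one")
  mixed <- list(recs[[1]], recs[[4]])
  expect_error(run_cycle(mixed), "different systems")
})

test_that("antisymmetry and monotonicity hold on random record pairs", {
  set.seed(2024)
  for (k in 1:25) {
    g <- rnorm(2, -2.9e6, 1e3); sv <- rnorm(2, -100, 20)
    recs <- list(energy_record("sys", "ox", g[1], sv[1]),
                 energy_record("sys", "red", g[2], sv[2]))
    swp <- list(energy_record("sys", "red", g[1], sv[1]),
                energy_record("sys", "ox", g[2], sv[2]))
    a <- run_cycle(recs); b <- run_cycle(swp)
    expect_equal(b$dG_gas, -a$dG_gas, tolerance = 1e-9)
    expect_equal(b$ddG_solv, -a$ddG_solv, tolerance = 1e-9)
    expect_equal(b$dG_total, -a$dG_total, tolerance = 1e-9)
    expect_equal(b$dE, -a$dE, tolerance = 1e-9)
  }
  # E_calc strictly decreases as dG_total increases
  dgs <- sort(runif(20, -200, 200))
  es <- vapply(dgs, function(d) reference_potential(redox_potential(d)), 0)
  expect_true(all(diff(es) < 0))
})

test_that("unit conversions are exact and round-trip to 1e-9 relative", {
  expect_equal(convert_energy(1, "hartree", "kcal/mol"), 627.509474)
  expect_equal(convert_energy(92.35, "kcal/mol", "eV"), 92.35 / 23.060548)
  expect_equal(convert_energy(1, "kcal/mol", "kJ/mol"), 4.184)
  expect_equal(convert_energy(0, "eV", "hartree"), 0)

  set.seed(5)
  units <- c("hartree", "kcal/mol", "ev", "kj/mol")
  for (k in 1:40) {
    u <- sample(units, 2)
    v <- runif(1, -1e4, 1e4)
    back <- convert_energy(convert_energy(v, u[1], u[2]), u[2], u[1])
    expect_equal(back, v, tolerance = 1e-9)
  }
  expect_error(convert_energy(1, "hartree", "furlongs"), "unknown energy unit")
})

test_that("rounding is half-away-from-zero and the SHE sweep honours bounds", {
  expect_equal(round_half_up(c(2.675, -2.675, 0.005, -0.005), 2),
               c(2.68, -2.68, 0.01, -0.01))
  recs <- read_energy_table(make_paper_energy_table())
  res <- run_cycle(recs[vapply(recs, function(r) r$system == "WT", TRUE)])
  sw <- she_sweep(res)
  expect_equal(min(sw$she), 4.28)
  expect_equal(max(sw$she), 4.74)
  expect_equal(sw$E_calc, res$dE - sw$she)
})
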