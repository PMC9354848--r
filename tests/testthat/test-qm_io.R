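toy_geometry <- function(frozen = c(FALSE, TRUE, FALSE)) {
  data.frame(element = c("O", "H", "H"),
             x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0,
             frozen = frozen, stringsAsFactors = FALSE)
}

test_that("deck emission encodes level, charge/multiplicity and freeze flags", {
  s <- make_t1_site()
  cl <- carve_cluster(s, find_metal_sites(s)[[1]], cueo_t1_preset())
  decks <- cluster_decks(cl)
  expect_length(decks, 6)
  expect_setequal(names(decks),
                  c("ox_opt_freq", "ox_sp_gas", "ox_sp_solvent",
                    "red_opt_freq", "red_sp_gas", "red_sp_solvent"))

  ox <- strsplit(decks$ox_opt_freq, "\n")[[1]]
  expect_match(ox[1], "^# opt freq B3LYP/6-311G\\*")
  expect_match(ox[1], "EmpiricalDispersion=GD3BJ")
  expect_match(ox[1], "SCRF=\\(SMD,Solvent=Water\\)")
  expect_identical(ox[5], "1 2")
  red <- strsplit(decks$red_sp_gas, "\n")[[1]]
  expect_match(red[1], "^# M062X/def2TZVP")
  expect_false(grepl("SCRF", red[1]))
  expect_identical(red[5], "0 1")

  # one Cartesian line per atom; frozen flag -1 on the alpha carbons
  coords <- ox[6:(5 + nrow(cl$atoms))]
  flags <- as.integer(sub("^\\S+\\s+(-?\\d+)\\s.*", "\\1", coords))
  expect_equal(sum(flags == -1L), sum(cl$atoms$frozen))
  expect_true(all(flags %in% c(-1L, 0L)))

  # byte-determinism
  expect_identical(cluster_decks(cl)$ox_opt_freq, decks$ox_opt_freq)
})

test_that("charge/multiplicity parity violations are rejected", {
  g <- toy_geometry()
  expect_error(qm_job_spec("sp_gas", charge = 0, multiplicity = 2, g),
               "inconsistent with multiplicity")
  expect_silent(qm_job_spec("sp_gas", charge = 0, multiplicity = 1, g))
  expect_silent(qm_job_spec("sp_gas", charge = 1, multiplicity = 2, g))
  expect_error(qm_job_spec("sp_gas", charge = 0, multiplicity = 0, g),
               ">= 1")
})

test_that("parse_log captures the last SCF energy, Gibbs energy and status", {
  log1 <- make_mock_log("sp_gas", scf = -3025.123456)
  p1 <- parse_log(log1)
  expect_equal(p1$final_scf_energy, -3025.123456)
  expect_true(is.na(p1$gibbs_free_energy))
  expect_true(p1$normal_termination)
  expect_identical(p1$method, "M062X")

  log2 <- make_mock_log("opt_freq", scf = -3025.987654,
                        gibbs = -3025.543210, method = "B3LYP",
                        basis = "6-311G*")
  p2 <- parse_log(log2)
  expect_equal(p2$final_scf_energy, -3025.987654)
  expect_equal(p2$gibbs_free_energy, -3025.543210)

  # truncated log: abnormal termination, energies still recovered
  trunc <- strsplit(log1, "\n")[[1]]
  trunc <- trunc[!grepl("Normal termination", trunc)]
  expect_warning(p3 <- parse_log(trunc), "termination")
  expect_false(p3$normal_termination)

  expect_error(suppressWarnings(parse_log("garbage line")), "no SCF energy")
})

test_that("energy tables normalise units and validate completeness", {
  recs <- read_energy_table(make_paper_energy_table())
  expect_length(recs, 4)
  expect_setequal(vapply(recs, function(r) paste(r$system, r$state), ""),
                  c("WT ox", "WT red", "L502K ox", "L502K red"))

  # identical energies expressed in Hartree agree after conversion
  h <- 627.509474
  csv_h <- paste(
    "system,state,G_gas,dG_solv,unit",
    sprintf("WT,ox,%.10f,%.10f,hartree", -2949799.37 / h, -122.04 / h),
    sprintf("WT,red,%.10f,%.10f,hartree", -2949931.72 / h, -82.05 / h),
    sep = "\n")
  recs_h <- read_energy_table(csv_h)
  expect_equal(recs_h[[1]]$G_gas, -2949799.37, tolerance = 1e-6 / 3e6)
  expect_equal(recs_h[[2]]$dG_solv, -82.05, tolerance = 1e-6)

  # JSON input is accepted
  js <- jsonlite::toJSON(data.frame(
    system = "X", state = c("ox", "red"), G_gas = c(-10, -20),
    dG_solv = c(-1, -2), unit = "kcal/mol"))
  expect_length(read_energy_table(as.character(js)), 2)

  only_ox <- paste("system,state,G_gas,dG_solv,unit",
                   "WT,ox,-1,-1,kcal/mol", sep = "\n")
  expect_error(read_energy_table(only_ox), "missing an 'red'")
  bad_unit <- paste("system,state,G_gas,dG_solv,unit",
                    "WT,ox,-1,-1,furlongs", "WT,red,-2,-2,furlongs",
                    sep = "\n")
  expect_error(read_energy_table(bad_unit), "unknown unit")
})

test_that("logs_to_record composes gas and solvation energies correctly", {
  e_opt <- -3025.400000; g_opt <- -3025.150000   # thermal corr = +0.25 Ha
  e_gas <- -3025.900000; e_sol <- -3025.950000
  rec <- logs_to_record(
    "WT", "ox",
    opt_freq = parse_log(make_mock_log("opt_freq", e_opt, g_opt)),
    sp_gas = parse_log(make_mock_log("sp_gas", e_gas)),
    sp_solvent = parse_log(make_mock_log("sp_solvent", e_sol))
  )
  h <- 627.509474
  expect_equal(rec$G_gas, (e_gas + 0.25) * h, tolerance = 1e-9)
  expect_equal(rec$dG_solv, (e_sol - e_gas) * h, tolerance = 1e-9)

  rec2 <- logs_to_record(
    "WT", "ox",
    opt_freq = parse_log(make_mock_log("opt_freq", e_opt, g_opt)),
    sp_gas = parse_log(make_mock_log("sp_gas", e_gas)),
    sp_solvent = parse_log(make_mock_log("sp_solvent", e_sol)),
    thermal = FALSE
  )
  expect_equal(rec2$G_gas, e_gas * h, tolerance = 1e-9)
})
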