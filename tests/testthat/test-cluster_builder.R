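test_that("find_metal_sites matches elements and orders by serial", {
  s <- make_t1_site()
  sites <- find_metal_sites(s)
  expect_length(sites, 1)
  expect_identical(sites[[1]]$metal$element, "CU")
  expect_equal(sites[[1]]$oxidized_charge, 2L)
  expect_equal(sites[[1]]$reduced_charge, 1L)

  expect_length(find_metal_sites(s, "ZN"), 0)

  # four coppers in one structure, scrambled record order
  lines <- vapply(c(3L, 1L, 4L, 2L), function(i) {
    pdb_line(i, "CU", "CU", "A", 600L + i, i * 5, 0, 0,
             element = "CU", record = "HETATM")
  }, "")
  s4 <- read_structure(lines)
  sites4 <- find_metal_sites(s4)
  expect_length(sites4, 4)
  expect_equal(vapply(sites4, function(x) x$metal$serial, 0), 1:4)
})

test_that("coordination shell returns donors within cutoff, sorted", {
  s <- make_t1_site()
  site <- find_metal_sites(s)[[1]]

  sh <- coordination_shell(s, site, 2.6, c("N", "S"))
  expect_equal(sh$distance, c(2.05, 2.10, 2.25), tolerance = 1e-9)
  expect_identical(sh$name, c("ND1", "ND1", "SG"))

  expect_equal(nrow(coordination_shell(s, site, 0.5)), 0)
  # the long axial thioether enters at a wider cutoff
  expect_equal(nrow(coordination_shell(s, site, 3.0)), 4)

  expect_error(coordination_shell(s, 99999, 2.6), "not found")
})

test_that("carving yields capped, frozen, charge-consistent clusters", {
  s <- make_t1_site()
  site <- find_metal_sites(s)[[1]]
  specs <- cueo_t1_preset()
  cl <- carve_cluster(s, site, specs)

  # cap count equals the severed-bond count from the topology oracle
  expect_equal(sum(cl$atoms$is_cap), severed_bond_count(s, specs))
  # every cap is a hydrogen bonded (<= 1.2 A) to exactly one heavy atom
  caps <- cl$atoms[cl$atoms$is_cap, ]
  heavy <- cl$atoms[cl$atoms$element != "H", ]
  for (i in seq_len(nrow(caps))) {
    d <- sqrt((heavy$x - caps$x[i])^2 + (heavy$y - caps$y[i])^2 +
                (heavy$z - caps$z[i])^2)
    expect_equal(sum(d <= 1.2), 1)
  }
  expect_setequal(unique(caps$name), c("HL1", "HL2"))

  # frozen set is exactly the five alpha carbons; caps are free
  expect_equal(sum(cl$atoms$frozen), 5)
  expect_identical(unique(cl$atoms$name[cl$atoms$frozen]), "CA")
  expect_false(any(cl$atoms$frozen & cl$atoms$is_cap))

  # heavy-atom conservation (the copper is auto-included beyond the roster)
  expect_equal(sum(cl$atoms$element != "H" &
                     cl$atoms$serial != site$metal$serial),
               expected_heavy_atoms(s, specs[specs$resseq != 600, ]))

  # backbone beyond the cut is gone
  expect_false(any(cl$atoms$name %in% c("N", "C", "O")))

  # metal-bound thiolate: no HG, fragment charge -1
  expect_false("HG" %in% cl$atoms$name[cl$atoms$resseq == 500])
  expect_equal(cl$fragments$charge[cl$fragments$resseq == 500], -1L)
  expect_true(all(cl$fragments$charge[cl$fragments$resseq != 500] == 0L))

  expect_equal(cl$charge_ox - cl$charge_red, 1L)
  expect_error(carve_cluster(s, NULL, specs), "metal site")
})

test_that("a pre-deprotonated metal-bound Cys warns but still charges -1", {
  s <- make_t1_site()
  s$atoms <- s$atoms[!(s$atoms$resseq == 500 & s$atoms$name == "HG"), ]
  site <- find_metal_sites(s)[[1]]
  expect_warning(cl <- carve_cluster(s, site, cueo_t1_preset()),
                 "pre-deprotonated")
  expect_equal(cl$fragments$charge[cl$fragments$resseq == 500], -1L)
})

test_that("a residue lacking its alpha carbon is rejected", {
  s <- make_t1_site()
  s$atoms <- s$atoms[!(s$atoms$resseq == 502 & s$atoms$name == "CA"), ]
  site <- find_metal_sites(s)[[1]]
  expect_error(carve_cluster(s, site, cueo_t1_preset()), "CA")
})

test_that("charge/spin assignment follows the fragment sum and d-count", {
  s <- make_t1_site()
  site <- find_metal_sites(s)[[1]]

  # one thiolate: (+1, 2) / (0, 1)
  cl <- carve_cluster(s, site, cueo_t1_preset())
  cs <- assign_charge_spin(cl)
  expect_equal(unname(cs), c(1, 2, 0, 1))

  # no charged fragments (thiol out of the shell): (+2, 2) / (+1, 1)
  r <- default_t1_roster()
  r$distance[r$resname == "CYS"] <- 3.5
  far <- make_t1_site(fixture_spec(roster = r))
  cl2 <- carve_cluster(far, find_metal_sites(far)[[1]], cueo_t1_preset())
  expect_equal(unname(assign_charge_spin(cl2)), c(2, 2, 1, 1))

  # two thiolates: oxidized total drops to 0
  r2 <- default_t1_roster()
  r2$resname[4] <- "CYS"; r2$anchor[4] <- "SG"; r2$distance[4] <- 2.30
  two <- make_t1_site(fixture_spec(roster = r2))
  cl3 <- carve_cluster(two, find_metal_sites(two)[[1]],
                       cueo_t1_preset())
  expect_equal(sum(cl3$fragments$charge), -2L)
  expect_equal(unname(assign_charge_spin(cl3))[1], 0)

  # unsupported couple needs explicit multiplicities
  fe_line <- pdb_line(999, "FE", "FE", "A", 700, 20, 20, 20,
                      element = "FE", record = "HETATM")
  pdb <- strsplit(write_structure(s, "pdb"), "\n")[[1]]
  s_fe <- read_structure(c(pdb[pdb != "END"], fe_line))
  fe_site <- find_metal_sites(s_fe, "FE")[[1]]
  cl_fe <- suppressWarnings(
    carve_cluster(s_fe, fe_site, cueo_t1_preset()))
  expect_error(assign_charge_spin(cl_fe, fe_site), "multiplicity rule")
  cs_fe <- assign_charge_spin(cl_fe, fe_site,
                              multiplicities = c(ox = 6, red = 5))
  expect_equal(unname(cs_fe)[c(2, 4)], c(6, 5))
})

test_that("carving invariants hold on randomized rosters", {
  # >= 20 random rosters on a wide clash-free ring
  set.seed(101)
  for (k in 1:24) {
    n <- sample(3:5, 1)
    rn <- sample(names(ANCHOR_OF), n, replace = TRUE)
    roster <- wide_ring_roster(rn, distances = runif(n, 6, 8))
    s <- make_t1_site(fixture_spec(roster = roster, seed = k))
    site <- find_metal_sites(s)[[1]]
    specs <- data.frame(chain = "A", resseq = roster$resseq)
    cl <- carve_cluster(s, site, specs)

    expect_equal(sum(cl$atoms$is_cap), severed_bond_count(s, specs))
    expect_equal(sum(cl$atoms$element != "H" &
                       cl$atoms$serial != site$metal$serial),
                 expected_heavy_atoms(s, specs))
    expect_equal(cl$charge_ox - cl$charge_red, 1L)
    # no heavy atom appears or disappears beyond the backbone rule
    sel <- select_residues(s, specs)
    kept_serials <- cl$atoms$serial[!cl$atoms$is_cap &
                                      cl$atoms$element != "H"]
    src <- sel$atoms[sel$atoms$element != "H", ]
    removed <- src$name %in% c("N", "C", "O", "OXT")
    expect_setequal(setdiff(kept_serials, site$metal$serial),
                    src$serial[!removed])
  }
})
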