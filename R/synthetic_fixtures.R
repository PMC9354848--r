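# Synthetic fixtures: toy type-1 copper sites with full hydrogens, mock QM
# logs, and the embedded published energy table, so that every stage of the
# pipeline is testable without downloads or a QM engine.
#
# Residue mimics use minimal realistic topologies (imidazole-bearing His,
# thiol Cys, thioether Met, aliphatic Leu, amine Lys) built from idealised
# bond lengths and tetrahedral angles. They are sufficient for carving,
# capping and charge logic; rotamer realism is not attempted.

TET_COS <- -1 / 3
TET_SIN <- sqrt(8) / 3

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# the three remaining tetrahedral directions around a centre with one bond
# along `a`; phase rotates the triple about `a`
tet_three <- function(a, phase = 0) {
  a <- unitv(a)
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p1 <- unitv(cross3(a, ref))
  p2 <- cross3(a, p1)
  lapply(phase + c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    TET_COS * a + TET_SIN * (cos(phi) * p1 + sin(phi) * p2)
  })
}

# pick from a list of unit vectors the one maximising dot(v, pref)
pick_dir <- function(dirs, pref) {
  scores <- vapply(dirs, function(d) sum(d * pref), 0)
  dirs[[which.max(scores)]]
}

# rotation matrix taking the +z axis onto unit vector u
rot_ez_to <- function(u) {
  u <- unitv(u)
  ez <- c(0, 0, 1)
  c_ <- sum(ez * u)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # flip about x
  v <- cross3(ez, u)
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# --- residue templates ----------------------------------------------------
# Local frame: the anchor atom (metal donor, or CG/NZ for non-coordinating
# residues) sits at the origin; the residue extends into z > 0; the metal
# will lie on the -z axis.

tpl <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

tpl_add <- function(t, name, element, pos) {
  t$rows[[name]] <- list(name = name, element = element, pos = pos)
  invisible(t)
}

tpl_pos <- function(t, name) t$rows[[name]]$pos

tpl_df <- function(t) {
  rows <- t$rows
  data.frame(
    name = vapply(rows, `[[`, "", "name"),
    element = vapply(rows, `[[`, "", "element"),
    x = vapply(rows, function(r) r$pos[1], 0),
    y = vapply(rows, function(r) r$pos[2], 0),
    z = vapply(rows, function(r) r$pos[3], 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# backbone N, H, C, O, HA around an existing CA; u_side points CA -> CB
add_backbone <- function(t, u_side) {
  ca <- tpl_pos(t, "CA")
  dirs <- tet_three(u_side)
  up <- c(0, 0, 1)
  d_n <- pick_dir(dirs, up)
  rest <- Filter(function(d) sum(abs(d - d_n)) > 1e-9, dirs)
  d_c <- pick_dir(rest, c(1, 0, 0.2))
  d_ha <- Filter(function(d) sum(abs(d - d_c)) > 1e-9, rest)[[1]]
  n <- ca + 1.46 * d_n
  c_ <- ca + 1.52 * d_c
  tpl_add(t, "N", "N", n)
  tpl_add(t, "H", "H", n + 1.01 * pick_dir(tet_three(unitv(ca - n)), up))
  tpl_add(t, "C", "C", c_)
  tpl_add(t, "O", "O", c_ + 1.23 * pick_dir(tet_three(unitv(ca - c_)), up))
  tpl_add(t, "HA", "H", ca + 1.09 * d_ha)
  invisible(t)
}

add_h2 <- function(t, hnames, centre, back, fwd) {
  # two hydrogens completing a tetrahedral carbon with bonds back/fwd
  w <- -unitv(back + fwd)
  p <- unitv(cross3(back, fwd))
  hdir1 <- unitv(w * cos(0.9553) + p * sin(0.9553))
  hdir2 <- unitv(w * cos(0.9553) - p * sin(0.9553))
  tpl_add(t, hnames[1], "H", centre + 1.09 * hdir1)
  tpl_add(t, hnames[2], "H", centre + 1.09 * hdir2)
  invisible(t)
}

add_ch3 <- function(t, hnames, centre, back) {
  dirs <- tet_three(back)
  for (i in 1:3) tpl_add(t, hnames[i], "H", centre + 1.09 * dirs[[i]])
  invisible(t)
}

# imidazole-bearing His mimic, metal donor ND1 at the origin; the
# non-coordinating ring nitrogen NE2 keeps its hydrogen (epsilon tautomer
# seen from the metal side: the coordinating N is bare)
tmpl_his <- function() {
  t <- tpl()
  s <- 1.37                      # aromatic ring bond
  r5 <- s / (2 * sin(pi / 5))    # circumradius of the pentagon
  ctr <- c(0, 0, r5)
  ang <- -pi / 2 + 2 * pi / 5 * (0:4)
  ringnames <- c("ND1", "CE1", "NE2", "CD2", "CG")
  ringel <- c("N", "C", "N", "C", "C")
  for (i in 1:5) {
    tpl_add(t, ringnames[i], ringel[i],
            ctr + r5 * c(cos(ang[i]), 0, sin(ang[i])))
  }
  ring_h <- function(name, hname, len) {
    p <- tpl_pos(t, name)
    tpl_add(t, hname, "H", p + len * unitv(p - ctr))
  }
  ring_h("CE1", "HE1", 1.08)
  ring_h("NE2", "HE2", 1.01)
  ring_h("CD2", "HD2", 1.08)

  cg <- tpl_pos(t, "CG")
  u_out <- unitv(cg - ctr)
  cb <- cg + 1.50 * u_out
  tpl_add(t, "CB", "C", cb)
  d_ca <- unitv(c(-0.3, 0.8, 0.52))
  ca <- cb + 1.53 * d_ca
  tpl_add(t, "CA", "C", ca)
  add_h2(t, c("HB2", "HB3"), cb, unitv(cg - cb), d_ca)
  add_backbone(t, unitv(cb - ca))
  t
}

# Cys mimic, donor SG at the origin, thiol HG present (removed on carving
# when the thiolate coordinates the metal)
tmpl_cys <- function() {
  t <- tpl()
  t1 <- unitv(c(0.8165, 0, 0.5774))
  tpl_add(t, "SG", "S", c(0, 0, 0))
  tpl_add(t, "HG", "H", 1.34 * pick_dir(tet_three(t1), c(0, 1, 0)))
  cb <- 1.81 * t1
  tpl_add(t, "CB", "C", cb)
  d_ca <- pick_dir(tet_three(unitv(-t1)), c(0, 0, 1))
  ca <- cb + 1.53 * d_ca
  tpl_add(t, "CA", "C", ca)
  add_h2(t, c("HB2", "HB3"), cb, unitv(-cb), d_ca)
  add_backbone(t, unitv(cb - ca))
  t
}

# Met mimic, thioether donor SD at the origin
tmpl_met <- function() {
  t <- tpl()
  t1 <- unitv(c(0.8165, 0, 0.5774))
  tpl_add(t, "SD", "S", c(0, 0, 0))
  ce <- 1.81 * pick_dir(tet_three(t1), c(0, 1, 0.2))
  tpl_add(t, "CE", "C", ce)
  add_ch3(t, c("HE1", "HE2", "HE3"), ce, unitv(-ce))
  cg <- 1.81 * t1
  tpl_add(t, "CG", "C", cg)
  d_cb <- pick_dir(tet_three(unitv(-t1)), c(0, 0, 1))
  cb <- cg + 1.53 * d_cb
  tpl_add(t, "CB", "C", cb)
  add_h2(t, c("HG2", "HG3"), cg, unitv(-cg), d_cb)
  d_ca <- pick_dir(tet_three(unitv(cg - cb)), c(0, 0.4, 1))
  ca <- cb + 1.53 * d_ca
  tpl_add(t, "CA", "C", ca)
  add_h2(t, c("HB2", "HB3"), cb, unitv(cg - cb), d_ca)
  add_backbone(t, unitv(cb - ca))
  t
}

# Leu mimic, anchored (not metal-bound) at CG
tmpl_leu <- function() {
  t <- tpl()
  t1 <- unitv(c(0.8165, 0, 0.5774))
  tpl_add(t, "CG", "C", c(0, 0, 0))
  dirs <- tet_three(t1)
  cd1 <- 1.53 * pick_dir(dirs, c(0, 1, 0))
  cd2 <- 1.53 * pick_dir(dirs, c(0, -1, 0))
  hgd <- Filter(function(d) {
    sum(abs(1.53 * d - cd1)) > 1e-9 && sum(abs(1.53 * d - cd2)) > 1e-9
  }, dirs)[[1]]
  tpl_add(t, "CD1", "C", cd1)
  add_ch3(t, c("HD11", "HD12", "HD13"), cd1, unitv(-cd1))
  tpl_add(t, "CD2", "C", cd2)
  add_ch3(t, c("HD21", "HD22", "HD23"), cd2, unitv(-cd2))
  tpl_add(t, "HG", "H", 1.09 * hgd)
  cb <- 1.53 * t1
  tpl_add(t, "CB", "C", cb)
  d_ca <- pick_dir(tet_three(unitv(-t1)), c(0, 0, 1))
  ca <- cb + 1.53 * d_ca
  tpl_add(t, "CA", "C", ca)
  add_h2(t, c("HB2", "HB3"), cb, unitv(-cb), d_ca)
  add_backbone(t, unitv(cb - ca))
  t
}

# neutral Lys mimic, anchored at the terminal amine NZ
tmpl_lys <- function() {
  t <- tpl()
  t1 <- unitv(c(0.8165, 0, 0.5774))
  tpl_add(t, "NZ", "N", c(0, 0, 0))
  hz <- tet_three(t1)
  tpl_add(t, "HZ1", "H", 1.01 * pick_dir(hz, c(0, 1, 0)))
  tpl_add(t, "HZ2", "H", 1.01 * pick_dir(hz, c(0, -1, 0)))
  ce <- 1.47 * t1
  tpl_add(t, "CE", "C", ce)
  d_cd <- pick_dir(tet_three(unitv(-t1)), c(0, 0, 1))
  cd <- ce + 1.53 * d_cd
  tpl_add(t, "CD", "C", cd)
  add_h2(t, c("HE2", "HE3"), ce, unitv(-ce), d_cd)
  d_cg <- pick_dir(tet_three(unitv(ce - cd)), c(0, 0.4, 1))
  cg <- cd + 1.53 * d_cg
  tpl_add(t, "CG", "C", cg)
  add_h2(t, c("HD2", "HD3"), cd, unitv(ce - cd), d_cg)
  d_cb <- pick_dir(tet_three(unitv(cd - cg)), c(0, -0.4, 1))
  cb <- cg + 1.53 * d_cb
  tpl_add(t, "CB", "C", cb)
  add_h2(t, c("HG2", "HG3"), cg, unitv(cd - cg), d_cb)
  d_ca <- pick_dir(tet_three(unitv(cg - cb)), c(0, 0.4, 1))
  ca <- cb + 1.53 * d_ca
  tpl_add(t, "CA", "C", ca)
  add_h2(t, c("HB2", "HB3"), cb, unitv(cg - cb), d_ca)
  add_backbone(t, unitv(cb - ca))
  t
}

RESIDUE_TEMPLATES <- list(HIS = tmpl_his, CYS = tmpl_cys, MET = tmpl_met,
                          LEU = tmpl_leu, LYS = tmpl_lys)

#' Default roster of the toy T1 copper site
#'
#' Five residues arranged around a single copper: two histidines and a
#' cysteine as equatorial donors (trigonal, as at a type-1 site), an
#' axial methionine thioether at a long distance, and a non-coordinating
#' residue 502 (Leu in the wild-type mimic, Lys when
#' `variant = TRUE`) on the opposite axis.
#'
#' @param variant logical; swap residue 502 from Leu to Lys.
#' @return data frame with columns `resname`, `resseq`, `anchor`
#'   (the atom placed at `distance` from the metal), `distance`
#'   (Angstrom), `ux`, `uy`, `uz` (placement direction from the metal).
#' @export
default_t1_roster <- function(variant = FALSE) {
  r <- data.frame(
    resname = c("HIS", "CYS", ifelse(variant, "LYS", "LEU"), "HIS", "MET"),
    resseq = c(443L, 500L, 502L, 505L, 510L),
    anchor = c("ND1", "SG", ifelse(variant, "NZ", "CG"), "ND1", "SD"),
    distance = c(2.05, 2.25, ifelse(variant, 3.5, 4.2), 2.10, 2.90),
    ux = c(1, -0.5, 0, -0.5, 0),
    uy = c(0, -sqrt(3) / 2, 0, sqrt(3) / 2, 0),
    uz = c(0, 0, -1, 0, 1),
    # spin of each residue about its metal-anchor axis, tuned so the
    # idealised side chains stay clash-free (min non-bonded separation
    # 2.4 Angstrom across the assembled site)
    phase = c(3 * pi / 4, 3 * pi / 4, 7 * pi / 4, 5 * pi / 4, 0),
    stringsAsFactors = FALSE
  )
  r
}

#' Fixture specification for [make_t1_site()]
#'
#' @param roster residue roster as from [default_t1_roster()].
#' @param chain chain identifier.
#' @param metal_resseq residue number given to the copper heteroatom.
#' @param seed integer seed; only consumed when `jitter = TRUE`.
#' @param jitter logical; when `TRUE`, each residue is additionally spun
#'   by a random phase about its own metal-anchor axis. Anchor-metal
#'   distances are preserved exactly.
#' @return list of class `qmx_fixture_spec`.
#' @export
fixture_spec <- function(roster = default_t1_roster(), chain = "A",
                         metal_resseq = 600L, seed = 1L, jitter = FALSE) {
  stopifnot(is.data.frame(roster), nrow(roster) >= 1L)
  if (any(roster$distance <= 1.5)) {
    stop("anchor distances must exceed the covalent-clash minimum of 1.5 Angstrom")
  }
  structure(list(roster = roster, chain = chain,
                 metal_resseq = as.integer(metal_resseq),
                 seed = as.integer(seed), jitter = isTRUE(jitter)),
            class = "qmx_fixture_spec")
}

#' Generate a toy T1 copper-site structure
#'
#' Places a copper atom at the origin and each roster residue with its
#' anchor atom at exactly the requested distance along the requested
#' direction, using idealised internal geometry and full hydrogens. The
#' result is PDB-writable and deterministic for a given spec.
#'
#' @param spec a [fixture_spec()].
#' @return a `qmx_structure`.
#' @export
#' @examples
#' s <- make_t1_site()
#' structure_residues(s)
make_t1_site <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "qmx_fixture_spec"))
  r <- spec$roster
  phases <- if (is.null(r$phase)) rep(0, nrow(r)) else r$phase
  if (spec$jitter) {
    # small spins keep the tuned clash-free arrangement
    phases <- phases +
      withr_seed(spec$seed, stats::runif(nrow(r), -pi / 16, pi / 16))
  }

  pieces <- list()
  for (i in seq_len(nrow(r))) {
    fn <- RESIDUE_TEMPLATES[[r$resname[i]]]
    if (is.null(fn)) {
      stop(sprintf("no template for residue '%s'", r$resname[i]))
    }
    df <- tpl_df(fn())
    ai <- which(df$name == r$anchor[i])
    if (length(ai) != 1L) {
      stop(sprintf("template %s has no anchor atom '%s'",
                   r$resname[i], r$anchor[i]))
    }
    loc <- as.matrix(df[, c("x", "y", "z")])
    # shift anchor to origin, spin about local z, orient +z along u
    loc <- sweep(loc, 2, loc[ai, ])
    ph <- phases[i]
    spin <- matrix(c(cos(ph), sin(ph), 0, -sin(ph), cos(ph), 0, 0, 0, 1),
                   3, 3)
    u <- unitv(c(r$ux[i], r$uy[i], r$uz[i]))
    rot <- rot_ez_to(u)
    glob <- t(rot %*% spin %*% t(loc)) +
      matrix(rep(r$distance[i] * u, each = nrow(loc)), ncol = 3)
    df$x <- glob[, 1]; df$y <- glob[, 2]; df$z <- glob[, 3]
    df$resname <- r$resname[i]
    df$resseq <- r$resseq[i]
    pieces[[i]] <- df
  }

  all_df <- do.call(rbind, pieces)
  atoms <- data.frame(
    serial = seq_len(nrow(all_df) + 1L),
    name = c(all_df$name, "CU"),
    altloc = "",
    resname = c(all_df$resname, "CU"),
    chain = spec$chain,
    resseq = as.integer(c(all_df$resseq, spec$metal_resseq)),
    x = c(all_df$x, 0), y = c(all_df$y, 0), z = c(all_df$z, 0),
    occupancy = 1,
    element = c(all_df$element, "CU"),
    record = c(rep("ATOM", nrow(all_df)), "HETATM"),
    stringsAsFactors = FALSE
  )

  check_fixture_clashes(atoms, r, spec)
  new_structure(atoms, title = sprintf("synthetic T1 Cu site (seed %d)",
                                       spec$seed))
}

# inter-residue (and metal/non-anchor) clash screen at 1.5 Angstrom
check_fixture_clashes <- function(atoms, roster, spec) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res_id <- paste(atoms$resseq)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  same <- outer(res_id, res_id, `==`)
  anchor_key <- paste(roster$resseq, roster$anchor)
  is_anchor <- paste(atoms$resseq, atoms$name) %in% anchor_key
  is_metal <- atoms$element == "CU" & atoms$resseq == spec$metal_resseq
  allowed <- same | (outer(is_metal, is_anchor, `&`) |
                       outer(is_anchor, is_metal, `&`))
  bad <- which(d < 1.5 & !allowed, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "fixture clash: %s %d:%s and %s %d:%s at %.2f Angstrom",
      atoms$resname[i], atoms$resseq[i], atoms$name[i],
      atoms$resname[j], atoms$resseq[j], atoms$name[j], d[i, j]))
  }
  invisible(TRUE)
}

#' Generate a mock QM engine log
#'
#' Produces Gaussian-style log text that [parse_log()] round-trips
#' exactly: a route echo, a short SCF history whose last entry is the
#' seeded energy, a thermochemistry free-energy line for `opt_freq` jobs,
#' and a termination banner.
#'
#' @param job_type `"opt_freq"`, `"sp_gas"` or `"sp_solvent"`.
#' @param scf final SCF energy, Hartree.
#' @param gibbs Gibbs free energy (Hartree); required for `opt_freq`,
#'   ignored otherwise.
#' @param method,basis level echoed on the route line.
#' @param normal emit the normal-termination banner (default `TRUE`).
#' @return log text as a single string.
#' @export
make_mock_log <- function(job_type = c("sp_gas", "sp_solvent", "opt_freq"),
                          scf, gibbs = NULL, method = "M062X",
                          basis = "def2TZVP", normal = TRUE) {
  job_type <- match.arg(job_type)
  stopifnot(is.finite(scf))
  lines <- c(
    " Entering Gaussian System",
    sprintf(" #%s %s/%s", if (job_type == "opt_freq") " opt freq" else "",
            method, basis),
    sprintf(" SCF Done:  E(RM062X) =  %.6f     A.U. after   14 cycles",
            scf + 0.004217),
    sprintf(" SCF Done:  E(RM062X) =  %.6f     A.U. after    9 cycles",
            scf)
  )
  if (job_type == "opt_freq") {
    if (is.null(gibbs) || !is.finite(gibbs)) {
      stop("opt_freq mock logs need a finite gibbs energy")
    }
    lines <- c(lines,
               " Temperature   298.150 Kelvin.  Pressure   1.00000 Atm.",
               sprintf(" Sum of electronic and thermal Free Energies=     %.6f",
                       gibbs))
  }
  if (normal) {
    lines <- c(lines, " Normal termination of Gaussian 16 at Mon Jan  1 00:00:00 2026.")
  }
  paste(c(lines, ""), collapse = "\n")
}

#' The embedded published energy table
#'
#' CSV text with the gas-phase Gibbs free energies and solvation free
#' energies (kcal/mol) of the oxidized and reduced states of the
#' wild-type and L502K T1-site cluster models, as published. Feeding this
#' through [read_energy_table()] and [run_cycle()] reproduces the
#' published potentials end to end.
#'
#' @return CSV text.
#' @export
#' @examples
#' recs <- read_energy_table(make_paper_energy_table())
#' length(recs)   # 4
make_paper_energy_table <- function() {
  paste(
    "system,state,G_gas,dG_solv,unit",
    "WT,ox,-2949799.37,-122.04,kcal/mol",
    "WT,red,-2949931.72,-82.05,kcal/mol",
    "L502K,ox,-2984537.94,-88.45,kcal/mol",
    "L502K,red,-2984656.64,-85.04,kcal/mol",
    "", sep = "\n")
}

#' Experimental onset potentials of the reference systems
#'
#' @return named vector of experimental potentials (V vs SHE) for the
#'   wild-type and L502K systems, used to report calculated-minus-
#'   experimental deviations.
#' @export
experimental_potentials <- function() {
  c(WT = 0.35, L502K = 0.44)
}
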