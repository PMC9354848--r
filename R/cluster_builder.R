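# Cluster construction: metal-site detection, coordination shells,
# side-chain + C-alpha carving with hydrogen link-atom caps, frozen-atom
# bookkeeping, and per-redox-state charge/spin assignment.

# atomic numbers for parity checks (charge vs spin multiplicity)
ATOMIC_NUMBERS <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9, NA_ = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA_ = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, MO = 42, I = 53
)

atomic_number <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA_"   # sodium vs R's NA
  el[el == "CA"] <- "CA_"
  z <- ATOMIC_NUMBERS[el]
  if (any(is.na(z))) {
    stop(sprintf("unknown element(s): %s",
                 paste(unique(element[is.na(z)]), collapse = ", ")))
  }
  unname(z)
}

# formal charges of common one-electron couples, by element
METAL_COUPLES <- list(
  CU = c(ox = 2L, red = 1L),
  FE = c(ox = 3L, red = 2L),
  MN = c(ox = 3L, red = 2L),
  CO = c(ox = 3L, red = 2L)
)

BACKBONE_REMOVE <- c("N", "C", "O", "OXT")
AMIDE_HYDROGENS <- c("H", "HN", "H1", "H2", "H3", "HT1", "HT2", "HT3")

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Find metal sites in a structure
#'
#' One site is returned per atom whose element matches, ordered by serial
#' number. Formal charges of the one-electron couple default to the common
#' couple for the element (e.g. Cu(II)/Cu(I)); supply them explicitly for
#' anything unusual. Donor shells are left unfilled; see
#' [coordination_shell()].
#'
#' @param s a `qmx_structure`.
#' @param elements character vector of element symbols to match
#'   (default `"CU"`).
#' @param oxidized_charge,reduced_charge optional integer formal charges of
#'   the couple; `oxidized_charge` must equal `reduced_charge + 1`.
#' @return list of `qmx_metal_site` objects (possibly empty), each with
#'   fields `metal` (one-row atom data frame), `oxidized_charge`,
#'   `reduced_charge`, `donors`.
#' @export
find_metal_sites <- function(s, elements = "CU",
                             oxidized_charge = NULL, reduced_charge = NULL) {
  stopifnot(inherits(s, "qmx_structure"))
  elements <- toupper(elements)
  hits <- which(s$atoms$element %in% elements)
  hits <- hits[order(s$atoms$serial[hits])]
  lapply(hits, function(i) {
    el <- s$atoms$element[i]
    if (is.null(oxidized_charge)) {
      couple <- METAL_COUPLES[[el]]
      if (is.null(couple)) {
        stop(sprintf(
          "no default redox couple for element %s; supply oxidized_charge/reduced_charge",
          el))
      }
      ox <- couple[["ox"]]; red <- couple[["red"]]
    } else {
      ox <- as.integer(oxidized_charge)
      red <- if (is.null(reduced_charge)) ox - 1L else as.integer(reduced_charge)
    }
    if (ox != red + 1L) {
      stop("oxidized_charge must equal reduced_charge + 1 (one-electron couple)")
    }
    structure(
      list(metal = s$atoms[i, , drop = FALSE],
           oxidized_charge = ox, reduced_charge = red, donors = NULL),
      class = "qmx_metal_site"
    )
  })
}

#' @export
print.qmx_metal_site <- function(x, ...) {
  m <- x$metal
  cat(sprintf("<qmx_metal_site> %s serial %d (%s %s%d), couple +%d/+%d\n",
              m$element, m$serial, m$resname, m$chain, m$resseq,
              x$oxidized_charge, x$reduced_charge))
  if (!is.null(x$donors) && nrow(x$donors)) {
    cat(sprintf("  donors: %s\n",
                paste(sprintf("%s@%.2f", x$donors$name, x$donors$distance),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Coordination shell of a metal atom
#'
#' All atoms of the donor elements within `cutoff` (inclusive) of the
#' metal, by Euclidean distance, sorted ascending. Atoms belonging to the
#' metal's own residue are excluded.
#'
#' @param s a `qmx_structure`.
#' @param metal a one-row atom data frame (as in a `qmx_metal_site`), a
#'   `qmx_metal_site`, or a serial number present in `s`.
#' @param cutoff distance cutoff in Angstrom (default 2.6, spanning
#'   typical Cu-N/Cu-S bond lengths).
#' @param donor_elements element symbols eligible as donors
#'   (default N, S, O).
#' @return data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resseq`, `element`, `distance`, sorted by distance.
#' @export
coordination_shell <- function(s, metal, cutoff = 2.6,
                               donor_elements = c("N", "S", "O")) {
  stopifnot(inherits(s, "qmx_structure"), cutoff > 0)
  m <- resolve_metal_atom(s, metal)
  a <- s$atoms
  d <- sqrt((a$x - m$x)^2 + (a$y - m$y)^2 + (a$z - m$z)^2)
  same_res <- a$chain == m$chain & a$resseq == m$resseq
  keep <- a$element %in% toupper(donor_elements) & d <= cutoff & !same_res
  out <- a[keep, c("serial", "name", "resname", "chain", "resseq", "element")]
  out$distance <- d[keep]
  out <- out[order(out$distance, out$serial), ]
  rownames(out) <- NULL
  out
}

resolve_metal_atom <- function(s, metal) {
  if (inherits(metal, "qmx_metal_site")) metal <- metal$metal
  if (is.data.frame(metal)) {
    serial <- metal$serial[1]
  } else if (is.numeric(metal)) {
    serial <- metal
  } else {
    stop("metal must be a metal site, an atom row, or a serial number")
  }
  i <- match(serial, s$atoms$serial)
  if (is.na(i)) stop(sprintf("metal atom serial %s not found in structure", serial))
  s$atoms[i, , drop = FALSE]
}

#' Carving rules
#'
#' Bundles the tunable parameters of the carving step.
#'
#' @param cutoff coordination-shell cutoff in Angstrom used to decide which
#'   Cys thiols are metal-bound (and thus deprotonated); default 2.6.
#' @param donor_elements donor element symbols for the shell.
#' @param cap_length C-H bond length for link-atom caps, Angstrom
#'   (default 1.09).
#' @param frozen_names atom names to freeze; default `"CA"` freezes exactly
#'   the alpha carbons. Override to freeze additional boundary atoms.
#' @return a list of class `qmx_carve_rules`.
#' @export
carve_rules <- function(cutoff = 2.6, donor_elements = c("N", "S", "O"),
                        cap_length = 1.09, frozen_names = "CA") {
  stopifnot(cutoff > 0, cap_length > 0)
  structure(list(cutoff = cutoff, donor_elements = toupper(donor_elements),
                 cap_length = cap_length, frozen_names = frozen_names),
            class = "qmx_carve_rules")
}

#' Carve a truncated, capped, partially frozen cluster model
#'
#' Implements the side-chain + C-alpha truncation scheme: for every
#' amino-acid residue in the selection the backbone is severed at the
#' Calpha-N and Calpha-C(carbonyl) bonds, each severed bond is healed by a
#' hydrogen link atom placed along the original bond vector at the standard
#' C-H length, and the backbone atoms beyond the cut (N, amide H, C, O,
#' OXT) are removed. Alpha carbons are marked frozen so the cluster keeps
#' the scaffold geometry during optimisation; link atoms are not frozen.
#'
#' A cysteine whose SG lies within the coordination-shell cutoff of the
#' metal is treated as a metal-bound thiolate: its HG is removed and the
#' fragment carries a formal charge of -1. All other standard fragments are
#' neutral. Non-amino-acid residues in the selection (e.g. the metal ion)
#' are passed through unchanged.
#'
#' @param s a `qmx_structure` with hydrogens present on the selected
#'   residues (the carver validates protonation, it does not add protons).
#' @param site a `qmx_metal_site` from [find_metal_sites()].
#' @param specs residue specifications as in [select_residues()]; the
#'   metal's own residue is included automatically.
#' @param rules a [carve_rules()] object.
#' @return an object of class `qmx_cluster`: list with `atoms` (atom data
#'   frame with logical columns `is_cap` and `frozen`), `fragments`
#'   (`label`, `resname`, `chain`, `resseq`, `charge`), `site`,
#'   `charge_ox`, `charge_red`, `multiplicity_ox`, `multiplicity_red`,
#'   `provenance`.
#' @export
carve_cluster <- function(s, site, specs, rules = carve_rules()) {
  stopifnot(inherits(s, "qmx_structure"), inherits(rules, "qmx_carve_rules"))
  if (!inherits(site, "qmx_metal_site")) {
    stop("a metal site is required to carve a cluster (charge bookkeeping)")
  }
  specs <- normalize_specs(specs)
  metal <- site$metal
  if (!any(specs$chain == metal$chain & specs$resseq == metal$resseq)) {
    specs <- rbind(specs,
                   data.frame(chain = metal$chain, resseq = metal$resseq))
  }
  sel <- select_residues(s, specs)
  shell <- coordination_shell(s, site, rules$cutoff, rules$donor_elements)

  key <- residue_keys(sel)
  pieces <- list(); frags <- list()
  for (k in unique(key)) {
    res <- sel$atoms[key == k, , drop = FALSE]
    label <- sprintf("%s %s%d", res$resname[1], res$chain[1], res$resseq[1])
    is_aa <- res$resname[1] %in% STANDARD_AA ||
      all(c("CA", "N", "C") %in% res$name)
    if (!is_aa) {
      # not an amino acid (metal ion, water, ...): pass through uncut
      pieces[[k]] <- transform(res, is_cap = FALSE)
      if (res$serial[1] != metal$serial) {
        frags[[k]] <- fragment_row(res, 0L)
      }
      next
    }
    carved <- carve_residue(res, rules)
    charge <- 0L
    if (res$resname[1] == "CYS") {
      sg <- carved[carved$name == "SG", , drop = FALSE]
      if (nrow(sg) == 1L &&
          sg$serial %in% shell$serial) {
        hg <- which(carved$name == "HG")
        if (length(hg)) {
          carved <- carved[-hg, , drop = FALSE]
        } else {
          warning(sprintf(
            "%s: metal-bound SG has no HG in input; assuming pre-deprotonated thiolate",
            label))
        }
        charge <- -1L
      }
    }
    pieces[[k]] <- carved
    frags[[k]] <- fragment_row(res, charge)
  }

  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  # caps get fresh serials after all originals
  ncap <- sum(atoms$is_cap)
  if (ncap > 0) {
    atoms$serial[atoms$is_cap] <- max(atoms$serial[!atoms$is_cap]) +
      seq_len(ncap)
  }
  frozen_names <- rules$frozen_names
  atoms$frozen <- atoms$name %in% frozen_names & !atoms$is_cap

  fragments <- do.call(rbind, frags)
  rownames(fragments) <- NULL
  charge_sum <- sum(fragments$charge)

  cm <- structure(
    list(atoms = atoms, fragments = fragments, site = site,
         charge_ox = site$oxidized_charge + charge_sum,
         charge_red = site$reduced_charge + charge_sum,
         multiplicity_ox = NA_integer_, multiplicity_red = NA_integer_,
         provenance = specs),
    class = "qmx_cluster"
  )
  cs <- try(assign_charge_spin(cm, site), silent = TRUE)
  if (!inherits(cs, "try-error")) {
    cm$multiplicity_ox <- cs[["mult_ox"]]
    cm$multiplicity_red <- cs[["mult_red"]]
  }
  cm
}

fragment_row <- function(res, charge) {
  data.frame(
    label = sprintf("%s %s%d", res$resname[1], res$chain[1], res$resseq[1]),
    resname = res$resname[1], chain = res$chain[1], resseq = res$resseq[1],
    charge = as.integer(charge), stringsAsFactors = FALSE
  )
}

# sever CA-N and CA-C(carbonyl), cap along the original bond vectors
carve_residue <- function(res, rules) {
  label <- sprintf("%s %s%d", res$resname[1], res$chain[1], res$resseq[1])
  ica <- which(res$name == "CA")
  if (length(ica) != 1L) stop(sprintf("%s lacks a unique CA atom", label))
  ca <- c(res$x[ica], res$y[ica], res$z[ica])

  caps <- list()
  cap_name <- c(N = "HL1", C = "HL2")   # amino-side / carbonyl-side caps
  for (nm in c("N", "C")) {
    j <- which(res$name == nm)
    if (length(j) == 1L) {
      target <- c(res$x[j], res$y[j], res$z[j])
      pos <- ca + rules$cap_length * unitv(target - ca)
      cap <- res[ica, , drop = FALSE]
      cap$name <- cap_name[[nm]]; cap$element <- "H"
      cap$x <- pos[1]; cap$y <- pos[2]; cap$z <- pos[3]
      cap$occupancy <- 1
      caps[[nm]] <- cap
    }
  }
  drop <- res$name %in% c(BACKBONE_REMOVE, AMIDE_HYDROGENS)
  kept <- res[!drop, , drop = FALSE]
  kept$is_cap <- FALSE
  if (length(caps)) {
    capdf <- do.call(rbind, caps)
    capdf$is_cap <- TRUE
    kept <- rbind(kept, capdf)
  }
  kept
}

#' @export
print.qmx_cluster <- function(x, ...) {
  cat(sprintf(
    "<qmx_cluster> %d atoms (%d caps, %d frozen), charge ox/red %+d/%+d, 2S+1 ox/red %s/%s\n",
    nrow(x$atoms), sum(x$atoms$is_cap), sum(x$atoms$frozen),
    x$charge_ox, x$charge_red, x$multiplicity_ox, x$multiplicity_red))
  print(x$fragments[, c("label", "charge")], row.names = FALSE)
  invisible(x)
}

#' Per-redox-state total charge and spin multiplicity
#'
#' The total charge of each state is the metal formal charge plus the sum
#' of the fragment formal charges. Spin multiplicity follows the metal
#' d-electron count: Cu(II) (d9) is a doublet, Cu(I) (d10) a singlet. For
#' any other metal/oxidation-state pair, multiplicities must be supplied.
#'
#' @param cluster a `qmx_cluster`.
#' @param site a `qmx_metal_site`; defaults to the cluster's own site.
#' @param multiplicities optional named vector `c(ox = ..., red = ...)`
#'   overriding the d-count rule.
#' @return named numeric vector `c(charge_ox, mult_ox, charge_red,
#'   mult_red)`.
#' @export
#' @examples
#' s <- make_t1_site()
#' site <- find_metal_sites(s)[[1]]
#' cl <- carve_cluster(s, site, cueo_t1_preset())
#' assign_charge_spin(cl)   # c(1, 2, 0, 1) for the Cu T1 preset
assign_charge_spin <- function(cluster, site = cluster$site,
                               multiplicities = NULL) {
  stopifnot(inherits(cluster, "qmx_cluster"),
            inherits(site, "qmx_metal_site"))
  charge_sum <- sum(cluster$fragments$charge)
  charge_ox <- site$oxidized_charge + charge_sum
  charge_red <- site$reduced_charge + charge_sum
  stopifnot(charge_ox - charge_red == 1L)

  if (!is.null(multiplicities)) {
    m_ox <- as.integer(multiplicities[["ox"]])
    m_red <- as.integer(multiplicities[["red"]])
  } else {
    el <- site$metal$element
    key <- sprintf("%s:%d/%d", el, site$oxidized_charge, site$reduced_charge)
    if (identical(key, "CU:2/1")) {
      m_ox <- 2L; m_red <- 1L   # d9 doublet / d10 singlet
    } else {
      stop(sprintf(
        "no multiplicity rule for %s; supply multiplicities = c(ox=, red=)",
        key))
    }
  }
  if (m_ox < 1L || m_red < 1L) stop("multiplicity must be >= 1")
  c(charge_ox = charge_ox, mult_ox = m_ox,
    charge_red = charge_red, mult_red = m_red)
}

#' The CueO T1-site residue preset
#'
#' The hand-picked first- and second-shell roster used for the multicopper
#' oxidase T1 site: His443, Cys500, residue 502 (Leu in the wild type, Lys
#' in the variant), His505, Met510, plus the copper ion.
#'
#' @param chain chain identifier (default `"A"`).
#' @param metal_resseq residue number of the copper heteroatom record
#'   (default 600, as emitted by [make_t1_site()]).
#' @return a residue-spec data frame for [select_residues()] /
#'   [carve_cluster()].
#' @export
cueo_t1_preset <- function(chain = "A", metal_resseq = 600L) {
  data.frame(chain = chain,
             resseq = as.integer(c(443, 500, 502, 505, 510, metal_resseq)),
             stringsAsFactors = FALSE)
}

#' Export a cluster model as a structure
#'
#' @param cluster a `qmx_cluster`.
#' @return a `qmx_structure` whose atoms include the link-atom caps
#'   (named `HL`).
#' @export
cluster_structure <- function(cluster) {
  stopifnot(inherits(cluster, "qmx_cluster"))
  cols <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "x", "y", "z", "occupancy", "element", "record")
  new_structure(cluster$atoms[, cols], title = "carved cluster model")
}
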