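# QM engine I/O: Gaussian-style input decks for the protocol's three job
# types, output-log parsing, and plain energy-table ingestion.

#' Level-of-theory templates for the three job types
#'
#' The defaults encode the protocol exactly: geometry optimisation and
#' frequencies at B3LYP-D3(BJ)/6-311G* in SMD water, gas-phase single
#' points at M062X/def2TZVP, and solvated single points at M062X/6-311G*.
#'
#' @return named list of per-job-type templates, each with `method`,
#'   `basis`, `dispersion`, `solvent_model`.
#' @export
default_levels <- function() {
  list(
    opt_freq = list(method = "B3LYP", basis = "6-311G*",
                    dispersion = "GD3BJ", solvent_model = "SMD-water"),
    sp_gas = list(method = "M062X", basis = "def2TZVP",
                  dispersion = "", solvent_model = "none"),
    sp_solvent = list(method = "M062X", basis = "6-311G*",
                      dispersion = "", solvent_model = "SMD-water")
  )
}

#' Specify a single QM job
#'
#' @param job_type one of `"opt_freq"`, `"sp_gas"`, `"sp_solvent"`.
#' @param charge total charge, integer.
#' @param multiplicity spin multiplicity (2S+1), positive integer.
#' @param geometry data frame with columns `element`, `x`, `y`, `z`, and
#'   logical `frozen`.
#' @param method,basis,dispersion,solvent_model level of theory; defaults
#'   come from [default_levels()] for the job type. `solvent_model` is
#'   `"none"` or `"SMD-water"`.
#' @param title deck title line.
#' @return a list of class `qmx_job_spec`.
#' @export
qm_job_spec <- function(job_type, charge, multiplicity, geometry,
                        method = NULL, basis = NULL, dispersion = NULL,
                        solvent_model = NULL, title = "cluster model job") {
  job_type <- match.arg(job_type, c("opt_freq", "sp_gas", "sp_solvent"))
  lvl <- default_levels()[[job_type]]
  stopifnot(is.data.frame(geometry),
            all(c("element", "x", "y", "z", "frozen") %in% names(geometry)))
  if (nrow(geometry) == 0L) stop("geometry must be non-empty")
  multiplicity <- as.integer(multiplicity)
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  spec <- structure(list(
    job_type = job_type, charge = as.integer(charge),
    multiplicity = multiplicity, geometry = geometry,
    method = method %||% lvl$method, basis = basis %||% lvl$basis,
    dispersion = dispersion %||% lvl$dispersion,
    solvent_model = solvent_model %||% lvl$solvent_model,
    title = title
  ), class = "qmx_job_spec")
  check_parity(spec)
  spec
}

# electron-count parity must be consistent with multiplicity parity:
# even electron count <-> odd multiplicity
check_parity <- function(spec) {
  n_el <- sum(atomic_number(spec$geometry$element)) - spec$charge
  if ((n_el + spec$multiplicity) %% 2 == 0) {
    stop(sprintf(
      "charge %d implies %d electrons, inconsistent with multiplicity %d",
      spec$charge, n_el, spec$multiplicity))
  }
  invisible(spec)
}

#' Write a Gaussian-style input deck
#'
#' Emits a route line encoding method, basis, dispersion and solvent, the
#' charge/multiplicity line, and one Cartesian line per atom carrying a
#' freeze integer between the element and the coordinates (-1 frozen,
#' 0 free). Byte output is deterministic for identical specs.
#'
#' @param spec a [qm_job_spec()].
#' @return deck text as a single string.
#' @export
write_deck <- function(spec) {
  stopifnot(inherits(spec, "qmx_job_spec"))
  check_parity(spec)
  route <- paste0("# ", switch(spec$job_type,
                               opt_freq = "opt freq ",
                               sp_gas = "", sp_solvent = ""),
                  spec$method, "/", spec$basis)
  if (nzchar(spec$dispersion)) {
    route <- paste0(route, " EmpiricalDispersion=", spec$dispersion)
  }
  if (spec$solvent_model == "SMD-water") {
    route <- paste0(route, " SCRF=(SMD,Solvent=Water)")
  } else if (spec$solvent_model != "none") {
    stop(sprintf("unknown solvent model '%s'", spec$solvent_model))
  }
  g <- spec$geometry
  coords <- sprintf("%-4s %4d %13.6f %13.6f %13.6f",
                    pdb_case_element(toupper(g$element)),
                    ifelse(g$frozen, -1L, 0L), g$x, g$y, g$z)
  paste(c(route, "", spec$title, "",
          sprintf("%d %d", spec$charge, spec$multiplicity),
          coords, "", ""), collapse = "\n")
}

#' Parse a QM engine output log
#'
#' Captures the last SCF energy, the thermochemistry Gibbs free energy
#' when present, and the termination status from Gaussian-style log text.
#'
#' @param text log content: single string, lines, or a file path.
#' @return a list of class `qmx_parsed_log` with `final_scf_energy`
#'   (Hartree), `gibbs_free_energy` (Hartree or `NA`),
#'   `normal_termination` (logical), `method`, `basis`.
#' @export
parse_log <- function(text) {
  lines <- as_text_lines(text)

  scf <- grep("SCF Done:", lines, value = TRUE)
  if (length(scf) == 0L) stop("no SCF energy found in log")
  last <- scf[length(scf)]
  e <- regmatches(last, regexpr("=\\s*-?[0-9]+\\.[0-9]+", last))
  final_scf <- as.numeric(sub("=\\s*", "", e))

  gibbs <- NA_real_
  gl <- grep("Sum of electronic and thermal Free Energies", lines,
             value = TRUE)
  if (length(gl)) {
    m <- regmatches(gl[length(gl)],
                    regexpr("-?[0-9]+\\.[0-9]+", gl[length(gl)]))
    gibbs <- as.numeric(m)
  }

  normal <- any(grepl("Normal termination", lines))
  if (!normal) {
    warning("log does not report normal termination; energies may be unconverged")
  }

  method <- ""; basis <- ""
  rl <- grep("^ ?#", lines, value = TRUE)
  if (length(rl)) {
    mb <- regmatches(rl[1], regexpr("[A-Za-z0-9]+/[^ ]+", rl[1]))
    if (length(mb)) {
      parts <- strsplit(mb, "/", fixed = TRUE)[[1]]
      method <- parts[1]; basis <- parts[2]
    }
  }

  structure(list(final_scf_energy = final_scf, gibbs_free_energy = gibbs,
                 normal_termination = normal, method = method,
                 basis = basis),
            class = "qmx_parsed_log")
}

#' @export
print.qmx_parsed_log <- function(x, ...) {
  cat(sprintf("<qmx_parsed_log> SCF %.6f Ha, G %s, %s\n",
              x$final_scf_energy,
              if (is.na(x$gibbs_free_energy)) "absent"
              else sprintf("%.6f Ha", x$gibbs_free_energy),
              if (x$normal_termination) "normal termination"
              else "ABNORMAL termination"))
  invisible(x)
}

#' Read an energy table into energy records
#'
#' Accepts CSV text/files with header `system,state,G_gas,dG_solv,unit`
#' or the equivalent JSON (array of objects). Values are normalised to
#' kcal/mol internally; accepted units are `"kcal/mol"` and `"hartree"`.
#'
#' @param text CSV or JSON content, or a path to such a file.
#' @return list of [energy_record()] objects, one per row, with every
#'   system carrying both an `ox` and a `red` record.
#' @export
read_energy_table <- function(text) {
  lines <- as_text_lines(text)
  raw <- paste(lines, collapse = "\n")
  if (grepl("^\\s*[\\[{]", raw)) {
    df <- as.data.frame(jsonlite::fromJSON(raw))
  } else {
    df <- utils::read.csv(text = raw, stringsAsFactors = FALSE,
                          strip.white = TRUE)
  }
  need <- c("system", "state", "G_gas", "dG_solv", "unit")
  if (!all(need %in% names(df))) {
    stop(sprintf("energy table must provide columns: %s",
                 paste(need, collapse = ", ")))
  }
  df$unit <- tolower(df$unit)
  bad_unit <- setdiff(unique(df$unit), c("hartree", "kcal/mol"))
  if (length(bad_unit)) {
    stop(sprintf("unknown unit(s): %s", paste(bad_unit, collapse = ", ")))
  }
  for (sys in unique(df$system)) {
    st <- df$state[df$system == sys]
    if (!all(c("ox", "red") %in% st)) {
      stop(sprintf("system '%s' is missing an '%s' record", sys,
                   setdiff(c("ox", "red"), st)[1]))
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    energy_record(
      system = df$system[i], state = df$state[i],
      G_gas = convert_energy(df$G_gas[i], df$unit[i], "kcal/mol"),
      dG_solv = convert_energy(df$dG_solv[i], df$unit[i], "kcal/mol")
    )
  })
}

#' Build the six protocol decks for a cluster
#'
#' For each redox state (oxidized, reduced) one deck per job type:
#' `opt_freq`, `sp_gas`, `sp_solvent`, using the cluster's per-state
#' charge and multiplicity and its frozen-atom flags.
#'
#' @param cluster a `qmx_cluster`.
#' @param levels level templates as from [default_levels()].
#' @return named list of six deck strings, names like `"ox_opt_freq"`.
#' @export
cluster_decks <- function(cluster, levels = default_levels()) {
  stopifnot(inherits(cluster, "qmx_cluster"))
  g <- data.frame(element = cluster$atoms$element,
                  x = cluster$atoms$x, y = cluster$atoms$y,
                  z = cluster$atoms$z, frozen = cluster$atoms$frozen,
                  stringsAsFactors = FALSE)
  states <- list(
    ox = c(cluster$charge_ox, cluster$multiplicity_ox),
    red = c(cluster$charge_red, cluster$multiplicity_red)
  )
  out <- list()
  for (st in names(states)) {
    for (jt in names(levels)) {
      lvl <- levels[[jt]]
      spec <- qm_job_spec(
        jt, charge = states[[st]][1], multiplicity = states[[st]][2],
        geometry = g, method = lvl$method, basis = lvl$basis,
        dispersion = lvl$dispersion, solvent_model = lvl$solvent_model,
        title = sprintf("cluster %s state, %s", st, jt)
      )
      out[[paste(st, jt, sep = "_")]] <- write_deck(spec)
    }
  }
  out
}

#' Energy records from parsed logs
#'
#' Composes one [energy_record()] per redox state from the three parsed
#' logs of that state. The gas-phase Gibbs free energy is the `sp_gas`
#' electronic energy plus the thermal correction of the `opt_freq` job
#' (its Gibbs free energy minus its own electronic energy); the solvation
#' free energy is the solvated minus the gas-phase single-point energy at
#' the same geometry.
#'
#' @param system system label.
#' @param state `"ox"` or `"red"`.
#' @param opt_freq,sp_gas,sp_solvent `qmx_parsed_log` objects.
#' @param thermal include the thermal correction from the frequency job
#'   (default `TRUE`); set `FALSE` for an electronic-only composition.
#' @return an [energy_record()] in kcal/mol.
#' @export
logs_to_record <- function(system, state, opt_freq, sp_gas, sp_solvent,
                           thermal = TRUE) {
  stopifnot(inherits(opt_freq, "qmx_parsed_log"),
            inherits(sp_gas, "qmx_parsed_log"),
            inherits(sp_solvent, "qmx_parsed_log"))
  corr <- 0
  if (thermal) {
    if (is.na(opt_freq$gibbs_free_energy)) {
      stop("opt_freq log carries no Gibbs free energy; cannot apply thermal correction")
    }
    corr <- opt_freq$gibbs_free_energy - opt_freq$final_scf_energy
  }
  g_gas <- sp_gas$final_scf_energy + corr
  dg_solv <- sp_solvent$final_scf_energy - sp_gas$final_scf_energy
  energy_record(system, state,
                G_gas = convert_energy(g_gas, "hartree", "kcal/mol"),
                dG_solv = convert_energy(dg_solv, "hartree", "kcal/mol"))
}
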