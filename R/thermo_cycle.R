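# Thermodynamic cycle for one-electron reduction potentials.
#
# The solution-phase reduction free energy is decomposed as
#   dG = dG_gas + ddG_solv
# with dG_gas = G_g(red) - G_g(ox) from gas-phase thermochemistry and
# ddG_solv = dG_sol(red) - dG_sol(ox) from an implicit solvent model.
# The absolute potential follows as dE = -dG / (n F) and is referenced to
# the standard hydrogen electrode: E_calc = dE - E_SHE.
#
# All free energies are carried in kcal/mol; F is carried as the
# kcal/mol-per-eV factor (23.060548) so that for n = 1 the division yields
# volts directly.

#' Construct an energy record
#'
#' One record holds the gas-phase Gibbs free energy and the solvation free
#' energy of one redox state of one system, in kcal/mol.
#'
#' @param system system label (e.g. `"WT"`).
#' @param state `"ox"` or `"red"`.
#' @param G_gas gas-phase Gibbs free energy, kcal/mol.
#' @param dG_solv solvation free energy, kcal/mol.
#' @return a list of class `qmx_energy_record`.
#' @export
energy_record <- function(system, state, G_gas, dG_solv) {
  state <- match.arg(state, c("ox", "red"))
  if (!is.finite(G_gas) || !is.finite(dG_solv)) {
    stop("energies must be finite")
  }
  structure(list(system = system, state = state,
                 G_gas = as.numeric(G_gas), dG_solv = as.numeric(dG_solv)),
            class = "qmx_energy_record")
}

#' Gas-phase reduction free energy difference
#'
#' @param G_g_ox,G_g_red gas-phase Gibbs free energies of the oxidized and
#'   reduced states, kcal/mol.
#' @return `G_g_red - G_g_ox`, kcal/mol.
#' @export
delta_g_gas <- function(G_g_ox, G_g_red) {
  stopifnot(is.finite(G_g_ox), is.finite(G_g_red))
  G_g_red - G_g_ox
}

#' Differential solvation free energy
#'
#' @param dG_sol_ox,dG_sol_red solvation free energies of the oxidized and
#'   reduced states, kcal/mol.
#' @return `dG_sol_red - dG_sol_ox`, kcal/mol.
#' @export
delta_delta_g_sol <- function(dG_sol_ox, dG_sol_red) {
  stopifnot(is.finite(dG_sol_ox), is.finite(dG_sol_red))
  dG_sol_red - dG_sol_ox
}

#' Solution-phase reduction free energy
#'
#' @param dG_gas gas-phase reduction free energy, kcal/mol.
#' @param ddG_solv differential solvation free energy, kcal/mol.
#' @return the exact sum, kcal/mol.
#' @export
reduction_free_energy <- function(dG_gas, ddG_solv) {
  stopifnot(is.finite(dG_gas), is.finite(ddG_solv))
  dG_gas + ddG_solv
}

#' Absolute reduction potential from a free energy
#'
#' `dE = -dG / (n F)` with the Faraday constant expressed as
#' 23.060548 kcal/mol per eV.
#'
#' @param dG_total solution-phase reduction free energy, kcal/mol.
#' @param n number of electrons transferred (>= 1).
#' @return potential in volts.
#' @export
redox_potential <- function(dG_total, n = 1L) {
  stopifnot(is.finite(dG_total))
  if (!is_count(n) || n < 1) stop("n must be a positive integer")
  -dG_total / (n * EV_TO_KCAL)
}

#' Reference a potential to the standard hydrogen electrode
#'
#' @param dE absolute potential, volts.
#' @param she absolute SHE potential, volts (default 4.44 V, the IUPAC
#'   value for water; literature values span 4.28-4.74 V).
#' @return `dE - she`, volts.
#' @export
reference_potential <- function(dE, she = SHE_DEFAULT) {
  stopifnot(is.finite(dE), is.finite(she))
  dE - she
}

#' Run the full thermodynamic cycle for one system
#'
#' Composes [delta_g_gas()], [delta_delta_g_sol()],
#' [reduction_free_energy()], [redox_potential()] and
#' [reference_potential()] for an oxidized/reduced record pair.
#'
#' @param records a list of exactly two [energy_record()] objects for the
#'   same system, one with `state = "ox"` and one with `state = "red"`.
#' @param n number of electrons (default 1).
#' @param she absolute SHE reference, volts (default 4.44).
#' @return a list of class `qmx_redox_result` with full-precision fields
#'   `dG_gas`, `ddG_solv`, `dG_total` (kcal/mol), `dE`, `E_calc`,
#'   `she_reference` (V), `n_electrons`, `system`, and a `rounded` sublist
#'   with the same quantities rounded half-away-from-zero to 2 decimals.
#' @export
#' @examples
#' recs <- read_energy_table(make_paper_energy_table())
#' wt <- recs[vapply(recs, function(r) r$system == "WT", TRUE)]
#' run_cycle(wt)$rounded$E_calc   # -0.44 V
run_cycle <- function(records, n = 1L, she = SHE_DEFAULT) {
  stopifnot(is.list(records))
  records <- records[vapply(records, inherits, TRUE, "qmx_energy_record")]
  states <- vapply(records, function(r) r$state, "")
  iox <- which(states == "ox"); ired <- which(states == "red")
  if (length(iox) != 1L || length(ired) != 1L) {
    stop("run_cycle needs exactly one 'ox' and one 'red' energy record")
  }
  ox <- records[[iox]]; red <- records[[ired]]
  if (!identical(ox$system, red$system)) {
    stop(sprintf("records belong to different systems: '%s' vs '%s'",
                 ox$system, red$system))
  }

  dG_gas <- delta_g_gas(ox$G_gas, red$G_gas)
  ddG_solv <- delta_delta_g_sol(ox$dG_solv, red$dG_solv)
  dG_total <- reduction_free_energy(dG_gas, ddG_solv)
  dE <- redox_potential(dG_total, n)
  E_calc <- reference_potential(dE, she)

  structure(list(
    system = ox$system, n_electrons = as.integer(n), she_reference = she,
    dG_gas = dG_gas, ddG_solv = ddG_solv, dG_total = dG_total,
    dE = dE, E_calc = E_calc,
    rounded = list(
      dG_gas = round_half_up(dG_gas), ddG_solv = round_half_up(ddG_solv),
      dG_total = round_half_up(dG_total), dE = round_half_up(dE),
      E_calc = round_half_up(E_calc)
    )
  ), class = "qmx_redox_result")
}

#' @export
print.qmx_redox_result <- function(x, ...) {
  cat(sprintf("Thermodynamic cycle: %s (n = %d, SHE = %.2f V)\n",
              x$system, x$n_electrons, x$she_reference))
  r <- x$rounded
  cat(sprintf("  dG_gas   = %9.2f kcal/mol\n", r$dG_gas))
  cat(sprintf("  ddG_solv = %9.2f kcal/mol\n", r$ddG_solv))
  cat(sprintf("  dG       = %9.2f kcal/mol\n", r$dG_total))
  cat(sprintf("  dE       = %9.2f V\n", r$dE))
  cat(sprintf("  E_calc   = %9.2f V vs SHE\n", r$E_calc))
  invisible(x)
}

#' Sweep the SHE reference over a range
#'
#' Recomputes `E_calc` of a cycle result for a grid of absolute SHE
#' values, covering the spread of literature assignments.
#'
#' @param result a `qmx_redox_result`.
#' @param from,to bounds of the sweep in volts (default 4.28-4.74).
#' @param by grid step, volts.
#' @return data frame with columns `she` and `E_calc`.
#' @export
she_sweep <- function(result, from = 4.28, to = 4.74, by = 0.02) {
  stopifnot(inherits(result, "qmx_redox_result"))
  she <- seq(from, to, by = by)
  data.frame(she = she, E_calc = result$dE - she)
}

#' Convert an energy value between units
#'
#' Supported units: `"hartree"`, `"kcal/mol"`, `"ev"`, `"kj/mol"`.
#' Conversions go through kcal/mol using fixed constants
#' (627.509474 kcal/mol/Hartree, 23.060548 kcal/mol/eV, 4.184 kJ/kcal).
#'
#' @param value numeric value(s).
#' @param from,to unit labels (case-insensitive).
#' @return converted value(s).
#' @export
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")   # 627.509474
convert_energy <- function(value, from, to) {
  to_kcal <- function(u) {
    switch(u,
           "hartree" = HARTREE_TO_KCAL,
           "kcal/mol" = 1,
           "ev" = EV_TO_KCAL,
           "kj/mol" = 1 / KCAL_TO_KJ,
           stop(sprintf("unknown energy unit '%s'", u)))
  }
  from <- tolower(from); to <- tolower(to)
  value * to_kcal(from) / to_kcal(to)
}
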