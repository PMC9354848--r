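# Structure I/O: PDB reading/writing, XYZ export, residue selection.
#
# Coordinates are stored in Angstrom throughout; PDB residue numbering is
# kept exactly as found in the file so that literature residue labels
# (e.g. H443, C500 of a multicopper oxidase) address residues directly.

# elements that occupy both characters of the PDB name/element columns
TWO_LETTER_ELEMENTS <- c(
  "CU", "ZN", "FE", "MN", "MG", "CA", "NA", "CL", "BR", "NI", "CO", "MO",
  "SE", "CD", "HG", "AL", "SI", "LI", "BE", "AS", "AG", "AU", "PT", "PB"
)

#' Read a macromolecular structure from PDB-format text
#'
#' Parses `ATOM` and `HETATM` records (wwPDB v3.3 fixed columns) into a
#' structure object. Metals in `HETATM` records are first-class atoms.
#' Waters are read like any other residue; they only enter a cluster if
#' explicitly selected. Hydrogens are taken as given - the reader never
#' adds or removes protons.
#'
#' When a record carries alternate locations, exactly one conformer is
#' retained per atom: the highest occupancy wins, ties broken by altloc
#' letter order. The number of dropped conformers is recorded in the
#' `n_altloc_dropped` field and reported with a message.
#'
#' @param text PDB content as a single string, a character vector of lines,
#'   or a path to an existing file.
#' @return An object of class `qmx_structure`: a list with `atoms` (a
#'   data frame with columns `serial`, `name`, `altloc`, `resname`, `chain`,
#'   `resseq`, `x`, `y`, `z`, `occupancy`, `element`, `record`), `title`,
#'   and `n_altloc_dropped`.
#' @export
#' @examples
#' s <- read_structure(write_structure(make_t1_site(), "pdb"))
#' nrow(s$atoms)
read_structure <- function(text) {
  lines <- as_text_lines(text)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop("no atom records: input is empty")
  }

  title <- ""
  tl <- grep("^TITLE", lines, value = TRUE)
  if (length(tl)) title <- trimws(substring(tl[1], 11))

  idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(idx) == 0L) {
    first <- lines[nzchar(trimws(lines))][1]
    stop(sprintf("no atom records: first line is '%s'", first %||% ""))
  }

  recs <- lines[idx]
  parse_num <- function(sub, what) {
    v <- suppressWarnings(as.numeric(trimws(sub)))
    bad <- which(!is.finite(v) & nzchar(trimws(sub)))
    bad2 <- which(!nzchar(trimws(sub)))
    bad <- sort(c(bad, if (what %in% c("x", "y", "z")) bad2))
    if (length(bad)) {
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, idx[bad[1]], recs[bad[1]]))
    }
    v
  }

  atoms <- data.frame(
    serial = parse_num(substr(recs, 7, 11), "serial"),
    name = trimws(substr(recs, 13, 16)),
    altloc = trimws(substr(recs, 17, 17)),
    resname = trimws(substr(recs, 18, 20)),
    chain = substr(recs, 22, 22),
    resseq = parse_num(substr(recs, 23, 26), "residue number"),
    x = parse_num(substr(recs, 31, 38), "x"),
    y = parse_num(substr(recs, 39, 46), "y"),
    z = parse_num(substr(recs, 47, 54), "z"),
    occupancy = suppressWarnings(as.numeric(substr(recs, 55, 60))),
    element = trimws(substr(recs, 77, 78)),
    record = trimws(substr(recs, 1, 6)),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1.0

  # element fallback: infer from the atom name when columns 77-78 are blank
  blank <- !nzchar(atoms$element)
  if (any(blank)) {
    atoms$element[blank] <- vapply(atoms$name[blank], infer_element, "")
  }
  atoms$element <- toupper(atoms$element)

  # altloc resolution: one conformer per (chain, resseq, name); groups
  # where no record carries an altloc letter are left untouched
  n_dropped <- 0L
  key <- paste(atoms$chain, atoms$resseq, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      if (length(i) == 1L) return(i)
      sub <- atoms[i, ]
      if (all(!nzchar(sub$altloc))) return(i)
      best <- order(-sub$occupancy, sub$altloc)[1]
      i[best]
    }), use.names = FALSE)
    keep <- sort(keep)
    n_dropped <- nrow(atoms) - length(keep)
    atoms <- atoms[keep, , drop = FALSE]
    message(sprintf("dropped %d alternate-location conformer(s)", n_dropped))
  }
  rownames(atoms) <- NULL

  if (anyDuplicated(atoms$serial)) {
    atoms$serial <- seq_len(nrow(atoms))
  }

  new_structure(atoms, title = title, n_altloc_dropped = n_dropped)
}

as_text_lines <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

infer_element <- function(name) {
  letters_only <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nzchar(letters_only)) return("X")
  two <- substr(letters_only, 1, 2)
  if (two %in% TWO_LETTER_ELEMENTS && !grepl("^H[A-Z]", letters_only)) {
    return(two)
  }
  substr(letters_only, 1, 1)
}

new_structure <- function(atoms, title = "", n_altloc_dropped = 0L) {
  stopifnot(is.data.frame(atoms))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  structure(
    list(atoms = atoms, title = title,
         n_altloc_dropped = as.integer(n_altloc_dropped)),
    class = "qmx_structure"
  )
}

#' @export
print.qmx_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<qmx_structure> %d atoms, %d residues%s\n",
              nrow(x$atoms), length(unique(rk)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

residue_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resseq, sep = "\r")
}

#' List residues of a structure
#'
#' @param s a `qmx_structure`.
#' @return data frame with one row per residue: `chain`, `resseq`,
#'   `resname`, `n_atoms`, in order of first appearance.
#' @export
structure_residues <- function(s) {
  stopifnot(inherits(s, "qmx_structure"))
  key <- residue_keys(s)
  first <- !duplicated(key)
  out <- s$atoms[first, c("chain", "resseq", "resname")]
  out$n_atoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Write a structure to PDB or XYZ text
#'
#' PDB output round-trips through [read_structure()] with coordinates equal
#' to three decimals. XYZ output is the standard count / comment /
#' `element x y z` layout with six-decimal coordinates.
#'
#' @param s a `qmx_structure`.
#' @param format `"pdb"` or `"xyz"` (case-insensitive).
#' @return a single string of file content.
#' @export
write_structure <- function(s, format = c("pdb", "xyz")) {
  stopifnot(inherits(s, "qmx_structure"))
  if (nrow(s$atoms) == 0L) stop("cannot write an empty structure")
  format <- tolower(format[1])
  if (!format %in% c("pdb", "xyz")) {
    stop(sprintf("unknown format '%s' (use 'pdb' or 'xyz')", format))
  }
  a <- s$atoms
  if (format == "xyz") {
    body <- sprintf("%-2s %13.6f %13.6f %13.6f",
                    pdb_case_element(a$element), a$x, a$y, a$z)
    return(paste(c(nrow(a), s$title, body, ""), collapse = "\n"))
  }
  lines <- character(0)
  if (nzchar(s$title)) lines <- sprintf("TITLE     %s", s$title)
  lines <- c(lines, sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$serial %% 100000, pdb_atom_name(a$name, a$element),
    a$altloc, a$resname, a$chain, a$resseq %% 10000, "",
    a$x, a$y, a$z, a$occupancy, 0, toupper(a$element)
  ), "END")
  paste(c(lines, ""), collapse = "\n")
}

# PDB name column: 1-letter elements start at column 14 unless 4 chars long
pdb_atom_name <- function(name, element) {
  mapply(function(n, e) {
    if (nchar(n) >= 4L || nchar(e) == 2L) {
      formatC(n, width = -4)
    } else {
      formatC(paste0(" ", n), width = -4)
    }
  }, name, element, USE.NAMES = FALSE)
}

# "CU" -> "Cu" for XYZ output
pdb_case_element <- function(el) {
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

#' Select residues from a structure
#'
#' Returns the sub-structure containing exactly the atoms of the named
#' residues, in their original order. Selection is explicit: waters and
#' ions are included only when listed.
#'
#' @param s a `qmx_structure`.
#' @param specs residue specifications: a data frame with columns `chain`
#'   and `resseq`, or a list of length-2 vectors `c(chain, resseq)`.
#' @return a `qmx_structure` with the selected atoms.
#' @export
select_residues <- function(s, specs) {
  stopifnot(inherits(s, "qmx_structure"))
  specs <- normalize_specs(specs)
  want <- paste(specs$chain, specs$resseq, sep = "\r")
  have <- residue_keys(s)
  missing <- !(want %in% have)
  if (any(missing)) {
    stop(sprintf(
      "residue spec(s) not found in structure: %s",
      paste(sprintf("(%s, %d)", specs$chain[missing],
                    specs$resseq[missing]), collapse = ", ")
    ))
  }
  keep <- have %in% want
  new_structure(s$atoms[keep, , drop = FALSE], title = s$title)
}

normalize_specs <- function(specs) {
  if (is.data.frame(specs)) {
    stopifnot(all(c("chain", "resseq") %in% names(specs)))
    out <- specs[, c("chain", "resseq")]
  } else if (is.list(specs)) {
    out <- data.frame(
      chain = vapply(specs, function(p) as.character(p[[1]]), ""),
      resseq = vapply(specs, function(p) as.numeric(p[[2]]), 0),
      stringsAsFactors = FALSE
    )
  } else {
    stop("specs must be a data frame or a list of (chain, resseq) pairs")
  }
  out$chain <- as.character(out$chain)
  out$resseq <- as.integer(out$resseq)
  rownames(out) <- NULL
  out
}
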