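# Geometry analysis: metal-ligand distance tables, state-to-state distance
# deltas, and SVD-based Kabsch superposition RMSD.

#' Metal-ligand distance report
#'
#' Euclidean distances from a metal atom to each named donor atom.
#'
#' @param x a `qmx_structure` or `qmx_cluster`.
#' @param metal metal selector as in [coordination_shell()].
#' @param donors donor atom selectors: a data frame with columns `chain`,
#'   `resseq`, `name`, or a character vector of labels `"chain:resseq:name"`
#'   (e.g. `"A:500:SG"`).
#' @param state optional state label carried on the report.
#' @return data frame of class `qmx_distance_report` with columns `metal`,
#'   `donor`, `distance` (Angstrom) and attribute `state`.
#' @export
metal_ligand_distances <- function(x, metal, donors, state = "") {
  s <- if (inherits(x, "qmx_cluster")) cluster_structure(x) else x
  stopifnot(inherits(s, "qmx_structure"))
  m <- resolve_metal_atom(s, metal)
  donors <- normalize_donor_specs(donors)

  a <- s$atoms
  rows <- lapply(seq_len(nrow(donors)), function(i) {
    j <- which(a$chain == donors$chain[i] & a$resseq == donors$resseq[i] &
                 a$name == donors$name[i])
    if (length(j) != 1L) {
      stop(sprintf("donor atom not found (or ambiguous): %s:%d:%s",
                   donors$chain[i], donors$resseq[i], donors$name[i]))
    }
    if (a$serial[j] == m$serial) {
      stop("metal-to-itself distance is not a ligand distance")
    }
    data.frame(
      metal = sprintf("%s%d", m$element, m$serial),
      donor = sprintf("%s:%d:%s", donors$chain[i], donors$resseq[i],
                      donors$name[i]),
      distance = dist3(c(m$x, m$y, m$z), c(a$x[j], a$y[j], a$z[j])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "state") <- state
  class(out) <- c("qmx_distance_report", class(out))
  out
}

normalize_donor_specs <- function(donors) {
  if (is.character(donors)) {
    parts <- strsplit(donors, ":", fixed = TRUE)
    ok <- vapply(parts, length, 0L) == 3L
    if (!all(ok)) {
      stop("donor labels must be 'chain:resseq:name'")
    }
    donors <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      resseq = as.integer(vapply(parts, `[`, "", 2)),
      name = vapply(parts, `[`, "", 3),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(donors),
            all(c("chain", "resseq", "name") %in% names(donors)))
  donors
}

#' Per-pair distance changes between two reports
#'
#' Pairs are matched by donor label; the delta is `b - a` (e.g. reduced
#' minus oxidized). Pairs whose absolute change exceeds `flag_threshold`
#' are flagged - small metal-ligand shifts (under ~0.1 Angstrom) indicate
#' a conserved coordination geometry across the redox couple.
#'
#' @param a,b `qmx_distance_report` objects with identical pair labels.
#' @param flag_threshold absolute-change flag level, Angstrom
#'   (default 0.1).
#' @return data frame with columns `donor`, `delta`, `flagged`.
#' @export
distance_deltas <- function(a, b, flag_threshold = 0.1) {
  stopifnot(inherits(a, "qmx_distance_report"),
            inherits(b, "qmx_distance_report"))
  unpaired <- c(setdiff(a$donor, b$donor), setdiff(b$donor, a$donor))
  if (length(unpaired)) {
    stop(sprintf("unpaired donor label(s): %s",
                 paste(unique(unpaired), collapse = ", ")))
  }
  i <- match(a$donor, b$donor)
  out <- data.frame(donor = a$donor,
                    delta = b$distance[i] - a$distance,
                    stringsAsFactors = FALSE)
  out$flagged <- abs(out$delta) > flag_threshold
  out
}

#' Minimal RMSD by Kabsch superposition
#'
#' Least-squares rigid superposition of two corresponding point sets via
#' singular value decomposition, with the proper-rotation constraint
#' (determinant +1) so reflections are never used - chirality is
#' preserved. Correspondence is positional: row i of `a` maps to row i
#' of `b`.
#'
#' @param coords_a,coords_b numeric matrices, n x 3, n >= 3.
#' @param selection optional integer row indices restricting the
#'   superposition (applied to both sets).
#' @return minimal RMSD in Angstrom.
#' @export
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch_rmsd(p, p)   # 0
kabsch_rmsd <- function(coords_a, coords_b, selection = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  if (ncol(a) != 3L || ncol(b) != 3L) stop("coordinates must be n x 3")
  n <- nrow(a)
  if (n != nrow(b)) stop("point sets must have equal size")
  if (n < 3L) stop("at least 3 corresponding points are required")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinates")
  }

  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)   # covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))    # enforce proper rotation
  r <- sv$v %*% s %*% t(sv$u)
  diff <- bc - ac %*% t(r)
  sqrt(sum(diff^2) / n)
}

#' Apply the Kabsch superposition to a moving set
#'
#' @param mobile,target n x 3 matrices; `mobile` is rotated/translated
#'   onto `target`.
#' @return the transformed `mobile` coordinates.
#' @export
kabsch_superpose <- function(mobile, target) {
  a <- as.matrix(mobile); b <- as.matrix(target)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3L, ncol(b) == 3L,
            nrow(a) >= 3L)
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  sv <- svd(crossprod(ac, bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(ac %*% t(r), 2, cb, `+`)
}
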