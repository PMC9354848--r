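# Shared helpers and independent oracles for the test suite.

ANCHOR_OF <- c(HIS = "ND1", CYS = "SG", LEU = "CG", LYS = "NZ", MET = "SD")

# residues on a wide ring (6-8 Angstrom): clash-free for any roster, used
# by randomized carving tests
wide_ring_roster <- function(resnames, distances = NULL) {
  n <- length(resnames)
  stopifnot(n >= 1, n <= 5)
  dirs <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                c(-0.5, -sqrt(3) / 2, 0), c(0, 0, 1), c(0, 0, -1))
  data.frame(
    resname = resnames, resseq = 100L + 10L * seq_len(n),
    anchor = unname(ANCHOR_OF[resnames]),
    distance = distances %||% rep(7, n),
    ux = dirs[seq_len(n), 1], uy = dirs[seq_len(n), 2],
    uz = dirs[seq_len(n), 3],
    phase = rep(0, n), stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) brute-force coordination shell, independent of the implementation
brute_force_shell <- function(s, metal_serial, cutoff, donor_elements) {
  a <- s$atoms
  m <- a[a$serial == metal_serial, ]
  hits <- data.frame(serial = integer(0), distance = numeric(0))
  for (i in seq_len(nrow(a))) {
    if (a$chain[i] == m$chain && a$resseq[i] == m$resseq) next
    if (!(a$element[i] %in% donor_elements)) next
    d <- sqrt((a$x[i] - m$x)^2 + (a$y[i] - m$y)^2 + (a$z[i] - m$z)^2)
    if (d <= cutoff) {
      hits <- rbind(hits, data.frame(serial = a$serial[i], distance = d))
    }
  }
  hits[order(hits$distance, hits$serial), , drop = FALSE]
}

# expected link-atom count: enumerate severed backbone bonds of the
# selected residues (CA-N and CA-C, when those neighbours exist)
severed_bond_count <- function(s, specs) {
  total <- 0L
  for (i in seq_len(nrow(specs))) {
    res <- s$atoms[s$atoms$chain == specs$chain[i] &
                     s$atoms$resseq == specs$resseq[i], ]
    if (!"CA" %in% res$name) next   # not an amino acid
    total <- total + ("N" %in% res$name) + ("C" %in% res$name)
  }
  total
}

# heavy atoms expected to survive carving (Cys HG is a hydrogen, so the
# thiolate rule never changes this count)
expected_heavy_atoms <- function(s, specs) {
  total <- 0L
  for (i in seq_len(nrow(specs))) {
    res <- s$atoms[s$atoms$chain == specs$chain[i] &
                     s$atoms$resseq == specs$resseq[i], ]
    heavy <- res$element != "H"
    if ("CA" %in% res$name) {
      removed <- res$name %in% c("N", "C", "O", "OXT")
      total <- total + sum(heavy & !removed)
    } else {
      total <- total + sum(heavy)
    }
  }
  total
}

# rotation matrix from z-y-x Euler angles
euler_rot <- function(a, b, c) {
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  rz %*% ry %*% rx
}

# independent numerical-minimisation RMSD oracle: minimise over rotation
# space (Euler angles) after centering, multi-start BFGS
rmsd_minimisation_oracle <- function(a, b, n_starts = 8) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  n <- nrow(a)
  f <- function(p) {
    r <- euler_rot(p[1], p[2], p[3])
    sqrt(sum((bc - ac %*% t(r))^2) / n)
  }
  starts <- rbind(c(0, 0, 0),
                  as.matrix(expand.grid(c(0.8, 2.4), c(0.8, 2.4),
                                        c(0.8, 2.4)))[seq_len(n_starts - 1), ])
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], f, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# minimal hand-written PDB lines for reader edge-case tests
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, altloc = "", element = "", record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) >= 4 || nchar(element) == 2) formatC(name, width = -4)
          else formatC(paste0(" ", name), width = -4),
          altloc, resname, chain, resseq, x, y, z, occ, 0, element)
}
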