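#' Multi-bead toy systems
#'
#' A `bead_system` is a small particle system with harmonic bonds, cosine
#' torsions on bead quadruples, and a smooth pairwise nonbonded
#' interaction, each bead carrying a group label.  It is the minimal
#' system on which a per-group energy decomposition (bonded,
#' self-nonbonded, pairwise-nonbonded) is meaningful, standing in for a
#' solvated solute.
#'
#' The nonbonded pair function is a repulsive-plus-well 12-6 form,
#' energy-shifted to zero at the cutoff:
#' `V(r) = eps * ((r0/r)^12 - 2 (r0/r)^6) - V_cut` inside the cutoff,
#' zero beyond it.
#' Directly bonded pairs (1-2 neighbours) are excluded from the nonbonded
#' sum.  With a box, nonbonded distances use the minimum-image
#' convention; bonds and torsions are never imaged (chains are kept
#' whole, far smaller than the box).
#'
#' @param positions n x 3 matrix, nm.
#' @param masses length-n vector, u.
#' @param group_label length-n integer vector, 1-based group index per bead.
#' @param bonds data.frame with columns `i, j, r0, kb`
#'   (nm, kJ mol^-1 nm^-2).
#' @param torsions data.frame with columns `i, j, k, l, mult, barrier`
#'   (multiplicity, kJ/mol); may have zero rows.
#' @param nb list with `eps` (kJ/mol), `r0` (nm), `cutoff` (nm).
#' @param box cubic box edge length (nm) or `NULL` for no periodicity.
#' @return an object of class `bead_system`.
#' @export
bead_system <- function(positions, masses, group_label, bonds,
                        torsions = empty_torsions(),
                        nb = list(eps = 0.5, r0 = 0.34, cutoff = 0.9),
                        box = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(masses) == n, length(group_label) == n,
            all(masses > 0))
  group_label <- as.integer(group_label)
  if (any(is.na(group_label)) || any(group_label < 1))
    stop("every bead must belong to exactly one group (positive label)")
  bonds <- as.data.frame(bonds)
  torsions <- as.data.frame(torsions)
  if (nrow(bonds) && any(bonds$i == bonds$j)) stop("bond connecting a bead to itself")
  sys <- structure(list(
    positions = positions, masses = as.numeric(masses),
    group_label = group_label, n_groups = max(group_label),
    bonds = bonds, torsions = torsions, nb = nb,
    box = if (is.null(box)) NULL else as.numeric(box)), class = "bead_system")
  sys$pairs <- nonbonded_pairs(sys)
  sys
}

empty_torsions <- function() {
  data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
             mult = numeric(), barrier = numeric())
}

# all i<j pairs minus 1-2 exclusions
nonbonded_pairs <- function(sys) {
  n <- nrow(sys$positions)
  if (n < 2) return(cbind(i = integer(), j = integer()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- cbind(i = idx[, "row"], j = idx[, "col"])
  if (nrow(sys$bonds)) {
    bkey <- paste(pmin(sys$bonds$i, sys$bonds$j), pmax(sys$bonds$i, sys$bonds$j))
    keep <- !(paste(pairs[, 1], pairs[, 2]) %in% bkey)
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs
}

#' Solute-plus-solvent bead system
#'
#' Builds a bonded solute chain (group 1) surrounded by free solvent
#' beads (group 2), emulating the solute / solvent group split used when
#' accelerating a solute independently of its solvent.  Solvent beads are
#' placed on a jittered cubic lattice so no two beads start inside the
#' repulsive core.  With `n_solute >= 4`, cosine torsions are defined on
#' every consecutive bead quadruple of the chain, giving the system
#' torsion-like coordinates; shorter chains have none.
#'
#' @param n_solute number of chain beads (>= 2).
#' @param n_solvent number of free solvent beads (>= 0).
#' @param seed integer seed; construction is deterministic given the seed.
#' @param torsion_barrier barrier of the chain torsions, kJ/mol.
#' @return a `bead_system` with groups `1` (solute) and `2` (solvent).
#' @examples
#' sys <- make_solute_solvent(4, 20, seed = 1)
#' table(sys$group_label)
#' @export
make_solute_solvent <- function(n_solute, n_solvent, seed = 1,
                                torsion_barrier = 6) {
  if (n_solute < 2) stop("n_solute must be >= 2")
  if (n_solvent < 0) stop("n_solvent must be >= 0")
  n <- n_solute + n_solvent
  r_bond <- 0.3
  # lattice spacing comfortably outside the nonbonded minimum
  spacing <- 0.45
  n_side <- ceiling((n + n_solute)^(1 / 3)) + 1
  box <- n_side * spacing

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # solute chain along x through the box centre, mild zig-zag in y
  pos_solute <- cbind(
    x = (seq_len(n_solute) - (n_solute + 1) / 2) * r_bond + box / 2,
    y = box / 2 + 0.05 * (-1)^(seq_len(n_solute)),
    z = box / 2)
  # solvent on lattice sites not too close to the solute, jittered
  grid1 <- (seq_len(n_side) - 0.5) * spacing
  lattice <- as.matrix(expand.grid(x = grid1, y = grid1, z = grid1))
  dmin <- apply(lattice, 1, function(p)
    min(sqrt(colSums((t(pos_solute) - p)^2))))
  lattice <- lattice[dmin > 0.35, , drop = FALSE]
  if (nrow(lattice) < n_solvent)
    stop("cannot place ", n_solvent, " solvent beads without overlap")
  sel <- sample.int(nrow(lattice), n_solvent)
  pos_solvent <- lattice[sel, , drop = FALSE] +
    matrix(runif(3 * n_solvent, -0.04, 0.04), ncol = 3)

  positions <- rbind(pos_solute, pos_solvent)
  bonds <- data.frame(i = seq_len(n_solute - 1), j = 2:n_solute,
                      r0 = r_bond, kb = 4000)
  torsions <- if (n_solute >= 4) {
    s <- seq_len(n_solute - 3)
    data.frame(i = s, j = s + 1, k = s + 2, l = s + 3,
               mult = 3, barrier = torsion_barrier)
  } else empty_torsions()
  bead_system(positions = positions,
              masses = rep(16, n),
              group_label = rep(c(1L, 2L), c(n_solute, n_solvent)),
              bonds = bonds, torsions = torsions, box = box)
}

# minimum-image displacement matrix (rows = vectors)
mi_vec <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

#' Dihedral angles of bead quadruples
#'
#' @param positions n x 3 matrix.
#' @param quads data.frame or matrix with columns `i, j, k, l`.
#' @return angles in degrees in \[-180, 180).
#' @export
dihedral_angle <- function(positions, quads) {
  quads <- as.matrix(as.data.frame(quads)[, c("i", "j", "k", "l")])
  b1 <- positions[quads[, 2], , drop = FALSE] - positions[quads[, 1], , drop = FALSE]
  b2 <- positions[quads[, 3], , drop = FALSE] - positions[quads[, 2], , drop = FALSE]
  b3 <- positions[quads[, 4], , drop = FALSE] - positions[quads[, 3], , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, n2)
  b2n <- sqrt(rowSums(b2^2))
  y <- rowSums(m1 * b2) / b2n
  x <- rowSums(n1 * n2)
  wrap_periodic(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Per-interaction energies and per-bead force contributions.
# Returns lists keyed by interaction class; forces are full n x 3
# matrices per class subset only where needed by callers.
bead_interactions <- function(sys, positions) {
  n <- nrow(positions)
  box <- sys$box
  out <- list()

  # bonds
  if (nrow(sys$bonds)) {
    bi <- sys$bonds$i; bj <- sys$bonds$j
    d <- positions[bj, , drop = FALSE] - positions[bi, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - sys$bonds$r0
    out$bond_e <- 0.5 * sys$bonds$kb * dr^2
    fmag <- -sys$bonds$kb * dr / r        # force on j along +d
    out$bond_f_j <- d * fmag              # force on j; on i is the negative
  } else {
    out$bond_e <- numeric()
    out$bond_f_j <- matrix(0, 0, 3)
  }

  # torsions: V = (barrier/2) * (1 + cos(mult * phi))
  nt <- nrow(sys$torsions)
  if (nt) {
    tq <- sys$torsions
    p1 <- positions[tq$i, , drop = FALSE]; p2 <- positions[tq$j, , drop = FALSE]
    p3 <- positions[tq$k, , drop = FALSE]; p4 <- positions[tq$l, , drop = FALSE]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
    b2n <- sqrt(rowSums(b2^2))
    phi <- atan2(rowSums(cross3(n1, n2) * b2) / b2n, rowSums(n1 * n2))
    out$torsion_e <- 0.5 * tq$barrier * (1 + cos(tq$mult * phi))
    dVdphi <- -0.5 * tq$barrier * tq$mult * sin(tq$mult * phi)
    # dphi/dr (standard closed form); F = -dV/dphi * dphi/dr
    dphi1 <- -n1 * (b2n / n1sq)
    dphi4 <- n2 * (b2n / n2sq)
    c12 <- rowSums(b1 * b2) / b2n^2
    c32 <- rowSums(b3 * b2) / b2n^2
    dphi2 <- -dphi1 + c12 * dphi1 - c32 * dphi4
    dphi3 <- -dphi4 - c12 * dphi1 + c32 * dphi4
    out$torsion_f <- list(f1 = -dVdphi * dphi1, f2 = -dVdphi * dphi2,
                          f3 = -dVdphi * dphi3, f4 = -dVdphi * dphi4)
  } else {
    out$torsion_e <- numeric()
    out$torsion_f <- NULL
  }

  # nonbonded pairs
  pr <- sys$pairs
  if (nrow(pr)) {
    d <- mi_vec(positions[pr[, 2], , drop = FALSE] -
                  positions[pr[, 1], , drop = FALSE], box)
    r2 <- rowSums(d^2)
    rc <- sys$nb$cutoff
    inside <- r2 < rc^2
    e <- numeric(nrow(pr))
    fmag <- numeric(nrow(pr))
    if (any(inside)) {
      r2i <- 1 / r2[inside]
      s6 <- (sys$nb$r0^2 * r2i)^3
      eps <- sys$nb$eps
      vshift <- eps * ((sys$nb$r0 / rc)^12 - 2 * (sys$nb$r0 / rc)^6)
      e[inside] <- eps * (s6^2 - 2 * s6) - vshift
      # dV/dr2 = eps * (-12 s12 + 12 s6) / (2 r2); force on j = -2 dV/dr2 * d
      fmag[inside] <- 12 * eps * (s6^2 - s6) * r2i
    }
    out$pair_e <- e
    out$pair_f_j <- d * fmag
  } else {
    out$pair_e <- numeric()
    out$pair_f_j <- matrix(0, 0, 3)
  }
  out
}

#' Total potential energy and forces of a bead system
#'
#' Independent plain summation over all interactions (the reference
#' against which the per-term decomposition is checked).
#'
#' @param sys a `bead_system`.
#' @param positions n x 3 matrix; defaults to the stored positions.
#' @return `bead_energy()` a scalar (kJ/mol); `bead_forces()` an
#'   n x 3 matrix (kJ mol^-1 nm^-1).
#' @export
bead_energy <- function(sys, positions = sys$positions) {
  ia <- bead_interactions(sys, positions)
  sum(ia$bond_e) + sum(ia$torsion_e) + sum(ia$pair_e)
}

#' @rdname bead_energy
#' @export
bead_forces <- function(sys, positions = sys$positions) {
  ia <- bead_interactions(sys, positions)
  accumulate_forces(sys, ia)$total
}

# scatter per-interaction contributions onto beads; optionally scaled
# per interaction (scale vectors aligned with bond/torsion/pair rows)
accumulate_forces <- function(sys, ia, bond_scale = NULL, torsion_scale = NULL,
                              pair_scale = NULL) {
  n <- nrow(sys$positions)
  f <- matrix(0, n, 3)
  if (nrow(sys$bonds)) {
    fb <- ia$bond_f_j
    if (!is.null(bond_scale)) fb <- fb * bond_scale
    for (col in 1:3) {
      f[, col] <- f[, col] +
        tab_sum(sys$bonds$j, fb[, col], n) - tab_sum(sys$bonds$i, fb[, col], n)
    }
  }
  if (nrow(sys$torsions)) {
    tf <- ia$torsion_f
    sc <- torsion_scale
    for (col in 1:3) {
      v1 <- tf$f1[, col]; v2 <- tf$f2[, col]; v3 <- tf$f3[, col]; v4 <- tf$f4[, col]
      if (!is.null(sc)) { v1 <- v1 * sc; v2 <- v2 * sc; v3 <- v3 * sc; v4 <- v4 * sc }
      f[, col] <- f[, col] + tab_sum(sys$torsions$i, v1, n) +
        tab_sum(sys$torsions$j, v2, n) + tab_sum(sys$torsions$k, v3, n) +
        tab_sum(sys$torsions$l, v4, n)
    }
  }
  if (nrow(sys$pairs)) {
    fp <- ia$pair_f_j
    if (!is.null(pair_scale)) fp <- fp * pair_scale
    for (col in 1:3) {
      f[, col] <- f[, col] +
        tab_sum(sys$pairs[, 2], fp[, col], n) - tab_sum(sys$pairs[, 1], fp[, col], n)
    }
  }
  list(total = f)
}

tab_sum <- function(idx, vals, n) {
  .cpp_index_sum(as.integer(idx), as.numeric(vals), as.integer(n))
}

#' Steepest-descent minimisation
#'
#' A few damped gradient-descent steps to relax strained starting
#' configurations before dynamics.
#'
#' @param sys a `bead_system`.
#' @param n_steps iteration budget.
#' @param step_size initial displacement scale (nm per unit force).
#' @return updated positions matrix.
#' @export
minimize_beads <- function(sys, n_steps = 200, step_size = 1e-4) {
  x <- sys$positions
  e <- bead_energy(sys, x)
  for (s in seq_len(n_steps)) {
    f <- bead_forces(sys, x)
    xn <- x + step_size * f
    en <- bead_energy(sys, xn)
    if (en < e) {
      x <- xn; e <- en; step_size <- step_size * 1.2
    } else {
      step_size <- step_size / 2
      if (step_size < 1e-12) break
    }
  }
  x
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("<bead_system> %d beads in %d group(s); %d bond(s), %d torsion(s), %d nonbonded pair(s)%s\n",
              nrow(x$positions), x$n_groups, nrow(x$bonds), nrow(x$torsions),
              nrow(x$pairs),
              if (is.null(x$box)) "" else sprintf("; box %.3g nm", x$box)))
  invisible(x)
}
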