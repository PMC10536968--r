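# Shared fixtures and independent brute-force oracles.

# random multi-group bead system: contiguous groups, chain bonds within
# each group, one torsion per group of >= 4 beads
random_bead_system <- function(n = 15, n_groups = 3, seed = 1, box = 3) {
  set.seed(seed)
  sizes <- rep(n %/% n_groups, n_groups)
  sizes[seq_len(n %% n_groups)] <- sizes[seq_len(n %% n_groups)] + 1
  glab <- rep(seq_len(n_groups), sizes)
  positions <- matrix(runif(3 * n, 0.2, box - 0.2), n, 3)
  bonds <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    idx <- which(glab == g)
    if (length(idx) < 2) return(NULL)
    data.frame(i = idx[-length(idx)], j = idx[-1],
               r0 = runif(length(idx) - 1, 0.2, 0.4),
               kb = runif(length(idx) - 1, 500, 2000))
  }))
  # keep bonded neighbours at plausible distances so energies stay tame
  for (b in seq_len(nrow(bonds))) {
    d <- positions[bonds$j[b], ] - positions[bonds$i[b], ]
    positions[bonds$j[b], ] <- positions[bonds$i[b], ] +
      d / sqrt(sum(d^2)) * bonds$r0[b] * runif(1, 0.8, 1.2)
  }
  torsions <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    idx <- which(glab == g)
    if (length(idx) < 4) return(NULL)
    data.frame(i = idx[1], j = idx[2], k = idx[3], l = idx[4],
               mult = sample(1:3, 1), barrier = runif(1, 2, 8))
  }))
  if (is.null(torsions)) torsions <- selgamd:::empty_torsions()
  bead_system(positions, masses = runif(n, 10, 20), group_label = glab,
              bonds = bonds, torsions = torsions, box = box)
}

# independent interaction-by-interaction energy split (scalar loops,
# re-deriving every energy from coordinates; never calls split_energy)
brute_split_energy <- function(sys, positions, catalogue) {
  e <- setNames(rep(0, nrow(catalogue)), catalogue$id)
  glab <- sys$group_label
  dual <- isTRUE(attr(catalogue, "dual_boost"))
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds$i[b]; j <- sys$bonds$j[b]
    r <- sqrt(sum((positions[j, ] - positions[i, ])^2))
    e[paste0("bonded_", glab[i])] <- e[paste0("bonded_", glab[i])] +
      0.5 * sys$bonds$kb[b] * (r - sys$bonds$r0[b])^2
  }
  for (t in seq_len(nrow(sys$torsions))) {
    tq <- sys$torsions[t, ]
    phi <- dihedral_angle(positions, tq) * pi / 180
    tgt <- if (dual) paste0("dihedral_", glab[tq$i]) else paste0("bonded_", glab[tq$i])
    e[tgt] <- e[tgt] + 0.5 * tq$barrier * (1 + cos(tq$mult * phi))
  }
  rc <- sys$nb$cutoff; eps <- sys$nb$eps; r0 <- sys$nb$r0
  vshift <- eps * ((r0 / rc)^12 - 2 * (r0 / rc)^6)
  bkey <- if (nrow(sys$bonds))
    paste(pmin(sys$bonds$i, sys$bonds$j), pmax(sys$bonds$i, sys$bonds$j))
  else character()
  n <- nrow(positions)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% bkey) next
    d <- positions[j, ] - positions[i, ]
    if (!is.null(sys$box)) d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    if (r >= rc) next
    v <- eps * ((r0 / r)^12 - 2 * (r0 / r)^6) - vshift
    gi <- glab[i]; gj <- glab[j]
    tgt <- if (gi == gj) paste0("self_", gi)
           else paste0("pair_", min(gi, gj), "-", max(gi, gj))
    e[tgt] <- e[tgt] + v
  }
  e
}

# central finite-difference forces from any scalar energy function
fd_forces <- function(efun, positions, h = 1e-6) {
  f <- positions * 0
  for (b in seq_len(nrow(positions))) for (c in 1:3) {
    xp <- positions; xp[b, c] <- xp[b, c] + h
    xm <- positions; xm[b, c] <- xm[b, c] - h
    f[b, c] <- -(efun(xp) - efun(xm)) / (2 * h)
  }
  f
}

# brute-force LEUS bias: double loop over grid points, polynomial
# biweight kernel with Heaviside cutoff at 2 sigma
brute_bias_energy <- function(bias, q) {
  g1 <- function(d, per) {
    d <- ((d + per / 2) %% per) - per / 2
    if (abs(d) >= 2 * bias$sigma) return(0)
    (1 - (d / (2 * bias$sigma))^2)^2
  }
  tot <- 0
  if (bias$n_dims == 1) {
    per <- diff(bias$ranges[[1]])
    ctr <- selgamd:::leus_centers(bias, 1)
    for (k in seq_len(bias$n_grid))
      tot <- tot + bias$c * bias$visits[k] * g1(q[1] - ctr[k], per)
  } else {
    ctr1 <- selgamd:::leus_centers(bias, 1)
    ctr2 <- selgamd:::leus_centers(bias, 2)
    for (k1 in seq_len(bias$n_grid)) for (k2 in seq_len(bias$n_grid))
      tot <- tot + bias$c * bias$visits[k1, k2] *
        g1(q[1] - ctr1[k1], diff(bias$ranges[[1]])) *
        g1(q[2] - ctr2[k2], diff(bias$ranges[[2]]))
  }
  tot
}

# two-letter toy linkage on (phi, psi)
toy_linkage <- function(name = "L1", angles = c("phi", "psi")) {
  linkage_definition(name, angles,
    list(A = list(c(-150, -30), c(-90, 90)),
         B = list(c(30, 150), c(-90, 90)),
         C = list(c(-150, -30), c(90, -90)),
         D = list(c(30, 150), c(90, -90))))
}
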