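test_that("catalogue holds exactly N + N + N(N-1)/2 terms", {
  for (N in 1:6) {
    sizes <- rep(2, N)
    groups <- lapply(seq_len(N), function(g)
      group_definition(paste0("g", g), (2 * g - 1):(2 * g)))
    catg <- build_catalogue(groups, n_beads = 2 * N)
    expect_equal(nrow(catg), 2 * N + N * (N - 1) / 2)
    expect_equal(sum(catg$kind == "bonded"), N)
    expect_equal(sum(catg$kind == "self"), N)
    expect_equal(sum(catg$kind == "pair"), N * (N - 1) / 2)
    catd <- build_catalogue(groups, n_beads = 2 * N, dual_boost = TRUE)
    expect_equal(nrow(catd), 2 * N + N * (N - 1) / 2 + N)
  }
  # N = 2 names
  g2 <- list(group_definition("a", 1:2), group_definition("b", 3:4))
  expect_setequal(build_catalogue(g2, 4)$id,
                  c("bonded_1", "bonded_2", "self_1", "self_2", "pair_1-2"))
})

test_that("non-partitions are rejected", {
  expect_error(build_catalogue(list(group_definition("a", 1:3),
                                    group_definition("b", 3:5)), 5),
               "overlap")
  expect_error(build_catalogue(list(group_definition("a", 1:3)), 5),
               "cover")
})

test_that("split energies match an independent brute-force tagging loop", {
  for (seed in 1:4) {
    sys <- random_bead_system(n = 14, n_groups = 3, seed = seed)
    catg <- build_catalogue(sys)
    e <- split_energy(sys, catalogue = catg)
    oracle <- brute_split_energy(sys, sys$positions, catg)
    expect_equal(e, oracle, tolerance = 1e-10)
    expect_equal(sum(e), bead_energy(sys), tolerance = 1e-12)
  }
  # dual boosting carves torsions out of bonded terms
  sys <- random_bead_system(n = 12, n_groups = 3, seed = 9)
  catd <- build_catalogue(sys, dual_boost = TRUE)
  ed <- split_energy(sys, catalogue = catd)
  oracle_d <- brute_split_energy(sys, sys$positions, catd)
  expect_equal(ed, oracle_d, tolerance = 1e-10)
  expect_equal(sum(ed), bead_energy(sys), tolerance = 1e-12)
})

test_that("split forces sum to the total and match finite differences", {
  sys <- random_bead_system(n = 9, n_groups = 3, seed = 11)
  catg <- build_catalogue(sys)
  fs <- split_forces(sys, catalogue = catg)
  ftot <- Reduce(`+`, fs)
  expect_lt(max(abs(ftot - bead_forces(sys))),
            1e-9 * max(1, max(abs(ftot))))
  # each per-term force is minus the gradient of that term's energy
  for (id in c("bonded_1", "self_2", "pair_1-2", "pair_2-3")) {
    efun <- function(x) split_energy(sys, x, catg)[[id]]
    fd <- fd_forces(efun, sys$positions)
    expect_lt(max(abs(fs[[id]] - fd)), 1e-5 * max(1, max(abs(fs[[id]]))))
  }
})

test_that("single-bond single-group system decomposes trivially", {
  sys <- make_solute_solvent(2, 0, seed = 1)
  sys1 <- bead_system(sys$positions, sys$masses, c(1, 1), sys$bonds,
                      box = sys$box)
  catg <- build_catalogue(sys1)
  e <- split_energy(sys1, catalogue = catg)
  r <- sqrt(sum((sys1$positions[2, ] - sys1$positions[1, ])^2))
  expect_equal(unname(e["bonded_1"]),
               0.5 * sys1$bonds$kb[1] * (r - sys1$bonds$r0[1])^2)
  # the bonded pair is excluded from nonbonded, so self energy is 0
  expect_equal(unname(e["self_1"]), 0)
  f <- split_forces(sys1, catalogue = catg)
  d <- sys1$positions[2, ] - sys1$positions[1, ]
  spring <- -sys1$bonds$kb[1] * (r - sys1$bonds$r0[1]) * d / r
  expect_equal(f[["bonded_1"]][2, ], unname(spring), tolerance = 1e-12)
})

test_that("bonded terms spanning two groups are an error", {
  sys <- make_solute_solvent(4, 4, seed = 2)
  # split the solute chain across two groups
  bad <- bead_system(sys$positions, sys$masses,
                     c(1, 1, 2, 2, rep(2, 4)), sys$bonds, sys$torsions,
                     box = sys$box)
  catg <- build_catalogue(bad)
  expect_error(split_energy(bad, catalogue = catg), "spans two groups")
})

test_that("region validation resolves membership and rejects conflicts", {
  sys <- make_solute_solvent(4, 10, seed = 1)
  catg <- build_catalogue(sys)
  rs <- validate_regions(list(
    acceleration_region("solute", c("1-1", "1-2")),
    acceleration_region("solvent", "2-2", accelerate = FALSE)), catg)
  expect_setequal(rs$regions$solute$member_terms,
                  c("bonded_1", "self_1", "pair_1-2"))
  expect_setequal(rs$regions$solvent$member_terms, c("bonded_2", "self_2"))
  expect_length(rs$unassigned, 0)
  # double-claimed term
  expect_error(validate_regions(list(
    acceleration_region("a", "pair_1-2"),
    acceleration_region("b", c("1-2", "2-2"))), catg), "claimed")
  # empty accelerated region
  expect_error(validate_regions(acceleration_region("e", character()), catg),
               "no member terms")
  # unknown term index
  expect_error(validate_regions(acceleration_region("x", "3-3"), catg),
               "nonexistent")
  # unassigned terms recorded as unboosted
  rs2 <- validate_regions(acceleration_region("solute", "1-1"), catg)
  expect_setequal(rs2$unassigned, c("bonded_2", "self_2", "pair_1-2"))
})

test_that("merging groups preserves term sums (refinement consistency)", {
  sys <- random_bead_system(n = 12, n_groups = 3, seed = 21)
  fine <- split_energy(sys, catalogue = build_catalogue(sys))
  merged <- bead_system(sys$positions, sys$masses,
                        ifelse(sys$group_label == 3, 2, sys$group_label),
                        sys$bonds, sys$torsions, box = sys$box)
  coarse <- split_energy(merged, catalogue = build_catalogue(merged))
  expect_equal(unname(coarse["bonded_1"]), unname(fine["bonded_1"]))
  expect_equal(unname(coarse["bonded_2"]),
               unname(fine["bonded_2"] + fine["bonded_3"]), tolerance = 1e-12)
  expect_equal(unname(coarse["self_2"]),
               unname(fine["self_2"] + fine["self_3"] + fine["pair_2-3"]),
               tolerance = 1e-12)
  expect_equal(unname(coarse["pair_1-2"]),
               unname(fine["pair_1-2"] + fine["pair_1-3"]), tolerance = 1e-12)
})
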