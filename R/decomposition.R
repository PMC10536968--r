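#' Atom groups and the energy-term catalogue
#'
#' Selective acceleration starts from a partition of the beads into
#' groups.  For `N` groups the potential energy is monitored as exactly
#' `N` bonded terms, `N` self-nonbonded terms and `N(N-1)/2` pairwise
#' nonbonded terms between distinct groups; when dual boosting is
#' requested, the torsional energy of each group is carved out of its
#' bonded term into a separate dihedral term (at most one per group).
#' Acceleration regions are then composed from these term indices.
#'
#' @name decomposition
NULL

#' Define an atom group
#'
#' @param label group name.
#' @param atom_indices 1-based bead indices belonging to the group.
#' @return a `group_definition`.
#' @export
group_definition <- function(label, atom_indices) {
  atom_indices <- sort(unique(as.integer(atom_indices)))
  if (!length(atom_indices)) stop("a group must contain at least one bead")
  structure(list(label = as.character(label), atom_indices = atom_indices),
            class = "group_definition")
}

#' Groups from a system's bead labels
#'
#' @param sys a `bead_system`.
#' @param labels optional character names, one per group index.
#' @return list of `group_definition`.
#' @export
groups_from_system <- function(sys, labels = NULL) {
  ng <- sys$n_groups
  labels <- labels %||% paste0("group", seq_len(ng))
  lapply(seq_len(ng), function(g)
    group_definition(labels[g], which(sys$group_label == g)))
}

check_partition <- function(groups, n_beads) {
  all_idx <- unlist(lapply(groups, `[[`, "atom_indices"))
  if (anyDuplicated(all_idx))
    stop("groups overlap: bead(s) ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "),
         " appear in more than one group")
  missing <- setdiff(seq_len(n_beads), all_idx)
  if (length(missing))
    stop("groups do not cover bead(s) ", paste(missing, collapse = ", "),
         "; groups must partition all beads")
  invisible(TRUE)
}

#' Build the energy-term catalogue
#'
#' For `N` groups the catalogue holds `N` bonded terms (`bonded_i`), `N`
#' self-nonbonded terms (`self_i`) and `N(N-1)/2` inter-group nonbonded
#' terms (`pair_i-j`, `i < j`), i.e. `2N + N(N-1)/2` terms; with
#' `dual_boost = TRUE`, `N` additional `dihedral_i` terms (the torsional
#' part of each group's bonded energy, then excluded from `bonded_i`).
#'
#' @param groups list of `group_definition` forming a partition, or a
#'   `bead_system` (its labels are used).
#' @param n_beads total bead count (required when `groups` is a list).
#' @param dual_boost add per-group dihedral terms.
#' @return a `term_catalogue`: data.frame with columns `id`, `kind`
#'   (`bonded`, `self`, `pair`, `dihedral`), `i`, `j` (`NA` except pairs),
#'   plus attributes `groups` and `dual_boost`.
#' @examples
#' g <- list(group_definition("solute", 1:4), group_definition("solvent", 5:24))
#' build_catalogue(g, n_beads = 24)
#' @export
build_catalogue <- function(groups, n_beads = NULL, dual_boost = FALSE) {
  if (inherits(groups, "bead_system")) {
    n_beads <- nrow(groups$positions)
    groups <- groups_from_system(groups)
  }
  if (is.null(n_beads)) n_beads <- max(unlist(lapply(groups, `[[`, "atom_indices")))
  check_partition(groups, n_beads)
  ng <- length(groups)
  cat_df <- data.frame(
    id = c(paste0("bonded_", seq_len(ng)), paste0("self_", seq_len(ng))),
    kind = rep(c("bonded", "self"), each = ng),
    i = rep(seq_len(ng), 2), j = NA_integer_,
    stringsAsFactors = FALSE)
  if (ng > 1) {
    pr <- t(combn(ng, 2))
    cat_df <- rbind(cat_df, data.frame(
      id = paste0("pair_", pr[, 1], "-", pr[, 2]),
      kind = "pair", i = pr[, 1], j = pr[, 2], stringsAsFactors = FALSE))
  }
  if (dual_boost) {
    cat_df <- rbind(cat_df, data.frame(
      id = paste0("dihedral_", seq_len(ng)),
      kind = "dihedral", i = seq_len(ng), j = NA_integer_,
      stringsAsFactors = FALSE))
  }
  structure(cat_df, groups = groups, dual_boost = dual_boost,
            class = c("term_catalogue", "data.frame"))
}

# map beads -> group index from a catalogue
catalogue_bead_groups <- function(catalogue, n_beads) {
  groups <- attr(catalogue, "groups")
  g <- integer(n_beads)
  for (gi in seq_along(groups)) g[groups[[gi]]$atom_indices] <- gi
  g
}

# classify every interaction of `sys` into a catalogue term; cached view
# used by both split_energy/split_forces and the dynamics engine.
term_assignment <- function(sys, catalogue) {
  n <- nrow(sys$positions)
  bg <- catalogue_bead_groups(catalogue, n)
  dual <- isTRUE(attr(catalogue, "dual_boost"))

  if (nrow(sys$bonds)) {
    gi <- bg[sys$bonds$i]; gj <- bg[sys$bonds$j]
    if (any(gi != gj))
      stop("bonded interaction spans two groups (bond ",
           which(gi != gj)[1], "); draw group boundaries at nonbonded interfaces")
    bond_term <- paste0("bonded_", gi)
  } else bond_term <- character()

  if (nrow(sys$torsions)) {
    tg <- cbind(bg[sys$torsions$i], bg[sys$torsions$j],
                bg[sys$torsions$k], bg[sys$torsions$l])
    if (any(tg != tg[, 1]))
      stop("torsion spans two groups; draw group boundaries at nonbonded interfaces")
    torsion_term <- paste0(if (dual) "dihedral_" else "bonded_", tg[, 1])
  } else torsion_term <- character()

  if (nrow(sys$pairs)) {
    gi <- bg[sys$pairs[, 1]]; gj <- bg[sys$pairs[, 2]]
    lo <- pmin(gi, gj); hi <- pmax(gi, gj)
    pair_term <- ifelse(lo == hi, paste0("self_", lo), paste0("pair_", lo, "-", hi))
  } else pair_term <- character()

  bad <- setdiff(unique(c(bond_term, torsion_term, pair_term)), catalogue$id)
  if (length(bad)) stop("internal: interaction assigned to unknown term ", bad[1])
  list(bond = bond_term, torsion = torsion_term, pair = pair_term)
}

#' Split the potential energy into catalogue terms
#'
#' Every bond (and torsion) is assigned to the bonded (or, under dual
#' boosting, dihedral) term of the group owning its beads; a bond or
#' torsion spanning two groups is an error.  Every nonbonded pair (a, b)
#' contributes to `self_i` when both beads are in group `i`, otherwise to
#' `pair_i-j`.  The values sum to the undecomposed total potential.
#'
#' @param sys a `bead_system`.
#' @param positions coordinates (defaults to the system's).
#' @param catalogue a `term_catalogue` for the system.
#' @return named numeric vector of energies (kJ/mol), one per term id.
#' @export
split_energy <- function(sys, positions = sys$positions, catalogue) {
  asg <- term_assignment(sys, catalogue)
  ia <- bead_interactions(sys, positions)
  e <- setNames(numeric(nrow(catalogue)), catalogue$id)
  add <- function(e, terms, vals) {
    if (length(vals)) {
      acc <- rowsum(vals, terms)
      e[rownames(acc)] <- e[rownames(acc)] + acc[, 1]
    }
    e
  }
  e <- add(e, asg$bond, ia$bond_e)
  e <- add(e, asg$torsion, ia$torsion_e)
  e <- add(e, asg$pair, ia$pair_e)
  e
}

#' Split the forces into catalogue terms
#'
#' @inheritParams split_energy
#' @return named list of n x 3 force matrices, one per term id; each is
#'   minus the gradient of that term's energy, and they sum to the total
#'   force.
#' @export
split_forces <- function(sys, positions = sys$positions, catalogue) {
  asg <- term_assignment(sys, catalogue)
  ia <- bead_interactions(sys, positions)
  n <- nrow(positions)
  out <- setNames(vector("list", nrow(catalogue)), catalogue$id)
  for (id in catalogue$id) out[[id]] <- matrix(0, n, 3)

  if (nrow(sys$bonds)) {
    for (id in unique(asg$bond)) {
      sel <- asg$bond == id
      sub <- sys; sub$bonds <- sys$bonds[sel, , drop = FALSE]
      sub$torsions <- empty_torsions(); sub$pairs <- sub$pairs[0, , drop = FALSE]
      out[[id]] <- out[[id]] + accumulate_forces(
        sub, list(bond_f_j = ia$bond_f_j[sel, , drop = FALSE]))$total
    }
  }
  if (nrow(sys$torsions)) {
    for (id in unique(asg$torsion)) {
      sel <- asg$torsion == id
      sub <- sys; sub$torsions <- sys$torsions[sel, , drop = FALSE]
      sub$bonds <- sys$bonds[0, , drop = FALSE]; sub$pairs <- sub$pairs[0, , drop = FALSE]
      tf <- lapply(ia$torsion_f, function(m) m[sel, , drop = FALSE])
      out[[id]] <- out[[id]] + accumulate_forces(sub, list(torsion_f = tf))$total
    }
  }
  if (nrow(sys$pairs)) {
    for (id in unique(asg$pair)) {
      sel <- asg$pair == id
      sub <- sys; sub$pairs <- sys$pairs[sel, , drop = FALSE]
      sub$bonds <- sys$bonds[0, , drop = FALSE]; sub$torsions <- empty_torsions()
      out[[id]] <- out[[id]] + accumulate_forces(
        sub, list(pair_f_j = ia$pair_f_j[sel, , drop = FALSE]))$total
    }
  }
  out
}

#' Define an acceleration region
#'
#' A region is a named set of catalogue term ids sharing one boost
#' potential.  Members may be given as term ids (`"bonded_1"`,
#' `"self_2"`, `"pair_1-2"`) or in the compact group-index notation:
#' `"1-1"` expands to all terms of group 1 (bonded, self and, when
#' present, dihedral), `"1-2"` to the inter-group pair term.
#'
#' @param name region name.
#' @param member_terms character vector of term ids / compact indices.
#' @param accelerate apply a boost to this region (an accelerated region
#'   must have at least one member term).
#' @param dual_boost boost the region's dihedral terms separately.
#' @param sigma0 per-region upper bound on the boost standard deviation
#'   (kJ/mol) used in parameter estimation.
#' @return an `acceleration_region` spec (membership resolved by
#'   [validate_regions()]).
#' @export
acceleration_region <- function(name, member_terms, accelerate = TRUE,
                                dual_boost = FALSE, sigma0 = 10) {
  structure(list(name = as.character(name),
                 member_terms = as.character(member_terms),
                 accelerate = isTRUE(accelerate),
                 dual_boost = isTRUE(dual_boost),
                 sigma0 = as.numeric(sigma0)),
            class = "acceleration_region")
}

expand_member_terms <- function(terms, catalogue) {
  out <- character()
  for (tm in terms) {
    if (tm %in% catalogue$id) { out <- c(out, tm); next }
    m <- regmatches(tm, regexec("^([0-9]+)-([0-9]+)$", tm))[[1]]
    if (length(m)) {
      i <- as.integer(m[2]); j <- as.integer(m[3])
      if (i == j) {
        ids <- catalogue$id[catalogue$kind %in% c("bonded", "self", "dihedral") &
                              catalogue$i == i]
      } else {
        ids <- catalogue$id[catalogue$kind == "pair" &
                              catalogue$i == min(i, j) & catalogue$j == max(i, j)]
      }
      if (!length(ids)) stop("region references nonexistent term index '", tm, "'")
      out <- c(out, ids)
      next
    }
    stop("region references nonexistent term index '", tm, "'")
  }
  unique(out)
}

#' Validate and resolve acceleration regions
#'
#' Resolves compact member notation against the catalogue, checks that no
#' term is claimed by two regions and that accelerated regions are
#' non-empty, and records the remaining catalogue terms as unboosted.
#'
#' @param specs list of `acceleration_region` (a single region may be
#'   passed bare).
#' @param catalogue a `term_catalogue`.
#' @return a `region_set`: list with `regions` (each with resolved
#'   `member_terms`, and `dihedral_terms` split out when the region has
#'   `dual_boost`), `unassigned` term ids, and the `catalogue`.
#' @export
validate_regions <- function(specs, catalogue) {
  if (inherits(specs, "acceleration_region")) specs <- list(specs)
  claimed <- character()
  regions <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "acceleration_region"))
    ids <- expand_member_terms(sp$member_terms, catalogue)
    dup <- intersect(ids, claimed)
    if (length(dup))
      stop("term '", dup[1], "' is claimed by more than one region")
    claimed <<- c(claimed, ids)
    if (sp$accelerate && !length(ids))
      stop("accelerated region '", sp$name, "' has no member terms")
    # keep catalogue order so energy sums are order-stable
    ids <- catalogue$id[catalogue$id %in% ids]
    dih <- ids[ids %in% catalogue$id[catalogue$kind == "dihedral"]]
    if (sp$dual_boost && !length(dih))
      warning("region '", sp$name,
              "' requests dual boosting but has no dihedral terms; ",
              "its dihedral sub-boost is identically zero")
    sp$member_terms <- if (sp$dual_boost) setdiff(ids, dih) else ids
    sp$dihedral_terms <- if (sp$dual_boost) dih else character()
    sp
  })
  names(regions) <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(names(regions))) stop("duplicate region names")
  structure(list(regions = regions,
                 unassigned = setdiff(catalogue$id, claimed),
                 catalogue = catalogue),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", length(x$regions), "region(s):\n")
  for (r in x$regions)
    cat(sprintf("  %s [%s%s]: %s%s\n", r$name,
                if (r$accelerate) "boosted" else "unboosted",
                if (r$dual_boost) ", dual" else "",
                paste(r$member_terms, collapse = " "),
                if (length(r$dihedral_terms))
                  paste0(" | dihedral: ", paste(r$dihedral_terms, collapse = " "))
                else ""))
  if (length(x$unassigned))
    cat("  unassigned (unboosted):", paste(x$unassigned, collapse = " "), "\n")
  invisible(x)
}
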