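#' Integrator configuration
#'
#' Settings for the leapfrog Langevin (BAOAB) integrator.  The Langevin
#' thermostat gives rigorous canonical sampling on toy systems; there is
#' no barostat (fixed volume) and no constraint algorithm.
#'
#' @param timestep ps (> 0).
#' @param temperature K (> 0).
#' @param friction collision rate, 1/ps (>= 0; 0 gives pure leapfrog).
#' @param n_steps number of integration steps (>= 0).
#' @param output_stride record every this many steps (frame 0 is always
#'   recorded; frame count is `floor(n_steps / output_stride) + 1`).
#' @param seed integer seed; one seeded stream per run, consumed only by
#'   the integrator (bias providers receive no randomness).
#' @return an `integrator_config`.
#' @export
integrator_config <- function(timestep = 0.002, temperature = 300,
                              friction = 2, n_steps = 1000L,
                              output_stride = 10L, seed = 1L) {
  stopifnot(timestep > 0, temperature > 0, friction >= 0, n_steps >= 0,
            output_stride >= 1)
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, n_steps = as.integer(n_steps),
                 output_stride = as.integer(output_stride),
                 seed = as.integer(seed)),
            class = "integrator_config")
}

new_trajectory <- function(times, positions, term_energies, boost, cv,
                           final_state, cfg) {
  structure(list(times = times, positions = positions,
                 term_energies = term_energies, boost = boost, cv = cv,
                 final_state = final_state, cfg = cfg),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %.4g ps; %d energy term(s), %d boost column(s)\n",
              length(x$times), max(x$times), ncol(x$term_energies),
              ncol(x$boost)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

surface_spec_for_cpp <- function(surface) {
  list(periodic = surface$periodic,
       period = if (is.finite(surface$period)) surface$period else 0,
       offset = surface$offset,
       cos_amp = surface$cos_amp, cos_mult = surface$cos_mult,
       cos_phase = surface$cos_phase,
       g_center = surface$g_center, g_depth = surface$g_depth,
       g_width = surface$g_width,
       harm_k = surface$harm_k, harm_x0 = surface$harm_x0)
}

default_x0 <- function(surface) {
  if (surface$harm_k != 0) return(surface$harm_x0)
  grid <- seq(-surface$period / 2, surface$period / 2, length.out = 721)
  grid[which.min(surface_energy(surface, grid))]
}

# low-level surface propagation; bias: NULL, gamd_params, or leus_bias
surface_segment <- function(surface, cfg, bias = NULL, x0, v0, seed,
                            n_steps = cfg$n_steps) {
  bias_type <- 0L; E <- 0; k <- 0
  visits <- numeric(); bc <- 0; bs <- 1; ng <- 0L; glo <- 0; ghi <- 0
  le_update <- FALSE
  if (inherits(bias, "gamd_params")) {
    bias_type <- 1L; E <- bias$E; k <- bias$k
  } else if (inherits(bias, "leus_bias")) {
    if (bias$n_dims != 1)
      stop("surface dynamics supports 1-dimensional LEUS biases")
    bias_type <- 2L
    visits <- as.numeric(bias$visits); bc <- bias$c; bs <- bias$sigma
    ng <- bias$n_grid; glo <- bias$ranges[[1]][1]; ghi <- bias$ranges[[1]][2]
    le_update <- !bias$frozen
  } else if (!is.null(bias)) stop("unsupported bias provider for a surface")
  res <- .cpp_surface_langevin(surface_spec_for_cpp(surface), surface$mass,
                               cfg$timestep, cfg$friction, cfg$temperature,
                               as.integer(n_steps), cfg$output_stride,
                               x0, v0, as.integer(seed),
                               bias_type, E, k, visits, bc, bs,
                               as.integer(ng), glo, ghi, le_update)
  res
}

segment_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483647)
}

#' Run Langevin dynamics
#'
#' Propagates a `potential_surface` or a `bead_system` with the BAOAB
#' Langevin integrator, recording times, positions, per-term potential
#' energies, per-region boost energies (zero when unbiased) and CV values
#' every `output_stride` steps.
#'
#' For surfaces the single energy term is the total potential and the CV
#' is the coordinate itself; `bias` may be `NULL`, a [gamd_params]
#' (harmonic boost on the total potential) or a 1D [leus_bias] (grid bias
#' on the coordinate; its visit counts grow during the run unless
#' frozen — the updated bias is returned as attribute `"bias"`).
#'
#' For bead systems `bias` may be `NULL` or a list
#' `list(regions = <region_set>, params = <named list of gamd_params>,
#' dihedral_params = <named list>)` for selective boosting; per-term
#' energies follow the catalogue of `regions` (or a single-group
#' catalogue when unbiased).
#'
#' @param system `potential_surface` or `bead_system`.
#' @param cfg an [integrator_config()].
#' @param bias optional bias provider (see Details).
#' @param x0,v0 optional initial state.
#' @param cv_def for bead systems, a data.frame of torsion quadruples
#'   (columns `i, j, k, l`, optional `name`) whose dihedral angles are
#'   recorded as CVs; defaults to the system's torsions.
#' @return a `trajectory`.
#' @export
run_md <- function(system, cfg, bias = NULL, x0 = NULL, v0 = NULL,
                   cv_def = NULL) {
  UseMethod("run_md")
}

#' @export
run_md.potential_surface <- function(system, cfg, bias = NULL, x0 = NULL,
                                     v0 = NULL, cv_def = NULL) {
  x0 <- x0 %||% default_x0(system)
  v0 <- v0 %||% 0
  res <- surface_segment(system, cfg, bias, x0, v0, cfg$seed)
  traj <- new_trajectory(
    times = res$times,
    positions = matrix(res$x, ncol = 1, dimnames = list(NULL, "x")),
    term_energies = matrix(res$V, ncol = 1, dimnames = list(NULL, "total")),
    boost = matrix(res$dV, ncol = 1, dimnames = list(NULL, "dV_total")),
    cv = matrix(res$x, ncol = 1, dimnames = list(NULL, "cv")),
    final_state = list(x = res$x_final, v = res$v_final), cfg = cfg)
  attr(traj, "stats") <- res$stats
  if (inherits(bias, "leus_bias") && !bias$frozen) {
    bias$visits[] <- res$visits
    attr(traj, "bias") <- bias
  }
  traj
}

#' @export
run_md.bead_system <- function(system, cfg, bias = NULL, x0 = NULL,
                               v0 = NULL, cv_def = NULL) {
  set.seed(cfg$seed)
  st <- init_bead_state(system, cfg, x0, v0)
  if (is.null(bias)) {
    catalogue <- build_catalogue(system)
    boost <- NULL
  } else {
    stopifnot(is.list(bias), inherits(bias$regions, "region_set"))
    catalogue <- bias$regions$catalogue
    boost <- bias
  }
  res <- bead_dynamics(system, cfg, st$x, st$v, cfg$n_steps, catalogue,
                       boost = boost, cv_def = cv_def)
  res$trajectory
}

maxwell_velocities <- function(masses, temperature) {
  n <- length(masses)
  matrix(rnorm(3 * n), n, 3) * sqrt(kB * temperature / masses)
}

init_bead_state <- function(system, cfg, x0, v0) {
  x <- x0 %||% system$positions
  v <- v0 %||% maxwell_velocities(system$masses, cfg$temperature)
  list(x = x, v = v)
}

# core bead propagation loop (RNG state is the caller's responsibility).
# boost: NULL, list(regions=, params=, dihedral_params=) for selective
# boosting, or list(reference=TRUE, params=<gamd_params>) for the
# monolithic single-boost reference.
bead_dynamics <- function(sys, cfg, x, v, n_steps, catalogue,
                          boost = NULL, cv_def = NULL, stats = NULL) {
  dt <- cfg$timestep
  kT <- kB * cfg$temperature
  c1 <- exp(-cfg$friction * dt)
  c2 <- sqrt((1 - c1^2) * kT / sys$masses)
  m <- sys$masses
  stride <- cfg$output_stride
  nt <- nrow(catalogue)
  asg <- term_assignment(sys, catalogue)
  tidx <- list(bond = match(asg$bond, catalogue$id),
               torsion = match(asg$torsion, catalogue$id),
               pair = match(asg$pair, catalogue$id))
  # row index list per term, per interaction class
  rows_of <- function(idx) lapply(seq_len(nt), function(t) which(idx == t))
  rws <- list(bond = rows_of(tidx$bond), torsion = rows_of(tidx$torsion),
              pair = rows_of(tidx$pair))
  term_energy_vec <- function(ia) {
    e <- numeric(nt)
    for (t in seq_len(nt))
      e[t] <- sum(ia$bond_e[rws$bond[[t]]]) + sum(ia$torsion_e[rws$torsion[[t]]]) +
        sum(ia$pair_e[rws$pair[[t]]])
    e
  }

  reference <- isTRUE(boost$reference)
  selective <- !is.null(boost) && !reference
  if (selective) {
    regions <- boost$regions$regions
    accel <- vapply(regions, `[[`, TRUE, "accelerate")
    params <- boost$params
    dparams <- boost$dihedral_params
    memb <- lapply(regions, function(r) match(r$member_terms, catalogue$id))
    dmemb <- lapply(regions, function(r) match(r$dihedral_terms, catalogue$id))
    nr <- length(regions)
    # per-term scale slot: column 1 + region index (1 = unboosted)
    term_slot <- rep(1L, nt)
    for (r in seq_len(nr)) term_slot[c(memb[[r]], dmemb[[r]])] <-
      ifelse(catalogue$kind[c(memb[[r]], dmemb[[r]])] == "dihedral",
             1L + nr + r, 1L + r)
    boost_names <- names(regions)
  } else {
    nr <- 1L
    boost_names <- character()  # single dV_total column only
  }

  if (is.null(cv_def)) cv_def <- sys$torsions
  cv_def <- as.data.frame(cv_def)
  has_cv <- nrow(cv_def) > 0
  cv_names <- if (has_cv) {
    if (!is.null(cv_def$name)) as.character(cv_def$name)
    else paste0("phi", seq_len(nrow(cv_def)))
  } else character()

  n_frames <- n_steps %/% stride + 1L
  times <- numeric(n_frames)
  pos <- array(NA_real_, c(n_frames, nrow(sys$positions), 3))
  term_e_out <- matrix(NA_real_, n_frames, nt, dimnames = list(NULL, catalogue$id))
  n_boost_cols <- length(boost_names) + 1L
  boost_out <- matrix(0, n_frames, n_boost_cols,
                      dimnames = list(NULL, c(if (length(boost_names))
                        paste0("dV_", boost_names), "dV_total")))
  cv_out <- matrix(NA_real_, n_frames, length(cv_names),
                   dimnames = list(NULL, cv_names))

  if (is.null(stats) && (selective || reference))
    stats <- replicate(if (selective) 2 * nr else 1, region_stats(), simplify = FALSE)

  eval_state <- function(xx) {
    ia <- bead_interactions(sys, xx)
    te <- term_energy_vec(ia)
    dv <- numeric(nr)
    if (selective) {
      lam <- rep(1, 1 + 2 * nr)
      for (r in seq_len(nr)) {
        if (!accel[r]) next
        Vr <- sum(te[memb[[r]]])
        lam[1 + r] <- force_scale(Vr, params[[r]])
        dv[r] <- boost_energy(Vr, params[[r]])
        if (length(dmemb[[r]])) {
          Vd <- sum(te[dmemb[[r]]])
          if (!is.null(dparams[[r]])) {
            lam[1 + nr + r] <- force_scale(Vd, dparams[[r]])
            dv[r] <- dv[r] + boost_energy(Vd, dparams[[r]])
          }
        }
      }
      scl <- lam[term_slot]
      f <- accumulate_forces(sys, ia,
                             bond_scale = scl[tidx$bond],
                             torsion_scale = scl[tidx$torsion],
                             pair_scale = scl[tidx$pair])$total
    } else if (reference) {
      Vtot <- (sum(ia$bond_e) + sum(ia$torsion_e)) + sum(ia$pair_e)
      lam <- force_scale(Vtot, boost$params)
      dv[1] <- boost_energy(Vtot, boost$params)
      f <- accumulate_forces(sys, ia,
                             bond_scale = rep(lam, nrow(sys$bonds)),
                             torsion_scale = rep(lam, nrow(sys$torsions)),
                             pair_scale = rep(lam, nrow(sys$pairs)))$total
    } else {
      f <- accumulate_forces(sys, ia)$total
    }
    if (!all(is.finite(f))) stop("non-finite force encountered")
    list(te = te, dv = dv, f = f, ia = ia)
  }

  update_stats <- function(st, te, ia) {
    if (is.null(st)) return(NULL)
    if (selective) {
      for (r in seq_len(nr)) {
        st[[r]] <- stats_push(st[[r]], sum(te[memb[[r]]]))
        if (length(dmemb[[r]]))
          st[[nr + r]] <- stats_push(st[[nr + r]], sum(te[dmemb[[r]]]))
      }
    } else if (reference) {
      st[[1]] <- stats_push(st[[1]], (sum(ia$bond_e) + sum(ia$torsion_e)) + sum(ia$pair_e))
    }
    st
  }

  es <- eval_state(x)
  stats <- update_stats(stats, es$te, es$ia)
  record <- function(fr, step, es) {
    times[fr] <<- step * dt
    pos[fr, , ] <<- x
    term_e_out[fr, ] <<- es$te
    boost_out[fr, ] <<- if (length(boost_names)) c(es$dv, sum(es$dv))
                        else sum(es$dv)
    if (has_cv) cv_out[fr, ] <<- dihedral_angle(x, cv_def)
  }
  record(1L, 0L, es)
  fr <- 1L

  for (step in seq_len(n_steps)) {
    v <- v + (0.5 * dt) * es$f / m
    x <- x + (0.5 * dt) * v
    v <- c1 * v + c2 * matrix(rnorm(length(m) * 3), length(m), 3)
    x <- x + (0.5 * dt) * v
    es <- eval_state(x)
    v <- v + (0.5 * dt) * es$f / m
    stats <- update_stats(stats, es$te, es$ia)
    if (step %% stride == 0L) {
      fr <- fr + 1L
      record(fr, step, es)
    }
  }

  traj <- new_trajectory(times, pos, term_e_out, boost_out, cv_out,
                         final_state = list(x = x, v = v), cfg = cfg)
  list(trajectory = traj, stats = stats, x = x, v = v)
}
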