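#' GaMD boost parameters
#'
#' The harmonic boost adds `dV = k/2 (E - V)^2` whenever the region
#' energy `V` falls below the threshold `E`, and nothing otherwise.
#' Under the lower-bound rule the threshold is the maximal observed
#' energy of the region, `E = v_max`, and the force constant is
#' `k = k0 / (v_max - v_min)` with the dimensionless `k0` in (0, 1].
#'
#' @param E energy threshold, kJ/mol.
#' @param k curvature, 1/(kJ/mol) (>= 0; 0 disables the boost).
#' @param k0 dimensionless strength in (0, 1] (bookkeeping; `k` is what
#'   is applied).
#' @param sigma0 the sigma0 used during estimation, kJ/mol.
#' @return a `gamd_params`.
#' @export
gamd_params <- function(E, k, k0 = NA_real_, sigma0 = NA_real_) {
  stopifnot(is.numeric(E), is.numeric(k), length(E) == 1, length(k) == 1,
            k >= 0)
  structure(list(E = E, k = k, k0 = k0, sigma0 = sigma0),
            class = "gamd_params")
}

#' @export
print.gamd_params <- function(x, ...) {
  cat(sprintf("<gamd_params> E = %.6g kJ/mol, k = %.6g (kJ/mol)^-1 (k0 = %.4g, sigma0 = %.4g)\n",
              x$E, x$k, x$k0, x$sigma0))
  invisible(x)
}

#' Harmonic boost energy
#'
#' `dV = k/2 (E - V)^2` for `V < E`, else 0.  Always non-negative;
#' vectorised over `V`.
#'
#' @param V region potential energy, kJ/mol.
#' @param params a [gamd_params()].
#' @return boost energy, kJ/mol.
#' @examples
#' p <- gamd_params(E = 10, k = 0.1)
#' boost_energy(c(0, 10, 20), p)  # 5, 0, 0
#' @export
boost_energy <- function(V, params) {
  ifelse(V < params$E, 0.5 * params$k * (params$E - V)^2, 0)
}

#' Boost force-scaling factor
#'
#' The biased force on every coordinate contributing to a region is the
#' unbiased force times `lambda = d(V + dV)/dV = 1 - k (E - V)` for
#' `V < E`, else 1.  With `E = v_max`, `k0 <= 1` and `V >= v_min`,
#' `lambda` lies in \[0, 1\].
#'
#' @inheritParams boost_energy
#' @return dimensionless scale factor, vectorised over `V`.
#' @export
force_scale <- function(V, params) {
  ifelse(V < params$E, 1 - params$k * (params$E - V), 1)
}

#' Streaming region-energy statistics
#'
#' Running minimum, maximum, mean and (population) standard deviation of
#' a region's potential energy, accumulated with Welford's algorithm so
#' that search phases can update them sample by sample or in batches.
#'
#' @return `region_stats()` a fresh accumulator; `stats_push()` the
#'   updated accumulator; `stats_merge()` the pooled accumulator;
#'   `stats_summary()` a list with `v_min`, `v_max`, `v_avg`, `v_std`,
#'   `n_samples`.
#' @export
region_stats <- function() {
  structure(list(n = 0, mean = 0, m2 = 0, min = Inf, max = -Inf),
            class = "region_stats")
}

#' @rdname region_stats
#' @param stats a `region_stats`.
#' @param values numeric vector of new energy samples (kJ/mol).
#' @export
stats_push <- function(stats, values) {
  n <- length(values)
  if (n == 0) return(stats)
  if (n == 1) {
    stats$n <- stats$n + 1
    d <- values - stats$mean
    stats$mean <- stats$mean + d / stats$n
    stats$m2 <- stats$m2 + d * (values - stats$mean)
    if (values < stats$min) stats$min <- values
    if (values > stats$max) stats$max <- values
    return(stats)
  }
  m <- mean(values)
  batch <- structure(list(n = n, mean = m, m2 = sum((values - m)^2),
                          min = min(values), max = max(values)),
                     class = "region_stats")
  stats_merge(stats, batch)
}

#' @rdname region_stats
#' @param a,b `region_stats` accumulators to pool.
#' @export
stats_merge <- function(a, b) {
  if (b$n == 0) return(a)
  if (a$n == 0) return(b)
  n <- a$n + b$n
  d <- b$mean - a$mean
  structure(list(n = n,
                 mean = a$mean + d * b$n / n,
                 m2 = a$m2 + b$m2 + d^2 * a$n * b$n / n,
                 min = min(a$min, b$min), max = max(a$max, b$max)),
            class = "region_stats")
}

#' @rdname region_stats
#' @export
stats_summary <- function(stats) {
  list(v_min = stats$min, v_max = stats$max, v_avg = stats$mean,
       v_std = if (stats$n > 0) sqrt(stats$m2 / stats$n) else NaN,
       n_samples = stats$n)
}

# merge the C++ kernel's per-step stats vector into an accumulator
stats_merge_cpp <- function(stats, sv) {
  b <- structure(list(n = sv[["n"]], mean = sv[["mean"]], m2 = sv[["m2"]],
                      min = sv[["min"]], max = sv[["max"]]),
                 class = "region_stats")
  stats_merge(stats, b)
}

#' Estimate boost parameters from search statistics
#'
#' Lower-bound rule: `E = v_max`,
#' `k0 = min(1, (sigma0 / v_std) * (v_max - v_min) / (v_max - v_avg))`,
#' `k = k0 / (v_max - v_min)`.  `sigma0` caps the standard deviation of
#' the boost so that reweighting stays reliable.  Degenerate statistics
#' (`v_max == v_min`) yield no-boost parameters (`k = 0`) with a warning.
#'
#' @param stats a [region_stats()] accumulator (>= 2 samples).
#' @param sigma0 kJ/mol (> 0).
#' @param mode only `"lower"` (threshold at the observed maximum) is
#'   implemented.
#' @return a [gamd_params()].
#' @export
estimate_parameters <- function(stats, sigma0 = 10, mode = "lower") {
  mode <- match.arg(mode, "lower")
  s <- stats_summary(stats)
  if (s$n_samples < 2) stop("need at least 2 samples to estimate parameters")
  stopifnot(sigma0 > 0)
  if (!(s$v_max > s$v_min)) {
    warning("degenerate statistics (v_max == v_min); boost disabled")
    return(gamd_params(E = s$v_max, k = 0, k0 = 0, sigma0 = sigma0))
  }
  k0 <- min(1, (sigma0 / s$v_std) * (s$v_max - s$v_min) / (s$v_max - s$v_avg))
  gamd_params(E = s$v_max, k = k0 / (s$v_max - s$v_min), k0 = k0,
              sigma0 = sigma0)
}

#' Dual boost of per-term energies
#'
#' Given the per-term energies of one frame, computes for every region
#' the boost on its non-dihedral energy (parameters `params`) and, when
#' the region carries dihedral terms, a separate boost on its dihedral
#' energy (parameters `dihedral_params`); regions without dihedral terms
#' get a zero dihedral boost.  The total boost on the Hamiltonian is the
#' sum of all sub-boosts.
#'
#' @param term_energies named numeric vector over catalogue term ids.
#' @param regions a validated `region_set`.
#' @param params named list of [gamd_params()], one per accelerated region.
#' @param dihedral_params named list of [gamd_params()] for the dihedral
#'   sub-boosts (entries may be missing for regions without torsions).
#' @return data.frame with columns `region`, `dV_total` (non-dihedral
#'   part), `dV_dihedral`, `dV` (their sum).
#' @export
apply_dual_boost <- function(term_energies, regions, params,
                             dihedral_params = list()) {
  stopifnot(inherits(regions, "region_set"))
  rows <- lapply(regions$regions, function(r) {
    dv <- dvd <- 0
    if (r$accelerate) {
      V <- sum(term_energies[r$member_terms])
      dv <- boost_energy(V, params[[r$name]])
      if (length(r$dihedral_terms) && !is.null(dihedral_params[[r$name]])) {
        Vd <- sum(term_energies[r$dihedral_terms])
        dvd <- boost_energy(Vd, dihedral_params[[r$name]])
      }
    }
    data.frame(region = r$name, dV_total = dv, dV_dihedral = dvd,
               dV = dv + dvd, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Production GaMD run with fixed parameters
#'
#' @param system `potential_surface` or `bead_system`.
#' @param cfg an [integrator_config()].
#' @param params for surfaces, a single [gamd_params()]; for bead
#'   systems, a named list of [gamd_params()] keyed by region name.
#' @param regions for bead systems, a validated `region_set`.
#' @param dihedral_params optional named list for dual boosting.
#' @param ... passed to [run_md()].
#' @return a `trajectory` with per-frame per-region boost energies.
#' @export
run_gamd <- function(system, cfg, params, regions = NULL,
                     dihedral_params = list(), ...) {
  if (inherits(system, "potential_surface")) {
    stopifnot(inherits(params, "gamd_params"))
    run_md(system, cfg, bias = params, ...)
  } else {
    stopifnot(inherits(regions, "region_set"))
    run_md(system, cfg,
           bias = list(regions = regions, params = params,
                       dihedral_params = dihedral_params), ...)
  }
}

#' Monolithic single-boost GaMD reference
#'
#' Non-selective reference implementation: one harmonic boost applied to
#' the total potential energy, scaling the total force by a single
#' factor.  With one acceleration region covering every term of a
#' one-group system and the same seed, [run_gamd()] reproduces this
#' trajectory bit for bit.
#'
#' @param system a `bead_system`.
#' @param cfg an [integrator_config()].
#' @param params a [gamd_params()] for the total potential.
#' @param x0,v0,cv_def as in [run_md()].
#' @return a `trajectory` (single boost column).
#' @export
run_gamd_reference <- function(system, cfg, params, x0 = NULL, v0 = NULL,
                               cv_def = NULL) {
  stopifnot(inherits(system, "bead_system"), inherits(params, "gamd_params"))
  set.seed(cfg$seed)
  st <- init_bead_state(system, cfg, x0, v0)
  catalogue <- build_catalogue(system)
  res <- bead_dynamics(system, cfg, st$x, st$v, cfg$n_steps, catalogue,
                       boost = list(reference = TRUE, params = params),
                       cv_def = cv_def)
  res$trajectory
}

#' Search/production staging protocol
#'
#' Three stages: (1) a conventional-MD search collecting region-energy
#' statistics without any bias; (2) an adaptive GaMD search in which the
#' boost parameters are re-estimated every `update_interval` steps from
#' the cumulative statistics (cMD plus all search frames so far); (3) a
#' production run with the parameters frozen at their final stage-2
#' values.  A zero-length stage 2 means production uses parameters
#' derived from the cMD statistics alone.
#'
#' @param system `potential_surface` or `bead_system`.
#' @param cfg an [integrator_config()]; its `n_steps` is ignored in
#'   favour of `stage_steps`.
#' @param stage_steps list with `cmd`, `search`, `production` step counts
#'   (`cmd > 0`, `production > 0`, `search >= 0`).
#' @param regions for bead systems, a validated `region_set`; `NULL` for
#'   surfaces (single region = total potential).
#' @param sigma0 default sigma0 (kJ/mol) for regions that do not carry
#'   their own.
#' @param update_interval steps between stage-2 parameter updates;
#'   default `max(1, search / 50)`.
#' @return list with `params` (per region; surfaces: one `gamd_params`),
#'   `dihedral_params`, `production` (trajectory), `search_stats`
#'   (final accumulators), and `stages` (step bookkeeping).
#' @export
run_protocol <- function(system, cfg, stage_steps, regions = NULL,
                         sigma0 = 10, update_interval = NULL) {
  stage_steps <- lapply(stage_steps, as.integer)
  if (is.null(stage_steps$cmd) || stage_steps$cmd <= 0)
    stop("stage lengths must be positive (cmd)")
  if (is.null(stage_steps$production) || stage_steps$production <= 0)
    stop("stage lengths must be positive (production)")
  search <- stage_steps$search %||% 0L
  if (search < 0) stop("stage lengths must be non-negative (search)")
  update_interval <- as.integer(update_interval %||% max(1, search %/% 50))
  if (search > 0 && update_interval > search)
    stop("update interval exceeds the search stage length")

  if (inherits(system, "potential_surface")) {
    run_protocol_surface(system, cfg, stage_steps$cmd, search,
                         stage_steps$production, sigma0, update_interval)
  } else {
    stopifnot(inherits(regions, "region_set"))
    run_protocol_beads(system, cfg, stage_steps$cmd, search,
                       stage_steps$production, regions, sigma0,
                       update_interval)
  }
}

run_protocol_surface <- function(surface, cfg, n_cmd, n_search, n_prod,
                                 sigma0, update_interval) {
  x <- default_x0(surface); v <- 0
  seg <- 0L
  stats <- region_stats()

  # stage 1: unbiased cMD, statistics only
  res <- surface_segment(surface, cfg, NULL, x, v,
                         segment_seed(cfg$seed, seg), n_steps = n_cmd)
  stats <- stats_merge_cpp(stats, res$stats)
  x <- res$x_final; v <- res$v_final
  params <- estimate_parameters(stats, sigma0)

  # stage 2: adaptive search, cumulative statistics
  remaining <- n_search
  while (remaining > 0) {
    seg <- seg + 1L
    len <- min(update_interval, remaining)
    res <- surface_segment(surface, cfg, params, x, v,
                           segment_seed(cfg$seed, seg), n_steps = len)
    stats <- stats_merge_cpp(stats, res$stats)
    x <- res$x_final; v <- res$v_final
    params <- estimate_parameters(stats, sigma0)
    remaining <- remaining - len
  }

  # stage 3: production, parameters frozen
  prod_cfg <- cfg
  prod_cfg$n_steps <- as.integer(n_prod)
  prod_cfg$seed <- segment_seed(cfg$seed, seg + 1L)
  production <- run_md(surface, prod_cfg, bias = params, x0 = x, v0 = v)
  list(params = params, dihedral_params = NULL, production = production,
       search_stats = stats,
       stages = list(cmd = n_cmd, search = n_search, production = n_prod,
                     update_interval = update_interval))
}

run_protocol_beads <- function(system, cfg, n_cmd, n_search, n_prod,
                               regions, sigma0, update_interval) {
  set.seed(cfg$seed)
  st <- init_bead_state(system, cfg, NULL, NULL)
  x <- st$x; v <- st$v
  catalogue <- regions$catalogue
  regs <- regions$regions
  nr <- length(regs)
  stats <- replicate(2 * nr, region_stats(), simplify = FALSE)
  sig <- vapply(regs, function(r) r$sigma0 %||% sigma0, 0)

  estimate_all <- function(stats) {
    params <- dparams <- setNames(vector("list", nr), names(regs))
    for (r in seq_len(nr)) {
      if (!regs[[r]]$accelerate) next
      params[[r]] <- estimate_parameters(stats[[r]], sig[r])
      if (length(regs[[r]]$dihedral_terms) && stats[[nr + r]]$n >= 2)
        dparams[[r]] <- estimate_parameters(stats[[nr + r]], sig[r])
    }
    list(params = params, dparams = dparams)
  }

  # stage 1: unbiased cMD with statistics
  res <- bead_dynamics(system, cfg, x, v, n_cmd, catalogue,
                       boost = list(regions = regions,
                                    params = lapply(regs, function(r) gamd_params(-Inf, 0)),
                                    dihedral_params = list()),
                       stats = stats)
  stats <- res$stats; x <- res$x; v <- res$v
  est <- estimate_all(stats)

  # stage 2: adaptive search
  remaining <- n_search
  while (remaining > 0) {
    len <- min(update_interval, remaining)
    res <- bead_dynamics(system, cfg, x, v, len, catalogue,
                         boost = list(regions = regions, params = est$params,
                                      dihedral_params = est$dparams),
                         stats = stats)
    stats <- res$stats; x <- res$x; v <- res$v
    est <- estimate_all(stats)
    remaining <- remaining - len
  }

  # stage 3: production, frozen parameters
  res <- bead_dynamics(system, cfg, x, v, n_prod, catalogue,
                       boost = list(regions = regions, params = est$params,
                                    dihedral_params = est$dparams))
  list(params = est$params, dihedral_params = est$dparams,
       production = res$trajectory, search_stats = stats,
       stages = list(cmd = n_cmd, search = n_search, production = n_prod,
                     update_interval = update_interval))
}
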