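#' Local elevation umbrella sampling bias
#'
#' A LEUS bias is a periodic grid over an `n_dims`-dimensional CV
#' subspace (dihedral angles, degrees).  During the local-elevation (LE)
#' build-up phase every integration step increments the visit count
#' `n_k` of the grid cell containing the current CV value; the bias
#' energy is the sum of repulsive kernels
#' `B(Q) = sum_k c * n_k * g(MI(Q - Q*_k))`, with `Q*_k` the cell
#' centres, `MI` the minimum-image displacement, and `g` a finitely
#' supported polynomial bump (biweight) kernel,
#' `g(d) = (1 - (d / (2 sigma))^2)^2` inside `|d| < 2 sigma` and zero
#' beyond (the Heaviside factor), so `g(0) = 1` and both the bias and
#' its force reach zero continuously at the cutoff — kernels with value
#' or slope jumps there inject unphysical steps the integrator cannot
#' sample correctly.  In the
#' umbrella-sampling (US) phase the bias is frozen, making the biased
#' Hamiltonian time independent, and frames are reweighted with
#' `exp(+beta B(Q))`.
#'
#' Defaults follow the standard glycosidic-linkage setup: `n_grid = 36`
#' cells per dimension, `sigma = 360 / n_grid` degrees,
#' `c = 0.005` kJ/mol per visit, up to 2 dimensions.
#'
#' @param n_dims CV dimensionality (1 or 2).
#' @param n_grid grid cells per dimension.
#' @param c force constant, kJ/mol per visit.
#' @param sigma kernel width, degrees.
#' @param ranges list of `c(lo, hi)` per dimension (periodic), default
#'   `c(-180, 180)`.
#' @return an object of class `leus_bias` with zero visits, unfrozen.
#' @export
leus_bias <- function(n_dims = 1, n_grid = 36, c = 0.005,
                      sigma = 360 / n_grid, ranges = NULL) {
  stopifnot(n_dims %in% c(1, 2), n_grid >= 2, c >= 0, sigma > 0)
  ranges <- ranges %||% rep(list(c(-180, 180)), n_dims)
  if (!is.list(ranges)) ranges <- list(ranges)
  stopifnot(length(ranges) == n_dims)
  visits <- array(0, dim = rep(as.integer(n_grid), n_dims))
  structure(list(n_dims = as.integer(n_dims), n_grid = as.integer(n_grid),
                 c = c, sigma = sigma, ranges = ranges,
                 visits = visits, frozen = FALSE),
            class = "leus_bias")
}

#' @export
print.leus_bias <- function(x, ...) {
  cat(sprintf("<leus_bias> %dD grid %s, c = %g kJ/mol, sigma = %g deg, %s, %d visit(s)\n",
              x$n_dims, paste(rep(x$n_grid, x$n_dims), collapse = " x "),
              x$c, x$sigma, if (x$frozen) "frozen" else "building",
              sum(x$visits)))
  invisible(x)
}

#' Freeze a LEUS bias
#'
#' After freezing, visit counts never change; updates raise an error.
#'
#' @param bias a `leus_bias`.
#' @export
freeze_bias <- function(bias) {
  bias$frozen <- TRUE
  bias
}

leus_cells <- function(bias, Q) {
  Q <- matrix(as.numeric(Q), ncol = bias$n_dims)
  vapply(seq_len(bias$n_dims), function(d) {
    r <- bias$ranges[[d]]
    per <- r[2] - r[1]
    u <- (Q[, d] - r[1]) %% per
    pmin(pmax(floor(u / (per / bias$n_grid)), 0), bias$n_grid - 1) + 1L
  }, numeric(nrow(Q)))
}

leus_centers <- function(bias, d) {
  r <- bias$ranges[[d]]
  w <- (r[2] - r[1]) / bias$n_grid
  r[1] + (seq_len(bias$n_grid) - 0.5) * w
}

#' Record a visit (LE build-up step)
#'
#' Increments the visit count of the grid cell containing `Q` by one;
#' all other cells are unchanged.  Periodic coordinates are wrapped, so
#' `Q` and `Q + 360` land in the same cell.
#'
#' @param bias an unfrozen `leus_bias`.
#' @param Q CV value(s): numeric vector of length `n_dims`, or a matrix
#'   with `n_dims` columns to record several visits at once.
#' @return the updated `leus_bias`.
#' @export
le_update <- function(bias, Q) {
  if (bias$frozen) stop("cannot update a frozen LEUS bias")
  cells <- leus_cells(bias, Q)
  cells <- matrix(cells, ncol = bias$n_dims)
  for (row in seq_len(nrow(cells))) {
    idx <- cells[row, , drop = TRUE]
    if (bias$n_dims == 1) bias$visits[idx] <- bias$visits[idx] + 1
    else bias$visits[idx[1], idx[2]] <- bias$visits[idx[1], idx[2]] + 1
  }
  bias
}

#' LEUS bias energy
#'
#' `B(Q) = sum_k c n_k g(MI(Q - Q*_k))` over all grid cells, with the
#' truncated Gaussian kernel of the class description (product over
#' dimensions in 2D).  Zero everywhere when all visits are zero or
#' `c = 0`; never negative.
#'
#' @param bias a `leus_bias`.
#' @param Q CV value(s), as in [le_update()].
#' @return bias energy (kJ/mol), one value per row of `Q`.
#' @export
bias_energy <- function(bias, Q) {
  Q <- matrix(as.numeric(Q), ncol = bias$n_dims)
  if (bias$c == 0 || sum(bias$visits) == 0) return(numeric(nrow(Q)))
  kern <- lapply(seq_len(bias$n_dims), function(d) {
    per <- diff(bias$ranges[[d]])
    dmat <- outer(Q[, d], leus_centers(bias, d), `-`)
    dmat <- wrap_periodic(dmat, per)
    g <- (1 - (dmat / (2 * bias$sigma))^2)^2
    g[abs(dmat) >= 2 * bias$sigma] <- 0
    g
  })
  if (bias$n_dims == 1) {
    as.numeric(kern[[1]] %*% (bias$c * as.numeric(bias$visits)))
  } else {
    vapply(seq_len(nrow(Q)), function(row)
      bias$c * sum(bias$visits * outer(kern[[1]][row, ], kern[[2]][row, ])),
      0)
  }
}

#' Run the two-phase LEUS protocol on a 1D surface
#'
#' Phase 1 (LE, `le_steps` steps): every step increments the visit count
#' of the current CV cell, progressively filling the wells.  Phase 2
#' (US, `us_steps` steps): the bias is frozen and sampled; US frames
#' carry the bias energy `B(Q)` for reweighting.  `le_steps = 0` makes
#' the US phase plain unbiased dynamics (on the empty bias).
#'
#' @param surface a periodic 1D `potential_surface`; the CV is the
#'   coordinate itself.
#' @param cfg an [integrator_config()]; `n_steps` is ignored in favour
#'   of the phase lengths.
#' @param le_steps,us_steps phase lengths in steps (>= 0, us_steps > 0).
#' @param bias optional starting `leus_bias` (default: fresh bias with
#'   standard parameters).
#' @return list with `bias` (frozen), `le` and `us` trajectories; US
#'   frames' `boost` column holds `B(Q)`.
#' @export
run_leus <- function(surface, cfg, le_steps, us_steps, bias = NULL) {
  stopifnot(inherits(surface, "potential_surface"), surface$periodic)
  le_steps <- as.integer(le_steps); us_steps <- as.integer(us_steps)
  if (le_steps < 0 || us_steps <= 0) stop("phase lengths must be positive")
  bias <- bias %||% leus_bias(n_dims = 1,
                              ranges = list(c(-surface$period / 2,
                                              surface$period / 2)))
  le_traj <- NULL
  if (le_steps > 0) {
    le_cfg <- cfg; le_cfg$n_steps <- le_steps
    le_traj <- run_md(surface, le_cfg, bias = bias)
    bias <- attr(le_traj, "bias")
    x0 <- le_traj$final_state$x; v0 <- le_traj$final_state$v
  } else {
    x0 <- NULL; v0 <- NULL
  }
  bias <- freeze_bias(bias)
  us_cfg <- cfg; us_cfg$n_steps <- us_steps
  us_cfg$seed <- segment_seed(cfg$seed, 1L)
  us_traj <- run_md(surface, us_cfg, bias = bias, x0 = x0, v0 = v0)
  list(bias = bias, le = le_traj, us = us_traj)
}

#' Reweight umbrella-phase samples
#'
#' Unbiased probability per bin is proportional to the biased histogram
#' weighted by `exp(+beta B(Q))` per sample; the PMF is anchored at 0.
#'
#' @param cv CV values per US frame (vector or 2-column matrix).
#' @param bias_energy bias energy `B(Q)` per frame (kJ/mol), or a frozen
#'   `leus_bias` to evaluate at `cv` (an unfrozen bias is an error: the
#'   US phase requires a time-independent Hamiltonian).
#' @param bins,temperature,range,min_count as in [pmf_cumulant()].
#' @return a `fes` object.
#' @export
reweight_us <- function(cv, bias_energy, bins = 36, temperature = 300,
                        range = NULL, min_count = 10) {
  cv <- as.matrix(cv)
  if (inherits(bias_energy, "leus_bias")) {
    if (!bias_energy$frozen)
      stop("US reweighting requires a frozen bias")
    b <- selgamd::bias_energy(bias_energy, cv)
  } else b <- as.numeric(bias_energy)
  if (length(b) != nrow(cv)) stop("one bias energy per frame required")
  if (temperature <= 0) stop("temperature must be positive")
  edges <- resolve_bins(cv, bins, range)
  bi <- bin_index(cv, edges)
  ntot <- prod(bi$nbins)
  keep <- !is.na(bi$lin)
  lin <- bi$lin[keep]
  beta <- 1 / (kB * temperature)
  counts <- tabulate(lin, ntot)
  # per-sample weights exp(+beta B), shifted for overflow safety
  bmax <- max(b[keep], 0)
  wsum <- numeric(ntot)
  acc <- rowsum(exp(beta * (b[keep] - bmax)), lin)
  wsum[as.integer(rownames(acc))] <- acc[, 1]
  logp <- log(wsum / sum(wsum))
  finalize_pmf(logp, counts, edges, temperature, min_count,
               extra = list(method = "leus_us"))
}

#' Serialize a LEUS bias to delimited text
#'
#' Header lines (prefixed `#`) carry `n_dims`, `n_grid`, `c`, `sigma`,
#' the ranges and the frozen flag; the body is the visit-count grid.
#' Round-trips exactly.
#'
#' @param bias a `leus_bias`.
#' @param path file path.
#' @export
write_leus_bias <- function(bias, path) {
  hdr <- c("# selgamd leus bias v1",
           sprintf("# n_dims\t%d", bias$n_dims),
           sprintf("# n_grid\t%d", bias$n_grid),
           sprintf("# c\t%s", format(bias$c, digits = 17)),
           sprintf("# sigma\t%s", format(bias$sigma, digits = 17)),
           vapply(seq_len(bias$n_dims), function(d)
             sprintf("# range%d\t%s\t%s", d,
                     format(bias$ranges[[d]][1], digits = 17),
                     format(bias$ranges[[d]][2], digits = 17)), ""),
           sprintf("# frozen\t%d", as.integer(bias$frozen)))
  body <- if (bias$n_dims == 1) {
    paste(format(bias$visits, trim = TRUE, digits = 17))
  } else {
    apply(bias$visits, 1, function(row)
      paste(format(row, trim = TRUE, digits = 17), collapse = "\t"))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_leus_bias
#' @return `read_leus_bias()`: the reconstructed `leus_bias`.
#' @export
read_leus_bias <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) stop("malformed bias file: missing ", key)
    strsplit(ln, "\t")[[1]][-1]
  }
  n_dims <- as.integer(getv("n_dims"))
  n_grid <- as.integer(getv("n_grid"))
  ranges <- lapply(seq_len(n_dims), function(d)
    as.numeric(getv(paste0("range", d))))
  b <- leus_bias(n_dims = n_dims, n_grid = n_grid,
                 c = as.numeric(getv("c")), sigma = as.numeric(getv("sigma")),
                 ranges = ranges)
  vals <- lapply(strsplit(body, "\t"), as.numeric)
  if (n_dims == 1) {
    b$visits[] <- unlist(vals)
  } else {
    m <- do.call(rbind, vals)
    for (i in seq_len(nrow(m))) b$visits[i, ] <- m[i, ]
  }
  if (as.integer(getv("frozen")) == 1) b <- freeze_bias(b)
  b
}
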