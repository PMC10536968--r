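#' Free-energy surfaces from biased samples
#'
#' A biased sample is one recorded frame: its CV value(s) and the total
#' boost energy `dV >= 0` acting on the Hamiltonian at that frame.
#' Reweighting recovers the unbiased probability per CV bin; the PMF is
#' `-kB T ln p`, anchored so the minimum over occupied bins is exactly 0.
#' Bins never visited carry `NA` (a sentinel, not 0 or Inf).
#'
#' @name reweighting
NULL

resolve_bins <- function(cv, bins, range = NULL) {
  cv <- as.matrix(cv)
  d <- ncol(cv)
  if (!is.list(bins)) bins <- rep(list(bins), d)
  lapply(seq_len(d), function(ax) {
    b <- bins[[ax]]
    if (length(b) == 1) {
      r <- if (!is.null(range)) {
        if (is.list(range)) range[[ax]] else range
      } else {
        lo <- min(cv[, ax]); hi <- max(cv[, ax])
        pad <- (hi - lo) * 1e-9 + 1e-12
        c(lo - pad, hi + pad)
      }
      seq(r[1], r[2], length.out = b + 1)
    } else sort(b)
  })
}

bin_index <- function(cv, edges) {
  cv <- as.matrix(cv)
  idx <- lapply(seq_along(edges), function(ax) {
    i <- findInterval(cv[, ax], edges[[ax]], rightmost.closed = TRUE)
    i[i < 1 | i > length(edges[[ax]]) - 1] <- NA
    i
  })
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  lin <- idx[[1]]
  if (length(edges) == 2) lin <- idx[[1]] + (idx[[2]] - 1L) * nb[1]
  list(lin = lin, nbins = nb)
}

new_fes <- function(pmf, counts, edges, temperature, extra = list()) {
  structure(c(list(pmf = pmf, counts = counts, bin_edges = edges,
                   temperature = temperature), extra),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("<fes> %s bins, %d occupied, T = %g K, max PMF %.3g kJ/mol\n",
              paste(dim(as.array(x$pmf)) %||% length(x$pmf), collapse = " x "),
              sum(x$counts > 0), x$temperature, max(x$pmf, na.rm = TRUE)))
  invisible(x)
}

finalize_pmf <- function(logp, counts, edges, temperature, min_count,
                         extra = list()) {
  kT <- kB * temperature
  pmf <- -kT * logp
  pmf[counts == 0] <- NA
  pmf <- pmf - min(pmf, na.rm = TRUE)
  reliable <- counts >= min_count
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  if (length(nb) == 2) {
    dim(pmf) <- nb; dim(counts) <- nb; dim(reliable) <- nb
  }
  new_fes(pmf, counts, edges, temperature,
          c(list(reliable = reliable), extra))
}

prepare_samples <- function(cv, delta_v, temperature) {
  if (is.data.frame(cv)) cv <- as.matrix(cv)
  cv <- as.matrix(cv)
  if (length(delta_v) != nrow(cv))
    stop("delta_v must have one value per sample")
  if (!nrow(cv)) stop("empty input: no biased samples")
  if (any(delta_v < -1e-9)) stop("delta_v must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  list(cv = cv, dv = pmax(delta_v, 0))
}

#' Cumulant-expansion reweighting (second order)
#'
#' Per bin `j`, the unbiased probability is estimated as
#' `p(j) ~ p_biased(j) * exp(beta * mean(dV | j) + beta^2 * var(dV | j) / 2)`
#' (population variance), the second-order cumulant expansion of the
#' exponential average — robust to noise when the per-bin boost
#' distribution is near-Gaussian.
#'
#' @param cv CV values: vector (1D) or 2-column matrix/data.frame.
#' @param delta_v total boost energy per sample, kJ/mol (>= 0).
#' @param bins bin count per axis, or explicit break vector(s); a list
#'   for per-axis settings.
#' @param temperature K.
#' @param range optional c(lo, hi) (or list per axis) for equal-width
#'   binning; defaults to the data range.
#' @param min_count bins with fewer samples are flagged unreliable in
#'   the result's `reliable` field (reported, not enforced).
#' @return a `fes` object: `pmf` (kJ/mol, min 0 over occupied bins, `NA`
#'   where empty), `counts`, `bin_edges`, `temperature`, `reliable`.
#' @export
pmf_cumulant <- function(cv, delta_v, bins = 50, temperature = 300,
                         range = NULL, min_count = 10) {
  ps <- prepare_samples(cv, delta_v, temperature)
  edges <- resolve_bins(ps$cv, bins, range)
  bi <- bin_index(ps$cv, edges)
  ntot <- prod(bi$nbins)
  keep <- !is.na(bi$lin)
  lin <- bi$lin[keep]; dv <- ps$dv[keep]
  counts <- tabulate(lin, ntot)
  beta <- 1 / (kB * temperature)
  mean_dv <- var_dv <- numeric(ntot)
  if (length(lin)) {
    acc <- rowsum(cbind(dv, dv^2), lin)
    ids <- as.integer(rownames(acc))
    mean_dv[ids] <- acc[, 1] / counts[ids]
    var_dv[ids] <- pmax(acc[, 2] / counts[ids] - mean_dv[ids]^2, 0)
  }
  logp <- log(counts / sum(counts)) + beta * mean_dv + beta^2 * var_dv / 2
  finalize_pmf(logp, counts, edges, temperature, min_count,
               extra = list(method = "cumulant2"))
}

#' Exponential-average reweighting
#'
#' Per bin, `p(j) ~ p_biased(j) * mean(exp(beta dV) | j)`; overflow is
#' guarded by factoring out the per-bin maximum boost before
#' exponentiation.  Statistically noisier than [pmf_cumulant()] when a
#' few large boosts dominate, but exact in expectation.
#'
#' @inheritParams pmf_cumulant
#' @return a `fes` object (see [pmf_cumulant()]).
#' @export
pmf_exponential <- function(cv, delta_v, bins = 50, temperature = 300,
                            range = NULL, min_count = 10) {
  ps <- prepare_samples(cv, delta_v, temperature)
  edges <- resolve_bins(ps$cv, bins, range)
  bi <- bin_index(ps$cv, edges)
  ntot <- prod(bi$nbins)
  keep <- !is.na(bi$lin)
  lin <- bi$lin[keep]; dv <- ps$dv[keep]
  counts <- tabulate(lin, ntot)
  beta <- 1 / (kB * temperature)
  log_mean_exp <- numeric(ntot)
  if (length(lin)) {
    mx <- rep(-Inf, ntot)
    agg <- tapply(dv, lin, max)
    mx[as.integer(names(agg))] <- agg
    shifted <- exp(beta * (dv - mx[lin]))
    acc <- rowsum(shifted, lin)
    ids <- as.integer(rownames(acc))
    log_mean_exp[ids] <- beta * mx[ids] + log(acc[, 1] / counts[ids])
  }
  logp <- log(counts / sum(counts)) + log_mean_exp
  finalize_pmf(logp, counts, edges, temperature, min_count,
               extra = list(method = "exponential"))
}

#' Anharmonicity of a boost-energy distribution
#'
#' Reweighting-reliability diagnostic: the entropy deficit
#' `gamma = S_gauss - S_empirical`, where `S_gauss = ln(2 pi e var)/2`
#' is the differential entropy of a Gaussian with the sample
#' (population) variance and `S_empirical` is the differential entropy
#' of the samples estimated on a histogram with Freedman-Diaconis bin
#' width (`S = -sum p ln p + ln w`).  Since the Gaussian maximises
#' entropy at fixed variance, `gamma >= 0` up to estimator noise;
#' values near 0 indicate a near-Gaussian boost whose second-order
#' cumulant reweighting is safe.  Negative estimates are clamped to 0.
#'
#' @param delta_v numeric vector of boost energies (>= 100 samples).
#' @return `gamma`, dimensionless `>= 0`; exactly 0 (with a warning) for
#'   a zero-variance sample.
#' @export
anharmonicity <- function(delta_v) {
  delta_v <- as.numeric(delta_v)
  if (length(delta_v) < 100)
    stop("anharmonicity needs at least 100 samples")
  v <- mean(delta_v^2) - mean(delta_v)^2
  if (v <= 0 || !is.finite(v)) {
    warning("degenerate (zero-variance) boost distribution; gamma = 0")
    return(0)
  }
  s_gauss <- 0.5 * log(2 * pi * exp(1) * v)
  iqr <- diff(quantile(delta_v, c(0.25, 0.75), names = FALSE))
  w <- 2 * iqr * length(delta_v)^(-1 / 3)
  if (w <= 0) w <- diff(range(delta_v)) / ceiling(sqrt(length(delta_v)))
  breaks <- seq(min(delta_v) - w / 2, max(delta_v) + w, by = w)
  p <- tabulate(findInterval(delta_v, breaks), length(breaks) - 1)
  p <- p / sum(p)
  p <- p[p > 0]
  s_emp <- -sum(p * log(p)) + log(w)
  max(0, s_gauss - s_emp)
}

#' Mean and spread of the applied boost
#'
#' Sample mean and population standard deviation (divide by n) of the
#' boost energies, the conventional "average boosting potential
#' mean +/- sd" report.
#'
#' @param delta_v numeric vector of boost energies (non-empty).
#' @param digits decimals for the formatted string (default one, the
#'   usual reporting precision).
#' @return list with `mean`, `sd` (kJ/mol) and a formatted `label`.
#' @export
boost_summary <- function(delta_v, digits = 1) {
  if (!length(delta_v)) stop("empty input")
  m <- mean(delta_v)
  s <- sqrt(mean(delta_v^2) - m^2)
  if (!is.finite(s) || s < 0) s <- 0
  list(mean = m, sd = s,
       label = sprintf("%.*f ± %.*f kJ/mol", digits, m, digits, s))
}

#' Compare a 1D free-energy surface to an analytic reference
#'
#' RMS deviation (kJ/mol) between the estimated PMF and the reference
#' PMF evaluated at bin centres, over occupied bins whose reference PMF
#' lies below `max_pmf`.  Both surfaces are anchored at zero minimum
#' before comparison (no free offset is fitted).
#'
#' @param fes a 1D `fes`.
#' @param ref a `potential_surface` or a function of the bin centre
#'   returning the reference PMF in kJ/mol.
#' @param max_pmf compare only bins with reference PMF below this
#'   (kJ/mol); `Inf` compares all occupied bins.
#' @return list with `rms` (kJ/mol), `rms_kt` (units of kB T), `n_bins`.
#' @export
fes_rms <- function(fes, ref, max_pmf = Inf) {
  stopifnot(inherits(fes, "fes"), length(fes$bin_edges) == 1)
  centers <- (head(fes$bin_edges[[1]], -1) + tail(fes$bin_edges[[1]], -1)) / 2
  ref_pmf <- if (inherits(ref, "potential_surface")) {
    v <- surface_energy(ref, centers); v - min(v)
  } else {
    v <- ref(centers); v - min(v)
  }
  sel <- fes$counts > 0 & ref_pmf < max_pmf
  if (!any(sel)) stop("no occupied bins below the PMF threshold")
  est <- fes$pmf[sel] - min(fes$pmf[sel])
  refv <- ref_pmf[sel] - min(ref_pmf[sel])
  rms <- sqrt(mean((est - refv)^2))
  list(rms = rms, rms_kt = rms / (kB * fes$temperature), n_bins = sum(sel))
}

#' @importFrom stats quantile
NULL
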