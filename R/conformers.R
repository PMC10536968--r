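#' Glycosidic-linkage conformer encoding
#'
#' Each glycosidic linkage is described by two or three dihedral angles
#' (phi, psi and optionally omega).  A linkage definition names, for each
#' conformer letter A-D, a rectangular region on the torus: one periodic
#' angle interval per dihedral.  A frame's letter is the region its angle
#' tuple falls into; tuples outside every region are assigned to the
#' nearest region centre by periodic angular distance (or marked `"X"`
#' with `unassigned = "mark"`).  One letter per linkage per frame yields
#' the conformer string.
#'
#' @param name linkage name.
#' @param angles character vector of dihedral column names
#'   (e.g. `c("phi1", "psi1")`).
#' @param regions named list (names from `A`-`D`); each element a list of
#'   `c(lo, hi)` intervals (degrees, \[-180, 180)), one per dihedral, in
#'   the order of `angles`.  `lo > hi` denotes an interval wrapping
#'   through 180/-180.  Regions must be pairwise disjoint.
#' @return a `linkage_definition`.
#' @examples
#' lk <- linkage_definition("L1", c("phi1", "psi1"),
#'   list(A = list(c(-120, 0), c(-60, 60)),
#'        B = list(c(0, 120), c(-60, 60))))
#' @export
linkage_definition <- function(name, angles, regions) {
  stopifnot(is.character(angles), length(angles) >= 1)
  if (!all(names(regions) %in% c("A", "B", "C", "D")))
    stop("conformer letters must be drawn from A, B, C, D")
  if (anyDuplicated(names(regions))) stop("duplicate region letters")
  for (rg in regions)
    if (length(rg) != length(angles))
      stop("each region needs one interval per dihedral")
  def <- structure(list(name = as.character(name), angles = angles,
                        regions = regions),
                   class = "linkage_definition")
  if (regions_overlap(def)) stop("regions must be pairwise disjoint")
  def
}

in_interval_periodic <- function(x, iv) {
  x <- wrap_periodic(x)
  lo <- wrap_periodic(iv[1]); hi <- wrap_periodic(iv[2])
  if (lo <= hi) x >= lo & x < hi else x >= lo | x < hi
}

interval_center <- function(iv) {
  lo <- iv[1]; hi <- iv[2]
  if (wrap_periodic(lo) <= wrap_periodic(hi)) wrap_periodic((lo + hi) / 2)
  else wrap_periodic((lo + hi + 360) / 2)
}

regions_overlap <- function(def) {
  # probe on a coarse torus grid: disjointness check
  grid <- seq(-177.5, 177.5, by = 5)
  pts <- as.matrix(do.call(expand.grid, rep(list(grid), length(def$angles))))
  hits <- matrix(FALSE, nrow(pts), length(def$regions))
  for (r in seq_along(def$regions))
    hits[, r] <- region_membership(pts, def$regions[[r]])
  any(rowSums(hits) > 1)
}

region_membership <- function(pts, region) {
  inside <- rep(TRUE, nrow(pts))
  for (d in seq_along(region))
    inside <- inside & in_interval_periodic(pts[, d], region[[d]])
  inside
}

#' Encode dihedral time series into conformer strings
#'
#' @param angles data.frame (or matrix with column names) of dihedral
#'   angles in degrees, one row per frame; must contain every column
#'   named by every linkage.
#' @param linkages list of [linkage_definition()] (a single one may be
#'   passed bare).
#' @param times optional frame times (ps); defaults to 0, 1, 2, ...
#' @param unassigned `"nearest"` (default) assigns out-of-region tuples
#'   to the closest region centre by periodic distance; `"mark"` encodes
#'   them as `"X"`.
#' @return a `conformer_series`: list with `times`, `strings` (character,
#'   one string of `length(linkages)` letters per frame), `linkages`.
#' @export
encode_conformers <- function(angles, linkages, times = NULL,
                              unassigned = c("nearest", "mark")) {
  unassigned <- match.arg(unassigned)
  if (inherits(linkages, "linkage_definition")) linkages <- list(linkages)
  angles <- as.data.frame(angles)
  nf <- nrow(angles)
  letters_per_linkage <- lapply(linkages, function(lk) {
    missing <- setdiff(lk$angles, names(angles))
    if (length(missing))
      stop("missing dihedral column(s): ", paste(missing, collapse = ", "))
    pts <- as.matrix(angles[, lk$angles, drop = FALSE])
    lab <- rep(NA_character_, nf)
    for (letter in names(lk$regions)) {
      hit <- region_membership(pts, lk$regions[[letter]])
      lab[is.na(lab) & hit] <- letter
    }
    out <- is.na(lab)
    if (any(out)) {
      if (unassigned == "mark") {
        lab[out] <- "X"
      } else {
        centers <- vapply(lk$regions, function(rg)
          vapply(rg, interval_center, 0), numeric(length(lk$angles)))
        centers <- matrix(centers, nrow = length(lk$angles))
        d2 <- vapply(seq_len(ncol(centers)), function(r) {
          dd <- sweep(pts[out, , drop = FALSE], 2, centers[, r])
          rowSums(wrap_periodic(dd)^2)
        }, numeric(sum(out)))
        d2 <- matrix(d2, nrow = sum(out))
        lab[out] <- names(lk$regions)[apply(d2, 1, which.min)]
      }
    }
    lab
  })
  strings <- do.call(paste0, letters_per_linkage)
  structure(list(times = times %||% (seq_len(nf) - 1),
                 strings = strings,
                 linkages = vapply(linkages, `[[`, "", "name")),
            class = "conformer_series")
}

#' @export
print.conformer_series <- function(x, ...) {
  cat(sprintf("<conformer_series> %d frames, %d linkage(s), %d unique string(s)\n",
              length(x$strings), length(x$linkages),
              length(unique(x$strings))))
  invisible(x)
}

as_strings <- function(series) {
  if (inherits(series, "conformer_series")) series$strings
  else as.character(series)
}

#' Count conformer clusters
#'
#' Number of distinct conformer strings seen up to each frame
#' (nondecreasing cumulative curve) and in total.
#'
#' @param series a `conformer_series` or character vector of strings.
#' @return list with `total` and `cumulative` (integer vector per frame).
#' @export
count_clusters <- function(series) {
  s <- as_strings(series)
  if (!length(s)) stop("empty series")
  first <- !duplicated(s)
  list(total = sum(first), cumulative = cumsum(first))
}

#' Count transitions between conformers
#'
#' Number of consecutive-frame pairs with differing strings, and the
#' rate per ns from the series time span.
#'
#' @param series a `conformer_series` (or character vector with `times`).
#' @param times frame times in ps (taken from the series when absent).
#' @return list with `count` and `rate_per_ns` (`NA` when the time span
#'   is zero).
#' @export
count_transitions <- function(series, times = NULL) {
  s <- as_strings(series)
  if (length(s) < 2) stop("need at least 2 frames")
  times <- times %||% (if (inherits(series, "conformer_series")) series$times
                       else seq_along(s) - 1)
  n <- sum(s[-1] != s[-length(s)])
  span_ns <- (max(times) - min(times)) / 1000
  list(count = n, rate_per_ns = if (span_ns > 0) n / span_ns else NA_real_)
}

#' Filter conformers by dwell time
#'
#' Keeps the strings that persist: in `"contiguous"` mode (default) a
#' string qualifies if at least one unbroken run of it lasts `>= tau`;
#' in `"cumulative"` mode if its total occupancy does.  A run of `n`
#' frames recorded every `frame_dt` ps counts as `n * frame_dt` ps of
#' residence, so a run of exactly `tau` qualifies and
#' `dwell_filter(series, tau = frame_dt)` returns every observed string.
#'
#' @param series a `conformer_series` or character vector.
#' @param tau dwell threshold, ps (default 10; must be `>= frame_dt`).
#' @param frame_dt frame spacing, ps (inferred from the series times
#'   when possible).
#' @param mode `"contiguous"` or `"cumulative"`.
#' @return character vector of qualifying strings (sorted).
#' @export
dwell_filter <- function(series, tau = 10, frame_dt = NULL,
                         mode = c("contiguous", "cumulative")) {
  mode <- match.arg(mode)
  s <- as_strings(series)
  if (is.null(frame_dt)) {
    if (inherits(series, "conformer_series") && length(series$times) > 1)
      frame_dt <- series$times[2] - series$times[1]
    else stop("frame_dt required")
  }
  if (tau < frame_dt) stop("tau must be >= frame_dt")
  r <- rle(s)
  if (mode == "contiguous") {
    keep <- unique(r$values[r$lengths * frame_dt >= tau])
  } else {
    tot <- rowsum(r$lengths * frame_dt, r$values)
    keep <- rownames(tot)[tot[, 1] >= tau]
  }
  sort(keep)
}

#' Hamming distance between conformer strings
#'
#' Number of differing letter positions between two equal-length strings
#' (vectorised over pairs).
#'
#' @param s1,s2 character vectors of equal-length strings.
#' @return integer vector of distances.
#' @export
hamming <- function(s1, s2) {
  if (any(nchar(s1) != nchar(s2)))
    stop("Hamming distance requires equal-length strings")
  mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    s1, s2, USE.NAMES = FALSE)
}

#' Detect threshold-crossing events with a lifetime criterion
#'
#' Finds the maximal intervals in which a scalar CV stays below (or,
#' with `below = FALSE`, above) a threshold for at least `min_lifetime`.
#' An interval of `n` consecutive frames counts as `n * frame_dt` ps, so
#' a dip of exactly `min_lifetime` is one event.  The canonical use is
#' folding-event counting (e.g. RMSD `<= 0.3` nm sustained for
#' `>= 100` ps).
#'
#' @param x numeric CV series, one value per frame.
#' @param threshold crossing threshold (CV units).
#' @param min_lifetime minimum event duration, ps (>= `frame_dt`).
#' @param frame_dt frame spacing, ps.
#' @param below detect excursions below (`TRUE`) or above the threshold.
#' @param strict use strict inequality at the threshold (default: at or
#'   beyond counts as inside).
#' @return data.frame with one row per event: `start_frame`,
#'   `end_frame` (1-based, inclusive), `start_ps`, `end_ps`,
#'   `duration_ps`.
#' @export
detect_events <- function(x, threshold, min_lifetime, frame_dt,
                          below = TRUE, strict = FALSE) {
  if (min_lifetime < frame_dt) stop("min_lifetime must be >= frame_dt")
  inside <- if (below) {
    if (strict) x < threshold else x <= threshold
  } else {
    if (strict) x > threshold else x >= threshold
  }
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & (r$lengths * frame_dt >= min_lifetime)
  data.frame(start_frame = starts[sel], end_frame = ends[sel],
             start_ps = (starts[sel] - 1) * frame_dt,
             end_ps = (ends[sel] - 1) * frame_dt,
             duration_ps = r$lengths[sel] * frame_dt)
}
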