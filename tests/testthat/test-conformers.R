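test_that("encoding assigns region letters with periodic wrapping", {
  lk <- toy_linkage()
  # region centres map to their own letters
  ang <- data.frame(phi = c(-90, 90, -90, 90), psi = c(0, 0, 180, 180))
  cs <- encode_conformers(ang, lk)
  expect_equal(cs$strings, c("A", "B", "C", "D"))
  # psi = -179 lies in the wrapped interval [90, -90)
  cs2 <- encode_conformers(data.frame(phi = -90, psi = -179), lk)
  expect_equal(cs2$strings, "C")
  # a wrapping phi region
  lkw <- linkage_definition("W", "phi",
                            list(A = list(c(170, -170)), B = list(c(-10, 10))))
  expect_equal(encode_conformers(data.frame(phi = -179), lkw)$strings, "A")
  expect_equal(encode_conformers(data.frame(phi = 179), lkw)$strings, "A")
  expect_error(encode_conformers(data.frame(psi = 0), lkw), "missing dihedral")
})

test_that("out-of-region tuples go to the nearest centre (or X)", {
  lk <- toy_linkage()
  # phi = 0 is outside both A and B
  near <- encode_conformers(data.frame(phi = -5, psi = 0), lk)
  expect_equal(near$strings, "A")
  near2 <- encode_conformers(data.frame(phi = 5, psi = 0), lk)
  expect_equal(near2$strings, "B")
  marked <- encode_conformers(data.frame(phi = 5, psi = 0), lk,
                              unassigned = "mark")
  expect_equal(marked$strings, "X")
})

test_that("random series encoding matches a per-frame brute-force scan", {
  set.seed(8)
  lks <- list(toy_linkage("L1", c("phi1", "psi1")),
              toy_linkage("L2", c("phi2", "psi2")))
  ang <- data.frame(phi1 = runif(300, -180, 180),
                    psi1 = runif(300, -180, 180),
                    phi2 = runif(300, -180, 180),
                    psi2 = runif(300, -180, 180))
  cs <- encode_conformers(ang, lks)
  # brute force: test every region, else nearest centre
  oracle <- vapply(seq_len(300), function(fr) {
    paste0(vapply(lks, function(lk) {
      pt <- as.numeric(ang[fr, lk$angles])
      for (letter in names(lk$regions)) {
        rg <- lk$regions[[letter]]
        ok <- all(vapply(seq_along(rg), function(d)
          selgamd:::in_interval_periodic(pt[d], rg[[d]]), TRUE))
        if (ok) return(letter)
      }
      d2 <- vapply(lk$regions, function(rg)
        sum(selgamd:::wrap_periodic(pt - vapply(rg, selgamd:::interval_center, 0))^2), 0)
      names(lk$regions)[which.min(d2)]
    }, ""), collapse = "")
  }, "")
  expect_identical(cs$strings, oracle)
  # encoding is frame-local: shuffling frames shuffles letters identically
  perm <- sample(300)
  expect_identical(encode_conformers(ang[perm, ], lks)$strings,
                   cs$strings[perm])
})

test_that("cluster counting is cumulative and matches the set oracle", {
  s <- c("AA", "AA", "AB", "AA", "BB", "AB")
  cl <- count_clusters(s)
  expect_equal(cl$total, 3)
  expect_equal(cl$cumulative, c(1, 1, 2, 2, 3, 3))
  expect_true(all(diff(cl$cumulative) >= 0))
  expect_equal(count_clusters(rep("AAAA", 10))$total, 1)
  set.seed(9)
  r <- paste0(sample(LETTERS[1:4], 500, TRUE), sample(LETTERS[1:4], 500, TRUE))
  expect_equal(count_clusters(r)$total, length(unique(r)))
})

test_that("transition counting matches the pairwise oracle", {
  s <- rep(c("A", "B"), 10)
  expect_equal(count_transitions(s)$count, 19)
  expect_equal(count_transitions(rep("A", 5))$count, 0)
  set.seed(10)
  r <- sample(c("AA", "AB", "BA"), 400, TRUE)
  times <- (seq_along(r) - 1) * 2  # 2 ps spacing
  tr <- count_transitions(r, times = times)
  oracle <- sum(vapply(2:400, function(i) r[i] != r[i - 1], TRUE))
  expect_equal(tr$count, oracle)
  expect_equal(tr$rate_per_ns, oracle / (399 * 2 / 1000))
  # invariant under time reversal
  expect_equal(count_transitions(rev(r), times = times)$count, oracle)
})

test_that("dwell filtering honours the contiguous-run boundary", {
  # frame_dt 2 ps, tau 10 ps: a run of exactly 5 frames qualifies
  s <- c(rep("A", 5), "B", rep("C", 4), "B", rep("C", 3), "B")
  keep <- dwell_filter(s, tau = 10, frame_dt = 2)
  expect_equal(keep, "A")
  # cumulative mode counts total occupancy: C has 7 frames = 14 ps
  keepc <- dwell_filter(s, tau = 10, frame_dt = 2, mode = "cumulative")
  expect_setequal(keepc, c("A", "C"))
  # tau = frame_dt returns every observed string
  expect_setequal(dwell_filter(s, tau = 2, frame_dt = 2), unique(s))
  expect_error(dwell_filter(s, tau = 1, frame_dt = 2), "tau")
  # randomized series against a run-length oracle
  set.seed(11)
  r <- sample(c("A", "B", "C"), 600, TRUE, prob = c(0.6, 0.3, 0.1))
  tau <- 8; dt <- 2
  rl <- rle(r)
  oracle <- sort(unique(rl$values[rl$lengths * dt >= tau]))
  expect_equal(dwell_filter(r, tau = tau, frame_dt = dt), oracle)
})

test_that("Hamming distance is a metric on conformer strings", {
  expect_equal(hamming("AABA", "AABA"), 0)
  expect_equal(hamming("AABA", "AABB"), 1)
  expect_equal(hamming("ABCD", "DCBA"), 4)
  expect_error(hamming("AB", "ABC"), "equal-length")
  set.seed(12)
  rs <- replicate(30, paste0(sample(LETTERS[1:4], 5, TRUE), collapse = ""))
  for (i in 1:30) {
    for (j in 1:30) {
      expect_equal(hamming(rs[i], rs[j]), hamming(rs[j], rs[i]))
      for (k in sample(30, 3))
        expect_lte(hamming(rs[i], rs[j]),
                   hamming(rs[i], rs[k]) + hamming(rs[k], rs[j]))
    }
  }
})

test_that("event detection applies the lifetime criterion inclusively", {
  dt <- 10  # ps per frame
  # always above threshold: nothing
  expect_equal(nrow(detect_events(rep(1, 50), 0.3, 100, dt)), 0)
  # one dip of exactly 100 ps (10 frames)
  x <- rep(1, 50); x[11:20] <- 0.1
  ev <- detect_events(x, 0.3, 100, dt)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 11)
  expect_equal(ev$end_frame, 20)
  expect_equal(ev$duration_ps, 100)
  # a 9-frame dip misses the criterion
  x2 <- rep(1, 50); x2[11:19] <- 0.1
  expect_equal(nrow(detect_events(x2, 0.3, 100, dt)), 0)
  # above-threshold mode
  expect_equal(nrow(detect_events(1 - x, 0.7, 100, dt, below = FALSE)), 1)
  expect_error(detect_events(x, 0.3, 5, dt), "min_lifetime")
  # noisy series against a brute-force interval scan
  set.seed(13)
  y <- runif(800)
  ev2 <- detect_events(y, 0.25, 30, dt)
  r <- rle(y <= 0.25)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  sel <- r$values & r$lengths * dt >= 30
  expect_equal(ev2$start_frame, starts[sel])
  expect_equal(ev2$end_frame, ends[sel])
})
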