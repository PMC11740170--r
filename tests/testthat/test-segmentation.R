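# Direct linear-solve oracle for the walker rank: the stationary vector of
# v = (1 - restart) T' v + restart e solves (I - (1 - restart) T') v = restart e.
solve_rank <- function(tm, seed, restart = 0.15) {
  n <- nrow(tm)
  e <- numeric(n); e[seed] <- 1
  drop(solve(diag(n) - (1 - restart) * t(tm), restart * e))
}

# Rebuild the renormalized sub-chain and the deterministic seed pair the
# split uses, so the oracle can mirror it.
sub_chain <- function(tm, members) {
  a <- unclass(tm)[members, members, drop = FALSE]
  a / rowSums(a)
}

least_correlated_pair <- function(r, members) {
  sub <- r[members, members, drop = FALSE]
  sub[upper.tri(sub, diag = TRUE)] <- Inf
  ij <- arrayInd(which.min(sub), dim(sub))
  c(min(ij), max(ij))
}

test_that("affinity maps correlation onto [0, 1] and rows are stochastic", {
  s <- random_spectrum(30)
  tm <- build_transition(rbind(s, s))
  expect_equal(unclass(tm), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)

  x <- c(1, 2, 3, 4)
  tm3 <- build_transition(rbind(x, 5 - x, c(2, 1, 4, 3)))
  r <- attr(tm3, "correlation")
  expect_equal(r[1, 2], -1)
  # affinity for the anti-correlated pair is 0: no direct transition
  a <- unclass(tm3)
  expect_equal(a[1, 2], 0)

  withr::with_seed(6, {
    m <- matrix(rlnorm(8 * 25, log(10), 1), 8)
  })
  tm8 <- build_transition(m)
  expect_true(all(abs(rowSums(unclass(tm8)) - 1) < 1e-12))
  expect_warning(build_transition(rbind(x, rep(2, 4))), "zero-variance")
})

test_that("walker competition exactly separates a block-diagonal chain", {
  withr::with_seed(8, {
    a <- rlnorm(30, log(40), 1)
    b <- sample(a)  # same values, uncorrelated order
    m <- rbind(t(vapply(c(1.00, 1.01, 0.99), function(f) a * f, a)),
               t(vapply(c(1.00, 1.01, 0.99), function(f) b * f, b)))
  })
  tm <- build_transition(m)
  halves <- rankcompete_split(tm, 1:6)
  expect_setequal(lapply(halves, sort), list(1:3, 4:6))

  # a 2-pixel segment puts one pixel on each side
  expect_setequal(unlist(rankcompete_split(tm, c(2L, 5L))), c(2L, 5L))
})

test_that("power-iteration ranks match the direct linear solve", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      m <- matrix(rlnorm(8 * 20, log(10), 1), 8)
      tm <- build_transition(m)
      members <- sort(sample(8, sample(3:8, 1)))
      st <- sub_chain(tm, members)
      seeds <- least_correlated_pair(attr(tm, "correlation"), members)
      for (s in seeds) {
        v_direct <- solve_rank(st, s)
        v_power <- rmma:::personalized_rank(st, s)
        expect_lt(max(abs(v_direct - v_power)), 1e-8)
      }
      v1 <- solve_rank(st, seeds[1]); v2 <- solve_rank(st, seeds[2])
      expected_first <- v1 > v2 | (v1 == v2 & seeds[1] < seeds[2])
      expected_first[seeds[1]] <- TRUE; expected_first[seeds[2]] <- FALSE
      halves <- rankcompete_split(tm, members)
      expect_identical(halves[[1]], members[expected_first])
      expect_identical(halves[[2]], members[!expected_first])
    }
  })
})

test_that("divisive segmentation recovers classes and respects its caps", {
  # homogeneous data: one segment
  withr::with_seed(10, {
    base <- rlnorm(25, log(30), 1)
    homo <- t(vapply(1:8, function(i) base * runif(1, 0.9, 1.1), base))
  })
  expect_equal(length(diana_rankcompete(homo, 0.9)$segments), 1L)

  # three well-separated classes
  sim3 <- local({
    lay <- generate_array_layout(5, 3, groups = c("a", "b", "c"),
                                 standards = c(0, 5, 10))
    simulate_msi_dataset(lay, synth_config(seed = 21))
  })
  lay3 <- generate_array_layout(5, 3, groups = c("a", "b", "c"),
                                standards = c(0, 5, 10))
  asn <- assign_pixels(sim3$dataset, lay3)
  cls <- sim3$truth$pixel_class
  fg <- which(!is.na(asn$spot) & cls %in% c("a", "b", "c"))
  norm <- t(apply(sim3$dataset$spectra[fg, ], 1, tic_normalize))
  seg <- diana_rankcompete(norm, cohesion_stop = 0.9)
  expect_equal(length(seg$segments), 3L)
  expect_equal(mclust::adjustedRandIndex(seg$labels, cls[fg]), 1)

  capped <- diana_rankcompete(norm, cohesion_stop = 0.9, max_segments = 2)
  expect_equal(length(capped$segments), 2L)

  # partition property and determinism
  expect_setequal(unlist(seg$segments), seq_len(nrow(norm)))
  expect_equal(sum(lengths(seg$segments)), nrow(norm))
  seg2 <- diana_rankcompete(norm, cohesion_stop = 0.9)
  expect_identical(seg$labels, seg2$labels)
})

test_that("color positions span the least-correlated extreme pair", {
  fake_seg <- function(mean_spectra) {
    k <- nrow(mean_spectra)
    structure(list(segments = as.list(seq_len(k)), labels = seq_len(k),
                   mean_spectra = mean_spectra, cohesion = rep(1, k)),
              class = "segmentation")
  }
  two <- color_segments(fake_seg(rbind(c(1, 2, 3), c(3, 2, 1))))
  expect_setequal(two$positions, c(0, 1))

  # symmetric third segment lands mid-scale
  sym <- color_segments(fake_seg(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))))
  expect_equal(sym$positions[3], 0.5)
  expect_setequal(sym$positions[1:2], c(0, 1))

  one <- color_segments(fake_seg(rbind(c(1, 2, 3))))
  expect_equal(one$positions, 0.5)

  # brute-force extreme-pair oracle on random 5-segment cases
  withr::with_seed(11, {
    for (rep in 1:20) {
      ms <- matrix(rlnorm(5 * 12, log(10), 1), 5)
      seg <- color_segments(fake_seg(ms))
      r <- suppressWarnings(cor(t(ms)))
      lo <- which(r == min(r[lower.tri(r)]), arr.ind = TRUE)
      extremes <- sort(unique(as.vector(lo)))
      placed <- which(seg$positions %in% c(0, 1))
      expect_true(all(placed %in% extremes))
      expect_true(all(seg$positions >= 0 & seg$positions <= 1))
    }
  })
})

test_that("replicate spots of one sample share one majority segment color", {
  sim <- four_group_sim()
  fg <- foreground_spectra(sim)
  seg <- diana_rankcompete(fg$spectra, cohesion_stop = 0.9)
  rep_grp <- sim$layout$replicate_group[match(fg$spot, sim$layout$id)]
  agree <- tapply(seg$labels, rep_grp, function(l)
    max(table(l)) / length(l))
  expect_true(all(agree >= 0.95))
})
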