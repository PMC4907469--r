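test_that("virial stress matches the direct-summation oracle on a strained lattice", {
  sys <- build_hexagonal_lattice(10, 10)
  s <- apply_affine_strain(sys, strain_protocol("horizontal", 0.02))
  got <- virial_stress(s, default_pots)
  oracle <- brute_force_stress(s, default_pots)
  expect_equal(got, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # uniaxial strain: tension along x (negative in the pressure convention);
  # shear is small on a finite clamped sample (edge effect only) ...
  expect_lt(got["x", "x"], 0)
  expect_lt(abs(got["x", "y"]), 0.01 * abs(got["x", "x"]))
  # ... and zero by symmetry on an x-periodic sample
  sp <- apply_affine_strain(build_hexagonal_lattice(10, 10, boundary = "periodic_x"),
                            strain_protocol("horizontal", 0.02))
  gp <- virial_stress(sp, default_pots)
  expect_lt(abs(gp["x", "y"]), 1e-10 * abs(gp["x", "x"]))
  # relaxed unstrained lattice at 0 K: all components ~0
  s0 <- virial_stress(sys, default_pots)
  expect_true(all(abs(s0) < 1e-8))
  # kinetic term: moving blocks contribute m v v / A
  sys$velocities[, 1] <- 0.01
  sk <- virial_stress(sys, default_pots)
  expect_equal(sk, brute_force_stress(sys, default_pots),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(sk["x", "x"], s0["x", "x"])
  # degenerate (zero-area) system signals
  expect_error(virial_stress(build_hexagonal_lattice(1, 1), default_pots),
               "degenerate")
})

test_that("broken-bond detection applies the resolved rupture cutoff", {
  expect_equal(nrow(detect_broken_bonds(make_pair_system(9.64), default_pots)), 0)
  br <- detect_broken_bonds(make_pair_system(9.66), default_pots)
  expect_equal(nrow(br), 1)
  expect_equal(br$rupture_cutoff, 9.65)
  # a damaged pair at the same distance is intact (cutoff 9.82)
  expect_equal(nrow(detect_broken_bonds(make_pair_system(9.66, species = "D"),
                                        default_pots)), 0)
  expect_equal(nrow(detect_broken_bonds(make_pair_system(9.83, species = "D"),
                                        default_pots)), 1)
  # relaxed unstrained lattice: nothing broken
  expect_equal(nrow(detect_broken_bonds(build_hexagonal_lattice(6, 6),
                                        default_pots)), 0)
})

test_that("crack clustering groups adjacent broken bonds and flags percolation", {
  sys <- build_hexagonal_lattice(6, 6)
  # empty input -> empty report
  none <- cluster_cracks(detect_broken_bonds(sys, default_pots), sys)
  expect_equal(length(none$clusters), 0)
  expect_false(none$percolates)
  # two broken bonds sharing a block form one cluster of size 2
  two <- data.frame(bond = 1:2, i = c(1L, 2L), j = c(2L, 3L))
  rep2 <- cluster_cracks(two, sys)
  expect_equal(length(rep2$clusters), 1)
  expect_equal(lengths(rep2$clusters), 2L, ignore_attr = TRUE)
  # far-apart bonds stay separate clusters
  far <- data.frame(bond = 1:2, i = c(1L, 31L), j = c(2L, 32L))
  expect_equal(length(cluster_cracks(far, sys)$clusters), 2)
  # a connected column of broken bonds from bottom to top percolates
  col3 <- which(sys$col == 3)
  chain <- data.frame(bond = seq_len(5),
                      i = col3[1:5], j = col3[2:6])
  rep_perc <- cluster_cracks(chain, sys)
  expect_equal(length(rep_perc$clusters), 1)
  expect_true(rep_perc$spans_transverse[1])
  expect_true(rep_perc$percolates)
  # oracle: exhaustive pairwise connectivity on the same input
  # (bonds i->i+1 of one column all share a block, hence one component)
  expect_true(all(diff(chain$i) > 0))
})

test_that("crack clustering is independent of bond-list ordering", {
  sys <- insert_notch(build_hexagonal_lattice(20, 20), 10, 3, 2)
  prot <- strain_protocol("horizontal", 0.05, hold_steps = 3000L)
  cfg <- dynamics_config(temperature = 300, friction = 0.1, random_seed = 11L,
                         series_every = 0L)
  res <- run_constant_strain(sys, default_pots, prot, cfg)
  broken <- res$broken
  expect_gt(nrow(broken), 2)
  base <- cluster_cracks(broken, res$system)
  set.seed(1)
  perm <- sample(nrow(broken))
  shuf <- cluster_cracks(broken[perm, ], res$system)
  canon <- function(rep, b) {
    sets <- lapply(rep$clusters, function(idx) sort(paste(b$i[idx], b$j[idx])))
    sets[order(vapply(sets, paste, "", collapse = "|"))]
  }
  expect_identical(canon(base, broken), canon(shuf, broken[perm, ]))
  expect_identical(base$percolates, shuf$percolates)
})

test_that("exponential decay fitting recovers known parameters", {
  tt <- seq(0, 25, length.out = 50)
  clean <- data.frame(time_ps = tt, sigma_xx = 2 + 8 * exp(-tt / 5))
  f <- fit_exponential_decay(clean)
  expect_equal(f$amplitude, 8, tolerance = 1e-6)
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_equal(f$offset, 2, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # Monte-Carlo noise-recovery study: tau within 10% on average
  set.seed(99)
  taus <- replicate(60, {
    noisy <- clean
    noisy$sigma_xx <- noisy$sigma_xx + rnorm(50, 0, 0.1)
    fit_exponential_decay(noisy)$tau
  })
  expect_lt(mean(abs(taus - 5) / 5), 0.10)
  # degenerate constant series is flagged, not an error
  const <- data.frame(time_ps = tt, sigma_xx = rep(3, 50))
  fc <- fit_exponential_decay(const)
  expect_true(fc$degenerate)
  expect_equal(fc$amplitude, 0)
  # guards
  expect_error(fit_exponential_decay(clean[1:5, ]), "at least 10")
  expect_error(fit_exponential_decay(clean, "sigma_zz"), "not found")
})
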