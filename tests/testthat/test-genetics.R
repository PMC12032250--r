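test_that("fitness classes follow the LOF/functional allele partition", {
  expect_equal(drive_fitness_class(diplotype(c("D", "D"))), "homozygous_LOF")
  expect_equal(drive_fitness_class(diplotype(c("D", "R2"))), "homozygous_LOF")
  expect_equal(drive_fitness_class(diplotype(c("W", "R1"))), "functional")
  expect_equal(drive_fitness_class(diplotype(c("R1", "R1"))), "functional")
  expect_equal(drive_fitness_class(diplotype(c("D", "R1"))), "heterozygous_LOF")
  expect_equal(drive_fitness_class(diplotype(c("W", "R2"))), "heterozygous_LOF")
})

test_that("diplotypes are unordered: homologue swap gives the same object", {
  a <- diplotype(c("D", "W"), c("C", "E"))
  b <- diplotype(c("W", "D"), c("E", "C"))
  expect_identical(genotype_label(a), genotype_label(b))
  expect_identical(parse_genotype(genotype_label(a)), a)
})

test_that("gamete distribution reproduces the measured drive inheritance and
           resistance split arithmetic", {
  # female heterozygote at the measured female rate, full conversion, 1:9
  p <- drive_params(homing_female = 0.996, uncut_fraction = 0,
                    functional_fraction = 0.1)
  g <- gamete_distribution(diplotype(c("D", "W"), sex = "female"), p)
  expect_equal(g[["D:C"]], 0.996)
  expect_equal(g[["R1:C"]], 0.0004, tolerance = 1e-12)
  expect_equal(g[["R2:C"]], 0.0036, tolerance = 1e-12)

  # 1:999 split at 99% homing gives one functional resistance gamete in 1e5
  p2 <- drive_params(homing_female = 0.99, uncut_fraction = 0,
                     functional_fraction = 0.001)
  g2 <- gamete_distribution(diplotype(c("D", "W"), sex = "female"), p2)
  expect_equal(g2[["R1:C"]], 1e-5, tolerance = 1e-12)

  # no cleavable target: Mendelian regardless of homing
  g3 <- gamete_distribution(diplotype(c("D", "R2"), sex = "female"), p)
  expect_equal(unname(g3[c("D:C", "R2:C")]), c(0.5, 0.5))

  # homozygous wild type transmits only W:C
  g4 <- gamete_distribution(diplotype(c("W", "W"), sex = "male"), p)
  expect_equal(g4[["W:C"]], 1)

  # Mendelian limit: h = 0.5, u = 1
  p5 <- drive_params(homing_female = 0.5, homing_male = 0.5,
                     uncut_fraction = 1)
  g5 <- gamete_distribution(diplotype(c("D", "W"), sex = "female"), p5)
  expect_equal(unname(g5[c("W:C", "D:C")]), c(0.5, 0.5))
})

test_that("expected inheritance equals the sex-specific homing probability", {
  p <- drive_params(homing_female = 0.996, homing_male = 0.971)
  expect_equal(expected_inheritance(p, "female"), 0.996)
  expect_equal(expected_inheritance(p, "male"), 0.971)
  expect_equal(expected_inheritance(drive_params(homing_female = 0.5), "female"),
               0.5)
})

test_that("every gamete distribution sums to one over all genotype and sex
           combinations", {
  set.seed(41)
  for (rep in 1:5) {
    p <- random_params()
    for (dr in all_drive_pairs()) for (ef in all_eff_pairs())
      for (sx in c("female", "male")) {
        g <- gamete_distribution(diplotype(dr, ef, sx), p)
        expect_true(all(g >= 0))
        expect_lt(abs(sum(g) - 1), 1e-12)
      }
  }
})

test_that("gamete and cross distributions match brute-force enumeration", {
  set.seed(42)
  for (rep in 1:50) {
    p <- random_params()
    for (dr in all_drive_pairs()) for (ef in all_eff_pairs()) {
      sx <- sample(c("female", "male"), 1)
      g <- gamete_distribution(diplotype(dr, ef, sx), p)
      o <- oracle_gamete(dr, ef, sx, p)
      expect_lt(max(abs(g - o[names(g)])), 1e-12)
    }
    mo <- sample(all_drive_pairs(), 1)[[1]]
    fa <- sample(all_drive_pairs(), 1)[[1]]
    me <- sample(all_eff_pairs(), 1)[[1]]
    fe <- sample(all_eff_pairs(), 1)[[1]]
    d <- cross_distribution(diplotype(mo, me, "female"),
                            diplotype(fa, fe, "male"), p)
    expect_lt(max_dist_diff(d, oracle_cross(mo, me, fa, fe, p)), 1e-12)
    expect_lt(abs(sum(d) - 1), 1e-12)
  }
})

test_that("the effector locus is Mendelian in individuals lacking the drive", {
  set.seed(43)
  for (rep in 1:40) {
    p <- random_params()
    dr <- sample(setdiff(ALL_DRIVE, "D"), 2, replace = TRUE)
    ef <- sample(ALL_EFF, 2, replace = TRUE)
    g <- gamete_distribution(diplotype(dr, ef, sample(c("female", "male"), 1)), p)
    emarg <- vapply(ALL_EFF, function(e)
      sum(g[paste(ALL_DRIVE, e, sep = ":")]), numeric(1))
    expected <- setNames(numeric(3), ALL_EFF)
    for (i in 1:2) expected[ef[i]] <- expected[ef[i]] + 0.5
    expect_equal(emarg, expected, tolerance = 1e-12)
  }
})

test_that("cross distributions reproduce the hemizygote-by-wild-type
           transmission readout", {
  p <- drive_params()  # measured rates 0.996 / 0.971
  d_f <- cross_distribution(diplotype(c("D", "W"), sex = "female"),
                            diplotype(c("W", "W"), sex = "male"), p)
  expect_equal(carrier_probability(d_f, "D"), 0.996)
  d_m <- cross_distribution(diplotype(c("W", "W"), sex = "female"),
                            diplotype(c("D", "W"), sex = "male"), p)
  expect_equal(carrier_probability(d_m, "D"), 0.971)
  # homozygote crosses are degenerate
  d_hom <- cross_distribution(diplotype(c("D", "D"), sex = "female"),
                              diplotype(c("W", "W"), sex = "male"), p)
  expect_equal(unname(d_hom["D:C/W:C"]), 1)
  # both parents certain transmitters: no drive-free offspring
  p1 <- drive_params(homing_female = 1, homing_male = 1, uncut_fraction = 0)
  d_both <- cross_distribution(diplotype(c("D", "W"), sex = "female"),
                               diplotype(c("D", "W"), sex = "male"), p1)
  expect_equal(carrier_probability(d_both, "D"), 1)
  # sex contract enforced
  expect_error(cross_distribution(diplotype(c("D", "W"), sex = "male"),
                                  diplotype(c("W", "W"), sex = "male"), p),
               "female")
})

test_that("linked inheritance keeps marginals and reduces to independence at
           r = 0.5", {
  p_link <- drive_params(homing_female = 0.95, effector_homing = 0.9,
                         recombination_fraction = 0.1)
  dip <- diplotype(c("D", "W"), c("E", "C"), "female")
  g <- gamete_distribution(dip, p_link)
  expect_lt(abs(sum(g) - 1), 1e-12)
  dmarg <- vapply(ALL_DRIVE, function(d)
    sum(g[paste(d, ALL_EFF, sep = ":")]), numeric(1))
  expect_equal(dmarg[["D"]], 0.95)
  emarg <- vapply(ALL_EFF, function(e)
    sum(g[paste(ALL_DRIVE, e, sep = ":")]), numeric(1))
  expect_equal(emarg[["E"]], 0.9)
  # r = 0 keeps converted haplotypes fully coupled; D:E exceeds independence
  p0 <- drive_params(homing_female = 0.95, effector_homing = 0.9,
                     recombination_fraction = 0)
  g0 <- gamete_distribution(dip, p0)
  expect_gt(g0[["D:E"]], g[["D:E"]] - 1e-12)
  expect_equal(oracle_gamete(c("D", "W"), c("E", "C"), "female", p0)[names(g0)],
               g0, tolerance = 1e-12)
})

test_that("deterministic recursion matches mating-pair enumeration and its
           frozen example", {
  # frozen value computed by the independent pair-enumeration oracle
  p <- drive_params(homing_female = 0.984, homing_male = 0.984,
                    uncut_fraction = 0, functional_fraction = 0)
  nxt <- deterministic_step(c(W = 0.8, D = 0.2, R1 = 0, R2 = 0), p)
  expect_equal(nxt[["D"]], 0.35488, tolerance = 1e-12)
  expect_equal(nxt, oracle_step(c(W = 0.8, D = 0.2, R1 = 0, R2 = 0), p),
               tolerance = 1e-12)

  # random-parameter agreement with the oracle, including fitness weights
  set.seed(44)
  for (rep in 1:20) {
    pr <- random_params()
    q <- runif(4); q <- setNames(q / sum(q), c("W", "D", "R1", "R2"))
    w <- c(functional = runif(1, 0.2, 1), heterozygous_LOF = runif(1, 0.2, 1),
           homozygous_LOF = runif(1, 0.2, 1))
    expect_equal(deterministic_step(q, pr, w), oracle_step(q, pr, w),
                 tolerance = 1e-12)
  }
})

test_that("deterministic recursion honours fixation, neutrality and monotone
           spread", {
  p <- drive_params(homing_female = 0.9, homing_male = 0.9,
                    uncut_fraction = 0, functional_fraction = 0.1)
  # fixation is absorbing
  expect_equal(deterministic_step(c(W = 0, D = 1, R1 = 0, R2 = 0), p)[["D"]], 1)
  # neutral Mendelian locus is stationary
  pm <- drive_params(homing_female = 0.5, homing_male = 0.5, uncut_fraction = 1)
  q0 <- c(W = 0.55, D = 0.2, R1 = 0.15, R2 = 0.1)
  expect_equal(deterministic_step(q0, pm), q0, tolerance = 1e-12)
  # monotone spread until wild type is exhausted (u = 0 and u = 1 variants)
  for (u in c(0, 1)) {
    pu <- drive_params(homing_female = 0.8, homing_male = 0.8,
                       uncut_fraction = u, functional_fraction = 0)
    tr <- deterministic_trajectory(c(W = 0.95, D = 0.05, R1 = 0, R2 = 0),
                                   pu, 40)
    live <- which(tr[, "W"] > 1e-9)
    expect_true(all(diff(tr[live, "D"]) > 0))
  }
  # degenerate weights are an error
  expect_error(deterministic_step(c(W = 1, D = 0, R1 = 0, R2 = 0),
                                  p, c(functional = 0, heterozygous_LOF = 0,
                                       homozygous_LOF = 0)),
               "degenerate")
  # invalid parameter domain is an error
  expect_error(drive_params(homing_female = 1.2), "probability")
})
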