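test_that("region splitting follows the floored fraction convention", {
  s100 <- random_aa_sequence(100)
  regs <- split_regions(s100)
  expect_identical(regs[1], substr(s100, 1, 25))
  expect_identical(regs[9], substr(s100, 13, 87))
  expect_error(split_regions("ACDEFGH"), "at least 8")
})

test_that("the three 75% regions jointly cover the whole sequence", {
  set.seed(7)
  scheme <- region_scheme()
  for (i in 1:25) {
    L <- sample(50:500, 1)
    from <- floor(scheme[8:10, "start"] * L) + 1
    to <- floor(scheme[8:10, "end"] * L)
    covered <- sort(unique(unlist(Map(seq, from, to))))
    expect_identical(covered, 1:L)
    expect_true(all(to >= from))
  }
})

test_that("C/T/D matches hand-derived values on degenerate regions", {
  # homopolymer: pure composition, no transitions, uniform distribution
  v <- ctd_region_vector(strrep("A", 20))   # A is in group 1
  expect_equal(v[1:7], c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(v[8:28], rep(0, 21))
  expect_equal(v[29:33], c(0.05, 0.25, 0.5, 0.75, 1))
  # single residue
  v1 <- ctd_region_vector("C")               # C is group 7
  expect_equal(v1[1:7], c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(v1[8:28], rep(0, 21))
  expect_equal(v1[63 - 4:0], rep(1, 5))
  expect_error(ctd_region_vector(""), "non-empty")
})

test_that("C/T/D and the local descriptor agree with the brute-force oracle", {
  set.seed(41)
  for (i in 1:50) {
    region <- random_aa_sequence(sample(1:60, 1))
    expect_equal(ctd_region_vector(region), oracle_ctd(region),
                 tolerance = 1e-12)
  }
  for (i in 1:50) {
    s <- random_aa_sequence(sample(50:300, 1))
    got <- ld_vector(s)
    expect_length(got, 630)
    expect_equal(got, oracle_ld(s), tolerance = 1e-12)
  }
})

test_that("C/T/D invariants hold: compositions sum to 1, T and D in [0,1]", {
  set.seed(43)
  for (i in 1:25) {
    v <- matrix(ld_vector(random_aa_sequence(sample(50:200, 1))),
                nrow = 63)  # one column per region
    expect_equal(colSums(v[1:7, , drop = FALSE]), rep(1, 10),
                 tolerance = 1e-12)
    expect_true(all(v[8:28, ] >= 0 & v[8:28, ] <= 1))
    expect_true(all(v[29:63, ] >= 0 & v[29:63, ] <= 1))
  }
})

test_that("partition enumeration yields 35 valid 4/1/1/1 assignments", {
  parts <- enumerate_partitions()
  expect_identical(dim(parts), c(35L, 7L))
  expect_identical(nrow(unique(parts)), 35L)
  # lexicographic first assignment: G0 = groups 1-4, then 5,6,7 ascending
  expect_identical(parts[1, ], c(0L, 0L, 0L, 0L, 1L, 2L, 3L))
  for (i in 1:35) {
    sizes <- tabulate(parts[i, ] + 1L, 4L)
    expect_identical(sizes, c(4L, 1L, 1L, 1L))
  }
})

test_that("unit-circle placement matches the hand-evaluated example", {
  # "AA" with A in class G0: angles pi/6 and pi/3
  pts <- circle_trace("AA", c(0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(pts[, "x"]), c(0.8660, 0.5000), tolerance = 1e-4)
  expect_equal(unname(pts[, "y"]), c(0.5000, 0.8660), tolerance = 1e-4)
})

test_that("circle points lie on the unit circle in the class's quadrant", {
  set.seed(47)
  parts <- enumerate_partitions()
  for (i in 1:20) {
    s <- random_aa_sequence(sample(5:100, 1))
    pts <- circle_trace(s, parts[sample(35, 1), ])
    expect_equal(rowSums(pts^2), rep(1, nrow(pts)), tolerance = 1e-12)
  }
  # all residues of class G2 -> angles in [pi, 3pi/2)
  asg <- c(2L, 2L, 2L, 2L, 2L, 2L, 2L)  # every group in G2
  pts <- circle_trace(random_aa_sequence(40), asg)
  ang <- atan2(pts[, "y"], pts[, "x"]) %% (2 * pi)
  expect_true(all(ang >= pi & ang < 1.5 * pi))
})

test_that("F-vector matches hand evaluation and the brute-force oracle", {
  # "AA", A in G0: f1 = 0.6830, f2 = 0.0670 to 4 decimals
  fv <- fvector("AA")
  a_in_g0 <- which(enumerate_partitions()[, 1] == 0)  # A is in group 1
  i <- a_in_g0[1]
  expect_equal(round(fv[(i - 1) * 4 + 1], 4), 0.6830)
  expect_equal(round(fv[(i - 1) * 4 + 2], 4), 0.0670)
  set.seed(53)
  for (r in 1:50) {
    s <- random_aa_sequence(sample(2:150, 1))
    got <- fvector(s)
    expect_length(got, 140)
    expect_equal(got, oracle_fvector(s), tolerance = 1e-9)
  }
  # moment bounds: means in [-1, 1], dispersions non-negative
  fv <- matrix(fvector(random_aa_sequence(80)), nrow = 4)
  expect_true(all(abs(fv[c(1, 3), ]) <= 1))
  expect_true(all(fv[c(2, 4), ] >= 0))
})

test_that("property table is standardized over the 20 residues", {
  props <- property_table()
  expect_equal(mean(props[, "h1"]), 0, tolerance = 1e-12)
  expect_equal(mean(props[, "h2"]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(props[, "h1"]^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(mean(props[, "h2"]^2)), 1, tolerance = 1e-12)
})

test_that("pseudo-amino-acid composition variants match the oracle", {
  set.seed(59)
  for (r in 1:20) {
    s <- random_aa_sequence(sample(35:200, 1))
    expect_equal(apaac_vector(s), oracle_apaac(s), tolerance = 1e-9)
    expect_equal(apaacplus_vector(s), oracle_apaac(s, plus = TRUE),
                 tolerance = 1e-9)
  }
  expect_length(apaac_vector(random_aa_sequence(100)), 80)
  expect_length(apaacplus_vector(random_aa_sequence(100)), 140)
})

test_that("pseudo-amino-acid composition limits and short-sequence rules", {
  s <- random_aa_sequence(60)
  # zero weights reduce to the normalized composition followed by zeros
  v0 <- apaac_vector(s, apaac_config(w1 = 0))
  counts <- table(factor(strsplit(s, "")[[1]],
                         levels = sort(unique(strsplit(s, "")[[1]]))))
  expect_equal(sum(v0[1:20]), 1, tolerance = 1e-12)
  expect_equal(v0[21:80], rep(0, 60))
  vp0 <- apaacplus_vector(s, apaac_config(w1 = 0, w2 = 0))
  expect_equal(vp0[21:140], rep(0, 120))
  # w2 = 0: the first 20 + 2*lambda coordinates equal classic APAAC
  vp <- apaacplus_vector(s, apaac_config(w2 = 0))
  expect_equal(vp[1:80], apaac_vector(s), tolerance = 1e-12)
  expect_equal(vp[81:140], rep(0, 60))
  # length-45 sequence at lambda 30: triplet terms with 2k >= 45 vanish
  s45 <- random_aa_sequence(45)
  v45 <- apaacplus_vector(s45)
  ups <- matrix(v45[81:140], nrow = 2)  # columns = lags 1..30
  expect_true(all(ups[, (2 * (1:30)) >= 45] == 0))
  expect_equal(v45, oracle_apaac(s45, plus = TRUE), tolerance = 1e-9)
  # the first-20 block scaled by C recovers the raw frequencies exactly
  cfg <- apaac_config()
  expect_error(apaacplus_vector("XXXX"), "standard residues")
})

test_that("handcrafted vector concatenates its components", {
  s <- random_aa_sequence(90)
  hv <- handcrafted_vector(s)
  expect_length(hv, 910)
  expect_equal(hv[1:630], ld_vector(s))
  expect_equal(hv[631:770], fvector(s))
  expect_equal(hv[771:910], apaacplus_vector(s))
  expect_identical(hv, handcrafted_vector(s))
  # non-standard residues are stripped before encoding
  s_dirty <- paste0(substr(s, 1, 40), "XXBZ", substr(s, 41, 90))
  expect_equal(handcrafted_vector(s_dirty), hv)
})

test_that("featurize_records builds the feature matrix with chosen blocks", {
  recs <- gen_sequences(5, synthetic_config(seed = 15))
  m <- featurize_records(recs)
  expect_identical(dim(m), c(5L, 910L))
  expect_identical(rownames(m), recs$id)
  m2 <- featurize_records(recs, descriptors = c("apaac"))
  expect_identical(ncol(m2), 80L)
  expect_equal(m2[3, ], apaac_vector(recs$sequence[3]))
})
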