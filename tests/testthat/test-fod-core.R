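test_that("the Gaussian frame recovers box geometry and obeys the 3-sigma rule", {
  box <- as.matrix(expand.grid(x = c(-3, 3), y = c(-2, 2), z = c(-1, 1)))
  fr <- fit_gaussian_frame(box)
  expect_equal(fr$center, c(x = 0, y = 0, z = 0))
  expect_equal(unname(fr$sigma), c(1, 2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  fr2 <- fit_gaussian_frame(box, margin = 1.5)
  expect_equal(unname(fr2$sigma), (c(3, 2, 1) + 1.5) / 3, tolerance = 1e-9)
})

test_that("frame fitting is equivariant under rigid motions", {
  set.seed(1)
  cloud <- matrix(rnorm(150, sd = c(9, 5, 2)), ncol = 3L, byrow = TRUE)
  fr <- fit_gaussian_frame(cloud)
  rot <- random_rotation(); shift <- c(10, -4, 2)
  moved <- cloud %*% t(rot) + matrix(shift, nrow(cloud), 3L, byrow = TRUE)
  fr2 <- fit_gaussian_frame(moved)
  expect_equal(fr2$sigma, fr$sigma, tolerance = 1e-9)
  expect_equal(fr2$center, as.numeric(rot %*% fr$center) + shift,
               tolerance = 1e-9)
})

test_that("sigma matches a brute-force maximum-projection oracle", {
  set.seed(7)
  cloud <- matrix(rnorm(150, sd = c(12, 6, 3)), ncol = 3L, byrow = TRUE)
  fr <- fit_gaussian_frame(cloud, margin = 0.5)
  expect_equal(unname(fr$sigma), brute_sigma(cloud, fr, margin = 0.5),
               tolerance = 1e-12)
})

test_that("degenerate point clouds raise frame errors", {
  expect_error(fit_gaussian_frame(rbind(c(0, 0, 0), c(1, 1, 1))),
               "at least 3")
  line <- cbind(seq(0, 10, length.out = 12), 0, 0)
  expect_error(fit_gaussian_frame(line), "degenerate")
})

test_that("the theoretical field peaks at the center and matches pointwise evaluation", {
  fr <- structure(list(center = c(0, 0, 0), axes = diag(3),
                       sigma = c(5, 4, 3)), class = "gaussian_frame")
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0), c(0, 1, -1))
  tt <- theoretical_profile(pts, fr)
  expect_equal(tt$raw[1], 1)                       # Gaussian peak
  expect_equal(tt$p[2], tt$p[3])                   # symmetry about center
  expect_true(all(tt$p > 0))
  # 10-residue toy helix against scalar evaluation
  i <- 1:10
  helix <- cbind(3 * cos(i), 3 * sin(i), i - 5.5)
  fr2 <- fit_gaussian_frame(helix)
  expect_equal(theoretical_profile(helix, fr2)$p,
               brute_theoretical(helix, fr2), tolerance = 1e-12)
})

test_that("Levitt weight has the right endpoints and is decreasing", {
  expect_equal(levitt_weight(0), 1)
  expect_equal(levitt_weight(9), 0)
  expect_equal(levitt_weight(12), 0)
  r <- seq(0, 9, by = 0.01)
  expect_true(all(diff(levitt_weight(r)) <= 1e-12))
})

test_that("the observed field reduces to self terms beyond the cutoff", {
  rec <- random_records(2, seed = 3)
  rec$aa3 <- c("LEU", "ALA"); rec <- assign_hydrophobicity(rec, hydro_scale())
  rec$x <- c(0, 50); rec$y <- 0; rec$z <- 0
  oo <- observed_profile(rec)
  expect_equal(oo$raw, rec$h)
  # identical residues almost coincident share the field symmetrically
  rec2 <- random_records(2, seed = 4)
  rec2$aa3 <- "LEU"; rec2 <- assign_hydrophobicity(rec2, hydro_scale())
  rec2$x <- c(0, 1e-6); rec2$y <- 0; rec2$z <- 0
  oo2 <- observed_profile(rec2)
  expect_equal(oo2$p, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the observed field equals the brute-force pair sum", {
  for (seed in 1:5) {
    rec <- random_records(12, seed = seed, spread = 5)
    expect_equal(observed_profile(rec)$p, brute_observed(rec),
                 tolerance = 1e-12)
    expect_equal(observed_profile(rec, include_self = FALSE)$p,
                 brute_observed(rec, include_self = FALSE),
                 tolerance = 1e-12)
  }
  rec$h <- NA_real_
  expect_error(observed_profile(rec), "not assigned")
})

test_that("KL divergence matches closed forms and hand summation", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  set.seed(9)
  p <- runif(20); p <- p / sum(p)
  q <- runif(20); q <- q / sum(q)
  expect_equal(kl_divergence(p, q), brute_kl(p, q), tolerance = 1e-14)
  expect_gte(kl_divergence(p, q), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "undefined")
})

test_that("RD hits its analytic endpoints", {
  base <- hydro_profile(random_records(30, seed = 2))
  expect_equal(rd(profile_with_O(base, base$raw_T))$rd, 0)
  expect_equal(rd(profile_with_O(base, rep(1 / 30, 30)))$rd, 1)
  res <- rd(base)
  expect_equal(res$rd, res$dkl_OT / (res$dkl_OT + res$dkl_OR))
  expect_true(res$rd >= 0 && res$rd <= 1)
})

test_that("fragment profiles restrict and renormalize the parent field", {
  parent <- hydro_profile(random_records(40, seed = 6))
  whole <- fragment_profile(parent, seq_len(40))
  expect_equal(whole$T, parent$T)
  expect_equal(whole$O, parent$O)
  expect_equal(rd(whole)$rd, rd(parent)$rd)
  # two disjoint fragments partition the parent's raw arrays exactly
  a <- fragment_profile(parent, 1:15)
  b <- fragment_profile(parent, 16:40)
  expect_equal(c(a$raw_T, b$raw_T), parent$raw_T)
  expect_equal(c(a$raw_O, b$raw_O), parent$raw_O)
  expect_equal(sum(a$T), 1, tolerance = 1e-12)
  expect_equal(a$R, rep(1 / 15, 15))
  expect_identical(a$frame, parent$frame)
  expect_error(fragment_profile(parent, integer(0)), "empty")
  sel <- unit_selection(ranges = "A:1-15")
  expect_error(fragment_profile(parent, sel), "part_of_parent")
})

test_that("residue elimination keeps the parent field and renormalizes", {
  parent <- hydro_profile(random_records(25, seed = 8))
  same <- eliminate_residues(parent, character(0))
  expect_equal(rd(same)$rd, rd(parent)$rd)
  cut <- eliminate_residues(parent, c("A:3", "A:17"))
  expect_equal(cut$n, 23L)
  expect_equal(cut$raw_T, parent$raw_T[-c(3, 17)])
  expect_equal(cut$R, rep(1 / 23, 23))
  expect_identical(cut$frame, parent$frame)
  expect_error(eliminate_residues(parent, "A:99"), "not found")
  expect_error(eliminate_residues(parent,
                                  paste0("A:", 1:25, collapse = ",")),
               "at least 2|empties")
})

test_that("profiles are normalized and invariant under rigid motions", {
  for (seed in 1:5) {
    rec <- generate_structure(synthetic_spec(n_residues = 60, seed = seed))
    prof <- hydro_profile(rec)
    expect_equal(sum(prof$T), 1, tolerance = 1e-9)
    expect_equal(sum(prof$O), 1, tolerance = 1e-9)
    expect_equal(sum(prof$R), 1, tolerance = 1e-9)
    moved <- transform_records(rec, random_rotation(), rnorm(3, sd = 20))
    expect_equal(rd(hydro_profile(moved))$rd, rd(prof)$rd,
                 tolerance = 1e-9)
  }
})
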