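test_that("dihedral_angle handles planar cis/trans and constructed twists", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, -1, 0)), 180)  # anti / trans
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 0)     # syn / cis
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 0, 1)), 90, tolerance = 1e-9)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 0, -1)), -90, tolerance = 1e-9)
  # degenerate: collinear triple
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
})

test_that("terminal residues have the expected undefined angles", {
  h <- build_helix("GCGC", single_strand = TRUE)
  tt <- compute_torsions(h)
  first <- tt[tt$key == "A:1", ]
  expect_false(first$defined[first$angle == "alpha"])
  expect_true(first$defined[first$angle == "beta"])
  last <- tt[tt$key == "A:4", ]
  expect_false(last$defined[last$angle == "epsilon"])
  expect_false(last$defined[last$angle == "zeta"])
  expect_true(last$defined[last$angle == "chi"])
})

test_that("removing O3' undefines delta and epsilon", {
  h <- build_helix("GCGC", single_strand = TRUE)
  m <- h
  m$atoms <- m$atoms[!(m$atoms$key == "A:2" & m$atoms$atom == "O3'"), ]
  tt <- compute_torsions(m)
  r2 <- tt[tt$key == "A:2", ]
  expect_false(r2$defined[r2$angle == "delta"])
  expect_false(r2$defined[r2$angle == "epsilon"])
  expect_true(r2$defined[r2$angle == "gamma"])
  # alpha of the NEXT residue needs this O3' too
  r3 <- tt[tt$key == "A:3", ]
  expect_false(r3$defined[r3$angle == "alpha"])
})

test_that("torsions agree with an independent implementation (bio3d)", {
  skip_if_not_installed("bio3d")
  h <- build_helix("GCAU", single_strand = TRUE)
  at <- h$atoms
  coords_of <- function(key, atom) {
    r <- at[at$key == key & at$atom == atom, ]
    c(r$x, r$y, r$z)
  }
  tt <- compute_torsions(h)
  val <- function(key, ang) tt$value[tt$key == key & tt$angle == ang]
  # independently specified quadruples, evaluated by bio3d::torsion.xyz
  quads <- list(
    list("A:2", "beta", rbind(coords_of("A:2", "P"), coords_of("A:2", "O5'"),
                              coords_of("A:2", "C5'"), coords_of("A:2", "C4'"))),
    list("A:2", "alpha", rbind(coords_of("A:1", "O3'"), coords_of("A:2", "P"),
                               coords_of("A:2", "O5'"), coords_of("A:2", "C5'"))),
    list("A:2", "delta", rbind(coords_of("A:2", "C5'"), coords_of("A:2", "C4'"),
                               coords_of("A:2", "C3'"), coords_of("A:2", "O3'"))),
    list("A:2", "zeta", rbind(coords_of("A:2", "C3'"), coords_of("A:2", "O3'"),
                              coords_of("A:3", "P"), coords_of("A:3", "O5'"))),
    list("A:3", "chi", rbind(coords_of("A:3", "O4'"), coords_of("A:3", "C1'"),
                             coords_of("A:3", "N9"), coords_of("A:3", "C4")))
  )
  for (q in quads) {
    oracle <- bio3d::torsion.xyz(as.numeric(t(q[[3]])), atm.inc = 4)
    expect_equal(circular_diff(val(q[[1]], q[[2]]), oracle), 0,
                 tolerance = 1e-6)
  }
})

test_that("circular_diff truth table", {
  expect_equal(circular_diff(350, 10), 20)
  expect_equal(circular_diff(0, 180), 180)
  expect_equal(circular_diff(-170, 170), 20)
  expect_equal(circular_diff(25, 25), 0)
  expect_equal(circular_diff(c(350, 0), c(10, 180)), c(20, 180))
})

test_that("mcq_global is zero on identity and exact on constant offsets", {
  h <- build_helix("GCGAUC")
  t0 <- compute_torsions(h)
  m0 <- mcq_global(t0, t0)
  expect_equal(m0$global_value, 0, tolerance = 1e-12)
  expect_equal(m0$skipped, 0)

  for (delta in c(25, 90, 179)) {
    shifted <- t0
    shifted$value <- shifted$value + delta
    expect_equal(mcq_global(t0, shifted)$global_value, delta,
                 tolerance = 1e-9)
    expect_equal(mcq_global(t0, shifted, method = "arithmetic")$global_value,
                 delta, tolerance = 1e-9)
  }
})

test_that("mcq_global matches the direct circular-mean formula", {
  # two slots with differences 10 and 30 degrees -> circular mean 20
  t1 <- tibble::tibble(key = c("A:1", "A:1"), angle = c("alpha", "beta"),
                       value = c(100, 50))
  t2 <- tibble::tibble(key = c("A:1", "A:1"), angle = c("alpha", "beta"),
                       value = c(110, 80))
  got <- mcq_global(t1, t2)
  oracle <- atan2(mean(sin(c(10, 30) * pi / 180)),
                  mean(cos(c(10, 30) * pi / 180))) * 180 / pi
  expect_equal(got$global_value, oracle, tolerance = 1e-9)
  expect_equal(got$global_value, 20, tolerance = 1e-6)
  expect_equal(got$angles_compared, 2)
})

test_that("mcq errors without comparable slots and counts one-sided slots", {
  t1 <- tibble::tibble(key = "A:1", angle = "alpha", value = 10)
  t2 <- tibble::tibble(key = "A:1", angle = "alpha", value = NA_real_)
  expect_error(mcq_global(t1, t2), "no comparable")
  t3 <- tibble::tibble(key = c("A:1", "A:2"), angle = "alpha",
                       value = c(10, NA))
  t4 <- tibble::tibble(key = c("A:1", "A:2"), angle = "alpha",
                       value = c(30, 50))
  got <- mcq_global(t3, t4)
  expect_equal(got$angles_compared, 1)
  expect_equal(got$skipped, 1)
})

test_that("mcq is symmetric and rigid-motion invariant", {
  h <- build_helix("GCGAUC")
  m <- perturb(h, perturb_noise(0.4, seed = 6))
  t_h <- compute_torsions(h)
  t_m <- compute_torsions(m)
  expect_equal(mcq_global(t_h, t_m)$global_value,
               mcq_global(t_m, t_h)$global_value, tolerance = 1e-9)
  moved <- transform_structure(m, random_rotation(), c(12, 3, -8))
  expect_equal(mcq_global(t_h, compute_torsions(moved))$global_value,
               mcq_global(t_h, t_m)$global_value, tolerance = 1e-6)
})

test_that("a single chi bond rotation shows up as exactly one local difference", {
  h <- build_helix("GCGAUC")
  m <- perturb(h, perturb_bond("A:3", "chi", 40))
  loc <- mcq_local(compute_torsions(h), compute_torsions(m))
  nz <- loc$diffs[loc$diffs$diff > 1e-6, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$key, "A:3")
  expect_equal(as.character(nz$angle), "chi")
  expect_equal(nz$diff, 40, tolerance = 1e-6)
})

test_that("identical tables give all-zero local differences", {
  h <- build_helix("GCG", single_strand = TRUE)
  tt <- compute_torsions(h)
  loc <- mcq_local(tt, tt)
  expect_true(all(loc$diffs$diff < 1e-12))
  expect_equal(nrow(loc$skipped), 0)
})

test_that("sugar pucker phase of the A-form templates is C3'-endo", {
  h <- build_helix("ACGU", single_strand = TRUE)
  tt <- compute_torsions(h)
  P <- tt$value[tt$angle == "P"]
  expect_true(all(P > 0 & P < 36))  # north / C3'-endo range
})
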