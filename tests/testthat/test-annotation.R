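res_atoms <- function(model, key) model$atoms[model$atoms$key == key, ]

test_that("base frames are planar on the ideal templates and flag missing rings", {
  h <- build_helix("G", single_strand = TRUE)
  at <- res_atoms(h, "A:1")
  f <- base_frame(at)
  expect_true(f$ok)
  ring <- at[at$atom %in% rnassess:::.ring_atoms$G, ]
  resid <- abs((cbind(ring$x, ring$y, ring$z) -
                  matrix(f$origin, nrow(ring), 3, byrow = TRUE)) %*% f$z)
  expect_lt(max(resid), 1e-2)  # templates are near-exactly planar

  broken <- at[at$atom != "N7", ]
  expect_false(base_frame(broken)$ok)
})

test_that("frames rotate with the structure", {
  h <- build_helix("AC", single_strand = TRUE)
  set.seed(7)
  R <- random_rotation()
  moved <- transform_structure(h, R, c(3, -2, 9))
  for (k in res_keys(h)) {
    f1 <- base_frame(res_atoms(h, k))
    f2 <- base_frame(res_atoms(moved, k))
    expect_equal(f2$z, as.numeric(R %*% f1$z), tolerance = 1e-9)
    expect_equal(f2$x, as.numeric(R %*% f1$x), tolerance = 1e-9)
    expect_equal(f2$origin, as.numeric(R %*% f1$origin + c(3, -2, 9)),
                 tolerance = 1e-9)
  }
})

test_that("ideal duplexes annotate with one canonical WC pair per position", {
  for (seq_ in c("GGGG", "GCGCAU")) {
    h <- build_helix(seq_)
    bp <- detect_base_pairs(h)
    n <- nchar(seq_)
    expect_equal(nrow(bp), n)
    expect_true(all(bp$canonical_wc))
    expect_true(all(bp$orientation == "cis"))
    expect_true(all(bp$edge_i == "W" & bp$edge_j == "W"))
    # each chain A residue pairs its antiparallel chain B partner
    expect_setequal(paste(bp$res_i, bp$res_j),
                    paste0("A:", 1:n, " B:", n:1))
  }
})

test_that("distant and misoriented bases are rejected", {
  h <- build_helix("GC")
  # two residues far apart: first of chain A, last of chain B in a long helix
  long <- build_helix("GGGGGGGGGGGG", single_strand = TRUE)
  bp <- detect_base_pairs(long)
  expect_false(any(bp$res_i == "A:1" & bp$res_j == "A:12"))

  # rotating one base ~90 deg about its in-plane x-axis violates coplanarity
  twisted <- perturb(h, perturb_bond("A:1", "chi", 0))  # copy
  at <- res_atoms(twisted, "A:1")
  f <- base_frame(at)
  sel <- twisted$atoms$key == "A:1" &
    twisted$atoms$atom %in% c(rnassess:::.ring_atoms$G, "O6", "N2")
  xyz <- cbind(twisted$atoms$x[sel], twisted$atoms$y[sel],
               twisted$atoms$z[sel])
  R <- rnassess:::rotation_about(f$x, 90)
  xyz <- sweep(sweep(xyz, 2, f$origin) %*% t(R), 2, f$origin, "+")
  twisted$atoms$x[sel] <- xyz[, 1]
  twisted$atoms$y[sel] <- xyz[, 2]
  twisted$atoms$z[sel] <- xyz[, 3]
  bp2 <- detect_base_pairs(twisted)
  expect_false(any(bp2$res_i == "A:1"))
})

test_that("intra-chain neighbours stack but never base-pair", {
  single <- build_helix("AAAA", single_strand = TRUE)
  ints <- interactions_of(single)
  expect_equal(nrow(ints$pairs), 0)
  expect_equal(nrow(ints$stacks), 3)
  expect_setequal(paste(ints$stacks$res_i, ints$stacks$res_j),
                  c("A:1 A:2", "A:2 A:3", "A:3 A:4"))
})

test_that("perpendicular base planes at short range are not stacked", {
  h <- build_helix("GC", single_strand = TRUE)
  tilted <- h
  f <- base_frame(res_atoms(h, "A:2"))
  sel <- tilted$atoms$key == "A:2"
  xyz <- cbind(tilted$atoms$x[sel], tilted$atoms$y[sel], tilted$atoms$z[sel])
  R <- rnassess:::rotation_about(f$x, 90)
  xyz <- sweep(sweep(xyz, 2, f$origin) %*% t(R), 2, f$origin, "+")
  tilted$atoms$x[sel] <- xyz[, 1]
  tilted$atoms$y[sel] <- xyz[, 2]
  tilted$atoms$z[sel] <- xyz[, 3]
  expect_equal(nrow(detect_stacking(tilted)), 0)
})

test_that("the 4-bp duplex interaction set matches its construction", {
  h <- build_helix("GGGG")
  ints <- interactions_of(h)
  expect_equal(nrow(ints$pairs), 4)
  expect_true(all(ints$pairs$canonical_wc))
  expect_gte(nrow(ints$stacks), 6)
  expect_length(ints$skipped, 0)

  # single nucleotide: empty set; repeated runs identical
  single <- build_helix("G", single_strand = TRUE)
  ints1 <- interactions_of(single)
  expect_equal(nrow(ints1$pairs) + nrow(ints1$stacks), 0)
  expect_identical(interactions_of(h)$pairs, ints$pairs)
  expect_identical(interactions_of(h)$stacks, ints$stacks)
})

test_that("annotation is invariant under global rigid motion", {
  h <- build_helix("GCGCAU")
  ints <- interactions_of(h)
  set.seed(13)
  for (i in 1:3) {
    moved <- transform_structure(h, random_rotation(), rnorm(3, sd = 30))
    mi <- interactions_of(moved)
    expect_equal(mi$pairs, ints$pairs)
    expect_equal(mi$stacks, ints$stacks)
  }
})

test_that("canonical flag implies cis Watson-Crick on both edges", {
  h <- build_helix("GCGUAUGC")
  noisy <- perturb(h, perturb_noise(0.3, seed = 2))
  for (m in list(h, noisy)) {
    bp <- detect_base_pairs(m)
    canon <- bp[bp$canonical_wc, ]
    expect_true(all(canon$orientation == "cis"))
    expect_true(all(canon$edge_i == "W" & canon$edge_j == "W"))
  }
})

test_that("GU wobble counts as canonical Watson-Crick unless switched off", {
  gu <- make_face_pair("G", "U")
  bp <- detect_base_pairs(gu)
  expect_equal(nrow(bp), 1)
  expect_true(bp$canonical_wc)
  bp_strict <- detect_base_pairs(gu, wobble_as_wc = FALSE)
  expect_false(bp_strict$canonical_wc)
  # still a pair, just categorised as non-canonical
  expect_equal(nrow(bp_strict), 1)
})
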