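# minimal hand-built interaction sets and correspondences for count tests
fake_interactions <- function(pairs = NULL, stacks = NULL, label = "fake") {
  empty_p <- tibble::tibble(res_i = character(0), res_j = character(0),
                            base_i = character(0), base_j = character(0),
                            edge_i = character(0), edge_j = character(0),
                            orientation = character(0),
                            canonical_wc = logical(0))
  empty_s <- tibble::tibble(res_i = character(0), res_j = character(0))
  if (!is.null(pairs)) {
    pairs <- tibble::tibble(res_i = pairs[, 1], res_j = pairs[, 2],
                            base_i = "G", base_j = "C", edge_i = "W",
                            edge_j = "W", orientation = "cis",
                            canonical_wc = TRUE)
  } else pairs <- empty_p
  stacks <- if (is.null(stacks)) empty_s else
    tibble::tibble(res_i = stacks[, 1], res_j = stacks[, 2])
  structure(list(pairs = pairs, stacks = stacks, skipped = character(0),
                 source_label = label), class = "rna_interactions")
}

fake_correspondence <- function(keys) {
  structure(list(pairs = tibble::tibble(ref_key = keys, mod_key = keys,
                                        ref_base = "G", mod_base = "G"),
                 unmatched_reference = character(0),
                 unmatched_model = character(0), mode = "by-index"),
            class = "rna_correspondence")
}

test_that("interaction matching reproduces hand-enumerated counts", {
  keys <- paste0("A:", 1:12)
  co <- fake_correspondence(keys)
  ref <- fake_interactions(rbind(c("A:1", "A:2"), c("A:3", "A:4"),
                                 c("A:5", "A:6"), c("A:7", "A:8")))
  mod <- fake_interactions(rbind(c("A:1", "A:2"), c("A:3", "A:4"),
                                 c("A:9", "A:10")))
  counts <- match_interactions(ref, mod, co)
  wc <- counts[counts$category == "wc", ]
  expect_equal(c(wc$tp, wc$fp, wc$fn), c(2, 1, 2))

  # identical sets: perfect
  counts2 <- match_interactions(ref, ref, co)
  expect_equal(counts2$fp, rep(0L, 4))
  expect_equal(counts2$fn, rep(0L, 4))
  expect_equal(counts2$tp[counts2$category == "wc"], 4)

  # empty model: all reference interactions are missed
  counts3 <- match_interactions(ref, fake_interactions(), co)
  expect_equal(counts3$tp, rep(0L, 4))
  expect_equal(counts3$fn[counts3$category == "wc"], 4)
})

test_that("interactions with unmatched residues count as FP/FN", {
  co <- fake_correspondence(paste0("A:", 1:4))
  ref <- fake_interactions(rbind(c("A:1", "A:2"), c("A:3", "A:9"))) # A:9 unmatched
  mod <- fake_interactions(rbind(c("A:1", "A:2"), c("A:4", "A:77")))
  counts <- match_interactions(ref, mod, co)
  wc <- counts[counts$category == "wc", ]
  expect_equal(c(wc$tp, wc$fp, wc$fn), c(1, 1, 1))
})

test_that("inf_score matches the closed form and its edge cases", {
  expect_equal(inf_score(4, 0, 0), 1.0)
  expect_equal(inf_score(2, 1, 2), sqrt((2 / 3) * (1 / 2)), tolerance = 1e-4)
  expect_equal(inf_score(2, 1, 2), 0.5774, tolerance = 1e-4)
  expect_equal(inf_score(0, 5, 3), 0)
  expect_true(is.na(inf_score(0, 0, 0)))  # empty reference -> undefined
  expect_true(is.na(inf_score(0, 4, 0)))  # FP only, nothing to recover
  expect_error(inf_score(-1, 0, 0), "negative")
  # vectorised
  expect_equal(inf_score(c(4, 0), c(0, 5), c(0, 3)), c(1, 0))
})

test_that("deformation index is rmsd / inf with NA propagation", {
  expect_equal(deformation_index(10, 1), 10)
  expect_equal(deformation_index(12, 0.5), 24)
  expect_true(is.na(deformation_index(12, 0)))
  expect_true(is.na(deformation_index(12, NA)))
  # DI >= RMSD whenever INF <= 1
  set.seed(2)
  infs <- runif(20)
  expect_true(all(deformation_index(5, infs) >= 5))
})

test_that("deformation profile is zero for identical and rigidly moved copies", {
  h <- fixture_duplex()
  co <- identity_correspondence(h)
  dp0 <- deformation_profile(h, h, co)
  expect_equal(max(dp0$values), 0, tolerance = 1e-9)
  moved <- transform_structure(h, random_rotation(), c(10, -4, 2))
  dp1 <- deformation_profile(h, moved, co)
  expect_equal(max(dp1$values), 0, tolerance = 1e-9)
  expect_equal(dim(dp0$values), rep(length(res_keys(h)), 2))
})

test_that("a single displaced residue appears only in its own DP column", {
  h <- fixture_duplex()
  co <- identity_correspondence(h)
  m <- h
  sel <- m$atoms$key == "A:5"
  m$atoms$x[sel] <- m$atoms$x[sel] + 3
  dp <- deformation_profile(h, m, co)
  keys <- res_keys(h)
  others <- setdiff(keys, "A:5")
  for (anchor in c("A:1", "B:3", "A:9")) {
    expect_equal(dp$values[anchor, "A:5"], 3.0, tolerance = 1e-6)
    expect_lt(max(dp$values[anchor, setdiff(others, anchor)]), 1e-6)
  }
  # anchored on the displaced residue itself, everything else is ~3 away
  expect_equal(mean(dp$values["A:5", others]), 3.0, tolerance = 1e-6)
})

test_that("DP is invariant under rigid motion of either structure", {
  h <- build_helix("GCGAUC")
  co <- identity_correspondence(h)
  m <- perturb(h, perturb_noise(0.5, seed = 9))
  dp <- deformation_profile(h, m, co)
  set.seed(21)
  moved_m <- transform_structure(m, random_rotation(), rnorm(3, sd = 15))
  moved_h <- transform_structure(h, random_rotation(), rnorm(3, sd = 15))
  expect_equal(deformation_profile(h, moved_m, co)$values, dp$values,
               tolerance = 1e-8)
  expect_equal(deformation_profile(moved_h, m, co)$values, dp$values,
               tolerance = 1e-8)
})

test_that("domain summaries aggregate min/mean/max over blocks", {
  h <- fixture_duplex()
  co <- identity_correspondence(h)
  m <- h
  sel <- m$atoms$key == "A:9"
  m$atoms$y[sel] <- m$atoms$y[sel] + 2
  domains <- tibble::tibble(name = c("five_prime", "three_prime"),
                            chain = "A", start = c(1, 6), end = c(5, 10))
  dp <- deformation_profile(h, m, co, domains = domains)
  ds <- dp$domain_summaries
  expect_setequal(ds$domain, c("(all)", "five_prime", "three_prime"))
  five <- ds[ds$domain == "five_prime", ]
  expect_equal(five$max, 0, tolerance = 1e-9)   # displacement outside block
  three <- ds[ds$domain == "three_prime", ]
  expect_gt(three$max, 1.9)
  expect_warning(
    deformation_profile(h, m, co, domains = tibble::tibble(
      name = c("a", "b"), chain = "A", start = c(1, 3), end = c(5, 8))),
    "overlapping")
})

test_that("inf_breakdown on a noisy decoy stays consistent with its counts", {
  h <- fixture_duplex()
  m <- perturb(h, perturb_noise(0.1, seed = 4))
  co <- identity_correspondence(h)
  br <- inf_breakdown(h, m, co)
  expect_equal(br$inf[br$category == "wc"], 1)  # sigma 0.1 keeps the helix
  expect_true(all(br$inf[!is.na(br$inf)] >= 0 & br$inf[!is.na(br$inf)] <= 1))
  # pooled counts are the category sums
  expect_equal(br$tp[br$category == "all"],
               sum(br$tp[br$category != "all"]))
})
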