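test_that("self-docking the template onto its own UBA is exact", {
  tmpl <- make_template_complex(seed = 51)
  at <- tmpl$structure$atoms
  uba <- structure3d(at[at$chain == "T", ])
  units <- decompose_overlapping_ubas(tmpl$helices)
  model <- dock_ubiquitins(uba, units, tmpl)
  expect_equal(nrow(model$placements), 1)
  expect_equal(model$placements$rmsd, 0, tolerance = 1e-9)
  placed <- model$structure$atoms[model$structure$atoms$chain == "U1", ]
  orig <- at[at$chain == "U", ]
  expect_equal(as.matrix(placed[, c("x", "y", "z")]),
               as.matrix(orig[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("three ubiquitins dock on the three-unit solenoid without clashes", {
  fx <- fixture_docked_model()
  expect_equal(nrow(fx$model$placements), 3)
  expect_equal(fx$model$placements$chain, c("U1", "U2", "U3"))
  expect_true(all(fx$model$placements$rmsd < 1.0))
  cl <- detect_clashes(fx$model, cutoff = 2.4)
  expect_equal(nrow(cl$contacts), 0)
  # transforms are proper rotations
  for (tf in fx$model$transforms)
    expect_equal(det(tf$R), 1, tolerance = 1e-9)
})

test_that("units with too-short helices are rejected by name", {
  tmpl <- make_template_complex(seed = 52)
  at <- tmpl$structure$atoms
  uba <- structure3d(at[at$chain == "T", ])
  hel <- tmpl$helices
  hel$end[2] <- hel$start[2] + 1  # 2-residue helix
  units <- decompose_overlapping_ubas(hel)
  expect_error(dock_ubiquitins(uba, units, tmpl), "unit 1.*helix 2")
})

test_that("docking is equivariant under rigid motion of the receptor", {
  fx <- fixture_docked_model()
  tf <- rigid_transform(matrix(c(0, -1, 0, 0, 0, -1, 1, 0, 0), 3, 3,
                               byrow = TRUE), c(13, -6, 21))
  moved <- dock_ubiquitins(apply_transform(fx$sol$structure, tf),
                           fx$units, fx$template)
  back <- apply_transform(moved$structure, invert_transform(tf))
  ub_chains <- c("U1", "U2", "U3")
  i <- back$atoms$chain %in% ub_chains
  j <- fx$model$structure$atoms$chain %in% ub_chains
  expect_equal(as.matrix(back$atoms[i, c("x", "y", "z")]),
               as.matrix(fx$model$structure$atoms[j, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("distant chains report no clashes; superposed chains report all atoms", {
  ub <- make_ub_like_domain(seed = 53)
  far <- ub
  far$atoms$chain <- "V"
  far$atoms$x <- far$atoms$x + 80
  s <- structure3d(rbind(ub$atoms, far$atoms))
  expect_equal(nrow(detect_clashes(s, cutoff = 2.4)$contacts), 0)

  dup <- ub
  dup$atoms$chain <- "V"
  s2 <- structure3d(rbind(ub$atoms, dup$atoms))
  n_heavy <- sum(toupper(ub$atoms$element) != "H")
  cl_tight <- detect_clashes(s2, cutoff = 0.5)
  expect_gte(nrow(cl_tight$contacts), n_heavy)  # every atom hits its twin
  expect_equal(nrow(cl_tight$contacts), brute_clash_count(s2, "U", "V", 0.5))
  expect_gte(nrow(detect_clashes(s2, cutoff = 2.4)$contacts), n_heavy)
})

test_that("clash counts equal the all-pairs brute-force oracle", {
  ub <- make_ub_like_domain(seed = 54)
  other <- make_ub_like_domain(seed = 55)
  other$atoms$chain <- "V"
  set.seed(56)
  ang <- runif(1, 0, 2 * pi)
  tf <- rigid_transform(matrix(c(cos(ang), -sin(ang), 0,
                                 sin(ang), cos(ang), 0, 0, 0, 1),
                               3, 3, byrow = TRUE), runif(3, -4, 4))
  other <- apply_transform(other, tf)
  s <- structure3d(rbind(ub$atoms, other$atoms))
  for (cutoff in c(2.4, 5)) {
    cl <- detect_clashes(s, cutoff = cutoff)
    expect_equal(nrow(cl$contacts), brute_clash_count(s, "U", "V", cutoff))
  }
})

test_that("clash reports are invariant under relabeling and rigid motion", {
  ub <- make_ub_like_domain(seed = 57)
  other <- make_ub_like_domain(seed = 58)
  other$atoms$chain <- "V"
  other$atoms$x <- other$atoms$x + 6
  s <- structure3d(rbind(ub$atoms, other$atoms))
  n0 <- nrow(detect_clashes(s, cutoff = 3)$contacts)
  # swap chain labels
  swapped <- s
  swapped$atoms$chain <- ifelse(s$atoms$chain == "U", "V", "U")
  expect_equal(nrow(detect_clashes(swapped, cutoff = 3)$contacts), n0)
  # global rigid motion
  tf <- rigid_transform(matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3,
                               byrow = TRUE), c(-9, 2, 14))
  expect_equal(nrow(detect_clashes(apply_transform(s, tf),
                                   cutoff = 3)$contacts), n0)
})

test_that("the footprint exclusion removes only the modelled interface", {
  fx <- fixture_docked_model()
  with_fp <- detect_clashes(fx$model, cutoff = 4.5, exclude_footprint = TRUE)
  without <- detect_clashes(fx$model, cutoff = 4.5, exclude_footprint = FALSE)
  expect_gte(nrow(without$contacts), nrow(with_fp$contacts))
  dropped <- setdiff(
    do.call(paste, without$contacts[, c("chain1", "resno1", "chain2", "resno2")]),
    do.call(paste, with_fp$contacts[, c("chain1", "resno1", "chain2", "resno2")]))
  # every dropped contact involves a footprint residue of the matching copy
  for (key in dropped) {
    f <- strsplit(key, " ")[[1]]
    copy <- if (grepl("^U", f[3])) f[3] else f[1]
    rec_res <- as.integer(if (grepl("^U", f[3])) f[2] else f[4])
    expect_true(rec_res %in% fx$model$footprints[[copy]]$resno)
  }
})

test_that("linkage geometry uses the minimum over both directions", {
  m <- fake_linkage_pair(4)
  res <- assess_linkage(m, "K48", threshold = 9)
  expect_equal(res$distance, 4)
  expect_true(res$feasible)
  far <- assess_linkage(fake_linkage_pair(50), "K48", threshold = 9)
  expect_false(far$feasible)
  # boundary: exactly at the threshold is feasible
  at <- assess_linkage(fake_linkage_pair(9), "K48", threshold = 9)
  expect_true(at$feasible)
  # symmetric under swapping which copy donates the lysine
  m2 <- fake_linkage_pair(4)
  m2$structure$atoms$chain <- ifelse(m2$structure$atoms$chain == "U1",
                                     "U2", "U1")
  expect_equal(assess_linkage(m2, "K48", 9)$distance, 4)
})

test_that("K48/K63 linkage of adjacent docked ubiquitins is infeasible", {
  fx <- fixture_docked_model()
  for (lk in c("K48", "K63")) {
    res <- assess_linkage(fx$model, lk, threshold = 9)
    expect_equal(nrow(res), 2)  # adjacent pairs only
    expect_false(any(res$feasible))
    expect_true(all(res$distance > 0))
  }
})

test_that("linkage assessment errors on missing atoms and single copies", {
  m <- fake_linkage_pair(4)
  m$structure$atoms <- m$structure$atoms[m$structure$atoms$elety != "NZ" |
                                           m$structure$atoms$chain != "U2", ]
  expect_error(assess_linkage(m, "K48", 9), "missing atom NZ.*U2")
  single <- fake_linkage_pair(4)
  single$placements <- single$placements[1, ]
  expect_error(assess_linkage(single, "K48", 9), "at least 2")
})

test_that("template complexes validate their chains and helix count", {
  tmpl <- make_template_complex(seed = 59)
  expect_equal(nrow(tmpl$helices), 3)
  expect_error(template_complex(tmpl$structure, "T", "Z", tmpl$helices),
               "chain")
  expect_error(template_complex(tmpl$structure, "T", "U",
                                tmpl$helices[1:2, ]), "exactly 3")
})
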