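xyl <- make_sugar("xylose_4C1")
tet <- make_sugar("xylotetraose")

test_that("the dimensionality counter reproduces the search-space sizes", {
  expect_equal(count_dimensions(xyl, hydroxyls = TRUE,
                                ring_mode = "reduced"), 6L)
  expect_equal(count_dimensions(tet, hydroxyls = TRUE, glycosidic = TRUE,
                                ring_mode = "none"), 16L)
  expect_equal(count_dimensions(tet, hydroxyls = TRUE, glycosidic = TRUE,
                                ring_mode = "reduced"), 24L)
  expect_equal(count_dimensions(xyl, hydroxyls = TRUE,
                                ring_mode = "full"), 10L)
  expect_equal(count_dimensions(xyl, hydroxyls = FALSE,
                                ring_mode = "none"), 0L)
  # additivity over the option terms
  for (sug in list(xyl, tet)) {
    total <- count_dimensions(sug, TRUE, TRUE, "reduced")
    parts <- count_dimensions(sug, TRUE, FALSE, "none") +
      count_dimensions(sug, FALSE, TRUE, "none") +
      count_dimensions(sug, FALSE, FALSE, "reduced")
    expect_equal(total, parts)
  }
  expect_error(count_dimensions(list(hydroxyls = list())), "annotations")
})

test_that("dihedral realization hits targets and leaves bond lengths alone", {
  sp <- conformer_space(xyl, hydroxyls = TRUE, glycosidic = FALSE,
                        ring_mode = "reduced")
  expect_equal(space_dim(sp), 6L)
  x0 <- space_current_x(xyl, sp)
  # identity: realizing the current values reproduces the template
  r0 <- realize_conformer(xyl, sp, x0)
  expect_true(r0$ok)
  expect_lt(max(abs(r0$structure$positions - xyl$structure$positions)),
            1e-9)
  # full turn of one hydroxyl is the identity
  x1 <- x0; x1[1] <- x1[1] + 360
  r1 <- realize_conformer(xyl, sp, x1)
  expect_lt(kabsch_rmsd(r1$structure, xyl$structure), 1e-9)
  # dihedral oracle: measured value equals the requested target
  b <- bond_list(xyl$structure)
  lens0 <- vapply(seq_len(nrow(b)), function(k)
    vnorm_test(xyl$structure$positions[b[k, 1], ] -
               xyl$structure$positions[b[k, 2], ]), numeric(1))
  for (target in c(60, -45, 170)) {
    x2 <- x0; x2[2] <- target
    r2 <- realize_conformer(xyl, sp, x2)
    expect_equal(structure_dihedral(r2$structure, sp$specs[[2]]$atoms),
                 target, tolerance = 1e-6)
    lens <- vapply(seq_len(nrow(b)), function(k)
      vnorm_test(r2$structure$positions[b[k, 1], ] -
                 r2$structure$positions[b[k, 2], ]), numeric(1))
    expect_lt(max(abs(lens - lens0)), 1e-6)
  }
})

test_that("the reduced ring flip interconverts the two chairs", {
  sp <- conformer_space(xyl, hydroxyls = TRUE, glycosidic = FALSE,
                        ring_mode = "reduced")
  x0 <- space_current_x(xyl, sp)
  xf <- x0; xf[5] <- -x0[5]; xf[6] <- -x0[6]
  rf <- realize_conformer(xyl, sp, xf)
  expect_true(rf$ok)
  expect_equal(structure_dihedral(rf$structure, sp$specs[[5]]$atoms),
               xf[5], tolerance = 1e-3)
  # flipped ring coincides with the packaged 1C4 chair ring
  c14 <- make_sugar("xylose_1C4")
  expect_lt(kabsch(rf$structure$positions[1:6, ],
                   c14$structure$positions[1:6, ])$rmsd, 1e-5)
  # bond lengths preserved through the rebuild
  b <- bond_list(xyl$structure)
  dev <- vapply(seq_len(nrow(b)), function(k) {
    abs(vnorm_test(rf$structure$positions[b[k, 1], ] -
                   rf$structure$positions[b[k, 2], ]) -
        vnorm_test(xyl$structure$positions[b[k, 1], ] -
                   xyl$structure$positions[b[k, 2], ]))
  }, numeric(1))
  expect_lt(max(dev), 1e-6)
  # intermediate ring coordinate still closes the ring
  xh <- x0; xh[5] <- 0; xh[6] <- 0
  rh <- realize_conformer(xyl, sp, xh)
  expect_true(rh$ok)
  ring <- rh$structure$positions[1:6, ]
  expect_equal(vnorm_test(ring[6, ] - ring[1, ]),
               vnorm_test(xyl$structure$positions[6, ] -
                          xyl$structure$positions[1, ]),
               tolerance = 1e-3)
})

test_that("rigid adsorption placement preserves internal geometry exactly", {
  slab <- small_slab()
  sp <- adsorption_space(slab)
  conf <- xyl$structure
  d0 <- as.matrix(dist(conf$positions))
  set.seed(3)
  for (rep in 1:5) {
    x <- c(runif(1, 0, 2.5), runif(1, 0, 4.4), runif(1, 3, 12),
           runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360))
    sys <- realize_adsorption(conf, slab, sp, x)
    ads <- sys$positions[sys$tags == "adsorbate", ]
    expect_lt(max(abs(as.matrix(dist(ads)) - d0)), 1e-9)
  }
  # unrotated placement: center exactly at the requested height
  sys <- realize_adsorption(conf, slab, sp, c(0, 0, 5, 0, 0, 0))
  ctr <- geometric_center(sys, tags = "adsorbate")
  expect_equal(ctr[[3]] - top_layer_z(sys), 5, tolerance = 1e-9)
  expect_equal(ctr[[1]], 0, tolerance = 1e-9)
  # full azimuthal turn is the identity
  s1 <- realize_adsorption(conf, slab, sp, c(1, 2, 5, 10, 20, 30))
  s2 <- realize_adsorption(conf, slab, sp, c(1, 2, 5, 10, 20, 390))
  expect_lt(max(abs(s1$positions - s2$positions)), 1e-9)
})

test_that("search-space bounds, wrapping and periodicity behave", {
  slab <- small_slab()
  sp <- adsorption_space(slab)
  expect_equal(space_dim(sp), 6L)
  expect_equal(sp$vars$tag[1:3],
               c("translation_x", "translation_y", "translation_z"))
  x <- space_wrap(sp, c(-0.5, 10, 20, 361, 200, -10))
  expect_true(all(x >= sp$vars$lower & x <= sp$vars$upper))
  expect_equal(x[4], 1)      # periodic wrap
  expect_equal(x[3], 12)     # clipped to bound
  expect_equal(x[5], 180)    # clipped, non-periodic
  # periodic delta takes the short way round
  d <- space_delta(sp, c(0, 0, 3, 350, 0, 0), c(0, 0, 3, 10, 0, 0))
  expect_equal(d[4], -20)
  expect_error(search_space_new("a", 1, 1, FALSE, "dihedral"), "bounds")
})
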