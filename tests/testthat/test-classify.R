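test_that("annotations validate interval ordering and UCS placement", {
  expect_error(attc_annotation(c(5, 1), c(10, 14), c(20, 24), c(30, 34),
                               c(40, 44)), "interval")
  expect_error(attc_annotation(c(1, 12), c(10, 14), c(20, 24), c(30, 34),
                               c(40, 44)), "ordered")
  expect_error(attc_annotation(c(1, 5), c(10, 14), c(20, 24), c(30, 34),
                               c(40, 44), ucs = 22), "between")
  ann <- attc_annotation(c(1, 5), c(10, 14), c(20, 24), c(30, 34),
                         c(40, 44), ucs = c(7, 36))
  expect_s3_class(ann, "attc_annotation")
  # JSON sidecar round trip
  path <- file.path(tempdir(), "ann.json")
  write_attc_annotation(ann, path)
  expect_equal(read_attc_annotation(path), ann)
})

test_that("the five-group decision table classifies designed fixtures", {
  site <- fixture_site()
  straight <- hairpin_structure(site$sequence, fixture_straight_pairs(site))
  kinked <- hairpin_structure(site$sequence, fixture_kinked_pairs(site))
  bx <- site$boxes

  expect_equal(as.character(classify_conformation(straight, bx)),
               "straight_complete")
  expect_equal(as.character(classify_conformation(kinked, bx)),
               "kinked_complete")

  # a bubble inside the L helix: straight but incomplete, flagged bubble
  mid_L <- bx$L_outer[1] + 5:6
  bubble <- hairpin_structure(site$sequence,
                              drop_pairs(fixture_straight_pairs(site), mid_L))
  cls <- classify_conformation(bubble, bx)
  expect_equal(as.character(cls), "straight_incomplete")
  expect_true(attr(cls, "bubble"))

  # out-of-register with an opened L-box position: kinked incomplete
  ki <- hairpin_structure(site$sequence,
                          drop_pairs(fixture_kinked_pairs(site),
                                     bx$L_outer[1] + 4))
  expect_equal(as.character(classify_conformation(ki, bx)),
               "kinked_incomplete")

  # unpaired R box: other, regardless of the L arm
  other <- hairpin_structure(site$sequence,
                             drop_pairs(fixture_straight_pairs(site),
                                        iv_seq_(bx$R_outer)))
  expect_equal(as.character(classify_conformation(other, bx)), "other")

  # straight and register-shifted variants differ only in straight/kinked
  expect_equal(sub("straight", "kinked",
                   as.character(classify_conformation(straight, bx))),
               as.character(classify_conformation(kinked, bx)))
})

test_that("classification is total over folded ensembles", {
  site <- generate_attc_like_site(seed = 55, verify = FALSE)
  classes <- c("straight_complete", "straight_incomplete",
               "kinked_complete", "kinked_incomplete", "other")
  for (st in subopt_window(site$sequence, window_fraction = 0.25)) {
    cls <- classify_conformation(st, site$boxes)
    expect_true(as.character(cls) %in% classes)
  }
  expect_error(classify_conformation(
    hairpin_structure("GGGAAACCC", c(9, 8, 7, 0, 0, 0, 3, 2, 1)),
    site$boxes), "beyond")
})

test_that("the apical intermediate size counts the stem above the UCS", {
  site <- fixture_site()
  straight <- hairpin_structure(site$sequence, fixture_straight_pairs(site))
  # designed apical arm: L helix (14 bp) + VTS (7 nt) + L helix = 35 nt
  expect_equal(intermediate_size(straight, site$boxes), 35L)
  expect_equal(expected_intermediate_delta_L(straight, site$boxes), 23.8)

  f28 <- fixture_28nt_site()
  expect_equal(intermediate_size(f28$structure, f28$boxes), 28L)
  expect_equal(expected_intermediate_delta_L(f28$structure, f28$boxes),
               19.04)

  # a single apical pair spanning five nucleotides
  lone <- f28$structure
  pv <- integer(nchar(lone$sequence))
  pv[12] <- 16; pv[16] <- 12
  lone5 <- hairpin_structure(lone$sequence, pv)
  expect_equal(intermediate_size(lone5, f28$boxes), 5L)

  # no pairs above the UCS: undefined
  empty <- hairpin_structure(lone$sequence,
                             integer(nchar(lone$sequence)))
  expect_error(intermediate_size(empty, f28$boxes), "apical")
})

test_that("Boltzmann occupancies reproduce the printed two-state splits", {
  # bottom strand: straight favoured by 0.8 kJ/mol
  bs <- boltzmann_occupancy(c(-97.9, -97.1), c("straight", "kinked"))
  p <- bs$by_class$probability
  names(p) <- bs$by_class$class
  expect_equal(round(100 * p[["straight"]]), 58)
  expect_equal(round(100 * p[["kinked"]]), 42)
  # top strand: kinked favoured by 0.6 kJ/mol
  ts <- boltzmann_occupancy(c(-88.1, -88.7), c("straight", "kinked"))
  q <- ts$by_class$probability
  names(q) <- ts$by_class$class
  expect_equal(round(100 * q[["kinked"]]), 56)
  expect_equal(round(100 * q[["straight"]]), 44)
})

test_that("occupancies normalise, shift-invariantly and monotonically", {
  en <- c(-40, -42, -39.5, -41)
  occ <- boltzmann_occupancy(en)
  expect_equal(sum(occ$structures$probability), 1, tolerance = 1e-9)
  shifted <- boltzmann_occupancy(en + 100)
  expect_equal(occ$structures$probability, shifted$structures$probability,
               tolerance = 1e-12)
  expect_true(all(diff(occ$structures$probability[order(en,
                                                        decreasing = TRUE)]) >= 0))
  # equal energies share the ensemble evenly
  eq <- boltzmann_occupancy(rep(-10, 5))
  expect_equal(eq$structures$probability, rep(0.2, 5))
  expect_error(boltzmann_occupancy(numeric(0)), "at least one")
  expect_error(boltzmann_occupancy(c(-1, Inf)), "finite")
  # extreme energy gaps do not overflow
  big <- boltzmann_occupancy(c(-5000, -1))
  expect_equal(big$structures$probability[1], 1)
})

test_that("ensemble classification combines folding, classes and weights", {
  site <- fixture_site()
  straight <- hairpin_structure(site$sequence, fixture_straight_pairs(site),
                                free_energy = -97.9)
  kinked <- hairpin_structure(site$sequence, fixture_kinked_pairs(site),
                              free_energy = -97.1)
  occ <- classify_ensemble(list(straight, kinked), site$boxes)
  p <- occ$by_class$probability
  names(p) <- occ$by_class$class
  expect_equal(round(100 * p[["straight_complete"]]), 58)
  expect_equal(round(100 * p[["kinked_complete"]]), 42)
  expect_s3_class(autoplot(occ), "ggplot")
  gl <- glance(occ)
  expect_equal(gl$temperature_K, 298.15)
})
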