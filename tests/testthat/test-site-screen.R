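test_that("reverse complement is a valid involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  set.seed(61)
  for (rep in 1:20) {
    sq <- random_dna(sample(5:60, 1))
    expect_equal(reverse_complement(reverse_complement(sq)), sq)
  }
  expect_error(reverse_complement("ACGU"), "invalid base")
})

test_that("a perfect-stem site is fully straight on both strands", {
  # strong uninterrupted stem: the 5% window holds only the full fold
  stem <- "GCGGCCGCAGGCCGGATCCGCG"
  sq <- paste0(stem, "TTTAT", reverse_complement(stem))
  n <- nchar(sq)
  boxes <- attc_annotation(R_outer = c(1, 10), L_outer = c(11, 22),
                           vts = c(23, 27), L_inner = c(28, 39),
                           R_inner = c(40, n))
  scr <- screen_sites(c(perfect = sq), list(perfect = boxes))
  expect_equal(nrow(scr$sites), 2)
  expect_equal(scr$sites$p_straight_canonical, c(1, 1))
  expect_false(any(scr$sites$unfoldable))
})

test_that("straight-biased bottom strands beat their top strands", {
  sc <- generate_site_cohort(5, seed = 700)
  scr <- screen_sites(sc$sequences, sc$annotations)
  sm <- glance(scr)
  expect_equal(sort(sm$strand), c("bottom", "top"))
  expect_gt(sm$mean_p_straight[sm$strand == "bottom"],
            sm$mean_p_straight[sm$strand == "top"])
  # screening is deterministic and order-invariant
  scr2 <- screen_sites(rev(sc$sequences), sc$annotations)
  expect_equal(glance(scr2), sm)
  expect_equal(tidy(scr2), tidy(scr))
})

test_that("per-site screen probabilities match direct computation", {
  site <- generate_attc_like_site(seed = 77)
  scr <- screen_sites(c(x = site$sequence), list(x = site$boxes),
                      both_strands = FALSE)
  ens <- subopt_window(site$sequence)
  occ <- classify_ensemble(ens, site$boxes)
  straight <- sum(occ$by_class$probability[occ$by_class$class %in%
                                             c("straight_complete",
                                               "straight_incomplete")])
  expect_equal(scr$sites$p_straight_canonical, straight, tolerance = 1e-12)
  expect_equal(scr$sites$n_structures, length(ens))
})

test_that("unannotated and unfoldable sites are handled gracefully", {
  site <- generate_attc_like_site(seed = 78, verify = FALSE)
  floppy <- strrep("A", 60)
  boxes_f <- attc_annotation(c(1, 8), c(12, 20), c(25, 30), c(35, 43),
                             c(47, 55), ucs = 10)
  expect_warning(
    scr <- screen_sites(c(a = site$sequence, b = site$sequence,
                          c = floppy),
                        list(a = site$boxes, c = boxes_f)),
    "no annotation")
  expect_false("b" %in% scr$sites$site_id)
  expect_true(all(scr$sites$unfoldable[scr$sites$site_id == "c"]))
  # unfoldable entries never enter the cohort summary
  expect_equal(sum(glance(scr)$n_sites), sum(!scr$sites$unfoldable))
  expect_error(screen_sites(character(0), list()), "no sites")
})

test_that("FASTA plus JSON sidecars feed the screen from disk", {
  dir <- file.path(tempdir(), "screen-io")
  sc <- generate_site_cohort(2, seed = 701, out_dir = dir)
  scr_disk <- screen_sites(file.path(dir, "sites.fa"), dir)
  scr_mem <- screen_sites(sc$sequences, sc$annotations)
  expect_equal(tidy(scr_disk), tidy(scr_mem))
  out <- write_screen_results(scr_disk, file.path(dir, "out"))
  expect_true(file.exists(file.path(out, "screen_results.csv")))
  expect_true(file.exists(file.path(out, "screen_summary.json")))
})

test_that("imported ensembles bypass the built-in folding engine", {
  site <- generate_attc_like_site(seed = 79)
  ens <- subopt_window(site$sequence)
  paths <- vapply(seq_along(ens), function(k) {
    p <- file.path(tempdir(), sprintf("imp-%d.ct", k))
    write_ct(ens[[k]], p)
    p
  }, "")
  imported <- lapply(paths, read_ct)
  scr <- screen_sites(c(x = site$sequence), list(x = site$boxes),
                      both_strands = FALSE,
                      import = list(x.bottom = imported))
  direct <- screen_sites(c(x = site$sequence), list(x = site$boxes),
                         both_strands = FALSE)
  expect_equal(scr$sites$p_straight_canonical,
               direct$sites$p_straight_canonical, tolerance = 1e-4)
})
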