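cond <- folding_conditions()

test_that("the MFE equals the exhaustive minimum on short random sequences", {
  set.seed(41)
  tested <- 0
  for (rep in 1:14) {
    sq <- random_dna(sample(10:24, 1))
    oracle <- oracle_fold(sq, cond)
    bf <- min(c(oracle$energy_kcal, 0))
    st <- fold_mfe(sq, cond)
    expect_equal(st$free_energy, bf * 4.184, tolerance = 1e-9)
    tested <- tested + 1
  }
  expect_equal(tested, 14)
})

test_that("the suboptimal window is sound and complete vs enumeration", {
  set.seed(42)
  checked <- 0
  for (rep in 1:14) {
    sq <- random_dna(sample(17:25, 1), prob = c(.17, .33, .33, .17))
    oracle <- oracle_fold(sq, cond)
    bf <- min(c(oracle$energy_kcal, 0))
    if (bf > -1e-9) next
    wf <- 0.35                       # wide window stresses completeness
    keep <- oracle$energy_kcal <= bf + wf * abs(bf) + 1e-9 &
      oracle$energy_kcal <= 1e-9
    keys_bf <- sort(unique(vapply(which(keep), function(q)
      pairs_to_dotbracket(oracle$pairs[[q]]), "")))
    sub <- subopt_window(sq, cond, window_fraction = wf,
                         max_structures = 10000)
    keys_dp <- sort(vapply(sub, function(x)
      pairs_to_dotbracket(x$pairs), ""))
    expect_identical(keys_dp, keys_bf)
    # ascending energies, MFE first
    en <- vapply(sub, function(x) x$free_energy, 0)
    expect_true(all(diff(en) >= -1e-9))
    expect_equal(en[1], bf * 4.184, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("a perfect inverted repeat folds into its full stem", {
  sq <- paste0("GCGCGCGCGC", "TTTT", "GCGCGCGCGC")
  st <- fold_mfe(sq, cond)
  expect_equal(sum(st$pairs > 0) / 2, 10)
  expect_equal(st$pairs[1:10], 24:15)
  expect_lt(st$free_energy, -50)
  # and a poly-A folds not at all
  open <- fold_mfe(strrep("A", 30), cond)
  expect_equal(sum(open$pairs), 0)
  expect_equal(open$free_energy, 0)
})

test_that("two designed competing stems both appear in the window", {
  # a bistable sequence: the central G run can close either hairpin
  sq <- "CCCCCAAAAGGGGGAAAACCCCC"
  sub <- subopt_window(sq, cond, window_fraction = 0.05)
  dbs <- vapply(sub, function(x) pairs_to_dotbracket(x$pairs), "")
  expect_true("(((((....)))))........." %in% dbs)
  expect_true(".........(((((....)))))" %in% dbs)
  # near-degenerate by construction
  en <- vapply(sub, function(x) x$free_energy, 0)
  expect_lt(abs(en[1] - en[2]), 0.5)
  # confirmed against the enumeration oracle
  oracle <- oracle_fold(sq, cond)
  expect_equal(min(en), min(oracle$energy_kcal) * 4.184, tolerance = 1e-9)
})

test_that("a vanishing window keeps only co-optimal structures", {
  sq <- paste0("GCGCGCGCGC", "TTTT", "GCGCGCGCGC")
  sub <- subopt_window(sq, cond, window_fraction = 1e-9)
  expect_equal(length(sub), 1)
  expect_equal(sub[[1]]$free_energy, fold_mfe(sq, cond)$free_energy)
})

test_that("the reverse complement of a hairpin folds into the mirror", {
  sq <- paste0("GGCAGGCGGC", "TATTT", "GCCGCCTGCC")
  st <- fold_mfe(sq, cond)
  rc <- fold_mfe(reverse_complement(sq), cond)
  expect_equal(sum(st$pairs > 0), sum(rc$pairs > 0))
  n <- nchar(sq)
  mirrored <- integer(n)
  mirrored[n + 1 - which(st$pairs > 0)] <- n + 1 - st$pairs[st$pairs > 0]
  expect_equal(rc$pairs, mirrored)
})

test_that("returned energies are additive over the loop decomposition", {
  set.seed(43)
  site <- generate_attc_like_site(seed = 9, verify = FALSE)
  for (st in subopt_window(site$sequence, cond, 0.2)) {
    expect_equal(structure_energy(st, cond), st$free_energy,
                 tolerance = 1e-6)
  }
})

test_that("invalid sequences are rejected", {
  expect_error(fold_mfe("ACGTAC"), "length")
  expect_error(fold_mfe("ACGTNACGTNAC"), "invalid base")
  expect_error(fold_mfe(strrep("A", 300)), "length")
  expect_error(subopt_window("ACGTACGTACGT", window_fraction = 0), "window_fraction")
})

test_that("CT and dot-bracket files round-trip losslessly", {
  st <- fold_mfe(paste0("GCGCGCGCGC", "TTTT", "GCGCGCGCGC"), cond)
  ct <- file.path(tempdir(), "rt.ct")
  db <- file.path(tempdir(), "rt.db")
  write_ct(st, ct)
  back <- read_ct(ct)
  expect_equal(back$pairs, st$pairs)
  expect_equal(back$sequence, st$sequence)
  expect_equal(back$free_energy, st$free_energy, tolerance = 1e-4)
  write_dotbracket(st, db)
  back2 <- read_dotbracket(db)
  expect_equal(back2$pairs, st$pairs)
  expect_equal(back2$sequence, st$sequence)
  # kcal energies convert on import
  kc <- read_ct(ct, energy_unit = "kcal")
  expect_equal(kc$free_energy, st$free_energy * 4.184, tolerance = 1e-3)
})

test_that("malformed structure files fail with informative errors", {
  bad <- file.path(tempdir(), "bad.ct")
  writeLines(c("4  dG = 0  broken",
               "1 G 0 2 4 1", "2 C 1 3 0 2", "3 A 2 4 0 3", "4 T 3 0 2 4"),
             bad)
  expect_error(read_ct(bad), "paired to")
  writeLines(c("3  dG = 0  short", "1 G 0 2 0 1", "2 C 1 3 0 2"), bad)
  expect_error(read_ct(bad), "3 rows|declares")
  expect_error(dotbracket_to_pairs("(()"), "unbalanced")
  expect_error(hairpin_structure("GAAAC", c(5, 0, 0, 0, 2)), "symmetric")
  # crossing pairs (pseudoknot) rejected
  pv <- integer(16)
  pv[1] <- 12; pv[12] <- 1   # G.C
  pv[5] <- 16; pv[16] <- 5   # A.T crossing the first pair
  expect_error(hairpin_structure("GAAAAAAAAAACAAAT", pv), "crossing")
  expect_equal(dotbracket_to_pairs("(((...)))"),
               c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
})
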