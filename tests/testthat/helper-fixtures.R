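# Deterministic attC-like fixtures for the conformation decision table.
# One register-shift site design provides a sequence on which both the
# canonical (straight) and the shifted (kinked) pair tables are valid;
# variants with removed pairs cover the incomplete classes.

fixture_site <- function() {
  generate_attc_like_site(seed = 424, register_shift = TRUE, shift = 3,
                          verify = FALSE)
}

fixture_straight_pairs <- function(site) site$design$canonical

# the competing helix displaced by `shift` into the VTS/UCS, as designed
fixture_kinked_pairs <- function(site, shift = 3) {
  bx <- site$boxes
  n <- nchar(site$sequence)
  pv <- integer(n)
  canon <- site$design$canonical
  for (i in iv_seq_(bx$R_outer)) {             # R helix as in the canonical
    pv[i] <- canon[i]; pv[canon[i]] <- i
  }
  m <- bx$L_outer[2] - bx$L_outer[1] + 1
  for (t in 0:(m - 1)) {
    i <- bx$L_outer[1] + t; j <- bx$L_inner[2] - t - shift
    pv[i] <- j; pv[j] <- i
  }
  for (u in 0:(shift - 1)) {
    i <- bx$L_outer[1] - 1 - u; j <- bx$L_inner[2] - shift + 1 + u
    pv[i] <- j; pv[j] <- i
  }
  pv
}

iv_seq_ <- function(iv) seq.int(iv[1], iv[2])

drop_pairs <- function(pv, positions) {
  for (p in positions) {
    if (pv[p] > 0) { pv[pv[p]] <- 0L; pv[p] <- 0L }
  }
  pv
}

# hand-built site whose straight apical stem spans exactly 28 nt:
# R helix (5 bp), asymmetric UCS (3 + 1 nt), L helix (12 bp), 4-nt loop
fixture_28nt_site <- function() {
  s12 <- "GCAGGCCTGGAC"
  rc <- function(x) reverse_complement(x)
  seqn <- paste0("GGCGC", "AAA", s12, "TTTT", rc(s12), "A", rc("GGCGC"))
  n <- nchar(seqn)                             # 5+3+12+4+12+1+5 = 42
  boxes <- attc_annotation(R_outer = c(1, 5), L_outer = c(9, 20),
                           vts = c(21, 24), L_inner = c(25, 36),
                           R_inner = c(38, 42), ucs = c(6, 7, 8, 37))
  pv <- integer(n)
  for (t in 0:4) { pv[1 + t] <- n - t; pv[n - t] <- 1 + t }
  for (t in 0:11) { pv[9 + t] <- 36 - t; pv[36 - t] <- 9 + t }
  list(structure = hairpin_structure(seqn, pv), boxes = boxes)
}
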