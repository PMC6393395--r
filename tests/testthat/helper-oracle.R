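# Exhaustive enumeration of every admissible secondary structure of a
# short sequence: non-crossing, Watson-Crick or G.T pairs, hairpin loops
# >= 3 nt, every helix at least two stacked pairs. Structures are scored
# with the same loop decomposition the folding engine uses, so for
# n <= 25 the enumeration is an independent ground truth for both the
# minimum free energy and the contents of a suboptimal window.
enum_all_structures <- function(s) {
  pair_ok <- hairpintools:::PAIR_OK
  ok <- function(a, b) pair_ok[s[a], s[b]]
  rec <- function(i, j, forbid_close = 0L) {
    if (j - i + 1 < 7) return(list(integer(0)))
    out <- rec(i + 1L, j)                      # i unpaired
    for (jp in (i + 6L):j) {
      if (jp == forbid_close) next
      if (!ok(i, jp)) next
      hmax <- 2L
      while (ok(i + hmax, jp - hmax) &&
             (jp - hmax) - (i + hmax) - 1L >= 3L) hmax <- hmax + 1L
      for (h in 2:hmax) {
        if ((jp - h + 1L) - (i + h - 1L) - 1L < 3L) next
        okh <- TRUE
        for (t in 0:(h - 1L)) if (!ok(i + t, jp - t)) { okh <- FALSE; break }
        if (!okh) next
        helix <- unlist(lapply(0:(h - 1L), function(t) c(i + t, jp - t)))
        inner <- if ((jp - h) - (i + h) + 1 >= 7)
          rec(i + h, jp - h, forbid_close = jp - h) else list(integer(0))
        outer <- if (jp + 1L <= j) rec(jp + 1L, j) else list(integer(0))
        for (a in inner) for (b in outer)
          out[[length(out) + 1L]] <- c(helix, a, b)
      }
    }
    out
  }
  rec(1L, length(s))
}

pairlist_to_vec <- function(n, pl) {
  pv <- integer(n)
  if (length(pl)) {
    pi_ <- pl[c(TRUE, FALSE)]; pj <- pl[c(FALSE, TRUE)]
    pv[pi_] <- pj; pv[pj] <- pi_
  }
  pv
}

# brute-force all structures of a sequence with their energies (kcal/mol)
oracle_fold <- function(sequence, conditions = folding_conditions()) {
  s <- hairpintools:::seq_to_int(sequence)
  P <- hairpintools:::fold_params(conditions, n = length(s))
  pls <- enum_all_structures(s)
  pvs <- lapply(pls, function(pl) pairlist_to_vec(length(s), pl))
  en <- vapply(pvs, function(pv)
    hairpintools:::score_structure_kcal(s, pv, P), numeric(1))
  list(pairs = pvs, energy_kcal = en)
}

random_dna <- function(n, prob = c(.22, .28, .28, .22)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
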