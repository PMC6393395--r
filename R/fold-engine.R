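# Secondary-structure prediction for single-stranded DNA hairpins:
# a Zuker-style dynamic program over the nearest-neighbor model in
# fold-params.R, with banded suboptimal enumeration by best-first
# backtracking over the same recurrences.
#
# Matrices (energies kcal/mol, INF = forbidden), for i < j:
#   Vh2[i,j]  (i,j) paired AND stacked on (i+1,j-1): the only way a helix
#             may start, which bans isolated (lonely) pairs globally.
#   Vany[i,j] (i,j) paired; interior is a hairpin loop, a continued stack,
#             an interior loop leading to a new helix (Vh2), or a
#             multibranch loop.
#   WM[i,j]   >= 1 helix in a multibranch context (c per unpaired nt,
#             b per branch), decomposed canonically on the last branch.
#   WMM[i,j]  >= 2 helices in a multibranch context.
#   W[j]      exterior loop over prefix 1..j (unpaired bases free).
# Interior loops are capped at 30 unpaired nt total (standard practice).

INF_E <- 1e9

fold_matrices <- function(s, P) {
  n <- length(s)
  okM <- PAIR_OK[s, s]
  penM <- P$pen[s, s]
  Vany <- Vh2 <- WM <- WMM <- matrix(INF_E, n, n)
  # interior-loop combos (l1, l2 unpaired on each side), constant per fold
  combos <- expand.grid(l1 = 0:P$max_interior, l2 = 0:P$max_interior)
  combos <- combos[combos$l1 + combos$l2 >= 1 &
                     combos$l1 + combos$l2 <= P$max_interior, ]
  ilG <- interior_loop_G(P, combos$l1, combos$l2)
  b <- P$ml_b; cc <- P$ml_c
  if (n >= 6) {
    for (span in 4:(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        if (okM[i, j]) {
          stackG <- if (span >= 6 && okM[i + 1, j - 1])
            P$stack[s[i], s[j], s[i + 1], s[j - 1]] else NA_real_
          if (!is.na(stackG) && Vany[i + 1, j - 1] < INF_E)
            Vh2[i, j] <- stackG + Vany[i + 1, j - 1]
          best <- P$hairpinG[span - 1] + penM[i, j]
          if (Vh2[i, j] < best) best <- Vh2[i, j]
          if (span >= 8) {                       # interior loops
            k <- i + 1L + combos$l1
            l <- j - 1L - combos$l2
            keep <- which(l - k >= 6L)
            if (length(keep)) {
              kk <- k[keep]; ll <- l[keep]
              v <- Vh2[kk + (ll - 1L) * n]
              fin <- which(v < INF_E)
              if (length(fin)) {
                cand <- min(ilG[keep][fin] + penM[kk[fin] + (ll[fin] - 1L) * n] + v[fin])
                cand <- cand + penM[i, j]
                if (cand < best) best <- cand
              }
            }
          }
          if (span >= 15 && WMM[i + 1, j - 1] < INF_E) {  # multibranch
            cand <- P$ml_a + b + penM[i, j] + WMM[i + 1, j - 1]
            if (cand < best) best <- cand
          }
          Vany[i, j] <- best
        }
        if (span >= 6) {                         # WM: last branch at (m, j)
          ms <- i:(j - 6L)
          v <- Vh2[ms + (j - 1L) * n]
          fin <- which(v < INF_E)
          best <- if (j - 1L > i) WM[i, j - 1L] + cc else INF_E
          if (length(fin)) {
            mm <- ms[fin]
            pref <- cc * (mm - i)
            prev <- mm > i
            if (any(prev))
              pref[prev] <- pmin(WM[i + (mm[prev] - 2L) * n], pref[prev])
            cand <- min(pref + b + penM[mm + (j - 1L) * n] + v[fin])
            if (cand < best) best <- cand
          }
          WM[i, j] <- best
          if (span >= 13) {
            ms <- (i + 7L):(j - 6L)
            if (length(ms) > 0 && ms[1] <= ms[length(ms)]) {
              wmv <- WM[i + (ms - 2L) * n]
              v <- Vh2[ms + (j - 1L) * n]
              fin <- which(wmv < INF_E & v < INF_E)
              best <- if (j - 1L - i >= 13L) WMM[i, j - 1L] + cc else INF_E
              if (length(fin)) {
                mm <- ms[fin]
                cand <- min(wmv[fin] + b + penM[mm + (j - 1L) * n] + v[fin])
                if (cand < best) best <- cand
              }
              WMM[i, j] <- best
            }
          }
        }
      }
    }
  }
  W <- numeric(n + 1)                            # W[j + 1] = prefix 1..j
  for (j in seq_len(n)) {
    best <- W[j]
    if (j >= 7) {
      ms <- 1:(j - 6L)
      v <- Vh2[ms + (j - 1L) * n]
      fin <- which(v < INF_E)
      if (length(fin)) {
        mm <- ms[fin]
        cand <- min(W[mm] + penM[mm + (j - 1L) * n] + v[fin])
        if (cand < best) best <- cand
      }
    }
    W[j + 1] <- best
  }
  list(Vany = Vany, Vh2 = Vh2, WM = WM, WMM = WMM, W = W,
       okM = okM, penM = penM, combos = combos, ilG = ilG)
}

# Best-first banded backtracking over the recurrences above. Each state
# carries the exact energy of decided loops, the still-open intervals
# (type 1=W, 2=Vany, 3=Vh2, 4=WM, 5=WMM) and the pairs fixed so far; its
# bound adds the matrix minimum of every open interval, so states complete
# in nondecreasing energy order and every structure in the band is found.
wuchty_enumerate <- function(s, P, M, band, max_structures,
                             max_expansions = 200000L) {
  n <- length(s)
  mfe <- M$W[n + 1]
  limit <- mfe + band + 1e-7
  look <- function(type, i, j) {
    if (type == 1L) return(if (j <= 0) 0 else M$W[j + 1])
    if (i > j) return(INF_E)
    switch(type - 1L, M$Vany[i, j], M$Vh2[i, j], M$WM[i, j], M$WMM[i, j])
  }
  # queue as parallel lists
  q_en <- q_bound <- numeric(0)
  q_iv <- q_pairs <- list()
  push <- function(en, iv, pairs, bound) {
    q_en[[length(q_en) + 1L]] <<- en
    q_bound[[length(q_bound) + 1L]] <<- bound
    q_iv[[length(q_iv) + 1L]] <<- iv
    q_pairs[[length(q_pairs) + 1L]] <<- pairs
  }
  push(0, matrix(c(1L, 1L, n), 1), integer(0), mfe)
  out <- list()
  n_exp <- 0L
  while (length(q_en) > 0 && length(out) < max_structures &&
         n_exp < max_expansions) {
    n_exp <- n_exp + 1L
    at <- which.min(q_bound)
    en <- q_en[[at]]; iv <- q_iv[[at]]; pairs <- q_pairs[[at]]
    q_en <- q_en[-at]; q_bound <- q_bound[-at]
    q_iv <- q_iv[-at]; q_pairs <- q_pairs[-at]
    if (nrow(iv) == 0) {
      pv <- integer(n)
      if (length(pairs)) {
        pi_ <- pairs[c(TRUE, FALSE)]; pj <- pairs[c(FALSE, TRUE)]
        pv[pi_] <- pj; pv[pj] <- pi_
      }
      out[[length(out) + 1L]] <- list(pairs = pv, energy = en)
      next
    }
    r <- nrow(iv)
    type <- iv[r, 1]; i <- iv[r, 2]; j <- iv[r, 3]
    rest <- iv[-r, , drop = FALSE]
    rest_bound <- if (nrow(rest)) {
      sum(vapply(seq_len(nrow(rest)),
                 function(q) look(rest[q, 1], rest[q, 2], rest[q, 3]),
                 numeric(1)))
    } else 0
    try_move <- function(cost, children, new_pair = NULL) {
      nb <- en + cost + rest_bound
      if (length(children))
        for (ch in children) nb <- nb + look(ch[1], ch[2], ch[3])
      if (nb > limit || nb >= INF_E / 2) return()
      niv <- rest
      if (length(children))
        niv <- rbind(rest, do.call(rbind, children))
      np <- if (is.null(new_pair)) pairs else c(pairs, new_pair)
      push(en + cost, niv, np, nb)
    }
    if (type == 1L) {                       # exterior prefix 1..j
      if (j >= 1)
        try_move(0, if (j - 1 >= 1) list(c(1L, 1L, j - 1L)) else list())
      if (j >= 7) for (m in 1:(j - 6L)) {
        if (M$Vh2[m, j] >= INF_E) next
        ch <- list(c(3L, m, j))
        if (m - 1 >= 1) ch <- c(ch, list(c(1L, 1L, m - 1L)))
        try_move(M$penM[m, j], ch)
      }
    } else if (type == 2L) {                # Vany: (i, j) paired
      span <- j - i
      try_move(P$hairpinG[span - 1] + M$penM[i, j], list(),
               new_pair = c(i, j))
      if (span >= 6 && M$okM[i + 1, j - 1]) {
        sg <- P$stack[s[i], s[j], s[i + 1], s[j - 1]]
        if (!is.na(sg) && M$Vany[i + 1, j - 1] < INF_E)
          try_move(sg, list(c(2L, i + 1L, j - 1L)), new_pair = c(i, j))
      }
      if (span >= 8) {
        k <- i + 1L + M$combos$l1
        l <- j - 1L - M$combos$l2
        keep <- which(l - k >= 6L)
        for (q in keep) {
          if (M$Vh2[k[q], l[q]] >= INF_E) next
          try_move(M$ilG[q] + M$penM[i, j] + M$penM[k[q], l[q]],
                   list(c(3L, k[q], l[q])), new_pair = c(i, j))
        }
      }
      if (span >= 15 && M$WMM[i + 1, j - 1] < INF_E)
        try_move(P$ml_a + P$ml_b + M$penM[i, j],
                 list(c(5L, i + 1L, j - 1L)), new_pair = c(i, j))
    } else if (type == 3L) {                # Vh2: helix start at (i, j)
      sg <- P$stack[s[i], s[j], s[i + 1], s[j - 1]]
      if (!is.na(sg) && M$Vany[i + 1, j - 1] < INF_E)
        try_move(sg, list(c(2L, i + 1L, j - 1L)), new_pair = c(i, j))
    } else if (type == 4L) {                # WM
      if (j - 1 - i >= 6) try_move(P$ml_c, list(c(4L, i, j - 1L)))
      if (j - i >= 6) for (m in i:(j - 6L)) {
        if (M$Vh2[m, j] >= INF_E) next
        base <- P$ml_b + M$penM[m, j]
        if (m == i) {
          try_move(base, list(c(3L, m, j)))
        } else {
          try_move(base + P$ml_c * (m - i), list(c(3L, m, j)))
          if (m - 1 - i >= 6)
            try_move(base, list(c(3L, m, j), c(4L, i, m - 1L)))
        }
      }
    } else {                                # WMM
      if (j - 1 - i >= 13) try_move(P$ml_c, list(c(5L, i, j - 1L)))
      if (j - i >= 13) for (m in (i + 7L):(j - 6L)) {
        if (M$Vh2[m, j] >= INF_E || M$WM[i, m - 1] >= INF_E) next
        try_move(P$ml_b + M$penM[m, j],
                 list(c(3L, m, j), c(4L, i, m - 1L)))
      }
    }
  }
  # ascending energy, structurally distinct
  if (length(out) == 0) return(out)
  keys <- vapply(out, function(x) paste(x$pairs, collapse = ","), "")
  out <- out[!duplicated(keys)]
  out[order(vapply(out, function(x) x$energy, numeric(1)))]
}

fold_prepare <- function(sequence, conditions) {
  s <- seq_to_int(sequence)
  n <- length(s)
  if (n < 10 || n > 200)
    rlang::abort("sequence length must be between 10 and 200 nt.")
  P <- fold_params(conditions, n = n)
  M <- fold_matrices(s, P)
  list(s = s, P = P, M = M, mfe = M$W[n + 1])
}

#' Predict the minimum-free-energy structure of a DNA hairpin
#'
#' Folds a single-stranded DNA sequence with a nearest-neighbor energy
#' model (Watson-Crick and G.T wobble pairs, stacking enthalpies/entropies
#' with a monovalent-salt entropy correction, hairpin/bulge/internal loop
#' penalties and an affine multibranch term), assuming a linear
#' (unconstrained) molecule. Isolated single pairs are disallowed and
#' interior loops are capped at 30 unpaired nucleotides. The result is
#' deterministic.
#'
#' @param sequence DNA string, 10-200 nt, alphabet ACGT.
#' @param conditions A [folding_conditions()].
#' @return A [hairpin_structure()] with `free_energy` in kJ/mol (0 and no
#'   pairs if nothing stable forms).
#' @examples
#' fold_mfe("GCGCGCGCGCTTTTGCGCGCGCGC")
#' @export
fold_mfe <- function(sequence, conditions = folding_conditions()) {
  fp <- fold_prepare(sequence, conditions)
  if (fp$mfe > -1e-9)
    return(hairpin_structure(sequence, integer(length(fp$s)), 0))
  st <- wuchty_enumerate(fp$s, fp$P, fp$M, band = 1e-6,
                         max_structures = 1)[[1]]
  hairpin_structure(sequence, st$pairs, st$energy * KCAL_TO_KJ)
}

#' Enumerate suboptimal structures within an energy window
#'
#' Returns all structurally distinct secondary structures whose free
#' energy lies within `window_fraction` (default 5%) of the minimum free
#' energy, i.e. `dG <= 0` and `|dG - dG_mfe| <= window_fraction * |dG_mfe|`,
#' sorted by energy (the MFE structure first), up to `max_structures`.
#' This is the ensemble the conformer classification operates on.
#'
#' @inheritParams fold_mfe
#' @param window_fraction Fractional energy window above the MFE
#'   (0 < window_fraction < 1, default 0.05).
#' @param max_structures Cap on the number of returned structures
#'   (default 50).
#' @return A list of [hairpin_structure()] objects.
#' @export
subopt_window <- function(sequence, conditions = folding_conditions(),
                          window_fraction = 0.05, max_structures = 50) {
  if (!is.numeric(window_fraction) || window_fraction <= 0 ||
      window_fraction >= 1)
    rlang::abort("`window_fraction` must lie in (0, 1).")
  fp <- fold_prepare(sequence, conditions)
  if (fp$mfe > -1e-9)
    return(list(hairpin_structure(sequence, integer(length(fp$s)), 0)))
  band <- window_fraction * abs(fp$mfe)
  structs <- wuchty_enumerate(fp$s, fp$P, fp$M, band = band,
                              max_structures = max_structures)
  structs <- Filter(function(st) st$energy <= 1e-9, structs)
  lapply(structs, function(st)
    hairpin_structure(sequence, st$pairs, st$energy * KCAL_TO_KJ))
}
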