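# DNA nearest-neighbor thermodynamics: unified Watson-Crick stack
# enthalpies/entropies with G.T wobble stacks, entropic salt correction,
# and length-dependent loop penalties. Internal unit is kcal/mol; the
# public API reports kJ/mol.

#' Folding conditions
#'
#' Ionic conditions and temperature for DNA secondary-structure
#' prediction. Defaults match a typical force-spectroscopy buffer:
#' 0.25 M Na+, no Mg2+, 25 degrees C. Magnesium is accepted for
#' completeness but does not enter the energy model (predictions at the
#' default 0 M are unaffected).
#'
#' @param sodium Monovalent cation concentration (M, > 0).
#' @param magnesium Divalent cation concentration (M, >= 0); recorded but
#'   not used by the energy model.
#' @param temperature Temperature in degrees Celsius.
#' @return An object of class `folding_conditions`.
#' @export
folding_conditions <- function(sodium = 0.25, magnesium = 0,
                               temperature = 25) {
  if (!is.numeric(sodium) || sodium <= 0)
    rlang::abort("`sodium` must be > 0 (M).")
  if (!is.numeric(magnesium) || magnesium < 0)
    rlang::abort("`magnesium` must be >= 0 (M).")
  structure(list(sodium = sodium, magnesium = magnesium,
                 temperature = temperature),
            class = "folding_conditions")
}

BASES <- c("A", "C", "G", "T")

seq_to_int <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  s <- match(ch, BASES)
  if (anyNA(s))
    rlang::abort(sprintf("invalid base(s) in sequence: %s",
                         paste(unique(ch[is.na(s)]), collapse = ", ")))
  s
}

int_to_seq <- function(s) paste(BASES[s], collapse = "")

# allowed base pairs: Watson-Crick plus G.T wobble
PAIR_OK <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
PAIR_OK["A", "T"] <- PAIR_OK["T", "A"] <- TRUE
PAIR_OK["C", "G"] <- PAIR_OK["G", "C"] <- TRUE
PAIR_OK["G", "T"] <- PAIR_OK["T", "G"] <- TRUE

# Nearest-neighbor dimer parameters, "XY/WZ" = top strand 5'-XY-3' over
# bottom strand 3'-WZ-5'; pairs are (X,W) and (Y,Z). dH kcal/mol, dS cal/(mol K).
NN_STACKS <- list(
  # Watson-Crick / Watson-Crick
  "AA/TT" = c(-7.9, -22.2), "AT/TA" = c(-7.2, -20.4),
  "TA/AT" = c(-7.2, -21.3), "CA/GT" = c(-8.5, -22.7),
  "GT/CA" = c(-8.4, -22.4), "CT/GA" = c(-7.8, -21.0),
  "GA/CT" = c(-8.2, -22.2), "CG/GC" = c(-10.6, -27.2),
  "GC/CG" = c(-9.8, -24.4), "GG/CC" = c(-8.0, -19.9),
  # stacks containing one or two G.T wobbles
  "AG/TT" = c(1.0, 0.9),   "AT/TG" = c(-2.5, -8.3),
  "CG/GT" = c(-4.1, -11.7), "CT/GG" = c(-2.8, -8.0),
  "GG/CT" = c(3.3, 10.4),  "GG/TT" = c(5.8, 16.3),
  "GT/CG" = c(-4.4, -12.3), "GT/TG" = c(4.1, 9.5),
  "TG/AT" = c(-0.1, -1.7), "TG/GT" = c(-1.4, -6.2),
  "TT/AG" = c(-1.3, -5.3)
)

# loop-size penalties (kcal/mol at 37 C); linearly interpolated between
# tabulated sizes, Jacobson-Stockmayer extrapolated beyond 30
LOOP_DG37 <- list(
  hairpin = list(sizes = c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
                 dg = c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1,
                        5.3, 5.5, 5.7, 6.1, 6.3)),
  bulge = list(sizes = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
               dg = c(4.0, 2.9, 3.1, 3.2, 3.3, 3.5, 3.7, 3.9, 4.1, 4.3,
                      4.5, 4.8, 5.0, 5.2, 5.3, 5.6, 5.9)),
  internal = list(sizes = c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
                  dg = c(3.2, 3.6, 4.0, 4.4, 4.6, 4.8, 4.9, 4.9, 5.2, 5.4,
                         5.6, 5.8, 5.9, 6.3, 6.6)))

loop_table <- function(which, max_size) {
  tab <- LOOP_DG37[[which]]
  sizes <- seq(min(tab$sizes), max(max_size, 31))
  dg <- stats::approx(tab$sizes, tab$dg, xout = pmin(sizes, 30))$y
  big <- sizes > 30
  if (any(big))
    dg[big] <- dg[sizes == 30] +
      2.44 * 0.0019872 * 310.15 * log(sizes[big] / 30)
  out <- rep(Inf, max(sizes))
  out[sizes] <- dg
  out
}

KCAL_TO_KJ <- 4.184

# Precompute all temperature/salt-dependent energies for one condition
# set and sequence length. Returned energies are kcal/mol.
fold_params <- function(conditions = folding_conditions(), n = 200) {
  stopifnot(inherits(conditions, "folding_conditions"))
  TK <- conditions$temperature + 273.15
  salt_dS <- 0.368 * log(conditions$sodium)   # per stack, cal/(mol K)
  stack <- array(NA_real_, c(4, 4, 4, 4))     # [a, b, c, d]: outer pair (a,b), inner (c,d)
  for (key in names(NN_STACKS)) {
    hS <- NN_STACKS[[key]]
    fill <- function(k) {
      x <- match(substr(k, 1, 1), BASES); y <- match(substr(k, 2, 2), BASES)
      w <- match(substr(k, 4, 4), BASES); z <- match(substr(k, 5, 5), BASES)
      stack[x, w, y, z] <<- hS[1] - TK * (hS[2] + salt_dS) / 1000
    }
    fill(key)
    # same physical stack read from the other strand: "XY/WZ" -> "ZW/YX"
    rot <- paste0(substr(key, 5, 5), substr(key, 4, 4), "/",
                  substr(key, 2, 2), substr(key, 1, 1))
    fill(rot)
  }
  # terminal penalty for helix-end A.T or G.T pairs
  pen <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    ab <- c(BASES[a], BASES[b])
    if (PAIR_OK[a, b] && !setequal(ab, c("C", "G")))
      pen[a, b] <- 2.2 - TK * 6.9 / 1000
  }
  tscale <- TK / 310.15                        # loops treated as entropic
  list(TK = TK,
       stack = stack,
       pen = pen,
       hairpinG = loop_table("hairpin", n) * tscale,
       bulgeG = loop_table("bulge", n) * tscale,
       internalG = loop_table("internal", n) * tscale,
       asym_coef = 0.3, asym_max = 3.0,
       ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
       max_interior = 30L)
}

# energy (kcal/mol) of an internal/bulge loop with l1, l2 unpaired nt
interior_loop_G <- function(P, l1, l2) {
  tot <- l1 + l2
  ifelse(l1 == 0 | l2 == 0,
         P$bulgeG[pmax(tot, 1)],
         P$internalG[pmax(tot, 3)] +
           pmin(P$asym_coef * abs(l1 - l2), P$asym_max))
}

# direct children (immediately nested pairs) of the loop closed by the
# half-open interval; pairs is the full partner vector, 0 = unpaired
loop_children <- function(pairs, i, j) {
  out <- list()
  k <- i + 1L
  while (k <= j - 1L) {
    if (pairs[k] > k) {
      out[[length(out) + 1L]] <- c(k, pairs[k])
      k <- pairs[k] + 1L
    } else k <- k + 1L
  }
  out
}

# Free energy (kcal/mol) of a given structure under the same loop
# decomposition the folding engine uses. Independent of the dynamic
# program: walks the pair table loop by loop.
score_structure_kcal <- function(s, pairs, P) {
  n <- length(s)
  total <- 0
  # exterior loop: terminal penalty per top-level helix end
  for (ch in loop_children(pairs, 0L, n + 1L))
    total <- total + P$pen[s[ch[1]], s[ch[2]]]
  stack_pairs <- which(pairs > seq_along(pairs))
  for (i in stack_pairs) {
    j <- pairs[i]
    cs <- loop_children(pairs, i, j)
    if (length(cs) == 0) {
      total <- total + P$hairpinG[j - i - 1] + P$pen[s[i], s[j]]
    } else if (length(cs) == 1) {
      k <- cs[[1]][1]; l <- cs[[1]][2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + P$stack[s[i], s[j], s[k], s[l]]
      } else {
        total <- total + interior_loop_G(P, l1, l2) +
          P$pen[s[i], s[j]] + P$pen[s[k], s[l]]
      }
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(cs, function(x) x[2] - x[1] + 1L, 1L))
      total <- total + P$ml_a + P$ml_b * (length(cs) + 1) +
        P$ml_c * unpaired + P$pen[s[i], s[j]]
      for (ch in cs) total <- total + P$pen[s[ch[1]], s[ch[2]]]
    }
  }
  total
}

#' Recompute the free energy of a structure from its loop decomposition
#'
#' Scores an existing [hairpin_structure()] with the package's
#' nearest-neighbor model: the sum of stack energies and hairpin, bulge,
#' internal and multibranch loop penalties under the given conditions.
#' For structures produced by [fold_mfe()] or [subopt_window()] this
#' reproduces their `free_energy` (the energy model is additive over the
#' loop decomposition).
#'
#' @param structure A [hairpin_structure()].
#' @param conditions A [folding_conditions()].
#' @return Free energy in kJ/mol.
#' @export
structure_energy <- function(structure, conditions = folding_conditions()) {
  stopifnot(inherits(structure, "hairpin_structure"))
  s <- seq_to_int(structure$sequence)
  P <- fold_params(conditions, n = length(s))
  score_structure_kcal(s, structure$pairs, P) * KCAL_TO_KJ
}
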