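#' attC box annotation
#'
#' Describes the functional architecture of an attC hairpin on one strand,
#' with 1-based closed intervals ordered 5' to 3':
#' the outer integrase-binding box `R_outer` (R'' near the 5' end), the
#' outer L box `L_outer` (L''), the variable terminal structure `vts`
#' (the apical loop region), the inner L box `L_inner` (L') and the inner
#' R box `R_inner` (R'). `ucs` lists the positions of the unpaired central
#' spacer (the internal loop separating the R and L helices, on either
#' side), and `ehb` the extra-helical bases bulged out of the stem, which
#' are exempt from all pairing requirements.
#'
#' @param R_outer,L_outer,vts,L_inner,R_inner Length-2 integer vectors
#'   `c(start, end)`.
#' @param ucs Integer positions of the unpaired central spacer.
#' @param ehb Integer positions of extra-helical bases.
#' @return An object of class `attc_annotation`.
#' @export
attc_annotation <- function(R_outer, L_outer, vts, L_inner, R_inner,
                            ucs = integer(0), ehb = integer(0)) {
  iv <- list(R_outer = R_outer, L_outer = L_outer, vts = vts,
             L_inner = L_inner, R_inner = R_inner)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2] || v[1] < 1)
      rlang::abort(sprintf("`%s` must be a closed interval c(start, end).", nm))
  }
  ends <- vapply(iv, `[`, 1, 2)
  starts <- vapply(iv, `[`, 1, 1)
  if (any(starts[-1] <= ends[-5]))
    rlang::abort(
      "boxes must be non-overlapping and ordered R_outer < L_outer < vts < L_inner < R_inner.")
  ucs <- sort(unique(as.integer(ucs)))
  ehb <- sort(unique(as.integer(ehb)))
  in_gap <- (ucs > R_outer[2] & ucs < L_outer[1]) |
    (ucs > L_inner[2] & ucs < R_inner[1])
  if (length(ucs) && !all(in_gap))
    rlang::abort("`ucs` positions must lie between the R and L boxes.")
  structure(list(R_outer = as.integer(R_outer), L_outer = as.integer(L_outer),
                 vts = as.integer(vts), L_inner = as.integer(L_inner),
                 R_inner = as.integer(R_inner), ucs = ucs, ehb = ehb),
            class = "attc_annotation")
}

#' Read / write attC annotations as JSON sidecars
#'
#' The sidecar format is a JSON object with keys `R_outer`, `L_outer`,
#' `vts`, `L_inner`, `R_inner` (each `[start, end]`, 1-based closed) and
#' optional arrays `ucs` and `ehb`.
#'
#' @param path File path.
#' @return `read_attc_annotation()` returns an [attc_annotation()];
#'   `write_attc_annotation()` returns `path` invisibly.
#' @export
read_attc_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("R_outer", "L_outer", "vts", "L_inner", "R_inner")
  if (!all(need %in% names(x)))
    rlang::abort(sprintf("annotation %s lacks keys: %s", path,
                         paste(setdiff(need, names(x)), collapse = ", ")))
  attc_annotation(x$R_outer, x$L_outer, x$vts, x$L_inner, x$R_inner,
                  ucs = x$ucs %||% integer(0), ehb = x$ehb %||% integer(0))
}

#' @rdname read_attc_annotation
#' @param annotation An [attc_annotation()].
#' @export
write_attc_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "attc_annotation"))
  jsonlite::write_json(unclass(annotation), path, auto_unbox = FALSE)
  invisible(path)
}

iv_seq <- function(iv) seq.int(iv[1], iv[2])

# canonical partner map between two box intervals: the k-th non-EHB
# position of the outer box (5'->3') pairs the k-th non-EHB position of
# the inner box counted 3'->5'
canonical_partners <- function(outer, inner, ehb) {
  po <- setdiff(iv_seq(outer), ehb)
  pi_ <- rev(setdiff(iv_seq(inner), ehb))
  k <- min(length(po), length(pi_))
  list(outer = po[seq_len(k)], partner = pi_[seq_len(k)])
}

#' Classify a hairpin conformation from its attC box pairing
#'
#' Applies the five-group decision table used for attC folding ensembles:
#' * `other`: the R box is not fully paired (a non-EHB position of R'' has
#'   no partner inside R', or vice versa).
#' * With the R box paired, the structure is `straight` when the L boxes
#'   pair in their canonical register (modal offset between canonical and
#'   actual partners is zero) and `kinked` when they pair out of register;
#'   it is `complete` when every non-EHB L-box position is paired and
#'   `incomplete` otherwise (e.g. a bubble in the L helix).
#'
#' Extra-helical bases are exempt everywhere. When no L-outer position is
#' paired at all the register is undefined and taken as canonical (such
#' structures are `straight_incomplete`). The result carries a `bubble`
#' attribute: `TRUE` for straight-incomplete structures whose L box is
#' opened by an internal bubble, which remain structurally close to the
#' straight conformation.
#'
#' @param structure A [hairpin_structure()].
#' @param boxes An [attc_annotation()] covering the sequence.
#' @return One of `"straight_complete"`, `"straight_incomplete"`,
#'   `"kinked_complete"`, `"kinked_incomplete"`, `"other"`, with attribute
#'   `bubble`.
#' @export
classify_conformation <- function(structure, boxes) {
  stopifnot(inherits(structure, "hairpin_structure"),
            inherits(boxes, "attc_annotation"))
  n <- nchar(structure$sequence)
  if (boxes$R_inner[2] > n)
    rlang::abort("annotation extends beyond the sequence.")
  pr <- structure$pairs
  ehb <- boxes$ehb
  ro <- setdiff(iv_seq(boxes$R_outer), ehb)
  ri <- setdiff(iv_seq(boxes$R_inner), ehb)
  r_ok <- all(pr[ro] >= boxes$R_inner[1] & pr[ro] <= boxes$R_inner[2]) &&
    all(pr[ri] >= boxes$R_outer[1] & pr[ri] <= boxes$R_outer[2])
  cls <- if (!r_ok) {
    "other"
  } else {
    lo <- setdiff(iv_seq(boxes$L_outer), ehb)
    li <- setdiff(iv_seq(boxes$L_inner), ehb)
    complete <- all(pr[lo] > 0) && all(pr[li] > 0)
    canon <- canonical_partners(boxes$L_outer, boxes$L_inner, ehb)
    paired <- canon$outer[pr[canon$outer] > 0]
    offset <- if (length(paired) == 0) 0L else
      modal_int(canon$partner[match(paired, canon$outer)] - pr[paired])
    paste0(if (offset == 0L) "straight" else "kinked",
           if (complete) "_complete" else "_incomplete")
  }
  bubble <- FALSE
  if (cls == "straight_incomplete") {
    lo_li <- c(setdiff(iv_seq(boxes$L_outer), ehb),
               setdiff(iv_seq(boxes$L_inner), ehb))
    bubble <- any(pr[lo_li] == 0)
  }
  structure(cls, bubble = bubble)
}

#' Size of the mechanically stable intermediate (apical stem)
#'
#' The intermediate that survives the minor unfolding step is the apical
#' part of the hairpin above the unpaired central spacer: all nucleotides
#' enclosed by (and including) the outermost base pair located apical of
#' the 5'-side UCS internal loop. For the canonical straight attC_bs fold
#' this spans the L helix plus the terminal structure (35 nt); the kinked
#' fold buries part of that arm and leaves a 28-nt apical stem.
#'
#' @param structure A [hairpin_structure()].
#' @param boxes An [attc_annotation()] with at least one 5'-side UCS
#'   position.
#' @return Integer number of nucleotides.
#' @export
intermediate_size <- function(structure, boxes) {
  stopifnot(inherits(structure, "hairpin_structure"),
            inherits(boxes, "attc_annotation"))
  ucs5 <- boxes$ucs[boxes$ucs < boxes$vts[1]]
  if (length(ucs5) == 0)
    rlang::abort("annotation has no 5'-side UCS positions.")
  thr <- max(ucs5)
  pr <- structure$pairs
  cand <- which(seq_along(pr) > thr & pr > seq_along(pr))
  if (length(cand) == 0)
    rlang::abort("no base pair apical of the UCS: intermediate undefined.")
  i <- min(cand)
  as.integer(pr[i] - i + 1L)
}

#' Expected contour-length change of the intermediate's unfolding
#'
#' `intermediate_size()` converted to nm at 0.68 nm/nt (no closure term:
#' the intermediate is an internal step). A 35-nt apical stem yields
#' 23.8 nm, a 28-nt stem 19.04 nm.
#'
#' @inheritParams intermediate_size
#' @return Contour-length change in nm.
#' @export
expected_intermediate_delta_L <- function(structure, boxes) {
  expected_delta_L(intermediate_size(structure, boxes),
                   full_unfolding = FALSE)
}

#' Boltzmann occupancies of a conformational ensemble
#'
#' Converts per-structure folding free energies into equilibrium
#' occupancies, \eqn{p_i = e^{-\Delta G_i / RT} / \sum_j e^{-\Delta G_j / RT}}
#' with R = 8.314 J/(mol K), computed with a max-shift for numerical
#' stability, and aggregates them by conformation class.
#'
#' @param energies Free energies in kJ/mol (finite).
#' @param classes Optional character vector of conformation classes, one
#'   per structure (e.g. from [classify_conformation()]).
#' @param temperature Temperature in K (default 298.15).
#' @return An object of class `ensemble_occupancy`: list with
#'   `structures` (tibble of energy, class, probability), `by_class`
#'   (tibble of class, probability) and `temperature`.
#' @examples
#' # straight vs kinked attC bottom strand at the printed free energies
#' boltzmann_occupancy(c(-97.9, -97.1), c("straight", "kinked"))
#' @export
boltzmann_occupancy <- function(energies, classes = NULL,
                                temperature = hp_constants$T_default) {
  if (length(energies) == 0) rlang::abort("at least one structure required.")
  if (any(!is.finite(energies))) rlang::abort("energies must be finite.")
  if (is.null(classes)) classes <- rep("all", length(energies))
  if (length(classes) != length(energies))
    rlang::abort("`classes` must match `energies` in length.")
  RT <- hp_constants$R_gas * temperature / 1000   # kJ/mol
  z <- -energies / RT
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  structures <- tibble::tibble(free_energy = energies,
                               class = as.character(classes),
                               probability = p)
  by_class <- structures |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(probability = sum(.data$probability), .groups = "drop")
  structure(list(structures = structures, by_class = by_class,
                 temperature = temperature),
            class = "ensemble_occupancy")
}

#' @export
print.ensemble_occupancy <- function(x, ...) {
  cat(sprintf("<ensemble_occupancy> %d structure(s) at %g K\n",
              nrow(x$structures), x$temperature))
  for (r in seq_len(nrow(x$by_class)))
    cat(sprintf("  %-20s %5.1f%%\n", x$by_class$class[r],
                100 * x$by_class$probability[r]))
  invisible(x)
}

#' Classify a folding ensemble and compute class occupancies
#'
#' Runs [classify_conformation()] on every structure of an ensemble (as
#' returned by [subopt_window()]) and feeds the free energies into
#' [boltzmann_occupancy()].
#'
#' @param structures A list of [hairpin_structure()] objects with
#'   free energies.
#' @param boxes An [attc_annotation()].
#' @param temperature Temperature in K.
#' @return An `ensemble_occupancy` whose `structures` tibble also carries
#'   the `bubble` flag per structure.
#' @export
classify_ensemble <- function(structures, boxes,
                              temperature = hp_constants$T_default) {
  stopifnot(length(structures) >= 1)
  cls <- vapply(structures, function(st)
    as.character(classify_conformation(st, boxes)), "")
  bub <- vapply(structures, function(st)
    attr(classify_conformation(st, boxes), "bubble"), TRUE)
  en <- vapply(structures, function(st) st$free_energy, 0)
  occ <- boltzmann_occupancy(en, cls, temperature)
  occ$structures$bubble <- bub
  occ
}
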