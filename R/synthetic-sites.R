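# Designed attC-like sequences: R and L helices separated by an unpaired
# central spacer (UCS), capped by a variable terminal structure (VTS),
# with optional extra-helical bases, G.T wobbles for strand asymmetry and
# an optional out-of-register competing helix (kinked design). Sequences
# are built by constraint propagation over the intended structures and
# verified by folding them.

# union-find with complement parity: positions are nodes, an intended
# base pair forces the two bases to be Watson-Crick complements
uf_new <- function(n) list2env(list(parent = seq_len(n),
                                    parity = integer(n)), parent = emptyenv())

uf_find <- function(uf, x) {
  x <- as.integer(x)
  p <- 0L
  while (uf$parent[x] != x) {
    p <- (p + uf$parity[x]) %% 2L
    x <- uf$parent[x]
  }
  c(x, p)
}

uf_union <- function(uf, x, y, rel) {
  fx <- uf_find(uf, x); fy <- uf_find(uf, y)
  if (fx[1] == fy[1])
    return((fx[2] + fy[2]) %% 2L == rel)      # FALSE on contradiction
  uf$parent[fy[1]] <- fx[1]
  uf$parity[fy[1]] <- (fx[2] + fy[2] + rel) %% 2L
  TRUE
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
WOBBLE_PARTNER <- c(G = "T", T = "G")

#' Generate an attC-like site with a designed folding ensemble
#'
#' Builds a DNA sequence whose canonical structure is the straight attC
#' hairpin: an R helix (`r_stem` pairs), an asymmetric UCS internal loop
#' (`ucs5`/`ucs3` unpaired nt), an L helix (`l_stem` pairs) and a VTS
#' apical loop (`vts` nt), with `n_ehb` extra-helical bases bulged into
#' the inner R box. Options:
#' * `n_gt` replaces that many central R-helix Watson-Crick pairs by G.T
#'   wobbles. Wobbles fold on this strand but turn into A.C mismatches on
#'   the reverse complement, making the straight fold strand-specific
#'   (bottom-strand biased), as in natural attC sites.
#' * `register_shift` additionally threads a competing helix through the
#'   L arm, shifted by `shift` positions into the VTS/UCS, so the folding
#'   window also contains a kinked conformation.
#'
#' The design is verified by folding: the default design must yield a
#' straight-complete MFE structure with the designed apical-stem size,
#' the shifted design at least one kinked-complete structure in the
#' suboptimal window. Random bases are redrawn up to `max_tries` times
#' until verification passes.
#'
#' @param seed Integer seed (mandatory; designs are reproducible).
#' @param r_stem,l_stem Helix lengths in bp (defaults 10 and 14).
#' @param vts Apical loop length in nt (default 7; the default straight
#'   apical stem thus spans `2 * l_stem + vts` = 35 nt).
#' @param ucs5,ucs3 Unpaired central spacer sizes 5' and 3' of the L
#'   helix (defaults 4 and 2).
#' @param n_ehb Number of extra-helical bases bulged into the inner R box
#'   (default 1).
#' @param n_gt Number of G.T wobble pairs placed in the R helix
#'   (default 0).
#' @param register_shift Design a competing out-of-register helix
#'   (default `FALSE`).
#' @param shift Register offset of the competing helix (default 3 nt).
#' @param conditions [folding_conditions()] used for verification.
#' @param window_fraction Suboptimal window used for verification.
#' @param max_tries Maximum redesign attempts (default 30).
#' @param verify Set `FALSE` to skip fold-based verification.
#' @return A list of class `attc_site`: `sequence`, `boxes`
#'   (an [attc_annotation()]) and `design` (intended pair tables).
#' @export
generate_attc_like_site <- function(seed, r_stem = 10, l_stem = 14, vts = 7,
                                    ucs5 = 4, ucs3 = 2, n_ehb = 1, n_gt = 0,
                                    register_shift = FALSE, shift = 3,
                                    conditions = folding_conditions(),
                                    window_fraction = 0.05, max_tries = 30,
                                    verify = TRUE) {
  if (missing(seed)) rlang::abort("`seed` is mandatory for site designs.")
  stopifnot(r_stem >= 4, l_stem >= 6, vts >= 4, ucs5 >= 1, ucs3 >= 1,
            n_ehb >= 0, n_gt >= 0, shift >= 1)
  if (register_shift && (shift > ucs5 || vts - shift < 3))
    rlang::abort("`shift` too large for the chosen ucs5/vts sizes.")
  n <- r_stem + ucs5 + l_stem + vts + l_stem + ucs3 + r_stem + n_ehb
  if (n < 50 || n > 80)
    rlang::abort(sprintf(
      "designed site is %d nt; choose sizes giving 50-80 nt.", n))

  # coordinates
  Ro <- c(1, r_stem)
  ucs5_pos <- (r_stem + 1):(r_stem + ucs5)
  Lo <- c(r_stem + ucs5 + 1, r_stem + ucs5 + l_stem)
  Vt <- c(Lo[2] + 1, Lo[2] + vts)
  Li <- c(Vt[2] + 1, Vt[2] + l_stem)
  ucs3_pos <- (Li[2] + 1):(Li[2] + ucs3)
  Ri <- c(Li[2] + ucs3 + 1, n)
  # EHBs bulge inside the inner R box, after its first two paired bases
  ehb <- if (n_ehb > 0) Ri[1] + 2L + seq_len(n_ehb) - 1L else integer(0)
  ri_paired <- setdiff(iv_seq(Ri), ehb)

  canonical <- list()
  for (t in 0:(r_stem - 1))
    canonical[[length(canonical) + 1L]] <- c(Ro[1] + t, rev(ri_paired)[t + 1])
  for (t in 0:(l_stem - 1))
    canonical[[length(canonical) + 1L]] <- c(Lo[1] + t, Li[2] - t)
  shifted <- NULL
  if (register_shift) {
    shifted <- list()
    # contiguous helix displaced by `shift`: L'' plus the UCS 5' tail
    # pairs L' plus the VTS 3' tail
    for (t in 0:(l_stem - 1))
      shifted[[length(shifted) + 1L]] <- c(Lo[1] + t, Li[2] - t - shift)
    for (u in 0:(shift - 1))
      shifted[[length(shifted) + 1L]] <- c(Lo[1] - 1 - u, Li[2] - l_stem - shift + 1 + u + l_stem)
  }

  build <- function() {
    uf <- uf_new(n)
    for (pr in c(canonical, shifted))
      if (!uf_union(uf, pr[1], pr[2], 1L))
        rlang::abort("design infeasible: a base would have to pair itself.")
    roots <- vapply(seq_len(n), function(x) uf_find(uf, x)[1], 1L)
    pars <- vapply(seq_len(n), function(x) uf_find(uf, x)[2], 1L)
    stem_pos <- c(iv_seq(Ro), iv_seq(Lo), iv_seq(Li), ri_paired)
    urt <- unique(roots)
    # stems GC-rich (stability), loops AT-rich (fewer spurious pairs)
    base_of_root <- stats::setNames(vapply(urt, function(r) {
      pr <- if (r %in% stem_pos) c(.12, .38, .38, .12) else c(.35, .15, .15, .35)
      sample(c("A", "C", "G", "T"), 1, prob = pr)
    }, ""), urt)
    seq_ch <- ifelse(pars == 0L, base_of_root[as.character(roots)],
                     COMPLEMENT[base_of_root[as.character(roots)]])
    # G.T wobbles deep in the R helix (positions only the canonical
    # design constrains)
    if (n_gt > 0) {
      picks <- canonical[unique(round(seq(3, r_stem - 2,
                                          length.out = n_gt)))]
      for (pr in picks) {
        seq_ch[pr[1]] <- "G"; seq_ch[pr[2]] <- "T"
      }
    }
    paste(seq_ch, collapse = "")
  }

  boxes <- attc_annotation(Ro, Lo, Vt, Li, Ri,
                           ucs = c(ucs5_pos, ucs3_pos), ehb = ehb)
  canon_pairs <- integer(n)
  for (pr in canonical) { canon_pairs[pr[1]] <- pr[2]; canon_pairs[pr[2]] <- pr[1] }

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      sq <- build()
      if (!verify)
        return(structure(list(sequence = sq, boxes = boxes,
                              design = list(canonical = canon_pairs)),
                         class = "attc_site"))
      ok <- tryCatch({
        ens <- subopt_window(sq, conditions, window_fraction)
        cls <- vapply(ens, function(st)
          as.character(classify_conformation(st, boxes)), "")
        if (register_shift) {
          any(cls == "kinked_complete")
        } else {
          cls[1] == "straight_complete" &&
            intermediate_size(ens[[1]], boxes) == 2 * l_stem + vts
        }
      }, error = function(e) FALSE)
      if (ok)
        return(structure(list(sequence = sq, boxes = boxes,
                              design = list(canonical = canon_pairs)),
                         class = "attc_site"))
    }
    rlang::abort(sprintf(
      "no verified design in %d attempts (n = %d, register_shift = %s); try other stem sizes.",
      max_tries, n, register_shift))
  })
}

#' @export
print.attc_site <- function(x, ...) {
  cat(sprintf("<attc_site> %d nt\n  %s\n", nchar(x$sequence), x$sequence))
  cat(sprintf("  boxes: R'' %d-%d, L'' %d-%d, VTS %d-%d, L' %d-%d, R' %d-%d\n",
              x$boxes$R_outer[1], x$boxes$R_outer[2], x$boxes$L_outer[1],
              x$boxes$L_outer[2], x$boxes$vts[1], x$boxes$vts[2],
              x$boxes$L_inner[1], x$boxes$L_inner[2], x$boxes$R_inner[1],
              x$boxes$R_inner[2]))
  invisible(x)
}

#' Generate a cohort of attC-like sites with annotations
#'
#' Designs `n_sites` straight-biased sites (G.T wobbles in the R helix by
#' default, so bottom and top strands fold differently) and returns them
#' as a named sequence vector plus matching annotations, optionally
#' writing a multi-FASTA and JSON annotation sidecars.
#'
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `sites.fa` and
#'   `<id>.json` annotation files there.
#' @param ... Passed to [generate_attc_like_site()].
#' @return A list with `sequences` (named character) and `annotations`
#'   (named list of [attc_annotation()]).
#' @export
generate_site_cohort <- function(n_sites, seed, out_dir = NULL, n_gt = 2,
                                 n_ehb = 0, ...) {
  sites <- lapply(seq_len(n_sites), function(k)
    generate_attc_like_site(seed = seed + k, n_gt = n_gt, n_ehb = n_ehb,
                            ...))
  ids <- sprintf("site-%03d", seq_len(n_sites))
  seqs <- stats::setNames(vapply(sites, function(x) x$sequence, ""), ids)
  anns <- stats::setNames(lapply(sites, function(x) x$boxes), ids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(as.vector(rbind(paste0(">", ids), seqs)),
               file.path(out_dir, "sites.fa"))
    for (id in ids)
      write_attc_annotation(anns[[id]], file.path(out_dir,
                                                  paste0(id, ".json")))
  }
  list(sequences = seqs, annotations = anns)
}
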