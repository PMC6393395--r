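#' Reverse complement of a DNA sequence
#'
#' Standard reverse complement (an involution), used to obtain the top
#' strand of an attC site from its bottom strand.
#'
#' @param sequence Character vector of DNA strings (A/C/G/T).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  vapply(sequence, function(sq) {
    seq_to_int(sq)                       # validates the alphabet
    paste(rev(COMPLEMENT[strsplit(toupper(sq), "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# annotation of the reverse-complement strand: intervals mirror and the
# inner/outer boxes swap roles
mirror_annotation <- function(boxes, n) {
  mi <- function(iv) c(n - iv[2] + 1L, n - iv[1] + 1L)
  attc_annotation(R_outer = mi(boxes$R_inner), L_outer = mi(boxes$L_inner),
                  vts = mi(boxes$vts), L_inner = mi(boxes$L_outer),
                  R_inner = mi(boxes$R_outer),
                  ucs = sort(n - boxes$ucs + 1L),
                  ehb = sort(n - boxes$ehb + 1L))
}

#' Read a multi-FASTA of attC sites
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_sites_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("FASTA not found: ", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    if (length(heads) == 0) rlang::abort("no FASTA records found.")
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads])
    ends <- c(heads[-1] - 1L, length(lines))
    stats::setNames(vapply(seq_along(heads), function(k)
      paste(lines[(heads[k] + 1):ends[k]], collapse = ""), ""), ids)
  }
}

#' Screen a set of attC sites for conformer occupancies
#'
#' For every site, folds the bottom strand and (optionally) its reverse
#' complement (the top strand) with [subopt_window()], classifies the
#' resulting ensemble with [classify_conformation()] under the site's box
#' annotation (mirrored for the top strand), and converts the ensemble
#' energies into Boltzmann class occupancies. The per-site probability of
#' a canonical straight fold aggregates the straight classes
#' (complete plus incomplete, bubbles included, by default). The cohort
#' summary reports mean and standard deviation of that probability per
#' strand over foldable sites.
#'
#' Sites without an annotation are skipped with a warning; sites whose
#' window contains no paired structure are flagged unfoldable and
#' excluded from the summary. Structures may also be supplied from an
#' external folding tool via `import`: a named list (by `site_id.strand`)
#' of lists of [hairpin_structure()], e.g. read with [read_ct()], which
#' then bypasses the built-in folding for those entries.
#'
#' @param sequences Named character vector of bottom-strand sequences, or
#'   a FASTA path.
#' @param annotations Named list of [attc_annotation()] objects, or a
#'   directory containing `<site_id>.json` sidecars.
#' @param conditions A [folding_conditions()].
#' @param window_fraction Energy window (default 0.05).
#' @param max_structures Per-strand ensemble cap (default 50).
#' @param both_strands Also screen the reverse complement (default TRUE).
#' @param straight_classes Classes counted as canonical straight.
#' @param import Optional named list of pre-folded ensembles (see above).
#' @return An object of class `site_screen`: list with `sites` (per
#'   site x strand tibble) and `summary` (per-strand mean and SD of
#'   `p_straight_canonical`).
#' @export
screen_sites <- function(sequences, annotations,
                         conditions = folding_conditions(),
                         window_fraction = 0.05, max_structures = 50,
                         both_strands = TRUE,
                         straight_classes = c("straight_complete",
                                              "straight_incomplete"),
                         import = NULL) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- read_sites_fasta(sequences)
  if (length(sequences) == 0) rlang::abort("no sites supplied.")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    rlang::abort("sequences must be named by site id.")
  if (is.character(annotations) && length(annotations) == 1) {
    dirp <- annotations
    annotations <- lapply(names(sequences), function(id) {
      f <- file.path(dirp, paste0(id, ".json"))
      if (file.exists(f)) read_attc_annotation(f) else NULL
    })
    names(annotations) <- names(sequences)
  }
  rows <- list()
  for (id in names(sequences)) {
    boxes <- annotations[[id]]
    if (is.null(boxes)) {
      rlang::warn(sprintf("site %s has no annotation; skipped.", id))
      next
    }
    strands <- if (both_strands) c("bottom", "top") else "bottom"
    for (strand in strands) {
      sq <- if (strand == "bottom") toupper(sequences[[id]])
            else reverse_complement(sequences[[id]])
      bx <- if (strand == "bottom") boxes
            else mirror_annotation(boxes, nchar(sq))
      key <- paste(id, strand, sep = ".")
      ens <- if (!is.null(import) && !is.null(import[[key]])) import[[key]]
             else subopt_window(sq, conditions, window_fraction,
                                max_structures)
      foldable <- any(vapply(ens, function(st) any(st$pairs > 0), TRUE))
      if (!foldable) {
        rows[[key]] <- tibble::tibble(
          site_id = id, strand = strand, n_structures = 0L,
          p_straight_complete = NA_real_, p_straight_incomplete = NA_real_,
          p_kinked_complete = NA_real_, p_kinked_incomplete = NA_real_,
          p_other = NA_real_, p_straight_canonical = NA_real_,
          unfoldable = TRUE)
        next
      }
      occ <- classify_ensemble(ens, bx,
                               temperature = conditions$temperature + 273.15)
      getp <- function(cl) {
        v <- occ$by_class$probability[occ$by_class$class == cl]
        if (length(v)) v else 0
      }
      rows[[key]] <- tibble::tibble(
        site_id = id, strand = strand, n_structures = length(ens),
        p_straight_complete = getp("straight_complete"),
        p_straight_incomplete = getp("straight_incomplete"),
        p_kinked_complete = getp("kinked_complete"),
        p_kinked_incomplete = getp("kinked_incomplete"),
        p_other = getp("other"),
        p_straight_canonical = sum(vapply(straight_classes, getp, 0)),
        unfoldable = FALSE)
    }
  }
  if (length(rows) == 0) rlang::abort("no screenable sites.")
  sites <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$site_id, .data$strand)
  summary <- sites |>
    dplyr::filter(!.data$unfoldable) |>
    dplyr::group_by(.data$strand) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     mean_p_straight = mean(.data$p_straight_canonical),
                     sd_p_straight = stats::sd(.data$p_straight_canonical),
                     .groups = "drop")
  structure(list(sites = sites, summary = summary,
                 window_fraction = window_fraction,
                 conditions = conditions),
            class = "site_screen")
}

#' @export
print.site_screen <- function(x, ...) {
  cat(sprintf("<site_screen> %d site-strand entries (window %.0f%%)\n",
              nrow(x$sites), 100 * x$window_fraction))
  for (r in seq_len(nrow(x$summary)))
    cat(sprintf("  %s strand: p(straight canonical) = %.2f +/- %.2f (n = %d)\n",
                x$summary$strand[r], x$summary$mean_p_straight[r],
                x$summary$sd_p_straight[r], x$summary$n_sites[r]))
  invisible(x)
}

#' Write screen results to CSV and JSON
#'
#' @param screen A [screen_sites()] result.
#' @param out_dir Output directory (created if needed): writes
#'   `screen_results.csv` and `screen_summary.json`.
#' @return `out_dir`, invisibly.
#' @export
write_screen_results <- function(screen, out_dir) {
  stopifnot(inherits(screen, "site_screen"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(screen$sites, file.path(out_dir, "screen_results.csv"))
  jsonlite::write_json(screen$summary,
                       file.path(out_dir, "screen_summary.json"),
                       digits = NA)
  invisible(out_dir)
}
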