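#' DNA hairpin secondary structure
#'
#' Couples a DNA sequence with a pair table and a folding free energy.
#' The pair table is a 1-based integer vector with `pairs[i] = j` when
#' bases i and j are paired and 0 when i is unpaired. Structures must be
#' symmetric and non-crossing (no pseudoknots), every pair must be
#' Watson-Crick or a G.T wobble, and hairpin loops must contain at least
#' 3 nucleotides.
#'
#' @param sequence DNA string (A/C/G/T, 5' to 3').
#' @param pairs Integer partner vector (0 = unpaired).
#' @param free_energy Folding free energy in kJ/mol (`NA` if unknown).
#' @return An object of class `hairpin_structure`.
#' @examples
#' hairpin_structure("GCGCTTTTGCGC", c(12, 11, 10, 9, 0, 0, 0, 0, 4, 3, 2, 1))
#' @export
hairpin_structure <- function(sequence, pairs, free_energy = NA_real_) {
  s <- seq_to_int(sequence)
  pairs <- as.integer(pairs)
  validate_pairs(s, pairs)
  structure(list(sequence = toupper(sequence), pairs = pairs,
                 free_energy = free_energy),
            class = "hairpin_structure")
}

validate_pairs <- function(s, pairs) {
  n <- length(s)
  if (length(pairs) != n)
    rlang::abort("pair table length does not match the sequence.")
  if (any(pairs < 0) || any(pairs > n))
    rlang::abort("pair table entries out of range.")
  idx <- which(pairs > 0)
  if (any(pairs[idx] == idx))
    rlang::abort("a base cannot pair with itself.")
  if (any(pairs[pairs[idx]] != idx))
    rlang::abort("pair table is not symmetric.")
  ip <- idx[pairs[idx] > idx]
  if (any(pairs[ip] - ip - 1L < 3L))
    rlang::abort("hairpin loops must contain at least 3 nucleotides.")
  bad <- ip[!PAIR_OK[cbind(s[ip], s[pairs[ip]])]]
  if (length(bad))
    rlang::abort(sprintf(
      "non-canonical pair(s) (only Watson-Crick and G.T allowed) at: %s",
      paste(bad, collapse = ", ")))
  # crossing check: opening/closing must nest
  open <- integer(0)
  for (k in seq_len(n)) {
    if (pairs[k] > k) open <- c(open, pairs[k])
    else if (pairs[k] != 0 && pairs[k] < k) {
      if (length(open) == 0 || open[length(open)] != k)
        rlang::abort("pair table contains crossing pairs (pseudoknot).")
      open <- open[-length(open)]
    }
  }
  invisible(TRUE)
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("<hairpin_structure> %d nt, %d pairs, dG = %s kJ/mol\n",
              nchar(x$sequence), sum(x$pairs > 0) / 2,
              ifelse(is.na(x$free_energy), "NA",
                     sprintf("%.2f", x$free_energy))))
  cat(" ", x$sequence, "\n ", pairs_to_dotbracket(x$pairs), "\n")
  invisible(x)
}

#' Convert between pair tables and dot-bracket strings
#'
#' @param pairs Integer partner vector (0 = unpaired).
#' @return `pairs_to_dotbracket()` returns a dot-bracket string;
#'   `dotbracket_to_pairs()` returns an integer partner vector.
#' @export
pairs_to_dotbracket <- function(pairs) {
  db <- rep(".", length(pairs))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs != 0 & pairs < seq_along(pairs)] <- ")"
  paste(db, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    rlang::abort("dot-bracket string may only contain '(', ')' and '.'.")
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (length(stack) == 0) rlang::abort("unbalanced dot-bracket string.")
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- k; pairs[k] <- i
    }
  }
  if (length(stack)) rlang::abort("unbalanced dot-bracket string.")
  pairs
}

#' Read and write connectivity-table (CT) and dot-bracket files
#'
#' The CT format is the 6-column connectivity table used by folding tools:
#' a header line `N  dG = E  title` followed by one line per base
#' (index, base, previous, next, partner, original index). Dot-bracket
#' files contain an optional `>`-header, the sequence line and the
#' structure line (with an optional trailing energy in parentheses).
#' Round trips through either format preserve sequence and pairs exactly.
#'
#' @param path File path.
#' @param energy_unit Unit of the energy in a CT header being read:
#'   `"kJ"` (default, as written by this package) or `"kcal"` (converted
#'   to kJ/mol on read).
#' @return `read_ct()` and `read_dotbracket()` return a
#'   [hairpin_structure()]; the writers return `path` invisibly.
#' @export
read_ct <- function(path, energy_unit = c("kJ", "kcal")) {
  energy_unit <- match.arg(energy_unit)
  lines <- readLines(path)
  if (length(lines) < 2) rlang::abort("CT file too short.")
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head[1]))
  if (is.na(n)) rlang::abort("CT header must start with the sequence length.")
  energy <- NA_real_
  em <- regmatches(lines[1], regexec("dG\\s*=\\s*(-?[0-9.]+)", lines[1]))[[1]]
  if (length(em) == 2) energy <- as.numeric(em[2])
  if (energy_unit == "kcal" && !is.na(energy)) energy <- energy * KCAL_TO_KJ
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    rlang::abort(sprintf("CT body has %d rows but header declares %d.",
                         length(body), n))
  base <- character(n); pairs <- integer(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(f) < 5)
      rlang::abort(sprintf("CT line %d: expected >= 5 columns.", r + 1))
    idx <- as.integer(f[1])
    if (is.na(idx) || idx != r)
      rlang::abort(sprintf("CT line %d: index column is %s, expected %d.",
                           r + 1, f[1], r))
    base[r] <- f[2]
    pairs[r] <- as.integer(f[5])
  }
  s <- seq_to_int(paste(base, collapse = ""))
  bad <- which(pairs > 0 & (pairs > n | pairs == seq_len(n)))
  if (length(bad))
    rlang::abort(sprintf("CT line %d: partner index out of range.", bad[1] + 1))
  prt <- which(pairs > 0)
  asym <- prt[pairs[pairs[prt]] != prt]
  if (length(asym))
    rlang::abort(sprintf(
      "CT line %d: base %d is paired to %d but %d is paired to %d.",
      asym[1] + 1, asym[1], pairs[asym[1]], pairs[asym[1]],
      pairs[pairs[asym[1]]]))
  hairpin_structure(paste(base, collapse = ""), pairs, energy)
}

#' @rdname read_ct
#' @param structure A [hairpin_structure()].
#' @param title Title placed in the header line.
#' @export
write_ct <- function(structure, path, title = "hairpintools") {
  stopifnot(inherits(structure, "hairpin_structure"))
  s <- strsplit(structure$sequence, "")[[1]]
  n <- length(s)
  head <- sprintf("%d  dG = %.4f  %s", n,
                  ifelse(is.na(structure$free_energy), 0,
                         structure$free_energy), title)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), s, seq_len(n) - 1L,
                  c(seq_len(n - 1L) + 1L, 0L), structure$pairs, seq_len(n))
  writeLines(c(head, rows), path)
  invisible(path)
}

#' @rdname read_ct
#' @export
write_dotbracket <- function(structure, path, title = "hairpintools") {
  stopifnot(inherits(structure, "hairpin_structure"))
  energy <- if (is.na(structure$free_energy)) "" else
    sprintf(" (%.4f)", structure$free_energy)
  writeLines(c(paste0(">", title), structure$sequence,
               paste0(pairs_to_dotbracket(structure$pairs), energy)), path)
  invisible(path)
}

#' @rdname read_ct
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2) rlang::abort("dot-bracket file too short.")
  seqline <- trimws(lines[1])
  strline <- trimws(lines[2])
  energy <- NA_real_
  em <- regmatches(strline, regexec("\\((-?[0-9.]+)\\)\\s*$", strline))[[1]]
  if (length(em) == 2) {
    energy <- as.numeric(em[2])
    strline <- trimws(sub("\\((-?[0-9.]+)\\)\\s*$", "", strline))
  }
  if (nchar(strline) != nchar(seqline))
    rlang::abort("sequence and structure lines differ in length.")
  hairpin_structure(seqline, dotbracket_to_pairs(strline), energy)
}
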