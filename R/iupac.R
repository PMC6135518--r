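# IUPAC nucleotide ambiguity codes: each letter names a set of concrete bases.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_LETTERS <- names(.IUPAC)

# Complement map over the full 15-letter alphabet.
.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Reverse lookup: sorted concatenation of a base set -> its minimal code.
.IUPAC_ENCODE <- local({
  keys <- vapply(.IUPAC, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC), keys)
})

# 15 x 15 logical: strict_match[p, t] <- t is a concrete base of expansion(p).
# For ambiguous t it is FALSE by definition (a literal 'N' on a template is
# not any single base). lenient_match[p, t] <- expansions intersect.
.IUPAC_STRICT <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(.IUPAC_LETTERS, .IUPAC_LETTERS))
  for (p in .IUPAC_LETTERS) m[p, intersect(.IUPAC[[p]], c("A", "C", "G", "T"))] <- TRUE
  for (p in .IUPAC_LETTERS) for (t in .IUPAC_LETTERS)
    if (t %in% .IUPAC[[p]]) m[p, t] <- TRUE
  m
})
.IUPAC_LENIENT <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(.IUPAC_LETTERS, .IUPAC_LETTERS))
  for (p in .IUPAC_LETTERS) for (t in .IUPAC_LETTERS)
    m[p, t] <- length(intersect(.IUPAC[[p]], .IUPAC[[t]])) > 0L
  m
})

.check_iupac <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty character string", call. = FALSE)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), .IUPAC_LETTERS)
  if (length(bad))
    stop("invalid IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  ch
}

#' Degeneracy fold of an IUPAC sequence
#'
#' The number of distinct concrete A/C/G/T sequences a degenerate
#' oligonucleotide represents: the product over positions of the size of the
#' IUPAC base set at each position. Computed without enumeration, so
#' arbitrarily degenerate sequences are handled.
#'
#' @param x A single 5'->3' nucleotide string over the 15-letter IUPAC
#'   alphabet (case-insensitive).
#' @return A positive number (integer-valued; returned as double to avoid
#'   overflow for very degenerate sequences).
#' @examples
#' iupac_degeneracy("ACGT")   # 1
#' iupac_degeneracy("AYR")    # 4
#' @export
iupac_degeneracy <- function(x) {
  ch <- .check_iupac(x)
  prod(vapply(.IUPAC[ch], length, 1L))
}

#' Expand an IUPAC sequence into its concrete sequences
#'
#' Enumerates every concrete A/C/G/T sequence obtained by substituting each
#' ambiguity code with each member of its base set. The size of the result
#' equals [iupac_degeneracy()]. Expansion is refused above `cap` to guard
#' against combinatorial blow-up; the error condition carries class
#' `"vertcoi_cap_exceeded"` so callers can distinguish it from an
#' invalid-alphabet error.
#'
#' @inheritParams iupac_degeneracy
#' @param cap Maximum degeneracy that will be enumerated (default 4096).
#' @return Character vector of concrete sequences (unordered set semantics).
#' @examples
#' iupac_expand("AY")  # "AC" "AT"
#' @export
iupac_expand <- function(x, cap = 4096) {
  ch <- .check_iupac(x)
  d <- prod(vapply(.IUPAC[ch], length, 1L))
  if (d > cap) {
    stop(structure(
      class = c("vertcoi_cap_exceeded", "error", "condition"),
      list(message = sprintf("degeneracy %g exceeds expansion cap %g", d, cap),
           call = sys.call(-1L))))
  }
  out <- do.call(expand.grid,
                 c(rev(unname(.IUPAC[ch])), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reversed above so output is
  # in lexicographic-ish order of the original positions.
  apply(out[, rev(seq_along(ch)), drop = FALSE], 1L, paste, collapse = "")
}

#' Reverse complement of an IUPAC sequence
#'
#' Reverses the sequence and complements each code under the IUPAC complement
#' map (A<->T, C<->G, R<->Y, K<->M, S and W self-complementary, B<->V,
#' D<->H, N<->N). An involution: `iupac_revcomp(iupac_revcomp(x)) == x`.
#'
#' @inheritParams iupac_degeneracy
#' @return The reverse-complemented string, upper case.
#' @examples
#' iupac_revcomp("CAR")  # "YTG"
#' @export
iupac_revcomp <- function(x) {
  ch <- .check_iupac(x)
  paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Single-position primer/template base matching
#'
#' Decides whether a primer code matches a template code at one aligned
#' position. In `strict` mode (the default, appropriate for concrete
#' templates) the template character must be a member of the primer code's
#' base set; a literal ambiguity code on the template (e.g. `N` in a
#' deposited sequence) never strict-matches. In lenient mode the two base
#' sets need only intersect.
#'
#' @param primer,template Single IUPAC characters (vectorized elementwise;
#'   recycled to a common length).
#' @param strict Logical; strict set-membership (default) versus
#'   set-intersection matching.
#' @return Logical vector.
#' @examples
#' iupac_match("Y", "C")                  # TRUE
#' iupac_match("R", "N")                  # FALSE
#' iupac_match("R", "N", strict = FALSE)  # TRUE
#' @export
iupac_match <- function(primer, template, strict = TRUE) {
  p <- toupper(primer); t <- toupper(template)
  if (any(!p %in% .IUPAC_LETTERS) || any(!t %in% .IUPAC_LETTERS))
    stop("invalid IUPAC character", call. = FALSE)
  n <- max(length(p), length(t))
  p <- rep_len(p, n); t <- rep_len(t, n)
  m <- if (strict) .IUPAC_STRICT else .IUPAC_LENIENT
  m[cbind(p, t)]
}

#' Minimal IUPAC code covering a set of concrete bases
#'
#' @param bases Character vector drawn from A/C/G/T (duplicates ignored).
#' @return The single IUPAC letter whose base set is exactly `unique(bases)`.
#' @export
iupac_code <- function(bases) {
  b <- sort(unique(toupper(bases)))
  if (length(b) == 0L || any(!b %in% c("A", "C", "G", "T")))
    stop("bases must be a non-empty subset of A, C, G, T", call. = FALSE)
  unname(.IUPAC_ENCODE[paste(b, collapse = "")])
}

# Mismatch offsets (0-based from the 3' end) of a primer laid over a
# same-length template site, using the ispcr matching rule: strict for
# concrete template bases, lenient for ambiguous ones (so an N on a deposited
# reference does not abolish binding).
.site_mismatch_offsets <- function(primer_chars, site_chars) {
  n <- length(primer_chars)
  stopifnot(length(site_chars) == n)
  concrete <- site_chars %in% c("A", "C", "G", "T")
  ok <- logical(n)
  ok[concrete] <- .IUPAC_STRICT[cbind(primer_chars[concrete], site_chars[concrete])]
  if (any(!concrete)) {
    valid <- site_chars %in% .IUPAC_LETTERS
    ok[!concrete & valid] <-
      .IUPAC_LENIENT[cbind(primer_chars[!concrete & valid],
                           site_chars[!concrete & valid])]
  }
  rev_offsets <- (n - 1L):0L
  sort(rev_offsets[!ok])
}
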