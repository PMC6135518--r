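# Independent brute-force oracles, deliberately implemented differently from
# the package internals (set enumeration and per-position loops).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Exhaustive expansion by iterated outer product.
brute_expand <- function(seq) {
  out <- ""
  for (ch in strsplit(seq, "", fixed = TRUE)[[1L]])
    out <- as.vector(outer(out, IUPAC_SETS[[ch]], paste0))
  sort(out)
}

# Concrete complement/revcomp used to build expected values.
brute_revcomp_concrete <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# Does primer code p match template char t? (strict for concrete t, lenient
# for ambiguous t — the in-silico PCR rule.)
oracle_char_match <- function(p, t) {
  if (t %in% c("A", "C", "G", "T")) t %in% IUPAC_SETS[[p]]
  else length(intersect(IUPAC_SETS[[p]], IUPAC_SETS[[t]])) > 0L
}

# All qualifying sites of `primer` on the + strand of `template`, by direct
# per-position looping. Returns data.frame(start, end, mismatches).
oracle_plus_sites <- function(primer, template, max_mm = 3, clamp = 3) {
  pch <- strsplit(primer, "", fixed = TRUE)[[1L]]
  tch <- strsplit(template, "", fixed = TRUE)[[1L]]
  m <- length(pch); n <- length(tch)
  res <- list()
  for (s in seq_len(max(0L, n - m + 1L))) {
    mm <- 0L; clamp_bad <- FALSE
    for (k in seq_len(m)) {
      if (!oracle_char_match(pch[k], tch[s + k - 1L])) {
        mm <- mm + 1L
        if (m - k < clamp) clamp_bad <- TRUE
      }
    }
    if (!clamp_bad && mm <= max_mm)
      res[[length(res) + 1L]] <- c(start = s, end = s + m - 1L,
                                   mismatches = mm)
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  as.data.frame(do.call(rbind, res))
}

# Minus-strand sites found by scanning the reverse-complemented template and
# mapping coordinates back — a different route than the implementation's
# reverse-complemented primer scan.
oracle_minus_sites <- function(primer, template, max_mm = 3, clamp = 3) {
  n <- nchar(template)
  hits <- oracle_plus_sites(primer, brute_revcomp_concrete(template),
                            max_mm, clamp)
  if (!nrow(hits)) return(hits)
  out <- data.frame(start = n - hits$end + 1L, end = n - hits$start + 1L,
                    mismatches = hits$mismatches)
  out[order(out$start), , drop = FALSE]
}

# Exhaustive amplicon oracle: every forward + site combined with every
# downstream reverse - site.
oracle_amplicons <- function(forward, reverse, template, max_mm = 3,
                             clamp = 3, len_bounds = c(50, 2000)) {
  f <- oracle_plus_sites(forward, template, max_mm, clamp)
  r <- oracle_minus_sites(reverse, template, max_mm, clamp)
  res <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    if (r$start[j] <= f$end[i]) next
    len <- r$end[j] - f$start[i] + 1L
    if (len < len_bounds[1] || len > len_bounds[2]) next
    res[[length(res) + 1L]] <- c(start = f$start[i], end = r$end[j],
                                 length = len)
  }
  if (!length(res))
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$start, out$end), , drop = FALSE]
}

# Random degenerate primer for property tests: mostly concrete bases with a
# few 2-fold codes, as in real degenerate oligos.
random_degenerate_primer <- function(len = 21) {
  twofold <- c("R", "Y", "S", "W", "K", "M")
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  k <- sample(0:4, 1L)
  if (k > 0L) {
    pos <- sample(seq_len(len - 3L), k)   # keep the 3' clamp concrete
    ch[pos] <- sample(twofold, k, replace = TRUE)
  }
  paste(ch, collapse = "")
}

# Plant (a possibly corrupted expansion of) a primer site into a template at
# a given position; orientation "F" plants the oligo sense, "R" plants its
# reverse complement.
plant_site <- function(template, primer, at, orientation = "F",
                       n_errors = 0) {
  oligo <- sample(brute_expand(primer), 1L)
  if (n_errors > 0L) {
    och <- strsplit(oligo, "", fixed = TRUE)[[1L]]
    pos <- sample(seq_along(och), n_errors)
    och[pos] <- vapply(och[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    oligo <- paste(och, collapse = "")
  }
  if (orientation == "R") oligo <- brute_revcomp_concrete(oligo)
  paste0(substr(template, 1L, at - 1L), oligo,
         substr(template, at + nchar(oligo), nchar(template)))
}
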