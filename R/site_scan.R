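#' Per-column base profiles of a grouped alignment
#'
#' Splits an aligned set of sequences into target (vertebrate) and non-target
#' (mosquito) groups and computes per-column A/C/G/T/gap counts for each
#' group. The returned object also retains the character matrices needed by
#' the window-scoring functions.
#'
#' @param aln `data.frame` with columns `id`, `bases` (equal-length, gapped
#'   allowed) and `group` (`"target"` / `"non-target"`).
#' @return Object of class `vertcoi_profiles` with elements `ncol`,
#'   `n_target`, `n_nontarget`, `target_counts` and `nontarget_counts`
#'   (5 x ncol matrices, rows A,C,G,T,`-`), and the internal character
#'   matrices.
#' @export
profile_alignment <- function(aln) {
  if (!all(c("id", "bases", "group") %in% names(aln)))
    stop("alignment needs columns id, bases, group", call. = FALSE)
  if (!all(aln$group %in% c("target", "non-target")))
    stop("group labels must be 'target' or 'non-target'", call. = FALSE)
  if (!any(aln$group == "target") || !any(aln$group == "non-target"))
    stop("need at least one target and one non-target sequence",
         call. = FALSE)
  lens <- nchar(aln$bases)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: records differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(aln$bases), "", fixed = TRUE))
  rownames(mat) <- aln$id
  counts <- function(m) {
    apply(m, 2L, function(col)
      c(A = sum(col == "A"), C = sum(col == "C"), G = sum(col == "G"),
        T = sum(col == "T"), gap = sum(col == "-")))
  }
  tmat <- mat[aln$group == "target", , drop = FALSE]
  nmat <- mat[aln$group == "non-target", , drop = FALSE]
  structure(list(
    ncol = ncol(mat),
    n_target = nrow(tmat), n_nontarget = nrow(nmat),
    target_counts = counts(tmat), nontarget_counts = counts(nmat),
    target_mat = tmat, nontarget_mat = nmat),
    class = "vertcoi_profiles")
}

# Column-level statistics shared by consensus_window / score_window / scan:
# the minimal IUPAC consensus code per column (target bases at within-group
# frequency >= min_base_freq, frequencies over non-gap target bases), whether
# low-frequency target bases were dropped (tolerated target mismatches),
# target gap fractions, log2 per-column degeneracy, per-target-sequence match
# indicators, and the full/partial non-target mismatch classification.
.column_stats <- function(profiles, min_base_freq) {
  stopifnot(inherits(profiles, "vertcoi_profiles"))
  nc <- profiles$ncol
  tc <- profiles$target_counts
  nongap <- colSums(tc[c("A", "C", "G", "T"), , drop = FALSE])
  gap_frac <- tc["gap", ] / profiles$n_target

  code <- character(nc)
  dropped <- logical(nc)
  log2deg <- numeric(nc)
  for (j in seq_len(nc)) {
    if (nongap[j] == 0L) { code[j] <- NA_character_; next }
    freq <- tc[c("A", "C", "G", "T"), j] / nongap[j]
    keep <- names(freq)[freq >= min_base_freq]
    if (!length(keep)) keep <- names(freq)[which.max(freq)]
    code[j] <- iupac_code(keep)
    dropped[j] <- any(freq > 0 & freq < min_base_freq)
    log2deg[j] <- log2(length(keep))
  }

  match_mat <- function(m) {
    out <- matrix(FALSE, nrow(m), nc)
    valid <- !is.na(code)
    for (j in which(valid)) {
      col <- m[, j]
      ok <- col %in% .IUPAC_LETTERS
      res <- logical(length(col))
      res[ok] <- .ISPCR_MATCH[cbind(rep(code[j], sum(ok)), col[ok])]
      out[, j] <- res   # gaps and invalid characters mismatch
    }
    out
  }
  t_match <- match_mat(profiles$target_mat)
  n_match <- match_mat(profiles$nontarget_mat)
  n_hit <- colSums(n_match)
  list(code = code, dropped = dropped, gap_frac = gap_frac,
       log2deg = log2deg, t_match = t_match,
       full = n_hit == 0L & !is.na(code),
       partial = n_hit > 0L & n_hit < profiles$n_nontarget)
}

#' Degenerate consensus of an alignment window
#'
#' For each column in the window, the minimal IUPAC code covering every
#' target-group base whose within-group frequency (over non-gap bases) is at
#' least `min_base_freq`. Rarer bases are dropped; the target sequences that
#' carry them become tolerated target mismatches.
#'
#' @param profiles A [profile_alignment()] result.
#' @param start,len Window start column (1-based) and length.
#' @param min_base_freq Minimum within-group base frequency for inclusion in
#'   the consensus (default 0.05).
#' @return The consensus as a single IUPAC string.
#' @export
consensus_window <- function(profiles, start, len, min_base_freq = 0.05) {
  cols <- seq.int(start, start + len - 1L)
  if (start < 1L || max(cols) > profiles$ncol)
    stop("window outside alignment", call. = FALSE)
  gap_major <- profiles$target_counts["gap", cols] > profiles$n_target / 2
  if (any(gap_major))
    stop("window contains a gap-majority column", call. = FALSE)
  st <- .column_stats(profiles, min_base_freq)
  paste(st$code[cols], collapse = "")
}

.kernel <- function(offsets) 1 / (1 + offsets)

#' Score one candidate priming window
#'
#' Computes the full site-candidate record for a window: consensus,
#' target coverage (fraction of target sequences matched at every column),
#' degeneracy fold, non-target mismatch structure (full: no non-target
#' sequence matches the consensus code at the column; partial: some but not
#' all mismatch), tolerated target mismatches, specificity class, and a
#' score
#' \deqn{w_1 \cdot coverage + w_2 \sum_{full} k(o) - w_3 \log_2(degeneracy)
#'   - w_4 \sum_{target-mm} k(o)}
#' with 3'-proximity kernel \eqn{k(o) = 1/(1+o)}, `o` the 0-based offset
#' from the 3' end. Orientation decides which window edge is 3': the right
#' edge for `"forward"`, the left edge for `"reverse"` (the oligo for a
#' reverse site is the reverse complement of the sense-strand consensus).
#'
#' @inheritParams consensus_window
#' @param orientation `"forward"` or `"reverse"`.
#' @param weights Named numeric `c(w1, w2, w3, w4)`.
#' @return One-row `data.frame` (a `SiteCandidate`): `start`, `end`,
#'   `length`, `orientation`, `consensus`, `target_coverage`, `degeneracy`,
#'   `n_full`, `n_partial`, `specificity_class`, `score`, plus list-columns
#'   `full_offsets`, `partial_offsets`, `target_mismatch_offsets`.
#' @export
score_window <- function(profiles, start, len,
                         orientation = c("forward", "reverse"),
                         min_base_freq = 0.05,
                         weights = c(w1 = 1, w2 = 1, w3 = 0.1, w4 = 1)) {
  orientation <- match.arg(orientation)
  cols <- seq.int(start, start + len - 1L)
  consensus <- consensus_window(profiles, start, len, min_base_freq)
  st <- .column_stats(profiles, min_base_freq)
  offs <- if (orientation == "forward") rev(seq_along(cols)) - 1L else
    seq_along(cols) - 1L

  mm_in_window <- rowSums(!st$t_match[, cols, drop = FALSE])
  coverage <- mean(mm_in_window == 0L)
  deg <- 2^sum(st$log2deg[cols])
  full_off <- sort(offs[st$full[cols]])
  part_off <- sort(offs[st$partial[cols]])
  tmm_off <- sort(offs[st$dropped[cols]])
  score <- unname(weights["w1"]) * coverage +
    unname(weights["w2"]) * sum(.kernel(full_off)) -
    unname(weights["w3"]) * log2(deg) -
    unname(weights["w4"]) * sum(.kernel(tmm_off))
  out <- data.frame(
    start = as.integer(start), end = as.integer(start + len - 1L),
    length = as.integer(len), orientation = orientation,
    consensus = consensus, target_coverage = coverage,
    degeneracy = deg, n_full = length(full_off),
    n_partial = length(part_off),
    specificity_class = if (length(full_off)) "vertebrate universal" else
      "universal",
    score = score, stringsAsFactors = FALSE)
  out$full_offsets <- list(full_off)
  out$partial_offsets <- list(part_off)
  out$target_mismatch_offsets <- list(tmm_off)
  out
}

#' Scan a grouped alignment for candidate priming sites
#'
#' Slides windows of every length in `min_len:max_len`, in both
#' orientations, over all alignment columns; windows containing a column
#' with more than `max_target_gap_frac` gaps in the target group, windows
#' above the degeneracy cap, and windows below the coverage floor are
#' discarded. Survivors are scored as in [score_window()] and returned
#' ranked by score; ties broken by lower degeneracy, more 3'-proximal
#' non-target full mismatch, leftmost start, then longer window.
#'
#' @param aln Grouped alignment `data.frame` (see [profile_alignment()]).
#' @param min_len,max_len Window length bounds (default 20-25 bp).
#' @param max_degeneracy Degeneracy-fold cap (default 512).
#' @param min_coverage Minimum target coverage (default 0.90).
#' @param max_target_gap_frac Maximum per-column target-group gap fraction
#'   inside a window (default 0.10).
#' @inheritParams score_window
#' @return `data.frame` of ranked site candidates (see [score_window()]).
#' @export
scan_priming_sites <- function(aln, min_len = 20, max_len = 25,
                               max_degeneracy = 512, min_coverage = 0.90,
                               min_base_freq = 0.05,
                               max_target_gap_frac = 0.10,
                               weights = c(w1 = 1, w2 = 1, w3 = 0.1, w4 = 1)) {
  profiles <- profile_alignment(aln)
  if (profiles$ncol < min_len)
    stop("alignment shorter than the minimum window length", call. = FALSE)
  st <- .column_stats(profiles, min_base_freq)
  nc <- profiles$ncol
  col_ok <- st$gap_frac <= max_target_gap_frac & !is.na(st$code)

  # Sliding sums via cumulative sums.
  cs <- function(v) c(0, cumsum(v))
  win_sum <- function(v, L) { s <- cs(v); s[(L + 1L):(nc + 1L)] - s[1L:(nc - L + 1L)] }
  mm_cum <- cbind(0, t(apply(!st$t_match, 1L, cumsum)))  # n_target x (nc+1)

  res <- list()
  for (L in seq.int(min_len, max_len)) {
    starts <- seq_len(nc - L + 1L)
    valid <- win_sum(!col_ok, L) == 0
    deg <- 2^win_sum(st$log2deg, L)
    valid <- valid & deg <= max_degeneracy
    mmw <- mm_cum[, starts + L, drop = FALSE] - mm_cum[, starts, drop = FALSE]
    coverage <- colMeans(mmw == 0L)
    valid <- valid & coverage >= min_coverage
    if (!any(valid)) next
    # 3'-proximity weighted sums for both orientations.
    fw_full <- fw_tmm <- rv_full <- rv_tmm <- numeric(length(starts))
    minoff_f <- minoff_r <- rep(Inf, length(starts))
    for (k in 0:(L - 1L)) {
      colk_full <- st$full[starts + k]
      colk_tmm <- st$dropped[starts + k]
      fw_full <- fw_full + colk_full * .kernel(L - 1L - k)
      fw_tmm <- fw_tmm + colk_tmm * .kernel(L - 1L - k)
      rv_full <- rv_full + colk_full * .kernel(k)
      rv_tmm <- rv_tmm + colk_tmm * .kernel(k)
      minoff_f[colk_full & (L - 1L - k) < minoff_f] <- L - 1L - k
      minoff_r[colk_full & k < minoff_r] <- k
    }
    nfull <- win_sum(st$full, L)
    npart <- win_sum(st$partial, L)
    for (ori in c("forward", "reverse")) {
      sel <- which(valid)
      if (!length(sel)) next
      w2term <- if (ori == "forward") fw_full[sel] else rv_full[sel]
      w4term <- if (ori == "forward") fw_tmm[sel] else rv_tmm[sel]
      score <- unname(weights["w1"]) * coverage[sel] +
        unname(weights["w2"]) * w2term -
        unname(weights["w3"]) * log2(deg[sel]) -
        unname(weights["w4"]) * w4term
      res[[length(res) + 1L]] <- data.frame(
        start = as.integer(sel), end = as.integer(sel + L - 1L),
        length = L, orientation = ori,
        target_coverage = coverage[sel], degeneracy = deg[sel],
        n_full = as.integer(nfull[sel]), n_partial = as.integer(npart[sel]),
        min_full_offset = if (ori == "forward") minoff_f[sel] else
          minoff_r[sel],
        score = score, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    out <- data.frame(start = integer(), end = integer(), length = integer(),
                      orientation = character(), target_coverage = numeric(),
                      degeneracy = numeric(), n_full = integer(),
                      n_partial = integer(), min_full_offset = numeric(),
                      consensus = character(), specificity_class = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, res)
  out$consensus <- vapply(seq_len(nrow(out)), function(i)
    paste(st$code[out$start[i]:out$end[i]], collapse = ""), "")
  out$specificity_class <- ifelse(out$n_full > 0L, "vertebrate universal",
                                  "universal")
  ord <- order(-out$score, out$degeneracy, out$min_full_offset, out$start,
               -out$length, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair forward and reverse site candidates into primer pairs
#'
#' Maps candidate windows from alignment coordinates onto an ungapped
#' reference sequence and emits every forward x reverse combination whose
#' primer-inclusive amplicon length (forward window start through reverse
#' window 3' end, on the ungapped reference) lies within `length_bounds`.
#' The reverse oligo is emitted as the reverse complement of its
#' sense-strand consensus.
#'
#' When exactly one forward and one reverse candidate are supplied, an
#' invalid geometry (reverse site not downstream of the forward site, or a
#' window mapping onto a reference gap) is an error; in bulk use such
#' combinations are dropped silently.
#'
#' @param candidates Candidate table from [scan_priming_sites()] (needs
#'   `start`, `end`, `orientation`, `consensus`).
#' @param aln The grouped alignment the candidates came from.
#' @param reference_id `id` of the alignment row to use as the ungapped
#'   length reference.
#' @param length_bounds Allowed amplicon lengths, bp (default `c(100, 800)`).
#' @return `data.frame` with `forward_start`, `reverse_end` (alignment
#'   coords), `forward_seq`, `reverse_seq` (5'->3' oligos), and
#'   `amplicon_bp`.
#' @export
pair_candidates <- function(candidates, aln, reference_id,
                            length_bounds = c(100, 800)) {
  ref <- aln$bases[match(reference_id, aln$id)]
  if (is.na(ref)) stop("reference id not in alignment", call. = FALSE)
  rch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  refpos <- cumsum(rch != "-")
  is_gap <- rch == "-"
  fwd <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rev_ <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  strict <- nrow(fwd) == 1L && nrow(rev_) == 1L
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev_))) {
    f <- fwd[i, ]; r <- rev_[j, ]
    if (r$start <= f$end) {
      if (strict) stop("reverse site not downstream of forward site",
                       call. = FALSE)
      next
    }
    if (any(is_gap[f$start:f$end]) || any(is_gap[r$start:r$end])) {
      if (strict) stop("window maps onto a gap in the reference",
                       call. = FALSE)
      next
    }
    len <- refpos[r$end] - refpos[f$start] + 1L
    if (len < length_bounds[1] || len > length_bounds[2]) next
    if (len < nchar(f$consensus) + nchar(r$consensus)) next
    out[[length(out) + 1L]] <- data.frame(
      forward_start = f$start, forward_end = f$end,
      reverse_start = r$start, reverse_end = r$end,
      forward_seq = f$consensus,
      reverse_seq = iupac_revcomp(r$consensus),
      amplicon_bp = as.integer(len), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(forward_start = integer(), forward_end = integer(),
                      reverse_start = integer(), reverse_end = integer(),
                      forward_seq = character(), reverse_seq = character(),
                      amplicon_bp = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
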