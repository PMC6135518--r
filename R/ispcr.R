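# Combined primer-vs-template matching rule for in-silico PCR: strict
# set-membership when the template base is concrete, lenient set-intersection
# when the template itself carries an ambiguity code (an N in a deposited
# reference should not abolish predicted binding).
.ISPCR_MATCH <- local({
  m <- .IUPAC_LENIENT
  concrete <- c("A", "C", "G", "T")
  m[, concrete] <- .IUPAC_STRICT[, concrete]
  m
})

#' In-silico PCR matching parameters
#'
#' @param max_mismatches Maximum primer/template mismatches tolerated per
#'   primer outside the 3' clamp (default 3).
#' @param clamp Number of 3'-terminal primer bases in which no mismatch is
#'   tolerated (default 3) — mismatches there block polymerase extension.
#' @param product_length Length-2 numeric, allowed primer-inclusive product
#'   lengths in bp (default `c(50, 2000)`).
#' @return A `vertcoi_match_params` list.
#' @export
match_params <- function(max_mismatches = 3, clamp = 3,
                         product_length = c(50, 2000)) {
  stopifnot(max_mismatches >= 0, clamp >= 0,
            length(product_length) == 2L,
            product_length[1] <= product_length[2])
  structure(list(max_mismatches = as.integer(max_mismatches),
                 clamp = as.integer(clamp),
                 product_length = as.numeric(product_length)),
            class = "vertcoi_match_params")
}

.as_seq_table <- function(x, what = "sequences") {
  if (is.data.frame(x)) {
    if (!all(c("id", "bases") %in% names(x)))
      stop(what, " data.frame needs columns id, bases", call. = FALSE)
    return(x)
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x))
      names(x) <- paste0("seq", seq_along(x))
    return(data.frame(id = names(x), bases = unname(x),
                      stringsAsFactors = FALSE))
  }
  stop(what, " must be a data.frame or character vector", call. = FALSE)
}

# Scan one strand: primer characters pch against template integer codes tidx.
# Returns data.frame(start, mismatches) plus the per-position mismatch offsets
# (computed only for qualifying starts). `offset_of_k` maps primer position k
# (1-based along the scanned string) to a 0-based offset from the primer 3'.
.scan_positions <- function(pch, tidx, max_mm, clamp, offset_of_k) {
  m <- length(pch)
  n <- length(tidx)
  if (m > n) stop("primer longer than template", call. = FALSE)
  npos <- n - m + 1L
  pidx <- match(pch, .IUPAC_LETTERS)
  mm_total <- integer(npos)
  mm_clamp <- integer(npos)
  in_clamp <- offset_of_k(seq_len(m)) < clamp
  for (k in seq_len(m)) {
    bad <- !.ISPCR_MATCH[pidx[k], tidx[k:(k + npos - 1L)]]
    mm_total <- mm_total + bad
    if (in_clamp[k]) mm_clamp <- mm_clamp + bad
  }
  keep <- which(mm_total <= max_mm & mm_clamp == 0L)
  offs <- lapply(keep, function(s) {
    bad_k <- which(!.ISPCR_MATCH[cbind(pidx, tidx[s:(s + m - 1L)])])
    sort(offset_of_k(bad_k))
  })
  list(start = keep, mismatches = mm_total[keep], offsets = offs)
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands of an ungapped template for sites where the primer
#' anneals under the mismatch model: at most `max_mismatches` mismatches and
#' none within the 3' clamp. Matching is strict set-membership against
#' concrete template bases and lenient against ambiguous ones. Exhaustive and
#' deterministic.
#'
#' @param primer IUPAC primer string, 5'->3'.
#' @param template Ungapped template string (A/C/G/T/N and other ambiguity
#'   codes allowed).
#' @param params [match_params()].
#' @param template_id Optional id recorded in the result.
#' @return `data.frame` with columns `template_id`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based inclusive span on the + strand), `mismatches`,
#'   and list-column `mismatch_offsets` (0-based offsets from the primer 3'
#'   end).
#' @export
find_binding_sites <- function(primer, template, params = match_params(),
                               template_id = NA_character_) {
  stopifnot(inherits(params, "vertcoi_match_params"))
  if (grepl("-", template, fixed = TRUE))
    stop("template must be ungapped", call. = FALSE)
  pch <- .check_iupac(primer, "primer")
  tch <- .check_iupac(template, "template")
  tidx <- match(tch, .IUPAC_LETTERS)
  m <- length(pch)

  # + strand: primer 3' end is the rightmost base of the span.
  plus <- .scan_positions(pch, tidx, params$max_mismatches, params$clamp,
                          offset_of_k = function(k) m - k)
  # - strand: scan the primer's reverse complement along the + strand; the
  # primer 3' end then maps to the leftmost base of the span.
  rch <- strsplit(iupac_revcomp(primer), "", fixed = TRUE)[[1L]]
  minus <- .scan_positions(rch, tidx, params$max_mismatches, params$clamp,
                           offset_of_k = function(k) k - 1L)

  n_sites <- length(plus$start) + length(minus$start)
  res <- data.frame(
    template_id = rep(template_id, n_sites),
    strand = c(rep("+", length(plus$start)), rep("-", length(minus$start))),
    start = c(plus$start, minus$start),
    end = c(plus$start, minus$start) + m - 1L,
    mismatches = c(plus$mismatches, minus$mismatches),
    stringsAsFactors = FALSE)
  res$mismatch_offsets <- c(plus$offsets, minus$offsets)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Predict PCR products of a primer pair on a template
#'
#' Combines every forward-primer site on the + strand with every
#' reverse-primer site on the - strand lying downstream, keeping
#' primer-inclusive product lengths within `params$product_length`. An empty
#' result means no predicted amplification; it is not an error.
#'
#' @param forward,reverse IUPAC primer strings, each 5'->3' on its own strand.
#' @inheritParams find_binding_sites
#' @return `data.frame` with columns `template_id`, `start`, `end`, `length`
#'   (primer-inclusive bp), `product` (excised + strand sequence),
#'   `forward_mismatches`, `reverse_mismatches`.
#' @export
predict_amplicons <- function(forward, reverse, template,
                              params = match_params(),
                              template_id = NA_character_) {
  f <- find_binding_sites(forward, template, params, template_id)
  f <- f[f$strand == "+", , drop = FALSE]
  r <- find_binding_sites(reverse, template, params, template_id)
  r <- r[r$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    if (r$start[j] <= f$end[i]) next
    len <- r$end[j] - f$start[i] + 1L
    if (len < params$product_length[1] || len > params$product_length[2]) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id,
      start = f$start[i], end = r$end[j], length = len,
      product = substr(template, f$start[i], r$end[j]),
      forward_mismatches = f$mismatches[i],
      reverse_mismatches = r$mismatches[j],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      product = character(), forward_mismatches = integer(),
                      reverse_mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Screen a primer pair for target versatility and non-target exclusion
#'
#' Runs [predict_amplicons()] over a panel of target and non-target
#' templates and tallies amplification verdicts — the in-silico analogue of
#' gel-based versatility/specificity scoring, collapsed to amplified / none.
#'
#' @inheritParams predict_amplicons
#' @param targets,nontargets Template panels: `data.frame(id, bases)` or
#'   (named) character vectors. `nontargets` may be empty, in which case the
#'   non-target fraction is reported as `NA` (not applicable), never as a
#'   spurious 0 or 1.
#' @return List of class `vertcoi_screen`: `$verdicts` (per-template
#'   data.frame with `id`, `group`, `amplified`, `n_products`),
#'   `$target_fraction`, `$nontarget_fraction`, `$params`.
#' @export
specificity_screen <- function(forward, reverse, targets, nontargets,
                               params = match_params()) {
  tg <- .as_seq_table(targets, "targets")
  ng <- .as_seq_table(nontargets, "nontargets")
  if (nrow(tg) == 0L) stop("need at least one target template", call. = FALSE)
  one <- function(tab, group) {
    if (nrow(tab) == 0L)
      return(data.frame(id = character(), group = character(),
                        amplified = logical(), n_products = integer(),
                        stringsAsFactors = FALSE))
    n <- vapply(seq_len(nrow(tab)), function(i)
      nrow(predict_amplicons(forward, reverse, tab$bases[i], params,
                             tab$id[i])), 0L)
    data.frame(id = tab$id, group = group, amplified = n > 0L,
               n_products = n, stringsAsFactors = FALSE)
  }
  verdicts <- rbind(one(tg, "target"), one(ng, "non-target"))
  structure(list(
    verdicts = verdicts,
    target_fraction = mean(verdicts$amplified[verdicts$group == "target"]),
    nontarget_fraction = if (nrow(ng) == 0L) NA_real_ else
      mean(verdicts$amplified[verdicts$group == "non-target"]),
    params = params), class = "vertcoi_screen")
}

#' @export
print.vertcoi_screen <- function(x, ...) {
  cat("In-silico specificity screen\n")
  cat(sprintf("  targets amplified:     %d/%d (%.1f%%)\n",
              sum(x$verdicts$amplified[x$verdicts$group == "target"]),
              sum(x$verdicts$group == "target"), 100 * x$target_fraction))
  if (is.na(x$nontarget_fraction)) {
    cat("  non-targets amplified: not applicable (empty panel)\n")
  } else {
    cat(sprintf("  non-targets amplified: %d/%d (%.1f%%)\n",
                sum(x$verdicts$amplified[x$verdicts$group == "non-target"]),
                sum(x$verdicts$group == "non-target"),
                100 * x$nontarget_fraction))
  }
  cat(sprintf("  (max mismatches %d, 3' clamp %d, product %g-%g bp)\n",
              x$params$max_mismatches, x$params$clamp,
              x$params$product_length[1], x$params$product_length[2]))
  invisible(x)
}
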