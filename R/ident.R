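#' Percent identity between two sequences
#'
#' Global alignment with free end gaps (overlap alignment); identity is
#' matches divided by aligned columns, terminal-gap columns excluded. A
#' deterministic, offline surrogate for the two-sequence similarity scores
#' used in barcode identification engines. Symmetric in its arguments.
#'
#' @param a,b Ungapped nucleotide strings (IUPAC codes tolerated), each at
#'   least `min_len` long.
#' @param min_len Minimum sequence length (default 50).
#' @return Identity as a fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, min_len = 50) {
  for (s in list(a, b)) .check_iupac(s, "sequence")
  if (nchar(a) < min_len || nchar(b) < min_len)
    stop("sequence shorter than the minimum length (", min_len, ")",
         call. = FALSE)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

.as_refdb <- function(db, what = "reference database") {
  if (!is.data.frame(db) || !all(c("id", "species", "bases") %in% names(db)))
    stop(what, " must be a data.frame with columns id, species, bases",
         call. = FALSE)
  if (nrow(db) == 0L) stop(what, " is empty", call. = FALSE)
  if (anyDuplicated(db$id)) stop("duplicate reference ids", call. = FALSE)
  db
}

#' Assign a species identity to a query sequence
#'
#' Computes [pairwise_identity()] of the query to every reference and applies
#' the barcode assignment rule: a species is assigned if the best hit reaches
#' the identity threshold (inclusive, default 98%) and no second species ties
#' with it. Two species tie when their identities are equal after rounding to
#' 0.01 percentage points.
#'
#' @param query Query nucleotide string (e.g. a predicted or sequenced
#'   amplicon).
#' @param db Reference table: `data.frame(id, species, bases)`; an optional
#'   `class` column is carried through to the hit table.
#' @param threshold Assignment threshold on identity (default 0.98,
#'   inclusive).
#' @param query_id Optional label for the query.
#' @return Object of class `vertcoi_ident`: `query_id`, `hits` (data.frame
#'   `reference`, `species`, `identity`, sorted descending), `status`
#'   (`assigned` / `ambiguous` / `unassigned`), `assigned_species`,
#'   `threshold`.
#' @export
identify_host <- function(query, db, threshold = 0.98,
                          query_id = NA_character_) {
  db <- .as_refdb(db)
  ident <- vapply(db$bases, function(r) pairwise_identity(query, r), 0,
                  USE.NAMES = FALSE)
  hits <- data.frame(reference = db$id, species = db$species,
                     identity = ident, stringsAsFactors = FALSE)
  if (!is.null(db$class)) hits$class <- db$class
  hits <- hits[order(-hits$identity, hits$species, hits$reference), ,
               drop = FALSE]
  rownames(hits) <- NULL
  cand <- hits$identity >= threshold - 1e-9
  if (!any(cand)) {
    status <- "unassigned"; species <- NA_character_
  } else {
    rounded <- round(hits$identity * 100, 2)
    top <- max(rounded[cand])
    top_species <- unique(hits$species[cand & rounded == top])
    if (length(top_species) > 1L) {
      status <- "ambiguous"; species <- NA_character_
    } else {
      status <- "assigned"; species <- top_species
    }
  }
  structure(list(query_id = query_id, hits = hits, status = status,
                 assigned_species = species, threshold = threshold),
            class = "vertcoi_ident")
}

#' @export
print.vertcoi_ident <- function(x, ...) {
  cat(sprintf("Identification of %s: %s",
              if (is.na(x$query_id)) "query" else x$query_id, x$status))
  if (!is.na(x$assigned_species))
    cat(" -> ", x$assigned_species, sep = "")
  cat(sprintf("\n  best hit %.2f%% (threshold %.0f%%), %d references\n",
              100 * x$hits$identity[1], 100 * x$threshold, nrow(x$hits)))
  invisible(x)
}

#' Re-identify an unassigned query against supplementary references
#'
#' Mirrors the fallback used when a barcode database lacks the relevant
#' species or lineage: a query that failed the primary identification is
#' compared against independently obtained reference sequences only. On
#' success the status becomes `resolved_by_external_reference`; otherwise
#' the original result is returned unchanged.
#'
#' @param result An unassigned `vertcoi_ident` (precondition checked).
#' @param query The original query sequence.
#' @param external_db Supplementary references (`data.frame(id, species,
#'   bases)`).
#' @inheritParams identify_host
#' @return `vertcoi_ident`.
#' @export
resolve_external <- function(result, query, external_db, threshold = 0.98) {
  if (!inherits(result, "vertcoi_ident") || result$status != "unassigned")
    stop("resolve_external() requires an unassigned identification result",
         call. = FALSE)
  res2 <- identify_host(query, external_db, threshold, result$query_id)
  if (res2$status != "assigned") return(result)
  res2$status <- "resolved_by_external_reference"
  res2
}

#' Hierarchical amplification and identification of one blood meal
#'
#' Runs ordered in-silico PCR attempts over a blood-meal sample's template
#' fragments — by default the short 244-bp combination first, then 395, then
#' 664 — stopping at the first combination that yields a product on at least
#' one intact fragment. The product of the first success is identified
#' against the reference database; if every attempt fails the outcome status
#' is `no_amplification`.
#'
#' @param sample A blood-meal sample: list with elements `id`,
#'   `mosquito_species`, `bf_score`, `fragments` (character vector of
#'   ungapped template fragments), e.g. from [make_study()].
#' @param db Reference database (`data.frame(id, species, bases)`).
#' @param pairs Ordered primer-pair table with columns `pair`,
#'   `forward_seq`, `reverse_seq` (default: [coi_primer_pairs()] ordered
#'   shortest amplicon first).
#' @param params [match_params()].
#' @param threshold Identity threshold passed to [identify_host()].
#' @param external_db Optional supplementary references used via
#'   [resolve_external()] when the primary identification is unassigned.
#' @return Object of class `vertcoi_outcome`: `id`, `mosquito_species`,
#'   `bf_score`, `attempts` (data.frame `pair`, `success`), `product`,
#'   `identification` (`vertcoi_ident` or `NULL`), `status`.
#' @export
hierarchical_identify <- function(sample, db, pairs = NULL,
                                  params = match_params(),
                                  threshold = 0.98, external_db = NULL) {
  if (is.null(pairs)) {
    pairs <- coi_primer_pairs()
    pairs <- pairs[order(pairs$amplicon_bp), , drop = FALSE]
  }
  if (nrow(pairs) < 1L) stop("need at least one primer pair", call. = FALSE)
  attempts <- data.frame(pair = character(), success = logical(),
                         stringsAsFactors = FALSE)
  product <- NULL
  for (i in seq_len(nrow(pairs))) {
    hit <- NULL
    for (frag in sample$fragments) {
      if (nchar(frag) < max(nchar(pairs$forward_seq[i]),
                            nchar(pairs$reverse_seq[i]))) next
      amp <- predict_amplicons(pairs$forward_seq[i], pairs$reverse_seq[i],
                               frag, params, sample$id)
      if (nrow(amp)) { hit <- amp$product[1L]; break }
    }
    attempts <- rbind(attempts,
                      data.frame(pair = pairs$pair[i], success = !is.null(hit),
                                 stringsAsFactors = FALSE))
    if (!is.null(hit)) { product <- hit; break }
  }
  identification <- NULL
  if (is.null(product)) {
    status <- "no_amplification"
  } else {
    identification <- identify_host(product, db, threshold, sample$id)
    if (identification$status == "unassigned" && !is.null(external_db))
      identification <- resolve_external(identification, product, external_db,
                                         threshold)
    status <- identification$status
  }
  structure(list(id = sample$id, mosquito_species = sample$mosquito_species,
                 bf_score = sample$bf_score, attempts = attempts,
                 product = product, identification = identification,
                 status = status),
            class = "vertcoi_outcome")
}

#' @export
print.vertcoi_outcome <- function(x, ...) {
  cat(sprintf("Blood meal %s (%s, %s): %s after %d attempt(s)\n",
              x$id, x$mosquito_species, x$bf_score, x$status,
              nrow(x$attempts)))
  if (!is.null(x$identification) &&
      !is.na(x$identification$assigned_species))
    cat("  host:", x$identification$assigned_species, "\n")
  invisible(x)
}

#' Host-by-mosquito blood meal count table
#'
#' Cross-tabulates identification outcomes: one row per assigned host
#' species, plus `Unidentified` (amplified but not assigned) and
#' `No amplification` rows when applicable, one column per mosquito species.
#' Column sums equal the per-mosquito-species sample counts.
#'
#' @param outcomes List of `vertcoi_outcome` objects.
#' @return Integer matrix (possibly 0 x 0 for empty input).
#' @export
tabulate_hosts <- function(outcomes) {
  if (!length(outcomes)) return(matrix(integer(), 0L, 0L))
  ids <- vapply(outcomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  mosq <- vapply(outcomes, `[[`, "", "mosquito_species")
  host <- vapply(outcomes, function(o) {
    if (o$status == "no_amplification") return("No amplification")
    sp <- o$identification$assigned_species
    if (is.na(sp)) "Unidentified" else sp
  }, "")
  special <- c("Unidentified", "No amplification")
  lv <- c(sort(setdiff(unique(host), special)),
          intersect(special, unique(host)))
  tab <- table(factor(host, levels = lv), factor(mosq))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
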