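#' Read a FASTA file into a sequence table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a plain
#' `data.frame` with columns `id` and `bases`. Sequences are upper-cased and
#' RNA `U` is normalised to `T`. With `aligned = TRUE` the gap character `-`
#' is permitted and all records must share one length; otherwise gaps are
#' rejected.
#'
#' @param path Path to a FASTA file (any line wrapping accepted).
#' @param aligned Logical; read as a multiple alignment (equal lengths,
#'   `-` allowed)?
#' @return `data.frame` with character columns `id`, `bases`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA (", conditionMessage(e), ")",
                             call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  bases <- chartr("U", "T", toupper(as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  allowed <- .IUPAC_LETTERS
  if (aligned) {
    if (length(unique(nchar(bases))) != 1L)
      stop("ragged alignment: records differ in length", call. = FALSE)
    allowed <- c(allowed, "-")
  }
  chars <- unique(strsplit(paste(bases, collapse = ""), "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, allowed)
  if (length(bad))
    stop("invalid sequence character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data.frame(id = unname(ids), bases = unname(bases),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x Either a named character vector of sequences or a `data.frame`
#'   with columns `id` and `bases`.
#' @param path Output file path.
#' @param width Line-wrap width (default 70, always <= 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) x <- stats::setNames(x$bases, x$id)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named", call. = FALSE)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a primer definition table
#'
#' Tab-separated with columns `name`, `sequence`, `orientation` (`F` or `R`)
#' and optionally `specificity_class`. Sequences are validated against the
#' IUPAC alphabet.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `name`, `sequence`, `orientation`,
#'   `specificity_class` (NA when absent) and `degeneracy`.
#' @export
read_primers <- function(path) {
  # colClasses: a bare orientation column of F's would otherwise parse as
  # logical FALSE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(tab)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$orientation %in% c("F", "R")))
    stop("orientation must be 'F' or 'R'", call. = FALSE)
  tab$sequence <- vapply(tab$sequence,
                         function(s) paste(.check_iupac(s), collapse = ""), "")
  if (is.null(tab$specificity_class)) tab$specificity_class <- NA_character_
  tab$degeneracy <- vapply(tab$sequence, iupac_degeneracy, 0)
  tab[, c("name", "sequence", "orientation", "specificity_class", "degeneracy")]
}

#' The four published blood-meal COI primers
#'
#' The two forward and two reverse degenerate oligonucleotides designed to
#' amplify the vertebrate COI barcode region while excluding mosquito
#' templates: Mod_RepCOI_F/R (modified from a reptile barcoding pair) and the
#' de-novo VertCOI_7194_F / VertCOI_7216_R.
#'
#' @return `data.frame` as from [read_primers()].
#' @seealso [coi_primer_pairs()]
#' @export
coi_primers <- function() {
  read_primers(system.file("extdata", "vertcoi_primers.tsv",
                           package = "vertcoi", mustWork = TRUE))
}

#' The three published primer combinations
#'
#' Each pairs one forward with one reverse primer; the expected
#' primer-inclusive amplicon lengths on vertebrate COI are 664, 395 and
#' 244 bp. Ordered as used in the hierarchical identification workflow is
#' *not* implied here; see [hierarchical_identify()] for the default
#' short-amplicon-first order.
#'
#' @return `data.frame` with columns `pair`, `forward`, `reverse`,
#'   `forward_seq`, `reverse_seq`, `amplicon_bp`.
#' @export
coi_primer_pairs <- function() {
  p <- coi_primers()
  seq_of <- function(nm) p$sequence[match(nm, p$name)]
  out <- data.frame(
    pair = c("Mod_RepCOI_F+Mod_RepCOI_R",
             "VertCOI_7194_F+Mod_RepCOI_R",
             "Mod_RepCOI_F+VertCOI_7216_R"),
    forward = c("Mod_RepCOI_F", "VertCOI_7194_F", "Mod_RepCOI_F"),
    reverse = c("Mod_RepCOI_R", "Mod_RepCOI_R", "VertCOI_7216_R"),
    amplicon_bp = c(664L, 395L, 244L),
    stringsAsFactors = FALSE)
  out$forward_seq <- seq_of(out$forward)
  out$reverse_seq <- seq_of(out$reverse)
  out[, c("pair", "forward", "reverse", "forward_seq", "reverse_seq",
          "amplicon_bp")]
}

# Remove alignment gaps from a sequence string.
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
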