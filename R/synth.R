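# Evaluate expr with a temporarily seeded RNG, restoring global RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param n Length in nucleotides.
#' @param seed Optional integer seed (global RNG state is restored).
#' @return A single A/C/G/T string.
#' @export
random_dna <- function(n, seed = NULL) {
  .with_seed(seed, paste(sample(.BASES, n, replace = TRUE), collapse = ""))
}

#' Substitute a fixed fraction of positions
#'
#' Introduces exactly `round(divergence * nchar(seq))` substitutions at
#' positions drawn uniformly without replacement, each to a base different
#' from the original. Deterministic for a given seed. No indels: COI is
#' protein coding and effectively indel-free in vertebrates at this scale.
#'
#' @param seq A/C/G/T string.
#' @param divergence Fraction of positions to substitute, in `[0, 1)`.
#' @inheritParams random_dna
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(seq, divergence, seed = NULL) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)", call. = FALSE)
  ch <- .check_iupac(seq)
  k <- round(divergence * length(ch))
  if (k == 0L) return(paste(ch, collapse = ""))
  .with_seed(seed, {
    pos <- sample.int(length(ch), k)
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(.BASES, b), 1L), "")
    paste(ch, collapse = "")
  })
}

#' Parameters for a synthetic target/non-target COI alignment
#'
#' Defaults emulate the joint alignment the published primers were designed
#' from: 31 vertebrate (target) and 12 mosquito (non-target) sequences over
#' the ~658-bp COI barcode region. Divergences are substitution fractions per
#' sequence; implanted sites are windows kept invariant across targets with
#' specified discriminative columns versus all non-targets.
#'
#' @param n_target,n_nontarget Group sizes (defaults 31 and 12).
#' @param length Alignment length in bp (default 658, ungapped).
#' @param within_divergence Per-sequence divergence from the group ancestor
#'   (default 0.15, typical of a COI panel spanning several vertebrate
#'   classes — only deliberately conserved windows then survive the
#'   coverage and degeneracy filters).
#' @param between_divergence Divergence between target and non-target
#'   ancestors (default 0.25).
#' @param sites List of implanted-site specs, each a list with `start`,
#'   `length`, `orientation` (`"forward"`/`"reverse"`) and
#'   `mismatch_offsets` (0-based from the site's 3' end; empty for a
#'   universal site).
#' @return A `vertcoi_study_params` list.
#' @export
study_params <- function(n_target = 31, n_nontarget = 12, length = 658,
                         within_divergence = 0.15,
                         between_divergence = 0.25,
                         sites = list(
                           list(start = 40, length = 22,
                                orientation = "forward",
                                mismatch_offsets = c(0, 3, 7)),
                           list(start = 280, length = 22,
                                orientation = "reverse",
                                mismatch_offsets = c(0, 2)))) {
  stopifnot(within_divergence >= 0, within_divergence < 1,
            between_divergence >= 0, between_divergence < 1)
  for (s in sites) {
    stopifnot(s$start >= 1, s$start + s$length - 1 <= length,
              s$orientation %in% c("forward", "reverse"),
              all(s$mismatch_offsets >= 0),
              all(s$mismatch_offsets < s$length))
  }
  if (length(sites) > 1L) {
    iv <- t(vapply(sites, function(s) c(s$start, s$start + s$length - 1), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("implanted sites overlap", call. = FALSE)
  }
  structure(list(n_target = n_target, n_nontarget = n_nontarget,
                 length = length, within_divergence = within_divergence,
                 between_divergence = between_divergence, sites = sites),
            class = "vertcoi_study_params")
}

# First concrete base NOT matching an IUPAC code (used to force full
# non-target mismatches and 3'-clamp mismatches).
.mismatch_base <- function(code) {
  setdiff(.BASES, .IUPAC[[toupper(code)]])[1L]
}

# Deterministic concretization of a degenerate sequence: first base of each
# code's set.
.concretize <- function(seq) {
  ch <- .check_iupac(seq)
  paste(vapply(.IUPAC[ch], `[[`, "", 1L), collapse = "")
}

#' Generate a grouped alignment with implanted priming sites
#'
#' Radiates target and non-target groups from a common ancestor at the
#' configured divergences, then overwrites each implanted window: invariant
#' across all targets, and carrying, at the specified 3'-relative offsets, a
#' base in every non-target that matches no target base (a full
#' vertebrate/mosquito mismatch). The two columns flanking each implanted
#' window are made polymorphic among targets so that the implanted window —
#' not a shifted or extended neighbour — is the uniquely best-scoring
#' candidate. Ungapped and equal-length throughout, as expected for
#' protein-coding COI.
#'
#' @param params [study_params()].
#' @inheritParams random_dna
#' @return List: `aln` (data.frame `id`, `bases`, `group`) and `sites` (the
#'   ground-truth ledger: data.frame `start`, `end`, `length`,
#'   `orientation`, plus list-column `mismatch_offsets`).
#' @export
make_alignment <- function(params = study_params(), seed = NULL) {
  stopifnot(inherits(params, "vertcoi_study_params"))
  .with_seed(seed, {
    L <- params$length
    anc <- random_dna(L)
    targets <- vapply(seq_len(params$n_target), function(i)
      mutate_sequence(anc, params$within_divergence), "")
    nt_anc <- mutate_sequence(anc, params$between_divergence)
    nontargets <- vapply(seq_len(params$n_nontarget), function(i)
      mutate_sequence(nt_anc, params$within_divergence), "")

    tmat <- do.call(rbind, strsplit(targets, "", fixed = TRUE))
    nmat <- do.call(rbind, strsplit(nontargets, "", fixed = TRUE))
    anc_ch <- strsplit(anc, "", fixed = TRUE)[[1L]]

    for (s in params$sites) {
      cols <- seq.int(s$start, s$start + s$length - 1L)
      # conserved across targets
      tmat[, cols] <- matrix(anc_ch[cols], nrow(tmat), length(cols),
                             byrow = TRUE)
      nmat[, cols] <- matrix(anc_ch[cols], nrow(nmat), length(cols),
                             byrow = TRUE)
      # discriminative columns: every non-target differs from the target base
      mm_cols <- if (s$orientation == "forward")
        s$start + s$length - 1L - s$mismatch_offsets else
        s$start + s$mismatch_offsets
      for (j in mm_cols) nmat[, j] <- .mismatch_base(anc_ch[j])
      # polymorphic (but non-discriminative) flanks delimit the site: targets
      # split between the ancestral base and one alternative, non-targets
      # keep the ancestral base, which the flank's consensus code covers
      for (j in c(s$start - 1L, s$start + s$length)) {
        if (j < 1L || j > L) next
        alt <- setdiff(.BASES, anc_ch[j])[1L]
        half <- seq_len(ceiling(nrow(tmat) / 2))
        tmat[half, j] <- anc_ch[j]
        tmat[-half, j] <- alt
        nmat[, j] <- anc_ch[j]
      }
    }
    aln <- data.frame(
      id = c(sprintf("VERT%02d", seq_len(params$n_target)),
             sprintf("MOSQ%02d", seq_len(params$n_nontarget))),
      bases = c(apply(tmat, 1L, paste, collapse = ""),
                apply(nmat, 1L, paste, collapse = "")),
      group = c(rep("target", params$n_target),
                rep("non-target", params$n_nontarget)),
      stringsAsFactors = FALSE)
    ledger <- data.frame(
      start = vapply(params$sites, `[[`, 0, "start"),
      length = vapply(params$sites, function(s) s$length, 0),
      orientation = vapply(params$sites, `[[`, "", "orientation"),
      stringsAsFactors = FALSE)
    ledger$end <- ledger$start + ledger$length - 1
    ledger$mismatch_offsets <- lapply(params$sites, `[[`, "mismatch_offsets")
    list(aln = aln, sites = ledger[, c("start", "end", "length",
                                       "orientation", "mismatch_offsets")])
  })
}

#' Blood-meal digestion parameters
#'
#' Maps the visual digestion score (BF1 fresh to BF3 well-digested) to a
#' per-internucleotide-bond break probability. The defaults encode only the
#' ordering fresh < digested: BF1 templates are intact, BF2 lightly
#' fragmented, BF3 fragmented enough that long amplicons usually fail while
#' short ones often survive.
#'
#' @param bf_map Named numeric: break probability per bond for BF1, BF2, BF3
#'   (default `c(BF1 = 0, BF2 = 0.002, BF3 = 0.010)`), nondecreasing, in
#'   `[0, 1)`.
#' @return A `vertcoi_degradation_params` list.
#' @export
degradation_params <- function(bf_map = c(BF1 = 0, BF2 = 0.002,
                                          BF3 = 0.010)) {
  stopifnot(identical(names(bf_map), c("BF1", "BF2", "BF3")),
            all(bf_map >= 0), all(bf_map < 1), !is.unsorted(bf_map))
  structure(list(bf_map = bf_map), class = "vertcoi_degradation_params")
}

#' Fragment a template by random strand breaks
#'
#' Each of the `n - 1` internucleotide bonds breaks independently with
#' probability `lambda`; the fragments are the maximal unbroken runs, so a
#' fixed span of length `L` survives intact with probability
#' `(1 - lambda)^(L - 1)` — shorter fragments persist, which is why short
#' amplicons out-amplify long ones on digested blood meals.
#'
#' @param seq Template string.
#' @param lambda Per-bond break probability; alternatively supply `bf_score`
#'   and `dp` to resolve it from the digestion map.
#' @param bf_score `"BF1"`, `"BF2"` or `"BF3"` (used when `lambda` is NULL).
#' @param dp [degradation_params()].
#' @inheritParams random_dna
#' @return Character vector of fragments; their lengths sum to `nchar(seq)`.
#' @export
degrade_template <- function(seq, lambda = NULL, bf_score = NULL,
                             dp = degradation_params(), seed = NULL) {
  if (is.null(lambda)) {
    if (is.null(bf_score)) stop("supply lambda or bf_score", call. = FALSE)
    lambda <- dp$bf_map[[match.arg(bf_score, c("BF1", "BF2", "BF3"))]]
  }
  stopifnot(lambda >= 0, lambda < 1)
  n <- nchar(seq)
  if (n <= 1L || lambda == 0) return(seq)
  .with_seed(seed, {
    breaks <- which(runif(n - 1L) < lambda)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, n)
    substring(seq, starts, ends)
  })
}

# Sense-strand site geometry (1-based offsets relative to the forward-primer
# start) reproducing the published 244/395/664 primer-inclusive amplicons:
#   Mod_RepCOI_F at [0, 21], VertCOI_7216_R sense site at [221, 243],
#   VertCOI_7194_F at [269, 293], Mod_RepCOI_R sense site at [643, 663].
.COI_SITE_GEOMETRY <- data.frame(
  primer = c("Mod_RepCOI_F", "VertCOI_7216_R", "VertCOI_7194_F",
             "Mod_RepCOI_R"),
  offset = c(0L, 221L, 269L, 643L),
  orientation = c("F", "R", "F", "R"),
  # mosquito-mismatched (vertebrate universal) sites; Mod_RepCOI_R is
  # universal and stays intact in non-targets
  discriminative = c(TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

# Build a sense-strand template carrying one concrete expansion of each
# printed primer at the published amplicon geometry. flank5 gives the
# 1-based start of the forward Mod_RepCOI_F site minus one.
#
# VertCOI_7194_F and VertCOI_7216_R target the same conserved motif on
# opposite strands, so a site that matches one perfectly also matches the
# other; a template realizing exactly the three published product lengths
# must therefore carry, at each of those two sites, a mismatch that the
# site's own primer tolerates at its 5' end but that falls inside the
# cross-annealing primer's 3' clamp. Positions: the first base of the
# VertCOI_7194_F site (blocks VertCOI_7216_R's clamp) and the last sense
# base of the VertCOI_7216_R site (blocks VertCOI_7194_F's clamp).
.build_site_template <- function(backbone, flank5) {
  p <- coi_primers()
  ch <- strsplit(backbone, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(.COI_SITE_GEOMETRY))) {
    g <- .COI_SITE_GEOMETRY[i, ]
    oligo <- .concretize(p$sequence[match(g$primer, p$name)])
    sense <- if (g$orientation == "F") oligo else iupac_revcomp(oligo)
    pos <- flank5 + g$offset + seq_len(nchar(sense))
    ch[pos] <- strsplit(sense, "", fixed = TRUE)[[1L]]
  }
  ch[flank5 + 269L + 1L] <- .mismatch_base("C")   # 7194_F site, 5' base
  ch[flank5 + 221L + 23L] <- .mismatch_base("G")  # 7216_R site, 5' base
  paste(ch, collapse = "")
}

# Introduce 3'-clamp mismatches (offsets 0 and 1) against the full degenerate
# primer at each discriminative site of a sense-strand template.
.knockout_sites <- function(template, flank5) {
  p <- coi_primers()
  ch <- strsplit(template, "", fixed = TRUE)[[1L]]
  for (i in which(.COI_SITE_GEOMETRY$discriminative)) {
    g <- .COI_SITE_GEOMETRY[i, ]
    pseq <- strsplit(p$sequence[match(g$primer, p$name)], "", fixed = TRUE)[[1L]]
    m <- length(pseq)
    for (off in 0:1) {
      if (g$orientation == "F") {
        pos <- flank5 + g$offset + m - off
        ch[pos] <- .mismatch_base(pseq[m - off])
      } else {
        # the reverse primer's 3' end maps to the leftmost sense position;
        # a sense base b matches primer code c iff b is in the expansion of
        # complement(c)
        pos <- flank5 + g$offset + 1L + off
        ch[pos] <- .mismatch_base(.IUPAC_COMPLEMENT[[pseq[m - off]]])
      }
    }
  }
  paste(ch, collapse = "")
}

#' Synthetic full-length vertebrate COI-like template
#'
#' A synthetic stand-in for a full-length vertebrate COI sequence: a random
#' backbone carrying one concrete expansion of each of the four printed
#' primers at the sense-strand geometry that yields the published
#' primer-inclusive amplicons (244, 395 and 664 bp). Suitable for exercising
#' in-silico PCR when no real reference sequence is available offline. A
#' pre-generated copy (seed 1) ships as
#' `extdata/synthetic_vertebrate_coi.fasta`.
#'
#' @param length Total template length (default 1540, about a full COI gene).
#' @param flank5 Bases upstream of the forward Mod_RepCOI_F site
#'   (default 450).
#' @inheritParams random_dna
#' @return A single sequence string.
#' @export
synthetic_coi_template <- function(length = 1540, flank5 = 450,
                                   seed = NULL) {
  stopifnot(flank5 + 664 + 1 <= length)
  .with_seed(seed, .build_site_template(random_dna(length), flank5))
}

#' Generate a complete synthetic blood-meal study
#'
#' Ties the whole pipeline together in silico: a panel of vertebrate host
#' species radiated from a common COI-like template that carries intact
#' printed-primer sites (conserved across vertebrates), mosquito sequences
#' with 3'-clamp knockouts at the vertebrate-universal sites (the universal
#' Mod_RepCOI_R site stays intact), blood-meal samples with known hosts and
#' digestion-dependent template fragmentation, and a reference database that
#' can withhold species to exercise the external-resolution path.
#'
#' @param n_samples Number of blood meals (default 61).
#' @param n_hosts,n_mosquitoes Species-pool sizes (defaults 10 and 6).
#' @param host_divergence Between-host-species divergence outside primer
#'   sites (default 0.10).
#' @param mosquito_divergence Mosquito divergence from the vertebrate
#'   backbone outside primer sites (default 0.20).
#' @param bf_probs Sampling probabilities of digestion scores BF1-BF3
#'   (default `c(0.45, 0.45, 0.10)`: mostly fresh, occasionally
#'   well-digested).
#' @param dp [degradation_params()].
#' @param withhold_hosts Character vector of host species withheld from the
#'   primary database and placed in the external one (default none).
#' @param template_length Host template length (default 720).
#' @inheritParams random_dna
#' @return List: `samples` (list of blood-meal samples: `id`,
#'   `mosquito_species`, `bf_score`, `true_host`, `fragments`), `db` and
#'   `external_db` (reference data.frames `id`, `species`, `bases`,
#'   `provenance`), `hosts`, `mosquito_refs` (data.frame `id`, `bases`),
#'   `pairs` ([coi_primer_pairs()] ordered short-first).
#' @export
make_study <- function(n_samples = 61, n_hosts = 10, n_mosquitoes = 6,
                       host_divergence = 0.10, mosquito_divergence = 0.20,
                       bf_probs = c(BF1 = 0.45, BF2 = 0.45, BF3 = 0.10),
                       dp = degradation_params(),
                       withhold_hosts = character(),
                       template_length = 720, seed = NULL) {
  flank5 <- 25L
  stopifnot(flank5 + 664 + 1 <= template_length)
  .with_seed(seed, {
    backbone <- random_dna(template_length)
    host_names <- sprintf("Host_species_%02d", seq_len(n_hosts))
    mosq_names <- sprintf("Mosquito_species_%d", seq_len(n_mosquitoes))

    host_seqs <- vapply(host_names, function(h)
      .build_site_template(mutate_sequence(backbone, host_divergence),
                           flank5), "")
    mosq_seqs <- vapply(mosq_names, function(m)
      .knockout_sites(
        .build_site_template(mutate_sequence(backbone, mosquito_divergence),
                             flank5), flank5), "")

    refs <- data.frame(id = paste0("REF_", host_names),
                       species = host_names,
                       bases = unname(host_seqs),
                       provenance = "primary", stringsAsFactors = FALSE)
    withheld <- refs$species %in% withhold_hosts
    external <- refs[withheld, , drop = FALSE]
    external$provenance <- rep("external-supplement", nrow(external))

    samples <- lapply(seq_len(n_samples), function(i) {
      host <- sample(host_names, 1L)
      bf <- sample(names(bf_probs), 1L, prob = bf_probs)
      list(id = sprintf("BM%03d", i),
           mosquito_species = sample(mosq_names, 1L),
           bf_score = bf,
           true_host = host,
           fragments = degrade_template(host_seqs[[host]], bf_score = bf,
                                        dp = dp))
    })
    pairs <- coi_primer_pairs()
    pairs <- pairs[order(pairs$amplicon_bp), , drop = FALSE]
    list(samples = samples,
         db = refs[!withheld, , drop = FALSE],
         external_db = external,
         hosts = host_names,
         mosquito_refs = data.frame(id = mosq_names,
                                    bases = unname(mosq_seqs),
                                    stringsAsFactors = FALSE),
         pairs = pairs)
  })
}
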