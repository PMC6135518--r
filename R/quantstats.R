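#' Convert a mass concentration to molarity for a dsDNA amplicon
#'
#' `nM = ng_ul * 1e6 / (mass_per_bp * length_bp)`, with the community
#' standard 660 g/mol per double-stranded base pair. Linear in concentration
#' and inversely proportional to amplicon length — the correction used to
#' compare product yields across primer combinations that amplify different
#' fragment sizes.
#'
#' @param ng_ul Concentration(s) in ng/ul, >= 0.
#' @param length_bp Amplicon length(s) in bp, >= 1.
#' @param mass_per_bp Average dsDNA molar mass per bp (g/mol; default 660).
#' @return Concentration(s) in nM.
#' @export
ng_to_nM <- function(ng_ul, length_bp, mass_per_bp = 660) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  if (any(ng_ul < 0)) stop("concentration must be >= 0", call. = FALSE)
  ng_ul * 1e6 / (mass_per_bp * length_bp)
}

#' Classify a PCR product by concentration
#'
#' Sufficiency for Sanger sequencing uses the strict `> 45 nM` rule; the gel
#' band category is an operationalisation of qualitative strong/weak/none
#' calls with configurable thresholds: `none < weak_min <= weak <=
#' sufficiency < strong`.
#'
#' @param conc_nM Product concentration(s), nM, >= 0.
#' @param sufficiency Sequencing-sufficiency threshold, strict (default 45).
#' @param weak_min Lower bound of a weak band (default 10).
#' @return `data.frame` with columns `conc_nM`, `sufficient` (logical) and
#'   `band` (`"none"`/`"weak"`/`"strong"`).
#' @export
classify_product <- function(conc_nM, sufficiency = 45, weak_min = 10) {
  if (any(conc_nM < 0)) stop("concentration must be >= 0", call. = FALSE)
  band <- ifelse(conc_nM > sufficiency, "strong",
                 ifelse(conc_nM >= weak_min, "weak", "none"))
  data.frame(conc_nM = conc_nM, sufficient = conc_nM > sufficiency,
             band = band, stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  need <- c("template_category", "primer_combination", "conc_nM")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  records$template_category <- factor(records$template_category)
  records$primer_combination <- factor(records$primer_combination)
  records
}

.anova_table <- function(fit, sources) {
  a <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      # perfect-fit F ratios are reported as NaN below, not warned about
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- data.frame(Source = sources,
                    Df = a$Df, SumSq = a$`Sum Sq`, MeanSq = a$`Mean Sq`,
                    F = a$`F value`, P = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # a degenerate (e.g. constant) response leaves only rounding noise in the
  # decomposition; F is then undefined rather than a ratio of noise terms
  if (sum(out$SumSq) <= 1e-10 * max(1, abs(mean(fit$model[[1L]])))) {
    out$F <- ifelse(is.na(out$F), out$F, NaN)
    out$P <- ifelse(is.na(out$P), out$P, NaN)
  }
  class(out) <- c("vertcoi_anova", "data.frame")
  out
}

#' Fully crossed two-way ANOVA of product concentration
#'
#' Fixed-effects ANOVA of `conc_nM` on primer combination, template category
#' and their interaction. The design must be complete (every primer x
#' template cell non-empty); an empty cell is an explicit error. With a
#' 3-level primer factor and 6-level template factor over N records the
#' residual df is `N - 1 - 2 - 5 - 10`.
#'
#' @param records `data.frame` with columns `primer_combination`,
#'   `template_category`, `conc_nM`.
#' @return `data.frame` of class `vertcoi_anova` with rows Primer, Template,
#'   Primer:Template, Residuals and columns `Source`, `Df`, `SumSq`,
#'   `MeanSq`, `F`, `P`. With zero residual variance F is reported as NaN,
#'   not an error.
#' @export
crossed_anova <- function(records) {
  records <- .check_records(records)
  if (nlevels(records$primer_combination) < 2L ||
      nlevels(records$template_category) < 2L)
    stop("need at least two levels per factor", call. = FALSE)
  cells <- table(records$primer_combination, records$template_category)
  if (any(cells == 0L))
    stop("unbalanced design: empty primer x template cell(s)", call. = FALSE)
  fit <- stats::lm(conc_nM ~ primer_combination * template_category,
                   data = records)
  .anova_table(fit, c("Primer", "Template", "Primer:Template", "Residuals"))
}

#' One-way ANOVA of vertebrate-only product concentrations
#'
#' Restricts the records to vertebrate template categories (mosquito
#' templates and negative controls excluded) and decomposes `conc_nM` by
#' primer combination.
#'
#' @inheritParams crossed_anova
#' @param vertebrate_categories Template categories retained (default the
#'   four terrestrial vertebrate classes).
#' @return `vertcoi_anova` with rows Primer and Residuals.
#' @export
oneway_anova <- function(records,
                         vertebrate_categories = c("Amphibia", "Aves",
                                                   "Mammalia", "Reptilia")) {
  records <- .check_records(records)
  records <- droplevels(
    records[records$template_category %in% vertebrate_categories, ,
            drop = FALSE])
  if (nrow(records) == 0L) stop("no vertebrate records", call. = FALSE)
  if (nlevels(records$primer_combination) < 2L)
    stop("need at least two primer levels", call. = FALSE)
  fit <- stats::lm(conc_nM ~ primer_combination, data = records)
  .anova_table(fit, c("Primer", "Residuals"))
}

#' @export
print.vertcoi_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$SumSq <- round(y$SumSq); y$MeanSq <- round(y$MeanSq)
  y$F <- round(y$F, 2); y$P <- signif(y$P, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# Compact letter display by insert-and-absorb over significant pairs.
.letter_display <- function(levels_ordered, sig_pairs) {
  cols <- list(levels_ordered)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[k, 1L]; b <- sig_pairs[k, 2L]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col)
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      else nxt <- c(nxt, list(col))
    }
    nxt <- nxt[lengths(nxt) > 0L]
    sig <- vapply(nxt, function(s) paste(sort(s), collapse = "\r"), "")
    nxt <- nxt[!duplicated(sig)]
    absorb <- vapply(seq_along(nxt), function(i)
      any(vapply(seq_along(nxt), function(j)
        i != j && all(nxt[[i]] %in% nxt[[j]]), TRUE)), TRUE)
    cols <- nxt[!absorb]
  }
  # order letter groups by their most prominent (earliest-ordered) level
  first <- vapply(cols, function(col)
    min(match(col, levels_ordered)), 0)
  cols <- cols[order(first)]
  vapply(levels_ordered, function(lv)
    paste(letters[which(vapply(cols, function(col) lv %in% col, TRUE))],
          collapse = ""), "")
}

#' Tukey HSD compact letter display
#'
#' All pairwise comparisons between the levels of one factor with the
#' studentized-range (Tukey HSD) test, summarised as letters: levels sharing
#' a letter are not significantly different at `alpha`.
#'
#' @inheritParams crossed_anova
#' @param factor_name `"template_category"` or `"primer_combination"`.
#' @param alpha Familywise significance level (default 0.05).
#' @return `data.frame` with columns `level`, `mean`, `n`, `letters`,
#'   ordered by decreasing mean.
#' @export
tukey_groups <- function(records, factor_name = c("template_category",
                                                  "primer_combination"),
                         alpha = 0.05) {
  factor_name <- match.arg(factor_name)
  records <- .check_records(records)
  f <- droplevels(records[[factor_name]])
  if (nlevels(f) < 2L) stop("need at least two levels", call. = FALSE)
  dat <- data.frame(y = records$conc_nM, f = f)
  fit <- stats::aov(y ~ f, data = dat)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
  means <- tapply(dat$y, dat$f, mean)
  ord <- names(sort(means, decreasing = TRUE))
  pairs_ <- do.call(rbind, strsplit(rownames(hsd), "-", fixed = TRUE))
  sig <- pairs_[hsd[, "p adj"] < alpha, , drop = FALSE]
  letters_ <- .letter_display(ord, sig)
  data.frame(level = ord,
             mean = unname(means[ord]),
             n = as.integer(table(dat$f)[ord]),
             letters = unname(letters_[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a concentration record table
#'
#' Tab-separated records with columns `template_category`,
#' `primer_combination` and either `conc_nM` directly or `conc_ng_ul` plus
#' `amplicon_length` (then converted via [ng_to_nM()]). When both are
#' present their consistency is checked.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of quantification records.
#' @export
read_quant_records <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("template_category", "primer_combination")
  if (!all(need %in% names(tab)))
    stop("records TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  has_nm <- "conc_nM" %in% names(tab)
  has_ng <- all(c("conc_ng_ul", "amplicon_length") %in% names(tab))
  if (!has_nm && !has_ng)
    stop("need conc_nM, or conc_ng_ul plus amplicon_length", call. = FALSE)
  if (has_ng) {
    nm <- ng_to_nM(tab$conc_ng_ul, tab$amplicon_length)
    if (has_nm && any(abs(nm - tab$conc_nM) > 0.05 * pmax(tab$conc_nM, 1)))
      stop("conc_nM inconsistent with conc_ng_ul under the 660 g/mol rule",
           call. = FALSE)
    if (!has_nm) tab$conc_nM <- nm
  }
  tab
}

#' Simulate a product-concentration data set
#'
#' Generates records for a complete primer x template design with the
#' replicate counts of the validation experiment by default (93 vertebrate
#' blood-meal templates split 9/51/17/16 across classes, 14 mosquito-only
#' extracts, 4 negative controls, each amplified with all three primer
#' combinations). Cell means are additive in a template-category effect and
#' a primer effect; with all effects zero this simulates the null used for
#' type-I-error calibration.
#'
#' @param n_per_category Named replicate counts per template category.
#' @param category_means Named mean nM per template category.
#' @param primer_effects Named additive effects of the three combinations.
#' @param sd Residual standard deviation, nM (default 60).
#' @inheritParams random_dna
#' @return Quantification records `data.frame` (`extract`,
#'   `template_category`, `primer_combination`, `conc_nM`).
#' @export
simulate_quant_records <- function(
    n_per_category = c(Amphibia = 9, Aves = 51, Mammalia = 17,
                       Reptilia = 16, mosquito = 14, negative = 4),
    category_means = c(Amphibia = 150, Aves = 220, Mammalia = 160,
                       Reptilia = 200, mosquito = 15, negative = 5),
    primer_effects = c("664-pair" = 0, "395-pair" = 10, "244-pair" = 60),
    sd = 60, seed = NULL) {
  stopifnot(all(names(n_per_category) %in% names(category_means)))
  .with_seed(seed, {
    rows <- list()
    for (cat in names(n_per_category)) {
      for (i in seq_len(n_per_category[[cat]])) {
        extract <- sprintf("%s_%02d", cat, i)
        for (pr in names(primer_effects)) {
          mu <- category_means[[cat]] + primer_effects[[pr]]
          rows[[length(rows) + 1L]] <- data.frame(
            extract = extract, template_category = cat,
            primer_combination = pr,
            conc_nM = max(0, stats::rnorm(1L, mu, sd)),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
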