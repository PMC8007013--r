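#' Filter GWAS records to gene neighborhoods and a p-value threshold
#'
#' Keeps the records whose position falls within any gene interval
#' expanded by `pad` base pairs on both sides (boundaries inclusive, so
#' a record exactly `pad` bp outside the gene is retained) on the same
#' chromosome, and whose p-value is strictly below `alpha`.
#'
#' @param records Data.frame with columns `variant`, `chrom`, `pos`
#'   (1-based), `p`.
#' @param genes Data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param pad Non-negative padding in bp (default 6000).
#' @param alpha Significance cutoff in (0,1); strict `<` (default 0.05).
#' @return The retained subset of `records` (possibly empty), row order
#'   preserved.
#' @export
filter_gwas_region <- function(records, genes, pad = 6000L, alpha = 0.05) {
  stopifnot(all(c("variant", "chrom", "pos", "p") %in% names(records)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)),
            pad >= 0L, alpha > 0, alpha < 1)
  if (any(records$p <= 0 | records$p > 1)) stop("p-values must lie in (0, 1]")
  if (any(genes$start > genes$end)) stop("gene intervals need start <= end")
  in_region <- vapply(seq_len(nrow(records)), function(i) {
    g <- genes[genes$chrom == records$chrom[i], , drop = FALSE]
    any(records$pos[i] >= g$start - pad & records$pos[i] <= g$end + pad)
  }, logical(1))
  records[in_region & records$p < alpha, , drop = FALSE]
}

#' Probability a diploid individual carries at least one copy of an allele
#'
#' Under Hardy-Weinberg random mating, `1 - (1 - maf)^2`.
#'
#' @param maf Allele frequency in `[0, 1]` (vectorized).
#' @return Probability in `[0, 1]`.
#' @export
carrier_probability <- function(maf) {
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) stop("maf must lie in [0, 1]")
  1 - (1 - maf)^2
}

#' Probability of carrying at least one variant from a set
#'
#' Assuming Hardy-Weinberg genotypes and independence across variants
#' (no linkage disequilibrium), `1 - prod((1 - maf_i)^2)`.  The
#' `"allelic"` model counts alleles rather than diploid genotypes:
#' `1 - prod(1 - maf_i)`.  Missing frequencies are skipped with a
#' message, since a missing cell means unmeasured, not absent.
#'
#' @param mafs Numeric vector of allele frequencies in `[0, 1]`,
#'   `NA` = missing.
#' @param model `"hwe"` (diploid, default) or `"allelic"`.
#' @return Probability in `[0, 1]`.
#' @export
prob_any_variant <- function(mafs, model = c("hwe", "allelic")) {
  model <- match.arg(model)
  if (anyNA(mafs)) {
    message("skipping ", sum(is.na(mafs)), " missing frequency value(s)")
    mafs <- mafs[!is.na(mafs)]
  }
  if (length(mafs) == 0L) stop("no usable allele frequencies")
  if (any(mafs < 0 | mafs > 1)) stop("maf must lie in [0, 1]")
  miss <- if (model == "hwe") (1 - mafs)^2 else (1 - mafs)
  1 - prod(miss)
}

#' Per-population probability of at least one variant, versus global
#'
#' For each population column of a frequency table, computes
#' [prob_any_variant()] over the chosen variants and compares it with
#' the probability under the global column, as both a ratio and a
#' difference (the comparison convention differs between studies, so
#' both are reported).
#'
#' @param freq A `pop_freq` table ([read_frequency_table()]).
#' @param variants Variant ids to include (default: all rows).
#' @param model Passed to [prob_any_variant()].
#' @return Data.frame with columns `population`, `n_variants` (non-NA
#'   frequencies used), `p_any`, `p_any_global`, `ratio`, `difference`.
#' @export
population_risk <- function(freq, variants = NULL, model = "hwe") {
  stopifnot(inherits(freq, "pop_freq"))
  global <- attr(freq, "global_col")
  if (is.na(global)) stop("frequency table has no Global/Overall column")
  rows <- if (is.null(variants)) seq_len(nrow(freq)) else {
    idx <- match(variants, freq$variant)
    if (anyNA(idx)) stop("unknown variant id '", variants[is.na(idx)][1], "'")
    idx
  }
  pops <- attr(freq, "populations")
  p_global <- suppressMessages(
    prob_any_variant(freq[[global]][rows], model = model))
  out <- lapply(pops, function(p) {
    m <- freq[[p]][rows]
    data.frame(population = p, n_variants = sum(!is.na(m)),
               p_any = suppressMessages(prob_any_variant(m, model = model)),
               p_any_global = p_global)
  })
  out <- do.call(rbind, out)
  out$ratio <- out$p_any / out$p_any_global
  out$difference <- out$p_any - out$p_any_global
  out
}

#' Flag population frequencies that deviate from the global frequency
#'
#' A (variant, population) cell is flagged when it is far from the
#' global frequency in absolute terms (`|pop - global| >=
#' abs_threshold`) or in fold terms (`max/min >= fold_threshold`, with
#' the population frequency at least 0.001 so that noise on rare
#' variants does not fire the fold rule).  Thresholds are explicit
#' configuration; the defaults (0.10 absolute, 5-fold) mark skews of
#' the size seen for known population-stratified warfarin-response
#' variants.
#'
#' @param freq A `pop_freq` table with a Global/Overall column.
#' @param abs_threshold Absolute difference threshold (default 0.10).
#' @param fold_threshold Fold-change threshold (default 5).
#' @param eps Guard for fold changes against 0 (default 1e-6).
#' @return Data.frame with one row per non-missing (variant,
#'   population) cell: `variant`, `population`, `pop_maf`, `global_maf`,
#'   `abs_diff`, `fold_change`, `flagged`.
#' @export
skew_scan <- function(freq, abs_threshold = 0.10, fold_threshold = 5,
                      eps = 1e-6) {
  stopifnot(inherits(freq, "pop_freq"))
  global <- attr(freq, "global_col")
  if (is.na(global)) stop("frequency table has no Global/Overall column")
  pops <- setdiff(attr(freq, "populations"), global)
  rows <- lapply(pops, function(p) {
    data.frame(variant = freq$variant, population = p,
               pop_maf = freq[[p]], global_maf = freq[[global]])
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$pop_maf) & !is.na(out$global_maf), , drop = FALSE]
  out$abs_diff <- abs(out$pop_maf - out$global_maf)
  hi <- pmax(out$pop_maf, out$global_maf)
  lo <- pmin(out$pop_maf, out$global_maf)
  out$fold_change <- hi / pmax(lo, eps)
  out$flagged <- out$abs_diff >= abs_threshold |
    (out$fold_change >= fold_threshold & out$pop_maf >= 0.001)
  rownames(out) <- NULL
  out
}

#' Maximum frequency of a variant over a subset of populations
#'
#' Supports statements like "rare elsewhere (maximum x% among other
#' populations)": the maximum and arg-max population frequency of one
#' variant over all populations except those excluded.
#'
#' @param freq A `pop_freq` table.
#' @param variant Variant id (must match exactly one row).
#' @param exclude Populations to leave out (the focal population plus,
#'   by default, the Global/Overall column).
#' @param include_global Keep the Global/Overall column in the scan?
#' @return List with `max` and `population`.
#' @export
max_other_population <- function(freq, variant, exclude = character(),
                                 include_global = FALSE) {
  stopifnot(inherits(freq, "pop_freq"))
  i <- which(freq$variant == variant)
  if (length(i) == 0L) stop("unknown variant id '", variant, "'")
  i <- i[1]
  pops <- setdiff(attr(freq, "populations"), exclude)
  if (!include_global && !is.na(attr(freq, "global_col"))) {
    pops <- setdiff(pops, attr(freq, "global_col"))
  }
  vals <- vapply(pops, function(p) freq[[p]][i], numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no non-missing frequencies to scan")
  list(max = max(vals), population = names(vals)[which.max(vals)])
}
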