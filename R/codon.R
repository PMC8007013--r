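# Genetic-code helpers built on Biostrings::GENETIC_CODE (DNA codons).

.genetic_code <- function() Biostrings::GENETIC_CODE

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

# codons encoding the same amino acid as `codon`
.syn_family <- function(codon) {
  gc <- .genetic_code()
  aa <- gc[[codon]]
  if (is.null(aa) || aa == "*") stop("'", codon, "' is not a sense codon")
  names(gc)[gc == aa]
}

#' Validate and normalize a codon usage table
#'
#' @param usage Named numeric vector of non-negative codon frequencies
#'   (counts, fractions or per-thousand; every statistic here is
#'   invariant to the overall scale).  All 61 sense codons must be
#'   present; stop codons are dropped if present.
#' @return Named numeric vector over the 61 sense codons, class
#'   `codon_usage`.
#' @export
codon_usage <- function(usage) {
  stopifnot(is.numeric(usage), !is.null(names(usage)))
  names(usage) <- gsub("U", "T", toupper(names(usage)), fixed = TRUE)
  sense <- .sense_codons()
  missing <- setdiff(sense, names(usage))
  if (length(missing)) {
    stop("codon usage table is missing ", length(missing),
         " sense codon(s), e.g. ", missing[1])
  }
  usage <- usage[sense]
  if (any(usage < 0)) stop("codon frequencies must be non-negative")
  structure(usage, class = "codon_usage")
}

#' Read a codon usage TSV (codon, frequency)
#'
#' @param path TSV with header and columns codon, frequency.
#' @return A [codon_usage()] object.
#' @export
read_codon_usage <- function(path) {
  df <- read.delim(path, colClasses = "character")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(v))) stop("non-numeric codon frequency in ", path)
  codon_usage(setNames(v, df[[1]]))
}

#' A constructed human-like codon usage table
#'
#' A deterministic synthetic stand-in for an organism usage table, for
#' examples and tests: within each synonymous family, frequencies fall
#' off geometrically (ratio 0.55) from the family's most-used codon, and
#' families are scaled so the table sums to 1000 (per-thousand units).
#' It reproduces the *qualitative* structure real tables have (a clear
#' major codon per family, rare minor codons) without claiming any
#' organism's actual values; analyses meant for publication should
#' supply a real table via [read_codon_usage()].
#'
#' @param ratio Geometric fall-off between successive codons in a
#'   family, in (0, 1].
#' @return A [codon_usage()] object (per-thousand scale).
#' @export
toy_codon_usage <- function(ratio = 0.55) {
  gc <- .genetic_code()
  sense <- .sense_codons()
  out <- setNames(numeric(length(sense)), sense)
  for (aa in unique(gc[sense])) {
    fam <- sort(names(gc)[gc == aa])  # fixed order => deterministic
    w <- ratio^(seq_along(fam) - 1)
    out[fam] <- w / sum(w)
  }
  codon_usage(out / sum(out) * 1000)
}

#' Split a CDS into codons
#'
#' @param cds Coding sequence (character scalar over ACGT), length a
#'   multiple of 3.  A terminal stop codon is dropped; internal stop
#'   codons are an error.
#' @return Character vector of sense codons.
#' @export
split_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- gsub("U", "T", toupper(cds), fixed = TRUE)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) stop("CDS length must be a positive multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- .genetic_code()
  aa <- gc[codons]
  if (length(codons) > 1L && aa[length(codons)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  codons
}

#' Codon counts of a coding sequence
#'
#' @inheritParams split_codons
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_counts <- function(cds) {
  codons <- split_codons(cds)
  tab <- table(factor(codons, levels = .sense_codons()))
  setNames(as.integer(tab), names(tab))
}

#' Adjacent codon-pair counts of a coding sequence
#'
#' @inheritParams split_codons
#' @return Named integer vector over observed 6-mer codon pairs
#'   (codon1 followed by codon2).
#' @export
codon_pair_counts <- function(cds) {
  codons <- split_codons(cds)
  if (length(codons) < 2L) return(setNames(integer(0), character(0)))
  pairs <- paste0(codons[-length(codons)], codons[-1])
  tab <- table(pairs)
  setNames(as.integer(tab), names(tab))
}

#' Relative synonymous codon usage (RSCU)
#'
#' `RSCU(c) = n_c / ((1/k) * sum of counts over c's synonymous family)`,
#' where k is the family size: 1 under uniform usage within the family,
#' ranging over `[0, k]`.
#'
#' @param counts Named numeric vector of codon counts or frequencies
#'   (e.g. [codon_counts()] or a [codon_usage()] table).
#' @param codon Sense codon (3-mer over ACGT; U accepted).
#' @return RSCU value.
#' @export
rscu <- function(counts, codon) {
  codon <- gsub("U", "T", toupper(codon), fixed = TRUE)
  fam <- .syn_family(codon)
  n <- counts[fam]
  n[is.na(n)] <- 0
  tot <- sum(n)
  if (tot <= 0) stop("synonymous family of '", codon, "' has zero total count")
  unname(n[match(codon, fam)] / (tot / length(fam)))
}

#' Relative synonymous codon pair usage (RSCPU)
#'
#' The codon-pair analogue of RSCU: a pair's count divided by the mean
#' count over all codon pairs encoding the same amino-acid pair.
#'
#' @param pair_counts Named numeric vector of codon-pair counts, keys
#'   6-mers (codon1 followed by codon2), e.g. [codon_pair_counts()].
#' @param pair Codon pair as a 6-mer string or length-2 codon vector.
#' @return RSCPU value.
#' @export
rscpu <- function(pair_counts, pair) {
  if (length(pair) == 2L) pair <- paste0(pair[1], pair[2])
  pair <- gsub("U", "T", toupper(pair), fixed = TRUE)
  stopifnot(nchar(pair) == 6L)
  c1 <- substr(pair, 1L, 3L)
  c2 <- substr(pair, 4L, 6L)
  fam <- as.vector(outer(.syn_family(c1), .syn_family(c2), paste0))
  n <- pair_counts[fam]
  n[is.na(n)] <- 0
  tot <- sum(n)
  if (tot <= 0) stop("synonymous pair family of '", pair, "' has zero total count")
  unname(n[match(pair, fam)] / (tot / length(fam)))
}

# per-codon usage landscape: actual, family max, family min, family mean
.usage_landscape <- function(codons, usage) {
  gc <- .genetic_code()
  fam_stats <- lapply(split(unclass(usage), gc[names(unclass(usage))]), function(f) {
    c(max = max(f), min = min(f), avg = mean(f))
  })
  aa <- gc[codons]
  st <- do.call(rbind, fam_stats[aa])
  list(actual = unclass(usage)[codons], max = st[, "max"],
       min = st[, "min"], avg = st[, "avg"])
}

#' %MinMax codon-usage profile of a coding sequence
#'
#' For each full window of `window` codons, compares the mean usage of
#' the actual codons (Actual) with the mean usage of the most-used
#' (Max), least-used (Min) and average (Avg) synonymous alternatives at
#' each position:
#' `+100 * (Actual - Avg) / (Max - Avg)` when Actual > Avg, else
#' `-100 * (Avg - Actual) / (Avg - Min)`; 0 when Actual equals Avg or
#' the family is degenerate (Max == Avg or Avg == Min).  Values lie in
#' `[-100, 100]`; positive stretches are enriched in common codons,
#' negative stretches in rare codons.  The statistic is invariant to a
#' global rescaling of the usage table.
#'
#' @inheritParams split_codons
#' @param usage A [codon_usage()] table.
#' @param window Odd window size in codons (default 17).
#' @return Numeric vector of length `n_codons - window + 1`, one value
#'   per window, named by the 1-based codon index of the window center.
#' @export
percent_minmax <- function(cds, usage, window = 17L) {
  usage <- codon_usage(usage)
  codons <- split_codons(cds)
  n <- length(codons)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L) stop("window must be a positive odd integer")
  if (window > n) stop("CDS (", n, " codons) shorter than window (", window, ")")
  ls <- .usage_landscape(codons, usage)
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  actual <- roll(ls$actual); mx <- roll(ls$max)
  mn <- roll(ls$min); av <- roll(ls$avg)
  val <- numeric(length(actual))
  up <- actual > av
  dn <- actual < av
  val[up] <- 100 * (actual[up] - av[up]) / (mx[up] - av[up])
  val[dn] <- -100 * (av[dn] - actual[dn]) / (av[dn] - mn[dn])
  val[!is.finite(val)] <- 0
  val <- pmin(pmax(val, -100), 100)
  names(val) <- seq_len(n - window + 1L) + (window - 1L) %/% 2L
  val
}

#' Windowed rare-codon density
#'
#' Fraction of codons per window whose usage lies in the bottom quartile
#' of their synonymous family (single-codon families are never rare).
#' A coarse proxy for local rare-codon enrichment.
#'
#' @inheritParams percent_minmax
#' @return Numeric vector, one value per full window.
#' @export
rare_codon_density <- function(cds, usage, window = 17L) {
  usage <- codon_usage(usage)
  codons <- split_codons(cds)
  n <- length(codons)
  if (window > n) stop("CDS shorter than window")
  rare <- vapply(codons, .is_rare_codon, logical(1), usage = usage)
  cs <- cumsum(c(0, as.numeric(rare)))
  out <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  names(out) <- seq_len(n - window + 1L) + (window - 1L) %/% 2L
  out
}

.is_rare_codon <- function(codon, usage) {
  fam <- .syn_family(codon)
  if (length(fam) < 2L) return(FALSE)
  f <- unclass(usage)[fam]
  unname(unclass(usage)[codon] <= quantile(f, 0.25))
}

#' Codon-level deltas for a coding single-nucleotide variant
#'
#' Applies a coding substitution to a CDS and reports the codon-usage
#' consequences: change in RSCU of the affected codon, change in RSCPU
#' averaged over the (up to) two codon pairs containing it, the change
#' in the \%MinMax profile at every window covering the codon, and a
#' rare-codon flag for the wild-type codon (bottom quartile of its
#' synonymous family).
#'
#' @param cds Wild-type coding sequence.
#' @param variant An `hgvs_variant` with `region == "cds"`; its anchor
#'   is the 1-based position within `cds`.
#' @param usage A [codon_usage()] table (used for \%MinMax and the rare
#'   flag).
#' @param counts Codon counts used for RSCU; `"cds"` (default) derives
#'   them from `cds` itself, or pass a named count/frequency vector.
#' @param pair_counts Codon-pair counts for RSCPU; `"cds"` (default)
#'   derives them from `cds`, or pass a named vector.
#' @param window \%MinMax window (odd, codons).
#' @return A `variant_codon_delta` object: list with `variant`,
#'   `old_codon`, `new_codon`, `synonymous`, `delta_rscu`,
#'   `delta_rscpu` (mean; `NA` if no pair family has counts),
#'   `pair_deltas` (raw per-pair deltas), `delta_minmax` (named vector
#'   over covering windows), `rare_codon_flag`.
#' @export
variant_codon_delta <- function(cds, variant, usage, counts = "cds",
                                pair_counts = "cds", window = 17L) {
  stopifnot(inherits(variant, "hgvs_variant"))
  if (variant$region != "cds") stop("variant is not in the coding sequence")
  usage <- codon_usage(usage)
  cds <- gsub("U", "T", toupper(cds), fixed = TRUE)
  pos <- variant$anchor
  if (pos < 1L || pos > nchar(cds)) stop("variant position outside the CDS")
  if (substr(cds, pos, pos) != variant$ref) {
    stop("reference allele mismatch at CDS position ", pos, ": CDS has '",
         substr(cds, pos, pos), "', variant says '", variant$ref, "'")
  }
  mut <- cds
  substr(mut, pos, pos) <- variant$alt
  codons_wt <- split_codons(cds)
  idx <- (pos - 1L) %/% 3L + 1L
  if (idx > length(codons_wt)) stop("variant falls in the terminal stop codon")
  old_codon <- codons_wt[idx]
  new_codon <- old_codon
  substr(new_codon, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- variant$alt
  gc <- .genetic_code()
  if (gc[[new_codon]] == "*") stop("variant introduces a stop codon")
  synonymous <- gc[[old_codon]] == gc[[new_codon]]

  if (identical(counts, "cds")) counts <- codon_counts(cds)
  if (identical(pair_counts, "cds")) pair_counts <- codon_pair_counts(cds)
  d_rscu <- rscu(counts, new_codon) - rscu(counts, old_codon)

  pair_of <- function(a, b) paste0(a, b)
  pairs <- list()
  if (idx > 1L) {
    pairs[["prev"]] <- c(pair_of(codons_wt[idx - 1L], old_codon),
                         pair_of(codons_wt[idx - 1L], new_codon))
  }
  if (idx < length(codons_wt)) {
    pairs[["next"]] <- c(pair_of(old_codon, codons_wt[idx + 1L]),
                         pair_of(new_codon, codons_wt[idx + 1L]))
  }
  pair_deltas <- vapply(pairs, function(pr) {
    tryCatch(rscpu(pair_counts, pr[2]) - rscpu(pair_counts, pr[1]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (length(pair_deltas) && all(is.na(pair_deltas))) {
    warning("no codon-pair family has counts; RSCPU delta is NA")
  }
  d_rscpu <- if (length(pair_deltas)) mean(pair_deltas, na.rm = TRUE) else NA_real_
  if (is.nan(d_rscpu)) d_rscpu <- NA_real_

  n_cod <- length(codons_wt)
  dmm <- NULL
  if (window <= n_cod) {
    mm_wt <- percent_minmax(cds, usage, window)
    mm_mut <- percent_minmax(mut, usage, window)
    starts <- seq_len(n_cod - window + 1L)
    cover <- starts <= idx & idx <= starts + window - 1L
    dmm <- (mm_mut - mm_wt)[cover]
  }

  structure(list(variant = variant, old_codon = old_codon,
                 new_codon = new_codon, synonymous = synonymous,
                 delta_rscu = d_rscu, delta_rscpu = d_rscpu,
                 pair_deltas = pair_deltas, delta_minmax = dmm,
                 rare_codon_flag = .is_rare_codon(old_codon, usage)),
            class = "variant_codon_delta")
}

#' @export
print.variant_codon_delta <- function(x, ...) {
  cat(sprintf("<variant_codon_delta> %s: %s->%s (%s), dRSCU %.3f, dRSCPU %s, rare WT codon: %s\n",
              format_hgvs(x$variant), x$old_codon, x$new_codon,
              if (x$synonymous) "synonymous" else "missense",
              x$delta_rscu,
              if (is.na(x$delta_rscpu)) "NA" else sprintf("%.3f", x$delta_rscpu),
              x$rare_codon_flag))
  invisible(x)
}
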