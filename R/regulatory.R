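#' Hexamer score of the neighborhood of one position
#'
#' Sums the table scores of every 6-mer that overlaps the center
#' position within an 11-nt window (center +/- 5, clipped at the
#' sequence ends): up to six hexamers contribute.
#'
#' @param seq Character scalar over ACGT.
#' @param center 1-based position.
#' @param table Named numeric hexamer score map (see
#'   [read_score_table()]); keys missing from the map score 0.
#' @return Numeric score.
#' @export
hexamer_window_score <- function(seq, center, table) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  n <- nchar(seq)
  center <- as.integer(center)
  if (center < 1L || center > n) stop("center position outside the sequence")
  lo <- max(1L, center - 5L)
  hi <- min(n, center + 5L)
  s_min <- max(lo, center - 5L)
  s_max <- min(center, hi - 5L)
  if (s_max < s_min) return(0)
  starts <- seq.int(s_min, s_max)
  hex <- substring(seq, starts, starts + 5L)
  s <- table[hex]
  s[is.na(s)] <- 0
  sum(s)
}

#' Splicing-change assessment from hexamer score tables
#'
#' Each external splice-prediction tool is modeled as a named hexamer
#' score table.  For every table the change in [hexamer_window_score()]
#' between the wild-type and mutant sequence at the variant position is
#' computed, and compared with one standard deviation of that table's
#' own score scale.  Aggregation rule: the verdict is `"likely"` when
#' every table reports a nonzero change *and* every change exceeds one
#' standard deviation; `"possible"` when every table reports a nonzero
#' change but not all exceed the threshold; `"none"` otherwise.
#' Intronic variants carry an extra highlight flag, since a splicing
#' change inside an intron is the more credible signal.
#'
#' @param wt,mut Wild-type and mutant sequences (equal length, differing
#'   at exactly the variant position).
#' @param variant An `hgvs_variant` (used for the region flag).
#' @param position 1-based variant position within `wt`/`mut`.
#' @param tables Named list of hexamer score maps.
#' @param sd_mode How the one-standard-deviation threshold is scaled:
#'   `"table"` (default) uses the sd of the table's score values;
#'   `"positional"` uses the sd of per-position window scores of the
#'   wild-type sequence under that table.
#' @return A `splicing_assessment` object: list with `per_table`
#'   (data.frame: table, wt_score, mut_score, delta, threshold,
#'   exceeds_1sd), `verdict` in `c("none","possible","likely")`,
#'   `intron_highlight`.
#' @export
assess_splicing <- function(wt, mut, variant, position, tables,
                            sd_mode = c("table", "positional")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(variant, "hgvs_variant"), length(tables) >= 1L)
  if (nchar(wt) != nchar(mut)) stop("wild-type and mutant sequences differ in length")
  diffs <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
  if (!identical(diffs, as.integer(position))) {
    stop("sequences must differ at exactly the variant position")
  }
  if (is.null(names(tables))) names(tables) <- paste0("table", seq_along(tables))
  rows <- lapply(names(tables), function(nm) {
    tbl <- tables[[nm]]
    ws <- hexamer_window_score(wt, position, tbl)
    ms <- hexamer_window_score(mut, position, tbl)
    thr <- if (sd_mode == "table") {
      sd(tbl)
    } else {
      sd(vapply(seq_len(nchar(wt)), hexamer_window_score,
                numeric(1), seq = wt, table = tbl))
    }
    data.frame(table = nm, wt_score = ws, mut_score = ms,
               delta = ms - ws, threshold = thr,
               exceeds_1sd = abs(ms - ws) > thr)
  })
  per_table <- do.call(rbind, rows)
  all_change <- all(per_table$delta != 0)
  verdict <- if (all_change && all(per_table$exceeds_1sd)) {
    "likely"
  } else if (all_change) "possible" else "none"
  structure(list(per_table = per_table, verdict = verdict,
                 intron_highlight = variant$region == "intron"),
            class = "splicing_assessment")
}

#' @export
print.splicing_assessment <- function(x, ...) {
  cat(sprintf("<splicing_assessment> verdict: %s%s\n", x$verdict,
              if (x$intron_highlight) " (intronic)" else ""))
  print(x$per_table, row.names = FALSE)
  invisible(x)
}

#' Summarize miRNA binding-score changes for one variant
#'
#' Takes per-miRNA predicted binding scores (0-100 scale) for the
#' wild-type and mutant sequence; an absent score means the site is not
#' predicted at all and counts as 0 in the delta.  A summary is issued
#' only when every nonzero delta shares a direction and the total
#' absolute change reaches `min_total` (default 5): `"gained"` /
#' `"lost"` when a site crosses from absent to present (score at or
#' above `presence_threshold`) or vice versa, otherwise `"increase"` /
#' `"decrease"` by direction.  Upstream (5' UTR) variants are flagged,
#' where a binding change bears on translation of the downstream ORF.
#'
#' @param records Data.frame with columns `mirna`, `wt`, `mut` (numeric
#'   scores, `NA` = absent).
#' @param variant Optional `hgvs_variant` used for the upstream flag.
#' @param min_total Minimum total absolute change for a summary.
#' @param presence_threshold Score at or above which a site counts as
#'   present (default 50).
#' @return A `mirna_change_set` object: list with `records` (plus a
#'   `delta` column), `summary` in
#'   `c("none","gained","lost","increase","decrease")`,
#'   `total_abs_change`, `upstream_flag`.
#' @export
summarize_mirna <- function(records, variant = NULL, min_total = 5,
                            presence_threshold = 50) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("mirna", "wt", "mut") %in% names(records)))
  wt <- records$wt
  mut <- records$mut
  if (all(is.na(wt)) && all(is.na(mut))) stop("all scores absent")
  wt0 <- ifelse(is.na(wt), 0, wt)
  mut0 <- ifelse(is.na(mut), 0, mut)
  delta <- mut0 - wt0
  records$delta <- delta
  nz <- delta[delta != 0]
  agree <- length(nz) > 0L && (all(nz > 0) || all(nz < 0))
  total <- sum(abs(delta))
  summary <- "none"
  if (agree && total >= min_total) {
    gained <- any(is.na(wt) & mut0 >= presence_threshold)
    lost <- any(is.na(mut) & wt0 >= presence_threshold)
    summary <- if (all(nz > 0)) {
      if (gained) "gained" else "increase"
    } else {
      if (lost) "lost" else "decrease"
    }
  }
  structure(list(records = records, summary = summary,
                 total_abs_change = total,
                 upstream_flag = !is.null(variant) &&
                   variant$region == "five_utr"),
            class = "mirna_change_set")
}

#' @export
print.mirna_change_set <- function(x, ...) {
  cat(sprintf("<mirna_change_set> %d miRNA(s): summary '%s', total |delta| %g%s\n",
              nrow(x$records), x$summary, x$total_abs_change,
              if (x$upstream_flag) " (upstream variant)" else ""))
  invisible(x)
}

#' Global statistics of miRNA binding-score deltas
#'
#' Mean and median of `mut - wt` over all miRNA-variant score pairs
#' (absent scores as 0), the dataset-level summary of whether variants
#' tend to raise or lower predicted miRNA binding.
#'
#' @param records Data.frame with columns `wt` and `mut` pooled over
#'   all variants.
#' @return List with `mean_delta`, `median_delta`, `n`.
#' @export
mirna_global_stats <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("wt", "mut") %in% names(records)))
  delta <- ifelse(is.na(records$mut), 0, records$mut) -
    ifelse(is.na(records$wt), 0, records$wt)
  list(mean_delta = mean(delta), median_delta = median(delta),
       n = length(delta))
}
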