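#' Built-in minimum-free-energy fold (weighted base-pair DP)
#'
#' A Nussinov-style dynamic program over a DNA/RNA string: secondary
#' structures are non-crossing sets of base pairs with at least 3
#' unpaired bases inside every hairpin loop, pair energies GC = -3,
#' AU = -2, GU = -1 (T read as U), and the fold energy is the sum over
#' pairs.  Returns the minimum energy over all structures (<= 0; the
#' empty structure scores 0).  Deterministic and desk-scale; it ranks
#' stability changes rather than reproducing nearest-neighbor
#' thermodynamics.
#'
#' @param seq Character scalar over ACGT(U/N); N never pairs.
#' @return Integer energy <= 0.
#' @examples
#' fold_mfe("GGGAAAACCC")  # -9: three GC pairs around a 4-base loop
#' @export
fold_mfe <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  .nussinov_energy(seq)
}

#' MFE change caused by a single-nucleotide substitution
#'
#' Folds the wild-type and mutant sequence of a window centered on the
#' variant with the same backend and reports the energy difference
#' (mutant minus wild type): positive deltas destabilize the predicted
#' fold.
#'
#' @param transcript Character scalar, the (pre-mRNA or mRNA) sequence.
#' @param position 1-based substitution position within `transcript`.
#' @param alt Alternate base (must differ from the reference base).
#' @param window_size Odd window length in nucleotides (default 501,
#'   matching the flank convention used for miRNA scoring); truncated at
#'   the transcript ends.
#' @param backend Folding function `f(seq) -> energy`; default
#'   [fold_mfe()].
#' @param backend_name Label stored in the result.
#' @return An `mfe_result` object: list with `backend`, `mfe_wt`,
#'   `mfe_mut`, `delta` (`mfe_mut - mfe_wt`), `window` (1-based
#'   inclusive start/end).
#' @export
delta_mfe <- function(transcript, position, alt, window_size = 501L,
                      backend = fold_mfe, backend_name = "builtin") {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  transcript <- gsub("U", "T", toupper(transcript), fixed = TRUE)
  n <- nchar(transcript)
  position <- as.integer(position)
  window_size <- as.integer(window_size)
  if (position < 1L || position > n) stop("position outside the transcript")
  if (window_size %% 2L == 0L) stop("window_size must be odd")
  alt <- gsub("U", "T", toupper(alt), fixed = TRUE)
  ref <- substr(transcript, position, position)
  if (alt == ref) stop("alternate base equals the reference base '", ref, "'")
  half <- (window_size - 1L) %/% 2L
  lo <- max(1L, position - half)
  hi <- min(n, position + half)
  wt <- substr(transcript, lo, hi)
  mut <- wt
  substr(mut, position - lo + 1L, position - lo + 1L) <- alt
  e_wt <- backend(wt)
  e_mut <- backend(mut)
  structure(list(backend = backend_name, mfe_wt = e_wt, mfe_mut = e_mut,
                 delta = e_mut - e_wt, window = c(start = lo, end = hi)),
            class = "mfe_result")
}

#' @export
print.mfe_result <- function(x, ...) {
  cat(sprintf("<mfe_result> [%s] window %d-%d: WT %g, mutant %g, delta %+g\n",
              x$backend, x$window["start"], x$window["end"],
              x$mfe_wt, x$mfe_mut, x$delta))
  invisible(x)
}

#' Null distribution of MFE deltas from random substitutions
#'
#' Samples `n_samples` random single substitutions (uniform position,
#' uniform alternate base among the three non-reference bases) on the
#' transcript and computes each delta with the same backend and window,
#' giving the resampling null used to normalize observed deltas.
#'
#' @inheritParams delta_mfe
#' @param n_samples Number of null draws (>= 30).
#' @param seed Integer seed; the null is bit-reproducible given it.
#' @return An `mfe_null` object: list with `deltas`, `mu`, `sigma`
#'   (sample sd), `n_samples`, `seed`.
#' @export
mfe_null <- function(transcript, window_size = 501L, backend = fold_mfe,
                     n_samples = 1000L, seed = 1729L) {
  stopifnot(n_samples >= 30L)
  transcript <- gsub("U", "T", toupper(transcript), fixed = TRUE)
  n <- nchar(transcript)
  bases <- c("A", "C", "G", "T")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- sample.int(n, n_samples, replace = TRUE)
  deltas <- vapply(pos, function(p) {
    ref <- substr(transcript, p, p)
    alt <- sample(setdiff(bases, ref), 1L)
    delta_mfe(transcript, p, alt, window_size, backend)$delta
  }, numeric(1))
  structure(list(deltas = deltas, mu = mean(deltas), sigma = sd(deltas),
                 n_samples = n_samples, seed = seed),
            class = "mfe_null")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Z-score an observed MFE delta against a resampling null
#'
#' @param observed Observed delta (mutant minus wild type energy).
#' @param null An [mfe_null()], or pass `transcript` (plus the other
#'   null parameters) to build one.
#' @inheritParams mfe_null
#' @return List with `z` (NA with a warning when the null sd is 0) and
#'   `null`.
#' @export
mfe_zscore <- function(observed, null = NULL, transcript = NULL,
                       window_size = 501L, backend = fold_mfe,
                       n_samples = 1000L, seed = 1729L) {
  if (is.null(null)) {
    if (is.null(transcript)) stop("supply a null or a transcript to build one")
    null <- mfe_null(transcript, window_size, backend, n_samples, seed)
  }
  stopifnot(inherits(null, "mfe_null"))
  if (null$sigma == 0) {
    warning("null standard deviation is 0; z-score undefined")
    return(list(z = NA_real_, null = null))
  }
  list(z = (observed - null$mu) / null$sigma, null = null)
}

#' Consensus over per-backend MFE z-scores
#'
#' Multi-predictor aggregation rule: the backends agree in direction
#' when all nonzero z-scores share a sign; only then is the mean
#' z-score reported.  The change is flagged *strong* when, in addition,
#' every |z| exceeds 1 (every backend sees a change beyond one standard
#' deviation of its null).
#'
#' @param z Numeric vector of z-scores, one per backend (>= 1).
#' @return An `mfe_consensus` object: list with `z`,
#'   `direction_agreement`, `mean_z` (NA without agreement),
#'   `strong_flag`.
#' @export
mfe_consensus <- function(z) {
  stopifnot(is.numeric(z), length(z) >= 1L, !anyNA(z))
  nz <- z[z != 0]
  agreement <- length(nz) == 0L || all(nz > 0) || all(nz < 0)
  structure(list(
    z = z,
    direction_agreement = agreement,
    mean_z = if (agreement) mean(z) else NA_real_,
    strong_flag = agreement && all(abs(z) > 1)
  ), class = "mfe_consensus")
}

#' @export
print.mfe_consensus <- function(x, ...) {
  cat(sprintf("<mfe_consensus> z = (%s): %s%s\n",
              paste(sprintf("%.3f", x$z), collapse = ", "),
              if (x$direction_agreement)
                sprintf("mean z %.3f", x$mean_z) else "no direction agreement",
              if (x$strong_flag) " [strong]" else ""))
  invisible(x)
}
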