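#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`.  Wraps [utils::adist()] with
#' unit costs.  Empty strings are allowed.
#'
#' @param a,b Character scalars.
#' @return Non-negative integer.
#' @examples
#' lev_distance("kitten", "sitting")  # 3
#' @export
lev_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(adist(a, b)[1, 1])
}

#' Pairwise Levenshtein distance matrix for MSA sequences
#'
#' Distances are computed on the *de-gapped* sequences: alignment gaps
#' are artifacts of the alignment, and keeping them would double-count
#' indel columns.
#'
#' @param x An [msa()] object, or a named character vector of sequences.
#' @return Symmetric integer matrix with zero diagonal, dimnames = ids.
#' @export
lev_distance_matrix <- function(x) {
  seqs <- if (inherits(x, "msa")) x$seqs else x
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  plain <- gsub("-", "", seqs, fixed = TRUE)
  d <- adist(plain)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# Affinity propagation on a similarity matrix (Frey & Dueck message
# passing).  Deterministic: no noise is added; ties resolve to the
# lowest index through which.max.  Returns exemplar indices, or NULL if
# the exemplar set never stabilizes.
.affinity_propagation <- function(S, damping = 0.9, max_iter = 1000L,
                                  stable_iter = 50L) {
  n <- nrow(S)
  if (n == 1L) return(1L)
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  prev <- NULL
  stable <- 0L
  for (iter in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev)) {
      stable <- stable + 1L
      if (stable >= stable_iter && length(ex) > 0L) return(ex)
    } else {
      stable <- 0L
      prev <- ex
    }
  }
  NULL
}

#' Deduplicate an MSA by exemplar clustering on Levenshtein distances
#'
#' Clusters the non-anchor sequences by affinity propagation on the
#' similarity matrix `-Levenshtein(de-gapped sequences)` and keeps only
#' the cluster exemplars; anchor sequences are always retained.  This
#' mirrors removing near-duplicate homologs (e.g. many strains of the
#' same virus) while keeping the sequences the analysis is about.
#' Columns are never touched, so downstream column statistics see the
#' same coordinate system.
#'
#' @param x An [msa()] object.
#' @param preference Shared exemplar preference: `"auto"` (default,
#'   half the median off-diagonal similarity — sparse enough to merge
#'   near-duplicates while leaving a set of mutually distant exemplars
#'   untouched, which makes deduplication idempotent), `"median"` (the
#'   median off-diagonal similarity), or a numeric value.
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum message-passing iterations.
#' @return An `msa` containing the exemplars plus all anchors, in the
#'   original row order.  If message passing does not stabilize, falls
#'   back (with a warning) to one representative per group of identical
#'   de-gapped sequences (the distance-0 connected components).
#' @export
dedup_msa <- function(x, preference = "auto", damping = 0.9,
                      max_iter = 1000L) {
  stopifnot(inherits(x, "msa"))
  ids <- names(x$seqs)
  pool <- setdiff(ids, x$anchors)
  if (length(pool) == 0L) return(x)
  if (length(pool) == 1L) {
    keep <- ids %in% c(pool, x$anchors)
    return(msa(x$seqs[keep], x$alphabet, x$anchors))
  }
  D <- lev_distance_matrix(x$seqs[pool])
  S <- -D
  storage.mode(S) <- "double"
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "auto")) {
    median(off) / 2
  } else if (identical(preference, "median")) {
    median(off)
  } else {
    as.numeric(preference)
  }
  diag(S) <- pref
  # Exactly tied similarities (e.g. groups of identical sequences) make
  # the message passing oscillate symmetrically; a deterministic,
  # index-ordered perturbation far below the similarity scale breaks the
  # ties without affecting which clusters form.
  n <- nrow(S)
  eps <- 1e-9 * max(1, max(abs(S)))
  S <- S + eps * matrix(seq_len(n * n), n, n)
  ex <- .affinity_propagation(S, damping = damping, max_iter = max_iter)
  if (is.null(ex)) {
    warning("affinity propagation did not stabilize; ",
            "falling back to one representative per identical-sequence group")
    plain <- gsub("-", "", x$seqs[pool], fixed = TRUE)
    ex <- which(!duplicated(plain))
  }
  keep <- ids %in% c(pool[ex], x$anchors)
  msa(x$seqs[keep], x$alphabet, x$anchors)
}

#' Fraction of target positions matching a reference in an MSA
#'
#' Over the columns where the *target* sequence has a non-gap residue,
#' the fraction whose residue equals the reference sequence's residue at
#' that column.  Used to compare a protein with its homolog when both
#' sit in one MSA.
#'
#' @param x An [msa()] object.
#' @param ref_id,target_id Sequence ids in `x`.
#' @return A number in `[0, 1]`.
#' @export
pairwise_fraction_matching <- function(x, ref_id, target_id) {
  stopifnot(inherits(x, "msa"))
  if (!ref_id %in% names(x$seqs)) stop("unknown reference id '", ref_id, "'")
  if (!target_id %in% names(x$seqs)) stop("unknown target id '", target_id, "'")
  ref <- strsplit(x$seqs[[ref_id]], "")[[1]]
  tgt <- strsplit(x$seqs[[target_id]], "")[[1]]
  use <- tgt != "-"
  if (!any(use)) stop("target sequence '", target_id, "' is entirely gaps")
  mean(tgt[use] == ref[use])
}

#' Per-column conservation of a reference sequence in an MSA
#'
#' For each requested column i, computes the match probability
#' `P(x_i)` = (number of sequences whose residue equals the reference
#' residue) / (number of non-gap sequences at that column).  Sequences
#' gapped at a column are excluded from both numerator and denominator,
#' so alignment coverage is not conflated with conservation.  The
#' additive conservation score is `sum(log P(x_i))` (natural log),
#' non-positive and 0 only under perfect conservation; under column
#' independence `exp` of the sum is the probability of drawing the
#' reference residues from the alignment.  Columns with `P = 0`
#' contribute `-Inf` and are reported separately, together with a
#' finite sum over the remaining columns.
#'
#' @param x An [msa()] object.
#' @param ref_id Reference (wild-type) sequence id.
#' @param columns Integer vector of 1-based column indices, or `"all"`.
#' @param include_ref Count the reference sequence itself?  `TRUE`
#'   (default) treats the reference as one of the alignment's
#'   sequences, so `P >= 1/n` always; `FALSE` scores the reference
#'   against the rest of the alignment only, allowing `P = 0` at
#'   columns where nothing else matches.
#' @return A `conservation_profile` object: list with `p` (named by
#'   column index), `fraction_matching` (mean of `p`; for a single
#'   column exactly `P` at that column), `loglikelihood_sum`,
#'   `loglikelihood_mean`, `finite_loglikelihood_sum`, `zero_columns`,
#'   `ref_id`.
#' @export
column_conservation <- function(x, ref_id, columns = "all",
                                include_ref = TRUE) {
  stopifnot(inherits(x, "msa"))
  if (!ref_id %in% names(x$seqs)) stop("unknown reference id '", ref_id, "'")
  mat <- do.call(rbind, strsplit(unname(x$seqs), ""))
  if (!include_ref) {
    keep <- names(x$seqs) != ref_id
    if (!any(keep)) stop("no sequences besides the reference")
    mat <- mat[keep, , drop = FALSE]
  }
  ncol_msa <- ncol(mat)
  if (identical(columns, "all")) columns <- seq_len(ncol_msa)
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > ncol_msa)) stop("column index out of range")
  ref <- strsplit(x$seqs[[ref_id]], "")[[1]]
  p <- vapply(columns, function(j) {
    col <- mat[, j]
    nongap <- col != "-"
    if (!any(nongap)) stop("all sequences gapped at column ", j)
    if (ref[j] == "-") stop("reference is gapped at column ", j)
    sum(col[nongap] == ref[j]) / sum(nongap)
  }, numeric(1))
  names(p) <- columns
  logp <- log(p)
  zero <- columns[p == 0]
  structure(list(
    p = p,
    fraction_matching = mean(p),
    loglikelihood_sum = sum(logp),
    loglikelihood_mean = sum(logp) / length(p),
    finite_loglikelihood_sum = sum(logp[is.finite(logp)]),
    zero_columns = zero,
    ref_id = ref_id
  ), class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation_profile> ref '%s', %d column(s): fraction matching %.4f, sum log P %.4f\n",
    x$ref_id, length(x$p), x$fraction_matching, x$loglikelihood_sum))
  invisible(x)
}
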