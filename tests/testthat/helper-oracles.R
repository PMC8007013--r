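# Independent oracles used to validate the package's primitives.
# Both deliberately avoid the implementation's algorithmic route.

# Brute-force Levenshtein: iterative deepening over edit scripts.
# can_edit(a, b, k): can a be turned into b with at most k single-char
# edits?  Explores delete/insert/substitute at the first mismatch only
# (a sound restriction of the full edit-script space).
can_edit <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (abs(na - nb) > k) return(FALSE)
  if (na == 0L) return(nb <= k)
  if (nb == 0L) return(na <= k)
  if (substr(a, 1, 1) == substr(b, 1, 1)) {
    return(can_edit(substr(a, 2, na), substr(b, 2, nb), k))
  }
  if (k == 0L) return(FALSE)
  can_edit(substr(a, 2, na), substr(b, 2, nb), k - 1L) ||  # substitute
    can_edit(a, substr(b, 2, nb), k - 1L) ||               # insert
    can_edit(substr(a, 2, na), b, k - 1L)                  # delete
}

lev_oracle <- function(a, b) {
  for (k in 0:(nchar(a) + nchar(b))) {
    if (can_edit(a, b, k)) return(k)
  }
  stop("unreachable")
}

# Exhaustive-structure MFE oracle: enumerates every valid secondary
# structure (non-crossing pairs, >= 3 unpaired bases in each hairpin)
# by deciding the leftmost base (unpaired, or paired with each legal
# partner), summing pair energies, and taking the minimum.
.pair_e <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
  0
}

.enum_energies <- function(v, i, j) {
  if (i > j) return(0)
  res <- .enum_energies(v, i + 1L, j)  # leftmost base unpaired
  if (j >= i + 4L) {
    for (k in (i + 4L):j) {
      e <- .pair_e(v[i], v[k])
      if (e == 0) next
      inner <- .enum_energies(v, i + 1L, k - 1L)
      right <- .enum_energies(v, k + 1L, j)
      res <- c(res, as.vector(outer(inner, right, `+`)) + e)
    }
  }
  res
}

mfe_oracle <- function(seq) {
  v <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  min(.enum_energies(v, 1L, length(v)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

extdata <- function(f) system.file("extdata", f, package = "coagvar")
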