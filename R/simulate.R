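# Synthetic-data generators.  Every generator runs on its own RNG
# stream: seed + a stable per-generator offset, so adding a generator
# (or calling them in a different order) never perturbs existing
# fixtures.  The caller's RNG state is saved and restored.

.with_sim_seed <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(expr)
}

#' Simulate an MSA with controlled per-column conservation
#'
#' Draws a uniform-random reference sequence; every other sequence
#' matches the reference at column i with probability `q[i]` and
#' otherwise carries a uniform different residue.  By construction the
#' expected column match probability estimated by
#' [column_conservation()] (reference included in the count) is
#' `(1 + (n-1) q) / n`, converging to `q` as sequences are added.
#'
#' @param n_seq Total number of sequences including the reference
#'   (>= 2).
#' @param n_col Number of columns.
#' @param q Per-column match probability, scalar or length-`n_col`
#'   vector in `[0, 1]`.
#' @param seed Integer seed (mandatory; generators are deterministic).
#' @param ref_id Id of the reference sequence (always an anchor).
#' @return An [msa()] object (nucleotide), anchors = `ref_id`.
#' @export
sim_msa <- function(n_seq, n_col, q, seed, ref_id = "ref") {
  stopifnot(n_seq >= 2L, n_col >= 1L, all(q >= 0 & q <= 1))
  q <- rep_len(q, n_col)
  .with_sim_seed(seed, 101L, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_col, replace = TRUE)
    seqs <- character(n_seq)
    seqs[1] <- paste(ref, collapse = "")
    for (s in seq_len(n_seq - 1L)) {
      match <- runif(n_col) < q
      res <- ref
      if (any(!match)) {
        res[!match] <- vapply(ref[!match], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      }
      seqs[s + 1L] <- paste(res, collapse = "")
    }
    names(seqs) <- c(ref_id, paste0("seq", seq_len(n_seq - 1L)))
    msa(seqs, "nuc", anchors = ref_id)
  })
}

#' Simulate a coding sequence with controlled codon-usage bias
#'
#' Draws amino acids uniformly and, within each synonymous family,
#' picks the codon from a mixture interpolating between uniform family
#' usage (`bias = 0`) and always the family's most-used codon
#' (`bias = 1`) under the supplied usage table.  No stop codons are
#' produced.
#'
#' @param n_codons Number of codons.
#' @param bias Bias strength in `[0, 1]`.
#' @param usage A [codon_usage()] table (default [toy_codon_usage()]).
#' @param seed Integer seed.
#' @return Character scalar of length `3 * n_codons`.
#' @export
sim_cds <- function(n_codons, bias, usage = toy_codon_usage(), seed = 1L) {
  stopifnot(n_codons >= 1L, bias >= 0, bias <= 1)
  usage <- codon_usage(usage)
  gc <- .genetic_code()
  aas <- setdiff(unique(gc), "*")
  fams <- lapply(aas, function(a) names(gc)[gc == a])
  names(fams) <- aas
  .with_sim_seed(seed, 202L, {
    aa_draw <- sample(aas, n_codons, replace = TRUE)
    codons <- vapply(aa_draw, function(a) {
      fam <- fams[[a]]
      f <- unclass(usage)[fam]
      w <- (1 - bias) / length(fam) + bias * (f == max(f)) / sum(f == max(f))
      sample(fam, 1L, prob = w)
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' Simulate a population allele-frequency table
#'
#' Each variant gets a base frequency; population cells are the base
#' plus small Gaussian noise (clipped to `[0, 1]`), optionally shifted
#' by spike deltas; the Global column is the population mean weighted
#' by the stated population sizes, so it always lies within the convex
#' hull of the population values.
#'
#' @param base_maf Named numeric vector: base frequency per variant.
#' @param populations Character vector of population labels (the Global
#'   column is added in front).
#' @param weights Population sizes/weights (normalized internally;
#'   default equal).
#' @param spikes Optional data.frame with columns `variant`,
#'   `population`, `delta`; a spike pushing a cell outside `[0, 1]` is
#'   an error.
#' @param noise_sd Gaussian noise sd on unspiked cells (default 0.002).
#' @param seed Integer seed.
#' @return A `pop_freq` object with global column `"Global"`.
#' @export
sim_freq_table <- function(base_maf, populations, weights = NULL,
                           spikes = NULL, noise_sd = 0.002, seed = 1L) {
  stopifnot(!is.null(names(base_maf)), all(base_maf >= 0 & base_maf <= 1))
  if (is.null(weights)) weights <- rep(1, length(populations))
  stopifnot(length(weights) == length(populations), all(weights > 0))
  weights <- weights / sum(weights)
  .with_sim_seed(seed, 303L, {
    m <- matrix(NA_real_, nrow = length(base_maf), ncol = length(populations),
                dimnames = list(names(base_maf), populations))
    for (j in seq_along(populations)) {
      m[, j] <- pmin(pmax(base_maf + rnorm(length(base_maf), 0, noise_sd), 0), 1)
    }
    if (!is.null(spikes)) {
      for (i in seq_len(nrow(spikes))) {
        v <- spikes$variant[i]; p <- spikes$population[i]
        if (!v %in% rownames(m) || !p %in% colnames(m)) {
          stop("spike references unknown variant or population")
        }
        new <- m[v, p] + spikes$delta[i]
        if (new < 0 || new > 1) stop("spike pushes frequency outside [0, 1]")
        m[v, p] <- new
      }
    }
    global <- as.vector(m %*% weights)
    df <- data.frame(variant = names(base_maf), Global = global,
                     as.data.frame(m, optional = TRUE),
                     check.names = FALSE, row.names = NULL)
    raw <- as.matrix(format(df[-1], digits = 15, trim = TRUE, scientific = FALSE))
    rownames(raw) <- df$variant
    structure(df, class = c("pop_freq", "data.frame"),
              populations = c("Global", populations),
              global_col = "Global", raw = raw)
  })
}

#' Simulate a hexamer score table with known spread
#'
#' Scores drawn i.i.d. Normal(0, `sd`) over all `4^6` hexamers, the
#' shape [assess_splicing()] assumes when it scales its threshold by a
#' table's standard deviation.
#'
#' @param sd Score standard deviation.
#' @param seed Integer seed.
#' @return Named numeric vector over all 4096 hexamers.
#' @export
sim_hexamer_table <- function(sd = 1, seed = 1L) {
  .with_sim_seed(seed, 404L, {
    kmers <- .all_kmers(6L)
    setNames(rnorm(length(kmers), 0, sd), kmers)
  })
}

#' Simulate a per-variant miRNA score record set with a known total shift
#'
#' `n` miRNA records present in both wild type and mutant, with a total
#' directional binding change of exactly `total` split evenly, so the
#' summary rule's firing threshold can be probed at its boundary.
#'
#' @param n Number of miRNA records.
#' @param total Total signed change (`sum(mut - wt)`).
#' @param wt_base Wild-type score level (0-100 scale).
#' @param seed Integer seed.
#' @return Data.frame with columns `mirna`, `wt`, `mut`.
#' @export
sim_mirna_records <- function(n, total, wt_base = 60, seed = 1L) {
  stopifnot(n >= 1L)
  .with_sim_seed(seed, 505L, {
    data.frame(mirna = paste0("miR-", seq_len(n)),
               wt = rep(wt_base, n),
               mut = wt_base + total / n)
  })
}

#' Simulate a GWAS summary table with spiked in-region significant hits
#'
#' Builds `n_sig` records inside the padded gene regions with p-values
#' strictly below `alpha`, plus decoys that fail exactly one condition:
#' half lie in region with p at or above `alpha`, half lie outside the
#' padded region with p below `alpha`.  [filter_gwas_region()] at the
#' same `pad`/`alpha` must recover exactly the spiked records.
#'
#' @param genes Data.frame with `gene`, `chrom`, `start`, `end`.
#' @param n_sig Number of true in-region significant records.
#' @param n_decoy Number of decoys.
#' @param pad,alpha Region padding and p-value cutoff the truth is
#'   defined against.
#' @param seed Integer seed.
#' @return Data.frame `variant`, `chrom`, `pos`, `p`, with attribute
#'   `truth` (ids of the spiked records).
#' @export
sim_gwas_table <- function(genes, n_sig, n_decoy, pad = 6000L,
                           alpha = 0.05, seed = 1L) {
  stopifnot(nrow(genes) >= 1L, n_sig >= 0L, n_decoy >= 0L)
  .with_sim_seed(seed, 606L, {
    pick_gene <- function() genes[sample.int(nrow(genes), 1L), ]
    sig <- lapply(seq_len(n_sig), function(i) {
      g <- pick_gene()
      data.frame(variant = sprintf("sig%03d", i), chrom = g$chrom,
                 pos = sample(seq(max(1L, g$start - pad), g$end + pad), 1L),
                 p = runif(1, 1e-6, alpha * 0.999))
    })
    decoys <- lapply(seq_len(n_decoy), function(i) {
      g <- pick_gene()
      if (i %% 2L == 0L) {
        # in region, not significant (alpha itself must be excluded:
        # the filter is strictly below alpha)
        data.frame(variant = sprintf("dec%03d", i), chrom = g$chrom,
                   pos = sample(seq(max(1L, g$start - pad), g$end + pad), 1L),
                   p = runif(1, alpha, 1))
      } else {
        # significant, outside every padded region
        far <- max(genes$end) + pad + sample.int(50000L, 1L)
        data.frame(variant = sprintf("dec%03d", i), chrom = g$chrom,
                   pos = far, p = runif(1, 1e-6, alpha * 0.999))
      }
    })
    out <- do.call(rbind, c(sig, decoys))
    rownames(out) <- NULL
    attr(out, "truth") <- sprintf("sig%03d", seq_len(n_sig))
    out
  })
}
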