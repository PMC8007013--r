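#' Parse a FASTA file or string into a named vector of sequences
#'
#' Reads plain (unaligned) FASTA via [Biostrings::readBStringSet()] and
#' validates the residues against the requested alphabet.  Nucleotide
#' sequences are normalized to DNA (U becomes T, uppercase); allowed
#' letters are ACGTN.  Protein sequences allow the 20 standard amino
#' acids plus X.
#'
#' @param x Path to a FASTA file, or a character scalar containing FASTA
#'   text (recognized by a leading `>`).
#' @param alphabet `"auto"`, `"nuc"` or `"prot"`.  With `"auto"` the
#'   alphabet is guessed: sequences consisting only of ACGTUN are called
#'   nucleotide.
#' @return Named character vector of residues (names are record ids, the
#'   first whitespace-delimited token of each header), with attributes
#'   `alphabet` and `descriptions` (full header lines).  Record order is
#'   preserved.
#' @examples
#' parse_fasta(">a\nACGU\n>b\nGGTT\n")
#' @export
parse_fasta <- function(x, alphabet = c("auto", "nuc", "prot")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^\\s*>", x)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(x, path)
  } else {
    path <- x
    if (!file.exists(path)) stop("no such file: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA input contains no records")
  res <- toupper(as.character(set))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (any(!nzchar(res))) {
    stop("empty sequence for record '", ids[which(!nzchar(res))[1]], "'")
  }
  if (alphabet == "auto") {
    alphabet <- if (all(grepl("^[ACGTUN]+$", res))) "nuc" else "prot"
  }
  if (alphabet == "nuc") {
    res <- gsub("U", "T", res, fixed = TRUE)
    .check_alphabet(res, ids, "ACGTN", "nucleotide")
  } else {
    .check_alphabet(res, ids, "ACDEFGHIKLMNPQRSTVWYX", "protein")
  }
  names(res) <- ids
  structure(res, alphabet = alphabet, descriptions = headers)
}

.check_alphabet <- function(res, ids, letters, label) {
  rx <- sprintf("[^%s]", letters)
  m <- regexpr(rx, res)
  bad <- which(m > 0L)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                 label, substr(res[i], m[i], m[i]), ids[i], m[i]))
  }
  invisible(TRUE)
}

#' Multiple sequence alignment container
#'
#' A light container for an MSA: equal-length gapped sequences over a
#' nucleotide or protein alphabet, plus a set of *anchor* ids that
#' deduplication must never remove (in the original analysis, the SARS
#' and SARS-CoV-2 sequences).
#'
#' @param seqs Named character vector of aligned sequences (gaps `-`).
#' @param alphabet `"nuc"` or `"prot"`.
#' @param anchors Character vector of ids that must be retained by
#'   [dedup_msa()]; must be a subset of `names(seqs)`.
#' @return An object of class `msa`.
#' @export
msa <- function(seqs, alphabet = c("nuc", "prot"), anchors = character()) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in MSA")
  w <- unique(nchar(seqs))
  if (length(w) != 1L || w < 1L) stop("aligned sequences must share one positive length")
  if (!all(anchors %in% names(seqs))) stop("anchors must be existing sequence ids")
  letters <- if (alphabet == "nuc") "ACGTN-" else "ACDEFGHIKLMNPQRSTVWYX-"
  .check_alphabet(seqs, names(seqs), letters, alphabet)
  structure(list(seqs = seqs, alphabet = alphabet,
                 anchors = unique(anchors)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d %s sequences x %d columns (%d anchors)\n",
              length(x$seqs), x$alphabet, nchar(x$seqs[[1]]),
              length(x$anchors)))
  invisible(x)
}

#' Read an aligned FASTA file into an [msa()] object
#'
#' @param path Aligned FASTA file (or FASTA text), gaps as `-`.
#' @inheritParams msa
#' @return An `msa` object.
#' @export
read_msa <- function(path, alphabet = c("nuc", "prot"), anchors = character()) {
  alphabet <- match.arg(alphabet)
  if (grepl("^\\s*>", path)) {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf), add = TRUE)
    writeLines(path, tf)
    path <- tf
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("an MSA needs at least two sequences")
  res <- toupper(as.character(set))
  if (alphabet == "nuc") res <- gsub("U", "T", res, fixed = TRUE)
  names(res) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  msa(res, alphabet, anchors)
}

#' Write an [msa()] object as aligned FASTA
#'
#' @param x An `msa` object.
#' @param path Output path.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  writeLines(paste0(">", names(x$seqs), "\n", x$seqs), path)
  invisible(path)
}

# region codes used throughout: 5' UTR, coding, intron, 3' UTR
.hgvs_regions <- c("five_utr", "cds", "intron", "three_utr")

#' Parse a simplified HGVS c.-notation variant name
#'
#' Supports single-nucleotide substitutions in coding-transcript (c.)
#' coordinates, the only variant class the pipeline annotates:
#' `TRANSCRIPT:c.POS REF>ALT` with `POS` one of `-N` (5' UTR), `N`
#' (coding), `N+M` / `N-M` (intron, offset from the exon boundary at
#' coding position N), or `*N` (3' UTR).
#'
#' @param name Variant name, e.g. `"NM_024006.4:c.283+837T>C"`.
#' @return An object of class `hgvs_variant`: a list with `transcript`,
#'   `region` (one of `"five_utr"`, `"cds"`, `"intron"`, `"three_utr"`),
#'   `anchor` (signed c. coordinate; positive number for `*N` positions),
#'   `intron_offset` (signed integer, `NA` unless intronic), `ref`, `alt`.
#' @examples
#' parse_hgvs("NM_024006.4:c.-1639G>A")
#' parse_hgvs("NM_000062.2:c.*1323G>A")
#' @export
parse_hgvs <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  rx <- "^([A-Za-z0-9_.]+):c\\.(\\*\\d+|-?\\d+([+-]\\d+)?)([ACGT])>([ACGT])$"
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 0L) stop("malformed HGVS c. substitution: '", name, "'")
  transcript <- m[2]
  pos <- m[3]
  ref <- m[5]
  alt <- m[6]
  if (ref == alt) stop("reference and alternate allele are identical in '", name, "'")
  offset <- NA_integer_
  if (startsWith(pos, "*")) {
    region <- "three_utr"
    anchor <- as.integer(sub("\\*", "", pos))
  } else if (grepl("^-\\d+$", pos)) {
    region <- "five_utr"
    anchor <- as.integer(pos)
  } else if (grepl("^\\d+[+-]\\d+$", pos)) {
    region <- "intron"
    anchor <- as.integer(sub("([+-]).*$", "", pos))
    offset <- as.integer(regmatches(pos, regexpr("[+-]\\d+$", pos)))
  } else {
    region <- "cds"
    anchor <- as.integer(pos)
  }
  if (anchor == 0L) stop("HGVS coordinates have no position 0: '", name, "'")
  structure(list(transcript = transcript, region = region, anchor = anchor,
                 intron_offset = offset, ref = ref, alt = alt),
            class = "hgvs_variant")
}

#' Format an `hgvs_variant` back to its HGVS name
#'
#' Inverse of [parse_hgvs()]: `format_hgvs(parse_hgvs(x)) == x` for every
#' supported name.
#'
#' @param v An `hgvs_variant`.
#' @return Character scalar.
#' @export
format_hgvs <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  pos <- switch(v$region,
    three_utr = paste0("*", v$anchor),
    intron    = paste0(v$anchor, sprintf("%+d", v$intron_offset)),
    as.character(v$anchor))
  sprintf("%s:c.%s%s>%s", v$transcript, pos, v$ref, v$alt)
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat(sprintf("<hgvs_variant> %s [%s]\n", format_hgvs(x), x$region))
  invisible(x)
}

#' Human-readable location label for a variant
#'
#' @param v An `hgvs_variant`.
#' @return One of `"5' UTR"`, `"Exon"`, `"Intron"`, `"3' UTR"`.
#' @export
hgvs_location <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  switch(v$region,
         five_utr = "5' UTR", cds = "Exon",
         intron = "Intron", three_utr = "3' UTR")
}

#' Read a population allele-frequency table
#'
#' Reads a TSV whose rows are variants and whose columns are population
#' minor-allele frequencies in `[0, 1]` (gnomAD/dbSNP style).  Blank
#' cells become `NA` (missing), never 0.  Bit-identical duplicate rows
#' (as printed in some published tables) are collapsed with a message;
#' duplicate rows with conflicting values are an error.
#'
#' @param path TSV file with a header row; first column (or `id_col`)
#'   holds variant ids.
#' @param id_col Name or index of the variant-id column.
#' @param meta_cols Optional character vector of non-frequency columns to
#'   carry along (e.g. a gene or classification column).
#' @return A `pop_freq` object: a data.frame with the id column
#'   `variant`, any `meta_cols`, and one numeric column per population.
#'   Attributes: `populations` (ordered labels), `global_col` (the
#'   detected Global/Overall column, if any), `raw` (the original cell
#'   strings, for lossless re-serialization).
#' @export
read_frequency_table <- function(path, id_col = 1L, meta_cols = NULL) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (is.numeric(id_col)) id_col <- names(df)[id_col]
  pops <- setdiff(names(df), c(id_col, meta_cols))
  if (length(pops) == 0L) stop("frequency table has no population columns")
  if (anyDuplicated(pops)) stop("population labels must be unique")
  key <- do.call(paste, c(df[c(id_col, meta_cols)], sep = "\r"))
  if (anyDuplicated(key)) {
    full <- do.call(paste, c(df, sep = "\r"))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      if (length(unique(full[rows])) > 1L) {
        stop("conflicting duplicate rows for variant '", df[[id_col]][rows[1]], "'")
      }
    }
    drop <- duplicated(full)
    if (any(drop)) {
      message("collapsed ", sum(drop), " bit-identical duplicate row(s)")
      df <- df[!drop, , drop = FALSE]
    }
  }
  raw <- as.matrix(df[pops])
  rownames(raw) <- df[[id_col]]
  out <- df[c(id_col, meta_cols)]
  names(out)[1] <- "variant"
  for (p in pops) {
    s <- trimws(df[[p]])
    v <- suppressWarnings(as.numeric(s))
    bad <- nzchar(s) & is.na(v)
    if (any(bad)) stop("non-numeric frequency '", s[bad][1], "' in column '", p, "'")
    v[!nzchar(s)] <- NA_real_
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("allele frequency outside [0,1] in column '", p, "'")
    }
    out[[p]] <- v
  }
  global <- pops[tolower(pops) %in% c("global", "overall")]
  structure(out, class = c("pop_freq", "data.frame"),
            populations = pops,
            global_col = if (length(global)) global[1] else NA_character_,
            raw = raw)
}

#' Write a `pop_freq` table back to TSV, preserving original cell strings
#'
#' Cells read by [read_frequency_table()] are written back exactly as
#' the decimal strings of the source file, so a read/write cycle is
#' lossless.
#'
#' @param x A `pop_freq` object.
#' @param path Output TSV path.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "pop_freq"))
  pops <- attr(x, "populations")
  raw <- attr(x, "raw")
  meta <- setdiff(names(x), c("variant", pops))
  df <- cbind(x[c("variant", meta)],
              as.data.frame(raw, check.names = FALSE, optional = TRUE))
  names(df)[1] <- "variant"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a k-mer score table (e.g. splicing hexamer scores)
#'
#' Reads a two-column TSV of k-mer and numeric score.  The returned map
#' is complete over all `4^k` k-mers; k-mers absent from the file
#' default to 0, and the number of defaulted entries is recorded (and
#' messaged) so silent truncation of a table is visible.
#'
#' @param path TSV with header and columns k-mer, score.
#' @param key_length Expected k-mer length (6 for splicing hexamers).
#' @return Named numeric vector over all k-mers of the stated length,
#'   with attribute `n_defaulted`.
#' @export
read_score_table <- function(path, key_length = 6L) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("score table needs k-mer and score columns")
  kmer <- toupper(trimws(df[[1]]))
  score <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(score))) {
    stop("non-numeric score '", df[[2]][which(is.na(score))[1]], "'")
  }
  bad <- !grepl(sprintf("^[ACGT]{%d}$", key_length), kmer)
  if (any(bad)) {
    stop("key '", kmer[bad][1], "' is not an ACGT ", key_length, "-mer")
  }
  if (anyDuplicated(kmer)) {
    for (k in unique(kmer[duplicated(kmer)])) {
      if (length(unique(score[kmer == k])) > 1L) {
        stop("duplicate key '", k, "' with differing scores")
      }
    }
    keep <- !duplicated(kmer)
    kmer <- kmer[keep]; score <- score[keep]
  }
  all_kmers <- .all_kmers(key_length)
  out <- setNames(numeric(length(all_kmers)), all_kmers)
  out[kmer] <- score
  n_def <- length(all_kmers) - length(kmer)
  if (n_def > 0L) message(n_def, " absent ", key_length, "-mer(s) defaulted to 0")
  attr(out, "n_defaulted") <- n_def
  out
}

.all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}
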