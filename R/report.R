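#' Assemble the per-variant annotation table
#'
#' Bundles the stage outputs for a set of variants into one table, one
#' row per input variant (duplicate inputs keep duplicate rows), with
#' the presentation rules applied:
#' \itemize{
#'   \item splicing verdicts are shown only when not `"none"`, with a
#'     highlight flag for intronic variants;
#'   \item the mean MFE z-score is shown only when the backends agree in
#'     direction, with a strong flag when every |z| exceeds 1;
#'   \item a miRNA summary is shown only when the direction-agreement /
#'     total-change rule fired, with an upstream flag for 5' UTR
#'     variants.
#' }
#' Absent stages render as `NA` (blank cells on write), never as 0.
#'
#' @param variants List of `hgvs_variant` objects (or character names,
#'   parsed on the fly).
#' @param conservation Named numeric vector of fraction-matching values,
#'   keyed by variant name.
#' @param splicing Named list of [assess_splicing()] results.
#' @param mfe Named list of [mfe_consensus()] results.
#' @param mirna Named list of [summarize_mirna()] results.
#' @return Data.frame with columns `variant`, `location`,
#'   `fraction_matching`, `splicing`, `splice_highlight`, `mfe_z`,
#'   `mfe_strong`, `mirna_summary`, `mirna_upstream`.
#' @export
build_annotation_table <- function(variants, conservation = NULL,
                                   splicing = NULL, mfe = NULL,
                                   mirna = NULL) {
  variants <- lapply(variants, function(v) {
    if (is.character(v)) parse_hgvs(v) else v
  })
  stopifnot(all(vapply(variants, inherits, logical(1), "hgvs_variant")))
  ids <- vapply(variants, format_hgvs, character(1))
  .check_keys <- function(x, what) {
    if (!is.null(x) && length(x) && !all(names(x) %in% ids)) {
      stop(what, " output references unknown variant id '",
           setdiff(names(x), ids)[1], "'")
    }
  }
  .check_keys(conservation, "conservation")
  .check_keys(splicing, "splicing")
  .check_keys(mfe, "mfe")
  .check_keys(mirna, "mirna")
  rows <- lapply(seq_along(variants), function(i) {
    id <- ids[i]
    v <- variants[[i]]
    spl <- splicing[[id]]
    cons <- mfe[[id]]
    mir <- mirna[[id]]
    data.frame(
      variant = id,
      location = hgvs_location(v),
      fraction_matching = if (!is.null(conservation) && id %in% names(conservation))
        unname(conservation[[id]]) else NA_real_,
      splicing = if (!is.null(spl) && spl$verdict != "none")
        paste(.cap(spl$verdict), "splicing change") else NA_character_,
      splice_highlight = !is.null(spl) && spl$verdict != "none" &&
        spl$intron_highlight,
      mfe_z = if (!is.null(cons) && cons$direction_agreement)
        cons$mean_z else NA_real_,
      mfe_strong = !is.null(cons) && cons$strong_flag,
      mirna_summary = if (!is.null(mir) && mir$summary != "none")
        paste("miRNA", mir$summary) else NA_character_,
      mirna_upstream = !is.null(mir) && mir$summary != "none" &&
        mir$upstream_flag
    )
  })
  do.call(rbind, rows)
}

.cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Write an annotation table as TSV
#'
#' Styling is encoded as explicit logical flag columns
#' (`splice_highlight`, `mfe_strong`, `mirna_upstream`) rather than
#' colors; `NA` cells are written blank.
#'
#' @param x Data.frame from [build_annotation_table()].
#' @param path Output TSV path.
#' @export
write_annotation_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an annotation TSV written by [write_annotation_table()]
#'
#' @param path TSV path.
#' @return Data.frame with the same column types as
#'   [build_annotation_table()] produces.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, colClasses = "character", na.strings = "")
  df$fraction_matching <- as.numeric(df$fraction_matching)
  df$mfe_z <- as.numeric(df$mfe_z)
  for (col in c("splice_highlight", "mfe_strong", "mirna_upstream")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}
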