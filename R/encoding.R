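#' The 20 standard amino acids, one-letter codes, alphabetical
#' @keywords internal
#' @noRd
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Map a physicochemical factor score into (0, 1)
#'
#' Residue factor scores (here, the Atchley molecular-volume factor) are
#' signed reals; the grey model requires a strictly positive series. The
#' logistic transform `1 / (1 + exp(-x))` maps any finite score into the
#' open interval (0, 1) and preserves order.
#'
#' @param factor_score Numeric vector of finite factor scores.
#' @return Numeric vector of the same length, strictly inside (0, 1).
#' @examples
#' code_from_factor(0)       # 0.5, the symmetry point
#' code_from_factor(-0.733)  # alanine's code, 0.325 to 3 d.p.
#' @export
code_from_factor <- function(factor_score) {
  if (!is.numeric(factor_score) || length(factor_score) == 0L) {
    stop("`factor_score` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(factor_score))) {
    stop("`factor_score` must be finite", call. = FALSE)
  }
  stats::plogis(factor_score)
}

#' Residue code table
#'
#' Builds the table mapping each of the 20 standard amino acids to its
#' molecular-volume factor score and the derived numeric code in (0, 1).
#' The default scores ship with the package as a plain tab-separated
#' resource; supply `path` to substitute any other single-factor
#' physicochemical encoding (two columns: `residue`, `factor_score`).
#'
#' Codes are always computed at full floating precision from the factor
#' scores, never read pre-rounded, so downstream grey-model fits do not
#' compound rounding error.
#'
#' @param path Optional path to a two-column TSV (`residue`, `factor_score`)
#'   covering exactly the 20 standard residues.
#' @return A data frame of class `residue_code_table` with columns
#'   `residue`, `factor_score`, `numeric_code`, ordered alphabetically by
#'   one-letter code.
#' @examples
#' tab <- residue_code_table()
#' round(tab$numeric_code[tab$residue == "Y"], 3)  # 0.957
#' @export
residue_code_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "molecular_volume_factors.tsv",
                        package = "greyDBP", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "factor_score") %in% names(tab))) {
    stop("residue table needs columns `residue` and `factor_score`",
         call. = FALSE)
  }
  tab$residue <- toupper(trimws(tab$residue))
  if (anyDuplicated(tab$residue)) {
    stop("residue table contains duplicated residues", call. = FALSE)
  }
  missing <- setdiff(AA_ALPHABET, tab$residue)
  extra <- setdiff(tab$residue, AA_ALPHABET)
  if (length(missing) || length(extra)) {
    stop("residue table must cover exactly the 20 standard amino acids ",
         "(missing: ", paste(missing, collapse = ","),
         "; unexpected: ", paste(extra, collapse = ","), ")", call. = FALSE)
  }
  tab <- tab[match(AA_ALPHABET, tab$residue), c("residue", "factor_score")]
  tab$numeric_code <- code_from_factor(tab$factor_score)
  rownames(tab) <- tab$residue
  class(tab) <- c("residue_code_table", "data.frame")
  tab
}

#' Encode a protein sequence as a numeric series
#'
#' Translates each standard residue into its numeric code, producing the
#' strictly positive series the GM(2,1) grey model is fitted to. Order is
#' preserved. Non-standard characters (X, B, Z, U, O, J, gaps, ...) are
#' either dropped (`"skip"`, the default, with a warning) or rejected
#' (`"error"`, naming the first offending position).
#'
#' @param sequence A single amino acid string; case-insensitive.
#' @param table A [residue_code_table()].
#' @param unknown_policy `"skip"` or `"error"`.
#' @return Numeric vector of codes, one per encodable residue, with
#'   attribute `n_skipped` giving the number of dropped characters.
#' @examples
#' round(encode_sequence("AY"), 3)  # 0.325 0.957
#' @export
encode_sequence <- function(sequence, table = residue_code_table(),
                            unknown_policy = c("skip", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, table$residue)
  bad <- which(is.na(idx))
  if (length(bad) && unknown_policy == "error") {
    stop(sprintf("non-standard residue '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  if (length(bad)) {
    warning(sprintf("skipped %d non-standard residue(s)", length(bad)),
            call. = FALSE)
  }
  series <- table$numeric_code[idx[!is.na(idx)]]
  attr(series, "n_skipped") <- length(bad)
  series
}
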