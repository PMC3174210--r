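#' Amino acid composition
#'
#' Occurrence frequencies of the 20 standard residues, in alphabetical
#' one-letter order. Non-standard characters are excluded from both the
#' counts and the denominator, so the result is always a distribution over
#' the 20 standard types.
#'
#' @param sequence A single amino acid string with at least one standard
#'   residue; case-insensitive.
#' @return Named numeric vector of length 20 summing to 1.
#' @examples
#' amino_acid_composition("AAY")  # A = 2/3, Y = 1/3
#' @export
amino_acid_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  total <- sum(counts)
  if (total == 0L) {
    stop("sequence contains no standard amino acid residues", call. = FALSE)
  }
  setNames(as.numeric(counts) / total, AA_ALPHABET)
}

#' Column names of the 23-component PseAAC vector
#' @keywords internal
#' @noRd
PSEAAC_COLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                 "abs_a1", "abs_a2", "abs_b")

#' 23-component pseudo amino acid composition
#'
#' Concatenates the 20 amino acid frequencies with the grey-model feature
#' triple (|a1|, |a2|, |b|) fitted to the molecular-volume encoding of the
#' sequence. No rescaling is applied between the two blocks; the downstream
#' tree ensemble is invariant to monotone per-feature scaling anyway.
#'
#' @inheritParams encode_sequence
#' @return Named numeric vector of length 23 (`A` ... `Y`, `abs_a1`,
#'   `abs_a2`, `abs_b`).
#' @examples
#' v <- pseaac("ACDEFGHIKLMNPQRSTVWY")
#' sum(v[1:20])  # 1
#' @export
pseaac <- function(sequence, table = residue_code_table(),
                   unknown_policy = c("skip", "error")) {
  series <- encode_sequence(sequence, table, unknown_policy)
  if (length(series) < 4L) {
    stop(sprintf(
      "sequence has %d encodable residue(s); GM(2,1) needs at least 4",
      length(series)), call. = FALSE)
  }
  c(amino_acid_composition(sequence), grey_features(series))
}

#' Feature matrix for a set of sequences
#'
#' Applies [pseaac()] to each sequence; sequences with fewer than four
#' encodable residues are dropped with a message naming them.
#'
#' @param sequences Character vector of amino acid sequences.
#' @param ids Character vector of row identifiers (defaults to names of
#'   `sequences` or seq_1..seq_n).
#' @inheritParams encode_sequence
#' @return Numeric matrix, one 23-column row per usable sequence, rownames
#'   set to ids; attribute `skipped` lists the ids of dropped sequences.
#' @export
pseaac_matrix <- function(sequences, ids = NULL,
                          table = residue_code_table(),
                          unknown_policy = c("skip", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  if (is.null(ids)) {
    ids <- if (!is.null(names(sequences))) names(sequences) else
      sprintf("seq_%d", seq_along(sequences))
  }
  stopifnot(length(ids) == length(sequences))
  rows <- vector("list", length(sequences))
  ok <- logical(length(sequences))
  for (i in seq_along(sequences)) {
    row <- tryCatch(
      suppressWarnings(pseaac(sequences[[i]], table, unknown_policy)),
      error = function(e) NULL)
    ok[i] <- !is.null(row)
    rows[i] <- list(row)
  }
  if (any(!ok)) {
    message("dropped ", sum(!ok), " sequence(s) unusable for PseAAC: ",
            paste(ids[!ok], collapse = ", "))
  }
  mat <- do.call(rbind, rows[ok])
  rownames(mat) <- ids[ok]
  colnames(mat) <- PSEAAC_COLS
  attr(mat, "skipped") <- ids[!ok]
  mat
}

#' Write / read a feature matrix as TSV
#'
#' Plain tab-separated text with an `id` column followed by the 23 PseAAC
#' columns. Values are written with 17 significant digits so the round trip
#' through [read_features()] is bit-exact.
#'
#' @param mat Numeric matrix with 23 columns and rownames (ids).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(mat, path) {
  stopifnot(is.matrix(mat), ncol(mat) == length(PSEAAC_COLS))
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[PSEAAC_COLS[j]]] <- sprintf("%.17g", mat[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @return `read_features()` returns the numeric matrix with rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", rep("numeric", 23L)))
  if (!identical(names(df), c("id", PSEAAC_COLS))) {
    stop("feature file header must be: id, ", paste(PSEAAC_COLS, collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(df[, PSEAAC_COLS])
  rownames(mat) <- df$id
  mat
}
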