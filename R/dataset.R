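#' Read a FASTA file of protein records
#'
#' Headers are parsed up to the first whitespace as the record id. A
#' trailing `|1` (binding) or `|0` (non-binding) token on the id is
#' recognised as a class label; alternatively pass a two-column sidecar TSV
#' (`id`, `label`, where label is `1`/`0` or `binding`/`non-binding`).
#' Structural problems (empty file, header with no sequence, sequence before
#' any header) are reported with the offending line number; duplicate ids
#' are reported by id.
#'
#' @param path FASTA file path.
#' @param labels Optional path to a label sidecar TSV.
#' @return A data frame of class `protein_dataset` with columns `id`,
#'   `sequence`, and `label` (factor with levels `binding`, `non-binding`,
#'   `NA` when unlabeled).
#' @export
read_fasta <- function(path, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  header_at <- which(startsWith(lines, ">"))
  if (length(header_at) == 0L) {
    stop(sprintf("%s: no FASTA header found (line 1)", path), call. = FALSE)
  }
  first_content <- which(keep)[1]
  if (!startsWith(lines[first_content], ">")) {
    stop(sprintf("%s: sequence data before first header (line %d)",
                 path, first_content), call. = FALSE)
  }
  ids <- character(0); seqs <- character(0)
  bounds <- c(header_at, length(lines) + 1L)
  for (i in seq_along(header_at)) {
    h <- header_at[i]
    id <- strsplit(trimws(sub("^>", "", lines[h])), "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("%s: empty record id (line %d)", path, h), call. = FALSE)
    }
    body <- lines[seq(h + 1L, bounds[i + 1L] - 1L)[seq_len(bounds[i + 1L] - h - 1L)]]
    seq <- paste(gsub("\\s", "", body), collapse = "")
    if (!nzchar(seq)) {
      stop(sprintf("%s: header '%s' has no sequence (line %d)", path, id, h),
           call. = FALSE)
    }
    ids <- c(ids, id); seqs <- c(seqs, seq)
  }

  label <- rep(NA_character_, length(ids))
  tok <- regmatches(ids, regexpr("\\|[01]$", ids))
  has_tok <- grepl("\\|[01]$", ids)
  label[has_tok] <- ifelse(sub("\\|", "", tok) == "1", "binding", "non-binding")
  ids[has_tok] <- sub("\\|[01]$", "", ids[has_tok])

  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate record id '%s'", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }

  if (!is.null(labels)) {
    sidecar <- utils::read.delim(labels, stringsAsFactors = FALSE,
                                 colClasses = "character")
    names(sidecar)[1:2] <- c("id", "label")
    m <- match(ids, sidecar$id)
    lab <- sidecar$label[m]
    lab[lab %in% c("1", "binding")] <- "binding"
    lab[lab %in% c("0", "non-binding")] <- "non-binding"
    label <- lab
  }

  protein_dataset(ids, seqs, label)
}

#' Construct a labeled protein dataset
#'
#' @param id Character vector of unique, non-empty record ids.
#' @param sequence Character vector of non-empty amino acid sequences.
#' @param label Optional labels (`binding` / `non-binding`, or NA).
#' @return A `protein_dataset` data frame.
#' @export
protein_dataset <- function(id, sequence, label = NA_character_) {
  stopifnot(length(id) == length(sequence))
  if (length(id) && (any(!nzchar(id)) || anyDuplicated(id))) {
    stop("record ids must be non-empty and unique", call. = FALSE)
  }
  if (length(sequence) && any(!nzchar(sequence))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  label <- factor(rep_len(as.character(label), length(id)),
                  levels = c("binding", "non-binding"))
  structure(data.frame(id = as.character(id), sequence = as.character(sequence),
                       label = label, stringsAsFactors = FALSE),
            class = c("protein_dataset", "data.frame"))
}

#' @export
print.protein_dataset <- function(x, ...) {
  counts <- table(x$label, useNA = "ifany")
  cat(sprintf("protein_dataset: %d record(s) [%s]\n", nrow(x),
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write records to FASTA
#'
#' Labels, when present, are carried in the header as a trailing `|1`/`|0`
#' token so that [read_fasta()] round-trips them.
#'
#' @param records A `protein_dataset` (or data frame with `id`, `sequence`,
#'   optional `label`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    if (!is.null(records$label) && !is.na(records$label[i])) {
      id <- paste0(id, "|", if (records$label[i] == "binding") "1" else "0")
    }
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    out <- c(out, paste0(">", id), substring(seq, starts,
                                             pmin(starts + width - 1L, nchar(seq))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Benchmark screening filters
#'
#' `filter_min_length()` removes sequences shorter than `min_len` residues
#' (likely fragments); `filter_x_runs()` removes sequences whose longest run
#' of consecutive `X` characters exceeds `max_run` (too many unknown
#' residues). Both return a disjoint, exhaustive partition of the input.
#'
#' @param records A `protein_dataset`.
#' @param min_len Minimum sequence length kept (default 50).
#' @param max_run Longest tolerated run of consecutive X (default 10).
#' @return A list with elements `kept` and `removed`, both `protein_dataset`s.
#' @export
filter_min_length <- function(records, min_len = 50L) {
  keep <- nchar(records$sequence) >= min_len
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' @rdname filter_min_length
#' @export
filter_x_runs <- function(records, max_run = 10L) {
  longest_x <- vapply(records$sequence, function(s) {
    runs <- regmatches(s, gregexpr("X+", toupper(s)))[[1]]
    if (length(runs) == 0L) 0L else max(nchar(runs))
  }, integer(1), USE.NAMES = FALSE)
  keep <- longest_x <= max_run
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Greedy pairwise-identity redundancy filter
#'
#' A reproducible, dependency-free stand-in for culling servers such as
#' PISCES: records are visited in input order and a record is kept only if
#' its identity to every previously kept record is at most `max_identity`.
#' Identity is matches / alignment length (PID1) of a global
#' Needleman-Wunsch alignment under BLOSUM62 with gap opening 10 and gap
#' extension 0.5. Pairs of real culling output can instead be imported as a
#' plain id list and applied with ordinary subsetting.
#'
#' @param records A `protein_dataset`.
#' @param max_identity Maximum tolerated pairwise identity fraction
#'   (default 0.25).
#' @return The kept records as a `protein_dataset`.
#' @export
greedy_identity_filter <- function(records, max_identity = 0.25) {
  n <- nrow(records)
  if (n <= 1L) return(records)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  kept <- integer(0)
  for (i in seq_len(n)) {
    redundant <- FALSE
    for (j in kept) {
      aln <- Biostrings::pairwiseAlignment(
        records$sequence[i], records$sequence[j], type = "global",
        substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5)
      if (Biostrings::pid(aln, type = "PID1") / 100 > max_identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  records[kept, , drop = FALSE]
}

#' Default per-class residue frequency profiles
#'
#' The positive (DNA-binding) profile is enriched in lysine and arginine
#' (0.15 each), mimicking the positive-charge bias of real DNA binders; the
#' remaining mass is spread uniformly. The negative profile is uniform
#' (0.05 per residue).
#'
#' @return A list with numeric vectors `binding` and `non_binding`, each a
#'   distribution over the 20 standard residues.
#' @export
default_class_profiles <- function() {
  pos <- setNames(rep((1 - 0.30) / 18, 20), AA_ALPHABET)
  pos[c("K", "R")] <- 0.15
  neg <- setNames(rep(0.05, 20), AA_ALPHABET)
  list(binding = pos, non_binding = neg)
}

#' Generate a synthetic labeled two-class dataset
#'
#' Sequences are drawn i.i.d. per position from a per-class residue
#' frequency profile, with lengths uniform on `length_range`. This emulates
#' the compositional signal that separates DNA binders from non-binders
#' (charge bias) while carrying none of the positional or evolutionary
#' structure of real proteins; it exists so every pipeline stage is testable
#' without downloads.
#'
#' @param n_per_class Records per class (the benchmark uses 212).
#' @param length_range Integer pair `(min, max)`; min must be >= 50 to match
#'   the fragment filter.
#' @param profiles List with `binding` and `non_binding` residue
#'   distributions (defaults to [default_class_profiles()]).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A labeled `protein_dataset` with `2 * n_per_class` records.
#' @export
generate_synthetic <- function(n_per_class = 212L,
                               length_range = c(50L, 300L),
                               profiles = default_class_profiles(),
                               seed = 1L) {
  stopifnot(n_per_class >= 1L, length(length_range) == 2L,
            length_range[1] >= 50L, length_range[1] <= length_range[2])
  for (p in profiles[c("binding", "non_binding")]) {
    if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("class profiles must be valid distributions over the 20 residues",
           call. = FALSE)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draw <- function(profile, n, tag) {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = profile),
            collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s_%03d", tag, seq_len(n)), sequence = seqs,
               stringsAsFactors = FALSE)
  }
  pos <- draw(profiles$binding, n_per_class, "bind")
  neg <- draw(profiles$non_binding, n_per_class, "nonb")
  protein_dataset(c(pos$id, neg$id), c(pos$sequence, neg$sequence),
                  rep(c("binding", "non-binding"), each = n_per_class))
}
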