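#' Canonical PSI-BLAST amino-acid column order
#'
#' The 20 standard residues in the order printed by the PSI-BLAST ASCII
#' PSSM header (`A R N D C Q E G H I L K M F P S T W Y V`). All score
#' matrices in this package index their 20 columns by this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity codes tolerated in FASTA input (B/Z/X/U/O plus gap-free J).
AA_AMBIG <- c("B", "Z", "X", "U", "O", "J")

#' Read a multi-record FASTA file of protein sequences
#'
#' Thin validated wrapper around [Biostrings::readAAStringSet()]. Residues
#' are upper-cased and surrounding whitespace stripped; record ids are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are protein ids).
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(suppressWarnings(Biostrings::readAAStringSet(path)),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty header in '", path, "'", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop("empty sequence for id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- paste0(c(AA_ORDER, AA_AMBIG, "*", "-"), collapse = "")
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector (names are ids).
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a PSSM object
#'
#' A position-specific scoring matrix: one row per residue of the protein,
#' 20 columns of log-odds substitution scores in the canonical
#' [AA_ORDER] column order.
#'
#' @param protein_id Protein identifier (nonempty string).
#' @param scores Numeric N x 20 matrix with finite entries.
#' @return An object of class `"pssm"`.
#' @export
pssm <- function(protein_id, scores) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L, nzchar(protein_id))
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("PSSM must have exactly 20 columns, got ", ncol(scores), call. = FALSE)
  if (nrow(scores) < 1L) stop("PSSM must have at least one row", call. = FALSE)
  if (!all(is.finite(scores))) stop("PSSM scores must be finite", call. = FALSE)
  storage.mode(scores) <- "double"
  colnames(scores) <- AA_ORDER
  rownames(scores) <- NULL
  structure(list(protein_id = protein_id, scores = scores, n = nrow(scores)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s': %d residues x 20 scores (range %g..%g)\n",
              x$protein_id, x$n, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, a column-header
#' line, then one row per residue carrying the position index, the residue
#' letter, 20 log-odds columns and 20 weighted-percentage columns, followed
#' by trailer lines. Only the first 20 numeric columns (the log-odds block)
#' are retained, matching the evolutionary-score input the pipeline uses.
#'
#' @param path Path to an ASCII PSSM file.
#' @param protein_id Id to assign; defaults to the file name without
#'   extension.
#' @return A [pssm] object whose row count equals the residue count.
#' @export
read_ascii_pssm <- function(path, protein_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  # data rows start with an integer position index followed by a residue letter
  is_row <- grepl("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!any(is_row))
    stop("no PSSM data rows found in '", path, "' (truncated file?)", call. = FALSE)
  rows <- lines[is_row]
  mat <- matrix(NA_real_, nrow = length(rows), ncol = 20L)
  res <- character(length(rows))
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    res[i] <- tok[2]
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    # full dialect: 20 log-odds + 20 percentages (+ 2 info/weight trailers);
    # accept >= 20 numeric fields but require the canonical 40 when present
    if (anyNA(num[seq_len(min(20L, length(num)))]))
      stop("non-numeric score in PSSM row ", i, " of '", path, "'", call. = FALSE)
    if (length(num) != 20L && length(num) < 40L)
      stop("PSSM row ", i, " of '", path, "' has ", length(num),
           " numeric fields; expected 40 (or a bare 20-column block)",
           call. = FALSE)
    mat[i, ] <- num[1:20]
  }
  out <- pssm(protein_id, mat)
  attr(out, "residues") <- paste0(res, collapse = "")
  out
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_ascii_pssm()] parses back bit-exactly for
#' integer scores: two header lines, the column-header line, one row per
#' residue with 20 log-odds and 20 (zero-filled) percentage columns, and a
#' trailer. Used by the synthetic-fixture writer so synthetic and real
#' inputs travel the same code path.
#'
#' @param x A [pssm] object.
#' @param path Output file path.
#' @param residues Optional residue string (length `x$n`); defaults to the
#'   per-row argmax column letter.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(x, path, residues = NULL) {
  stopifnot(inherits(x, "pssm"))
  if (is.null(residues)) {
    residues <- attr(x, "residues")
    if (is.null(residues))
      residues <- paste0(AA_ORDER[max.col(x$scores, ties.method = "first")],
                         collapse = "")
  }
  stopifnot(nchar(residues) == x$n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", AA_ORDER), collapse = " "),
                    "  ",
                    paste(sprintf("%3s", AA_ORDER), collapse = " ")), con)
  fmt <- function(v) paste(sprintf("%3d", as.integer(round(v))), collapse = " ")
  for (i in seq_len(x$n)) {
    writeLines(sprintf("%5d %s  %s  %s  %4.2f %8.2f",
                       i, substr(residues, i, i),
                       fmt(x$scores[i, ]),
                       paste(rep("  0", 20L), collapse = " "),
                       0, 0), con)
  }
  writeLines(c("", "                      K         Lambda", ""), con)
  invisible(path)
}

#' Read a labeled protein-pair list
#'
#' Tab-separated file with three columns `id_a`, `id_b`, `label` (0 =
#' non-interacting, 1 = interacting). Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @param ids Optional character vector of known protein ids; if supplied,
#'   every pair id must resolve against it.
#' @return A data.frame with columns `id_a`, `id_b` (character) and
#'   `label` (integer), rows in file order.
#' @export
read_pair_list <- function(path, ids = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(id_a = character(0), id_b = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("pair-list line ", which(nf != 3L)[1], " has ", nf[nf != 3L][1],
         " fields; expected 3 (id_a, id_b, label)", call. = FALSE)
  df <- data.frame(id_a = vapply(parts, `[`, "", 1L),
                   id_b = vapply(parts, `[`, "", 2L),
                   label = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
                   stringsAsFactors = FALSE)
  if (anyNA(df$label) || !all(df$label %in% c(0L, 1L)))
    stop("pair labels must be 0 or 1", call. = FALSE)
  if (!is.null(ids)) {
    missing <- setdiff(unique(c(df$id_a, df$id_b)), ids)
    if (length(missing))
      stop("pair list references unknown id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a labeled pair list as TSV
#'
#' @param pairs Data.frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id_a\tid_b\tlabel", con)
  writeLines(sprintf("%s\t%s\t%d", pairs$id_a, pairs$id_b, pairs$label), con)
  invisible(path)
}

#' Drop proteins shorter than a minimum length
#'
#' Benchmark PPI datasets are conventionally restricted to proteins of at
#' least 50 residues; this utility applies that length filter to a
#' sequence collection. Sequence-identity clustering is out of scope here
#' and must be done upstream with a dedicated tool.
#'
#' @param seqs Named character vector of sequences.
#' @param min_length Minimum residue count to keep (default 50).
#' @return The filtered named vector.
#' @export
filter_min_length <- function(seqs, min_length = 50L) {
  seqs[nchar(seqs) >= min_length]
}
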