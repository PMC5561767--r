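#' Construct a PSSM object
#'
#' A PSSM is an `L x 20` matrix of per-position residue scores for one
#' protein, together with the residue order of its columns and the residue
#' observed at each position. Positions are 1-based in files and in the
#' `sequence` field; row `i` of `scores` is position `i`.
#'
#' @param protein_id Single string identifying the protein.
#' @param scores Numeric `L x 20` matrix (rows = positions, columns =
#'   residues in `column_order`).
#' @param column_order Character vector of the 20 residue one-letter codes
#'   giving the column order; defaults to the PSI-BLAST order.
#' @param sequence Optional character vector of length `L` with the residue
#'   letter at each position (PSI-BLAST's second column). Defaults to `"X"`.
#' @param source One of `"psiblast_ascii"`, `"pseudo_dayhoff"`,
#'   `"synthetic"`.
#' @return An object of class `"pssm"` with fields `protein_id`, `length`,
#'   `scores`, `column_order`, `sequence`, `source`.
#' @examples
#' p <- new_pssm("toy", matrix(0, 25, 20))
#' p$length
#' @export
new_pssm <- function(protein_id, scores,
                     column_order = pssm_residues(),
                     sequence = NULL,
                     source = c("synthetic", "psiblast_ascii", "pseudo_dayhoff")) {
  source <- match.arg(source)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L) {
    stop("PSSM scores must have exactly 20 columns, got ", ncol(scores))
  }
  if (nrow(scores) < 1L) stop("PSSM must have at least one position row")
  column_order <- as.character(column_order)
  if (length(column_order) != 20L || !setequal(column_order, pssm_residues())) {
    stop("column_order must be a permutation of the 20 standard residue codes")
  }
  L <- nrow(scores)
  if (is.null(sequence)) sequence <- rep("X", L)
  if (length(sequence) != L) {
    stop("sequence must have one residue letter per position (", L, ")")
  }
  colnames(scores) <- column_order
  structure(
    list(protein_id = as.character(protein_id), length = L, scores = scores,
         column_order = column_order, sequence = as.character(sequence),
         source = source),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s': %d positions x 20 residues (source: %s)\n",
              x$protein_id, x$length, x$source))
  cat("columns:", paste(x$column_order, collapse = " "), "\n")
  invisible(x)
}

#' Test two PSSMs for equality of scores and layout
#'
#' Compares length, column order and scores (after aligning columns);
#' `protein_id` must match, `source` is provenance and is ignored.
#'
#' @param a,b `"pssm"` objects.
#' @param tol Numeric tolerance on scores.
#' @return `TRUE` or `FALSE`.
#' @export
pssm_equal <- function(a, b, tol = 1e-9) {
  if (a$length != b$length) return(FALSE)
  if (!identical(a$protein_id, b$protein_id)) return(FALSE)
  sb <- b$scores[, a$column_order, drop = FALSE]
  max(abs(a$scores - sb)) <= tol
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Residues are upper-cased; characters outside the 20 standard codes are
#' mapped to `"X"` with a warning. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are ids, values residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("failed to parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA record with empty sequence: ", ids[empty[1L]])
  }
  std <- paste(pssm_residues(), collapse = "")
  nonstd <- grepl(sprintf("[^%s]", std), seqs)
  if (any(nonstd)) {
    warning("non-standard residues mapped to X in record(s): ",
            paste(ids[nonstd], collapse = ", "))
    seqs <- gsub(sprintf("[^%s]", std), "X", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, a residue-name header
#' row, then one row per position holding the 1-based position index, the
#' query residue, 20 integer log-odds scores, 20 weighted-percentage
#' columns, and (optionally) two trailing per-row statistics. The PSSM
#' `scores` are the log-odds block; the percentage block is returned as an
#' attribute `"percentages"` for users who prefer it.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A [new_pssm()] object with `source = "psiblast_ascii"`; the
#'   per-row residue letters populate `sequence`.
#' @export
parse_ascii_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  letters20 <- pssm_residues()
  header_i <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) %in% c(20L, 40L) && all(nchar(tok) == 1L) &&
        setequal(unique(tok), letters20)) {
      header_i <- i
      break
    }
  }
  if (is.na(header_i)) {
    stop("no PSSM column header found in ", path,
         " (expected a line of 20 or 40 residue letters)")
  }
  column_order <- strsplit(trimws(lines[header_i]), "\\s+")[[1]][1:20]

  rows <- list(); residues <- character(); index <- integer()
  for (i in seq(header_i + 1L, length(lines))) {
    if (i > length(lines)) break
    line <- trimws(lines[i])
    if (line == "") break
    tok <- strsplit(line, "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(tok[1]))
    if (is.na(pos)) break  # footer statistics (K, Lambda) or similar
    if (length(tok) < 2L || !grepl("^[A-Za-z*]$", tok[2])) {
      stop("malformed PSSM row at line ", i, " of ", path,
           ": missing residue letter")
    }
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(nums)) {
      stop("malformed PSSM row at line ", i, " of ", path,
           ": non-numeric score field")
    }
    # 40 score/percentage columns, optionally followed by 2 per-row stats
    if (!length(nums) %in% c(40L, 42L)) {
      stop("malformed PSSM row at line ", i, " of ", path, ": expected 40 ",
           "numeric columns (plus optional 2 statistics), got ", length(nums))
    }
    index <- c(index, pos)
    residues <- c(residues, toupper(tok[2]))
    rows[[length(rows) + 1L]] <- nums[1:40]
  }
  if (length(rows) == 0L) stop("no PSSM data rows found in ", path)
  if (!identical(index, seq_along(index))) {
    stop("non-contiguous position indices in ", path,
         " (expected 1..", length(index), ")")
  }
  block <- do.call(rbind, rows)
  pssm <- new_pssm(
    protein_id = sub("\\.[A-Za-z0-9]+$", "", basename(path)),
    scores = block[, 1:20, drop = FALSE],
    column_order = column_order,
    sequence = residues,
    source = "psiblast_ascii"
  )
  attr(pssm, "percentages") <- block[, 21:40, drop = FALSE]
  pssm
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits a file parseable by [parse_ascii_pssm()]. Scores are written
#' rounded to the nearest integer (the dialect's native precision); the
#' percentage block and trailing per-row statistics are written as zeros.
#'
#' @param pssm A [new_pssm()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"
  ), con)
  hdr <- paste0("      ",
                paste(sprintf("%3s", rep(pssm$column_order, 2)), collapse = ""))
  writeLines(hdr, con)
  sc <- round(pssm$scores)
  for (i in seq_len(pssm$length)) {
    writeLines(paste0(
      sprintf("%5d %s ", i, pssm$sequence[i]),
      paste(sprintf("%4d", sc[i, ]), collapse = ""),
      paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
      sprintf("  %.2f %.2f", 0, 0)
    ), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format NCBI BLAST ships (comment lines
#' starting with `#`, a header row of residue codes, one labelled row per
#' residue). Only the 20 standard residues are retained; the result is
#' checked for symmetry.
#'
#' @param path Path to an NCBI-format matrix file.
#' @param name Matrix name to record (defaults to the file name).
#' @return A 20 x 20 symmetric numeric matrix with dimnames in the file's
#'   residue order (restricted to the 20 standard codes), with attribute
#'   `"name"`.
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & trimws(lines) != ""]
  if (length(lines) < 2L) stop("not an NCBI matrix file: ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labs <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(vals) <- list(labs, cols)
  keep <- intersect(cols, pssm_residues())
  if (length(keep) != 20L) {
    stop("matrix in ", path, " does not cover the 20 standard residues")
  }
  m <- vals[keep, keep]
  if (max(abs(m - t(m))) > 0) stop("substitution matrix is not symmetric: ", path)
  attr(m, "name") <- name
  m
}

#' The Dayhoff PAM250 mutation matrix
#'
#' The classic Dayhoff mutation-probability-derived PAM250 log-odds matrix,
#' read from the NCBI-format copy bundled with the package.
#'
#' @return A 20 x 20 symmetric integer-valued matrix (see
#'   [read_substitution_matrix()]).
#' @export
dayhoff_matrix <- function() {
  path <- system.file("extdata", "PAM250.txt", package = "sipwelm",
                      mustWork = TRUE)
  read_substitution_matrix(path, name = "PAM250")
}

#' Pseudo-PSSM of a single sequence from a substitution matrix
#'
#' Fallback profile when no PSI-BLAST PSSM is available. The PSSM score of
#' residue j at position i is `sum_k m(i,k) * n(j,k)`, where `m(i,k)` is the
#' observed frequency of residue k at position i and `n` is a substitution
#' matrix. For a single sequence the frequency is an indicator of the
#' residue actually present, so row i is simply the substitution-matrix row
#' of that residue, reordered to the PSSM column order.
#'
#' @param residues Residue string (20 standard one-letter codes only).
#' @param sub Substitution matrix from [read_substitution_matrix()];
#'   defaults to [dayhoff_matrix()].
#' @param id Protein id to record.
#' @return A [new_pssm()] object with `source = "pseudo_dayhoff"`.
#' @export
compute_pseudo_pssm <- function(residues, sub = dayhoff_matrix(), id = "query") {
  residues <- toupper(as.character(residues))
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  if (length(residues) == 0L || identical(residues, "")) {
    stop("empty sequence")
  }
  bad <- which(!residues %in% pssm_residues())
  if (length(bad) > 0L) {
    stop("non-standard residue '", residues[bad[1L]], "' at position ", bad[1L])
  }
  cols <- pssm_residues()
  scores <- sub[residues, cols, drop = FALSE]
  rownames(scores) <- NULL
  new_pssm(id, scores, column_order = cols, sequence = residues,
           source = "pseudo_dayhoff")
}
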