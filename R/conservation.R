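#' Read a multiple sequence alignment
#'
#' FASTA or Clustal alignments via \pkg{seqinr}. Rows must have equal
#' length; the gap character is `-`.
#'
#' @param path alignment file.
#' @param format `"auto"` (guess from content), `"fasta"` or `"clustal"`.
#' @return object of class `lasso_msa`: list with `ids` and `rows`
#'   (uppercase aligned strings).
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "clustal") return(read_clustal(path))
  aln <- seqinr::read.alignment(path, format = format)
  new_msa(aln$nam, toupper(unlist(aln$seq)))
}

# Clustal via seqinr where possible; seqinr's reader requires the block of
# names to repeat (two or more wrapped blocks), so single-block files fall
# back to a direct scan of "<name> <chunk>" lines
read_clustal <- function(path) {
  aln <- tryCatch(seqinr::read.alignment(path, format = "clustal"),
                  error = function(e) NULL)
  if (!is.null(aln) && !anyNA(aln$nam) && !any(aln$nam == "NA"))
    return(new_msa(aln$nam, toupper(unlist(aln$seq))))
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "CLUSTAL")) stop("not a Clustal file: ", path)
  lines <- lines[-1L]
  body <- lines[nchar(trimws(lines)) > 0L & !startsWith(lines, " ")]
  m <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z.~-]+)", body))
  m <- m[lengths(m) == 3L]
  ids <- vapply(m, `[[`, character(1L), 2L)
  chunks <- vapply(m, `[[`, character(1L), 3L)
  uid <- unique(ids)
  rows <- vapply(uid, function(id)
    paste(chunks[ids == id], collapse = ""), character(1L))
  new_msa(uid, rows)
}

#' @rdname read_msa
#' @param ids sequence identifiers.
#' @param rows aligned sequences (equal-length strings).
#' @export
new_msa <- function(ids, rows) {
  rows <- toupper(as.character(rows))
  stopifnot(length(rows) >= 1L, length(ids) == length(rows))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must all have equal length")
  structure(list(ids = as.character(ids), rows = rows), class = "lasso_msa")
}

#' @export
print.lasso_msa <- function(x, ...) {
  cat(sprintf("<lasso_msa> %d sequences, %d columns\n",
              length(x$rows), nchar(x$rows[1L])))
  invisible(x)
}

# pairwise identity: matches over columns where both rows are non-gap
pair_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  sum(ca[both] == cb[both]) / sum(both)
}

#' Remove highly redundant alignment rows
#'
#' Greedy reduction: rows are visited in order and a row is dropped when its
#' pairwise identity to an already-kept row reaches `identity`. Idempotent.
#'
#' @param msa a `lasso_msa`.
#' @param identity redundancy threshold as a fraction (default 0.95).
#' @return the reduced `lasso_msa`.
#' @export
msa_dedupe <- function(msa, identity = 0.95) {
  keep <- integer()
  for (i in seq_along(msa$rows)) {
    dup <- any(vapply(keep, function(k)
      pair_identity(msa$rows[i], msa$rows[k]) >= identity, logical(1L)))
    if (!dup) keep <- c(keep, i)
  }
  new_msa(msa$ids[keep], msa$rows[keep])
}

#' Conservation of the two bridge-forming cysteines
#'
#' Fraction of alignment rows with a `C` at each of the two bridge columns;
#' gapped rows count as non-C (all aligned structures enter the
#' denominator).
#'
#' @param msa a `lasso_msa`.
#' @param col_i,col_j 1-based alignment columns of the bridge residues.
#' @return numeric vector `c(frac_i, frac_j)`.
#' @export
cysteine_conservation <- function(msa, col_i, col_j) {
  w <- nchar(msa$rows[1L])
  if (col_i < 1L || col_i > w || col_j < 1L || col_j > w)
    stop("alignment column out of range (width ", w, ")")
  frac <- function(col) mean(substr(msa$rows, col, col) == "C")
  c(frac_i = frac(col_i), frac_j = frac(col_j))
}

#' Bridge conservation class
#'
#' Highly conserved iff both cysteines are present in more than 80% of the
#' aligned structures; poorly conserved iff at least one is present in less
#' than 30%; medium otherwise. Boundaries are strict, so (0.8, 0.8) is
#' medium.
#'
#' @param frac_i,frac_j per-cysteine conservation fractions in [0, 1].
#' @return `"high"`, `"medium"` or `"poor"`.
#' @export
bridge_class <- function(frac_i, frac_j) {
  stopifnot(frac_i >= 0, frac_i <= 1, frac_j >= 0, frac_j <= 1)
  if (frac_i < 0.30 || frac_j < 0.30) return("poor")
  if (frac_i > 0.80 && frac_j > 0.80) return("high")
  "medium"
}

#' Map a structure residue to its alignment column
#'
#' Uses the structure's own (gapped) row in the MSA: the k-th non-gap
#' character of that row corresponds to structure residue k.
#'
#' @param msa a `lasso_msa`.
#' @param row_id identifier of the structure's row.
#' @param residue 1-based residue position in the ungapped sequence.
#' @return alignment column index.
#' @export
residue_to_column <- function(msa, row_id, residue) {
  r <- match(row_id, msa$ids)
  if (is.na(r)) stop("row '", row_id, "' not in alignment")
  chars <- strsplit(msa$rows[r], "")[[1L]]
  cols <- which(chars != "-")
  if (residue < 1L || residue > length(cols))
    stop("residue ", residue, " outside the ungapped row (length ",
         length(cols), ")")
  cols[residue]
}

#' Conservation table for a set of bridges
#'
#' @param msa a `lasso_msa`.
#' @param bridges data.frame with alignment columns `col_i`, `col_j` (one
#'   row per bridge).
#' @param path optional TSV output file.
#' @return data.frame with fractions and conservation class per bridge.
#' @export
conservation_table <- function(msa, bridges, path = NULL) {
  out <- do.call(rbind, lapply(seq_len(nrow(bridges)), function(k) {
    f <- cysteine_conservation(msa, bridges$col_i[k], bridges$col_j[k])
    data.frame(col_i = bridges$col_i[k], col_j = bridges$col_j[k],
               frac_i = unname(f[1L]), frac_j = unname(f[2L]),
               class = bridge_class(f[1L], f[2L]))
  }))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
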