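#' Aggregate survey statistics over classification results
#'
#' Summarizes a set of per-chain detection results the way PDB-wide lasso
#' surveys are reported: counts per major type, the fraction of C-tail
#' piercing loops, the fraction of loops whose bridge-nearest piercing is
#' negative, bridge-to-nearest-piercing distance histograms split by that
#' sign, pierced-loops-per-chain and fingerprint counts. Two-sided (LL/LLS)
#' loops are excluded from the tail and sign fractions, exactly as the
#' survey convention excludes them (their two tails have no single
#' "piercing side").
#'
#' @param results list of `lasso_result` objects (see [detect_chain()]).
#' @return object of class `lasso_survey`: list with `major_counts`,
#'   `tail_fraction`, `negative_fraction`, `distance_hist_by_sign`,
#'   `loops_per_chain`, `fingerprint_counts`, `n_chains`, `n_pierced_loops`.
#' @export
lasso_survey <- function(results) {
  rows <- list()
  loops_per_chain <- integer()
  fingerprints <- character()
  for (res in results) {
    stopifnot(inherits(res, "lasso_result"))
    pierced <- 0L
    for (lp in res$loops) {
      if (!is.null(lp$error) || lp$klass == "L0") next
      pierced <- pierced + 1L
      p <- lp$piercings
      nearest <- p[which.min(ifelse(p$tail == "C",
                                    p$seg_from - lp$res_j,
                                    lp$res_i - p$seg_from)), ]
      rows[[length(rows) + 1L]] <- data.frame(
        major = lp$major, klass = lp$klass,
        tail = nearest$tail, nearest_sign = nearest$sign,
        bridge_distance = lp$bridge_distance)
    }
    loops_per_chain <- c(loops_per_chain, pierced)
    fingerprints <- c(fingerprints, res$fingerprint$text)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(major = character(), klass = character(), tail = character(),
               nearest_sign = integer(), bridge_distance = integer())
  one_sided <- tab[!tab$klass %in% c("LL", "LLS"), , drop = FALSE]
  frac <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  hist_by <- function(sgn) {
    d <- one_sided$bridge_distance[one_sided$nearest_sign == sgn]
    if (length(d) == 0L) return(table(integer()))
    table(factor(d, levels = seq.int(min(d), max(d))))
  }
  structure(list(
    major_counts = table(tab$major),
    tail_fraction = frac(one_sided$tail == "C"),
    negative_fraction = frac(one_sided$nearest_sign < 0L),
    distance_hist_by_sign = list(positive = hist_by(1L), negative = hist_by(-1L)),
    loops_per_chain = table(loops_per_chain),
    fingerprint_counts = table(fingerprints[fingerprints != ""]),
    n_chains = length(results),
    n_pierced_loops = nrow(tab)),
    class = "lasso_survey")
}

#' @export
print.lasso_survey <- function(x, ...) {
  cat(sprintf("Lasso survey over %d chain(s), %d pierced loop(s)\n",
              x$n_chains, x$n_pierced_loops))
  if (length(x$major_counts)) {
    cat("  major types: ",
        paste(names(x$major_counts), as.integer(x$major_counts),
              sep = ":", collapse = "  "), "\n")
  }
  cat(sprintf("  C-tail fraction (non-LL): %s\n", fmt_frac(x$tail_fraction)))
  cat(sprintf("  negative-nearest fraction (non-LL): %s\n",
              fmt_frac(x$negative_fraction)))
  invisible(x)
}

fmt_frac <- function(f) {
  if (is.na(f)) "undefined (no one-sided loops)" else sprintf("%.1f%%", 100 * f)
}

#' Write survey summaries as TSV
#'
#' @param survey a `lasso_survey`.
#' @param path output file prefix; `<path>_majors.tsv` and
#'   `<path>_fingerprints.tsv` are written.
#' @export
write_survey <- function(survey, path) {
  mj <- as.data.frame(survey$major_counts, stringsAsFactors = FALSE)
  names(mj) <- c("major", "count")
  utils::write.table(mj, paste0(path, "_majors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fp <- as.data.frame(survey$fingerprint_counts, stringsAsFactors = FALSE)
  if (ncol(fp) == 2L) names(fp) <- c("fingerprint", "count")
  utils::write.table(fp, paste0(path, "_fingerprints.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
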