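#' Chain, bridge and covalent-loop containers
#'
#' A `lasso_chain` holds one polymer chain as an ordered residue table
#' (1-based sequential `index`, original author numbering in `resno`,
#' 3-letter `name`, CA coordinates, isotropic B-factor, and a `virtual` flag
#' for residues modelled into gaps), plus optional alternative coordinate
#' sets (NMR models), recorded gaps, side-chain atoms relevant to bridges,
#' and any loop-closing bond records read from the source file.
#'
#' @param id chain identifier (single string).
#' @param residues data.frame with columns `index`, `resno`, `name`,
#'   `x`, `y`, `z`, `bfactor`, `virtual`.
#' @param models optional list of n x 3 CA coordinate matrices, one per model;
#'   model 1 must equal the coordinates in `residues`.
#' @param gaps data.frame of gap records (`start`, `end`, `n_missing`,
#'   `modeled`). Before gap modelling `start`/`end` are the indices of the
#'   flanking real residues; afterwards they delimit the inserted virtual span.
#' @param sidechain data.frame of side-chain heavy atoms (`index`, `atom`,
#'   `x`, `y`, `z`).
#' @param links data.frame of loop-closing bond records from the file
#'   (`resno_i`, `atom_i`, `resno_j`, `atom_j`, `rec`).
#' @return An object of class `lasso_chain`.
#' @export
new_chain <- function(id, residues, models = NULL,
                      gaps = empty_gaps(), sidechain = empty_sidechain(),
                      links = empty_links()) {
  stopifnot(is.data.frame(residues),
            all(c("index", "resno", "name", "x", "y", "z",
                  "bfactor", "virtual") %in% names(residues)))
  if (is.unsorted(residues$index, strictly = TRUE))
    stop("residue indices must be strictly increasing")
  if (anyNA(residues[, c("x", "y", "z")]))
    stop("all residues must have CA coordinates")
  if (!is.null(models)) {
    n <- nrow(residues)
    ok <- vapply(models, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3L,
                 logical(1L))
    if (!all(ok)) stop("all models must be n x 3 matrices over the same residue list")
  }
  structure(list(id = as.character(id), residues = residues, models = models,
                 gaps = gaps, sidechain = sidechain, links = links),
            class = "lasso_chain")
}

empty_gaps <- function() {
  data.frame(start = integer(), end = integer(), n_missing = integer(),
             modeled = logical())
}

empty_sidechain <- function() {
  data.frame(index = integer(), atom = character(),
             x = numeric(), y = numeric(), z = numeric())
}

empty_links <- function() {
  data.frame(resno_i = integer(), atom_i = character(),
             resno_j = integer(), atom_j = character(), rec = character())
}

#' @export
print.lasso_chain <- function(x, ...) {
  nr <- nrow(x$residues)
  nv <- sum(x$residues$virtual)
  cat(sprintf("<lasso_chain '%s'> %d residues (%d virtual), %d model(s), %d gap(s)\n",
              x$id, nr, nv, max(1L, length(x$models)), nrow(x$gaps)))
  invisible(x)
}

#' @export
length.lasso_chain <- function(x) nrow(x$residues)

# CA coordinates as an n x 3 matrix
chain_coords <- function(chain) {
  as.matrix(chain$residues[, c("x", "y", "z")])
}

new_bridges <- function(res_i = integer(), res_j = integer(),
                        chemistry = character(), source = character()) {
  stopifnot(all(res_i != res_j))
  swap <- res_i > res_j
  if (any(swap)) {
    tmp <- res_i[swap]; res_i[swap] <- res_j[swap]; res_j[swap] <- tmp
  }
  data.frame(res_i = as.integer(res_i), res_j = as.integer(res_j),
             chemistry = as.character(chemistry), source = as.character(source))
}

#' Extract covalent loops closed by bridges
#'
#' Each bridge closes the backbone span `res_i..res_j` into a covalent loop;
#' the flanking chain pieces are its N- and C-terminal tails. Loops whose
#' span is shorter than `min_span` residues are omitted (too short to span a
#' surface) and recorded in the `omitted` attribute.
#'
#' @param chain a `lasso_chain`.
#' @param bridges data.frame as returned by [detect_bridges()].
#' @param min_span minimal loop span in residues (default 4).
#' @return list of covalent loops (class `lasso_loop`), sorted by `res_i`,
#'   with an `omitted` attribute describing skipped bridges.
#' @export
extract_loops <- function(chain, bridges, min_span = 4L) {
  n <- nrow(chain$residues)
  if (nrow(bridges) > 0 && any(bridges$res_i < 1L | bridges$res_j > n))
    stop("bridge refers to residues outside the chain")
  omitted <- list()
  loops <- list()
  if (nrow(bridges) > 0) {
    ord <- order(bridges$res_i, bridges$res_j)
    bridges <- bridges[ord, , drop = FALSE]
    for (k in seq_len(nrow(bridges))) {
      b <- bridges[k, ]
      span_len <- b$res_j - b$res_i + 1L
      if (span_len < min_span) {
        omitted[[length(omitted) + 1L]] <-
          list(bridge = b, reason = "span-too-short")
        next
      }
      loops[[length(loops) + 1L]] <- structure(
        list(bridge = b,
             res_i = b$res_i, res_j = b$res_j,
             span = seq.int(b$res_i, b$res_j),
             n_tail = if (b$res_i > 1L) seq_len(b$res_i - 1L) else integer(),
             c_tail = if (b$res_j < n) seq.int(b$res_j + 1L, n) else integer()),
        class = "lasso_loop")
    }
  }
  attr(loops, "omitted") <- omitted
  loops
}

#' @export
print.lasso_loop <- function(x, ...) {
  cat(sprintf("<lasso_loop> span %d..%d (%s bridge), N-tail %d, C-tail %d residues\n",
              x$res_i, x$res_j, x$bridge$chemistry,
              length(x$n_tail), length(x$c_tail)))
  invisible(x)
}
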