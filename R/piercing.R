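#' Find oriented crossings of a tail through a spanning surface
#'
#' Every CA-CA segment of the tail polyline is tested against every surface
#' triangle with signed-volume orientation predicates (exact up to floating
#' point): segment PQ crosses triangle ABC iff P and Q lie strictly on
#' opposite sides of the triangle plane and the line PQ passes through the
#' triangle. Intersections on shared triangle edges are counted once
#' (deduplicated by parametric position). A segment lying exactly in a
#' triangle plane is resolved by a deterministic symbolic perturbation of
#' the segment, never random jitter, so results are machine-reproducible.
#'
#' The crossing sign is `+` iff the chain direction of *increasing residue
#' index* has positive dot product with the local triangle normal (triangles
#' are wound by the right-hand rule around the loop traversed N to C).
#' `tail_points` must be ordered *away from the loop*, starting at the
#' bridge residue; for the N-terminal tail that order runs against residue
#' numbering, which `tail_label = "N"` accounts for.
#'
#' @param surface a `lasso_surface` with consistent winding.
#' @param tail_points k x 3 matrix of CA positions ordered away from the loop.
#' @param tail_label `"N"` or `"C"`.
#' @param tail_resid integer vector of residue indices parallel to
#'   `tail_points` (used to report piercing segments); defaults to
#'   `1..k` which is only adequate for synthetic polylines.
#' @return data.frame of crossings ordered along the tail away from the
#'   loop: `tail`, `seg_from` (loop-proximal residue of the segment),
#'   `seg_to`, `sign` (+1/-1), `t` in [0,1] along the segment, `x`,`y`,`z`.
#' @export
find_crossings <- function(surface, tail_points, tail_label = c("C", "N"),
                           tail_resid = NULL) {
  tail_label <- match.arg(tail_label)
  orientation <- if (tail_label == "C") 1L else -1L
  if (is.null(tail_resid)) tail_resid <- seq_len(nrow(tail_points))
  stopifnot(length(tail_resid) == nrow(tail_points))
  V <- surface$V; F <- surface$F
  A <- V[F[, 1L], , drop = FALSE]
  B <- V[F[, 2L], , drop = FALSE]
  C <- V[F[, 3L], , drop = FALSE]
  scale <- max(1, max(abs(V)))
  tol <- 1e-12 * scale^3
  out <- list()
  nseg <- nrow(tail_points) - 1L
  if (nseg < 1L) return(empty_crossings())
  for (s in seq_len(nseg)) {
    p <- tail_points[s, ]; q <- tail_points[s + 1L, ]
    hits <- segment_tri_hits(p, q, A, B, C, tol)
    if (is.null(hits)) {
      # in-plane degeneracy: deterministic symbolic perturbation
      delta <- c(1, 2, 3) * 1e-7 * max(scale, vnorm(q - p))
      hits <- segment_tri_hits(p + delta, q + delta, A, B, C, tol)
      if (is.null(hits)) hits <- empty_hits()
    }
    if (nrow(hits) == 0L) next
    hits <- hits[order(hits$t), , drop = FALSE]
    # intersections shared by adjacent triangles (common edge/vertex): once
    keep <- !duplicated(round(hits$t / 1e-9))
    hits <- hits[keep, , drop = FALSE]
    hits$tail <- tail_label
    hits$seg_from <- tail_resid[s]
    hits$seg_to <- tail_resid[s + 1L]
    hits$sign <- as.integer(hits$sign * orientation)
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) return(empty_crossings())
  cr <- do.call(rbind, out)
  cr <- cr[, c("tail", "seg_from", "seg_to", "sign", "t", "x", "y", "z")]
  rownames(cr) <- NULL
  cr
}

empty_crossings <- function() {
  data.frame(tail = character(), seg_from = integer(), seg_to = integer(),
             sign = integer(), t = numeric(),
             x = numeric(), y = numeric(), z = numeric())
}

empty_hits <- function() {
  data.frame(sign = integer(), t = numeric(),
             x = numeric(), y = numeric(), z = numeric())
}

# all triangle crossings of one segment; NULL signals an unresolved
# in-plane degeneracy that needs the perturbation fallback
segment_tri_hits <- function(p, q, A, B, C, tol) {
  P <- matrix(p, nrow(A), 3L, byrow = TRUE)
  Q <- matrix(q, nrow(A), 3L, byrow = TRUE)
  N <- rowcross(B - A, C - A)                 # winding normal
  d1 <- rowSums(N * (P - A))                  # signed volume * 2
  d2 <- rowSums(N * (Q - A))
  # segment in a triangle's plane while overlapping its extent: degenerate
  degen <- abs(d1) <= tol & abs(d2) <= tol
  if (any(degen)) {
    near <- overlap_bbox(p, q, A[degen, , drop = FALSE],
                         B[degen, , drop = FALSE], C[degen, , drop = FALSE])
    if (any(near)) return(NULL)
  }
  # endpoint exactly on a triangle plane: symbolic tie-break to the positive
  # side, so a touch-and-cross counts once and a touch-and-return not at all;
  # tie-broken contacts must pass strictly through the triangle interior
  # (a graze through a corner or edge at the endpoint is not a crossing)
  tie <- (abs(d1) <= tol | abs(d2) <= tol) & !degen
  d1[abs(d1) <= tol & !degen] <- tol
  d2[abs(d2) <= tol & !degen] <- tol
  cand <- which(d1 * d2 < 0 & !degen)
  if (length(cand) == 0L) return(empty_hits())
  res <- empty_hits()
  for (i in cand) {
    a <- A[i, ]; b <- B[i, ]; c <- C[i, ]
    s1 <- det3(q - p, a - p, b - p)
    s2 <- det3(q - p, b - p, c - p)
    s3 <- det3(q - p, c - p, a - p)
    edge_tol <- if (tie[i]) -tol else tol
    pos <- c(s1, s2, s3) >= -edge_tol
    neg <- c(s1, s2, s3) <= edge_tol
    if (all(pos) || all(neg)) {
      t <- d1[i] / (d1[i] - d2[i])
      pt <- p + t * (q - p)
      res[nrow(res) + 1L, ] <- list(sign = if (d2[i] > d1[i]) 1L else -1L,
                                    t = t, x = pt[1], y = pt[2], z = pt[3])
    }
  }
  res
}

det3 <- function(u, v, w) {
  u[1L] * (v[2L] * w[3L] - v[3L] * w[2L]) -
  u[2L] * (v[1L] * w[3L] - v[3L] * w[1L]) +
  u[3L] * (v[1L] * w[2L] - v[2L] * w[1L])
}

# rough overlap test between a segment's bbox and triangle bboxes
overlap_bbox <- function(p, q, A, B, C) {
  if (nrow(A) == 0L) return(logical())
  lo <- pmin(p, q); hi <- pmax(p, q)
  tmin <- pmin(A, B, C); tmax <- pmax(A, B, C)
  ok <- rep(TRUE, nrow(A))
  for (d in 1:3) ok <- ok & tmin[, d] <= hi[d] + 1e-9 & tmax[, d] >= lo[d] - 1e-9
  ok
}

#' Reduction parameters for crossings
#'
#' @param min_tail_depth minimal residues of tail beyond a crossing for it to
#'   count as a genuine piercing (default 3).
#' @param cancel_eps spatial radius in Angstrom within which an adjacent
#'   opposite-sign crossing pair is treated as surface wobble (default 2.0).
#' @param cancel_sep maximal residue separation of a cancelling pair
#'   (default 1).
#' @export
reduce_params <- function(min_tail_depth = 3L, cancel_eps = 2.0,
                          cancel_sep = 1L) {
  stopifnot(min_tail_depth >= 0L, cancel_eps >= 0, cancel_sep >= 0L)
  structure(list(min_tail_depth = as.integer(min_tail_depth),
                 cancel_eps = cancel_eps, cancel_sep = as.integer(cancel_sep)),
            class = "reduce_params")
}

#' Reduce raw crossings to genuine piercings
#'
#' First, adjacent opposite-sign crossing pairs whose intersection points
#' lie within `cancel_eps` and whose segments are within `cancel_sep`
#' residues are removed pairwise (local surface wobble), repeatedly until
#' stable. Then crossings with fewer than `min_tail_depth` residues of tail
#' beyond them are dropped as too shallow. Survivors are re-ranked 1..K
#' outward from the loop.
#'
#' @param crossings data.frame from [find_crossings()] (single tail,
#'   ordered along the tail away from the loop).
#' @param tail_end_resid residue index of the outermost tail residue.
#' @param params a [reduce_params()] list.
#' @return data.frame of piercings: crossing columns plus `depth` and `rank`.
#' @export
reduce_crossings <- function(crossings, tail_end_resid, params = reduce_params()) {
  cr <- crossings
  repeat {
    if (nrow(cr) < 2L) break
    removed <- FALSE
    for (i in seq_len(nrow(cr) - 1L)) {
      if (cr$sign[i] != -cr$sign[i + 1L]) next
      d <- vnorm(c(cr$x[i] - cr$x[i + 1L], cr$y[i] - cr$y[i + 1L],
                   cr$z[i] - cr$z[i + 1L]))
      sep <- abs(cr$seg_from[i + 1L] - cr$seg_from[i])
      if (d <= params$cancel_eps && sep <= params$cancel_sep) {
        cr <- cr[-c(i, i + 1L), , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  if (nrow(cr) > 0L) {
    cr$depth <- abs(tail_end_resid - cr$seg_to) + 1L
    cr <- cr[cr$depth >= params$min_tail_depth, , drop = FALSE]
  } else cr$depth <- integer()
  cr$rank <- seq_len(nrow(cr))
  rownames(cr) <- NULL
  cr
}

#' Sequential distance between the bridge and the nearest piercing
#'
#' The minimum over piercings of the residue count between the
#' bridge-forming residue on the piercing tail's side and the loop-proximal
#' residue of the piercing segment.
#'
#' @param loop a `lasso_loop`.
#' @param piercings piercing table from [reduce_crossings()] (both tails may
#'   be rbind-ed together).
#' @return integer distance, or `NA` (with an undefined-distance warning)
#'   when no piercing exists.
#' @export
bridge_piercing_distance <- function(loop, piercings) {
  if (is.null(piercings) || nrow(piercings) == 0L)
    return(undefined_distance("no piercings: bridge-piercing distance undefined"))
  d <- ifelse(piercings$tail == "C",
              piercings$seg_from - loop$res_j,
              loop$res_i - piercings$seg_from)
  as.integer(min(d))
}

#' Write a piercing table as TSV
#'
#' @param result a `lasso_result` from [detect_chain()].
#' @param path output file.
#' @export
write_piercing_table <- function(result, path) {
  rows <- do.call(rbind, lapply(result$loops, function(lp) {
    if (is.null(lp$piercings) || nrow(lp$piercings) == 0L) return(NULL)
    data.frame(chain = result$chain_id,
               loop = paste0(lp$res_i, "-", lp$res_j),
               tail = lp$piercings$tail,
               segment = paste0(lp$piercings$seg_from, "-", lp$piercings$seg_to),
               sign = ifelse(lp$piercings$sign > 0, "+", "-"),
               depth = lp$piercings$depth,
               rank = lp$piercings$rank)
  }))
  if (is.null(rows))
    rows <- data.frame(chain = character(), loop = character(), tail = character(),
                       segment = character(), sign = character(),
                       depth = integer(), rank = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
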