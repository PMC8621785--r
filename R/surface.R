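#' Span an initial triangulated surface on a covalent loop
#'
#' The loop's CA positions, traversed in increasing residue order and closed
#' by the bridge edge, form the boundary polygon. The initial surface is a
#' triangle fan from the boundary centroid, wound so that each triangle
#' normal agrees with the loop orientation (right-hand rule, loop traversed
#' N to C). Boundary vertices are fixed; only interior vertices may move
#' during minimization.
#'
#' @param loop a `lasso_loop` (span of at least 4 residues).
#' @param chain the `lasso_chain` carrying the CA coordinates.
#' @return object of class `lasso_surface`: list with `V` (vertices, n x 3),
#'   `F` (triangle index triples, consistent winding), `boundary` (ordered
#'   boundary vertex indices), `fixed` (logical per vertex), `area`.
#' @export
triangulate_loop <- function(loop, chain) {
  pts <- chain_coords(chain)[loop$span, , drop = FALSE]
  triangulate_polygon(pts)
}

#' @rdname triangulate_loop
#' @param pts m x 3 matrix of boundary polygon vertices in traversal order.
#' @export
triangulate_polygon <- function(pts) {
  m <- nrow(pts)
  stopifnot(m >= 3L)
  centroid <- colMeans(pts)
  V <- rbind(pts, centroid)
  F <- cbind(seq_len(m), c(seq_len(m)[-1L], 1L), m + 1L)
  s <- new_surface(V, F, boundary = seq_len(m),
                   fixed = c(rep(TRUE, m), FALSE))
  if (s$area < 1e-9 * max(1, max(rownorm(sweep(pts, 2L, centroid))))^2)
    stop("degenerate-surface: loop vertices are collinear")
  s
}

new_surface <- function(V, F, boundary, fixed, converged = NA) {
  a <- surface_area(V, F)
  structure(list(V = V, F = F, boundary = boundary, fixed = fixed,
                 area = a, converged = converged),
            class = "lasso_surface")
}

#' @export
print.lasso_surface <- function(x, ...) {
  cat(sprintf("<lasso_surface> %d vertices, %d triangles, area %.3f\n",
              nrow(x$V), nrow(x$F), x$area))
  invisible(x)
}

# total area of a triangle mesh
surface_area <- function(V, F) {
  A <- V[F[, 1L], , drop = FALSE]
  B <- V[F[, 2L], , drop = FALSE]
  C <- V[F[, 3L], , drop = FALSE]
  sum(0.5 * rownorm(rowcross(B - A, C - A)))
}

#' Minimization parameters
#'
#' @param max_iter maximal number of vertex sweeps (default 200).
#' @param rel_tol relative-area convergence tolerance per sweep (default 1e-4).
#' @param max_edge edge-length refinement threshold in the coordinate units;
#'   `NULL` (default) uses the mean boundary edge length.
#' @param refine_rounds rounds of global 1-to-4 midpoint subdivision applied
#'   when any edge exceeds `max_edge` (default 1).
#' @return list of class `min_params`.
#' @export
min_params <- function(max_iter = 200L, rel_tol = 1e-4, max_edge = NULL,
                       refine_rounds = 1L) {
  stopifnot(max_iter >= 1L, rel_tol > 0)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 max_edge = max_edge, refine_rounds = as.integer(refine_rounds)),
            class = "min_params")
}

#' Shrink a spanning surface towards minimal area
#'
#' Interior vertices are moved one at a time (deterministic index order) by
#' area-gradient descent with backtracking, boundary vertices immobile, so
#' the total area is non-increasing across sweeps. When any edge exceeds
#' `max_edge` the mesh is first refined by midpoint subdivision (new
#' vertices on boundary edges stay fixed on the boundary polyline).
#' Iteration stops when the relative area change per sweep drops below
#' `rel_tol` or after `max_iter` sweeps (then `converged = FALSE`).
#'
#' @param surface a `lasso_surface`.
#' @param params a [min_params()] list.
#' @return the minimized `lasso_surface` with a `converged` flag.
#' @export
minimize_surface <- function(surface, params = min_params()) {
  V <- surface$V; F <- surface$F; fixed <- surface$fixed
  max_edge <- params$max_edge
  if (is.null(max_edge)) {
    b <- surface$boundary
    eb <- V[c(b[-1L], b[1L]), , drop = FALSE] - V[b, , drop = FALSE]
    max_edge <- mean(rownorm(eb))
  }
  for (r in seq_len(params$refine_rounds)) {
    if (max_edge_length(V, F) <= max_edge) break
    ref <- subdivide_mesh(V, F, fixed)
    V <- ref$V; F <- ref$F; fixed <- ref$fixed
  }

  # incidence: triangles touching each free vertex
  free <- which(!fixed)
  inc <- lapply(free, function(v) which(F[, 1L] == v | F[, 2L] == v | F[, 3L] == v))
  area <- surface_area(V, F)
  scale <- max_edge
  converged <- FALSE
  for (sweep in seq_len(params$max_iter)) {
    prev <- area
    for (k in seq_along(free)) {
      v <- free[k]
      tri <- F[inc[[k]], , drop = FALSE]
      a0 <- surface_area(V, tri)
      g <- vertex_area_gradient(V, tri, v)
      gn <- vnorm(g)
      if (gn < 1e-14) next
      step <- min(0.25 * scale, a0 / gn) / gn    # cautious first step
      for (bt in 1:30) {
        cand <- V[v, ] - step * g
        Vc <- V; Vc[v, ] <- cand
        a1 <- surface_area(Vc, tri)
        if (a1 < a0) { V <- Vc; break }
        step <- step / 2
      }
    }
    area <- surface_area(V, F)
    if (prev - area < params$rel_tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  new_surface(V, F, surface$boundary, fixed, converged = converged)
}

max_edge_length <- function(V, F) {
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3L, 1L)])
  max(rownorm(V[e[, 2L], , drop = FALSE] - V[e[, 1L], , drop = FALSE]))
}

# gradient of the summed area of triangles `tri` w.r.t. vertex v:
# for triangle (a,b,c), d Area / d a = 0.5 * unit_normal x (c - b)
vertex_area_gradient <- function(V, tri, v) {
  g <- c(0, 0, 0)
  for (t in seq_len(nrow(tri))) {
    idx <- tri[t, ]
    pos <- which(idx == v)[1L]
    a <- V[idx[pos], ]
    b <- V[idx[pos %% 3L + 1L], ]
    c <- V[idx[(pos + 1L) %% 3L + 1L], ]
    n <- vcross(b - a, c - a)
    nn <- vnorm(n)
    if (nn < 1e-14) next
    g <- g + 0.5 * vcross(n / nn, c - b)
  }
  g
}

# global 1-to-4 midpoint subdivision; midpoints of edges between two fixed
# vertices lie on the boundary polyline and are themselves fixed
subdivide_mesh <- function(V, F, fixed) {
  nv <- nrow(V)
  edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  mid <- new.env(parent = emptyenv())
  Vl <- lapply(seq_len(nv), function(i) V[i, ])
  fx <- as.list(fixed)
  get_mid <- function(i, j) {
    k <- edge_key(i, j)
    if (!is.null(mid[[k]])) return(mid[[k]])
    Vl[[length(Vl) + 1L]] <<- (V[i, ] + V[j, ]) / 2
    fx[[length(fx) + 1L]] <<- fixed[i] && fixed[j]
    mid[[k]] <- length(Vl)
    length(Vl)
  }
  Fn <- matrix(0L, nrow = 4L * nrow(F), ncol = 3L)
  r <- 0L
  for (t in seq_len(nrow(F))) {
    a <- F[t, 1L]; b <- F[t, 2L]; c <- F[t, 3L]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    Fn[r + 1L, ] <- c(a, ab, ca)
    Fn[r + 2L, ] <- c(ab, b, bc)
    Fn[r + 3L, ] <- c(ca, bc, c)
    Fn[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(V = do.call(rbind, Vl), F = Fn, fixed = unlist(fx))
}

#' Export a surface mesh as Wavefront OBJ (visual debugging)
#'
#' @param surface a `lasso_surface`.
#' @param path output file.
#' @export
write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  apply(surface$V, 1L, function(v)
    writeLines(sprintf("v %.6f %.6f %.6f", v[1], v[2], v[3]), con))
  apply(surface$F, 1L, function(f)
    writeLines(sprintf("f %d %d %d", f[1], f[2], f[3]), con))
  invisible(path)
}
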