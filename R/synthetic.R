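#' Deterministically build a chain with a prescribed lasso type
#'
#' The covalent loop is a regular planar polygon of `loop_len` CA positions
#' in the z = 0 plane, traversed counterclockwise (seen from +z) in
#' increasing residue order and closed by a synthetic disulfide-style bridge
#' between its first and last residue, so the loop surface normal points
#' along +z and a crossing in the +z direction (along increasing residue
#' index) is a `+` piercing. Each prescribed piercing is realized by routing
#' the tail through the polygon interior at laterally well-separated
#' crossing points; consecutive same-sign (supercoiling) crossings travel
#' around the loop exterior between them. Waypoint legs are subdivided at
#' CA-like spacing (`bond_len`), and every tail extends well beyond its last
#' crossing, so no genuine piercing is shallow. Coordinates are a pure
#' function of the arguments (no randomness).
#'
#' @param minor_label target minor lasso label (see [classify_loop()]), e.g.
#'   `"L-1C"`, `"LS2--N"`, `"LL+1,+2"`, or `"L0"`.
#' @param loop_len residues in the covalent loop (>= 6).
#' @param tail_clearance vertical/lateral clearance of the tail route in
#'   Angstrom (default 6).
#' @param bond_len CA-CA spacing in Angstrom (default 3.8).
#' @param min_tail_depth residues guaranteed beyond the last crossing
#'   (default 6; comfortably above the reduction threshold).
#' @return list with `chain` (a `lasso_chain`), `bridges` (one-row bridge
#'   table), and `label`.
#' @export
make_lasso_fixture <- function(minor_label, loop_len = 12L, tail_clearance = 6,
                               bond_len = 3.8, min_tail_depth = 6L) {
  stopifnot(loop_len >= 6L)
  signs <- parse_minor(minor_label)
  m <- as.integer(loop_len)
  R <- bond_len / (2 * sin(pi / m))
  phi <- 2 * pi * (seq_len(m) - 1L) / m
  loop_pts <- cbind(R * cos(phi), R * sin(phi), 0)

  # distinct interior crossing points, mutually separated beyond the
  # wobble-cancellation radius so genuine crossings can never merge
  K <- length(signs$n_signs) + length(signs$c_signs)
  q <- matrix(numeric(), 0L, 2L)
  if (K > 0L) {
    r_in <- 0.35 * R
    alpha <- 0.4 + 2 * pi * (seq_len(K) - 1L) / K
    q <- cbind(r_in * cos(alpha), r_in * sin(alpha))
    if (K > 1L) {
      sepmin <- min(stats::dist(q))
      if (sepmin <= 2.5) stop("crossing points too close at loop_len ", m,
                              ": increase loop_len")
    }
  }
  qn <- q[seq_along(signs$n_signs), , drop = FALSE]
  qc <- q[length(signs$n_signs) + seq_along(signs$c_signs), , drop = FALSE]

  h <- tail_clearance
  clear <- tail_clearance
  route <- function(start, attach_dir, geo_signs, qxy) {
    # waypoints of an outward walk realizing the geometric crossing
    # directions geo_signs (+1 = upward) at interior points qxy
    W <- list(start)
    push <- function(x, y, z) W[[length(W) + 1L]] <<- c(x, y, z)
    if (length(geo_signs) == 0L) {
      # unpierced tail: walk straight out of the loop plane, then away
      push(start[1L] + (R + clear) * attach_dir[1L],
           start[2L] + (R + clear) * attach_dir[2L], h)
      push(start[1L] + (R + 2 * clear) * attach_dir[1L],
           start[2L] + (R + 2 * clear) * attach_dir[2L],
           h + (min_tail_depth + 2L) * bond_len)
    } else {
      g1 <- geo_signs[1L]
      u <- unitize(c(start[1L], start[2L], 0))[1:2]
      push((R + clear) * u[1L], (R + clear) * u[2L], -g1 * h)
      push(qxy[1L, 1L], qxy[1L, 2L], -g1 * h)
      push(qxy[1L, 1L], qxy[1L, 2L], g1 * h)        # crossing 1
      if (length(geo_signs) > 1L) for (k in 2L:length(geo_signs)) {
        gp <- geo_signs[k - 1L]; gk <- geo_signs[k]
        if (gk == -gp) {                             # already on entry side
          push(qxy[k, 1L], qxy[k, 2L], -gk * h)
        } else {                                     # supercoil: exterior detour
          ue <- unitize(c(qxy[k, 1L], qxy[k, 2L], 0))[1:2]
          push((R + clear) * ue[1L], (R + clear) * ue[2L], gp * h)
          push((R + clear) * ue[1L], (R + clear) * ue[2L], -gk * h)
          push(qxy[k, 1L], qxy[k, 2L], -gk * h)
        }
        push(qxy[k, 1L], qxy[k, 2L], gk * h)         # crossing k
      }
      gK <- geo_signs[length(geo_signs)]
      uex <- unitize(c(qxy[nrow(qxy), 1L], qxy[nrow(qxy), 2L], 0))[1:2]
      push((R + 2 * clear) * uex[1L], (R + 2 * clear) * uex[2L], gK * h)
      push((R + 2 * clear) * uex[1L], (R + 2 * clear) * uex[2L],
           gK * (h + (min_tail_depth + 2L) * bond_len))
    }
    subdivide_polyline(do.call(rbind, W), bond_len)
  }

  # C-tail: outward walk direction equals increasing residue order, so the
  # geometric crossing direction is the label sign itself; the N-tail runs
  # against residue order, so its geometric direction is the flipped sign
  c_pts <- route(loop_pts[m, ], unitize(c(loop_pts[m, 1:2], 0))[1:2],
                 signs$c_signs, qc)
  n_pts <- route(loop_pts[1L, ], unitize(c(loop_pts[1L, 1:2], 0))[1:2],
                 -signs$n_signs, qn)

  n_tail <- n_pts[rev(seq_len(nrow(n_pts))[-1L]), , drop = FALSE]
  c_tail <- c_pts[-1L, , drop = FALSE]
  coords <- rbind(n_tail, loop_pts, c_tail)
  a <- nrow(n_tail)
  n_res <- nrow(coords)
  name <- rep("GLY", n_res)
  name[c(a + 1L, a + m)] <- "CYS"
  res <- data.frame(index = seq_len(n_res), resno = seq_len(n_res),
                    name = name, x = coords[, 1L], y = coords[, 2L],
                    z = coords[, 3L], bfactor = NA_real_, virtual = FALSE)
  chain <- new_chain("A", res)
  bridges <- new_bridges(a + 1L, a + m, "disulfide", "synthetic")
  list(chain = chain, bridges = bridges, label = minor_label)
}

# resample a waypoint polyline at spacing <= step, keeping the waypoints
subdivide_polyline <- function(W, step) {
  out <- list(W[1L, ])
  for (k in seq_len(nrow(W) - 1L)) {
    p <- W[k, ]; q <- W[k + 1L, ]
    len <- vnorm(q - p)
    nseg <- max(1L, ceiling(len / step))
    for (s in seq_len(nseg)) out[[length(out) + 1L]] <- p + (s / nseg) * (q - p)
  }
  do.call(rbind, out)
}

#' Sample a lassoed ideal chain
#'
#' A closed equilateral random polygon (the covalent loop) plus a freely
#' jointed tail of unit steps from the bridge residue: no volume, no
#' interactions, fixed unit distance between neighboring beads. The polygon
#' is generated by drawing random unit steps and alternating mean-removal
#' (to close the walk) with renormalization (to restore unit lengths) until
#' closure is exact to 1e-9 -- a simple closed-walk sampler adequate for
#' property tests, not an exact uniform measure.
#'
#' @param loop_len number of loop beads (>= 3).
#' @param tail_len number of tail beads.
#' @param seed integer seed; identical seeds give identical chains.
#' @return list with `chain` and `bridges` as in [make_lasso_fixture()].
#' @export
sample_ideal_chain <- function(loop_len, tail_len, seed) {
  stopifnot(loop_len >= 3L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m <- as.integer(loop_len)
  u <- matrix(stats::rnorm(3L * m), m, 3L)
  u <- u / rownorm(u)
  for (it in 1:10000) {
    u <- sweep(u, 2L, colMeans(u))
    u <- u / rownorm(u)
    if (max(abs(colSums(u))) < 1e-9) break
  }
  if (max(abs(colSums(u))) >= 1e-9) stop("closed-polygon sampler failed to converge")
  verts <- apply(rbind(0, u[-m, , drop = FALSE]), 2L, cumsum)
  verts <- matrix(verts, ncol = 3L)
  tail <- matrix(numeric(), 0L, 3L)
  if (tail_len > 0L) {
    steps <- matrix(stats::rnorm(3L * tail_len), tail_len, 3L)
    steps <- steps / rownorm(steps)
    tail <- sweep(apply(steps, 2L, cumsum), 2L, verts[m, ], `+`)
    tail <- matrix(tail, ncol = 3L)
  }
  coords <- rbind(verts, tail)
  res <- data.frame(index = seq_len(nrow(coords)), resno = seq_len(nrow(coords)),
                    name = "UNK", x = coords[, 1L], y = coords[, 2L],
                    z = coords[, 3L], bfactor = NA_real_, virtual = FALSE)
  list(chain = new_chain("A", res),
       bridges = new_bridges(1L, m, "disulfide", "synthetic"))
}

#' Write a chain as xyz or as a minimal CA-only PDB
#'
#' The PDB writer emits CA ATOM records plus an SSBOND record per disulfide
#' bridge, so synthetic fixtures can exercise the full file-reading path.
#'
#' @param chain a `lasso_chain`.
#' @param path output file.
#' @param bridges optional bridge table for SSBOND records.
#' @export
write_xyz <- function(chain, path) {
  r <- chain$residues
  writeLines(sprintf("%d %.4f %.4f %.4f", r$index, r$x, r$y, r$z), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_ca_pdb <- function(chain, path, bridges = NULL) {
  r <- chain$residues
  lines <- character()
  if (!is.null(bridges) && nrow(bridges) > 0) {
    for (k in seq_len(nrow(bridges))) {
      if (bridges$chemistry[k] != "disulfide") next
      lines <- c(lines, sprintf(
        "SSBOND %3d CYS %s %4d    CYS %s %4d", k,
        chain$id, r$resno[bridges$res_i[k]], chain$id, r$resno[bridges$res_j[k]]))
    }
  }
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, r$name[i], chain$id, r$resno[i], r$x[i], r$y[i], r$z[i], 1,
      ifelse(is.na(r$bfactor[i]), 0, r$bfactor[i])))
  }
  # CA-only trace: add SG sites at the CA of bridge cysteines so the
  # geometric disulfide detector can pair them
  if (!is.null(bridges) && nrow(bridges) > 0) {
    lines <- c(lines, "END")
  } else lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Enumerate all minor lasso labels up to a piercing budget
#'
#' Every canonical minor label whose total piercing count is at most
#' `max_piercings` (including `"L0"`), obtained by classifying every
#' sign-list pair -- the full flower of types at that depth.
#'
#' @param max_piercings maximal total piercing count (default 3).
#' @return character vector of distinct minor labels.
#' @export
enumerate_minor_labels <- function(max_piercings = 3L) {
  labels <- "L0"
  all_strings <- function(k) {
    if (k == 0L) return(list(integer()))
    g <- expand.grid(rep(list(c(-1L, 1L)), k))
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  for (total in seq_len(max_piercings)) {
    for (i in 0:total) {
      j <- total - i
      for (sn in all_strings(i)) for (sc in all_strings(j)) {
        labels <- c(labels, classify_loop(sn, sc)$minor)
      }
    }
  }
  sort(unique(labels))
}
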