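# shared fixtures and independent oracles for the geometric tests

# minimal PDB text builder (CA + optional SG side-chain atoms)
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z, b = 10) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resn, chain, resno, x, y, z, 1, b)
}

# a straight CA trace with optional CYS SG atoms hanging off given residues
make_pdb_text <- function(resno, cys_at = integer(), sg_xyz = NULL,
                          chain = "A", b = 10, models = 1L, model_shift = 0) {
  body <- function(shift) {
    serial <- 0L
    unlist(lapply(seq_along(resno), function(i) {
      resn <- if (i %in% cys_at) "CYS" else "GLY"
      serial <<- serial + 1L
      out <- pdb_atom_line(serial, "CA", resn, chain, resno[i],
                           i * 3.8, 0, shift, b)
      if (i %in% cys_at && !is.null(sg_xyz)) {
        k <- match(i, cys_at)
        serial <<- serial + 1L
        out <- c(out, pdb_atom_line(serial, "SG", resn, chain, resno[i],
                                    sg_xyz[k, 1], sg_xyz[k, 2], sg_xyz[k, 3], b))
      }
      out
    }))
  }
  if (models == 1L) return(c(body(0), "END"))
  c(unlist(lapply(seq_len(models), function(m)
    c(sprintf("MODEL  %6d", m), body((m - 1L) * model_shift), "ENDMDL"))), "END")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# ---- analytic point-in-polygon crossing oracle (planar loop in z = 0) ----

# even-odd ray casting in 2D
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# signed plane crossings of a polyline through z = 0 that fall inside the
# polygon; a point exactly on the plane counts as lying on the positive side
pip_crossings <- function(poly_xy, pts) {
  z <- pts[, 3]
  z[z == 0] <- .Machine$double.xmin
  out <- data.frame(seg = integer(), sign = integer(),
                    x = numeric(), y = numeric())
  for (s in seq_len(nrow(pts) - 1L)) {
    if (sign(z[s]) == sign(z[s + 1L])) next
    t <- z[s] / (z[s] - z[s + 1L])
    xy <- pts[s, 1:2] + t * (pts[s + 1L, 1:2] - pts[s, 1:2])
    if (point_in_polygon(xy, poly_xy))
      out[nrow(out) + 1L, ] <- list(s, if (z[s + 1L] > z[s]) 1L else -1L,
                                    xy[1], xy[2])
  }
  out
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- max(0, min(1, sum((p - a) * ab) / sum(ab * ab)))
  sqrt(sum((p - (a + t * ab))^2))
}

dist_to_polygon <- function(pt, poly) {
  n <- nrow(poly)
  min(vapply(seq_len(n), function(i)
    dist_point_segment(pt, poly[i, ], poly[i %% n + 1L, ]), numeric(1)))
}

# random planar star-shaped loop + zig-zag tail instance with well-separated
# crossings; returns NULL when the draw violates the safety margins
random_planar_instance <- function() {
  m <- sample(8:12, 1L)
  R <- 8
  ang <- 2 * pi * (seq_len(m) - 1L) / m + runif(m, -0.15, 0.15)
  rad <- R * runif(m, 0.7, 1)
  poly <- cbind(rad * cos(ang), rad * sin(ang))
  nw <- sample(3:7, 1L)
  w_xy <- matrix(runif(2L * nw, -1.4 * R, 1.4 * R), nw, 2L)
  w_z <- runif(nw, 1.5, 7) * sample(c(-1, 1), nw, replace = TRUE)
  start <- c(1.3 * poly[m, ], 0)
  pts <- rbind(start, cbind(w_xy, w_z))
  # safety margins: every plane crossing at least 0.8 from the boundary,
  # crossings on nearby segments at least 3 apart (no wobble ambiguity)
  z <- pts[, 3]; z[z == 0] <- .Machine$double.xmin
  for (s in seq_len(nrow(pts) - 1L)) {
    if (sign(z[s]) == sign(z[s + 1L])) next
    t <- z[s] / (z[s] - z[s + 1L])
    xy <- pts[s, 1:2] + t * (pts[s + 1L, 1:2] - pts[s, 1:2])
    if (dist_to_polygon(xy, poly) < 0.8) return(NULL)
  }
  cr <- pip_crossings(poly, pts)
  if (nrow(cr) >= 2L) {
    for (i in seq_len(nrow(cr) - 1L)) {
      d <- sqrt(sum((c(cr$x[i], cr$y[i]) - c(cr$x[i + 1L], cr$y[i + 1L]))^2))
      if (abs(cr$seg[i + 1L] - cr$seg[i]) <= 1L && d < 3) return(NULL)
    }
  }
  list(poly = poly, pts = pts, oracle = cr)
}

# detect a fixture chain and return the minor label of its single loop
fixture_minor <- function(label, ...) {
  fx <- make_lasso_fixture(label, ...)
  r <- detect_chain(fx$chain, bridges = fx$bridges)
  r$loops[[1L]]$minor
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

transform_chain <- function(chain, Rm = diag(3), shift = c(0, 0, 0), mirror = FALSE) {
  co <- as.matrix(chain$residues[, c("x", "y", "z")])
  if (mirror) co[, 3] <- -co[, 3]
  co <- sweep(co %*% t(Rm), 2L, shift, `+`)
  chain$residues$x <- co[, 1]
  chain$residues$y <- co[, 2]
  chain$residues$z <- co[, 3]
  chain
}
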