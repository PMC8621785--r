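unit_square <- function() {
  triangulate_polygon(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
}

test_that("oriented crossings follow the right-hand-rule sign convention", {
  s <- unit_square()     # counterclockwise seen from +z: normal along +z
  up <- rbind(c(0.5, 0.5, -1), c(0.5, 0.5, 1))
  cr <- find_crossings(s, up, "C")
  expect_equal(nrow(cr), 1L)
  expect_identical(cr$sign, 1L)
  expect_equal(c(cr$x, cr$y, cr$z), c(0.5, 0.5, 0), tolerance = 1e-12)
  down <- up[2:1, ]
  expect_identical(find_crossings(s, down, "C")$sign, -1L)
  # the same geometric passage by the N-tail is the opposite chain direction
  expect_identical(find_crossings(s, up, "N")$sign, -1L)
  outside <- rbind(c(5, 5, -1), c(5, 5, 1))
  expect_equal(nrow(find_crossings(s, outside, "C")), 0L)
})

test_that("a zig-zag tail yields ordered alternating crossings", {
  s <- unit_square()
  zig <- rbind(c(0.2, 0.2, -1), c(0.2, 0.2, 1), c(0.5, 0.5, 1),
               c(0.5, 0.5, -1), c(0.8, 0.8, -1), c(0.8, 0.8, 1))
  cr <- find_crossings(s, zig, "C")
  expect_equal(nrow(cr), 3L)
  expect_identical(cr$sign, c(1L, -1L, 1L))
  expect_true(!is.unsorted(cr$seg_from))
})

test_that("reduction drops shallow crossings and cancels wobble pairs", {
  deep <- data.frame(tail = "C", seg_from = 31L, seg_to = 32L, sign = 1L,
                     t = 0.5, x = 0, y = 0, z = 0)
  out <- reduce_crossings(deep, tail_end_resid = 51L)
  expect_equal(nrow(out), 1L)
  expect_identical(out$rank, 1L)
  expect_identical(out$depth, 20L)
  shallow <- reduce_crossings(deep, tail_end_resid = 32L)   # 1 residue beyond
  expect_equal(nrow(shallow), 0L)
  # (+,-,+) with the (-,+) pair 0.5 apart on adjacent segments -> single +
  tri <- data.frame(tail = "C", seg_from = c(31L, 35L, 36L),
                    seg_to = c(32L, 36L, 37L), sign = c(1L, -1L, 1L),
                    t = 0.5, x = c(0, 3, 3.3), y = c(0, 1, 1.4), z = 0)
  red <- reduce_crossings(tri, tail_end_resid = 60L)
  expect_equal(nrow(red), 1L)
  expect_identical(red$sign, 1L)
  expect_identical(red$seg_from, 31L)
})

test_that("inserting a local wobble leaves the reduced piercing list unchanged", {
  s <- unit_square()
  clean <- rbind(c(0.5, 0.5, -2), c(0.5, 0.5, 2), c(0.5, 0.5, 4),
                 c(0.5, 0.5, 6), c(0.5, 0.5, 8), c(0.5, 0.5, 10))
  wobble <- rbind(clean[1:2, ],
                  c(0.55, 0.5, -0.05), c(0.6, 0.5, 0.05),   # dip through and back
                  clean[3:6, ])
  red_clean <- reduce_crossings(find_crossings(s, clean, "C"),
                                tail_end_resid = nrow(clean))
  red_wob <- reduce_crossings(find_crossings(s, wobble, "C"),
                              tail_end_resid = nrow(wobble))
  expect_equal(nrow(red_clean), 1L)
  expect_equal(nrow(red_wob), 1L)
  expect_identical(red_wob$sign, red_clean$sign)
})

test_that("mirror reflection flips every crossing sign and nothing else", {
  set.seed(3)
  for (rep in 1:20) {
    inst <- random_planar_instance()
    if (is.null(inst)) next
    s <- minimize_surface(triangulate_polygon(cbind(inst$poly, 0)))
    cr <- find_crossings(s, inst$pts, "C")
    mirror <- function(M) { M[, 3] <- -M[, 3]; M }
    sm <- minimize_surface(triangulate_polygon(mirror(cbind(inst$poly, 0))))
    crm <- find_crossings(sm, mirror(inst$pts), "C")
    expect_identical(crm$sign, -cr$sign)
    expect_identical(crm$seg_from, cr$seg_from)
  }
})

test_that("crossing count and signs are rigid-motion invariant", {
  set.seed(5)
  got_one <- FALSE
  for (rep in 1:10) {
    inst <- random_planar_instance()
    if (is.null(inst) || nrow(inst$oracle) == 0L) next
    got_one <- TRUE
    s <- minimize_surface(triangulate_polygon(cbind(inst$poly, 0)))
    cr <- find_crossings(s, inst$pts, "C")
    Rm <- random_rotation()
    shift <- runif(3, -20, 20)
    mv <- function(M) sweep(M %*% t(Rm), 2L, shift, `+`)
    s2 <- minimize_surface(triangulate_polygon(mv(cbind(inst$poly, 0))))
    cr2 <- find_crossings(s2, mv(inst$pts), "C")
    expect_identical(cr2$sign, cr$sign)
    expect_identical(cr2$seg_from, cr$seg_from)
  }
  expect_true(got_one)
})

test_that("reduced piercings match the point-in-polygon oracle on random planar instances", {
  set.seed(101)
  n_ok <- 0L
  tries <- 0L
  while (n_ok < 200L && tries < 2000L) {
    tries <- tries + 1L
    inst <- random_planar_instance()
    if (is.null(inst)) next
    n_ok <- n_ok + 1L
    s <- minimize_surface(triangulate_polygon(cbind(inst$poly, 0)))
    cr <- find_crossings(s, inst$pts, "C")
    red <- reduce_crossings(cr, tail_end_resid = nrow(inst$pts))
    oracle <- inst$oracle
    odepth <- nrow(inst$pts) - (oracle$seg + 1L) + 1L
    oracle <- oracle[odepth >= 3L, , drop = FALSE]
    expect_identical(red$sign, oracle$sign)
    expect_identical(red$seg_from, oracle$seg)
  }
  expect_gte(n_ok, 200L)
})

test_that("bridge-piercing sequential distance takes the minimum over piercings", {
  res <- data.frame(index = 1:50, resno = 1:50, name = "GLY", x = (1:50) * 3.8,
                    y = 0, z = 0, bfactor = NA_real_, virtual = FALSE)
  chain <- new_chain("A", res)
  loop <- extract_loops(chain,
                        lassotopo:::new_bridges(10L, 30L, "disulfide", "synthetic"))[[1L]]
  p1 <- data.frame(tail = "C", seg_from = 34L, seg_to = 35L, sign = 1L,
                   t = 0.5, x = 0, y = 0, z = 0, depth = 10L, rank = 1L)
  expect_identical(bridge_piercing_distance(loop, p1), 4L)
  p0 <- p1; p0$seg_from <- 30L; p0$seg_to <- 31L
  expect_identical(bridge_piercing_distance(loop, p0), 0L)
  p2 <- rbind(p1, within(p1, { seg_from <- 39L; seg_to <- 40L; rank <- 2L }))
  expect_identical(bridge_piercing_distance(loop, p2), 4L)
  pn <- data.frame(tail = "N", seg_from = 7L, seg_to = 6L, sign = -1L,
                   t = 0.5, x = 0, y = 0, z = 0, depth = 6L, rank = 1L)
  expect_identical(bridge_piercing_distance(loop, pn), 3L)
  expect_warning(d <- bridge_piercing_distance(loop, p1[0, ]),
                 class = "lasso_undefined_distance")
  expect_true(is.na(d))
})
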