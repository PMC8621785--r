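test_that("single-tail, supercoiled and two-sided loops get the field's labels", {
  cases <- list(
    list(n = integer(), c = -1L,          minor = "L-1C",    major = "L1",  klass = "L"),
    list(n = integer(), c = integer(),    minor = "L0",      major = "L0",  klass = "L0"),
    list(n = c(-1L, -1L), c = integer(),  minor = "LS2--N",  major = "LS2", klass = "LS"),
    list(n = 1L, c = c(1L, -1L),          minor = "LL+1,+2", major = "LL1,2", klass = "LL"),
    list(n = integer(), c = c(1L, -1L, 1L), minor = "L+3C",  major = "L3",  klass = "L"),
    list(n = integer(), c = c(1L, 1L, -1L), minor = "LS3++-C", major = "LS3", klass = "LS"),
    list(n = c(-1L, -1L), c = c(1L, -1L), minor = "LLS2--,+2", major = "LLS2,2", klass = "LLS"))
  for (cs in cases) {
    t <- classify_loop(cs$n, cs$c)
    expect_identical(t$minor, cs$minor)
    expect_identical(t$major, cs$major)
    expect_identical(t$klass, cs$klass)
  }
  expect_error(classify_loop(c("x")), "malformed")
})

test_that("character signs are accepted and parse_minor inverts the labelling", {
  expect_identical(classify_loop(c(), c("+", "-"))$minor, "L+2C")
  for (lab in enumerate_minor_labels(3L)) {
    s <- parse_minor(lab)
    expect_identical(classify_loop(s$n_signs, s$c_signs)$minor, lab)
  }
  expect_error(parse_minor("LS2+-N"), "consecutive")    # alternating is not LS
  expect_error(parse_minor("garbage"), "unparseable")
})

test_that("sign-flip maps minors pairwise and leaves majors unchanged", {
  for (lab in enumerate_minor_labels(3L)) {
    s <- parse_minor(lab)
    flipped <- classify_loop(-s$n_signs, -s$c_signs)
    expect_identical(flipped$major, classify_loop(s$n_signs, s$c_signs)$major)
    back <- parse_minor(flipped$minor)
    expect_identical(classify_loop(-back$n_signs, -back$c_signs)$minor, lab)
  }
  expect_identical(classify_loop(integer(), 1L)$minor, "L+1C")
  expect_identical(classify_loop(integer(), -1L)$minor, "L-1C")
})

test_that("swapping tails maps N labels to C labels and LLi,j to LLj,i", {
  for (lab in enumerate_minor_labels(3L)) {
    s <- parse_minor(lab)
    orig <- classify_loop(s$n_signs, s$c_signs)
    swap <- classify_loop(s$c_signs, s$n_signs)
    if (orig$klass %in% c("L", "LS")) {
      expect_identical(swap$minor, chartr("NC", "CN", orig$minor))
    } else if (orig$klass %in% c("LL", "LLS")) {
      parts <- strsplit(sub("^LLS?", "", orig$minor), ",")[[1L]]
      expect_identical(sub("^LLS?", "", swap$minor),
                       paste(rev(parts), collapse = ","))
    }
  }
})

test_that("the L1 major type expands to exactly 4 minor subtypes", {
  minors <- unique(vapply(list(list(1L, integer()), list(-1L, integer()),
                               list(integer(), 1L), list(integer(), -1L)),
                          function(s) classify_loop(s[[1L]], s[[2L]])$minor,
                          character(1L)))
  expect_setequal(minors, c("L+1N", "L-1N", "L+1C", "L-1C"))
  expect_length(minors, 4L)
})

test_that("fingerprints compress consecutive repeats and suppress L0", {
  t1 <- classify_loop(integer(), -1L)
  expect_identical(lasso_fingerprint(list(t1, t1))$text, "2L1")
  expect_identical(lasso_fingerprint(list(classify_loop(), t1))$text, "L1")
  expect_identical(lasso_fingerprint(list())$text, "")
  expect_identical(lasso_fingerprint(list("LS3", "L1", "L1", "LS2"))$text,
                   "LS32L1LS2")
  # non-consecutive duplicates stay expanded
  expect_identical(lasso_fingerprint(list("L1", "L2", "L1"))$text, "L1L2L1")
})

test_that("parse_fingerprint inverts the grammar and counts piercings", {
  p <- parse_fingerprint("LS32L1LS2")
  expect_identical(p$majors, c("LS3", "L1", "L1", "LS2"))
  expect_identical(p$n_loops, 4L)
  expect_identical(p$total_piercings, 7L)
  p <- parse_fingerprint("L1L2L12L2")
  expect_identical(p$n_loops, 5L)
  expect_identical(p$total_piercings, 8L)
  p <- parse_fingerprint("")
  expect_identical(p$n_loops, 0L)
  expect_identical(p$total_piercings, 0L)
  expect_identical(parse_fingerprint("LL4,3L2")$total_piercings, 9L)
  expect_error(parse_fingerprint("L1X"), "position")
  expect_error(parse_fingerprint("LL2"), "position")
})

test_that("fingerprint/parse round-trips over random type lists", {
  majors_pool <- setdiff(unique(vapply(enumerate_minor_labels(3L), function(l) {
    s <- parse_minor(l)
    classify_loop(s$n_signs, s$c_signs)$major
  }, character(1L))), "L0")
  set.seed(42)
  for (rep in 1:50) {
    majors <- sample(majors_pool, sample(1:6, 1L), replace = TRUE)
    fp <- lasso_fingerprint(as.list(majors))
    expect_identical(parse_fingerprint(fp$text)$majors, majors)
  }
})

test_that("evolution-flower moves reach the expected neighbor types", {
  expect_identical(flower_neighbors("L0", "terminal_piercing"), "L1")
  expect_setequal(flower_neighbors("L1", "terminal_piercing"),
                  c("L0", "L2", "LL1,1", "LS2"))
  expect_true("L3" %in% flower_neighbors("L1", "terminal_slipknot"))
  # a fully one-sided supercoil cannot arise from a slipknot move
  minors <- flower_neighbors("L1", "terminal_slipknot", level = "minor")
  expect_false(any(c("LS3---N", "LS3---C", "LS3+++N", "LS3+++C") %in% minors))
  expect_true(all(c("LS3++-C", "LS3--+N") %in% minors))
})
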