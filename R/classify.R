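#' Classify a covalent loop from its per-tail signed piercing sequences
#'
#' Sign lists are ordered from the loop outward along each tail. The class
#' is `L0` (unpierced), `L` (one tail, alternating signs), `LS`
#' (supercoiling: one tail with at least two consecutive crossings from the
#' same side), `LL` (both tails pierce, each alternating) or `LLS` (both
#' tails pierce, at least one supercoiled).
#'
#' Minor labels follow the field's nomenclature: `L-1C`, `L+3C` (sign of the
#' loop-proximal, rank-1 piercing, then count, then tail letter);
#' `LS2--N`, `LS3++-C` (count, full sign string, tail letter);
#' `LL+1,+2` (N part first: rank-1 sign and count per tail);
#' `LLS2--,+2` (a supercoiled tail written LS-style as count plus sign
#' string). Major labels suppress signs and tail: `L1`, `LS2`, `LL1,2`,
#' `LLS2,2`.
#'
#' @param n_signs,c_signs piercing signs of the N- and C-terminal tail,
#'   ordered loop-outward; numeric (+1/-1) or character (`"+"`/`"-"`)
#'   vectors, possibly empty.
#' @return object of class `lasso_type`: list with `n_signs`, `c_signs`,
#'   `klass`, `minor`, `major`.
#' @export
classify_loop <- function(n_signs = integer(), c_signs = integer()) {
  n <- normalize_signs(n_signs)
  c_ <- normalize_signs(c_signs)
  sup_n <- is_supercoiled(n)
  sup_c <- is_supercoiled(c_)
  if (length(n) == 0L && length(c_) == 0L) {
    klass <- "L0"; minor <- "L0"; major <- "L0"
  } else if (length(n) == 0L || length(c_) == 0L) {
    s <- if (length(n)) n else c_
    tl <- if (length(n)) "N" else "C"
    if (is_supercoiled(s)) {
      klass <- "LS"
      minor <- paste0("LS", length(s), sign_string(s), tl)
      major <- paste0("LS", length(s))
    } else {
      klass <- "L"
      minor <- paste0("L", sign_char(s[1L]), length(s), tl)
      major <- paste0("L", length(s))
    }
  } else {
    part <- function(s) {
      if (is_supercoiled(s)) paste0(length(s), sign_string(s))
      else paste0(sign_char(s[1L]), length(s))
    }
    if (sup_n || sup_c) {
      klass <- "LLS"
      minor <- paste0("LLS", part(n), ",", part(c_))
      major <- paste0("LLS", length(n), ",", length(c_))
    } else {
      klass <- "LL"
      minor <- paste0("LL", part(n), ",", part(c_))
      major <- paste0("LL", length(n), ",", length(c_))
    }
  }
  structure(list(n_signs = n, c_signs = c_, klass = klass,
                 minor = minor, major = major),
            class = "lasso_type")
}

#' @export
print.lasso_type <- function(x, ...) {
  cat(sprintf("<lasso_type> %s (major %s, class %s)\n", x$minor, x$major, x$klass))
  invisible(x)
}

normalize_signs <- function(s) {
  if (length(s) == 0L) return(integer())
  if (is.character(s)) {
    bad <- !s %in% c("+", "-")
    if (any(bad)) stop("malformed sign symbol: ", s[bad][1L])
    return(ifelse(s == "+", 1L, -1L))
  }
  if (!all(s %in% c(-1, 1))) stop("signs must be +1/-1 or \"+\"/\"-\"")
  as.integer(s)
}

is_supercoiled <- function(s) {
  length(s) >= 2L && any(s[-1L] == s[-length(s)])
}

sign_char <- function(s) if (s > 0) "+" else "-"
sign_string <- function(s) paste(vapply(s, sign_char, character(1L)), collapse = "")

#' Parse a minor lasso label back into sign lists
#'
#' Inverse of the [classify_loop()] labelling; used by the synthetic fixture
#' generator. Alternating (`L`, and the alternating parts of `LL`) labels
#' expand to the alternating sign sequence starting from the stated rank-1
#' sign.
#'
#' @param label minor label such as `"L-1C"`, `"LS2--N"`, `"LL+1,+2"`,
#'   `"LLS2--,+2"`, or `"L0"`.
#' @return list with `n_signs` and `c_signs` (integer vectors).
#' @export
parse_minor <- function(label) {
  if (label == "L0") return(list(n_signs = integer(), c_signs = integer()))
  alt <- function(s0, k) s0 * (-1L)^(seq_len(k) - 1L)
  m <- regmatches(label, regexec("^L([+-])([0-9]+)([NC])$", label))[[1L]]
  if (length(m)) {
    s <- alt(if (m[2L] == "+") 1L else -1L, as.integer(m[3L]))
    return(if (m[4L] == "N") list(n_signs = s, c_signs = integer())
           else list(n_signs = integer(), c_signs = s))
  }
  m <- regmatches(label, regexec("^LS([0-9]+)([+-]+)([NC])$", label))[[1L]]
  if (length(m)) {
    k <- as.integer(m[2L])
    s <- normalize_signs(strsplit(m[3L], "")[[1L]])
    if (length(s) != k) stop("LS label sign string length mismatch: ", label)
    if (!is_supercoiled(s)) stop("LS label without consecutive equal signs: ", label)
    return(if (m[4L] == "N") list(n_signs = s, c_signs = integer())
           else list(n_signs = integer(), c_signs = s))
  }
  m <- regmatches(label,
                  regexec("^(LLS|LL)([+-][0-9]+|[0-9]+[+-]+),([+-][0-9]+|[0-9]+[+-]+)$",
                          label))[[1L]]
  if (length(m)) {
    part <- function(p) {
      pm <- regmatches(p, regexec("^([+-])([0-9]+)$", p))[[1L]]
      if (length(pm)) return(alt(if (pm[2L] == "+") 1L else -1L, as.integer(pm[3L])))
      pm <- regmatches(p, regexec("^([0-9]+)([+-]+)$", p))[[1L]]
      s <- normalize_signs(strsplit(pm[3L], "")[[1L]])
      if (length(s) != as.integer(pm[2L]))
        stop("supercoiled part length mismatch in: ", label)
      s
    }
    out <- list(n_signs = part(m[3L]), c_signs = part(m[4L]))
    chk <- classify_loop(out$n_signs, out$c_signs)
    if (chk$minor != label)
      stop("label '", label, "' is not canonical (expected '", chk$minor, "')")
    return(out)
  }
  stop("unparseable minor lasso label: ", label)
}

#' Build the lasso fingerprint of a chain
#'
#' Concatenation of the major lasso types of all pierced loops in their
#' sequential order, with `L0` suppressed and runs of identical consecutive
#' majors compressed with a multiplicity prefix (`"2L1"`).
#'
#' @param types list of `lasso_type` objects (or major label strings) in
#'   sequential loop order.
#' @return object of class `lasso_fingerprint`: list with `majors`
#'   (uncompressed, L0 removed) and `text`.
#' @export
lasso_fingerprint <- function(types) {
  majors <- vapply(types, function(t)
    if (inherits(t, "lasso_type")) t$major else as.character(t), character(1L))
  majors <- majors[majors != "L0"]
  if (length(majors) == 0L)
    return(structure(list(majors = character(), text = ""),
                     class = "lasso_fingerprint"))
  r <- rle(majors)
  text <- paste0(ifelse(r$lengths > 1L, r$lengths, ""), r$values, collapse = "")
  structure(list(majors = majors, text = text), class = "lasso_fingerprint")
}

#' @export
print.lasso_fingerprint <- function(x, ...) {
  cat(sprintf("<lasso_fingerprint> \"%s\" (%d pierced loop(s))\n",
              x$text, length(x$majors)))
  invisible(x)
}

#' Parse a lasso fingerprint string
#'
#' Inverse of [lasso_fingerprint()] up to L0 suppression. The grammar reads,
#' left to right, an optional multiplicity (digits before an `L`), then a
#' major label: `LLS`/`LL` with two single-digit piercing counts separated
#' by a comma, or `LS`/`L` with one single-digit count. Counts are single
#' digits (no deposited structure comes close to ten piercings of one loop);
#' multiplicities may have several digits.
#'
#' @param text fingerprint string, e.g. `"LS32L1LS2"`; `""` is the trivial
#'   fingerprint.
#' @return list with `majors` (expanded label vector), `n_loops`, and
#'   `total_piercings` (an `LLi,j` major contributes i+j).
#' @export
parse_fingerprint <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  majors <- character()
  pos <- 1L
  n <- nchar(text)
  fail <- function(pos) stop("fingerprint grammar error at position ", pos,
                             " in \"", text, "\"")
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([0-9]*)(LLS|LL|LS|L)", rest))[[1L]]
    if (length(m) == 0L) fail(pos)
    mult <- if (m[2L] == "") 1L else as.integer(m[2L])
    if (mult < 1L) fail(pos)
    pos <- pos + nchar(m[1L])
    head <- m[3L]
    rest <- substr(text, pos, n)
    if (head %in% c("LL", "LLS")) {
      mm <- regmatches(rest, regexec("^([0-9]),([0-9])", rest))[[1L]]
      if (length(mm) == 0L) fail(pos)
      label <- paste0(head, mm[2L], ",", mm[3L])
      pos <- pos + nchar(mm[1L])
    } else {
      mm <- regmatches(rest, regexec("^([0-9])", rest))[[1L]]
      if (length(mm) == 0L) fail(pos)
      if (head == "L" && mm[2L] == "0") fail(pos - 1L)   # L0 never appears
      label <- paste0(head, mm[2L])
      pos <- pos + 1L
    }
    majors <- c(majors, rep(label, mult))
  }
  list(majors = majors, n_loops = length(majors),
       total_piercings = sum(vapply(majors, major_piercings, integer(1L))))
}

#' Piercing count encoded by one major label
#'
#' @param major a major label (`"L3"`, `"LS2"`, `"LL4,3"`, `"LLS2,2"`).
#' @return integer piercing count (i+j for two-sided types).
#' @export
major_piercings <- function(major) {
  m <- regmatches(major, regexec("^(LLS|LL)([0-9]+),([0-9]+)$", major))[[1L]]
  if (length(m)) return(as.integer(m[3L]) + as.integer(m[4L]))
  m <- regmatches(major, regexec("^(LS|L)([0-9]+)$", major))[[1L]]
  if (length(m)) return(as.integer(m[3L]))
  stop("not a major lasso label: ", major)
}

# all minor realizations (sign-list pairs) of a major label
major_realizations <- function(major) {
  alt_strings <- function(k) {
    if (k == 0L) return(list(integer()))
    list(1L * (-1L)^(seq_len(k) - 1L), -1L * (-1L)^(seq_len(k) - 1L))
  }
  all_strings <- function(k) {
    if (k == 0L) return(list(integer()))
    g <- expand.grid(rep(list(c(-1L, 1L)), k))
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  sup_strings <- function(k) Filter(is_supercoiled, all_strings(k))
  out <- list()
  add <- function(n, c_) out[[length(out) + 1L]] <<- list(n_signs = n, c_signs = c_)
  if (major == "L0") { add(integer(), integer()); return(out) }
  m <- regmatches(major, regexec("^(LLS|LL)([0-9]+),([0-9]+)$", major))[[1L]]
  if (length(m)) {
    i <- as.integer(m[3L]); j <- as.integer(m[4L])
    if (m[2L] == "LL") {
      for (sn in alt_strings(i)) for (sc in alt_strings(j)) add(sn, sc)
    } else {
      for (sn in all_strings(i)) for (sc in all_strings(j))
        if (is_supercoiled(sn) || is_supercoiled(sc)) add(sn, sc)
    }
    return(out)
  }
  m <- regmatches(major, regexec("^(LS|L)([0-9]+)$", major))[[1L]]
  if (!length(m)) stop("not a major lasso label: ", major)
  k <- as.integer(m[3L])
  strs <- if (m[2L] == "L") alt_strings(k) else sup_strings(k)
  for (s in strs) { add(s, integer()); add(integer(), s) }
  out
}

#' Evolution-flower neighborhood of a lasso type
#'
#' Lasso types reachable from `major` by a single evolutionary move:
#' `terminal_piercing` appends or removes one signed crossing at the free
#' (terminal) end of either tail; `terminal_slipknot` appends an
#' opposite-sign pair (`+,-` or `-,+`) at a tail end -- the slipknot
#' conformation through which two piercings appear at once. Every minor
#' realization of `major` is expanded, the move applied, and the resulting
#' labels collected.
#'
#' @param major a major lasso label (or `"L0"`).
#' @param move `"terminal_piercing"` or `"terminal_slipknot"`.
#' @param level collect `"major"` (default) or `"minor"` labels.
#' @return sorted character vector of distinct neighbor labels.
#' @export
flower_neighbors <- function(major,
                             move = c("terminal_piercing", "terminal_slipknot"),
                             level = c("major", "minor")) {
  move <- match.arg(move)
  level <- match.arg(level)
  reals <- major_realizations(major)
  res <- character()
  grab <- function(n, c_) {
    t <- classify_loop(n, c_)
    res <<- c(res, if (level == "major") t$major else t$minor)
  }
  for (r in reals) {
    for (tail in c("n", "c")) {
      s <- if (tail == "n") r$n_signs else r$c_signs
      other <- if (tail == "n") r$c_signs else r$n_signs
      emit <- function(snew) {
        if (tail == "n") grab(snew, other) else grab(other, snew)
      }
      if (move == "terminal_piercing") {
        emit(c(s, 1L)); emit(c(s, -1L))
        if (length(s) > 0L) emit(s[-length(s)])
      } else {
        emit(c(s, 1L, -1L)); emit(c(s, -1L, 1L))
      }
    }
  }
  sort(unique(res))
}
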