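# Average residue volumes (A^3) from standard van der Waals volume tables
# (Zamyatnin-style partial residue volumes); used as the "bulkiness" scale.
.residue_volumes <- c(
  ALA =  88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY =  60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER =  89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# centered moving mean with truncated windows at the ends
windowed_mean <- function(v, window) {
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(v[lo:hi], na.rm = TRUE)
  }, numeric(1L))
}

new_profile <- function(values, kind, window) {
  structure(list(values = values, kind = kind, window = as.integer(window)),
            class = "lasso_profile")
}

#' @export
print.lasso_profile <- function(x, ...) {
  cat(sprintf("<lasso_profile> kind %s, %d residues, window %d\n",
              x$kind, length(x$values), x$window))
  invisible(x)
}

#' Local concentration of bulky residues along a sequence
#'
#' Per-residue mean side-chain volume over a centered window. A piercing
#' residue mechanically blocked by bulky neighbors sits near a local
#' maximum of this profile.
#'
#' @param sequence amino-acid sequence: a character vector of 3-letter
#'   codes, a vector of 1-letter codes, or a single 1-letter string.
#'   Unknown codes get the mean residue volume.
#' @param window odd smoothing window in residues (default 5).
#' @return a `lasso_profile` of kind `"bulkiness"`.
#' @export
bulkiness_profile <- function(sequence, window = 5L) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  if (length(sequence) == 0L) stop("empty sequence")
  sequence <- toupper(sequence)
  one <- nchar(sequence) == 1L
  sequence[one] <- unname(.aa1to3[sequence[one]])
  vol <- unname(.residue_volumes[sequence])
  vol[is.na(vol)] <- mean(.residue_volumes)
  new_profile(windowed_mean(vol, window), "bulkiness", window)
}

#' Rigidity profile from B-factors or an NMR ensemble
#'
#' Crystal chains: windowed mean of the CA B-factors. NMR chains (at least
#' two models): every model is superposed onto model 1 by a least-squares CA
#' fit, and the per-residue mean square deviation of CA positions about the
#' ensemble mean is smoothed with the same window. Low values mark rigid,
#' stabilized chain regions.
#'
#' @param chain a `lasso_chain`.
#' @param window odd smoothing window in residues (default 5).
#' @return a `lasso_profile` of kind `"bfactor"` or `"msd"`.
#' @export
bfactor_profile <- function(chain, window = 5L) {
  if (!is.null(chain$models) && length(chain$models) >= 2L) {
    ref <- chain$models[[1L]]
    fitted <- lapply(chain$models, function(m) kabsch_fit(m, ref))
    n <- nrow(ref)
    arr <- array(unlist(fitted), dim = c(n, 3L, length(fitted)))
    mean_pos <- apply(arr, c(1L, 2L), mean)
    dev2 <- sapply(seq_along(fitted), function(k)
      rowSums((arr[, , k] - mean_pos)^2))
    msd <- rowMeans(dev2)
    return(new_profile(windowed_mean(msd, window), "msd", window))
  }
  b <- chain$residues$bfactor
  if (all(is.na(b)))
    stop("chain has neither B-factors nor at least two models")
  new_profile(windowed_mean(b, window), "bfactor", window)
}

#' Local extrema of a profile
#'
#' Indices whose value is strictly better (smaller for `"min"`, larger for
#' `"max"`) than both neighbors. A plateau of equal values strictly better
#' than both flanking values reports its midpoint. Chain ends are never
#' extrema.
#'
#' @param profile a `lasso_profile` (or bare numeric vector), length >= 3.
#' @param mode `"min"` or `"max"`.
#' @return integer vector of 1-based residue indices.
#' @export
local_extrema <- function(profile, mode = c("min", "max")) {
  mode <- match.arg(mode)
  v <- if (inherits(profile, "lasso_profile")) profile$values else profile
  stopifnot(length(v) >= 3L)
  if (mode == "max") v <- -v
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer()
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next      # touching a chain end
    if (r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L])
      out <- c(out, (starts[k] + ends[k]) %/% 2L)
  }
  out
}

#' Sequential distance from a piercing residue to the nearest extremum
#'
#' @param piercing_residue residue index of the piercing (by convention, the
#'   loop-proximal residue of the piercing segment).
#' @param extrema integer vector of extremum indices.
#' @return minimal absolute sequential distance in residues, or `NA` with an
#'   undefined-distance warning when `extrema` is empty.
#' @export
piercing_extremum_distance <- function(piercing_residue, extrema) {
  if (length(extrema) == 0L)
    return(undefined_distance("no extrema: piercing-extremum distance undefined"))
  as.integer(min(abs(piercing_residue - extrema)))
}

#' Stabilization report for the piercings of a chain
#'
#' For every piercing residue, the sequential distance to the nearest local
#' maximum of the bulky-residue concentration and to the nearest local
#' minimum of the B-factor (or NMR mean-square-deviation) profile.
#'
#' @param chain a `lasso_chain`.
#' @param piercings piercing table ([reduce_crossings()] output, both tails).
#' @param window odd smoothing window (default 5).
#' @return data.frame with `piercing_residue`, `d_bulky`, `d_bfac`, `kind`.
#' @export
stability_report <- function(chain, piercings, window = 5L) {
  if (is.null(piercings) || nrow(piercings) == 0L)
    return(data.frame(piercing_residue = integer(), d_bulky = integer(),
                      d_bfac = integer(), kind = character()))
  bulky <- bulkiness_profile(chain$residues$name, window)
  max_b <- local_extrema(bulky, "max")
  flex <- tryCatch(bfactor_profile(chain, window), error = function(e) NULL)
  min_f <- if (is.null(flex)) integer() else local_extrema(flex, "min")
  pr <- piercings$seg_from
  data.frame(
    piercing_residue = pr,
    d_bulky = vapply(pr, function(p)
      suppressWarnings(piercing_extremum_distance(p, max_b)), integer(1L)),
    d_bfac = vapply(pr, function(p)
      suppressWarnings(piercing_extremum_distance(p, min_f)), integer(1L)),
    kind = if (is.null(flex)) NA_character_ else flex$kind)
}
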