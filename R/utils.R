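# small geometry helpers shared across modules

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitize <- function(a) {
  n <- vnorm(a)
  if (n == 0) stop("cannot normalize a zero vector")
  a / n
}

# rowwise cross product for n x 3 matrices
rowcross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

rownorm <- function(A) sqrt(rowSums(A * A))

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares fit of one coordinate set onto another, used when turning an
#' NMR ensemble into a per-residue positional-deviation profile.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matching rows.
#' @return The mobile matrix rotated and translated onto `fixed`.
#' @keywords internal
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3L, ncol(fixed) == 3L)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(fixed, 2L, cf)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  out <- A %*% t(R)
  sweep(out, 2L, cf, `+`)
}

# condition helper: undefined sequential distance (empty piercing/extrema set)
undefined_distance <- function(msg) {
  warning(structure(class = c("lasso_undefined_distance", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
  NA_integer_
}
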