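#' @useDynLib semfma, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov dnorm optimize pchisq pnorm qnorm quantile
#'   median rnorm setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# stacked unique off-diagonal entries of a symmetric matrix, canonical
# order: column-major lower triangle (x-block variables precede y-block)
lower_vec <- function(m) m[lower.tri(m)]

# names "v2:v1", "v3:v1", ... matching lower_vec() order
lower_vec_names <- function(vars) {
  p <- length(vars)
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  paste(vars[idx[, 1L]], vars[idx[, 2L]], sep = ":")
}

# inverse of lower_vec: symmetric matrix with unit diagonal
vec_to_corr <- function(v, p) {
  m <- diag(p)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

block_diag <- function(a, b) {
  out <- matrix(0, nrow(a) + nrow(b), ncol(a) + ncol(b))
  out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  out[nrow(a) + seq_len(nrow(b)), ncol(a) + seq_len(ncol(b))] <- b
  out
}

symmetrize <- function(m) (m + t(m)) / 2

is_psd <- function(m, tol = 1e-8) {
  if (length(m) == 0L) return(TRUE)
  ev <- eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(1, max(abs(ev)))
}

stop_semfma <- function(msg, class) {
  stop(structure(class = c(class, "semfma_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
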