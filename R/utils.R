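# internal helpers shared across modules

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' L_p norm of a perturbation or image
#'
#' `p = Inf` is the maximum absolute pixel value, `p = 2` the Euclidean
#' norm of the flattened array.
#'
#' @param x a numeric array or vector.
#' @param p `2` or `Inf`.
#' @return a nonnegative scalar.
#' @export
lpNorm <- function(x, p) {
  if (identical(p, Inf)) return(max(abs(x)))
  if (identical(as.numeric(p), 2)) return(sqrt(sum(as.numeric(x)^2)))
  stop("p must be 2 or Inf")
}

# coerce ImageSet / (N,H,W,C) array / single (H,W,C) image to a batch array
asImageArray <- function(x) {
  if (is(x, "ImageSet")) return(x@images)
  if (!is.array(x)) stop("expected an ImageSet or a numeric array")
  d <- dim(x)
  if (length(d) == 3L) {
    arr <- array(x, dim = c(1L, d))
    return(arr)
  }
  if (length(d) == 4L) return(x)
  stop("image arrays must have shape (N, H, W, C) or (H, W, C)")
}

# (N,H,W,C) batch -> D x N matrix, column = image flattened in (H,W,C) order
flattenBatch <- function(arr) {
  d <- dim(arr)
  m <- aperm(arr, c(2L, 3L, 4L, 1L))
  dim(m) <- c(prod(d[2:4]), d[1])
  m
}

# D x N matrix -> (N,H,W,C) batch
unflattenBatch <- function(m, shape) {
  n <- ncol(m)
  dim(m) <- c(shape, n)
  aperm(m, c(4L, 1L, 2L, 3L))
}

# proportional allocation of n items to weights w: round(n * w / sum(w)),
# remainder (either sign) absorbed by the largest-weight class
allocateCounts <- function(n, w) {
  cnt <- round(n * w / sum(w))
  cnt[which.max(w)] <- cnt[which.max(w)] + (n - sum(cnt))
  as.integer(cnt)
}

checkShapeMatch <- function(rho, shape) {
  if (!identical(as.integer(dim(rho)), as.integer(shape)))
    stop("perturbation shape (", paste(dim(rho), collapse = "x"),
         ") does not match image shape (", paste(shape, collapse = "x"), ")")
  invisible(TRUE)
}

# extract the raw rho array from a UAP or pass a bare array through
asRho <- function(rho) {
  if (is(rho, "UAP")) rho@rho else rho
}

uapIdOf <- function(rho) {
  if (is(rho, "UAP")) {
    if (identical(rho@sourceModelId, "random")) "random"
    else paste0(rho@sourceModelId, if (!is.null(rho@config))
      paste0("/", rho@config@mode, "-seed", rho@config@seed) else "")
  } else "array"
}
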