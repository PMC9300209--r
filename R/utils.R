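## Internal numerical helpers shared across the likelihood, estimation and
## calibration code. Nothing here is exported.

## log(sum(exp(x))) without overflow; x may contain -Inf.
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log-sum-exp for a matrix (one result per row); max.col keeps the
## row-maximum search in C.
.rowLogSumExp <- function(x) {
  j <- max.col(x, ties.method = "first")
  m <- x[cbind(seq_along(j), j)]
  out <- m
  ok <- is.finite(m)
  if (any(ok))
    out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

.assertFinite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

## Gauss-Legendre nodes/weights on [0, 1], cached by order.
.glCache <- new.env(parent = emptyenv())
.gaussLegendre01 <- function(n) {
  key <- as.character(n)
  got <- .glCache[[key]]
  if (!is.null(got)) return(got)
  ## Golub-Welsch from the Jacobi matrix of the Legendre recurrence.
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values                      # nodes on [-1, 1]
  w <- 2 * e$vectors[1L, ]^2
  ord <- order(x)
  out <- list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
  .glCache[[key]] <- out
  out
}

## Convergence of an nlm() result: clean termination codes, or a code-3 exit
## ("no lower point found") whose gradient is numerically zero -- the usual
## way nlm reports an optimum it cannot improve along its last direction.
.nlmConverged <- function(opt) {
  opt$code %in% c(1L, 2L) ||
    (opt$code == 3L &&
       max(abs(opt$gradient)) < 1e-4 * max(1, abs(opt$minimum)))
}

## Deterministic per-replicate seed stream: master seed plus a documented
## counter over (region, replicate); kept below 2^31 - 1.
.deriveSeed <- function(seed, region, replicate) {
  as.integer((as.double(seed) + 7919 * as.double(region) +
                as.double(replicate)) %% 2147483587)
}
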