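#' @keywords internal
"_PACKAGE"

## NULL-default helper used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components of a binary matrix
#'
#' Two-pass union-find labelling at an explicit connectivity. Used for focus
#' growth (orthogonal neighbours only) and for edge-map post-processing.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 (orthogonal neighbours) or 8 (orthogonal + diagonal).
#' @return integer matrix of the same shape; 0 = background, 1..k = components.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j]) next
    nbr <- integer(0)
    if (i > 1 && m[i - 1L, j]) nbr <- c(nbr, lab[i - 1L, j])
    if (j > 1 && m[i, j - 1L]) nbr <- c(nbr, lab[i, j - 1L])
    if (connectivity == 8) {
      if (i > 1 && j > 1 && m[i - 1L, j - 1L]) nbr <- c(nbr, lab[i - 1L, j - 1L])
      if (i < nr && j > 1 && m[i + 1L, j - 1L]) nbr <- c(nbr, lab[i + 1L, j - 1L])
    }
    if (length(nbr) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(nbr, find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (x in roots) parent[x] <- r
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

## Rasterize the convex hull of a set of pixel coordinates (row, col) onto a
## grid of the given dimensions. Boundary pixels are included.
rasterize_convex_hull <- function(rows, cols, dim_out) {
  stopifnot(length(rows) == length(cols), length(rows) > 0)
  out <- matrix(FALSE, dim_out[1], dim_out[2])
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) <= 2) {
    out[pts] <- TRUE
    return(out)
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  n <- length(h)
  rr <- max(1L, floor(min(hx))):min(dim_out[1], ceiling(max(hx)))
  cc <- max(1L, floor(min(hy))):min(dim_out[2], ceiling(max(hy)))
  grid <- expand.grid(r = rr, c = cc)
  # chull returns vertices clockwise; a point is inside iff every edge cross
  # product has the same (non-positive) sign, with tolerance for the boundary
  inside <- rep(TRUE, nrow(grid))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    cr <- ex * (grid$c - hy[k]) - ey * (grid$r - hx[k])
    inside <- inside & (cr <= 1e-9)
  }
  out[cbind(grid$r[inside], grid$c[inside])] <- TRUE
  out
}

## Freeman chain-code perimeter by Moore boundary tracing: straight steps
## contribute 1, diagonal steps sqrt(2). `mask` must contain a single
## 8-connected region without holes touching its outer boundary.
chain_code_perimeter <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(0)
  if (sum(m) == 1) return(4)   # lone pixel: its own four edges
  # pad so tracing never leaves bounds
  p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  idx <- which(p, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]  # leftmost-topmost
  # Moore neighbourhood in clockwise order starting from W
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  per <- 0
  cur <- start
  entered_from <- 1L  # pretend we entered from the West
  first_step <- NULL
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((entered_from - 1L + s) %% 8L) + 1L
      r2 <- cur[1] + dr[k]; c2 <- cur[2] + dc[k]
      if (p[r2, c2]) {
        step_len <- if (dr[k] != 0 && dc[k] != 0) sqrt(2) else 1
        per <- per + step_len
        # next search starts from the backtrack direction
        entered_from <- ((k - 1L + 5L) %% 8L) + 1L
        prev <- cur
        cur <- c(r2, c2)
        if (is.null(first_step)) first_step <- c(prev, cur)
        found <- TRUE
        break
      }
    }
    if (!found) return(4)   # isolated pixel cluster fallback
    if (all(cur == start) && !is.null(first_step)) {
      # require repeating the first transition to terminate (handles spurs)
      for (s in 0:7) {
        k <- ((entered_from - 1L + s) %% 8L) + 1L
        r2 <- cur[1] + dr[k]; c2 <- cur[2] + dc[k]
        if (p[r2, c2]) break
      }
      if (all(c(cur[1], cur[2], r2, c2) == first_step)) break
      if (per > 8 * sum(m)) break  # safety: cannot loop forever
    }
  }
  per
}

#' Otsu threshold for a numeric sample
#'
#' Histogram-based Otsu threshold: the cut maximizing the between-class
#' variance over a fixed-width binning of the sample range.
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return the threshold value (a bin edge); values strictly greater are
#'   "above". `NA` with a warning if `x` is (nearly) constant.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) < .Machine$double.eps) {
    warning("degenerate sample: no Otsu threshold defined")
    return(NA_real_)
  }
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- sum(counts); mu_t <- mu[nbins]
  # between-class variance for a cut after bin k (vectorized)
  k <- seq_len(nbins - 1)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1)
  m0 <- mu[k][valid] / w0[valid]
  m1 <- (mu_t - mu[k][valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (m0 - m1)^2
  edges[which.max(bcv) + 1]
}

## Draw a fresh integer seed stream from one master seed; keeps every source
## of randomness tied to a single run seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
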