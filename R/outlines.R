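## Open-outline geometric morphometrics: equal-arc-length resampling along a
## cubic spline, Bookstein baseline registration of the two endpoints, and a
## discrete cosine transform harmonic representation per coordinate axis.

#' Construct an outline
#'
#' @param coords two-column matrix or data frame of ordered x, y points.
#' @param label specimen or species label.
#' @return an `outline`: list with `coords` (n x 2 matrix) and `label`.
#' @export
outline <- function(coords, label = NA_character_) {
  m <- as.matrix(coords)
  if (ncol(m) != 2) stopf("outline coordinates must have 2 columns")
  if (nrow(m) < 3) stopf("outline needs at least 3 points")
  dup <- which(rowSums(abs(diff(m))) == 0)
  if (length(dup)) m <- m[-(dup + 1L), , drop = FALSE]
  if (nrow(m) < 3) stopf("outline degenerate after removing duplicate points")
  if (all(m[1, ] == m[nrow(m), ]))
    stopf("outline must be open (first point != last point)")
  colnames(m) <- c("x", "y")
  structure(list(coords = m, label = label), class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("Open outline '%s': %d points\n", x$label, nrow(x$coords)))
  invisible(x)
}

#' @export
plot.outline <- function(x, ...) {
  graphics::plot(x$coords, type = "l", asp = 1, xlab = "x", ylab = "y",
                 main = x$label, ...)
  invisible(x)
}

#' Resample an outline to equally spaced points
#'
#' Interpolates the polyline with natural cubic splines in x and y against
#' cumulative arc length, then places `n` points at equal arc-length spacing
#' along the spline (arc length measured on a fine subdivision of the
#' spline). Endpoints are preserved exactly.
#'
#' @param o an `outline`.
#' @param n number of output points (200 by convention).
#' @param refine subdivision factor used to measure spline arc length.
#' @return resampled `outline`.
#' @export
resample_outline <- function(o, n = 200, refine = 25) {
  stopifnot(inherits(o, "outline"), n >= 3)
  m <- o$coords
  d <- sqrt(rowSums(diff(m)^2))
  if (sum(d) <= 0) stopf("degenerate outline: zero total length")
  s <- c(0, cumsum(d))
  fx <- stats::splinefun(s, m[, 1], method = "natural")
  fy <- stats::splinefun(s, m[, 2], method = "natural")
  ## fine subdivision to measure true arc length along the spline
  sf <- seq(0, s[length(s)], length.out = refine * nrow(m))
  xf <- fx(sf); yf <- fy(sf)
  af <- c(0, cumsum(sqrt(diff(xf)^2 + diff(yf)^2)))
  target <- seq(0, af[length(af)], length.out = n)
  sp <- stats::approx(af, sf, xout = target, ties = "ordered")$y
  out <- cbind(fx(sp), fy(sp))
  out[1, ] <- m[1, ]; out[n, ] <- m[nrow(m), ]
  outline(out, o$label)
}

#' Bookstein baseline registration
#'
#' Applies the similarity transform (translation, rotation, scaling) sending
#' the outline's two endpoints to (-0.5, 0) and (0.5, 0). Shape is otherwise
#' unchanged, so any rotated, scaled, or translated copy of an outline maps
#' to the same registered outline.
#'
#' @param o an `outline`.
#' @return registered `outline`.
#' @export
bookstein_align <- function(o) {
  stopifnot(inherits(o, "outline"))
  m <- o$coords
  z <- complex(real = m[, 1], imaginary = m[, 2])
  n <- length(z)
  base <- z[n] - z[1]
  if (Mod(base) == 0) stopf("coincident endpoints: cannot register")
  w <- (z - (z[1] + z[n]) / 2) / base
  outline(cbind(Re(w), Im(w)), o$label)
}

#' DCT harmonic amplitudes of a registered outline
#'
#' Computes the orthonormal DCT-II of each coordinate signal of the
#' registered, resampled outline and retains orders 1..`n_harm` (order 0, the
#' mean position, is dropped: registration has already removed position).
#'
#' @param o a registered, resampled `outline`.
#' @param n_harm number of harmonic orders retained per axis (21 by
#'   convention).
#' @return `harmonics`: list with `x`, `y` (length-`n_harm` amplitude
#'   vectors), `n_points`, `label`.
#' @export
dct_harmonics <- function(o, n_harm = 21) {
  stopifnot(inherits(o, "outline"))
  m <- o$coords
  if (nrow(m) <= n_harm) stopf("outline has fewer points than retained orders")
  structure(list(x = dct2(m[, 1])[1 + seq_len(n_harm)],
                 y = dct2(m[, 2])[1 + seq_len(n_harm)],
                 n_points = nrow(m), label = o$label),
            class = "harmonics")
}

## Orthonormal DCT-II: a_k = c_k * sum_j x_j cos(pi k (2j+1) / (2N)),
## c_0 = sqrt(1/N), c_k = sqrt(2/N). Returns orders 0..N-1. Internal.
dct2 <- function(x) {
  N <- length(x)
  j <- seq_len(N) - 1
  k <- j
  M <- cos(pi * outer(k, 2 * j + 1) / (2 * N))
  a <- as.vector(M %*% x)
  a * c(sqrt(1 / N), rep(sqrt(2 / N), N - 1))
}

## Inverse orthonormal DCT-II (DCT-III). Internal.
idct2 <- function(a, N = length(a)) {
  K <- length(a)
  j <- seq_len(N) - 1
  k <- seq_len(K) - 1
  cf <- c(sqrt(1 / N), rep(sqrt(2 / N), K - 1))
  M <- cos(pi * outer(2 * j + 1, k) / (2 * N))
  as.vector(M %*% (a * cf))
}

#' Rebuild an outline from retained harmonics
#'
#' @param h a `harmonics` object.
#' @param n number of points in the reconstruction.
#' @return an `outline` reconstructed from the retained orders (order 0 set
#'   to zero, i.e. centred on the registration frame).
#' @export
reconstruct_outline <- function(h, n = 200) {
  stopifnot(inherits(h, "harmonics"))
  ax <- c(0, h$x); ay <- c(0, h$y)
  ## amplitudes were computed at h$n_points; rescale the orthonormal factors
  ## to the reconstruction length
  sx <- idct2(ax * sqrt(n / h$n_points), n)
  sy <- idct2(ay * sqrt(n / h$n_points), n)
  outline(cbind(sx, sy), h$label)
}

#' Registered DCT coefficients for a set of outlines
#'
#' Full pipeline: resample to `n_points`, Bookstein-register, take DCT
#' harmonics, and stack the x- and y-amplitudes into one row per specimen.
#'
#' @param outlines list of `outline` objects.
#' @param n_points resampling density.
#' @param n_harm harmonic orders per axis.
#' @return numeric matrix (specimens x `2 * n_harm`), rownames = labels,
#'   colnames `x1..xh, y1..yh`.
#' @export
outline_coefficients <- function(outlines, n_points = 200, n_harm = 21) {
  rows <- lapply(outlines, function(o) {
    h <- dct_harmonics(bookstein_align(resample_outline(o, n_points)), n_harm)
    c(h$x, h$y)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(outlines, function(o) o$label, "")
  colnames(m) <- c(paste0("x", seq_len(n_harm)), paste0("y", seq_len(n_harm)))
  m
}

#' Read outlines from a long-format CSV
#'
#' Expects columns `specimen`, `point`, `x`, `y`; points are ordered by
#' `point` within specimen.
#'
#' @param path CSV file.
#' @return named list of `outline` objects.
#' @export
read_outlines_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "point", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("outline CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[order(df$specimen, df$point), ]
  sp <- split(df, df$specimen)
  out <- lapply(names(sp), function(nm)
    outline(sp[[nm]][, c("x", "y")], nm))
  names(out) <- names(sp)
  out
}

#' Write outlines to a long-format CSV
#' @param outlines list of `outline` objects.
#' @param path output file.
#' @export
write_outlines_csv <- function(outlines, path) {
  tab <- do.call(rbind, lapply(outlines, function(o)
    data.frame(specimen = o$label, point = seq_len(nrow(o$coords)),
               x = o$coords[, 1], y = o$coords[, 2])))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read outlines from a TPS file
#'
#' Minimal TPS reader: `LM=` / `OUTLINES=`-free files with `LM=n` blocks and
#' an `ID=` per specimen.
#'
#' @param path TPS file.
#' @return named list of `outline` objects.
#' @export
read_outlines_tps <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (grepl("^LM=", l, ignore.case = TRUE)) {
      n <- as.integer(sub("^LM=", "", l, ignore.case = TRUE))
      pts <- do.call(rbind, lapply(lines[i + seq_len(n)], function(s)
        as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
      i <- i + n + 1
      id <- NA_character_
      while (i <= length(lines) && !grepl("^LM=", trimws(lines[i]), ignore.case = TRUE)) {
        if (grepl("^ID=", trimws(lines[i]), ignore.case = TRUE))
          id <- sub("^ID=", "", trimws(lines[i]), ignore.case = TRUE)
        i <- i + 1
      }
      out[[length(out) + 1L]] <- outline(pts, id)
    } else i <- i + 1
  }
  names(out) <- vapply(out, function(o) o$label, "")
  out
}
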