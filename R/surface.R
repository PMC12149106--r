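#' The 3x3 PMC surface
#'
#' A policy's nine first-level values, arranged row-major into a 3x3
#' matrix — row 1 = (X1, X2, X3), row 2 = (X4, X5, X6), row 3 =
#' (X7, X8, X9) — and rendered as a 3-D surface whose concavity exposes
#' the policy's weak dimensions. The mean of the nine cells times 9
#' equals the full-precision PMC index of those values; flattening
#' row-major recovers the nine values in order.
#'
#' @param x a `pmc_scores` object, or a numeric vector of exactly nine
#'   first-level values in \[0, 1\].
#' @param policy which policy to take from a `pmc_scores` object (index
#'   or policy id).
#' @return A `pmc_surface`: a 3x3 numeric matrix with attribute
#'   `policy_id`.
#' @examples
#' s <- pmc_surface(c(0.67, 1, 0.25, 1, 0.5, 0.5, 0.67, 0.5, 0.8))
#' s
#' flatten(s)
#' mean(s) * 9   # full-precision PMC
#' @export
pmc_surface <- function(x, policy = 1L) {
  vals <- if (inherits(x, "pmc_scores")) {
    if (ncol(x$first_level) != 9L) {
      stop("the PMC surface is defined for 9-primary schemas only",
           call. = FALSE)
    }
    x$first_level[policy, ]
  } else {
    as.numeric(x)
  }
  if (length(vals) != 9L) {
    stop("a PMC surface needs exactly nine first-level values",
         call. = FALSE)
  }
  if (anyNA(vals) || any(vals < 0 | vals > 1)) {
    stop("first-level values must lie in [0, 1]", call. = FALSE)
  }
  pid <- if (inherits(x, "pmc_scores")) {
    rownames(x$first_level)[if (is.character(policy))
      match(policy, rownames(x$first_level)) else policy]
  } else NULL
  structure(matrix(vals, nrow = 3L, ncol = 3L, byrow = TRUE),
            policy_id = pid, class = c("pmc_surface", "matrix", "array"))
}

#' @rdname pmc_surface
#' @param surface a `pmc_surface`.
#' @return `flatten()`: the nine values in row-major (X1..X9) order.
#' @export
flatten <- function(surface) {
  stopifnot(inherits(surface, "pmc_surface"))
  as.vector(t(unclass(surface)))
}

#' Upsampled surface grid
#'
#' Interpolates the 3x3 anchor grid onto a finer mesh with a
#' tensor-product cubic spline (natural end conditions, applied along
#' rows then columns), clamped to \[0, 1\]. The interpolant passes
#' through the nine anchors exactly, so smoothing only adds
#' intermediate points; `upsample = 1` returns the anchors themselves.
#'
#' @param surface a `pmc_surface`.
#' @param upsample subdivisions per cell edge (default 25, the
#'   rendering default).
#' @return List with `x`, `y` (grid coordinates on \[1, 3\]; x runs
#'   along columns of the 3x3 matrix, y along rows) and `z` (matrix of
#'   interpolated heights indexed `[x, y]`, the [graphics::persp()]
#'   convention).
#' @export
surface_grid <- function(surface, upsample = 25L) {
  stopifnot(inherits(surface, "pmc_surface"), upsample >= 1L)
  z0 <- unclass(surface)
  fine <- seq(1, 3, length.out = 2L * upsample + 1L)
  # interpolate each row along x (the column coordinate), then each
  # fine x-column along y (the row coordinate)
  zx <- t(vapply(1:3, function(i) {
    stats::splinefun(1:3, z0[i, ], method = "natural")(fine)
  }, numeric(length(fine))))          # [row i, fine x]
  z <- vapply(seq_along(fine), function(a) {
    stats::splinefun(1:3, zx[, a], method = "natural")(fine)
  }, numeric(length(fine)))           # [fine y, fine x]
  z <- pmin(pmax(t(z), 0), 1)         # -> [x, y]
  list(x = fine, y = fine, z = z)
}

#' @rdname pmc_surface
#' @export
print.pmc_surface <- function(x, ...) {
  pid <- attr(x, "policy_id")
  cat(sprintf("PMC surface%s (full-precision PMC = %.4g)\n",
              if (!is.null(pid)) paste0(" of ", pid) else "",
              sum(x)))
  m <- unclass(x)
  attr(m, "policy_id") <- NULL
  dimnames(m) <- list(c("X1-X3", "X4-X6", "X7-X9"), NULL)
  print(m)
  invisible(x)
}

#' Render a PMC surface
#'
#' Draws the surface in 3-D perspective with heights mapped
#' monotonically to colour depth; `smooth = TRUE` (default) upsamples
#' by the clamped tensor spline of [surface_grid()], which reproduces
#' the nine anchor heights exactly, and the anchors are annotated with
#' their values. `render_surface()` writes the plot to a PNG or SVG
#' file chosen by extension.
#'
#' @param x,surface a `pmc_surface`.
#' @param smooth interpolate between anchors?
#' @param upsample subdivisions per cell edge when smoothing.
#' @param theta,phi viewing angles passed to [graphics::persp()].
#' @param annotate label the nine anchors with their values?
#' @param path output file ending in `.png` or `.svg`.
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @param ... further arguments to [graphics::persp()].
#' @return The persp transformation matrix, invisibly;
#'   `render_surface()` returns `path` invisibly.
#' @export
plot.pmc_surface <- function(x, smooth = TRUE, upsample = 25L,
                             theta = -35, phi = 25, annotate = TRUE, ...) {
  g <- if (smooth) surface_grid(x, upsample) else
    list(x = 1:3, y = 1:3, z = t(unclass(x)))
  # facet colours from mean height, monotone in [0,1]
  nz <- nrow(g$z); mz <- ncol(g$z)
  zf <- (g$z[-1, -1] + g$z[-1, -mz] + g$z[-nz, -1] + g$z[-nz, -mz]) / 4
  pal <- grDevices::hcl.colors(100, "YlGnBu", rev = TRUE)
  col <- pal[pmin(100L, pmax(1L, ceiling(zf * 100)))]
  pid <- attr(x, "policy_id")
  tm <- graphics::persp(g$x, g$y, g$z, zlim = c(0, 1), col = col,
                        theta = theta, phi = phi, expand = 0.7,
                        xlab = "X", ylab = "Y", zlab = "first-level value",
                        ticktype = "detailed", border = NA, shade = NA,
                        main = if (!is.null(pid))
                          sprintf("PMC surface: %s", pid) else "PMC surface",
                        ...)
  if (annotate) {
    z0 <- unclass(x)
    for (i in 1:3) for (j in 1:3) {
      pt <- grDevices::trans3d(j, i, z0[i, j], tm)
      graphics::points(pt, pch = 19, cex = 0.6)
      graphics::text(pt, labels = format(z0[i, j], digits = 3), pos = 3,
                     cex = 0.7)
    }
  }
  invisible(tm)
}

#' @rdname plot.pmc_surface
#' @export
render_surface <- function(surface, path, smooth = TRUE, upsample = 25L,
                           width = NULL, height = NULL, ...) {
  stopifnot(inherits(surface, "pmc_surface"))
  ext <- tolower(tools::file_ext(path))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  }
  switch(ext,
         png = grDevices::png(path, width = width %||% 800,
                              height = height %||% 640),
         svg = grDevices::svg(path, width = width %||% 8,
                              height = height %||% 6.4),
         stop("output must end in .png or .svg", call. = FALSE))
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(surface, smooth = smooth, upsample = upsample, ...)
  invisible(path)
}
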