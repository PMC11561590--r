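#' Structured grid over the solution + skin geometry
#'
#' Cell-centred rectangular grid on a domain of `extent[1] x extent[2]`
#' metres centred at the origin, with an optional skin rectangle (also
#' centred) embedded in the surrounding solution.  A cell belongs to the skin
#' iff its centre lies inside the rectangle, half-open on the max edges.
#' Defaults reproduce the cryovial cross-section: 20 mm x 20 mm solution
#' square with a 10 mm x 2 mm skin sample.
#'
#' @param nx,ny cell counts per axis (>= 8)
#' @param extent domain size in metres, `c(Lx, Ly)`
#' @param skin skin rectangle size in metres `c(sx, sy)`, or `NULL` for a
#'   homogeneous all-solution domain
#' @param thickness out-of-plane system thickness d_Z in metres
#' @return object of class `cryo_grid`: cell centres `x`, `y`, spacings
#'   `dx`, `dy`, logical `skin_mask` (length `nx*ny`, column-major with x
#'   fastest), cell volume `vol`, and the input geometry
#' @export
build_grid <- function(nx = 100, ny = 100, extent = c(0.020, 0.020),
                       skin = c(0.010, 0.002), thickness = 1) {
  stopifnot(nx >= 8, ny >= 8, all(extent > 0), thickness > 0)
  if (!is.null(skin)) {
    stopifnot(length(skin) == 2, all(skin > 0))
    if (skin[1] > extent[1] || skin[2] > extent[2])
      stop("skin rectangle larger than the domain")
  }
  dx <- extent[1] / nx
  dy <- extent[2] / ny
  xc <- -extent[1] / 2 + (seq_len(nx) - 0.5) * dx
  yc <- -extent[2] / 2 + (seq_len(ny) - 0.5) * dy
  X <- rep(xc, times = ny)
  Y <- rep(yc, each = nx)
  if (is.null(skin)) {
    mask <- rep(FALSE, nx * ny)
  } else {
    mask <- (X >= -skin[1] / 2) & (X < skin[1] / 2) &
            (Y >= -skin[2] / 2) & (Y < skin[2] / 2)
  }
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 x = xc, y = yc, xc_all = X, yc_all = Y,
                 extent = extent, skin = skin, thickness = thickness,
                 skin_mask = mask, n = nx * ny,
                 vol = dx * dy * thickness),
            class = "cryo_grid")
}

#' @export
print.cryo_grid <- function(x, ...) {
  cat(sprintf("<cryo_grid> %d x %d cells over %.3g x %.3g m (%d skin cells)\n",
              x$nx, x$ny, x$extent[1], x$extent[2], sum(x$skin_mask)))
  invisible(x)
}

# cell index of the cell containing point (px, py); x fastest
cell_at <- function(grid, px, py) {
  i <- pmin(pmax(ceiling((px + grid$extent[1] / 2) / grid$dx), 1), grid$nx)
  j <- pmin(pmax(ceiling((py + grid$extent[2] / 2) / grid$dy), 1), grid$ny)
  as.integer((j - 1) * grid$nx + i)
}
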