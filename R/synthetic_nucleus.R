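#' Specify a simulated nucleus
#'
#' The simulated nucleus is a hard voxelized sphere: DAPI fills it, lamin
#' forms a one-voxel shell on its surface, and the FISH channel is a
#' filled sphere of radius `signal_extent * radius` whose centre sits at
#' normalized boundary distance `signal_center` (0 = on the boundary,
#' 1 = at the centroid).  `signal_mode = "peripheral"` pins the centre to
#' the boundary, `"interior"` to 0.5 (halfway between periphery and
#' centre); `"custom"` uses `signal_center` as given.
#'
#' @param radius nuclear radius in voxels (>= 8).
#' @param voxel_size physical voxel edge, micrometres.
#' @param signal_mode one of `"peripheral"`, `"interior"`, `"custom"`.
#' @param signal_center normalized boundary distance of the signal centre
#'   in `[0, 1]`; required for `"custom"`, ignored otherwise.
#' @param signal_extent signal-sphere radius as a fraction of the nuclear
#'   radius, in `(0, 1]`; default 0.30.
#' @param noise_sd SD of additive Gaussian intensity noise (intensity
#'   units; foreground/background contrast is 180).
#' @param direction unit 3-vector from the centroid towards the signal
#'   centre; `NULL` = +x axis, `NA` = random direction.
#' @param pad voxels of background padding around the nucleus.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return an object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(radius = 25, voxel_size = 0.1,
                         signal_mode = c("peripheral", "interior", "custom"),
                         signal_center = NULL, signal_extent = 0.30,
                         noise_sd = 10, direction = NULL, pad = 3,
                         seed = NULL) {
  signal_mode <- match.arg(signal_mode)
  if (radius < 8) stop("radius must be at least 8 voxels")
  if (signal_mode == "peripheral") signal_center <- 0
  if (signal_mode == "interior") signal_center <- 0.5
  if (is.null(signal_center)) stop("signal_center required for custom mode")
  if (signal_center < 0 || signal_center > 1)
    stop("signal_center must be in [0, 1]")
  if (signal_extent <= 0 || signal_extent > 1)
    stop("signal_extent must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(radius = radius, voxel_size = voxel_size,
                 signal_mode = signal_mode, signal_center = signal_center,
                 signal_extent = signal_extent, noise_sd = noise_sd,
                 direction = direction, pad = pad, seed = seed),
            class = "nucleus_spec")
}

#' Generate a three-channel voxel stack for one simulated nucleus
#'
#' Channels are 3D arrays of equal shape with background intensity 20 and
#' foreground 200 plus Gaussian noise (clipped at 0 so intensities stay
#' non-negative).  Voxels belong to the nucleus when their centre lies
#' within `radius` of the grid centre; the lamin shell is the set of
#' inside voxels with a 6-neighbour outside.
#'
#' @param spec a [nucleus_spec()].
#' @return a `nucleus_stack`: list with arrays `dapi`, `lamin`, `fish`,
#'   plus `voxel_size` and the originating `spec`.
#' @examples
#' stk <- generate_nucleus_stack(nucleus_spec(radius = 10, noise_sd = 0))
#' dim(stk$dapi)
#' @export
generate_nucleus_stack <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  R <- spec$radius
  n <- as.integer(2 * ceiling(R + spec$pad) + 1)
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr)
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)  # squared distance to centre
  inside <- d2 <= R^2
  dim(inside) <- c(n, n, n)
  shell <- inside & !erode6(inside)

  dirv <- spec$direction
  if (is.null(dirv)) dirv <- c(1, 0, 0)
  if (length(dirv) == 1 && is.na(dirv)) {
    v <- rnorm(3)
    dirv <- v / sqrt(sum(v^2))
  }
  dirv <- dirv / sqrt(sum(dirv^2))
  fc <- c(ctr, ctr, ctr) + (1 - spec$signal_center) * R * dirv
  a <- spec$signal_extent * R
  fx <- (seq_len(n) - fc[1]); fy <- (seq_len(n) - fc[2]); fz <- (seq_len(n) - fc[3])
  fd2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  signal <- fd2 <= a^2
  dim(signal) <- c(n, n, n)
  if (!any(signal & inside))
    stop("signal sphere lies entirely outside the nucleus")

  bg <- 20; fg <- 200
  mk <- function(mask) {
    x <- array(bg, dim = c(n, n, n))
    x[mask] <- fg
    if (spec$noise_sd > 0) x <- x + rnorm(length(x), 0, spec$noise_sd)
    pmax(x, 0)
  }
  structure(list(dapi = mk(inside), lamin = mk(shell), fish = mk(signal),
                 voxel_size = spec$voxel_size, spec = spec),
            class = "nucleus_stack")
}

#' @export
print.nucleus_stack <- function(x, ...) {
  cat("<nucleus_stack> ", paste(dim(x$dapi), collapse = " x "),
      " voxels, voxel size ", x$voxel_size, " um, signal mode ",
      x$spec$signal_mode, "\n", sep = "")
  invisible(x)
}

# 6-neighbour erosion: TRUE where the voxel and all 6 neighbours are TRUE
# (voxels on the array border are never fully surrounded).
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift_and <- function(m, axis, by) {
    s <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1L) { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    else          { idx_dst[[axis]] <- 2:n;       idx_src[[axis]] <- 1:(n - 1) }
    s <- do.call(`[<-`, c(list(s), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
    s
  }
  for (axis in 1:3) {
    out <- out & shift_and(mask, axis, 1L)
    out <- out & shift_and(mask, axis, -1L)
  }
  out
}

# Surface voxels of a mask: inside but not in the 6-erosion.
surface_voxels <- function(mask) mask & !erode6(mask)
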