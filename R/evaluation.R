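## Comparison metrics and the permeability-scale optimiser.

#' Min-max-normalised root-mean-square error between two fields
#'
#' Both fields are transformed by `t(x) = (x - min(p_bar)) /
#' (max(p_bar) - min(p_bar))` -- the normalisation is fitted to the
#' reference field only and applied to both -- and the rms of the
#' differences is returned. This removes the dependence on the absolute
#' pressure boundary values.
#'
#' @param p_bar reference field values (the averaged discrete pressure).
#' @param f comparison field values at the same points.
#' @return dimensionless rms error.
#' @export
rms_error <- function(p_bar, f) {
  if (length(p_bar) != length(f)) stop("fields must share their points")
  if (length(p_bar) < 2L) stop("need at least two comparison points")
  rng <- range(p_bar)
  if (diff(rng) == 0) stop("reference field is constant: normalisation undefined")
  a <- (p_bar - rng[1]) / diff(rng)
  b <- (f - rng[1]) / diff(rng)
  sqrt(mean((a - b)^2))
}

#' Unsmoothness metric of a grid field
#'
#' Sum of the absolute responses of the 5-point discrete Laplacian kernel
#' applied slice-wise over the three axis-aligned slice families of the
#' grid (interior nodes of each slice). Lower values mean smoother fields;
#' a constant or axis-linear field scores 0.
#'
#' @param field nodal values on the grid (mesh ordering) or a 3-d array.
#' @param dims nodes per axis (ignored when `field` is an array).
#' @return dimensionless unsmoothness value.
#' @export
smoothness_psi <- function(field, dims = NULL) {
  a <- if (is.array(field) && length(dim(field)) == 3L) field
  else {
    if (is.null(dims)) stop("supply dims for a flat field vector")
    array(field, dim = dims)
  }
  d <- dim(a)
  lap2 <- function(arr, ax1, ax2) {
    idx <- function(axis, shift) {
      out <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      out[[ax1]] <- 2:(d[ax1] - 1L); out[[ax2]] <- 2:(d[ax2] - 1L)
      if (!is.null(axis)) out[[axis]] <- out[[axis]] + shift
      out
    }
    sub <- function(ix) a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    centre <- sub(idx(NULL, 0))
    resp <- sub(idx(ax1, -1L)) + sub(idx(ax1, 1L)) +
      sub(idx(ax2, -1L)) + sub(idx(ax2, 1L)) - 4 * centre
    sum(abs(resp))
  }
  lap2(a, 1, 2) + lap2(a, 1, 3) + lap2(a, 2, 3)
}

#' Optimal permeability scale
#'
#' Finds the scalar multiplier of the permeability field that minimises the
#' normalised rms error between the Darcy pressure and the averaged
#' discrete pressure. The profile is scanned over a deterministic
#' logarithmic grid and polished by golden-section minimisation on log
#' scale; the assembled system is reused across evaluations (only the
#' stiffness block scales).
#'
#' @param problem a `darcy_problem`.
#' @param mesh a `grid_mesh`.
#' @param p_bar reference pressures at the comparison points.
#' @param points optional mesh-node indices at which to compare (default:
#'   all mesh nodes).
#' @param log_range log10 half-width of the scan around scale 1.
#' @param n_scan scan points.
#' @param tol relative tolerance on the scale.
#' @return list with `scale`, `rms`, `profile` (data.frame scale/rms) and
#'   the assembly `cache`.
#' @export
optimise_k_scale <- function(problem, mesh, p_bar, points = NULL,
                             log_range = 4, n_scan = 33L, tol = 1e-3) {
  if (is.null(points)) points <- seq_len(nrow(mesh$points))
  cache <- darcy_assembly(problem, mesh)
  rms_at <- function(ls) {
    sol <- solve_darcy(problem, mesh, scale = 10^ls, cache = cache)
    rms_error(p_bar, sol$p[points])
  }
  grid_ls <- seq(-log_range, log_range, length.out = n_scan)
  prof <- vapply(grid_ls, rms_at, numeric(1))
  i0 <- which.min(prof)
  lo <- grid_ls[max(1L, i0 - 1L)]
  hi <- grid_ls[min(n_scan, i0 + 1L)]
  opt <- stats::optimize(rms_at, c(lo, hi), tol = tol / log(10))
  best_ls <- if (opt$objective <= prof[i0]) opt$minimum else grid_ls[i0]
  best_rms <- min(opt$objective, prof[i0])
  list(scale = 10^best_ls, rms = best_rms,
       profile = data.frame(scale = 10^grid_ls, rms = prof),
       cache = cache)
}
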