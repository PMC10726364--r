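## 2D rho-lambda occupancy surfaces: raw per-bin counts over every
## (rho, lambda) combination of every molecule and frame, plus a
## sampled/unsampled mask and a quantitative overlap score between surfaces.

#' Build a rho-lambda occupancy surface
#'
#' Histograms every (rho, lambda) point of a descriptor table on an
#' n_bins x n_bins grid (default 60 bins per axis). Lambda is binned on
#' [0, 360) to match the wrap convention; rho on a configurable range
#' (default [0, 2], covering the sampling observed in aqueous runs, rho up
#' to ~1.8). Points outside the rho range are tallied separately, never
#' dropped silently. Raw occupancy counts are kept: no density smoothing
#' and no free-energy transform.
#'
#' @param series a `descriptor_table` from [compute_series()], or any
#'   data.frame with `rho` and `lam` columns.
#' @param n_bins bins per axis (default 60).
#' @param rho_range numeric length-2, rho axis limits (default c(0, 2)).
#' @return a `rho_lambda_surface`: list with `counts` (n_bins x n_bins
#'   integer matrix, rho rows x lambda columns), `rho_edges`, `lam_edges`,
#'   `mask` (counts > 0), `total` (in-range points), `out_of_range`,
#'   `n_points` (total input points).
#' @export
build_surface <- function(series, n_bins = 60, rho_range = c(0, 2)) {
  stopifnot(is.data.frame(series), all(c("rho", "lam") %in% names(series)))
  if (!nrow(series)) stop("insufficient data: empty descriptor table")
  stopifnot(n_bins >= 1L, length(rho_range) == 2L, rho_range[1] < rho_range[2])
  rho <- series$rho
  lam <- wrap_360(series$lam)
  rho_edges <- seq(rho_range[1], rho_range[2], length.out = n_bins + 1L)
  lam_edges <- seq(0, 360, length.out = n_bins + 1L)
  inr <- rho >= rho_range[1] & rho <= rho_range[2]
  # right-open bins, last bin closed on the rho axis; lambda < 360 always
  ri <- findInterval(rho[inr], rho_edges, rightmost.closed = TRUE)
  li <- findInterval(lam[inr], lam_edges)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ri, levels = seq_len(n_bins)),
               factor(li, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts,
                 rho_edges = rho_edges, lam_edges = lam_edges,
                 n_bins = n_bins,
                 mask = counts > 0L,
                 total = sum(counts),
                 out_of_range = sum(!inr),
                 n_points = length(rho)),
            class = "rho_lambda_surface")
}

#' @export
print.rho_lambda_surface <- function(x, ...) {
  cat("<rho-lambda surface> ", x$n_bins, "x", x$n_bins, " bins, ",
      x$total, " points in range (", x$out_of_range, " out of range), ",
      sum(x$mask), " bins sampled\n", sep = "")
  invisible(x)
}

#' Overlap between two occupancy surfaces
#'
#' Histogram intersection of the count-normalised surfaces,
#' \deqn{O(a, b) = \sum_b \min(\hat a_b, \hat b_b) \in [0, 1],}
#' where hats denote counts divided by their in-range total. 1 means
#' identical normalised occupancy; 0 means disjoint sampled regions. The
#' score is symmetric and invariant to scaling either surface's counts by a
#' common positive factor, and quantifies statements like "two amide states
#' are dynamically similar".
#'
#' @param a,b `rho_lambda_surface` objects with identical binning.
#' @return overlap score in [0, 1].
#' @export
surface_overlap <- function(a, b) {
  stopifnot(inherits(a, "rho_lambda_surface"), inherits(b, "rho_lambda_surface"))
  if (!identical(dim(a$counts), dim(b$counts)) ||
      !isTRUE(all.equal(a$rho_edges, b$rho_edges)) ||
      !isTRUE(all.equal(a$lam_edges, b$lam_edges))) {
    stop("surfaces have mismatched binning; rebuild with identical n_bins and rho_range")
  }
  if (a$total == 0L || b$total == 0L) stop("insufficient data: empty surface")
  sum(pmin(a$counts / a$total, b$counts / b$total))
}

#' Export a surface as a TSV of bin centres and counts
#'
#' One row per bin: rho_center, lam_center, count, sampled. A display
#' column `lam_center_display` gives the (-180, 180] remapping used by
#' published-style plots.
#'
#' @param surface a `rho_lambda_surface`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  stopifnot(inherits(surface, "rho_lambda_surface"))
  rc <- (surface$rho_edges[-1] + surface$rho_edges[-length(surface$rho_edges)]) / 2
  lc <- (surface$lam_edges[-1] + surface$lam_edges[-length(surface$lam_edges)]) / 2
  df <- data.frame(
    rho_center = rep(rc, times = surface$n_bins),
    lam_center = rep(lc, each = surface$n_bins),
    lam_center_display = rep(lambda_display(lc), each = surface$n_bins),
    count = as.integer(surface$counts),
    sampled = as.logical(surface$mask)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a rho-lambda occupancy surface
#'
#' Thin base-graphics rendering of the raw counts; unsampled bins are shown
#' in a flat background colour so sampled and unsampled regions are
#' distinguishable.
#'
#' @param x a `rho_lambda_surface`.
#' @param display_lambda remap the lambda axis to (-180, 180] for display.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.rho_lambda_surface <- function(x, display_lambda = FALSE, ...) {
  z <- x$counts
  lam_edges <- x$lam_edges
  if (display_lambda) {
    # rotate columns so the axis runs (-180, 180]
    half <- x$n_bins %/% 2
    z <- z[, c((half + 1L):x$n_bins, seq_len(half)), drop = FALSE]
    lam_edges <- lam_edges - 180
  }
  z[z == 0L] <- NA  # background = unsampled
  graphics::image(x = x$rho_edges[-1], y = lam_edges[-1], z = z,
                  xlab = expression(rho), ylab = expression(lambda ~ "(deg)"),
                  col = grDevices::hcl.colors(64, "viridis"),
                  ...)
  invisible(x)
}
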