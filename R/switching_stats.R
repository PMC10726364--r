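## Delta-lambda switching statistics: per-molecule switch counts, the
## population mean x_bar, bootstrap uncertainty, and the cross-amide-state
## homogeneity parameter eta.

#' Frame-to-frame change in lambda
#'
#' Compares the inter-ring torsion between each frame i and the next frame
#' i + 1. Two conventions are offered:
#' \describe{
#'   \item{literal}{`|lam[i+1] - lam[i]|` on the wrapped [0, 360) values.
#'     This follows the stated switching procedure verbatim, but counts a
#'     spurious switch when the torsion drifts across the 0/360 boundary.}
#'   \item{circular}{`min(d, 360 - d)`, the shortest angular distance;
#'     boundary-safe.}
#' }
#' The default is "literal"; every summary records which convention was
#' used.
#'
#' @param lam numeric vector of per-frame lambda values in degrees, length
#'   >= 2 (values are wrapped to [0, 360) first).
#' @param convention "literal" or "circular".
#' @return numeric vector of length `length(lam) - 1`, non-negative degrees.
#' @export
#' @examples
#' delta_lambda(c(10, 40, 45, 70))          # 30, 5, 25
#' delta_lambda(c(355, 5))                  # literal: 350
#' delta_lambda(c(355, 5), "circular")      # 10
delta_lambda <- function(lam, convention = c("literal", "circular")) {
  convention <- match.arg(convention)
  if (length(lam) < 2L) {
    stop("insufficient data: need at least 2 frames to form delta-lambda")
  }
  d <- abs(diff(wrap_360(lam)))
  if (convention == "circular") d <- pmin(d, 360 - d)
  d
}

#' Count switching events in a delta-lambda series
#'
#' A switch in intramolecular aromatic ring organisation is a step whose
#' delta-lambda is at least the threshold (inclusive; default 20 degrees).
#'
#' @param dlam numeric vector of per-step delta-lambda values (degrees).
#' @param threshold switching threshold in degrees, > 0.
#' @return integer switch count.
#' @export
count_switches <- function(dlam, threshold = 20) {
  stopifnot(threshold > 0)
  sum(dlam >= threshold)
}

#' Population switching summary
#'
#' Counts switches for each molecule's lambda series and averages across
#' the population:
#' \deqn{\bar{x}_\lambda = \frac{1}{M} \sum_{m=1}^{M} n_{switch}(m).}
#'
#' @param lam_series lambda series per molecule: a matrix (frames x
#'   molecules, as from [lambda_matrix()]) or a list of numeric vectors.
#' @param threshold switching threshold in degrees (default 20).
#' @param convention delta-lambda convention, see [delta_lambda()].
#' @param label optional [amide_state_label()] carried into the summary.
#' @return a `switch_summary`: list with `per_molecule_switches`, `x_bar`,
#'   `n_frames`, `threshold`, `convention`, `label`.
#' @export
mean_switches <- function(lam_series, threshold = 20,
                          convention = c("literal", "circular"),
                          label = NULL) {
  convention <- match.arg(convention)
  if (is.matrix(lam_series)) {
    lam_series <- lapply(seq_len(ncol(lam_series)),
                         function(j) lam_series[, j])
  }
  if (!length(lam_series)) stop("insufficient data: empty ensemble")
  counts <- vapply(lam_series, function(lam) {
    count_switches(delta_lambda(lam, convention), threshold)
  }, integer(1))
  structure(list(per_molecule_switches = counts,
                 x_bar = mean(counts),
                 n_frames = length(lam_series[[1]]),
                 threshold = threshold,
                 convention = convention,
                 label = label),
            class = "switch_summary")
}

#' @export
print.switch_summary <- function(x, ...) {
  cat("<switch summary>")
  if (!is.null(x$label)) cat(" state", unclass(x$label))
  cat(": x_bar =", format(x$x_bar), "over", length(x$per_molecule_switches),
      "molecules (threshold", x$threshold, "deg,", x$convention,
      "convention)\n")
  invisible(x)
}

#' Bootstrap the population mean switch count
#'
#' Resamples with replacement and records the mean, giving an uncertainty
#' for x_bar. The default resampling unit is the per-molecule switch count
#' (x_bar is defined as a mean over molecules); `unit = "steps"` instead
#' resamples frame-level delta-lambda values and recounts, for series-level
#' uncertainty.
#'
#' @param x per-molecule switch counts (numeric vector, `unit = "molecules"`)
#'   or a list of per-step delta-lambda vectors (`unit = "steps"`).
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed RNG seed; recorded in the result for reproducibility.
#' @param unit resampling unit.
#' @param threshold switching threshold, used only for `unit = "steps"`.
#' @return a `bootstrap_result`: list with `resampled_x_bars`, `mean`, `sd`,
#'   `n_resamples`, `seed`, `unit`.
#' @export
bootstrap_x_bar <- function(x, n_resamples = 1000, seed = 1,
                            unit = c("molecules", "steps"), threshold = 20) {
  unit <- match.arg(unit)
  if (unit == "molecules") {
    counts <- as.numeric(x)
    if (length(counts) < 2L) {
      stop("insufficient data: need at least 2 molecules to bootstrap")
    }
    res <- with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        mean(counts[sample.int(length(counts), replace = TRUE)])
      }, numeric(1))
    })
  } else {
    stopifnot(is.list(x))
    if (length(x) < 2L) {
      stop("insufficient data: need at least 2 molecules to bootstrap")
    }
    res <- with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        mean(vapply(x, function(d) {
          count_switches(d[sample.int(length(d), replace = TRUE)], threshold)
        }, integer(1)))
      }, numeric(1))
    })
  }
  structure(list(resampled_x_bars = res,
                 mean = mean(res), sd = stats::sd(res),
                 n_resamples = n_resamples, seed = seed, unit = unit),
            class = "bootstrap_result")
}

#' Homogeneity of lambda exploration across amide states
#'
#' Eta is the ratio of the largest to the smallest population mean switch
#' count across a sequence's amide states,
#' \deqn{\eta = \bar{x}_{\lambda max} / \bar{x}_{\lambda min}.}
#' Eta of about 1 indicates that side-chain torsional exploration is
#' independent of the backbone amide configuration (homogeneous); eta well
#' above 1 indicates backbone-dependent (inhomogeneous) exploration. A zero
#' minimum yields +Inf with a warning rather than an error: degenerate but
#' representable.
#'
#' @param x_bar_by_state named numeric vector or list mapping amide-state
#'   short forms (e.g. "cc") to x_bar values; at least 2 states.
#' @return a `homogeneity_report`: list with `x_bar_by_state`, `x_bar_max`,
#'   `x_bar_min`, `state_max`, `state_min`, `eta`.
#' @export
compute_eta <- function(x_bar_by_state) {
  x <- unlist(x_bar_by_state)
  if (length(x) < 2L) {
    stop("insufficient data: eta requires at least 2 amide states")
  }
  if (any(x < 0)) stop("negative mean switch counts are impossible")
  i_max <- which.max(x); i_min <- which.min(x)
  eta <- if (x[i_min] == 0) {
    warning("x_bar_min = 0: eta is infinite")
    Inf
  } else {
    unname(x[i_max] / x[i_min])
  }
  structure(list(x_bar_by_state = x,
                 x_bar_max = unname(x[i_max]), x_bar_min = unname(x[i_min]),
                 state_max = names(x)[i_max], state_min = names(x)[i_min],
                 eta = eta),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat("<homogeneity report> eta =", format(x$eta), "\n")
  print(x$x_bar_by_state)
  invisible(x)
}

#' Bootstrap confidence interval for eta
#'
#' Resamples molecules with replacement independently within each amide
#' state, recomputes each state's x_bar and the resulting eta, and returns
#' percentile intervals of the bootstrap eta distribution.
#'
#' @param counts_by_state named list: amide state -> per-molecule switch
#'   counts.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.99).
#' @return list with `eta` (point estimate), `etas` (bootstrap draws),
#'   `lower`, `upper`, `level`, `seed`.
#' @export
bootstrap_eta <- function(counts_by_state, n_resamples = 1000, seed = 1,
                          level = 0.99) {
  stopifnot(is.list(counts_by_state), length(counts_by_state) >= 2L)
  point <- compute_eta(lapply(counts_by_state, mean))$eta
  etas <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      xb <- vapply(counts_by_state, function(cts) {
        mean(cts[sample.int(length(cts), replace = TRUE)])
      }, numeric(1))
      if (min(xb) == 0) Inf else max(xb) / min(xb)
    }, numeric(1))
  })
  qs <- stats::quantile(etas, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(eta = point, etas = etas, lower = qs[1], upper = qs[2],
       level = level, seed = seed)
}

#' Evaluate a localised RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
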