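## Per-frame geometric descriptors of intramolecular aromatic ring
## organisation: the ipso/para distance ratio rho and the inter-ring
## torsion lambda.

#' Ipso/para distance-ratio descriptor (rho)
#'
#' For two consecutive phenyl side chains, rho is the ratio of the
#' ipso-ipso to the para-para carbon distance,
#' \deqn{\rho = r_{ipso} / r_{para}.}
#' A value of 1.0 corresponds to exact face-to-face alignment of the two
#' rings; rho > 1 means the para carbons are closer than the ipso carbons
#' (burial of the ring "tips").
#'
#' The ratio orientation (ipso over para) is fixed so that rho > 1 implies
#' r_para < r_ipso.
#'
#' @param p_ipso1,p_ipso2 positions of the ipso carbons of ring 1 and ring 2
#'   (length-3 vectors or n x 3 matrices, Angstrom).
#' @param p_para1,p_para2 positions of the para carbons.
#' @return numeric vector of rho values (dimensionless, > 0).
#' @seealso [compute_lambda()], [compute_series()]
#' @export
#' @examples
#' # identical parallel rings stacked 3.5 A apart -> exactly 1
#' ring <- benzene_ring_template()
#' compute_rho(ring["CG", ], ring["CG", ] + c(0, 0, 3.5),
#'             ring["CZ", ], ring["CZ", ] + c(0, 0, 3.5))
compute_rho <- function(p_ipso1, p_ipso2, p_para1, p_para2) {
  r_ipso <- rownorm3(as_mat3(p_ipso1) - as_mat3(p_ipso2))
  r_para <- rownorm3(as_mat3(p_para1) - as_mat3(p_para2))
  if (any(r_para < 1e-10)) {
    stop("degenerate geometry: coincident para carbons (r_para = 0)")
  }
  r_ipso / r_para
}

#' Inter-ring torsion descriptor (lambda)
#'
#' The dihedral angle defined by the para1-ipso1-ipso2-para2 carbons of two
#' consecutive phenyl rings, computed with the standard IUPAC sign
#' convention and wrapped to [0, 360) by adding 360 degrees to any negative
#' value. Lambda = 180 (equivalently -180 before wrapping) corresponds to
#' coplanar rings in the anti arrangement; lambda = 0 to the syn (eclipsed)
#' arrangement.
#'
#' @param p_para1,p_ipso1,p_ipso2,p_para2 positions (length-3 vectors or
#'   n x 3 matrices, Angstrom), in torsion order.
#' @return numeric vector of angles in degrees in [0, 360).
#' @export
compute_lambda <- function(p_para1, p_ipso1, p_ipso2, p_para2) {
  wrap_360(torsion_signed(p_para1, p_ipso1, p_ipso2, p_para2))
}

#' Compute per-molecule descriptor series for a trajectory ensemble
#'
#' Evaluates rho and lambda for every molecule in every frame. Ring 1 is
#' always the ring nearer the N-terminus, which together with the wrap
#' convention makes lambda reproducible (swapping ring roles maps lambda to
#' (360 - lambda) mod 360 and leaves rho unchanged).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @return a `descriptor_table`: a data.frame with columns `molecule_id`,
#'   `frame`, `rho`, `lam`, `r_ipso`, `r_para`, one row per molecule per
#'   frame, ordered by molecule then frame.
#' @export
compute_series <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  nf <- ensemble$n_frames
  out <- vector("list", ensemble$n_molecules)
  for (m in seq_len(ensemble$n_molecules)) {
    sel <- ensemble$selections[[m]]
    # nf x 3 coordinate slices for the four defining carbons
    pi1 <- ensemble$coords[, sel$ring1_ipso, , drop = FALSE]; dim(pi1) <- c(nf, 3)
    pp1 <- ensemble$coords[, sel$ring1_para, , drop = FALSE]; dim(pp1) <- c(nf, 3)
    pi2 <- ensemble$coords[, sel$ring2_ipso, , drop = FALSE]; dim(pi2) <- c(nf, 3)
    pp2 <- ensemble$coords[, sel$ring2_para, , drop = FALSE]; dim(pp2) <- c(nf, 3)
    r_ipso <- rownorm3(pi1 - pi2)
    r_para <- rownorm3(pp1 - pp2)
    if (any(r_para < 1e-10)) {
      stop("degenerate geometry for molecule ", sel$molecule_id,
           " frame ", which(r_para < 1e-10)[1L], ": r_para = 0")
    }
    lam <- tryCatch(
      compute_lambda(pp1, pi1, pi2, pp2),
      error = function(e) stop("molecule ", sel$molecule_id, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    out[[m]] <- data.frame(
      molecule_id = sel$molecule_id,
      frame = seq_len(nf),
      rho = r_ipso / r_para,
      lam = lam,
      r_ipso = r_ipso,
      r_para = r_para,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("descriptor_table", "data.frame")
  res
}

#' Per-molecule lambda series as a matrix
#'
#' @param series a `descriptor_table` from [compute_series()].
#' @return an n_frames x n_molecules matrix of lambda values in degrees,
#'   columns named by molecule id.
#' @export
lambda_matrix <- function(series) {
  stopifnot(is.data.frame(series), all(c("molecule_id", "frame", "lam") %in% names(series)))
  ids <- unique(series$molecule_id)
  sapply(ids, function(id) series$lam[series$molecule_id == id],
         simplify = "array") -> m
  m <- matrix(m, ncol = length(ids), dimnames = list(NULL, as.character(ids)))
  m
}

#' Export a descriptor table as TSV
#'
#' Columns: molecule_id, frame, rho, lam, r_ipso, r_para.
#'
#' @param series a `descriptor_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
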