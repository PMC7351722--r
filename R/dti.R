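#' Scalar diffusion tensor metrics from eigenvalues
#'
#' Standard tensor-derived scalars from an ordered eigenvalue triple:
#' mean diffusivity MD = (l1+l2+l3)/3, axial diffusivity AD = l1, radial
#' diffusivity RD = (l2+l3)/2, and fractional anisotropy
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||.
#'
#' @param l1,l2,l3 Tensor eigenvalues with l1 >= l2 >= l3 >= 0 (vectors
#'   allowed, recycled elementwise).
#' @return Data frame with columns FA, MD, RD, AD and a logical
#'   \code{degenerate} flag (TRUE where all three eigenvalues are zero, in
#'   which case FA is defined as 0).
#' @examples
#' dti_scalar_metrics(1e-3, 1e-3, 1e-3)$FA  # 0 (isotropic)
#' dti_scalar_metrics(1e-3, 0, 0)$FA        # 1 (stick)
#' @export
dti_scalar_metrics <- function(l1, l2, l3) {
  n <- max(length(l1), length(l2), length(l3))
  l1 <- rep_len(l1, n); l2 <- rep_len(l2, n); l3 <- rep_len(l3, n)
  if (any(l1 < l2 - 1e-15 | l2 < l3 - 1e-15 | l3 < -1e-15))
    stop("eigenvalues must satisfy l1 >= l2 >= l3 >= 0")
  md <- (l1 + l2 + l3) / 3
  norm2 <- l1^2 + l2^2 + l3^2
  dev2 <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  degenerate <- norm2 == 0
  fa <- ifelse(degenerate, 0, sqrt(1.5) * sqrt(dev2) / sqrt(pmax(norm2, .Machine$double.xmin)))
  fa <- pmin(1, pmax(0, fa))
  data.frame(FA = fa, MD = md, RD = (l2 + l3) / 2, AD = l1,
             degenerate = degenerate)
}
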