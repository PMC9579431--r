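#' Restricted (natural) cubic spline basis
#'
#' Truncated-power restricted cubic basis in Harrell's normalization:
#' column 1 is the identity, and columns 2..(k-1) are
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'       + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' for interior knots \eqn{t_j}. The basis is linear beyond the boundary
#' knots; with 3 knots it spans two degrees of freedom.
#'
#' @param x numeric vector.
#' @param knots knot locations (strictly increasing, length >= 3). If NULL,
#'   placed at the 10th/50th/90th percentiles of `x` (for `n_knots = 3`) or
#'   equally spaced quantiles between 0.05 and 0.95 otherwise.
#' @param n_knots number of knots when `knots` is NULL.
#' @return matrix with `length(knots) - 1` columns and a `knots` attribute.
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 3) {
  stopifnot(is.numeric(x))
  if (is.null(knots)) {
    probs <- if (n_knots == 3) c(0.10, 0.50, 0.90)
             else seq(0.05, 0.95, length.out = n_knots)
    knots <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  }
  knots <- sort(knots)
  if (length(knots) < 3) stop("rcs_basis: need >= 3 distinct knots")
  if (length(unique(x)) < length(knots))
    stop("rcs_basis: fewer distinct values than knots")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cub(x - tj) - cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("lin", paste0("ns", seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}
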