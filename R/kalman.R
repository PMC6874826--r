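# Constant-velocity Kalman filter over the box state
# t = [u, v, s, r, u', v', s']. Center, area and their per-frame derivatives
# are coupled through the state-transition matrix; the aspect ratio r is
# carried as a constant. The process- and measurement-noise covariances are
# fixed diagonal matrices (reproduced verbatim, including the unit variance on
# the constant r component).

#' Kalman filter parameters for box tracking
#'
#' Bundles the fixed filter matrices and the association floor:
#' \itemize{
#'   \item \code{F} 7x7 state transition — identity plus unit coupling of
#'     (u, v, s) to their per-frame derivatives.
#'   \item \code{Q} 7x7 process noise — \code{diag(1, 1, 1, 1, 1e-2, 1e-2, 1e-4)}.
#'   \item \code{H} 4x7 measurement matrix selecting (u, v, s, r).
#'   \item \code{R} 4x4 measurement noise — \code{diag(1, 1, 10, 10)}.
#'   \item \code{P0} initial tracker covariance. The filter literature for this
#'     tracker leaves it open; the default is diagonal with moderate
#'     uncertainty on the four measured components and large uncertainty on
#'     the three unobserved derivatives.
#'   \item \code{min_iou} association floor: a detection/tracker pair with IOU
#'     not exceeding this value is never matched. Default 0.1 (strict
#'     inequality is required to match).
#' }
#'
#' @param p0_diag diagonal of the initial covariance \code{P0} (length 7).
#' @param min_iou association floor in \[0, 1).
#' @return List of class \code{filter_params}.
#' @export
filter_params <- function(p0_diag = c(10, 10, 10, 10, 1e4, 1e4, 1e4),
                          min_iou = 0.1) {
  stopifnot(length(p0_diag) == 7L, all(p0_diag >= 0),
            min_iou >= 0, min_iou < 1)
  F <- diag(7)
  F[1L, 5L] <- F[2L, 6L] <- F[3L, 7L] <- 1
  H <- cbind(diag(4), matrix(0, 4L, 3L))
  structure(list(
    F = F,
    Q = diag(c(1, 1, 1, 1, 1e-2, 1e-2, 1e-4)),
    H = H,
    R = diag(c(1, 1, 10, 10)),
    P0 = diag(p0_diag),
    min_iou = min_iou
  ), class = "filter_params")
}

# enforce exact symmetry after each matrix product
symmetrize <- function(m) (m + t(m)) / 2

#' Kalman prediction (time update)
#'
#' Propagates a tracker state and covariance one frame ahead: the state
#' becomes F t and the covariance F P F^T + Q.
#'
#' @param state length-7 state vector \code{[u, v, s, r, du, dv, ds]}.
#' @param P 7x7 state covariance.
#' @param params [filter_params()].
#' @return List with elements \code{state} and \code{P}.
#' @export
kf_predict <- function(state, P, params = filter_params()) {
  if (length(state) != 7L || any(!is.finite(state)))
    stop("tracker state must be 7 finite values")
  list(
    state = as.numeric(params$F %*% state),
    P = symmetrize(params$F %*% P %*% t(params$F) + params$Q)
  )
}

#' Kalman measurement update
#'
#' Incorporates a measurement \code{z = [u, v, s, r]} into an a-priori
#' state/covariance: innovation covariance S = H P H^T + R, gain
#' K = P H^T S^-1, Joseph-form covariance
#' (I - K H) P (I - K H)^T + K R K^T, innovation y = z - H state, posterior
#' state = state + K y. The Joseph form keeps the posterior covariance
#' symmetric positive semidefinite regardless of rounding.
#'
#' @param state,P a-priori state and covariance from [kf_predict()].
#' @param z measurement vector \code{c(u, v, s, r)} (see [box_to_state()]).
#' @param params [filter_params()].
#' @return List with \code{state}, \code{P} and \code{diagnostics}
#'   (list \code{S}, \code{K}, \code{y}).
#' @export
kf_update <- function(state, P, z, params = filter_params()) {
  if (length(z) != 4L || any(!is.finite(z)))
    stop("measurement must be 4 finite values (u, v, s, r)")
  H <- params$H
  S <- symmetrize(H %*% P %*% t(H) + params$R)
  # R is positive definite, so S is as well; a failure here indicates a
  # corrupted covariance upstream
  K <- P %*% t(H) %*% solve(S)
  IKH <- diag(7) - K %*% H
  P_post <- symmetrize(IKH %*% P %*% t(IKH) + K %*% params$R %*% t(K))
  y <- as.numeric(z - H %*% state)
  list(
    state = as.numeric(state + K %*% y),
    P = P_post,
    diagnostics = list(S = S, K = K, y = y)
  )
}
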