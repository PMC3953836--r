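#' Minimum-volume enclosing ellipsoid (Khachiyan algorithm)
#'
#' Computes the smallest-volume ellipsoid containing a 3-D point set by
#' Khachiyan's barycentric-coordinate ascent. The region is
#' `(p - center)' shape^{-1} (p - center) <= radius^2` with `radius = 1`;
#' `shape` is symmetric positive-definite.
#'
#' @param points n x 3 matrix, n >= 4, affinely independent
#' @param tol convergence tolerance on the duality gap (default 1e-7)
#' @param max_iter iteration cap (default 1e5)
#' @param on_degenerate `"error"` (default) or `"flag"`: what to do when the
#'   points are coplanar/collinear. With `"flag"` a rank-deficient region is
#'   returned with `degenerate = TRUE` and a ridge added to the shape.
#' @return object of class `ellipsoid_region` with fields `center`, `shape`,
#'   `radius`, `degenerate`
#' @export
min_ellipsoid <- function(points, tol = 1e-7, max_iter = 1e5,
                          on_degenerate = c("error", "flag")) {
  on_degenerate <- match.arg(on_degenerate)
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  d <- ncol(P)
  n <- nrow(P)
  if (n < d + 1L) stop("need at least d + 1 points")
  ctr <- colMeans(P)
  rank_ok <- qr(sweep(P, 2, ctr))$rank == d
  if (!rank_ok) {
    if (on_degenerate == "error")
      stop("degenerate input: points are affinely dependent (coplanar)")
    # rank-deficient fallback: covariance-shaped region inflated to cover
    # all points, with a small ridge keeping the quadratic form invertible
    S0 <- crossprod(sweep(P, 2, ctr)) / n
    S0 <- S0 + diag(d) * max(diag(S0), 1e-12) * 1e-8
    q <- rowSums((sweep(P, 2, ctr) %*% solve(S0)) * sweep(P, 2, ctr))
    return(structure(list(center = ctr, shape = S0 * max(q, 1), radius = 1,
                          degenerate = TRUE, tol = tol, iterations = 0L),
                     class = "ellipsoid_region"))
  }

  # Khachiyan ascent with Wolfe-Atwood away steps (linear convergence):
  # maximise log det of the lifted design matrix over barycentric weights u
  Q <- t(cbind(P, 1))                       # (d+1) x n lifted points
  u <- rep(1 / n, n)
  it <- 0L
  repeat {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    jp <- which.max(M)
    err_p <- M[jp] / (d + 1) - 1
    sup <- which(u > 1e-12)
    jm <- sup[which.min(M[sup])]
    err_m <- 1 - M[jm] / (d + 1)
    if (max(err_p, err_m) < tol || it >= max_iter) break
    if (err_p >= err_m) {                   # add step toward the worst point
      lam <- (M[jp] - d - 1) / ((d + 1) * (M[jp] - 1))
      u <- (1 - lam) * u
      u[jp] <- u[jp] + lam
    } else {                                # away step from an over-weighted point
      lam <- if (M[jm] > 1 + 1e-12)
        min((d + 1 - M[jm]) / ((d + 1) * (M[jm] - 1)), u[jm] / (1 - u[jm]))
      else u[jm] / (1 - u[jm])
      u <- (1 + lam) * u
      u[jm] <- u[jm] - lam
    }
    it <- it + 1L
  }
  center <- drop(u %*% P)
  S0 <- t(P) %*% (u * P) - tcrossprod(center)
  shape <- d * (S0 + t(S0)) / 2
  # inflate minimally so every generating point satisfies the membership
  # inequality exactly (the worst point sits on the boundary)
  ctr2 <- sweep(P, 2, center)
  qmax <- max(rowSums((ctr2 %*% solve(shape)) * ctr2))
  if (qmax > 1) shape <- shape * qmax
  structure(list(center = center, shape = shape, radius = 1,
                 degenerate = FALSE, tol = tol, iterations = it),
            class = "ellipsoid_region")
}

#' @export
print.ellipsoid_region <- function(x, ...) {
  cat(sprintf("<ellipsoid_region> center (%s), volume %.6g%s\n",
              paste(sprintf("%.4g", x$center), collapse = ", "),
              ellipsoid_volume(x),
              if (x$degenerate) " (rank-deficient)" else ""))
  invisible(x)
}

#' Ellipsoid volume
#'
#' @param region an `ellipsoid_region`
#' @return scalar volume
#' @export
ellipsoid_volume <- function(region) {
  d <- length(region$center)
  # unit-ball volume in d dims times sqrt(det(shape)) * radius^d
  unit <- pi^(d / 2) / gamma(d / 2 + 1)
  unit * sqrt(max(det(region$shape), 0)) * region$radius^d
}

# Mahalanobis-style quadratic form for rows of pts
ellipsoid_qform <- function(region, pts) {
  pts <- matrix(as.numeric(pts), ncol = length(region$center))
  ctr <- sweep(pts, 2, region$center)
  rowSums((ctr %*% solve(region$shape)) * ctr)
}

#' Ellipsoid membership
#'
#' Boundary points count as inside (within `tol`), matching the convention
#' used by the convergence counter.
#'
#' @param region an `ellipsoid_region`
#' @param p a 3-vector or m x 3 matrix of points
#' @param tol relative boundary tolerance
#' @return logical (vector if `p` is a matrix)
#' @export
contains <- function(region, p, tol = 1e-7) {
  q <- ellipsoid_qform(region, p)
  q <= region$radius^2 * (1 + tol)
}

#' Serialize / deserialize an ellipsoid region as JSON
#'
#' @param region an `ellipsoid_region`
#' @param path output (input) file path
#' @return `ellipsoid_from_json` returns an `ellipsoid_region`
#' @export
ellipsoid_to_json <- function(region, path) {
  jsonlite::write_json(list(center = region$center,
                            shape = region$shape,
                            radius = region$radius,
                            degenerate = region$degenerate),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname ellipsoid_to_json
#' @export
ellipsoid_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = as.numeric(x$center),
                 shape = as.matrix(x$shape),
                 radius = as.numeric(x$radius),
                 degenerate = isTRUE(x$degenerate)),
            class = "ellipsoid_region")
}
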