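# 3-D convex hulls and hull overlap. No computational-geometry package is
# assumed: the hull is built by the incremental (beneath-beyond) algorithm,
# adequate for the few hundred colour loci this package handles.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orient facet (i,j,k) of P so its normal points away from interior point o
orient_facet <- function(P, f, o) {
  n <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  if (sum(n * (P[f[1], ] - o)) < 0) f[c(2, 3)] <- f[c(3, 2)]
  f
}

# incremental convex hull of 3-D points; returns facets as index triples
# oriented outward, or degenerate = TRUE when rank < 3
quickhull3 <- function(P, eps = NULL) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  n <- nrow(P)
  scale <- max(apply(P, 2, function(v) diff(range(v))), .Machine$double.eps)
  if (is.null(eps)) eps <- 1e-10 * max(scale, 1)
  degenerate <- list(facets = NULL, volume = 0, degenerate = TRUE,
                     vertices = unique(P))
  if (n < 4L) return(degenerate)

  # initial simplex: spread-out extreme points
  i1 <- which.min(P[, 1])
  d1 <- rowSums((P - rep(P[i1, ], each = n))^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps) return(degenerate)
  u <- P[i2, ] - P[i1, ]
  d2 <- apply(P, 1, function(p) sum(cross3(p - P[i1, ], u)^2))
  i3 <- which.max(d2)
  if (sqrt(d2[i3]) / sqrt(sum(u^2)) <= eps) return(degenerate)
  n0 <- cross3(u, P[i3, ] - P[i1, ])
  n0 <- n0 / sqrt(sum(n0^2))
  d3 <- abs(as.numeric(P %*% n0) - sum(n0 * P[i1, ]))
  i4 <- which.max(d3)
  if (d3[i4] <= eps) return(degenerate)

  init <- c(i1, i2, i3, i4)
  inner <- colMeans(P[init, ])
  facets <- list(orient_facet(P, init[c(1, 2, 3)], inner),
                 orient_facet(P, init[c(1, 2, 4)], inner),
                 orient_facet(P, init[c(1, 3, 4)], inner),
                 orient_facet(P, init[c(2, 3, 4)], inner))

  facet_plane <- function(f) {
    nr <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    nr <- nr / sqrt(sum(nr^2))
    list(n = nr, d = sum(nr * P[f[1], ]))
  }
  planes <- lapply(facets, facet_plane)

  for (j in setdiff(seq_len(n), init)) {
    dist <- vapply(planes, function(pl) sum(pl$n * P[j, ]) - pl$d, numeric(1))
    vis <- which(dist > eps)
    if (length(vis) == 0L) next
    # horizon = undirected edges used by exactly one visible facet
    ve <- do.call(rbind, lapply(facets[vis], function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    key <- paste(pmin(ve[, 1], ve[, 2]), pmax(ve[, 1], ve[, 2]))
    horizon <- ve[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    facets <- facets[-vis]
    planes <- planes[-vis]
    for (r in seq_len(nrow(horizon))) {
      f <- orient_facet(P, c(horizon[r, ], j), inner)
      facets <- c(facets, list(f))
      planes <- c(planes, list(facet_plane(f)))
    }
  }

  fm <- do.call(rbind, facets)
  vol <- 0
  for (r in seq_len(nrow(fm))) {
    a <- P[fm[r, 1], ] - inner
    b <- P[fm[r, 2], ] - inner
    cc <- P[fm[r, 3], ] - inner
    vol <- vol + det(rbind(a, b, cc)) / 6
  }
  list(facets = fm, volume = vol, degenerate = FALSE,
       vertices = P[sort(unique(as.vector(fm))), , drop = FALSE],
       planes = planes, inner = inner, eps = eps)
}

#' Convex hull of 3-D points
#'
#' Exact convex-hull volume by the incremental algorithm. Fewer than four
#' points, or a coplanar/collinear set, yields volume 0 with
#' `degenerate = TRUE`.
#'
#' @param points n x 3 matrix of points
#' @return object of class `hull3` with fields `vertices` (hull vertex
#'   coordinates), `facets` (outward-oriented index triples into the input),
#'   `volume` and `degenerate`
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  h <- quickhull3(points)
  h$points <- points
  class(h) <- "hull3"
  h
}

#' @export
print.hull3 <- function(x, ...) {
  cat(sprintf("<hull3> volume %.6g, %d vertices%s\n", x$volume,
              nrow(x$vertices), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# unique bounding half-planes of a hull (facet planes deduplicated)
hull_planes <- function(h) {
  if (h$degenerate) stop("hull is degenerate")
  N <- do.call(rbind, lapply(h$planes, `[[`, "n"))
  d <- vapply(h$planes, `[[`, numeric(1), "d")
  key <- apply(cbind(round(N, 9), round(d, 9)), 1, paste, collapse = " ")
  keep <- !duplicated(key)
  list(N = N[keep, , drop = FALSE], d = d[keep])
}

#' Point-in-hull membership
#'
#' @param h a non-degenerate `hull3`
#' @param pts m x 3 matrix of query points
#' @param tol boundary tolerance (boundary counts as inside)
#' @return logical vector of length m
#' @export
in_hull <- function(h, pts, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pl <- hull_planes(h)
  slack <- pts %*% t(pl$N) - rep(pl$d, each = nrow(pts))
  apply(slack <= tol, 1, all)
}

# clip a vertex set (convex) by half-space n.x <= d; returns new vertex set
clip_vertices <- function(V, nrm, off, eps) {
  dist <- as.numeric(V %*% nrm) - off
  inside <- dist <= eps
  if (all(inside)) return(V)
  if (!any(inside)) return(V[0, , drop = FALSE])
  h <- quickhull3(V)
  newpts <- V[inside, , drop = FALSE]
  if (!h$degenerate) {
    ed <- do.call(rbind, lapply(seq_len(nrow(h$facets)), function(r) {
      f <- h$facets[r, ]
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    ed <- unique(t(apply(ed, 1, sort)))
    for (r in seq_len(nrow(ed))) {
      du <- dist[ed[r, 1]]; dv <- dist[ed[r, 2]]
      if ((du > eps && dv < -eps) || (dv > eps && du < -eps)) {
        t <- du / (du - dv)
        newpts <- rbind(newpts, V[ed[r, 1], ] + t * (V[ed[r, 2], ] - V[ed[r, 1], ]))
      }
    }
  }
  unique(round(newpts, 12))
}

#' Overlap of two convex hulls
#'
#' Exact mode clips one polytope by the bounding half-spaces of the other
#' and measures the intersection volume; Monte-Carlo mode estimates it by
#' uniform sampling in the joint bounding box and reports a standard error.
#'
#' @param a,b non-degenerate `hull3` objects
#' @param mode `"exact"` (default) or `"monte_carlo"`
#' @param n Monte-Carlo sample count
#' @param seed Monte-Carlo RNG seed
#' @return list with `overlap_volume`, `fraction_of_a` (share of a's volume),
#'   `fraction_of_union` (share of the combined volume), `se` (MC only)
#' @export
overlap_fraction <- function(a, b, mode = c("exact", "monte_carlo"),
                             n = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  if (a$degenerate || b$degenerate) stop("both hulls must be non-degenerate")
  se <- NA_real_
  if (mode == "exact") {
    V <- a$vertices
    pl <- hull_planes(b)
    eps <- max(a$eps, b$eps)
    for (r in seq_len(nrow(pl$N))) {
      V <- clip_vertices(V, pl$N[r, ], pl$d[r], eps)
      if (nrow(V) == 0L) break
    }
    ov <- if (nrow(V) >= 4L) max(quickhull3(V)$volume, 0) else 0
  } else {
    lo <- pmax(apply(a$vertices, 2, min), apply(b$vertices, 2, min))
    hi <- pmin(apply(a$vertices, 2, max), apply(b$vertices, 2, max))
    if (any(hi <= lo)) {
      ov <- 0; se <- 0
    } else {
      set.seed(seed)
      box <- prod(hi - lo)
      pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                   runif(n, lo[3], hi[3]))
      hit <- in_hull(a, pts) & in_hull(b, pts)
      p <- mean(hit)
      ov <- p * box
      se <- box * sqrt(p * (1 - p) / n)
    }
  }
  list(overlap_volume = ov,
       fraction_of_a = ov / a$volume,
       fraction_of_union = ov / (a$volume + b$volume - ov),
       se = se, mode = mode)
}
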