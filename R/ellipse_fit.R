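#' Fit an ellipse to boundary points
#'
#' Direct least-squares conic fit constrained to an ellipse (the numerically
#' stable partitioned form of the Fitzgibbon constraint `4AC - B^2 = 1`),
#' optionally followed by a geometric refinement that minimizes the radial
#' point-to-ellipse distance. The algebraic stage is deterministic and needs
#' no initialization; the refinement polishes the algebraic solution, which
#' matters at larger boundary noise where algebraic fits shrink the axes.
#'
#' The returned semi-axes follow the package's axis convention: `a_px` is the
#' semi-axis whose direction is closer to the image X axis (`|theta| <= 45`
#' degrees) and `b_px` the perpendicular one, so that `axis_ratio = a_px/b_px`
#' estimates the X/Y anisotropy `k` directly and fluctuates around 1 (rather
#' than being floored at 1) for isotropic circles. For an exact circle the
#' orientation is undefined and an arbitrary `theta` is returned.
#'
#' @param points a two-column matrix or data frame of boundary coordinates
#'   (`x` = column, `y` = row, pixels); at least 6 points in general position.
#' @param refine logical; run the geometric (radial-distance) refinement
#'   after the algebraic fit. Default `TRUE`.
#' @return an object of class `ellipse_params`: `cx`, `cy` (center, px),
#'   `a_px`, `b_px` (semi-axes, px), `theta_deg` (orientation of the `a_px`
#'   axis from X, in `[-90, 90)`), `axis_ratio` (`a_px/b_px`),
#'   `rms_residual` (root-mean-square radial distance of the points to the
#'   fitted ellipse, px), `n_points`.
#' @references Halir R., Flusser J. (1998) Numerically stable direct least
#'   squares fitting of ellipses.
#' @export
#' @examples
#' t <- seq(0, 2 * pi, length.out = 60)
#' pts <- cbind(x = 100 + 40 * cos(t), y = 50 + 12 * sin(t))
#' fit_ellipse(pts)
fit_ellipse <- function(points, refine = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("`points` must have x and y columns", call. = FALSE)
  pts <- pts[stats::complete.cases(pts[, 1:2, drop = FALSE]), 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 6L) stop("ellipse fitting needs at least 6 points", call. = FALSE)
  x <- pts[, 1]; y <- pts[, 2]

  # condition: center and scale to unit RMS radius
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  s <- sqrt(mean(xs^2 + ys^2))
  if (s < .Machine$double.eps) stop("degenerate point set (all points coincide)", call. = FALSE)
  xs <- xs / s; ys <- ys / s

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate point configuration (collinear or repeated points)", call. = FALSE)
  })
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  ok <- which(4 * V[1, ] * V[3, ] - V[2, ]^2 > 0)
  if (length(ok) == 0L) {
    stop("best-fit conic is not an ellipse (degenerate or hyperbolic data)", call. = FALSE)
  }
  a1 <- V[, ok[1]]
  coef_s <- c(a1, as.vector(T_ %*% a1))  # A B C D E F in the scaled frame

  geo <- conic_to_geometric(coef_s)
  # undo the conditioning transform
  geo$cx <- geo$cx * s + mx
  geo$cy <- geo$cy * s + my
  geo$a <- geo$a * s
  geo$b <- geo$b * s

  p <- c(geo$cx, geo$cy, geo$a, geo$b, geo$theta)
  if (isTRUE(refine) && n >= 6L) {
    # refine in data-centered coordinates so the procedure is exactly
    # translation-equivariant (optimizer paths depend on parameter scale)
    pc <- p; pc[1] <- p[1] - mx; pc[2] <- p[2] - my
    xc <- x - mx; yc <- y - my
    obj <- function(q) {
      if (q[3] <= 0 || q[4] <= 0) return(.Machine$double.xmax)
      sum(ellipse_radial_residuals(xc, yc, q)^2)
    }
    opt <- stats::optim(pc, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    if (is.finite(opt$value) && opt$value <= obj(pc)) pc <- opt$par
    p <- pc; p[1] <- pc[1] + mx; p[2] <- pc[2] + my
  }

  res <- ellipse_radial_residuals(x, y, p)
  axes <- orient_axes(p[3], p[4], p[5])
  structure(
    list(cx = p[1], cy = p[2], a_px = axes$a, b_px = axes$b,
         theta_deg = axes$theta_deg, axis_ratio = axes$a / axes$b,
         rms_residual = sqrt(mean(res^2)), n_points = n),
    class = "ellipse_params"
  )
}

# conic A x^2 + B xy + C y^2 + D x + E y + F = 0 -> center/axes/orientation
conic_to_geometric <- function(cf) {
  if (cf[1] + cf[3] < 0) cf <- -cf  # fix overall sign so A, C > 0
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F_ <- cf[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("best-fit conic is not an ellipse", call. = FALSE)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # constant term of the conic recentred at (cx, cy)
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F_
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / eg$values
  if (any(ax2 <= 0)) stop("best-fit conic is not a real ellipse", call. = FALSE)
  # eigen() orders by decreasing eigenvalue: values[1] is the larger, so
  # ax2[1] is the SHORTER semi-axis; report the axis along eigenvector 2 as
  # the first (longer) one.
  a_long <- sqrt(ax2[2]); a_short <- sqrt(ax2[1])
  v <- eg$vectors[, 2]
  theta <- atan2(v[2], v[1])
  list(cx = cx, cy = cy, a = a_long, b = a_short, theta = theta)
}

# signed radial residual: distance along the center ray from each point to
# the ellipse boundary (exact for the radial direction; a well-behaved
# geometric proxy for near-elliptic boundary data)
ellipse_radial_residuals <- function(x, y, p) {
  ct <- cos(p[5]); st <- sin(p[5])
  u <- ct * (x - p[1]) + st * (y - p[2])
  v <- -st * (x - p[1]) + ct * (y - p[2])
  r <- sqrt(u^2 + v^2)
  q <- sqrt((u / p[3])^2 + (v / p[4])^2)
  ifelse(q > 0, r * (1 - 1 / q), -min(p[3], p[4]))
}

# report the more-horizontal axis as a_px (direction within 45 deg of X)
orient_axes <- function(a1, a2, theta) {
  th <- ((theta / DEG + 90) %% 180) - 90  # fold to [-90, 90)
  if (abs(th) <= 45) {
    list(a = a1, b = a2, theta_deg = th)
  } else {
    th2 <- ((th + 180) %% 180) - 90
    list(a = a2, b = a1, theta_deg = th2)
  }
}
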