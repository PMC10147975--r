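#' Dipole potential in an infinite homogeneous anisotropic medium
#'
#' The singularity potential used by the full-subtraction source model:
#' \deqn{\phi_\infty(r) = \frac{1}{4\pi\sqrt{\det\Sigma}}
#'   \frac{m \cdot \Sigma^{-1}(r-r_0)}{\left[(r-r_0)^\top\Sigma^{-1}(r-r_0)\right]^{3/2}}}
#' For isotropic \eqn{\Sigma = \sigma I} this reduces to the familiar
#' \eqn{m\cdot(r-r_0)/(4\pi\sigma|r-r_0|^3)}.
#'
#' @param sigma 3x3 symmetric positive-definite conductivity tensor (S/m), or
#'   a scalar for an isotropic medium.
#' @param dipole_pos dipole position (mm).
#' @param dipole_moment dipole moment (A mm).
#' @param points n x 3 matrix of field points (mm).
#' @return numeric vector of potentials (V, given the A mm / S/m / mm units).
#' @export
analytic_dipole_infinite <- function(sigma, dipole_pos, dipole_moment, points) {
  if (length(sigma) == 1) sigma <- diag(3) * as.numeric(sigma)
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-12 * max(abs(sigma)))
    stop("analytic_dipole_infinite: sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("analytic_dipole_infinite: sigma must be positive definite")
  Ti <- solve(sigma)
  points <- matrix(points, ncol = 3)
  s <- sweep(points, 2, dipole_pos)
  if (any(rowSums(s^2) == 0))
    stop("analytic_dipole_infinite: field point coincides with the dipole position")
  Ts <- s %*% Ti
  rho2 <- rowSums(s * Ts)
  mT <- as.numeric(Ti %*% dipole_moment)
  num <- s %*% mT
  as.vector(num / (4 * pi * sqrt(det(sigma)) * rho2^1.5))
}

#' Multilayer sphere model for analytic dipole potentials
#'
#' Concentric spherical shells with isotropic conductivities and an
#' insulating exterior; the classical validation oracle for numerical
#' forward solvers.
#'
#' @param layer_radii interface radii in mm, inner to outer; the last entry
#'   is the outer (insulated) surface.
#' @param layer_conductivities S/m, one per layer, innermost first.
#' @param dipole_pos,dipole_moment dipole position (mm, strictly inside the
#'   innermost layer) and moment (A mm).
#' @param n_terms series truncation (default 80).
#' @return An `analytic_sphere_model` object.
#' @export
analytic_sphere_model <- function(layer_radii, layer_conductivities,
                                  dipole_pos, dipole_moment, n_terms = 80L) {
  layer_radii <- as.numeric(layer_radii)
  layer_conductivities <- as.numeric(layer_conductivities)
  stopifnot(length(layer_radii) == length(layer_conductivities),
            all(diff(layer_radii) > 0), all(layer_conductivities > 0),
            n_terms >= 1)
  b <- sqrt(sum(dipole_pos^2))
  if (b >= layer_radii[1])
    stop("analytic_sphere_model: dipole must lie strictly inside the innermost layer")
  structure(list(radii = layer_radii, sigma = layer_conductivities,
                 dipole_pos = as.numeric(dipole_pos),
                 dipole_moment = as.numeric(dipole_moment),
                 n_terms = as.integer(n_terms)),
            class = "analytic_sphere_model")
}

# Legendre P_n(x) and P_n^1(x) (positive convention, P_1^1 = sqrt(1-x^2))
# evaluated by upward recursion; internal, vectorized over x.
legendre_next <- function(n, x, Pn, Pnm1) ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
legendre1_next <- function(n, x, Pn1, Pnm11) ((2 * n + 1) * x * Pn1 - (n + 1) * Pnm11) / n

#' Dipole potential in a multilayer sphere (series solution)
#'
#' Evaluates the truncated Legendre series for the electric potential of a
#' current dipole inside a concentric multilayer sphere with insulating
#' exterior. Points may lie on the outer surface or anywhere inside; the
#' series for the layer containing each point is used (in the source layer
#' the singular part is evaluated in closed form, so the expansion is valid
#' at radii below the dipole eccentricity too).
#'
#' @param model an [analytic_sphere_model()].
#' @param points n x 3 matrix (mm), inside or on the outer sphere.
#' @param tol early-stopping tolerance on the relative size of the last term.
#' @return list with `potential` (numeric vector) and `terms_used`;
#'   a warning is raised if truncation dominates (no convergence).
#' @export
analytic_dipole_sphere <- function(model, points, tol = 1e-12) {
  stopifnot(inherits(model, "analytic_sphere_model"))
  points <- matrix(points, ncol = 3)
  R <- model$radii
  sig <- model$sigma
  L <- length(R)
  b <- sqrt(sum(model$dipole_pos^2))
  if (any(sqrt(rowSums(points^2)) > R[L] * (1 + 1e-9)))
    stop("analytic_dipole_sphere: points must lie on or inside the outer sphere")

  # rotate so the dipole sits on +z; x axis along the tangential moment part
  if (b > 1e-12) {
    ez <- model$dipole_pos / b
  } else {
    ez <- c(0, 0, 1)
  }
  m <- model$dipole_moment
  mr <- sum(m * ez)
  mt_vec <- m - mr * ez
  mt <- sqrt(sum(mt_vec^2))
  if (mt > 1e-15 * max(1, sqrt(sum(m^2)))) {
    ex <- mt_vec / mt
  } else {
    ex <- c(1, 0, 0)
    if (abs(sum(ex * ez)) > 0.9) ex <- c(0, 1, 0)
    ex <- ex - sum(ex * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
  }
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  Q <- rbind(ex, ey, ez)         # world -> dipole frame
  pl <- points %*% t(Q)
  r <- sqrt(rowSums(pl^2))
  ct <- ifelse(r > 1e-12, pl[, 3] / pmax(r, 1e-300), 1)
  ct <- pmin(pmax(ct, -1), 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  cph <- ifelse(st * r > 1e-12, pl[, 1] / pmax(r * st, 1e-300), 0)

  # layer containing each point (1 = innermost)
  lay <- findInterval(r * (1 - 1e-12), R) + 1L
  lay[lay > L] <- L

  # per-layer inner/outer reference radii for scaled basis functions
  Rin <- c(max(b, 1e-6 * R[1]), R[-L])
  Rout <- R

  sig1 <- sig[1]
  pref <- 1 / (4 * pi * sig1)

  phi <- numeric(nrow(points))
  # direct singular part for points in the source layer
  in1 <- lay == 1L
  if (any(in1))
    phi[in1] <- analytic_dipole_infinite(sig1, model$dipole_pos,
                                         model$dipole_moment, points[in1, , drop = FALSE])

  Pn <- ct; Pnm1 <- rep(1, length(ct))        # P_1, P_0
  Pn1 <- st; Pnm11 <- rep(0, length(ct))      # P_1^1, P_0^1
  max_term <- 0
  last_term <- Inf
  terms_used <- model$n_terms
  for (n in seq_len(model$n_terms)) {
    if (n > 1) {
      tmp <- legendre_next(n - 1, ct, Pn, Pnm1); Pnm1 <- Pn; Pn <- tmp
      tmp <- legendre1_next(n - 1, ct, Pn1, Pnm11); Pnm11 <- Pn1; Pn1 <- tmp
    }
    # source coefficients of r^-(n+1) in the source layer:
    #   radial part: n*mr*b^(n-1)/(4 pi sig1), tangential: mt*b^(n-1)/(4 pi sig1)
    # solve the scaled interface system for both angular orders at once
    co <- solve_layer_coeffs(n, R, sig, b, Rin, Rout)
    # co: list with matrices a (L x 2) and bb (L x 2) of scaled coefficients;
    # column 1 = m=0 (radial), column 2 = m=1 (tangential)
    src <- pref * b^(n - 1) * c(n * mr, mt)
    contrib <- numeric(length(r))
    for (l in seq_len(L)) {
      idx <- lay == l
      if (!any(idx)) next
      u <- (r[idx] / Rout[l])^n
      v <- (Rin[l] / pmax(r[idx], 1e-300))^(n + 1)
      if (l == 1L) {
        # only the regular (a) part; singular part already added in closed form
        c0 <- co$a[1, 1] * src[1]
        c1 <- co$a[1, 2] * src[2]
        contrib[idx] <- u * (c0 * Pn[idx] + c1 * Pn1[idx] * cph[idx])
      } else {
        a0 <- co$a[l, 1] * src[1]; a1 <- co$a[l, 2] * src[2]
        b0 <- co$b[l, 1] * src[1]; b1 <- co$b[l, 2] * src[2]
        contrib[idx] <- u * (a0 * Pn[idx] + a1 * Pn1[idx] * cph[idx]) +
                        v * (b0 * Pn[idx] + b1 * Pn1[idx] * cph[idx])
      }
    }
    phi <- phi + contrib
    last_term <- max(abs(contrib))
    max_term <- max(max_term, last_term)
    if (n >= 3 && last_term < tol * max(max_term, 1e-300)) {
      terms_used <- n
      break
    }
  }
  if (last_term > 1e-8 * max(max_term, 1e-300) && terms_used == model$n_terms)
    warning("analytic_dipole_sphere: series truncated before convergence; ",
            "increase n_terms")
  list(potential = phi, terms_used = terms_used)
}

# Solve the per-degree interface conditions of the multilayer sphere.
# Unknowns (scaled): a_l multiplies (r/Rout_l)^n, b_l multiplies
# (Rin_l/r)^(n+1); the source contributes a known b-type term in layer 1 with
# unit coefficient (the caller multiplies by the actual source strength).
# Returns scaled coefficients per layer for a unit source coefficient.
solve_layer_coeffs <- function(n, R, sig, b, Rin, Rout) {
  L <- length(R)
  nun <- 2 * L - 1                     # a_1..a_L, b_2..b_L
  A <- matrix(0, nun, nun)
  rhs <- numeric(nun)
  ai <- function(l) l                  # column of a_l
  bi <- function(l) L + l - 1          # column of b_l (l >= 2)
  # source: phi_src = 1 * r^-(n+1), i.e. scaled b-term in layer 1 with
  # reference radius b: value at r = (b/r)^(n+1) / b^(n+1) * b^(n+1)... we
  # use the raw form c * r^-(n+1) with c = 1 and fold scaling locally.
  row <- 0
  for (l in seq_len(L - 1)) {
    Rl <- R[l]
    # potential continuity at Rl
    row <- row + 1
    A[row, ai(l)] <- (Rl / Rout[l])^n
    if (l >= 2) A[row, bi(l)] <- (Rin[l] / Rl)^(n + 1)
    A[row, ai(l + 1)] <- -(Rl / Rout[l + 1])^n
    A[row, bi(l + 1)] <- -(Rin[l + 1] / Rl)^(n + 1)
    if (l == 1) rhs[row] <- -Rl^-(n + 1)
    # flux continuity at Rl: sigma * dphi/dr
    row <- row + 1
    A[row, ai(l)] <- sig[l] * n * (Rl / Rout[l])^n / Rl
    if (l >= 2) A[row, bi(l)] <- -sig[l] * (n + 1) * (Rin[l] / Rl)^(n + 1) / Rl
    A[row, ai(l + 1)] <- -sig[l + 1] * n * (Rl / Rout[l + 1])^n / Rl
    A[row, bi(l + 1)] <- sig[l + 1] * (n + 1) * (Rin[l + 1] / Rl)^(n + 1) / Rl
    if (l == 1) rhs[row] <- sig[1] * (n + 1) * Rl^-(n + 2)
  }
  # insulating outer boundary at R_L
  row <- row + 1
  RL <- R[L]
  A[row, ai(L)] <- n * (RL / Rout[L])^n / RL
  if (L >= 2) {
    A[row, bi(L)] <- -(n + 1) * (Rin[L] / RL)^(n + 1) / RL
    rhs[row] <- 0
  } else {
    rhs[row] <- (n + 1) * RL^-(n + 2)
  }
  sol <- solve(A, rhs)
  a <- matrix(0, L, 2)
  bb <- matrix(0, L, 2)
  a[, 1] <- sol[seq_len(L)]
  if (L >= 2) bb[2:L, 1] <- sol[(L + 1):nun]
  # identical radial structure for the m=1 order
  a[, 2] <- a[, 1]
  bb[, 2] <- bb[, 1]
  list(a = a, b = bb)
}

#' Shape and magnitude error metrics between potential vectors
#'
#' RDM (relative difference measure, the norm of the difference of the
#' unit-normalized vectors; 0 = identical shapes, sqrt(2) = orthogonal) and
#' MAG (magnitude ratio computed / reference).
#'
#' @param computed,reference equal-length numeric vectors; `reference` must
#'   be nonzero.
#' @return list with elements `rdm` and `mag`.
#' @export
rdm_mag <- function(computed, reference) {
  stopifnot(length(computed) == length(reference))
  nr <- sqrt(sum(reference^2))
  if (nr == 0) stop("rdm_mag: reference vector is zero")
  nc <- sqrt(sum(computed^2))
  list(rdm = sqrt(sum((computed / nc - reference / nr)^2)),
       mag = nc / nr)
}
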