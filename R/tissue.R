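#' Mean diffusivity and fractional anisotropy of a tensor image
#'
#' MD is the mean eigenvalue (computed as trace/3); FA is
#' \eqn{\sqrt{3/2}\,\|D - \bar\lambda I\|_F / \|D\|_F}, which equals the
#' usual eigenvalue formula. Zero tensors get FA = 0.
#'
#' @param dti a [tensor_image()].
#' @param mask optional [mask_image()]; outside voxels get 0.
#' @return list with `md` and `fa` ([scalar_image()]s).
#' @export
tensor_invariants <- function(dti, mask = NULL) {
  stopifnot(inherits(dti, "tensor_image"))
  t6 <- matrix(dti$values, nrow = 6)
  md <- (t6[1, ] + t6[4, ] + t6[6, ]) / 3
  # ||D||_F^2 and ||D - md I||_F^2 from components
  fn2 <- t6[1, ]^2 + t6[4, ]^2 + t6[6, ]^2 + 2 * (t6[2, ]^2 + t6[3, ]^2 + t6[5, ]^2)
  dev2 <- fn2 - 3 * md^2
  fa <- sqrt(1.5) * sqrt(pmax(dev2, 0) / pmax(fn2, 1e-300))
  fa[fn2 == 0] <- 0
  if (!is.null(mask)) {
    sel <- as.vector(mask$values)
    md[!sel] <- 0
    fa[!sel] <- 0
  }
  list(md = scalar_image(md, dti$grid), fa = scalar_image(fa, dti$grid))
}

#' Fuzzy C-means configuration
#'
#' @param n_clusters number of clusters (>= 2).
#' @param m fuzziness exponent (> 1; 2 is the conventional choice for
#'   diffusion-based tissue classification).
#' @param tol convergence tolerance on the centre shift.
#' @param max_iter iteration budget.
#' @param seed seed for the optional random restart.
#' @return An `fcm_config` object.
#' @export
fcm_config <- function(n_clusters = 2L, m = 2, tol = 1e-8, max_iter = 300L,
                       seed = 1L) {
  stopifnot(n_clusters >= 2, m > 1, tol > 0)
  structure(list(n_clusters = as.integer(n_clusters), m = m, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fcm_config")
}

#' Fuzzy C-means clustering
#'
#' Alternating optimization of the fuzzy C-means objective
#' \eqn{\sum_{ik} u_{ik}^m d_{ik}^2} with membership update
#' \eqn{u_{ik} = 1/\sum_j (d_{ik}/d_{jk})^{2/(m-1)}} and centre update
#' \eqn{c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}. Centres are
#' initialized deterministically at feature quantiles; if centres collapse,
#' one seeded random restart is attempted before failing.
#'
#' @param x n x p feature matrix.
#' @param config an [fcm_config()].
#' @return list with `memberships` (n x c, rows sum to 1), `centers`
#'   (c x p, sorted by first feature), `objective` (per-iteration values,
#'   non-increasing) and `iterations`.
#' @export
fcm <- function(x, config = fcm_config()) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < config$n_clusters)
    stop("fcm: need at least n_clusters distinct feature points")
  run <- function(centers) {
    c_n <- config$n_clusters
    expo <- 2 / (config$m - 1)
    obj <- numeric(0)
    for (it in seq_len(config$max_iter)) {
      d2 <- sapply(seq_len(c_n), function(i)
        rowSums(sweep(x, 2, centers[i, ], `-`)^2))
      d2 <- pmax(matrix(d2, nrow(x), c_n), 1e-300)
      um <- (1 / d2)^(expo / 2)
      u <- um / rowSums(um)
      um <- u^config$m
      obj <- c(obj, sum(um * d2))
      newc <- t(um) %*% x / colSums(um)
      shift <- max(abs(newc - centers))
      centers <- newc
      if (shift < config$tol) break
    }
    if (any(!is.finite(centers)) ||
        min(stats::dist(centers)) < 1e-12 * max(1, max(abs(centers))))
      return(NULL)
    list(memberships = u, centers = centers, objective = obj, iterations = it)
  }
  q <- seq(0.1, 0.9, length.out = config$n_clusters)
  init <- apply(x, 2, stats::quantile, probs = q)
  res <- run(matrix(init, config$n_clusters))
  if (is.null(res)) {
    set.seed(config$seed)
    init <- x[sample.int(nrow(x), config$n_clusters), , drop = FALSE]
    res <- run(init)
    if (is.null(res)) stop("fcm: cluster centres collapsed (degenerate data)")
  }
  ord <- order(res$centers[, 1])
  res$centers <- res$centers[ord, , drop = FALSE]
  res$memberships <- res$memberships[, ord, drop = FALSE]
  res
}

#' Head tissue class codes
#'
#' Label codes used in head label maps: WM 1, GM 2, CSF 3, skull 4, scalp 5,
#' electrode sheet 6.
#' @return data.frame with columns `label`, `name`.
#' @export
head_classes <- function() {
  data.frame(label = 1:6,
             name = c("white_matter", "gray_matter", "csf", "skull", "scalp",
                      "electrode_sheet"))
}

#' DTI-based brain tissue classification
#'
#' Two-stage fuzzy C-means on diffusion invariants: mean diffusivity first
#' separates CSF (the high-MD cluster) from brain parenchyma, then
#' fractional anisotropy within the parenchyma separates WM (the high-FA
#' cluster) from GM. Hard labels by maximum membership.
#'
#' @param dti a [tensor_image()].
#' @param brain_mask a [mask_image()].
#' @param config an [fcm_config()] (n_clusters is forced to 2 per stage).
#' @return A [label_image()] with WM 1, GM 2, CSF 3 inside the mask.
#' @export
classify_brain <- function(dti, brain_mask, config = fcm_config()) {
  stopifnot(inherits(dti, "tensor_image"), inherits(brain_mask, "mask_image"))
  sel <- as.vector(brain_mask$values)
  if (!any(sel)) stop("classify_brain: empty brain mask")
  inv <- tensor_invariants(dti)
  md <- as.vector(inv$md$values)[sel]
  fa <- as.vector(inv$fa$values)[sel]
  if (stats::sd(md) == 0 || stats::sd(fa) == 0)
    stop("classify_brain: constant diffusion feature; cannot classify")
  config$n_clusters <- 2L
  s1 <- fcm(matrix(md, ncol = 1), config)
  # centers sorted ascending: cluster 2 = high MD = CSF
  csf <- s1$memberships[, 2] > s1$memberships[, 1]
  lab <- integer(sum(sel))
  lab[csf] <- 3L
  paren <- !csf
  s2 <- fcm(matrix(fa[paren], ncol = 1), config)
  wm <- s2$memberships[, 2] > s2$memberships[, 1]
  lab[paren][wm] <- 1L
  lab[paren][!wm] <- 2L
  out <- integer(length(sel))
  out[sel] <- lab
  label_image(out, dti$grid)
}

#' Fuse brain labels, shells and electrode sheet into a head label map
#'
#' Builds skull and scalp shells by offsetting the brain mask (skull =
#' dilation by `shell_mm` minus brain; scalp = dilation by `2*shell_mm`
#' minus the skull dilation) and overlays the electrode sheet mask, which
#' overrides underlying classes. Class codes follow [head_classes()].
#'
#' @param brain_labels WM/GM/CSF [label_image()] from [classify_brain()].
#' @param brain_mask brain [mask_image()].
#' @param sheet_mask optional electrode-sheet [mask_image()].
#' @param shell_mm shell thickness in mm (default 4.4, i.e. 4 voxels at
#'   1.1 mm spacing).
#' @return A [label_image()] head label map.
#' @export
build_head_labelmap <- function(brain_labels, brain_mask, sheet_mask = NULL,
                                shell_mm = 4.4) {
  stopifnot(shell_mm > 0, inherits(brain_labels, "label_image"))
  d1 <- dilate_mask(brain_mask, shell_mm)
  d2 <- dilate_mask(brain_mask, 2 * shell_mm)
  edge_hit <- function(m) {
    v <- m$values
    any(v[1, , ], v[dim(v)[1], , ], v[, 1, ], v[, dim(v)[2], ],
        v[, , 1], v[, , dim(v)[3]])
  }
  if (edge_hit(d2))
    warning("build_head_labelmap: shells clipped by the grid boundary")
  lab <- as.vector(brain_labels$values)
  lab[as.vector(d1$values) & !as.vector(brain_mask$values)] <- 4L  # skull
  lab[as.vector(d2$values) & !as.vector(d1$values)] <- 5L          # scalp
  if (!is.null(sheet_mask)) lab[as.vector(sheet_mask$values)] <- 6L
  label_image(lab, brain_labels$grid)
}

#' Conductivity specification
#'
#' Isotropic class conductivities (S/m) and the white-matter anisotropy
#' mode. Defaults follow the standard EEG/ECoG literature values: scalp
#' 0.33, skull 0.012, CSF 1.79, GM 0.33, electrode sheet substrate 1e-6. WM
#' is anisotropic, derived from the diffusion tensor eigensystem: in
#' `"volume_normalized"` mode the conductivity eigenvalues are
#' \eqn{\sigma_i = \sigma_{ref} d_i / (d_1 d_2 d_3)^{1/3}} (so
#' \eqn{\det\sigma = \sigma_{ref}^3}); in `"linear"` mode
#' \eqn{\sigma_i = k d_i}.
#'
#' @param class_sigma named numeric: isotropic conductivity per class name
#'   of [head_classes()] (white_matter entry = fallback isotropic WM value).
#' @param wm_mode `"volume_normalized"` or `"linear"`.
#' @param wm_sigma_ref WM reference conductivity (S/m) for the
#'   volume-normalized mode.
#' @param wm_k scale factor (S s / mm^3 ... S/m per mm^2/s) for linear mode.
#' @param floor_eps eigenvalue floor (S/m) enforcing positive definiteness.
#' @return A `conductivity_spec` object.
#' @export
conductivity_spec <- function(class_sigma = c(white_matter = 0.14,
                                              gray_matter = 0.33, csf = 1.79,
                                              skull = 0.012, scalp = 0.33,
                                              electrode_sheet = 1e-6),
                              wm_mode = c("volume_normalized", "linear"),
                              wm_sigma_ref = 0.14, wm_k = 0.844 * 0.14 / 7e-4,
                              floor_eps = 1e-9) {
  wm_mode <- match.arg(wm_mode)
  if (any(class_sigma <= 0)) stop("conductivity_spec: conductivities must be positive")
  need <- head_classes()$name
  if (!all(need %in% names(class_sigma)))
    stop("conductivity_spec: missing class conductivities: ",
         paste(setdiff(need, names(class_sigma)), collapse = ", "))
  structure(list(class_sigma = class_sigma, wm_mode = wm_mode,
                 wm_sigma_ref = wm_sigma_ref, wm_k = wm_k,
                 floor_eps = floor_eps), class = "conductivity_spec")
}

#' Assign conductivity tensors to a head label map
#'
#' Non-WM voxels receive their isotropic class conductivity; WM voxels get
#' anisotropic tensors sharing the eigenvectors of the local diffusion
#' tensor, with eigenvalues mapped per the spec (Tuch-style fractional
#' scaling). Non-finite or non-positive WM tensors fall back to the
#' isotropic WM value with a warning.
#'
#' @param labels head [label_image()] (codes per [head_classes()]).
#' @param dti a [tensor_image()] on the same grid (required when WM voxels
#'   are present).
#' @param spec a [conductivity_spec()].
#' @return A [tensor_image()] of conductivity (S/m); background voxels are
#'   zero.
#' @export
assign_conductivity <- function(labels, dti = NULL, spec = conductivity_spec()) {
  stopifnot(inherits(labels, "label_image"))
  lab <- as.vector(labels$values)
  n <- length(lab)
  t6 <- matrix(0, 6, n)
  cls <- head_classes()
  for (i in seq_len(nrow(cls))) {
    if (cls$name[i] == "white_matter") next
    idx <- lab == cls$label[i]
    s <- spec$class_sigma[[cls$name[i]]]
    t6[1, idx] <- s; t6[4, idx] <- s; t6[6, idx] <- s
  }
  wm <- which(lab == 1L)
  if (length(wm)) {
    if (is.null(dti))
      stop("assign_conductivity: WM voxels present but no DTI supplied")
    stopifnot(grids_equal(labels$grid, dti$grid))
    d6 <- matrix(dti$values, nrow = 6)[, wm, drop = FALSE]
    eg <- cpp_sym3_eig(d6)
    ev <- eg$values           # 3 x nwm, descending
    vec <- eg$vectors         # 9 x nwm
    bad <- !apply(is.finite(ev), 2, all) | ev[3, ] <= 0
    sig_ev <- matrix(0, 3, length(wm))
    if (spec$wm_mode == "volume_normalized") {
      geo <- (ev[1, ] * ev[2, ] * ev[3, ])^(1 / 3)
      sig_ev <- spec$wm_sigma_ref * sweep(ev, 2, pmax(geo, 1e-300), `/`)
    } else {
      sig_ev <- spec$wm_k * ev
    }
    sig_ev <- pmax(sig_ev, spec$floor_eps)
    if (any(bad)) {
      warning("assign_conductivity: ", sum(bad),
              " WM voxels with degenerate tensors; isotropic fallback")
      sig_ev[, bad] <- spec$class_sigma[["white_matter"]]
      # fallback uses identity eigenvectors
      vec[, bad] <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
    }
    # rebuild packed tensors sum_i sig_i v_i v_i'
    v1 <- vec[1:3, , drop = FALSE]
    v2 <- vec[4:6, , drop = FALSE]
    v3 <- vec[7:9, , drop = FALSE]
    pack <- function(s, v) rbind(s * v[1, ]^2, s * v[1, ] * v[2, ],
                                 s * v[1, ] * v[3, ], s * v[2, ]^2,
                                 s * v[2, ] * v[3, ], s * v[3, ]^2)
    t6[, wm] <- pack(sig_ev[1, ], v1) + pack(sig_ev[2, ], v2) +
                pack(sig_ev[3, ], v3)
  }
  tensor_image(t6, labels$grid)
}
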