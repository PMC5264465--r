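#' Specification of a synthetic liver-tumor specimen
#'
#' Describes one voxelized specimen: a liver lobe (ellipsoid) carrying an
#' embedded spherical tumor at one of four weekly growth stages, a
#' branching hepatic vessel tree, tortuous tumor vessels with cluster
#' motifs and avascular (necrotic) regions, and a low-transmittance
#' suture inclusion.  Week defaults follow the reported xenograft series:
#' target vascular densities 3.51, 4.29, 2.62, 1.52 percent for weeks 1-4
#' (peaking at week 2), tumor radii growing strictly week over week, and
#' avascular fractions rising at weeks 3-4.
#'
#' Tumor volumes are desk-scaled: the default 1.152 mm cube (128^3 voxels
#' at 9 um) cannot hold hundreds of mm^3, so week radii follow a
#' compressed strictly-increasing trajectory while densities keep the
#' reported means.  Pass a larger `domain_mm` for full-scale specimens.
#'
#' @param week_stage Integer growth stage in 1..4.
#' @param domain_mm Physical domain size, mm triple.
#' @param voxel_um Isotropic voxel size in micrometres; must divide the
#'   domain evenly.
#' @param tumor_volume_mm3 Target tumor volume; default derived from the
#'   week stage.
#' @param vascular_density_pct Target intratumoral vascular density in
#'   percent; default from the week stage.
#' @param avascular_fraction Fraction of the tumor volume excluded from
#'   vascularisation (necrotic core); in [0, 1).
#' @param liver_density_pct Target vascular density of the surrounding
#'   liver tissue (the normal liver is more densely vascularised than the
#'   tumor).
#' @param suture List with elements `enabled`, `radius_um`, `length_frac`
#'   (of the tumor diameter), `absorption_multiplier`; NULL for defaults.
#' @param seed Integer seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(week_stage = 2, domain_mm = rep(0.576, 3), seed = 1)
#' spec$tumor_radius_mm
#' @export
phantom_spec <- function(week_stage = 2, domain_mm = rep(1.152, 3),
                         voxel_um = 9, tumor_volume_mm3 = NULL,
                         vascular_density_pct = NULL,
                         avascular_fraction = NULL,
                         liver_density_pct = 6,
                         suture = NULL, seed = 1) {
  week_stage <- as.integer(week_stage)
  if (!week_stage %in% 1:4) stop("week_stage must be in 1..4", call. = FALSE)
  if (voxel_um <= 0) stop("voxel_um must be > 0", call. = FALSE)
  stopifnot(length(domain_mm) == 3, all(domain_mm > 0))
  dim_f <- domain_mm * 1000 / voxel_um
  dim_i <- round(dim_f)
  if (any(abs(dim_f - dim_i) > 1e-6) || any(dim_i < 8)) {
    stop("voxel_um must divide domain_mm evenly (>= 8 voxels per axis)",
         call. = FALSE)
  }
  wd <- .week_defaults()
  explicit <- c(
    tumor_volume = !is.null(tumor_volume_mm3),
    density = !is.null(vascular_density_pct),
    avascular = !is.null(avascular_fraction)
  )
  if (is.null(vascular_density_pct)) {
    vascular_density_pct <- wd$density_pct[week_stage]
  }
  if (vascular_density_pct <= 0) {
    stop("target vascular density must be > 0", call. = FALSE)
  }
  if (is.null(avascular_fraction)) {
    avascular_fraction <- wd$avascular[week_stage]
  }
  if (avascular_fraction < 0 || avascular_fraction >= 1) {
    stop("avascular_fraction must lie in [0, 1)", call. = FALSE)
  }
  half <- min(domain_mm) / 2
  if (is.null(tumor_volume_mm3)) {
    r_t <- wd$radius_frac[week_stage] * half
    tumor_volume_mm3 <- 4 / 3 * pi * r_t^3
  } else {
    if (tumor_volume_mm3 <= 0) {
      stop("tumor_volume_mm3 must be > 0", call. = FALSE)
    }
    r_t <- (3 * tumor_volume_mm3 / (4 * pi))^(1 / 3)
  }
  if (r_t > 0.44 * min(domain_mm)) {
    warning("tumor radius close to the domain boundary; consider a larger ",
            "domain_mm")
  }
  su <- list(enabled = TRUE, radius_um = 3 * voxel_um, length_frac = 0.6,
             absorption_multiplier = 1)
  if (!is.null(suture)) {
    stopifnot(is.list(suture))
    su[names(suture)] <- suture
  }
  center <- domain_mm / 2
  structure(
    list(
      week_stage = week_stage,
      domain_mm = domain_mm,
      voxel_um = voxel_um,
      dim = as.integer(dim_i),
      tumor_volume_mm3 = tumor_volume_mm3,
      tumor_radius_mm = r_t,
      tumor_center_mm = center + c(0.05, -0.03, 0) * min(domain_mm),
      liver_center_mm = center,
      liver_axes_mm = 0.46 * domain_mm,
      vascular_density_pct = vascular_density_pct,
      avascular_fraction = avascular_fraction,
      liver_density_pct = liver_density_pct,
      suture = su,
      seed = as.integer(seed),
      explicit = explicit
    ),
    class = "phantom_spec"
  )
}

# staged defaults: density peaks at week 2, tumor radius strictly grows,
# avascular fraction rises at weeks 3-4
.week_defaults <- function() {
  list(
    density_pct = c(3.51, 4.29, 2.62, 1.52),
    avascular = c(0.02, 0.05, 0.18, 0.30),
    radius_frac = c(0.34, 0.42, 0.52, 0.62)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<phantom_spec> week %d, %s mm domain @ %g um (%s voxels)\n",
           "  tumor %.4g mm^3 (r = %.3g mm), target density %.3g%%, ",
           "avascular %.2g, seed %d\n"),
    x$week_stage, paste(signif(x$domain_mm, 4), collapse = " x "),
    x$voxel_um, paste(x$dim, collapse = "x"),
    x$tumor_volume_mm3, x$tumor_radius_mm, x$vascular_density_pct,
    x$avascular_fraction, x$seed
  ))
  invisible(x)
}

# is a set of points (n x 3, mm) inside the growth region?
.region_inside <- function(spec, region, p) {
  p <- matrix(p, ncol = 3)
  d_t <- sqrt(colSums((t(p) - spec$tumor_center_mm)^2))
  if (region == "tumor") {
    return(d_t <= 0.99 * spec$tumor_radius_mm)
  }
  e <- colSums(((t(p) - spec$liver_center_mm) / spec$liver_axes_mm)^2)
  e <= 1 & d_t > spec$tumor_radius_mm
}

# rotate unit vector `d` away from itself by `ang` radians, azimuth `az`
.rotate_dir <- function(d, ang, az) {
  d <- d / sqrt(sum(d^2))
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  w <- cos(az) * u + sin(az) * v
  cos(ang) * d + sin(ang) * w
}

#' Grow a stochastic bifurcating vessel tree
#'
#' Recursive dichotomous branching with a fixed geometric radius rule
#' (child radius = parent radius x `radius_ratio`) and per-segment
#' sinusoidal tortuosity.  Liver trees are regular bifurcations with low
#' tortuosity; tumor trees use wider branch angles, higher tortuosity and
#' spawn local "cluster" motifs of short twigs, emulating the irregular,
#' dendritic morphology of tumor neovasculature in which many tiny curved
#' vessels derive from a few thick ones.
#'
#' @param spec A [phantom_spec()].
#' @param region `"liver"` or `"tumor"`: the tissue compartment the tree
#'   must occupy.
#' @param seed Integer seed; identical spec + seed gives identical trees.
#' @param root_radius_um Radius of the root segment(s), micrometres.
#' @param radius_ratio Geometric per-generation radius ratio in (0, 1].
#' @param generations Number of branching generations below the root.
#' @param tortuosity Dimensionless curvature amplitude; 0 gives straight
#'   segments.
#' @param branch_angle_deg Length-2 range of branching half-angles.
#' @param n_roots Number of root segments (tumor trees are fed by a few
#'   thick vessels).
#' @param cluster_prob Per-node probability of spawning a cluster motif
#'   (tumor only).
#' @return An object of class `vessel_tree`: list with tibbles `nodes`
#'   (`id`, `x_mm`, `y_mm`, `z_mm`, `radius_um`, `gen`) and `edges`
#'   (`parent`, `child` + tortuosity parameters), plus `region`,
#'   `tortuosity` and `seed`.
#' @export
build_vessel_tree <- function(spec, region = c("liver", "tumor"),
                              seed = spec$seed,
                              root_radius_um = NULL, radius_ratio = NULL,
                              generations = NULL, tortuosity = NULL,
                              branch_angle_deg = NULL, n_roots = NULL,
                              cluster_prob = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  region <- match.arg(region)
  if (region == "tumor" && spec$tumor_radius_mm < spec$voxel_um * 1e-3) {
    stop("empty region: tumor has zero volume", call. = FALSE)
  }
  if (region == "liver" && any(spec$liver_axes_mm <= 0)) {
    stop("empty region: liver has zero volume", call. = FALSE)
  }
  defaults <- if (region == "liver") {
    list(root_radius_um = 45, radius_ratio = 0.80, generations = 5,
         tortuosity = 0.08, branch_angle_deg = c(25, 45), n_roots = 1,
         cluster_prob = 0)
  } else {
    list(root_radius_um = 27, radius_ratio = 0.80, generations = 6,
         tortuosity = 0.5, branch_angle_deg = c(15, 80), n_roots = 3,
         cluster_prob = 0.25)
  }
  root_radius_um <- root_radius_um %||% defaults$root_radius_um
  radius_ratio <- radius_ratio %||% defaults$radius_ratio
  generations <- generations %||% defaults$generations
  tortuosity <- tortuosity %||% defaults$tortuosity
  branch_angle_deg <- branch_angle_deg %||% defaults$branch_angle_deg
  n_roots <- n_roots %||% defaults$n_roots
  cluster_prob <- cluster_prob %||% defaults$cluster_prob
  stopifnot(root_radius_um > 0, radius_ratio > 0, radius_ratio <= 1,
            generations >= 0, tortuosity >= 0)

  len0 <- if (region == "liver") {
    0.28 * min(spec$domain_mm)
  } else {
    0.5 * spec$tumor_radius_mm
  }
  len_ratio <- 0.75

  withr::with_seed(seed, {
    pos <- list(); rad <- numeric(); gen <- integer()
    ed_parent <- integer(); ed_child <- integer()
    ed_amp <- numeric(); ed_waves <- integer(); ed_phase <- numeric()
    ed_nrm <- list(); ed_cluster <- logical()

    add_node <- function(p, r, g) {
      pos[[length(pos) + 1]] <<- pmin(pmax(p, 0), spec$domain_mm)
      rad[length(rad) + 1] <<- r
      gen[length(gen) + 1] <<- g
      length(rad)
    }
    add_edge <- function(par, chd, len, cluster = FALSE) {
      d <- pos[[chd]] - pos[[par]]
      dn <- sqrt(sum(d^2))
      nrm <- .rotate_dir(if (dn > 0) d / dn else c(0, 0, 1), pi / 2,
                         runif(1, 0, 2 * pi))
      ed_parent[length(ed_parent) + 1] <<- par
      ed_child[length(ed_child) + 1] <<- chd
      ed_amp[length(ed_amp) + 1] <<-
        tortuosity * len * 0.15 * runif(1, 0.5, 1.5)
      ed_waves[length(ed_waves) + 1] <<- sample(1:3, 1)
      ed_phase[length(ed_phase) + 1] <<- runif(1, 0, 2 * pi)
      ed_nrm[[length(ed_nrm) + 1]] <<- nrm
      ed_cluster[length(ed_cluster) + 1] <<- cluster
    }

    # roots
    queue <- list()
    for (k in seq_len(n_roots)) {
      if (region == "liver") {
        p0 <- spec$liver_center_mm - c(0.8 * spec$liver_axes_mm[1], 0, 0)
        d0 <- c(1, 0, 0)
      } else {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p0 <- spec$tumor_center_mm + 0.95 * spec$tumor_radius_mm * u
        d0 <- -u
      }
      id <- add_node(p0, root_radius_um, 0L)
      queue[[length(queue) + 1]] <- list(id = id, dir = d0, gen = 0L)
    }

    while (length(queue)) {
      nd <- queue[[1]]; queue[[1]] <- NULL
      if (nd$gen >= generations) next
      g1 <- nd$gen + 1L
      r1 <- rad[nd$id] * radius_ratio
      base_az <- runif(1, 0, 2 * pi)
      for (b in 1:2) {
        ang <- runif(1, branch_angle_deg[1], branch_angle_deg[2]) * pi / 180
        dir_c <- .rotate_dir(nd$dir, ang, base_az + (b - 1) * pi)
        len <- len0 * len_ratio^nd$gen * runif(1, 0.8, 1.2)
        p1 <- NULL
        for (try in 1:5) {
          cand <- pos[[nd$id]] + dir_c * len
          if (.region_inside(spec, region, cand)) { p1 <- cand; break }
          len <- len / 1.5
        }
        if (is.null(p1)) next
        cid <- add_node(p1, r1, g1)
        add_edge(nd$id, cid, len)
        queue[[length(queue) + 1]] <- list(id = cid, dir = dir_c, gen = g1)
      }
      # cluster motif: burst of short thin twigs (tumor morphology)
      if (cluster_prob > 0 && nd$gen >= 2 && runif(1) < cluster_prob) {
        m <- sample(4:7, 1)
        for (k in seq_len(m)) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          len <- 0.35 * len0 * len_ratio^nd$gen * runif(1, 0.6, 1.2)
          cand <- pos[[nd$id]] + u * len
          if (!.region_inside(spec, region, cand)) next
          cid <- add_node(cand, r1 * 0.6, g1)
          add_edge(nd$id, cid, len, cluster = TRUE)
        }
      }
    }

    nodes <- tibble::tibble(
      id = seq_along(rad),
      x_mm = vapply(pos, `[`, numeric(1), 1),
      y_mm = vapply(pos, `[`, numeric(1), 2),
      z_mm = vapply(pos, `[`, numeric(1), 3),
      radius_um = rad,
      gen = gen
    )
    edges <- tibble::tibble(
      parent = ed_parent, child = ed_child,
      amp_mm = ed_amp, waves = ed_waves, phase = ed_phase,
      nrm_x = vapply(ed_nrm, `[`, numeric(1), 1),
      nrm_y = vapply(ed_nrm, `[`, numeric(1), 2),
      nrm_z = vapply(ed_nrm, `[`, numeric(1), 3),
      cluster = ed_cluster
    )
    structure(
      list(nodes = nodes, edges = edges, region = region,
           tortuosity = tortuosity, seed = as.integer(seed)),
      class = "vessel_tree"
    )
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf(
    "<vessel_tree> %s: %d nodes, %d edges, radii %.3g-%.3g um, seed %d\n",
    x$region, nrow(x$nodes), nrow(x$edges),
    min(x$nodes$radius_um), max(x$nodes$radius_um), x$seed
  ))
  invisible(x)
}

# sampled centreline of one edge: positions (mm) and radii (um)
.edge_centreline <- function(tree, i, voxel_mm, radius_scale = 1) {
  e <- tree$edges[i, ]
  p0 <- unlist(tree$nodes[e$parent, c("x_mm", "y_mm", "z_mm")])
  p1 <- unlist(tree$nodes[e$child, c("x_mm", "y_mm", "z_mm")])
  r0 <- tree$nodes$radius_um[e$parent] * radius_scale
  r1 <- tree$nodes$radius_um[e$child] * radius_scale
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / (0.4 * voxel_mm)) + 1L)
  t <- seq(0, 1, length.out = n)
  nrm <- c(e$nrm_x, e$nrm_y, e$nrm_z)
  wob <- e$amp_mm * sin(2 * pi * e$waves * t + e$phase) * sin(pi * t)
  pts <- outer(t, p1 - p0) + matrix(p0, n, 3, byrow = TRUE) +
    outer(wob, nrm)
  list(pts = pts, r_um = r0 + t * (r1 - r0))
}

# stamp trees into a fresh occupancy grid, visiting edges in `order`
# (a tibble of tree_index/edge rows) and stopping once `target` voxels
# of `count_mask` are covered.  Edge order is shuffled deterministically
# upstream so any stopping point preserves the caliber mix of the forest.
.stamp_trees <- function(trees, spec, allowed_by_region, count_mask,
                         target = Inf, order = NULL) {
  dims <- spec$dim
  voxel_mm <- spec$voxel_um / 1000
  occupied <- array(FALSE, dims)
  counted <- 0L
  edge_log <- list()
  if (is.null(order)) {
    order <- dplyr::bind_rows(lapply(seq_along(trees), function(ti) {
      ne <- nrow(trees[[ti]]$edges)
      if (ne) tibble::tibble(tree_index = ti, edge = seq_len(ne)) else NULL
    }))
  }
  for (k in seq_len(nrow(order))) {
    if (counted >= target) break
    ti <- order$tree_index[k]; i <- order$edge[k]
    tree <- trees[[ti]]
    allowed <- allowed_by_region[[tree$region]]
    cl <- .edge_centreline(tree, i, voxel_mm)
    vox <- cl$pts / voxel_mm - 0.5 # 0-based voxel-centre coords
    hits <- cpp_stamp_spheres(
      vox[, 1], vox[, 2], vox[, 3], cl$r_um / spec$voxel_um,
      occupied, allowed, dims[1], dims[2], dims[3],
      count_mask = count_mask, target = target - counted
    )
    n_in <- if (length(hits)) sum(count_mask[hits]) else 0L
    counted <- counted + n_in
    edge_log[[length(edge_log) + 1]] <- tibble::tibble(
      tree_index = ti, edge = i, region = tree$region,
      radius_um = mean(cl$r_um), n_voxels = length(hits),
      sub_resolution = mean(cl$r_um) < spec$voxel_um / 2
    )
  }
  list(
    occupied = occupied, counted = counted,
    edges = dplyr::bind_rows(edge_log)
  )
}

#' Rasterize a specimen onto delta/beta/label voxel grids
#'
#' Voxelizes the liver lobe, tumor, avascular core, vessel trees and
#' suture into a label grid (priority suture > vessel > tumor > liver >
#' background at overlapping voxels) and fills per-voxel refractive-index
#' decrement (delta) and absorption index (beta) grids from the material
#' table at the reference energy.  Tumor-tree radii are calibrated by a
#' global scale factor (bisection) so that the vessel voxel fraction
#' inside the tumor matches the spec's target vascular density; the
#' residual `|achieved - target| / target` is reported as
#' `density_bound`.  Liver trees are stamped until the liver density
#' target is reached.
#'
#' @param spec A [phantom_spec()].
#' @param trees List of [build_vessel_tree()] results (possibly empty).
#' @param materials Material table as from [material_table()]; the default
#'   evaluates it at 15 keV (stored as the volume's reference energy).
#' @param calibrate Logical: bisect the tumor radius scale to hit the
#'   density target (default TRUE; FALSE stamps radii as given).
#' @return An object of class `phantom_volume`: delta/beta numeric arrays,
#'   integer `label` array, logical region masks, the exact ground-truth
#'   [quant_report()], `density_bound` and per-edge flags.
#' @export
rasterize_phantom <- function(spec, trees, materials = NULL,
                              calibrate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (inherits(trees, "vessel_tree")) trees <- list(trees)
  ref_energy <- 15
  materials <- materials %||% material_table(ref_energy)
  dims <- spec$dim
  voxel_mm <- spec$voxel_um / 1000

  xs <- ((seq_len(dims[1]) - 0.5) * voxel_mm)
  ys <- ((seq_len(dims[2]) - 0.5) * voxel_mm)
  zs <- ((seq_len(dims[3]) - 0.5) * voxel_mm)
  sq_outer <- function(cx, cy, cz, sx = 1, sy = 1, sz = 1) {
    a <- ((xs - cx) / sx)^2
    b <- ((ys - cy) / sy)^2
    cc <- ((zs - cz) / sz)^2
    outer(outer(a, b, `+`), cc, `+`)
  }

  liver <- sq_outer(spec$liver_center_mm[1], spec$liver_center_mm[2],
                    spec$liver_center_mm[3], spec$liver_axes_mm[1],
                    spec$liver_axes_mm[2], spec$liver_axes_mm[3]) <= 1
  tc <- spec$tumor_center_mm
  tumor <- sq_outer(tc[1], tc[2], tc[3]) <= spec$tumor_radius_mm^2

  # avascular (necrotic) core: one sphere holding the target fraction
  avascular <- array(FALSE, dims)
  if (spec$avascular_fraction > 0) {
    ra <- spec$avascular_fraction^(1 / 3) * spec$tumor_radius_mm
    off <- withr::with_seed(spec$seed + 7,
                            0.15 * spec$tumor_radius_mm *
                              { u <- rnorm(3); u / sqrt(sum(u^2)) })
    ac <- tc + off
    avascular <- sq_outer(ac[1], ac[2], ac[3]) <= ra^2 & tumor
  }

  # suture cylinder (computed first: it overrides vessels at labelling,
  # so stamping must avoid it for the density bookkeeping to be exact)
  suture <- array(FALSE, dims)
  if (isTRUE(spec$suture$enabled)) {
    rs_mm <- spec$suture$radius_um / 1000
    hl <- spec$suture$length_frac * spec$tumor_radius_mm
    r2s <- outer((xs - tc[1])^2, (ys - tc[2])^2, `+`)
    inz <- abs(zs - tc[3]) <= hl
    sl <- r2s <= rs_mm^2
    for (k in which(inz)) suture[, , k] <- sl
  }

  allowed <- list(
    tumor = tumor & !avascular & !suture,
    liver = liver & !tumor & !suture
  )
  n_tumor <- sum(tumor)
  target_tumor <- round(spec$vascular_density_pct / 100 * n_tumor)
  target_liver <- round(spec$liver_density_pct / 100 * sum(allowed$liver))

  tumor_trees <- Filter(function(t) t$region == "tumor", trees)
  liver_trees <- Filter(function(t) t$region == "liver", trees)

  # deterministic shuffle of the edge visiting order: stopping at the
  # density target then keeps the full caliber mix at every stage
  shuffled_order <- function(tl, salt) {
    ord <- dplyr::bind_rows(lapply(seq_along(tl), function(ti) {
      ne <- nrow(tl[[ti]]$edges)
      if (ne) tibble::tibble(tree_index = ti, edge = seq_len(ne)) else NULL
    }))
    if (!nrow(ord)) return(ord)
    withr::with_seed(spec$seed + salt, ord[sample.int(nrow(ord)), ])
  }

  # liver trees: stamp until the liver target is met
  liv <- .stamp_trees(liver_trees, spec, allowed, allowed$liver,
                      target = target_liver,
                      order = if (calibrate) shuffled_order(liver_trees, 17L))

  # tumor trees: stamp the shuffled edge sequence up to the density target
  tum <- NULL
  if (length(tumor_trees)) {
    tum <- .stamp_trees(
      tumor_trees, spec, allowed, tumor,
      target = if (calibrate) target_tumor else Inf,
      order = if (calibrate) shuffled_order(tumor_trees, 23L)
    )
  }

  occupied <- liv$occupied
  if (!is.null(tum)) occupied <- occupied | tum$occupied

  label <- array(0L, dims)
  label[liver] <- 1L
  label[tumor] <- 2L
  label[occupied] <- 3L

  if (any(suture)) label[suture] <- 4L

  lut_d <- numeric(5); lut_b <- numeric(5)
  lut_d[materials$label + 1] <- materials$delta
  lut_b[materials$label + 1] <- materials$beta
  lut_b[.label_codes()[["suture"]] + 1] <-
    lut_b[.label_codes()[["suture"]] + 1] * spec$suture$absorption_multiplier
  delta <- array(lut_d[label + 1L], dims)
  beta <- array(lut_b[label + 1L], dims)

  vessel_in_tumor <- sum(label == 3L & tumor)
  vox_mm3 <- (spec$voxel_um * 1e-3)^3
  achieved <- 100 * vessel_in_tumor / n_tumor
  bound <- abs(achieved - spec$vascular_density_pct) /
    spec$vascular_density_pct

  tum_edges <- if (!is.null(tum)) {
    dplyr::filter(tum$edges, .data$n_voxels > 0)
  } else tibble::tibble(radius_um = numeric())
  min_d <- if (nrow(tum_edges)) {
    2 * min(tum_edges$radius_um)
  } else NA_real_
  hist <- diameter_histogram(2 * tum_edges$radius_um, spec$voxel_um)

  gt <- quant_report(
    tumor_volume_mm3 = n_tumor * vox_mm3,
    vascular_volume_mm3 = vessel_in_tumor * vox_mm3,
    min_diameter_um = min_d,
    voxel_um = spec$voxel_um,
    week = spec$week_stage,
    diameter_histogram = hist
  )

  structure(
    list(
      delta = delta, beta = beta, label = label,
      voxel_um = spec$voxel_um, ref_energy_kev = ref_energy,
      masks = list(liver = liver, tumor = tumor, avascular = avascular,
                   suture = suture),
      ground_truth = gt,
      density_bound = bound,
      edges = dplyr::bind_rows(liv$edges,
                               if (!is.null(tum)) tum$edges else NULL),
      spec = spec
    ),
    class = "phantom_volume"
  )
}

#' @export
print.phantom_volume <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    paste0("<phantom_volume> %s voxels @ %g um, week %d\n",
           "  tumor %.4g mm^3, vascular %.4g mm^3, density %.3f%% ",
           "(target residual %.2g%%)\n"),
    paste(dim(x$label), collapse = "x"), x$voxel_um, gt$week,
    gt$tumor_volume_mm3, gt$vascular_volume_mm3, gt$vascular_density_pct,
    100 * x$density_bound
  ))
  invisible(x)
}

#' Build a complete specimen from a spec
#'
#' Convenience wrapper: grows the default liver and tumor vessel trees
#' from the spec's seed and rasterizes them.
#'
#' @inheritParams rasterize_phantom
#' @param ... Passed to [build_vessel_tree()] for the tumor tree.
#' @return A `phantom_volume`.
#' @export
build_phantom <- function(spec, materials = NULL, ...) {
  trees <- list(
    build_vessel_tree(spec, "liver", seed = spec$seed + 101L),
    build_vessel_tree(spec, "tumor", seed = spec$seed + 202L, ...)
  )
  ph <- rasterize_phantom(spec, trees, materials = materials)
  # top up with extra tumor trees if the forest cannot reach the target
  extra <- 0L
  while (ph$density_bound > 0.05 &&
         ph$ground_truth$vascular_density_pct <
           spec$vascular_density_pct && extra < 4L) {
    extra <- extra + 1L
    trees[[length(trees) + 1]] <-
      build_vessel_tree(spec, "tumor", seed = spec$seed + 202L + 13L * extra,
                        ...)
    ph <- rasterize_phantom(spec, trees, materials = materials)
  }
  ph
}

#' Staged four-week specimen series
#'
#' Generates one specimen per week with the staged defaults: tumor
#' volumes strictly increasing, vascular density rising to week 2 then
#' falling, avascular fraction growing at weeks 3-4.  Fields set
#' explicitly on `base_spec` (tumor volume, density, avascular fraction)
#' are held fixed across weeks instead of following the staged defaults.
#'
#' @param base_spec A [phantom_spec()] providing domain, voxel size,
#'   suture and any fixed overrides.
#' @param seed Integer base seed; week w uses `seed + w`.
#' @param weeks Integer vector of stages to generate.
#' @return A list of `phantom_volume` objects, one per week.
#' @export
stage_series <- function(base_spec, seed = base_spec$seed, weeks = 1:4) {
  stopifnot(inherits(base_spec, "phantom_spec"), all(weeks %in% 1:4))
  ex <- base_spec$explicit
  lapply(weeks, function(w) {
    spec_w <- phantom_spec(
      week_stage = w,
      domain_mm = base_spec$domain_mm,
      voxel_um = base_spec$voxel_um,
      tumor_volume_mm3 = if (ex[["tumor_volume"]]) {
        base_spec$tumor_volume_mm3
      } else NULL,
      vascular_density_pct = if (ex[["density"]]) {
        base_spec$vascular_density_pct
      } else NULL,
      avascular_fraction = if (ex[["avascular"]]) {
        base_spec$avascular_fraction
      } else NULL,
      liver_density_pct = base_spec$liver_density_pct,
      suture = base_spec$suture,
      seed = seed + w
    )
    build_phantom(spec_w)
  })
}

#' Ground-truth table of a phantom or phantom series
#'
#' @param x A `phantom_volume` or list of them.
#' @param ... Unused.
#' @return Tibble of ground-truth quant-report rows.
#' @method tidy phantom_volume
#' @export
tidy.phantom_volume <- function(x, ...) {
  out <- x$ground_truth
  class(out) <- class(tibble::tibble())
  out
}
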