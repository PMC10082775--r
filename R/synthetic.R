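# Synthetic two-channel dSTORM scene generator with ground truth.
#
# Emulates the acquisition statistics of 3D dSTORM imaging of
# mitochondrial nucleoids: nucleoids strung along mitochondrial tubules at
# ~1 um spacing, an antibody decoration layer ~20 nm thick, 10-500
# localizations per nucleoid, anisotropic localization noise (sigma_xy <
# sigma_z), hybridization-probe loci carrying regularly spaced labels
# within the probe extent, and uniform background localizations.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.runit <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

.rball <- function(n, radius) {
  .runit(n) * radius * runif(n)^(1 / 3)
}

#' Specification of a synthetic two-channel scene
#'
#' Collects every generator parameter with defaults matching the imaging
#' conditions the pipeline is designed for; the spec (with its seed) fully
#' determines the scene.
#'
#' @param box scene extent in nm (x, y, z); default 12 x 12 x 3 um (a thin
#'   axial slice, as acquired by biplane dSTORM).
#' @param n_tubules number of mitochondrial tubule paths.
#' @param spacing_mean,spacing_sd nucleoid spacing along a tubule (nm).
#' @param diameter_meanlog,diameter_sdlog,diameter_range lognormal law and
#'   truncation range (nm) for true nucleoid diameters.
#' @param shell_thickness antibody decoration layer thickness (nm).
#' @param stain_fill `"shell"` (anti-DNA + antibody fluorophores coat the
#'   nucleoid surface; default) or `"volume"` (staining throughout the
#'   mtDNA volume).
#' @param fluor_density fluorophores per nm^2 of nucleoid surface.
#' @param fluor_range clamp on fluorophores per nucleoid.
#' @param blink_mean mean blinks per fluorophore (1 + geometric).
#' @param sigma_xy,sigma_z lateral / axial localization noise sd (nm).
#' @param loci_mode `"distribution"` (counts drawn from `loci_probs`) or
#'   `"diameter_scaled"` (count grows with the true diameter).
#' @param loci_probs probabilities for 1..k loci per nucleoid.
#' @param loci_per_diameter nm of diameter per locus in
#'   `"diameter_scaled"` mode.
#' @param loci_min_gap if > 0, rejection-sample loci so that the realized
#'   label point clouds of distinct loci in a nucleoid are separated by
#'   more than this gap (nm); loci that cannot be placed are dropped (the
#'   ground truth records realized counts).
#' @param probe_length_bp,label_period_bp probe length and labeling period
#'   (nucleotides); 250/40 gives 6 labels, 1100/40 gives 27.
#' @param probe_extent maximal physical extension of the probe (nm).
#' @param antibody_reach extra reach of the antibody stack on each label
#'   (nm).
#' @param background_density background localizations per um^3.
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(box = c(12000, 12000, 3000),
                       n_tubules = 4,
                       spacing_mean = 1000, spacing_sd = 150,
                       diameter_meanlog = log(100), diameter_sdlog = 0.45,
                       diameter_range = c(40, 400),
                       shell_thickness = 20,
                       stain_fill = c("shell", "volume"),
                       fluor_density = 1.5e-3,
                       fluor_range = c(12, 140),
                       blink_mean = 3,
                       sigma_xy = 15, sigma_z = 30,
                       loci_mode = c("distribution", "diameter_scaled"),
                       loci_probs = c(0.40, 0.19, 0.16, 0.11, 0.08, 0.06),
                       loci_per_diameter = 70,
                       loci_min_gap = 0,
                       probe_length_bp = 250, label_period_bp = 40,
                       probe_extent = 60, antibody_reach = 20,
                       background_density = 0.2,
                       seed = 1L) {
  stain_fill <- match.arg(stain_fill)
  loci_mode <- match.arg(loci_mode)
  spec <- list(box = box, n_tubules = n_tubules,
               spacing_mean = spacing_mean, spacing_sd = spacing_sd,
               diameter_meanlog = diameter_meanlog,
               diameter_sdlog = diameter_sdlog,
               diameter_range = diameter_range,
               shell_thickness = shell_thickness,
               stain_fill = stain_fill,
               fluor_density = fluor_density, fluor_range = fluor_range,
               blink_mean = blink_mean,
               sigma_xy = sigma_xy, sigma_z = sigma_z,
               loci_mode = loci_mode, loci_probs = loci_probs,
               loci_per_diameter = loci_per_diameter,
               loci_min_gap = loci_min_gap,
               probe_length_bp = probe_length_bp,
               label_period_bp = label_period_bp,
               probe_extent = probe_extent,
               antibody_reach = antibody_reach,
               background_density = background_density,
               seed = as.integer(seed))
  lens <- unlist(spec[c("spacing_mean", "shell_thickness", "probe_extent",
                        "label_period_bp", "probe_length_bp")])
  if (any(lens <= 0)) stop("all lengths must be positive")
  structure(spec, class = "scene_spec")
}

#' Label positions along a hybridization probe
#'
#' Probes carry a fluorophore (or biotin) every `label_period` nucleotides,
#' so a probe of `length_bp` nucleotides holds
#' `floor(length_bp / label_period)` labels: 6 for the 250 bp probe, 27
#' for the 1100 bp probe.
#'
#' @param length_bp probe length in nucleotides.
#' @param label_period labeling period in nucleotides (default 40).
#' @return integer vector of label positions (nucleotides).
#' @export
make_probe <- function(length_bp, label_period = 40) {
  if (!is.numeric(length_bp) || length_bp <= 0 ||
      !is.numeric(label_period) || label_period <= 0)
    stop("length_bp and label_period must be positive")
  n <- floor(length_bp / label_period)
  if (n == 0L) return(integer(0))
  as.integer(label_period * seq_len(n))
}

# random tubule polylines: gently wandering paths, mostly lateral
.make_tubules <- function(spec) {
  box <- spec$box
  lapply(seq_len(spec$n_tubules), function(i) {
    start <- c(runif(1, 0.1, 0.9) * box[1], runif(1, 0.1, 0.9) * box[2],
               runif(1, 0.25, 0.75) * box[3])
    ang <- runif(1, 0, 2 * pi)
    dir <- c(cos(ang), sin(ang), runif(1, -0.1, 0.1))
    dir <- dir / sqrt(sum(dir^2))
    pts <- list(start)
    pos <- start
    step <- 600
    for (k in seq_len(40)) {
      ang2 <- rnorm(1, 0, 0.25)
      rot <- matrix(c(cos(ang2), -sin(ang2), 0,
                      sin(ang2), cos(ang2), 0,
                      0, 0, 1), 3, 3, byrow = TRUE)
      dir <- as.vector(rot %*% dir)
      dir[3] <- dir[3] + rnorm(1, 0, 0.03)
      dir <- dir / sqrt(sum(dir^2))
      nxt <- pos + step * dir
      if (any(nxt < 0.05 * box) || any(nxt > 0.95 * box)) break
      pts[[length(pts) + 1L]] <- nxt
      pos <- nxt
    }
    if (length(pts) < 2L)  # clamp a second waypoint inside the box
      pts[[2L]] <- pmin(pmax(pos + step * dir, 0.05 * box), 0.95 * box)
    do.call(rbind, pts)
  })
}

# positions at arclength s along a polyline
.along_path <- function(path, svals) {
  seglen <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seglen))
  t(vapply(svals, function(s) {
    if (s >= cum[length(cum)]) return(path[nrow(path), ])
    i <- findInterval(s, cum)
    f <- (s - cum[i]) / seglen[i]
    path[i, ] + f * (path[i + 1, ] - path[i, ])
  }, numeric(3)))
}

.truncated_lnorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rlnorm(n, meanlog, sdlog)
    out <- c(out, d[d >= range[1] & d <= range[2]])
  }
  out[seq_len(n)]
}

# emission: blinks per fluorophore (1 + geometric, mean blink_mean) plus
# anisotropic localization noise
.emit <- function(base, spec) {
  nf <- nrow(base)
  nb <- 1L + if (spec$blink_mean > 1)
    rgeom(nf, 1 / spec$blink_mean) else rep(0L, nf)
  pos <- base[rep(seq_len(nf), nb), , drop = FALSE]
  n <- nrow(pos)
  pos + cbind(rnorm(n, 0, spec$sigma_xy), rnorm(n, 0, spec$sigma_xy),
              rnorm(n, 0, spec$sigma_z))
}

# realized (pre-noise) label fluorophore positions of one probe locus
.locus_labels <- function(anchor, spec) {
  sites <- make_probe(spec$probe_length_bp, spec$label_period_bp)
  if (!length(sites)) sites <- spec$label_period_bp  # at least one label
  u <- .runit(1)[1, ]
  off <- spec$probe_extent * sites / spec$probe_length_bp
  lab <- matrix(anchor, length(off), 3, byrow = TRUE) + outer(off, u)
  lab + .rball(nrow(lab), spec$antibody_reach)
}

#' Simulate a two-channel dSTORM scene
#'
#' Places nucleoids along tubule paths at ~1 um spacing, decorates each
#' with channel-1 fluorophores (surface shell or filled volume), plants
#' probe loci whose labels blink in channel 2, adds uniform background,
#' and applies the blink multiplicity and localization noise of the spec.
#' The scene is deterministic given the spec (which includes the seed).
#'
#' @param spec a [scene_spec()].
#' @return list with `table` (a [loc_table]; channel 1 = nucleoid stain,
#'   channel 2 = probe) and `truth` (class `scene_ground_truth`: nucleoid
#'   table, locus table, and a per-localization parent table).
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    tubules <- .make_tubules(spec)
    centers <- list(); diam <- numeric(0)
    for (path in tubules) {
      total <- sum(sqrt(rowSums(diff(path)^2)))
      s <- runif(1, 0, spec$spacing_mean)
      svals <- numeric(0)
      while (s < total) {
        svals <- c(svals, s)
        s <- s + max(200, rnorm(1, spec$spacing_mean, spec$spacing_sd))
      }
      if (length(svals))
        centers[[length(centers) + 1L]] <- .along_path(path, svals)
    }
    if (!length(centers)) stop("spec yielded zero nucleoids")
    centers <- do.call(rbind, centers)
    nn <- nrow(centers)
    diam <- .truncated_lnorm(nn, spec$diameter_meanlog, spec$diameter_sdlog,
                             spec$diameter_range)

    loc <- list(); parent <- list()
    truth_loci <- list()
    n_loci_real <- integer(nn)

    target_loci <- switch(spec$loci_mode,
      distribution = sample.int(length(spec$loci_probs), nn, replace = TRUE,
                                prob = spec$loci_probs),
      diameter_scaled = pmax(1L, as.integer(floor(diam /
                                                  spec$loci_per_diameter))))

    for (i in seq_len(nn)) {
      r <- diam[i] / 2
      # channel 1: antibody fluorophores
      area <- 4 * pi * r^2
      nf <- min(max(round(area * spec$fluor_density), spec$fluor_range[1]),
                spec$fluor_range[2])
      base1 <- if (spec$stain_fill == "shell") {
        .runit(nf) * runif(nf, r, r + spec$shell_thickness) +
          matrix(centers[i, ], nf, 3, byrow = TRUE)
      } else {
        .rball(nf, r + spec$shell_thickness) +
          matrix(centers[i, ], nf, 3, byrow = TRUE)
      }
      e1 <- .emit(base1, spec)
      loc[[length(loc) + 1L]] <- cbind(e1, 1)
      parent[[length(parent) + 1L]] <-
        data.frame(parent = "nucleoid", nucleoid_id = i, locus_id = NA_integer_)[
          rep(1L, nrow(e1)), ]

      # channel 2: probe loci with optional realized-gap enforcement
      placed <- list()
      for (k in seq_len(target_loci[i])) {
        ok <- FALSE
        for (try in seq_len(50L)) {
          anchor <- centers[i, ] + .rball(1, r)[1, ]
          lab <- .locus_labels(anchor, spec)
          if (spec$loci_min_gap > 0 && length(placed)) {
            gaps <- vapply(placed, function(pl)
              sqrt(min(.cross_dist2(lab, pl$lab))), numeric(1))
            if (any(gaps <= spec$loci_min_gap)) next
          }
          placed[[length(placed) + 1L]] <- list(anchor = anchor, lab = lab)
          ok <- TRUE
          break
        }
        if (!ok) break  # nucleoid cannot host more separated loci
      }
      n_loci_real[i] <- length(placed)
      for (k in seq_along(placed)) {
        e2 <- .emit(placed[[k]]$lab, spec)
        loc[[length(loc) + 1L]] <- cbind(e2, 2)
        parent[[length(parent) + 1L]] <-
          data.frame(parent = "locus", nucleoid_id = i, locus_id = k)[
            rep(1L, nrow(e2)), ]
        truth_loci[[length(truth_loci) + 1L]] <-
          data.frame(nucleoid_id = i, locus_id = k,
                     x = placed[[k]]$anchor[1], y = placed[[k]]$anchor[2],
                     z = placed[[k]]$anchor[3])
      }
    }

    # background
    vol_um3 <- prod(spec$box) / 1e9
    nbg <- round(spec$background_density * vol_um3)
    if (nbg > 0) {
      bg <- cbind(runif(nbg, 0, spec$box[1]), runif(nbg, 0, spec$box[2]),
                  runif(nbg, 0, spec$box[3]))
      chb <- 1L + rbinom(nbg, 1L, 0.5)
      loc[[length(loc) + 1L]] <- cbind(bg, chb)
      parent[[length(parent) + 1L]] <-
        data.frame(parent = "background", nucleoid_id = NA_integer_,
                   locus_id = NA_integer_)[rep(1L, nbg), ]
    }

    locm <- do.call(rbind, loc)
    table <- loc_table(x = locm[, 1], y = locm[, 2], z = locm[, 3],
                       channel = locm[, 4],
                       metadata = list(generator = "simulate_scene",
                                       seed = spec$seed))
    truth <- structure(
      list(nucleoids = data.frame(id = seq_len(nn),
                                  x = centers[, 1], y = centers[, 2],
                                  z = centers[, 3], diameter = diam,
                                  n_loci = n_loci_real),
           loci = if (length(truth_loci)) do.call(rbind, truth_loci)
                  else data.frame(nucleoid_id = integer(0),
                                  locus_id = integer(0), x = numeric(0),
                                  y = numeric(0), z = numeric(0)),
           parent = {
             p <- do.call(rbind, parent); rownames(p) <- NULL; p
           },
           spec = unclass(spec)),
      class = "scene_ground_truth")
    list(table = table, truth = truth)
  })
}

#' Completely spatially random reference pattern
#'
#' `n` points uniform in a cube of the given edge (nm); the CSR null for
#' the Ripley statistics.
#'
#' @param n number of points (>= 2).
#' @param box_edge cube edge in nm.
#' @param seed integer seed.
#' @return a single-channel [loc_table].
#' @export
simulate_csr <- function(n, box_edge, seed = 1L) {
  stopifnot(n >= 2)
  .with_seed(seed, {
    loc_table(x = runif(n, 0, box_edge), y = runif(n, 0, box_edge),
              z = runif(n, 0, box_edge), channel = rep(1L, n),
              metadata = list(generator = "simulate_csr", seed = seed,
                              box_edge = box_edge))
  })
}

#' Write / read scene ground truth as JSON
#'
#' @param truth a `scene_ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_ground_truth"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "scene_ground_truth")
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  cat(sprintf(
    "scene_ground_truth: %d nucleoid(s), %d probe loci, %d localization(s)\n",
    nrow(x$nucleoids), nrow(x$loci), nrow(x$parent)))
  invisible(x)
}
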