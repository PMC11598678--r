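# Hessian-eigenvalue vein centerline extraction.
#
# Veins are locally linear dark tubes. At a tube the intensity profile
# across the axis is a dark valley, so the larger-magnitude Hessian
# eigenvalue is strongly positive across the tube while the along-axis
# eigenvalue stays near zero. A Frangi-style two-eigenvalue line filter
# restricted to that dark polarity yields a vesselness response; its
# thresholded support is thinned to a unit-width skeleton and refined.

#' Hessian filter configuration
#'
#' @param sigma Gaussian scales in pixels (vector for multi-scale maximum).
#' @param response_threshold Nonnegative response threshold; pixels with
#'   response strictly above it survive.
#' @param beta Frangi blobness control (ratio term).
#' @param c Frangi structureness control; `NULL` uses half the maximum
#'   structureness of the image at each scale (Frangi's heuristic).
#' @return Object of class `hessian_config`.
#' @export
hessian_config <- function(sigma = c(2, 3, 4), response_threshold = 0.15,
                           beta = 0.5, c = NULL) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (response_threshold < 0)
    stop("response_threshold must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, response_threshold = response_threshold,
                 beta = beta, c = c), class = "hessian_config")
}

#' Skeleton refinement configuration
#'
#' @param min_region_area Components smaller than this many pixels are
#'   removed.
#' @param max_gap_distance Endpoint pairs of different components closer
#'   than this (pixels) are joined by a straight rasterised segment.
#' @param spur_length Branches shorter than this hanging off a junction are
#'   pruned.
#' @export
refine_config <- function(min_region_area = 50, max_gap_distance = 15,
                          spur_length = 10) {
  if (min_region_area < 0 || max_gap_distance < 0 || spur_length < 0)
    stop("refine parameters must be nonnegative", call. = FALSE)
  structure(list(min_region_area = min_region_area,
                 max_gap_distance = max_gap_distance,
                 spur_length = spur_length), class = "refine_config")
}

#' Hessian eigenvalue maps at one Gaussian scale
#'
#' The image is smoothed with a Gaussian of scale `sigma` and second
#' partials are taken by central differences, giving the per-pixel symmetric
#' Hessian \[\[Irr, Irc\], \[Irc, Icc\]\] (row = first axis). Eigenvalues are
#' returned ordered by magnitude, `|l1| <= |l2|`. No scale normalisation is
#' applied here; the multi-scale response weights scales by sigma^2.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian scale (> 0).
#' @return List with matrices `l1` and `l2`.
#' @export
hessian_eigenvalues <- function(img, sigma) {
  assert_gray(img)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  S <- gaussian_blur(img, sigma)
  d2 <- c(1, -2, 1)
  d1 <- c(-0.5, 0, 0.5)
  Irr <- cpp_sepconv_reflect(S, d2, 1)
  Icc <- cpp_sepconv_reflect(S, 1, d2)
  Irc <- cpp_sepconv_reflect(S, d1, d1)
  tr2 <- (Irr + Icc) / 2
  disc <- sqrt(((Irr - Icc) / 2)^2 + Irc^2)
  ea <- tr2 + disc
  eb <- tr2 - disc
  swap <- abs(ea) < abs(eb)
  l2 <- ifelse(swap, eb, ea)
  l1 <- ifelse(swap, ea, eb)
  list(l1 = l1, l2 = l2)
}

#' Dark-tube vesselness response from Hessian eigenvalues
#'
#' Frangi's two-eigenvalue line filter with fixed dark-on-bright polarity:
#' the response is zero wherever `l2 <= 0` (a dark tube has a positive
#' across-axis second derivative) and otherwise
#' `exp(-Rb^2/(2 beta^2)) * (1 - exp(-S^2/(2 c^2)))` with `Rb = l1/l2` and
#' structureness `S = sqrt(l1^2 + l2^2)`.
#'
#' @param l1,l2 Eigenvalue maps from [hessian_eigenvalues()].
#' @param beta,c Filter controls; see [hessian_config()].
#' @return Response matrix in \[0, 1\].
#' @export
vein_response <- function(l1, l2, beta = 0.5, c = NULL) {
  if (!identical(dim(l1), dim(l2)))
    stop("eigenvalue maps must have identical shape", call. = FALSE)
  S2 <- l1^2 + l2^2
  if (is.null(c)) c <- max(sqrt(max(S2)) / 2, .Machine$double.eps)
  Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c^2)))
  v[l2 <= 0] <- 0
  v
}

#' Multi-scale vesselness of an image
#'
#' Per-pixel maximum of the dark-tube response over the configured scales,
#' with eigenvalues weighted by sigma^2 so responses are comparable across
#' scales.
#'
#' @param img Image matrix in \[0,1\].
#' @param cfg A [hessian_config()].
#' @return Response matrix.
#' @export
vesselness <- function(img, cfg = hessian_config()) {
  resp <- matrix(0, nrow(img), ncol(img))
  for (s in cfg$sigma) {
    e <- hessian_eigenvalues(img, s)
    v <- vein_response(e$l1 * s^2, e$l2 * s^2, beta = cfg$beta, c = cfg$c)
    resp <- pmax(resp, v)
  }
  resp
}

#' Extract a unit-width centerline skeleton from a response map
#'
#' Pixels with response strictly above the threshold are thinned
#' (Zhang-Suen) to an 8-connected skeleton.
#'
#' @param response Response matrix.
#' @param cfg A [hessian_config()] (only the threshold is used), or a
#'   number interpreted as the threshold.
#' @return Binary integer matrix.
#' @export
extract_centerline <- function(response, cfg = hessian_config()) {
  thr <- if (is.numeric(cfg)) cfg else cfg$response_threshold
  m <- matrix(as.integer(response > thr), nrow(response), ncol(response))
  if (!any(m == 1L)) {
    warning("no pixels above the response threshold; empty centerline")
    return(m)
  }
  cpp_thin(m)
}

skeleton_neighbors <- function(mask, i, j) {
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] > 0)
      out <- rbind(out, c(ii, jj))
  }
  out
}

# Remove branches of length <= spur_length that hang off a junction. Open
# curve ends that do not terminate at a junction are left alone.
prune_spurs <- function(mask, spur_length) {
  if (spur_length < 1) return(mask)
  deg <- neighbor_count(mask)
  ends <- which(mask > 0 & deg == 1)
  H <- nrow(mask)
  for (e in ends) {
    i <- (e - 1L) %% H + 1L; j <- (e - 1L) %/% H + 1L
    path <- list(c(i, j))
    prev <- c(NA, NA)
    cur <- c(i, j)
    hit_junction <- FALSE
    junction <- c(NA, NA)
    while (length(path) <= spur_length) {
      nb <- skeleton_neighbors(mask, cur[1], cur[2])
      if (!is.null(nb) && !is.na(prev[1]))
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      if (is.null(nb) || nrow(nb) == 0) break       # isolated end
      if (nrow(nb) > 1) {       # cur itself is the branching pixel
        hit_junction <- TRUE
        junction <- cur
        path <- path[-length(path)]
        break
      }
      nxt <- nb[1, ]
      if (neighbor_count_at(mask, nxt[1], nxt[2]) > 2) {
        hit_junction <- TRUE
        junction <- nxt
        break
      }
      prev <- cur; cur <- nxt
      path[[length(path) + 1L]] <- cur
    }
    if (hit_junction && length(path) <= spur_length) {
      for (p in path) mask[p[1], p[2]] <- 0L
      # the attachment pixel is deleted too when it is a simple point,
      # i.e. its remaining neighbours stay connected without it
      if (!is.na(junction[1]) && is_simple_point(mask, junction[1],
                                                 junction[2]))
        mask[junction[1], junction[2]] <- 0L
    }
  }
  mask
}

# TRUE if removing (i, j) leaves its remaining 8-neighbours in a single
# 8-connected cluster (so deletion cannot split the skeleton locally)
is_simple_point <- function(mask, i, j) {
  nb <- skeleton_neighbors(mask, i, j)
  if (is.null(nb) || nrow(nb) < 2) return(TRUE)
  n <- nrow(nb)
  adj <- abs(outer(nb[, 1], nb[, 1], "-")) <= 1 &
    abs(outer(nb[, 2], nb[, 2], "-")) <= 1
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    k <- queue[[1]]; queue <- queue[-1]
    nxt <- which(adj[k, ] & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

neighbor_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- mask
  s <- matrix(0L, H, W)
  for (dj in 0:2) for (di in 0:2) {
    if (di == 1 && dj == 1) next
    s <- s + p[di + 1:H, dj + 1:W]
  }
  s
}

neighbor_count_at <- function(mask, i, j) {
  nb <- skeleton_neighbors(mask, i, j)
  if (is.null(nb)) 0L else nrow(nb)
}

#' Refine a centerline skeleton
#'
#' Applies, in order: spur pruning (short branches off junctions), joining
#' of nearby endpoints of different components by straight segments, and
#' removal of small connected components. Joining never splits a component,
#' so the component count never increases.
#'
#' @param skel Binary skeleton matrix.
#' @param cfg A [refine_config()].
#' @return Refined binary skeleton.
#' @export
refine_centerline <- function(skel, cfg = refine_config()) {
  stopifnot(is_binary(skel))
  m <- matrix(as.integer(skel > 0), nrow(skel), ncol(skel))
  m <- prune_spurs(m, cfg$spur_length)
  # join endpoints of distinct components
  if (cfg$max_gap_distance > 0) {
    lab <- label8(m)
    deg <- neighbor_count(m)
    ends <- which(m > 0 & deg <= 1)
    if (length(ends) >= 2) {
      H <- nrow(m)
      ei <- (ends - 1L) %% H + 1L; ej <- (ends - 1L) %/% H + 1L
      el <- lab[ends]
      pairs <- NULL
      for (a in seq_along(ends)) for (b in seq_along(ends)) {
        if (b <= a || el[a] == el[b]) next
        d <- sqrt((ei[a] - ei[b])^2 + (ej[a] - ej[b])^2)
        if (d <= cfg$max_gap_distance) pairs <- rbind(pairs, c(a, b, d))
      }
      if (!is.null(pairs)) {
        pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
        comp_of <- seq_len(max(el))         # union-find over component labels
        find <- function(x) { while (comp_of[x] != x) x <- comp_of[x]; x }
        for (k in seq_len(nrow(pairs))) {
          a <- pairs[k, 1]; b <- pairs[k, 2]
          ra <- find(el[a]); rb <- find(el[b])
          if (ra == rb) next
          seg <- bresenham(c(ei[a], ej[a]), c(ei[b], ej[b]))
          m[seg] <- 1L
          comp_of[ra] <- rb
        }
      }
    }
  }
  # eliminate residual small components
  if (cfg$min_region_area > 0) {
    lab <- label8(m)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], max(lab))
      kill <- which(sizes < cfg$min_region_area)
      m[lab %in% kill] <- 0L
    }
  }
  m
}

#' Centerline coordinates of a skeleton mask
#'
#' @param skel Binary skeleton matrix.
#' @return Two-column (row, col) integer matrix.
#' @export
centerline_points <- function(skel) {
  which(skel > 0, arr.ind = TRUE)[, c("row", "col"), drop = FALSE]
}
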