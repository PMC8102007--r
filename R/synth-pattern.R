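# Ground-truthed synthetic pattern images and developmental series.
#
# The generator renders the cellular anatomy the segmentation stage
# assumes: dark melanophore disks tiling the dark elements of a layout,
# small orange xanthophore disks tiling the light regions, a light-pink
# background, and optional near-white glare disks emulating iridophore
# reflections.

# Logical H x W matrix of the layout's dark elements. Errors when the
# element geometry cannot fit the image.
elementRegion <- function(spec) {
  H <- spec@imageHeight; W <- spec@imageWidth
  n <- spec@nElements; w <- spec@elementWidth
  y <- matrix(seq_len(H) - 1, H, W)        # 0-based row coordinate
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  switch(spec@layout,
    blank = matrix(FALSE, H, W),
    uniform = matrix(TRUE, H, W),
    horizontal_stripes = {
      if (n < 1L) stop("horizontal_stripes needs nElements >= 1")
      if (n * w > H)
        stop(sprintf("element geometry exceeds image bounds: %d stripes of width %g do not fit height %d", n, w, H))
      centers <- (seq_len(n) - 0.5) * H / n - 0.5
      reg <- matrix(FALSE, H, W)
      for (c0 in centers) reg <- reg | (abs(y - c0) <= w / 2)
      reg
    },
    vertical_bars = {
      if (n < 1L) stop("vertical_bars needs nElements >= 1")
      if (n * w > W)
        stop(sprintf("element geometry exceeds image bounds: %d bars of width %g do not fit width %d", n, w, W))
      centers <- (seq_len(n) - 0.5) * W / n - 0.5
      reg <- matrix(FALSE, H, W)
      for (c0 in centers) reg <- reg | (abs(x - c0) <= w / 2)
      reg
    },
    spots = {
      if (n < 1L) stop("spots needs nElements >= 1")
      ctr <- spotCenters(H, W, n)
      if (w > min(H / ctr$nr, W / ctr$nc))
        stop(sprintf("element geometry exceeds image bounds: spot diameter %g does not fit a %d x %d grid in %d x %d px", w, ctr$nr, ctr$nc, H, W))
      reg <- matrix(FALSE, H, W)
      for (i in seq_len(n))
        reg <- reg | ((x - ctr$x[i])^2 + (y - ctr$y[i])^2 <= (w / 2)^2)
      reg
    })
}

# Grid of spot centers (0-based coordinates), row-major, first n kept.
spotCenters <- function(H, W, n) {
  nr <- max(1L, floor(sqrt(n)))
  nc <- ceiling(n / nr)
  ys <- (seq_len(nr) - 0.5) * H / nr - 0.5
  xs <- (seq_len(nc) - 0.5) * W / nc - 0.5
  g <- expand.grid(x = xs, y = ys)[seq_len(n), ]
  list(x = g$x, y = g$y, nr = nr, nc = nc)
}

# Jittered lattice restricted to a region (0-based coordinates).
# hex = TRUE gives the offset-row hexagonal packing seen inside dark
# elements; hex = FALSE a plain square grid.
latticeInRegion <- function(region, spacing, jitterSD, margin, hex = TRUE) {
  H <- nrow(region); W <- ncol(region)
  dy <- if (hex) spacing * sqrt(3) / 2 else spacing
  ys <- seq(spacing / 2, H - 1, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    xoff <- if (hex && i %% 2 == 0) spacing / 2 else 0
    xs <- seq(spacing / 2 + xoff, W - 1, by = spacing)
    cbind(x = xs, y = rep(ys[i], length(xs)))
  }))
  if (is.null(pts) || !nrow(pts)) return(pts)
  pts[, "x"] <- pts[, "x"] + rnorm(nrow(pts), 0, jitterSD)
  pts[, "y"] <- pts[, "y"] + rnorm(nrow(pts), 0, jitterSD)
  keep <- pts[, "x"] >= margin & pts[, "x"] <= W - 1 - margin &
    pts[, "y"] >= margin & pts[, "y"] <= H - 1 - margin
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(pts)
  inside <- region[cbind(round(pts[, "y"]) + 1L, round(pts[, "x"]) + 1L)]
  pts[inside, , drop = FALSE]
}

# Render an RGB image from cell positions; glare disks drawn last.
renderPattern <- function(spec, mel, melR, xan, xanR) {
  H <- spec@imageHeight; W <- spec@imageWidth
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- spec@backgroundColor[ch]
  if (!is.null(xan) && nrow(xan))
    img <- stampDisksRGB(img, xan[, "x"], xan[, "y"], xanR,
                         spec@xanthophoreColor)
  if (!is.null(mel) && nrow(mel))
    img <- stampDisksRGB(img, mel[, "x"], mel[, "y"], melR,
                         spec@melanophoreColor)
  if (spec@glareDensity > 0) {
    nGlare <- max(1L, round(spec@glareDensity * H * W / 15.67))
    gx <- runif(nGlare, 0, W - 1); gy <- runif(nGlare, 0, H - 1)
    gr <- sample(1:3, nGlare, replace = TRUE)
    val <- sample(250:255, nGlare, replace = TRUE)
    for (i in seq_len(nGlare))
      img <- stampDisksRGB(img, gx[i], gy[i], gr[i], rep(val[i], 3))
  }
  round(img)
}

xanRadiusFor <- function(spec) max(2, round(spec@cellRadius / 2))

# Melanophore placement: structured layouts use a jittered hexagonal
# lattice (the regular packing seen inside dark elements). The uniform
# layout -- a diffuse, fully melanized flank -- uses a slightly denser
# jittered square grid whose element disks tile the whole ROI, so its
# mask carries no axis structure.
placeMelanophores <- function(spec, region, margin) {
  if (spec@layout == "uniform")
    latticeInRegion(region, 0.92 * spec@cellSpacing, spec@jitterSD,
                    margin, hex = FALSE)
  else
    latticeInRegion(region, spec@cellSpacing, spec@jitterSD, margin)
}

#' Generate a ground-truthed synthetic pattern image
#'
#' Renders an idealized flank pattern: melanophores tile the layout's dark
#' elements on a jittered hexagonal lattice at `cellSpacing`, xanthophores
#' tile the light regions, and near-white glare disks are sprinkled at
#' `glareDensity`. Every planted cell is recorded in the returned ground
#' truth together with the true element mask, so segmentation and pattern
#' metrics can be validated against known answers.
#'
#' Identical seeds give bit-identical output. Cells are drawn as filled
#' disks with Gaussian-perturbed radii; a blank layout returns a pure
#' background image with no cells.
#'
#' @param spec a [PatternSpec-class].
#' @return list with elements `image` (H x W x 3 array, 0--255) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' out <- genPatternImage(patternSpec("horizontal_stripes", seed = 7))
#' nCells(out$truth@cells)
#' @export
genPatternImage <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    region <- elementRegion(spec)
    margin <- ceiling(spec@cellRadius) + 1
    mel <- placeMelanophores(spec, region, margin)
    xan <- if (spec@layout == "blank") NULL
    else latticeInRegion(!region, spec@cellSpacing, spec@jitterSD, 5)
    melR <- if (!is.null(mel) && nrow(mel))
      pmax(2, rnorm(nrow(mel), spec@cellRadius, 0.05 * spec@cellRadius))
    else numeric()
    xanR <- xanRadiusFor(spec)
    img <- renderPattern(spec, mel, melR, xan, xanR)
    nm <- if (is.null(mel)) 0L else nrow(mel)
    nx <- if (is.null(xan)) 0L else nrow(xan)
    cs <- cellSet(
      id = seq_len(nm + nx),
      x = c(if (nm) mel[, "x"], if (nx) xan[, "x"]),
      y = c(if (nm) mel[, "y"], if (nx) xan[, "y"]),
      area = c(if (nm) vapply(melR, function(r) nrow(diskOffsets(r)), 0),
               rep(nrow(diskOffsets(xanR)), nx)),
      class = c(rep("melanophore", nm), rep("xanthophore", nx)),
      frame = 0L)
    truth <- new("GroundTruth", cells = cs, elementMask = region * 255,
                 displacements = data.frame(id = integer(), day = integer(),
                                            dx = numeric(), dy = numeric()))
    list(image = img, truth = truth)
  })
}

#' Generate a developmental image series with persistent cell identities
#'
#' Emulates daily imaging of adult pattern formation: melanophores persist
#' across frames under a chosen motion regime, new cells appear unpaired
#' (de novo differentiation from unmelanized precursors, not division),
#' and cells may be lost. True per-cell, per-day displacement vectors are
#' recorded.
#'
#' Motion regimes: `"stripe_hold"` keeps cells near their positions (small
#' random wiggle, step length at most `0.2 * drift`); `"spot_consolidate"`
#' assigns every cell a personal target near the closest of a set of spot
#' attractor centers -- the attractor plus the cell's own offset shrunk by
#' `consolidation`, so cells pack into spots without collapsing onto a
#' point -- and moves it there by exactly `min(drift, distance)` px per
#' day. This is the stripes-breaking-into-spots regime.
#'
#' @param spec a [PatternSpec-class] defining the day-1 pattern.
#' @param nDays number of daily frames, >= 2.
#' @param appearanceRate expected new melanophores per day (Poisson).
#' @param drift maximum per-day displacement, px/day, >= 0.
#' @param motionMode `"stripe_hold"` or `"spot_consolidate"`.
#' @param lossRate per-cell, per-day probability of cell loss.
#' @param nSpotTargets number of spot attractor centers
#'   (`spot_consolidate` only); defaults to three per dark element.
#' @param consolidation fraction of each cell's offset from its attractor
#'   retained at the target (`spot_consolidate` only); smaller values give
#'   tighter spots.
#' @return list with `images` (list of `nDays` RGB arrays) and `truth`
#'   (a [GroundTruth-class] whose cells carry `frame` = day and whose
#'   `displacements` hold the true per-day vectors).
#' @export
genDevelopmentSeries <- function(spec, nDays, appearanceRate = 2,
                                 drift = 2, motionMode = c("stripe_hold",
                                                           "spot_consolidate"),
                                 lossRate = 0, nSpotTargets = NULL,
                                 consolidation = 0.35) {
  validObject(spec)
  motionMode <- match.arg(motionMode)
  if (nDays < 2) stop("nDays must be >= 2")
  if (drift < 0) stop("drift must be >= 0")
  if (lossRate < 0 || lossRate > 1) stop("lossRate must be in [0, 1]")
  withSeed(spec@seed, {
    H <- spec@imageHeight; W <- spec@imageWidth
    region <- elementRegion(spec)
    margin <- ceiling(spec@cellRadius) + 1
    mel <- placeMelanophores(spec, region, margin)
    if (is.null(mel)) mel <- cbind(x = numeric(), y = numeric())
    xan <- if (spec@layout == "blank") NULL
    else latticeInRegion(!region, spec@cellSpacing, spec@jitterSD, 5)
    xanR <- xanRadiusFor(spec)

    if (motionMode == "spot_consolidate") {
      if (is.null(nSpotTargets)) nSpotTargets <- max(4L, 3L * spec@nElements)
      tc <- spotCenters(H, W, nSpotTargets)
      # keep attractors inside the dark region where possible
      inReg <- region[cbind(pmin(pmax(round(tc$y) + 1L, 1L), H),
                            pmin(pmax(round(tc$x) + 1L, 1L), W))]
      if (any(inReg)) { tc$x <- tc$x[inReg]; tc$y <- tc$y[inReg] }
      targets <- cbind(x = tc$x, y = tc$y)
    }

    # personal target: nearest attractor + the cell's own offset shrunk,
    # so converging cells keep distinct, spaced destinations
    targetOf <- function(x, y) {
      if (motionMode != "spot_consolidate" || !nrow(targets))
        return(cbind(tx = x, ty = y))
      dx <- outer(x, targets[, "x"], "-")
      dy <- outer(y, targets[, "y"], "-")
      j <- max.col(-(dx * dx + dy * dy), ties.method = "first")
      cbind(tx = targets[j, "x"] + consolidation * (x - targets[j, "x"]),
            ty = targets[j, "y"] + consolidation * (y - targets[j, "y"]))
    }

    st <- data.frame(id = seq_len(nrow(mel)), x = mel[, "x"], y = mel[, "y"],
                     r = pmax(2, rnorm(nrow(mel), spec@cellRadius,
                                       0.05 * spec@cellRadius)))
    if (motionMode == "spot_consolidate" && nrow(st)) {
      tg <- targetOf(st$x, st$y); st$tx <- tg[, "tx"]; st$ty <- tg[, "ty"]
    }
    nextId <- nrow(st) + 1L
    darkIdx <- which(region)
    images <- vector("list", nDays)
    allCells <- list(); disp <- list()

    recordFrame <- function(day) {
      data.frame(id = st$id, x = st$x, y = st$y,
                 area = vapply(st$r, function(r) nrow(diskOffsets(r)), 0),
                 class = "melanophore", frame = as.integer(day))
    }

    for (day in seq_len(nDays)) {
      if (day > 1L) {
        x0 <- st$x; y0 <- st$y
        if (nrow(st)) {
          if (motionMode == "spot_consolidate" && nrow(targets)) {
            tx <- st$tx; ty <- st$ty
            d <- sqrt((tx - st$x)^2 + (ty - st$y)^2)
            step <- pmin(drift, d)
            ok <- d > 1e-12
            st$x[ok] <- st$x[ok] + step[ok] * (tx[ok] - st$x[ok]) / d[ok]
            st$y[ok] <- st$y[ok] + step[ok] * (ty[ok] - st$y[ok]) / d[ok]
          } else if (drift > 0) {
            ang <- runif(nrow(st), 0, 2 * pi)
            len <- runif(nrow(st), 0, 0.2 * drift)
            st$x <- pmin(pmax(st$x + len * cos(ang), 0), W - 1)
            st$y <- pmin(pmax(st$y + len * sin(ang), 0), H - 1)
          }
          disp[[length(disp) + 1L]] <- data.frame(
            id = st$id, day = as.integer(day),
            dx = st$x - x0, dy = st$y - y0)
        }
        if (lossRate > 0 && nrow(st))
          st <- st[runif(nrow(st)) >= lossRate, , drop = FALSE]
        nNew <- if (appearanceRate > 0) rpois(1, appearanceRate) else 0L
        if (nNew > 0L && length(darkIdx)) {
          pick <- sample(darkIdx, nNew, replace = TRUE)
          ny <- ((pick - 1L) %% H)        # 0-based row
          nx <- ((pick - 1L) %/% H)       # 0-based col
          add <- data.frame(
            id = seq.int(nextId, length.out = nNew),
            x = pmin(pmax(nx + runif(nNew, -0.5, 0.5), margin), W - 1 - margin),
            y = pmin(pmax(ny + runif(nNew, -0.5, 0.5), margin), H - 1 - margin),
            r = pmax(2, rnorm(nNew, spec@cellRadius, 0.05 * spec@cellRadius)))
          if (motionMode == "spot_consolidate") {
            tg <- targetOf(add$x, add$y)
            add$tx <- tg[, "tx"]; add$ty <- tg[, "ty"]
          }
          st <- rbind(st, add)
          nextId <- nextId + nNew
        }
      }
      allCells[[day]] <- recordFrame(day)
      images[[day]] <- renderPattern(spec, cbind(x = st$x, y = st$y), st$r,
                                     xan, xanR)
    }

    cdf <- do.call(rbind, allCells)
    cs <- new("CellSet", cells = cdf)
    ddf <- if (length(disp)) do.call(rbind, disp)
    else data.frame(id = integer(), day = integer(),
                    dx = numeric(), dy = numeric())
    truth <- new("GroundTruth", cells = cs, elementMask = region * 255,
                 displacements = ddf)
    list(images = images, truth = truth)
  })
}
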