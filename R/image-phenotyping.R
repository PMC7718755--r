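#' Segmentation configuration
#'
#' Parameters of the threshold-and-filter segmentation used for pouch
#' images. The defaults are the empirical settings of the study: roots are
#' segmented on the blue channel at 1.7x the median gray value, shoots on
#' the luminance ("8-bit") conversion at 1.4x the median; particles of at
#' most 300 px are treated as noise, and shoots are the particles above
#' 300 px whose Feret diameter gives the shoot length.
#'
#' @param channel `"blue"` (roots) or `"gray"` (shoots).
#' @param kThreshold multiple of the median gray value used as threshold
#'   (> 1; default 1.7 for roots, use 1.4 for shoots).
#' @param noiseMaxPx particles with pixel count \eqn{\le} this are removed
#'   (default 300).
#' @param particleMinPx shoots are particles with pixel count strictly
#'   above this (default 300, complementary to the noise rule).
#' @param connectivity 4 or 8 (default 8, ImageJ-like; keeps thin diagonal
#'   roots connected).
#' @param batchK optional per-batch threshold multiplier (default 1),
#'   standing in for the study's slight manual per-batch adjustment.
#' @param exclusionMask optional logical matrix; `TRUE` pixels are dropped
#'   from the foreground before labeling (replaces manual removal of large
#'   artifacts).
#' @return a `SegmentationConfig` list.
#' @export
segmentationConfig <- function(channel = c("blue", "gray"), kThreshold = 1.7,
                               noiseMaxPx = 300L, particleMinPx = 300L,
                               connectivity = 8L, batchK = 1,
                               exclusionMask = NULL) {
    channel <- match.arg(channel)
    stopifnot(kThreshold > 1, noiseMaxPx >= 0, connectivity %in% c(4L, 8L),
              batchK > 0)
    structure(list(channel = channel, kThreshold = kThreshold,
                   noiseMaxPx = as.integer(noiseMaxPx),
                   particleMinPx = as.integer(particleMinPx),
                   connectivity = as.integer(connectivity), batchK = batchK,
                   exclusionMask = exclusionMask),
              class = "SegmentationConfig")
}

# BT.601 luminance weights used for the "8-bit" grayscale conversion
.lumWeights <- c(0.299, 0.587, 0.114)

#' Extract a working channel from an image
#'
#' Roots are segmented on the blue channel (best separation from the gray
#' germination-paper background); shoots on a standard 8-bit grayscale
#' conversion, here the ITU-R BT.601 luminance
#' `0.299 R + 0.587 G + 0.114 B`. A grayscale input passes through
#' unchanged for either channel choice.
#'
#' @param image matrix (grayscale) or h-by-w-by-3 array on the 0-255 scale.
#' @param channel `"blue"` or `"gray"`.
#' @return a numeric matrix of the same height/width.
#' @export
extractChannel <- function(image, channel = c("blue", "gray")) {
    channel <- match.arg(channel)
    if (is.matrix(image)) return(image)
    if (length(dim(image)) == 3 && dim(image)[3] >= 3) {
        if (channel == "blue") return(image[, , 3])
        return(.lumWeights[1] * image[, , 1] + .lumWeights[2] * image[, , 2] +
               .lumWeights[3] * image[, , 3])
    }
    if (length(dim(image)) == 3 && dim(image)[3] == 1) return(image[, , 1])
    stop("image must be a grayscale matrix or an RGB array")
}

#' Median-scaled threshold
#'
#' The segmentation threshold is `k` times the median gray value of the
#' raster, clipped to the representable 8-bit range (0-255). With `k > 1`
#' and the strictly-greater binarization rule, a constant image yields an
#' empty foreground.
#'
#' @param gray numeric matrix on the 0-255 scale.
#' @param k positive multiplier (1.7 for roots, 1.4 for shoots).
#' @return the threshold value.
#' @export
medianThreshold <- function(gray, k) {
    stopifnot(length(gray) > 0, k > 0)
    min(max(k * stats::median(gray), 0), 255)
}

#' Binarize a gray raster
#'
#' Foreground = pixels strictly above the threshold.
#'
#' @param gray numeric matrix.
#' @param threshold scalar threshold.
#' @return logical matrix.
#' @export
binarize <- function(gray, threshold) gray > threshold

#' Label connected particles
#'
#' Connected-component labeling of a binary mask under 4- or
#' 8-connectivity, with deterministic label order: particles are numbered
#' by their first pixel in row-major order (0-based `(x, y)`, scanning rows
#' top to bottom). Implemented by run-based union-find.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return a `ParticleSet`: list with `labels` (integer matrix, 0 =
#'   background), `particles` (data.frame: `id`, `n_px`, bounding box
#'   `xmin, xmax, ymin, ymax`), and `connectivity`.
#' @export
labelParticles <- function(mask, connectivity = 8L) {
    stopifnot(connectivity %in% c(4L, 8L))
    h <- nrow(mask); w <- ncol(mask)
    labels <- matrix(0L, h, w)
    # collect runs of TRUE per row
    runs <- list(); nr <- 0L
    for (y in seq_len(h)) {
        r <- rle(as.logical(mask[y, ]))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
            nr <- nr + 1L
            runs[[nr]] <- c(y, starts[k], ends[k])
        }
    }
    if (nr == 0L)
        return(structure(list(labels = labels,
            particles = data.frame(id = integer(), n_px = integer(),
                xmin = integer(), xmax = integer(), ymin = integer(),
                ymax = integer()),
            connectivity = as.integer(connectivity)), class = "ParticleSet"))
    runs <- do.call(rbind, runs)   # y, x0, x1 (1-based)
    parent <- seq_len(nr)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
    ext <- if (connectivity == 8L) 1L else 0L
    prevRows <- split(seq_len(nr), runs[, 1])
    for (y in as.integer(names(prevRows))) {
        above <- prevRows[[as.character(y - 1L)]]
        if (is.null(above)) next
        for (i in prevRows[[as.character(y)]]) {
            for (j in above) {
                if (runs[i, 2] <= runs[j, 3] + ext &&
                    runs[j, 2] <= runs[i, 3] + ext) union(i, j)
            }
        }
    }
    root <- vapply(seq_len(nr), find, integer(1))
    # deterministic ids: order components by first run (row-major)
    firsts <- tapply(seq_len(nr), root, function(ii) min(ii))
    ord <- order(as.integer(firsts))
    idOf <- integer(max(root))
    idOf[as.integer(names(firsts))[ord]] <- seq_along(ord)
    for (i in seq_len(nr))
        labels[runs[i, 1], runs[i, 2]:runs[i, 3]] <- idOf[root[i]]
    nid <- length(ord)
    npx <- integer(nid); xmin <- rep(w, nid); xmax <- integer(nid)
    ymin <- rep(h, nid); ymax <- integer(nid)
    for (i in seq_len(nr)) {
        id <- idOf[root[i]]
        npx[id] <- npx[id] + runs[i, 3] - runs[i, 2] + 1L
        xmin[id] <- min(xmin[id], runs[i, 2]); xmax[id] <- max(xmax[id], runs[i, 3])
        ymin[id] <- min(ymin[id], runs[i, 1]); ymax[id] <- max(ymax[id], runs[i, 1])
    }
    structure(list(labels = labels,
        particles = data.frame(id = seq_len(nid), n_px = npx,
            xmin = xmin - 1L, xmax = xmax - 1L,   # 0-based pixel coords
            ymin = ymin - 1L, ymax = ymax - 1L),
        connectivity = as.integer(connectivity)), class = "ParticleSet")
}

#' @export
print.ParticleSet <- function(x, ...) {
    cat(sprintf("ParticleSet: %d particle(s), %d foreground px, %d-connectivity\n",
        nrow(x$particles), sum(x$particles$n_px), x$connectivity))
    invisible(x)
}

#' Pixel coordinates of one particle
#'
#' @param ps a `ParticleSet`.
#' @param id particle id.
#' @return two-column matrix of 0-based `(x, y)` pixel centers.
#' @export
particleCoords <- function(ps, id) {
    idx <- which(ps$labels == id, arr.ind = TRUE)
    cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

#' Remove noise particles by the 300-px size rule
#'
#' Particles with pixel count at most `noiseMaxPx` are removed (the study's
#' "0 to 300 pixels" noise definition, complementary to the shoot rule
#' "300 to infinity"); larger particles are kept. The removal log is
#' attached as attribute `"removalLog"`.
#'
#' @param ps a `ParticleSet`.
#' @param noiseMaxPx size cutoff (default 300).
#' @return the filtered `ParticleSet`.
#' @export
removeNoise <- function(ps, noiseMaxPx = 300L) {
    drop <- ps$particles$id[ps$particles$n_px <= noiseMaxPx]
    log <- ps$particles[ps$particles$id %in% drop, , drop = FALSE]
    labels <- ps$labels
    labels[labels %in% drop] <- 0L
    kept <- ps$particles[!(ps$particles$id %in% drop), , drop = FALSE]
    # relabel kept particles consecutively, preserving row-major order
    newId <- setNames(seq_len(nrow(kept)), kept$id)
    if (nrow(kept)) {
        nz <- labels != 0L
        labels[nz] <- as.integer(newId[as.character(labels[nz])])
        kept$id <- as.integer(newId[as.character(kept$id)])
    }
    rownames(kept) <- NULL
    out <- structure(list(labels = labels, particles = kept,
                          connectivity = ps$connectivity),
                     class = "ParticleSet")
    attr(out, "removalLog") <- log
    out
}

#' Total particle area in mm^2
#'
#' Sum of particle pixel counts converted with the calibration's area
#' scale (px per mm squared).
#'
#' @param ps a `ParticleSet`.
#' @param cal a [Calibration-class].
#' @return area in mm^2.
#' @export
totalArea <- function(ps, cal) {
    sum(ps$particles$n_px) * mm2PerPx(cal)
}

#' Feret diameter (maximum caliper) of a particle
#'
#' Maximum pairwise Euclidean distance between the particle's pixel
#' centers, converted to mm. Computed on the convex hull (which contains
#' both endpoints of the maximal pair); a single-pixel particle has Feret
#' diameter 0.
#'
#' @param particle two-column matrix of pixel coordinates (e.g. from
#'   [particleCoords()]), or a `ParticleSet` together with `id`.
#' @param cal a [Calibration-class]; omit (`NULL`) for the answer in px.
#' @param id particle id when `particle` is a `ParticleSet`.
#' @return Feret diameter in mm (or px when `cal` is `NULL`).
#' @export
feretDiameter <- function(particle, cal = NULL, id = NULL) {
    if (inherits(particle, "ParticleSet")) {
        stopifnot(!is.null(id))
        particle <- particleCoords(particle, id)
    }
    if (nrow(particle) == 0) stop("empty particle")
    dpx <- if (nrow(particle) == 1) 0 else {
        hull <- grDevices::chull(particle[, 1], particle[, 2])
        pts <- particle[hull, , drop = FALSE]
        sqrt(max(stats::dist(pts)^2))
    }
    if (is.null(cal)) dpx else dpx / pxPerMm(cal)
}

#' Measure one germination pouch image
#'
#' Orchestrates the full segmentation chain (channel extraction,
#' median-scaled threshold, binarization, particle labeling, noise removal,
#' measurement) and returns a one-row measurement record. Root area is the
#' total surviving particle area; shoot lengths are the Feret diameters of
#' particles strictly above `particleMinPx`.
#'
#' @param image raster (matrix or RGB array, 0-255) or a file path.
#' @param rootConfig [segmentationConfig()] for the root pass (`NULL` to
#'   skip roots).
#' @param shootConfig [segmentationConfig()] for the shoot pass (`NULL` to
#'   skip shoots).
#' @param cal a [Calibration-class] (required).
#' @param metadata list or one-row data.frame with operator-supplied
#'   fields: `line`, `location`, `batch`, `day` (3, 4 or 5), `root_count`,
#'   `germinated_seeds`, `quality_category` (1-4). Counts are visual
#'   metadata, not computed from the image.
#' @return a one-row `PouchMeasurement` data.frame: metadata columns plus
#'   `root_area_mm2`, `n_shoots`, `shoot_length_mm` (mean), and attribute
#'   `"shootLengthsMm"` with the per-shoot lengths.
#' @export
phenotypePouch <- function(image, rootConfig = segmentationConfig("blue", 1.7),
                           shootConfig = segmentationConfig("gray", 1.4),
                           cal, metadata = list()) {
    if (missing(cal) || !is(cal, "Calibration"))
        stop("a Calibration is required")
    if (is.character(image)) image <- readPouchImage(image)
    segment <- function(cfg) {
        gray <- extractChannel(image, cfg$channel)
        thr <- medianThreshold(gray, cfg$kThreshold * cfg$batchK)
        mask <- binarize(gray, thr)
        if (!is.null(cfg$exclusionMask)) mask <- mask & !cfg$exclusionMask
        removeNoise(labelParticles(mask, cfg$connectivity), cfg$noiseMaxPx)
    }
    rootArea <- NA_real_
    if (!is.null(rootConfig)) rootArea <- totalArea(segment(rootConfig), cal)
    shootLens <- numeric(0)
    if (!is.null(shootConfig)) {
        ps <- segment(shootConfig)
        big <- ps$particles$id[ps$particles$n_px > shootConfig$particleMinPx]
        shootLens <- vapply(big, function(i) feretDiameter(ps, cal, i),
                            numeric(1))
    }
    md <- as.list(metadata)
    out <- data.frame(
        line = md$line %||% NA_character_,
        location = md$location %||% NA_character_,
        batch = md$batch %||% NA,
        day = md$day %||% NA_integer_,
        root_area_mm2 = rootArea,
        n_shoots = length(shootLens),
        shoot_length_mm = if (length(shootLens)) mean(shootLens) else NA_real_,
        root_count = md$root_count %||% NA_integer_,
        germinated_seeds = md$germinated_seeds %||% NA_integer_,
        quality_category = md$quality_category %||% NA_integer_)
    attr(out, "shootLengthsMm") <- shootLens
    out
}
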