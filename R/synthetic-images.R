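#' Specification of a synthetic germination-pouch image
#'
#' Describes a pouch raster to be rendered by [renderPouchImage()]: a uniform
#' gray background, bright hard-edged root strokes (polylines with a stroke
#' width), upright shoot bars, and optional small bright specks emulating the
#' sub-threshold debris that the particle-size filter must remove. Because
#' strokes are rendered without anti-aliasing, the ground-truth mask and the
#' per-structure pixel areas are exact, which is what makes the segmentation
#' stage testable to zero tolerance.
#'
#' Pixel coordinates are 0-based and row-major: `(x, y)` with `x` the column
#' and `y` the row, pixel centers at integer coordinates.
#'
#' @param widthPx,heightPx canvas size in pixels.
#' @param backgroundGray background level, 0-255.
#' @param roots list of root strokes, each `list(points = , width = , gray = )`
#'   where `points` is an n-by-2 matrix of polyline vertices in pixel
#'   coordinates, `width` the stroke width in px and `gray` the level
#'   (must be at least 1.8x the background so the default 1.7x-median
#'   threshold always captures it).
#' @param shoots list of shoot bars, each
#'   `list(base = c(x, y), length = , width = , gray = )`; the bar extends
#'   upward (decreasing y) from the base.
#' @param specks list of noise specks, each `list(area = , gray = ,
#'   at = c(x, y))`; `at` may be omitted, in which case a position is drawn
#'   from the seeded stream. Speck areas must be below 300 px.
#' @param seed integer seed for speck placement; rendering is deterministic
#'   given the spec.
#' @return an object of class `ImageSpec`.
#' @seealso [renderPouchImage()]
#' @export
imageSpec <- function(widthPx, heightPx, backgroundGray = 100,
                      roots = list(), shoots = list(), specks = list(),
                      seed = NULL) {
    stopifnot(widthPx >= 1, heightPx >= 1,
              backgroundGray >= 0, backgroundGray <= 255)
    for (r in roots) {
        stopifnot(is.matrix(r$points), ncol(r$points) == 2,
                  nrow(r$points) >= 2, r$width > 0)
        if (r$gray < 1.8 * backgroundGray)
            stop("root gray level must be >= 1.8x the background")
        half <- r$width / 2
        if (any(r$points[, 1] - half < -0.5) ||
            any(r$points[, 1] + half > widthPx - 0.5) ||
            any(r$points[, 2] - half < -0.5) ||
            any(r$points[, 2] + half > heightPx - 0.5))
            stop("root stroke extends outside the canvas")
    }
    for (s in shoots) {
        stopifnot(length(s$base) == 2, s$length >= 1, s$width >= 1)
        if (s$gray < 1.5 * backgroundGray)
            stop("shoot gray level must be >= 1.5x the background")
        x0 <- ceiling(s$base[1] - s$width / 2)
        if (x0 < 0 || x0 + s$width - 1 > widthPx - 1 ||
            s$base[2] - s$length + 1 < 0 || s$base[2] > heightPx - 1)
            stop("shoot bar extends outside the canvas")
    }
    for (sp in specks) {
        if (sp$area >= 300) stop("speck area must be < 300 px")
        stopifnot(sp$area >= 1)
    }
    structure(list(widthPx = as.integer(widthPx),
                   heightPx = as.integer(heightPx),
                   backgroundGray = backgroundGray, roots = roots,
                   shoots = shoots, specks = specks, seed = seed),
              class = "ImageSpec")
}

# Pixels covered by one stroke segment: centers with signed perpendicular
# offset in [-w/2, w/2) and along-track parameter in [0, L]. Half-open on the
# perpendicular axis so an axis-aligned stroke of integer width w covers
# exactly w rows (or columns).
segmentPixels <- function(p0, p1, width, widthPx, heightPx) {
    v <- p1 - p0
    L <- sqrt(sum(v^2))
    half <- width / 2
    if (L == 0) {
        xs <- ceiling(p0[1] - half):(ceiling(p0[1] - half) + width - 1)
        ys <- ceiling(p0[2] - half):(ceiling(p0[2] - half) + width - 1)
        px <- expand.grid(x = xs, y = ys)
    } else {
        u <- v / L
        xr <- floor(min(p0[1], p1[1]) - half):ceiling(max(p0[1], p1[1]) + half)
        yr <- floor(min(p0[2], p1[2]) - half):ceiling(max(p0[2], p1[2]) + half)
        px <- expand.grid(x = xr, y = yr)
        dx <- px$x - p0[1]
        dy <- px$y - p0[2]
        t <- dx * u[1] + dy * u[2]
        s <- dx * u[2] - dy * u[1]    # signed perpendicular offset
        keep <- t >= 0 & t <= L & s >= -half & s < half
        px <- px[keep, , drop = FALSE]
    }
    px <- px[px$x >= 0 & px$x < widthPx & px$y >= 0 & px$y < heightPx, ,
             drop = FALSE]
    px
}

#' Render a synthetic pouch image with exact ground truth
#'
#' Rasterizes an [imageSpec()] to an 8-bit grayscale matrix. Structures are
#' hard-edged (no anti-aliasing), so the returned truth mask equals the
#' foreground pixel set exactly and per-structure areas are exact pixel
#' counts. Noise specks are rendered into the raster but are *not* part of
#' the truth mask; they stand for the small debris particles that the
#' 300-px size filter removes.
#'
#' @param spec an `ImageSpec`.
#' @return a list with elements
#'   \describe{
#'     \item{raster}{height-by-width numeric matrix, levels 0-255.}
#'     \item{truth}{list: `mask` (logical matrix of structure pixels),
#'       `structures` (data.frame: id, type, area_px, length_px),
#'       `areaPx` (total structure pixel count),
#'       `shootLengthsPx` (declared vertical lengths).}
#'   }
#' @examples
#' sp <- imageSpec(120, 80, backgroundGray = 100,
#'     roots = list(list(points = rbind(c(10, 40), c(109, 40)),
#'                       width = 10, gray = 220)))
#' out <- renderPouchImage(sp)
#' out$truth$areaPx   # exactly 1000
#' @export
renderPouchImage <- function(spec) {
    stopifnot(inherits(spec, "ImageSpec"))
    w <- spec$widthPx; h <- spec$heightPx
    raster <- matrix(spec$backgroundGray, nrow = h, ncol = w)
    mask <- matrix(FALSE, nrow = h, ncol = w)
    structures <- list()
    id <- 0L
    paint <- function(px, gray) {
        idx <- cbind(px$y + 1L, px$x + 1L)
        raster[idx] <<- gray
        mask[idx] <<- TRUE
        nrow(idx)
    }
    for (r in spec$roots) {
        pxall <- NULL
        for (k in seq_len(nrow(r$points) - 1)) {
            px <- segmentPixels(r$points[k, ], r$points[k + 1, ], r$width,
                                w, h)
            pxall <- rbind(pxall, px)
        }
        pxall <- unique(pxall)
        paint(pxall, r$gray)
        id <- id + 1L
        structures[[id]] <- data.frame(id = id, type = "root",
            area_px = nrow(pxall), length_px = NA_real_)
    }
    shootLens <- numeric(0)
    for (s in spec$shoots) {
        x0 <- ceiling(s$base[1] - s$width / 2)
        xs <- x0:(x0 + s$width - 1)
        ys <- (s$base[2] - s$length + 1):s$base[2]
        px <- expand.grid(x = xs, y = ys)
        paint(px, s$gray)
        id <- id + 1L
        structures[[id]] <- data.frame(id = id, type = "shoot",
            area_px = nrow(px), length_px = s$length)
        shootLens <- c(shootLens, s$length)
    }
    # specks: rendered but excluded from truth; placement never overlaps
    # structures so truth areas stay exact
    withSeed(spec$seed, {
        for (sp in spec$specks) {
            side <- max(1L, floor(sqrt(sp$area)))
            rem <- sp$area - side * side
            for (try in 1:100) {
                at <- sp$at %||% c(sample.int(w - side - 1L, 1) - 1L,
                                   sample.int(h - side - 2L, 1) - 1L)
                xs <- at[1]:(at[1] + side - 1L)
                ys <- at[2]:(at[2] + side - 1L)
                px <- expand.grid(x = xs, y = ys)
                if (rem > 0)
                    px <- rbind(px, data.frame(
                        x = at[1]:(at[1] + rem - 1L), y = at[2] + side))
                if (any(px$x < 0 | px$x >= w | px$y < 0 | px$y >= h))
                    { if (!is.null(sp$at)) stop("speck outside canvas"); next }
                # one-pixel clearance so a speck never merges (under
                # 8-connectivity) with a structure or another speck
                halo <- expand.grid(dx = -1:1, dy = -1:1)
                nx <- pmin(pmax(rep(px$x, each = 9) + halo$dx, 0), w - 1)
                ny <- pmin(pmax(rep(px$y, each = 9) + halo$dy, 0), h - 1)
                painted <- mask | raster != spec$backgroundGray
                if (any(painted[cbind(ny + 1L, nx + 1L)])) {
                    if (!is.null(sp$at)) break   # fixed position: skip paint
                    next
                }
                raster[cbind(px$y + 1L, px$x + 1L)] <- sp$gray
                break
            }
        }
    })
    structures <- if (id > 0) do.call(rbind, structures) else
        data.frame(id = integer(), type = character(),
                   area_px = integer(), length_px = numeric())
    list(raster = raster,
         truth = list(mask = mask, structures = structures,
                      areaPx = sum(mask), shootLengthsPx = shootLens))
}

#' Read / write pouch images
#'
#' Grayscale or RGB rasters are handled as numeric arrays on the 0-255
#' scale. PNG is read/written through the \pkg{png} package; TIFF and JPEG
#' are read through \pkg{tiff} / \pkg{jpeg} when those packages are present.
#'
#' @param raster matrix (grayscale) or h-by-w-by-3 array, levels 0-255.
#' @param path file path; format chosen by extension (.png, .tif/.tiff,
#'   .jpg/.jpeg).
#' @return `readPouchImage` returns the raster on the 0-255 scale;
#'   `writePouchImage` returns `path` invisibly.
#' @export
writePouchImage <- function(raster, path) {
    ext <- tolower(tools::file_ext(path))
    img <- raster / 255
    if (ext == "png") png::writePNG(img, path)
    else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("package 'tiff' required to write TIFF")
        tiff::writeTIFF(img, path)
    } else stop("unsupported image format: ", ext)
    invisible(path)
}

#' @rdname writePouchImage
#' @param path file path to read.
#' @export
readPouchImage <- function(path) {
    if (!file.exists(path)) stop("cannot read image: ", path)
    ext <- tolower(tools::file_ext(path))
    img <- if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("package 'tiff' required to read TIFF")
        tiff::readTIFF(path)
    } else if (ext %in% c("jpg", "jpeg")) {
        if (!requireNamespace("jpeg", quietly = TRUE))
            stop("package 'jpeg' required to read JPEG")
        jpeg::readJPEG(path)
    } else stop("unsupported image format: ", ext)
    img * 255
}
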