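#' @import methods
NULL

#' Length calibration for pouch images
#'
#' Links a pixel count to a physical length measured on the copy-stand grid,
#' fixing the scale used to convert segmented pixel areas to mm^2 and pixel
#' spans to mm. The two study sites used different cameras and therefore
#' different scales (Taipei: 450 px = 30 mm; Aberdeen: 222 px = 25.4 mm);
#' both ship as predefined calibrations, see [calibrationFor()].
#'
#' @slot pixels positive number of pixels spanning the reference length.
#' @slot millimetres the physical reference length in mm.
#' @export
setClass("Calibration",
    representation(pixels = "numeric", millimetres = "numeric"))

setValidity("Calibration", function(object) {
    msg <- NULL
    if (length(object@pixels) != 1L || !is.finite(object@pixels) ||
        object@pixels <= 0)
        msg <- c(msg, "'pixels' must be a single positive number")
    if (length(object@millimetres) != 1L || !is.finite(object@millimetres) ||
        object@millimetres <= 0)
        msg <- c(msg, "'millimetres' must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Calibration
#'
#' @param pixels number of pixels spanning the reference length.
#' @param millimetres the reference length in mm.
#' @return a [Calibration-class] object.
#' @examples
#' cal <- calibration(450, 30)   # 15 px per mm
#' pxPerMm(cal)
#' @export
calibration <- function(pixels, millimetres) {
    new("Calibration", pixels = as.numeric(pixels),
        millimetres = as.numeric(millimetres))
}

#' @describeIn calibration pixels per millimetre.
#' @param x a `Calibration`.
#' @export
pxPerMm <- function(x) {
    stopifnot(is(x, "Calibration"))
    x@pixels / x@millimetres
}

#' @describeIn calibration square millimetres per pixel (area scale).
#' @export
mm2PerPx <- function(x) (1 / pxPerMm(x))^2

#' Built-in site calibrations
#'
#' @param location `"taipei"` (450 px = 30 mm) or `"aberdeen"`
#'   (222 px = 25.4 mm).
#' @return a [Calibration-class].
#' @export
calibrationFor <- function(location = c("taipei", "aberdeen")) {
    location <- match.arg(tolower(location), c("taipei", "aberdeen"))
    switch(location,
        taipei   = calibration(450, 30),
        aberdeen = calibration(222, 25.4))
}

setMethod("show", "Calibration", function(object) {
    cat(sprintf("Calibration: %g px = %g mm (%.4f px/mm)\n",
        object@pixels, object@millimetres, pxPerMm(object)))
})

#' Genotype matrix with marker map
#'
#' Lines-by-markers matrix of additive biallelic codes (0 = reference
#' homozygote, 1 = heterozygote, 2 = alternate homozygote, `NA` = missing)
#' plus a marker map giving, per marker, the consensus-map linkage group
#' (`"Mrg01"`..`"Mrg33"`, or `"UKN"` for unmapped markers) and the position
#' in cM (`NA` for unmapped markers).
#'
#' @slot codes numeric matrix, rows = lines, columns = markers.
#' @slot map data.frame with columns `marker`, `lg`, `pos_cM`, row per
#'   marker, in column order of `codes`.
#' @export
setClass("GenotypeData",
    representation(codes = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
    msg <- NULL
    codes <- object@codes
    map <- object@map
    if (!is.numeric(codes))
        msg <- c(msg, "'codes' must be a numeric matrix")
    if (!all(c("marker", "lg", "pos_cM") %in% names(map)))
        msg <- c(msg, "'map' needs columns marker, lg, pos_cM")
    else {
        if (ncol(codes) != nrow(map))
            msg <- c(msg, "one map row per marker column required")
        else if (!is.null(colnames(codes)) &&
                 !identical(colnames(codes), as.character(map$marker)))
            msg <- c(msg, "colnames(codes) must match map$marker")
        mapped <- !is.na(map$pos_cM)
        if (any(map$pos_cM[mapped] < 0))
            msg <- c(msg, "map positions must be >= 0")
    }
    vals <- codes[!is.na(codes)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
        msg <- c(msg, "codes must be in {0, 1, 2, NA}")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param codes lines-by-markers numeric matrix of codes in \{0,1,2,NA\}.
#' @param map data.frame with columns `marker`, `lg`, `pos_cM`.
#' @return a [GenotypeData-class].
#' @export
genotypeData <- function(codes, map) {
    codes <- as.matrix(codes)
    storage.mode(codes) <- "double"
    map <- as.data.frame(map)
    map$marker <- as.character(map$marker)
    map$lg <- as.character(map$lg)
    map$pos_cM <- as.numeric(map$pos_cM)
    if (is.null(colnames(codes))) colnames(codes) <- map$marker
    rownames(map) <- NULL
    new("GenotypeData", codes = codes, map = map)
}

#' @describeIn genotypeData the codes matrix.
#' @param x a `GenotypeData`.
#' @export
genoCodes <- function(x) {
    stopifnot(is(x, "GenotypeData"))
    x@codes
}

#' @describeIn genotypeData the marker map data.frame.
#' @export
markerMap <- function(x) {
    stopifnot(is(x, "GenotypeData"))
    x@map
}

#' @describeIn genotypeData line (row) names.
#' @export
lineNames <- function(x) rownames(genoCodes(x))

#' @describeIn genotypeData marker (column) names.
#' @export
markerNames <- function(x) markerMap(x)$marker

setMethod("dim", "GenotypeData", function(x) dim(x@codes))

setMethod("show", "GenotypeData", function(object) {
    d <- dim(object)
    lgs <- unique(object@map$lg)
    cat(sprintf("GenotypeData: %d lines x %d markers on %d linkage group(s)\n",
        d[1], d[2], length(setdiff(lgs, "UKN"))))
    nmiss <- sum(is.na(object@codes))
    cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
        100 * nmiss / length(object@codes)))
    if ("UKN" %in% lgs)
        cat(sprintf("  unmapped markers: %d\n", sum(object@map$lg == "UKN")))
})

#' Subset a GenotypeData by lines and/or markers
#'
#' @param x a `GenotypeData`.
#' @param i line index (rows).
#' @param j marker index (columns).
#' @param ... ignored.
#' @param drop ignored; the result is always a `GenotypeData`.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
    codes <- x@codes
    map <- x@map
    if (!missing(i)) codes <- codes[i, , drop = FALSE]
    if (!missing(j)) {
        if (is.character(j)) j <- match(j, map$marker)
        codes <- codes[, j, drop = FALSE]
        map <- map[j, , drop = FALSE]
        rownames(map) <- NULL
    }
    new("GenotypeData", codes = codes, map = map)
})

#' Per-marker association scan result
#'
#' Holds the final fixed-effect scan of the iterative FEM/REM association
#' procedure together with the bookkeeping a reader needs to interpret it:
#' the pseudo-QTN set of the final model, the number of principal components
#' used, the Bonferroni threshold at the chosen alpha, the
#' Benjamini-Hochberg-significant set at the chosen q, and the genomic
#' inflation factor lambda of the final scan.
#'
#' @slot results data.frame with one row per marker: `marker`, `lg`,
#'   `pos_cM`, `effect`, `se`, `p`, `p_adj`, `pseudo_qtn` (logical),
#'   `flag` (character: "", "constant", "collinear").
#' @slot pseudoQtns character vector of pseudo-QTN marker names.
#' @slot nPcs integer, principal components included.
#' @slot alpha numeric, family-wise level for the Bonferroni rule.
#' @slot bonferroni numeric, the per-test threshold alpha/m.
#' @slot fdrQ numeric, FDR level for the step-up rule.
#' @slot lambda numeric, genomic inflation of the final scan.
#' @slot iterations integer, FEM/REM iterations run.
#' @slot converged logical, whether the pseudo-QTN set stabilised.
#' @export
setClass("AssociationResult",
    representation(results = "data.frame", pseudoQtns = "character",
        nPcs = "integer", alpha = "numeric", bonferroni = "numeric",
        fdrQ = "numeric", lambda = "numeric", iterations = "integer",
        converged = "logical"))

setValidity("AssociationResult", function(object) {
    msg <- NULL
    need <- c("marker", "lg", "pos_cM", "effect", "se", "p", "p_adj",
              "pseudo_qtn", "flag")
    if (!all(need %in% names(object@results)))
        msg <- c(msg, paste("results needs columns:",
                            paste(need, collapse = ", ")))
    else {
        p <- object@results$p
        if (any(!is.na(p) & (p <= 0 | p > 1)))
            msg <- c(msg, "p-values must lie in (0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn AssociationResult-class the per-marker results table.
#' @param x an `AssociationResult`.
#' @export
assocTable <- function(x) {
    stopifnot(is(x, "AssociationResult"))
    x@results
}

#' @describeIn AssociationResult-class pseudo-QTN marker names.
#' @export
pseudoQtns <- function(x) {
    stopifnot(is(x, "AssociationResult"))
    x@pseudoQtns
}

#' @describeIn AssociationResult-class genomic inflation factor of the
#'   final scan.
#' @export
inflationLambda <- function(x) {
    stopifnot(is(x, "AssociationResult"))
    x@lambda
}

#' @describeIn AssociationResult-class markers significant at the
#'   Bonferroni threshold.
#' @export
bonferroniHits <- function(x) {
    tab <- assocTable(x)
    tab$marker[!is.na(tab$p) & tab$p < x@bonferroni]
}

#' @describeIn AssociationResult-class markers in the BH-significant set at
#'   level `fdrQ`.
#' @export
fdrHits <- function(x) {
    tab <- assocTable(x)
    tab$marker[!is.na(tab$p_adj) & tab$p_adj <= x@fdrQ]
}

setMethod("show", "AssociationResult", function(object) {
    tab <- object@results
    cat(sprintf("AssociationResult: %d markers, %d PC(s), %d pseudo-QTN\n",
        nrow(tab), object@nPcs, length(object@pseudoQtns)))
    cat(sprintf("  Bonferroni (alpha = %g): %g -> %d hit(s)\n",
        object@alpha, object@bonferroni, length(bonferroniHits(object))))
    cat(sprintf("  FDR q = %g -> %d hit(s); lambda = %.3f\n",
        object@fdrQ, length(fdrHits(object)), object@lambda))
    cat(sprintf("  iterations: %d (%s)\n", object@iterations,
        if (object@converged) "converged" else "not converged"))
})
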