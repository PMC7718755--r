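#' Read a genotype matrix
#'
#' Two on-disk forms are supported: a CSV pair (codes matrix with line ids
#' in the first column and marker names as header, plus a map CSV with
#' `marker`, `lg`, `pos_cM`) and VCF. VCF genotypes are taken from the GT
#' field of biallelic SNP records (multiallelic records are skipped with a
#' warning); when no map CSV accompanies a VCF, CHROM is used as the
#' linkage group and POS is interpreted as cM x 1000 (the convention
#' [writeGenotypes()] uses), with `UKN` records left unmapped.
#'
#' @param path CSV codes matrix or VCF path.
#' @param format `"csv"` or `"vcf"` (default: by extension).
#' @param mapPath map CSV path (required for `"csv"`).
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(path, format = NULL, mapPath = NULL) {
    format <- format %||%
        (if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv")
    if (format == "csv") {
        if (is.null(mapPath)) stop("mapPath is required for CSV genotypes")
        codes <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        map <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
        if (!all(c("marker", "lg", "pos_cM") %in% names(map)))
            stop("malformed map: needs marker, lg, pos_cM")
        return(genotypeData(as.matrix(codes), map))
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    if (any(multi)) {
        warning(sum(multi), " multiallelic record(s) skipped")
        vcf <- vcf[!multi, ]
        fix <- vcfR::getFIX(vcf)
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    toCode <- function(g) {
        g <- sub("\\|", "/", g)
        out <- rep(NA_real_, length(g))
        out[g %in% c("0/0")] <- 0
        out[g %in% c("0/1", "1/0")] <- 1
        out[g %in% c("1/1")] <- 2
        out
    }
    codes <- matrix(toCode(as.vector(gt)), nrow = nrow(gt))   # markers x lines
    codes <- t(codes)
    rownames(codes) <- colnames(gt)
    colnames(codes) <- fix[, "ID"]
    if (!is.null(mapPath)) {
        map <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
    } else {
        lg <- fix[, "CHROM"]
        pos <- as.numeric(fix[, "POS"]) / 1000
        pos[lg == "UKN"] <- NA_real_
        map <- data.frame(marker = fix[, "ID"], lg = lg, pos_cM = pos)
    }
    genotypeData(codes, map)
}

#' Write genotypes as CSV matrix + map, and optionally VCF
#'
#' The CSV pair round-trips exactly through [readGenotypes()]. The VCF
#' writer emits a minimal plain-text VCFv4.2 with GT-only genotypes,
#' CHROM = linkage group and POS = round(cM x 1000) (unmapped markers get
#' their column index).
#'
#' @param G a [GenotypeData-class].
#' @param prefix output path prefix; writes `<prefix>_codes.csv` and
#'   `<prefix>_map.csv` (and `<prefix>.vcf` when `vcf = TRUE`).
#' @param vcf also write VCF (default `FALSE`).
#' @return named character vector of the written paths, invisibly.
#' @export
writeGenotypes <- function(G, prefix, vcf = FALSE) {
    stopifnot(is(G, "GenotypeData"))
    codesPath <- paste0(prefix, "_codes.csv")
    mapPath <- paste0(prefix, "_map.csv")
    utils::write.csv(genoCodes(G), codesPath)
    utils::write.csv(markerMap(G), mapPath, row.names = FALSE)
    paths <- c(codes = codesPath, map = mapPath)
    if (vcf) {
        vcfPath <- paste0(prefix, ".vcf")
        writeVcfText(G, vcfPath)
        paths <- c(paths, vcf = vcfPath)
    }
    invisible(paths)
}

writeVcfText <- function(G, path) {
    codes <- genoCodes(G)
    map <- markerMap(G)
    lines <- rownames(codes) %||% sprintf("line_%04d", seq_len(nrow(codes)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", lines), collapse = "\t")), con)
    gtOf <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(codes))) {
        g <- codes[, j]
        gt <- ifelse(is.na(g), "./.", gtOf[g + 1])
        pos <- if (is.na(map$pos_cM[j])) j else round(map$pos_cM[j] * 1000)
        writeLines(paste(c(map$lg[j], pos, map$marker[j], "A", "T", ".",
                           "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
    invisible(path)
}

#' Read / write pouch measurement and trait tables
#'
#' Thin CSV wrappers kept as named entry points so pipeline stages have
#' stable file contracts.
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @return the data.frame, or `path` invisibly for writers.
#' @export
readMeasurements <- function(path) utils::read.csv(path,
    stringsAsFactors = FALSE)

#' @rdname readMeasurements
#' @export
writeMeasurements <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE)
    invisible(path)
}

#' Load a pipeline run configuration
#'
#' YAML with any of: `seed`, `outdir`, `panel` (fields of [panelSpec()]),
#' `gwas` (`n_pcs`, `alpha`, `fdr_q`, `min_sep_cM`, `max_iter`), `qc`
#' thresholds, `n_images` (pouches rendered through the image stage).
#' Defaults are the study's printed settings.
#'
#' @param path YAML path, or `NULL` for the defaults.
#' @param overrides named list merged over the file values.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(path = NULL, overrides = list()) {
    cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
    cfg <- utils::modifyList(cfg, overrides)
    cfg$seed <- cfg$seed %||% 1L
    cfg$outdir <- cfg$outdir %||% tempfile("oatvigor_run_")
    cfg$panel <- cfg$panel %||% list()
    cfg$gwas <- utils::modifyList(
        list(n_pcs = 0, alpha = 0.1, fdr_q = 0.1, min_sep_cM = 1,
             max_iter = 10), cfg$gwas %||% list())
    cfg$n_images <- cfg$n_images %||% 6
    class(cfg) <- "RunConfig"
    cfg
}
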