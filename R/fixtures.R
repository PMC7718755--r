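fixturePath <- function(name)
    system.file("extdata", name, package = "oatvigor", mustWork = TRUE)

#' Packaged transcriptions of the published CORE-panel results
#'
#' Verbatim transcriptions of the published association tables for the
#' CORE oat panel (including duplicated markers and positions, so the
#' locus-deduplication logic can be exercised against the printed headline
#' counts), the check-variety list, the per-platform marker counts, and
#' the published per-site trait means. `homeologRegionFixture()` is a
#' *synthetic* toy region map for tests — the real consensus-map region
#' coordinates are user-supplied, see [readRegionMap()].
#'
#' @return a data.frame (see each function's columns).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
rootAssociationFixture <- function()
    utils::read.csv(fixturePath("root_trait_associations.csv"),
                    stringsAsFactors = FALSE)

#' @rdname fixtures
#' @export
shootAssociationFixture <- function()
    utils::read.csv(fixturePath("shoot_trait_associations.csv"),
                    stringsAsFactors = FALSE)

#' @rdname fixtures
#' @export
checkVarieties <- function()
    utils::read.csv(fixturePath("check_varieties.csv"),
                    stringsAsFactors = FALSE)$check

#' @rdname fixtures
#' @export
markerPlatformCounts <- function()
    utils::read.csv(fixturePath("marker_platform_counts.csv"),
                    stringsAsFactors = FALSE)

#' @rdname fixtures
#' @export
siteTraitMeans <- function()
    utils::read.csv(fixturePath("site_trait_means.csv"),
                    stringsAsFactors = FALSE)

#' @rdname fixtures
#' @export
homeologRegionFixture <- function()
    readRegionMap(fixturePath("homeolog_regions_synthetic.csv"))
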