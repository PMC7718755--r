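#' Summarize trait-associated SNPs into unique loci
#'
#' A unique locus is a unique position on the consensus map — several SNPs
#' at exactly the same (linkage group, cM) position count as one locus,
#' and one SNP associated with several traits counts once — while each
#' unmapped (UKN) SNP forms its own locus. Positions are compared at the
#' 0.1 cM resolution they are reported at; a co-location tolerance can be
#' widened via `colocTolCM`.
#'
#' @param records data.frame of association records with columns
#'   `marker`, `trait`, `lg`, `pos_cM` (`lg == "UKN"` or `NA` position for
#'   unmapped markers).
#' @param colocTolCM positions closer than this collapse into one locus
#'   (default 0: exact position match only).
#' @return list:
#'   \describe{
#'     \item{loci}{`LocusTable` data.frame: `locus_id`, `lg`, `pos_cM`,
#'       `n_snps`, `markers` (";"-joined), `traits` (";"-joined).}
#'     \item{counts}{list `n_snps` (unique SNPs) and `n_loci`.}
#'   }
#' @export
summarizeLoci <- function(records, colocTolCM = 0) {
    need <- c("marker", "trait", "lg", "pos_cM")
    stopifnot(all(need %in% names(records)))
    bad <- is.na(records$marker) &
        (is.na(records$pos_cM) | is.na(records$lg))
    if (any(bad)) stop("record lacking both marker id and map position")
    rec <- records
    unmapped <- is.na(rec$pos_cM) | (!is.na(rec$lg) & rec$lg == "UKN")
    rec$pos_cM <- round(as.numeric(rec$pos_cM), 1)
    key <- ifelse(unmapped, paste0("UKN:", rec$marker),
                  paste0(rec$lg, ":", sprintf("%.1f", rec$pos_cM)))
    if (colocTolCM > 0) {
        for (g in unique(rec$lg[!unmapped])) {
            idx <- which(!unmapped & rec$lg == g)
            idx <- idx[order(rec$pos_cM[idx])]
            grp <- cumsum(c(TRUE,
                diff(rec$pos_cM[idx]) > colocTolCM))
            key[idx] <- paste0(g, ":grp", grp)
        }
    }
    agg <- split(rec, key)
    loci <- do.call(rbind, lapply(names(agg), function(k) {
        d <- agg[[k]]
        data.frame(locus_id = k, lg = d$lg[1],
                   pos_cM = if (startsWith(k, "UKN")) NA_real_ else d$pos_cM[1],
                   n_snps = length(unique(d$marker)),
                   markers = paste(sort(unique(d$marker)), collapse = ";"),
                   traits = paste(sort(unique(d$trait)), collapse = ";"))
    }))
    loci <- loci[order(loci$lg, loci$pos_cM, loci$locus_id), , drop = FALSE]
    rownames(loci) <- NULL
    list(loci = loci,
         counts = list(n_snps = length(unique(rec$marker)),
                       n_loci = nrow(loci)))
}

#' Read a homeolog-region table
#'
#' Regions of the consensus map grouped into homeologous sets (one set =
#' corresponding segments across subgenomes). CSV columns: `set_id`,
#' `region_id`, `lg`, `start_cM`, `end_cM`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readRegionMap <- function(path) {
    regions <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("set_id", "region_id", "lg", "start_cM", "end_cM")
    if (!all(need %in% names(regions)))
        stop("region map needs columns: ", paste(need, collapse = ", "))
    if (any(regions$start_cM > regions$end_cM))
        stop("malformed region: start_cM > end_cM")
    regions
}

#' Assign loci to homeologous region sets
#'
#' Maps each locus to the region (closed interval on its linkage group)
#' containing it; a homeologous set is reported when at least two of its
#' member regions contain associated loci. Loci outside every region are
#' flagged with `NA`. If overlapping regions on one linkage group both
#' contain a locus, the ambiguity is logged and the locus goes to the
#' region whose midpoint is nearest. The assignment is idempotent and
#' stable under reordering of the region list.
#'
#' @param loci a `LocusTable` (from [summarizeLoci()]`$loci`).
#' @param regions a region table (see [readRegionMap()]).
#' @return the `LocusTable` with added `region_id` and `homeolog_set`
#'   columns; attribute `"sets"` summarizes the reported sets and
#'   attribute `"ambiguities"` the overlap log.
#' @export
assignHomeologSets <- function(loci, regions) {
    regions <- regions[order(regions$set_id, regions$region_id), ,
                       drop = FALSE]
    loci$region_id <- NA_character_
    ambiguities <- list()
    for (i in seq_len(nrow(loci))) {
        if (is.na(loci$pos_cM[i])) next
        hit <- which(regions$lg == loci$lg[i] &
                     regions$start_cM <= loci$pos_cM[i] &
                     loci$pos_cM[i] <= regions$end_cM)
        if (length(hit) > 1) {
            mid <- (regions$start_cM[hit] + regions$end_cM[hit]) / 2
            pick <- hit[which.min(abs(mid - loci$pos_cM[i]))]
            ambiguities[[length(ambiguities) + 1L]] <- data.frame(
                locus_id = loci$locus_id[i],
                candidates = paste(regions$region_id[hit], collapse = ";"),
                assigned = regions$region_id[pick])
            hit <- pick
        }
        if (length(hit) == 1) loci$region_id[i] <- regions$region_id[hit]
    }
    loci$homeolog_set <- regions$set_id[match(loci$region_id,
                                              regions$region_id)]
    # a set counts only when >= 2 of its member regions carry loci
    occ <- unique(loci[!is.na(loci$region_id),
                       c("homeolog_set", "region_id")])
    nreg <- table(occ$homeolog_set)
    reported <- names(nreg)[nreg >= 2]
    loci$homeolog_set[!(loci$homeolog_set %in% reported)] <- NA_character_
    setsSummary <- do.call(rbind, lapply(reported, function(s) {
        d <- loci[!is.na(loci$homeolog_set) & loci$homeolog_set == s, ]
        data.frame(set_id = s, n_loci = nrow(d),
                   lgs = paste(sort(unique(d$lg)), collapse = ";"))
    })) %||% data.frame(set_id = character(), n_loci = integer(),
                        lgs = character())
    attr(loci, "sets") <- setsSummary
    attr(loci, "ambiguities") <- if (length(ambiguities))
        do.call(rbind, ambiguities) else
        data.frame(locus_id = character(), candidates = character(),
                   assigned = character())
    loci
}

#' Allele contrast of one marker on one trait
#'
#' Per-allele-class (0/1/2; heterozygotes are their own class) trait
#' summaries for the whole panel, for each subgroup (e.g. spring vs.
#' southern germplasm), and for the union of the top and bottom trait
#' fractions — the view that shows whether a weak-effect marker
#' contributes more within specific genetic materials.
#'
#' @param trait named numeric vector of trait values (names = lines).
#' @param genotypes named numeric vector of codes \{0,1,2\} for one
#'   marker.
#' @param subgroups optional named factor of subgroup labels.
#' @param fraction top/bottom tail fraction in (0, 0.5]; 0.1 selects the
#'   top and bottom 10% (fraction 0.5 selects the whole panel for even
#'   n). `NULL` skips the tail view.
#' @return an `AlleleContrast` data.frame: `panel`, `class`, `n`, `mean`,
#'   `median`.
#' @export
alleleContrast <- function(trait, genotypes, subgroups = NULL,
                           fraction = 0.1) {
    lines <- intersect(names(trait), names(genotypes))
    tr <- trait[lines]
    ok <- !is.na(tr) & !is.na(genotypes[lines])
    tr <- tr[ok]; g <- genotypes[lines][ok]
    summarize <- function(panel, v, gg) {
        do.call(rbind, lapply(sort(unique(gg)), function(cl) {
            vv <- v[gg == cl]
            data.frame(panel = panel, class = cl, n = length(vv),
                       mean = if (length(vv)) mean(vv) else NA_real_,
                       median = if (length(vv)) stats::median(vv) else
                           NA_real_)
        }))
    }
    out <- summarize("all", tr, g)
    if (!is.null(subgroups)) {
        sg <- subgroups[names(tr)]
        for (s in levels(factor(sg))) {
            sel <- !is.na(sg) & sg == s
            out <- rbind(out, summarize(s, tr[sel], g[sel]))
        }
    }
    if (!is.null(fraction)) {
        stopifnot(fraction > 0, fraction <= 0.5)
        k <- floor(fraction * length(tr))
        ord <- order(tr)
        sel <- c(utils::head(ord, k), utils::tail(ord, k))
        out <- rbind(out, summarize("top_bottom", tr[sel], g[sel]))
    }
    rownames(out) <- NULL
    out
}

#' Export marker context sequences as FASTA
#'
#' Writes the context sequences of trait-associated markers for external
#' similarity searches; no alignment is performed here.
#'
#' @param markers data.frame with columns `marker` and `context_seq`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeContextFasta <- function(markers, path) {
    stopifnot(all(c("marker", "context_seq") %in% names(markers)))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(markers)))
        writeLines(c(paste0(">", markers$marker[i]),
                     markers$context_seq[i]), con)
    invisible(path)
}
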