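#' Derive seed-vigor traits from pouch measurements
#'
#' Computes the original and derived vigor traits from per-day pouch
#' measurements of one location:
#' \describe{
#'   \item{RN}{total root number / germinated seeds (from the latest day
#'     with counts).}
#'   \item{RSA_3, RSA_4, RSA_5}{root surface area per day, mm^2.}
#'   \item{SL_3, SL_4, SL_5}{mean shoot length per day, mm.}
#'   \item{AVRSA}{RSA_5 / RN, mm^2.}
#'   \item{RG_i}{RSA_i - RSA_(i-1), mm^2/day.}
#'   \item{RRGR_i}{RG_i / RSA_(i-1), 1/day.}
#'   \item{SG_i}{SL_i - SL_(i-1), mm/day.}
#'   \item{SRGR_i}{SG_i / SL_(i-1), 1/day (rate relative to the earlier
#'     shoot length, the unit-consistent reading; set
#'     `srgrLiteral = TRUE` for the alternative SG_i / SG_(i-1)).}
#' }
#' Missing inputs propagate to missing outputs; divisions by zero yield
#' `NA` with the reason recorded in attribute `"derivationLog"`.
#'
#' @param measurements data.frame of pouch measurements (one row per line
#'   and day) with columns `line`, `day`, `root_area_mm2`,
#'   `shoot_length_mm`, `root_count`, `germinated_seeds`,
#'   `quality_category`, `n_shoots`, and optionally `location`, `batch`.
#' @param srgrLiteral use the literal SG_i / SG_(i-1) form for SRGR
#'   (default `FALSE`).
#' @return a `TraitTable` data.frame, one row per line.
#' @export
deriveTraits <- function(measurements, srgrLiteral = FALSE) {
    stopifnot(all(c("line", "day") %in% names(measurements)))
    if (!all(measurements$day %in% c(3, 4, 5)))
        stop("days must be within {3, 4, 5}")
    getcol <- function(df, col) if (col %in% names(df)) df[[col]] else
        rep(NA, nrow(df))
    log <- list()
    note <- function(line, reason)
        log[[length(log) + 1L]] <<- data.frame(line = line, reason = reason)
    safeDiv <- function(num, den, line, what) {
        if (is.na(num) || is.na(den)) return(NA_real_)
        if (den == 0) { note(line, paste0(what, ": division by zero")); return(NA_real_) }
        num / den
    }
    rows <- lapply(split(measurements, measurements$line), function(d) {
        d <- d[order(d$day), , drop = FALSE]
        val <- function(col, day) {
            v <- getcol(d, col)[d$day == day]
            if (length(v) == 0 || all(is.na(v))) NA_real_ else v[!is.na(v)][1]
        }
        line <- d$line[1]
        rsa <- c(`3` = val("root_area_mm2", 3), `4` = val("root_area_mm2", 4),
                 `5` = val("root_area_mm2", 5))
        sl <- c(`3` = val("shoot_length_mm", 3), `4` = val("shoot_length_mm", 4),
                `5` = val("shoot_length_mm", 5))
        counted <- d[!is.na(getcol(d, "root_count")), , drop = FALSE]
        rn <- NA_real_
        if (nrow(counted)) {
            last <- counted[nrow(counted), ]
            if (is.na(last$germinated_seeds) || last$germinated_seeds == 0)
                note(line, "RN: zero or missing germinated seeds")
            else rn <- last$root_count / last$germinated_seeds
        }
        rg <- function(i) rsa[as.character(i)] - rsa[as.character(i - 1)]
        sg <- function(i) sl[as.character(i)] - sl[as.character(i - 1)]
        rg4 <- unname(rg(4)); rg5 <- unname(rg(5))
        sg4 <- unname(sg(4)); sg5 <- unname(sg(5))
        srgr <- function(i) {
            num <- if (i == 4) sg4 else sg5
            den <- if (srgrLiteral) (if (i == 4) NA_real_ else sg4)
                   else unname(sl[as.character(i - 1)])
            if (is.na(num)) return(NA_real_)
            safeDiv(num, den, line, sprintf("SRGR_%d", i))
        }
        data.frame(line = line,
            location = if ("location" %in% names(d)) d$location[1] else NA,
            batch = if ("batch" %in% names(d)) d$batch[1] else NA,
            RN = rn,
            RSA_3 = unname(rsa["3"]), RSA_4 = unname(rsa["4"]),
            RSA_5 = unname(rsa["5"]),
            SL_3 = unname(sl["3"]), SL_4 = unname(sl["4"]),
            SL_5 = unname(sl["5"]),
            AVRSA = safeDiv(unname(rsa["5"]), rn, line, "AVRSA"),
            RG_4 = rg4, RG_5 = rg5,
            RRGR_4 = if (is.na(rg4)) NA_real_ else
                safeDiv(rg4, unname(rsa["3"]), line, "RRGR_4"),
            RRGR_5 = if (is.na(rg5)) NA_real_ else
                safeDiv(rg5, unname(rsa["4"]), line, "RRGR_5"),
            SG_4 = sg4, SG_5 = sg5,
            SRGR_4 = srgr(4), SRGR_5 = srgr(5),
            germinated_seeds = if (nrow(counted))
                counted$germinated_seeds[nrow(counted)] else NA_integer_,
            quality_category = if (any(!is.na(getcol(d, "quality_category"))))
                max(getcol(d, "quality_category"), na.rm = TRUE) else NA_integer_,
            n_shoots = if (any(!is.na(getcol(d, "n_shoots"))))
                utils::tail(stats::na.omit(getcol(d, "n_shoots")), 1) else
                NA_integer_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "derivationLog") <- if (length(log)) do.call(rbind, log) else
        data.frame(line = character(), reason = character())
    out
}

.rootTraitCols <- c("RN", "RSA_3", "RSA_4", "RSA_5", "AVRSA",
                    "RG_4", "RG_5", "RRGR_4", "RRGR_5")
.shootTraitCols <- c("SL_3", "SL_4", "SL_5", "SG_4", "SG_5",
                     "SRGR_4", "SRGR_5")

#' Location-keyed QC rules for vigor traits
#'
#' The study's data-cleaning thresholds, keyed by location. Root-trait
#' records are discarded when the day-4-to-5 root growth rate falls below
#' the location cutoff (strictly below: a line at exactly the cutoff is
#' kept), when the image quality category exceeds 2, or when fewer than 5
#' seeds germinated. Shoot-trait records are discarded when the shoot
#' growth rate falls below the location cutoff or the emergence rule is
#' violated: by default at least `emergenceMin + 1` shoots must have
#' emerged at day 5 (more than 1 for Taipei, more than 3 for Aberdeen);
#' `emergenceLiteral = TRUE` flips this to the literal maximum reading
#' (discard when *more* shoots than the cutoff emerged).
#'
#' @param rg5Min named numeric: minimum RG_5 (mm^2/day) per location.
#' @param sg5Min named numeric: minimum SG_5 (mm/day) per location.
#' @param minGerminated minimum germinated seeds (default 5).
#' @param maxQuality highest acceptable image quality category (default 2).
#' @param emergenceMin named numeric: emergence cutoff per location.
#' @param emergenceLiteral logical, see above.
#' @return a `QCRules` list.
#' @export
qcRules <- function(rg5Min = c(taipei = 7, aberdeen = 4),
                    sg5Min = c(taipei = 12, aberdeen = 4),
                    minGerminated = 5, maxQuality = 2,
                    emergenceMin = c(taipei = 1, aberdeen = 3),
                    emergenceLiteral = FALSE) {
    structure(list(rg5Min = rg5Min, sg5Min = sg5Min,
                   minGerminated = minGerminated, maxQuality = maxQuality,
                   emergenceMin = emergenceMin,
                   emergenceLiteral = emergenceLiteral), class = "QCRules")
}

#' Apply the data-cleaning rules to a trait table
#'
#' Root and shoot trait blocks are screened independently: a line can pass
#' one and fail the other. Failing blocks have their trait columns set to
#' `NA` and the pass flags (`qc_root_pass`, `qc_shoot_pass`) set to
#' `FALSE`; every rejection is logged with the rule that fired. The filter
#' is idempotent: missing values never trigger a rule.
#'
#' @param table a `TraitTable` from [deriveTraits()] with a `location`
#'   column (or a single `location` given here).
#' @param rules a [qcRules()] object.
#' @param location location key used when the table has none.
#' @return list with `kept` (the table with flags and `NA`-ed failing
#'   blocks) and `log` (data.frame: `line`, `trait_class`, `rule`).
#' @export
qcFilter <- function(table, rules = qcRules(), location = NULL) {
    tab <- table
    loc <- tolower(as.character(if (!is.null(location)) rep(location, nrow(tab))
                                else tab$location))
    if (nrow(tab) && any(is.na(loc) | !(loc %in% names(rules$rg5Min))))
        stop("unknown location key; expected one of: ",
             paste(names(rules$rg5Min), collapse = ", "))
    log <- list()
    note <- function(line, cls, rule)
        log[[length(log) + 1L]] <<- data.frame(line = line, trait_class = cls,
                                               rule = rule)
    rootPass <- rep(TRUE, nrow(tab)); shootPass <- rep(TRUE, nrow(tab))
    if ("qc_root_pass" %in% names(tab)) rootPass <- tab$qc_root_pass
    if ("qc_shoot_pass" %in% names(tab)) shootPass <- tab$qc_shoot_pass
    for (i in seq_len(nrow(tab))) {
        l <- loc[i]
        if (rootPass[i]) {
            if (!is.na(tab$RG_5[i]) && tab$RG_5[i] < rules$rg5Min[[l]]) {
                rootPass[i] <- FALSE; note(tab$line[i], "root", "rg5_min")
            } else if (!is.na(tab$quality_category[i]) &&
                       tab$quality_category[i] > rules$maxQuality) {
                rootPass[i] <- FALSE; note(tab$line[i], "root", "image_quality")
            } else if (!is.na(tab$germinated_seeds[i]) &&
                       tab$germinated_seeds[i] < rules$minGerminated) {
                rootPass[i] <- FALSE; note(tab$line[i], "root", "germination")
            }
        }
        if (shootPass[i]) {
            emergedBad <- if (is.na(tab$n_shoots[i])) FALSE
                else if (rules$emergenceLiteral)
                    tab$n_shoots[i] > rules$emergenceMin[[l]]
                else tab$n_shoots[i] <= rules$emergenceMin[[l]]
            if (!is.na(tab$SG_5[i]) && tab$SG_5[i] < rules$sg5Min[[l]]) {
                shootPass[i] <- FALSE; note(tab$line[i], "shoot", "sg5_min")
            } else if (emergedBad) {
                shootPass[i] <- FALSE; note(tab$line[i], "shoot", "emergence")
            }
        }
    }
    tab[!rootPass, intersect(.rootTraitCols, names(tab))] <- NA_real_
    tab[!shootPass, intersect(.shootTraitCols, names(tab))] <- NA_real_
    tab$qc_root_pass <- rootPass
    tab$qc_shoot_pass <- shootPass
    list(kept = tab,
         log = if (length(log)) do.call(rbind, log) else
             data.frame(line = character(), trait_class = character(),
                        rule = character()))
}
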