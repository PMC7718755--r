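measRow <- function(line, day, rsa = NA, sl = NA, roots = NA, germ = NA,
                    qual = 1, shoots = NA, location = "taipei") {
    data.frame(line = line, location = location, batch = 1, day = day,
               root_area_mm2 = rsa, shoot_length_mm = sl,
               root_count = roots, germinated_seeds = germ,
               quality_category = qual, n_shoots = shoots)
}

test_that("derived traits satisfy their defining identities", {
    meas <- rbind(
        measRow("A", 3, rsa = 93.9, sl = 19.3),
        measRow("A", 4, rsa = 125.9, sl = 33.9),
        measRow("A", 5, rsa = 154.7, sl = 54, roots = 10, germ = 3,
                shoots = 5))
    tt <- deriveTraits(meas)
    expect_equal(tt$RG_5, 154.7 - 125.9)            # 28.8
    expect_equal(tt$RG_4, 125.9 - 93.9)
    expect_equal(tt$RRGR_5, tt$RG_5 / tt$RSA_4)
    expect_equal(tt$RRGR_4, tt$RG_4 / tt$RSA_3)
    expect_equal(tt$RN, 10 / 3)
    expect_equal(tt$AVRSA, tt$RSA_5 / tt$RN)
    expect_equal(tt$SG_5, 54 - 33.9)
    expect_equal(tt$SRGR_5, tt$SG_5 / tt$SL_4)

    # the alternative literal SRGR reading divides by the previous rate
    lit <- deriveTraits(meas, srgrLiteral = TRUE)
    expect_equal(lit$SRGR_5, lit$SG_5 / lit$SG_4)

    # flat growth: zero rate and zero relative rate
    flat <- rbind(measRow("B", 4, rsa = 50), measRow("B", 5, rsa = 50))
    tf <- deriveTraits(flat)
    expect_equal(tf$RG_5, 0)
    expect_equal(tf$RRGR_5, 0)
})

test_that("missing inputs and zero denominators propagate to NA with a logged reason", {
    meas <- rbind(measRow("C", 4, rsa = 0), measRow("C", 5, rsa = 10,
                                                    roots = 8, germ = 0))
    tt <- deriveTraits(meas)
    expect_true(is.na(tt$RRGR_5))     # RSA_4 = 0
    expect_true(is.na(tt$RN))         # zero germinated seeds
    expect_true(is.na(tt$AVRSA))
    expect_true(is.na(tt$RSA_3))
    expect_true(is.na(tt$RG_4))
    log <- attr(tt, "derivationLog")
    expect_true(any(grepl("division by zero", log$reason)))
    expect_true(any(grepl("germinated", log$reason)))
    expect_error(deriveTraits(measRow("D", 6, rsa = 1)), "days")
})

test_that("the cleaning rules fire at their exact printed boundaries", {
    base <- function(line, rg5, germ = 9, qual = 1, sg5 = 20, shoots = 5) {
        tt <- deriveTraits(rbind(
            measRow(line, 4, rsa = 100, sl = 30),
            measRow(line, 5, rsa = 100 + rg5, sl = 30 + sg5, roots = 30,
                    germ = germ, qual = qual, shoots = shoots)))
        tt
    }
    res <- qcFilter(rbind(base("strict", 6.9), base("kept", 7.0)))
    expect_false(res$kept$qc_root_pass[res$kept$line == "strict"])
    expect_true(res$kept$qc_root_pass[res$kept$line == "kept"])
    expect_true(is.na(res$kept$RG_5[res$kept$line == "strict"]))
    expect_equal(res$log$rule[res$log$line == "strict"], "rg5_min")

    germ4 <- qcFilter(base("few", 20, germ = 4))
    expect_false(germ4$kept$qc_root_pass)
    expect_equal(germ4$log$rule, "germination")

    qual3 <- qcFilter(base("blurry", 20, qual = 3))
    expect_false(qual3$kept$qc_root_pass)

    # aberdeen thresholds differ: RG_5 = 5 passes there but not in taipei
    ab <- base("ab", 5); ab$location <- "aberdeen"
    expect_true(qcFilter(ab)$kept$qc_root_pass)
    expect_false(qcFilter(base("tp", 5))$kept$qc_root_pass)

    # shoot rules: growth below cutoff, and the emergence rule
    slow <- qcFilter(base("slow", 20, sg5 = 11.9))
    expect_false(slow$kept$qc_shoot_pass)
    lone <- qcFilter(base("lone", 20, shoots = 1))
    expect_false(lone$kept$qc_shoot_pass)
    expect_equal(lone$log$rule, "emergence")
    # literal reading flips the emergence comparison
    lit <- qcFilter(base("many", 20, shoots = 5),
                    qcRules(emergenceLiteral = TRUE))
    expect_false(lit$kept$qc_shoot_pass)

    empty <- qcFilter(base("x", 20)[0, ])
    expect_equal(nrow(empty$kept), 0)
    expect_equal(nrow(empty$log), 0)

    bad <- base("x", 20); bad$location <- "mars"
    expect_error(qcFilter(bad), "unknown location")
})

test_that("cleaning is idempotent and partitions every record", {
    set.seed(10)
    tabs <- do.call(rbind, lapply(1:12, function(i) {
        rg5 <- runif(1, 0, 20); sg5 <- runif(1, 0, 25)
        deriveTraits(rbind(
            measRow(paste0("L", i), 4, rsa = 100, sl = 30),
            measRow(paste0("L", i), 5, rsa = 100 + rg5, sl = 30 + sg5,
                    roots = 30, germ = sample(3:9, 1),
                    qual = sample(1:4, 1), shoots = sample(1:6, 1))))
    }))
    first <- qcFilter(tabs)
    again <- qcFilter(first$kept)
    expect_identical(first$kept, again$kept)
    expect_equal(nrow(again$log), 0)
    expect_equal(sum(first$kept$qc_root_pass) +
                 sum(!first$kept$qc_root_pass), nrow(tabs))

    # a table generated without violations loses nothing
    clean <- do.call(rbind, lapply(1:5, function(i)
        deriveTraits(rbind(
            measRow(paste0("C", i), 4, rsa = 100, sl = 30),
            measRow(paste0("C", i), 5, rsa = 130, sl = 60, roots = 30,
                    germ = 9, qual = 1, shoots = 5)))))
    resC <- qcFilter(clean)
    expect_true(all(resC$kept$qc_root_pass))
    expect_true(all(resC$kept$qc_shoot_pass))
    expect_equal(nrow(resC$log), 0)
})
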