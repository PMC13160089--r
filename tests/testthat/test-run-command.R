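test_that("unknown commands and config keys are rejected by name", {
    d <- withr::local_tempdir()
    expect_error(runCommand("frobnicate", list(outdir = d)), "unknown command")
    expect_error(runCommand("denoise",
                            list(outdir = d, frip = 0.3, f = 0.1,
                                 rho = 0.01, bogus = 1)), "bogus")
    expect_error(runCommand("simulate",
                            list(outdir = d,
                                 sim = list(lef_speed = 2))), "lef_speed")
    expect_error(runCommand("denoise", list(frip = 0.3, f = 0, rho = 0)),
                 "outdir")
})

test_that("simulate command writes a profile with conserved leg counts", {
    d <- withr::local_tempdir()
    cfg <- list(outdir = d, seed = 3,
                sim = list(sites_per_replica = 400, n_replicas = 2,
                           lef_separation_bp = 20000, n_steps = 400),
                barriers = list(mode = "homogeneous",
                                target_occupancy_per_mb = 4))
    res <- runCommand("simulate", cfg)
    expect_true(file.exists(file.path(d, "profile.tsv")))
    expect_true(file.exists(file.path(d, "run-config.yaml")))
    prof <- res$profile
    expect_lte(sum(legCounts(prof)), 2 * prof@nLefs * nSnapshots(prof))
    expect_gte(res$frip, 0)

    # rerun with the same config reproduces outputs byte-identically
    d2 <- withr::local_tempdir()
    cfg2 <- cfg; cfg2$outdir <- d2
    runCommand("simulate", cfg2)
    expect_identical(readLines(file.path(d, "profile.tsv")),
                     readLines(file.path(d2, "profile.tsv")))
})

test_that("scan, adjust and threshold commands chain through files", {
    d <- withr::local_tempdir()
    cfg <- list(outdir = d, seed = 5, ratios = c(0.25, 1, 2), n_seeds = 3,
                sim = list(sites_per_replica = 400, n_replicas = 2,
                           lef_separation_bp = 20000, n_steps = 400),
                barriers = list(mode = "heterogeneous",
                                target_occupancy_per_mb = 4))
    res <- runCommand("scan-cohesin", cfg)
    expect_true(file.exists(file.path(d, "scan.tsv")))
    expect_equal(res$scan$ratio, c(0.25, 1, 2))

    # f_base 0 leaves the scan unchanged
    adj <- runCommand("adjust", list(outdir = d,
                                     scan_table = file.path(d, "scan.tsv"),
                                     f_base = 0, rho = res$rho))
    expect_equal(adj$adjusted$frip_adjusted, res$scan$frip_mean)

    thr <- runCommand("threshold",
                      list(outdir = d,
                           scan_table = file.path(d, "scan.tsv"),
                           rho = res$rho))
    expect_true(is.na(thr$threshold) ||
                thr$threshold %in% seq(0, 0.95, 0.05))

    ct <- runCommand("scan-ctcf",
                     list(outdir = withr::local_tempdir(), seed = 5,
                          ratios = c(0, 1), n_seeds = 2,
                          sim = cfg$sim, barriers = cfg$barriers))
    expect_equal(nrow(ct$scan), 2L)
})

test_that("synth, frip, rho, estimate-bg and denoise commands round-trip", {
    d <- withr::local_tempdir()
    syn <- runCommand("synth",
                      list(outdir = d, seed = 11, n_chroms = 1,
                           chrom_length = 3e6, n_peaks = 80,
                           peak_width = 300, n_reads = 20000,
                           read_length = 50, q = 1, f = 0.4))
    expect_true(all(file.exists(file.path(d,
        c("genome.chrom.sizes", "peaks.bed", "reads.bed")))))

    fr <- runCommand("frip",
                     list(outdir = d, reads = file.path(d, "reads.bed"),
                          peaks = file.path(d, "peaks.bed"),
                          genome = file.path(d, "genome.chrom.sizes")))
    expect_equal(fr$frip$rho, 0.008)
    expFrip <- 0.6 + 0.4 * 0.008
    expect_lt(abs(fr$frip$frip - expFrip), 0.02)

    rh <- runCommand("rho",
                     list(outdir = d, peaks = file.path(d, "peaks.bed"),
                          genome = file.path(d, "genome.chrom.sizes")))
    expect_equal(rh$rho, 0.008)

    # spike-in batch: recovered f matches the generation parameter
    tab <- data.frame(sample = "s1", R_UT = 1e6,
                      R_dep = 1e6 * (0.3 + 0.1 * 0.7), gamma = 0.1,
                      frip = fr$frip$frip, rho = 0.008)
    tsv <- file.path(d, "pairs.tsv")
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    bg <- runCommand("estimate-bg", list(outdir = d, table = tsv))
    expect_equal(bg$background$f_UT, 0.3, tolerance = 1e-12)

    dn <- runCommand("denoise",
                     list(outdir = d, frip = fr$frip$frip, f = 0.4,
                          rho = 0.008))
    expect_lt(abs(dn$frip_denoised - 1), 0.03)

    # YAML config path is accepted
    y <- file.path(d, "cfg.yaml")
    yaml::write_yaml(list(outdir = d, frip = 0.3032, f = 0.4,
                          rho = 0.008), y)
    dn2 <- runCommand("denoise", y)
    expect_equal(dn2$frip_denoised, 0.5)
})
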