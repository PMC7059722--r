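## Small-scale configuration used by generator tests
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 314, chrom_lengths = c(chr1 = 3e5, chr2 = 2e5),
         n_baits = 10L, n_contacts = 50000L),
    list(...))
  do.call(sim_config, args)
}

test_that("generators are pure functions of the configuration", {
  cfg <- small_cfg()
  a <- simulate_pets(cfg)
  b <- simulate_pets(cfg)
  expect_identical(a$contacts, b$contacts)
  expect_identical(a$baits, b$baits)
  ra <- simulate_read_pairs(cfg, a$contacts, a$baits)
  rb <- simulate_read_pairs(cfg, b$contacts, b$baits)
  expect_identical(ra$pairs, rb$pairs)
  ## different seed, different library
  c2 <- simulate_pets(small_cfg(seed = 315))
  expect_false(identical(a$contacts, c2$contacts))
})

test_that("null configuration plants nothing and baits do not overlap", {
  cfg <- small_cfg()
  sim <- simulate_pets(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(sim$contacts$origin == "background"))
  hits <- GenomicRanges::findOverlaps(sim$baits, drop.self = TRUE)
  expect_length(hits, 0L)
  expect_equal(length(sim$baits), 10L)
})

test_that("intra-chromosomal distances follow the configured decay law", {
  cfg <- sim_config(seed = 271, chrom_lengths = c(chr1 = 1e6),
                    n_baits = 2L, n_contacts = 100000L, f_trans = 0)
  sim <- simulate_pets(cfg)
  d <- abs(sim$contacts$pos2 - sim$contacts$pos1)
  ## analytic law of the retained |offset|: the shifted power law on the
  ## 1-kb step grid thinned by the boundary-survival factor (M - d)/M
  ## (uniform anchor, symmetric sign, out-of-bounds partners discarded)
  M <- 1e6
  dk <- ((1:1000) - 0.5) * 1000
  w <- (1 + dk / cfg$decay_d0)^(-cfg$decay_gamma) * pmax(M - dk, 0) / M
  cdf_th <- cumsum(w) / sum(w)
  step <- pmin(ceiling(d / 1000), 1000)
  cdf_emp <- cumsum(tabulate(step, 1000)) / length(step)
  ks <- max(abs(cdf_emp - cdf_th))
  expect_lt(ks, 0.02)
  ## monotone decreasing histogram over the first steps
  h <- tabulate(step, 20)
  expect_true(all(diff(h[1:10]) < 0))
})

test_that("artifact injection matches configured rates", {
  cfg <- small_cfg(self_ligation_rate = 0.1, duplicate_rate = 0,
                   low_mapq_rate = 0)
  sim <- simulate_pets(cfg)
  rp <- simulate_read_pairs(cfg, sim$contacts, sim$baits)
  n <- nrow(sim$contacts)
  ## self-ligation truth within 3 binomial SE of rate * n
  expect_lt(abs(rp$truth[["n_self_ligation"]] - 0.1 * n),
            3 * sqrt(n * 0.1 * 0.9) + 1)
  ## with duplicate rate 0, dedup removes only coordinate collisions
  ded <- dedup_pairs(rp$pairs)
  expect_gt(nrow(ded) / nrow(rp$pairs), 0.97)
  ## extract_pets recovers the planted self-ligations (plus library pairs
  ## that happen to fall inside one bait)
  px <- extract_pets(ded, sim$baits)
  expect_gte(px$summary[["self_ligation"]], 0.8 * rp$truth[["n_self_ligation"]])
  ## duplicates injected at 20% inflate the pair count accordingly
  cfg2 <- small_cfg(duplicate_rate = 0.2)
  sim2 <- simulate_pets(cfg2)
  rp2 <- simulate_read_pairs(cfg2, sim2$contacts, sim2$baits)
  expect_equal(rp2$truth[["n_duplicates"]] / (nrow(rp2$pairs) -
                 rp2$truth[["n_duplicates"]]), 0.2, tolerance = 0.02)
})

test_that("junction reads appear at the configured fraction and trim correctly", {
  cfg <- sim_config(seed = 99, chrom_lengths = c(chr1 = 1e5),
                    n_baits = 2L, n_contacts = 2000L,
                    junction_fraction = 0.2)
  sim <- simulate_pets(cfg)
  rp <- simulate_read_pairs(cfg, sim$contacts, sim$baits, sequences = TRUE)
  n <- length(rp$reads)
  frac <- rp$truth[["n_junction_reads"]] / n
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  trimmed <- trim_at_junction(rp$reads, min_len = 20)
  changed <- sum(!is.na(trimmed) & trimmed != rp$reads) +
    sum(is.na(trimmed))
  expect_equal(changed, rp$truth[["n_junction_reads"]])
  ## trimmed survivors no longer contain the site
  expect_false(any(grepl("GATC", trimmed[!is.na(trimmed)], fixed = TRUE)))
})

test_that("planted loops enrich contacts by the configured fold", {
  loops <- data.frame(bait = "bait003", chrom = NA, start = NA, end = NA,
                      fold = 30)
  cfg <- small_cfg()
  baits <- simulate_baits(cfg)
  b <- baits[mc(baits)$bait_id == "bait003"]
  loops$chrom <- as.character(GenomeInfoDb::seqnames(b))
  loops$start <- GenomicRanges::start(b) + 60000
  loops$end <- loops$start + 3999
  cfg2 <- small_cfg(loops = loops)
  sim <- simulate_pets(cfg2)
  expect_equal(nrow(sim$truth), 1L)
  expect_gt(sim$truth$n_planted, 0)
  ## planted count consistent with (fold - 1) x expected baseline
  mu <- (30 - 1) * sim$truth$expected_base
  expect_lt(abs(sim$truth$n_planted - mu),
            4 * sqrt(mu + mu^2 / cfg2$dispersion) + 2)
  ## fold = 1 plants nothing
  loops$fold <- 1
  sim1 <- simulate_pets(small_cfg(loops = loops))
  expect_equal(sim1$truth$n_planted, 0L)
})

test_that("time-course generator couples interactions to expression", {
  prom <- data.frame(promoter_id = sprintf("p%02d", 1:8),
                     class = rep(c("activated", "repressed"), each = 4))
  cfg0 <- small_cfg(noise_sd = 0, coupling_slope = 1)
  tc <- simulate_timecourse(cfg0, prom)
  ## zero noise, slope 1: E-P trajectory equals expression, r = 1
  for (i in 1:8)
    expect_equal(correlate_expression(tc$signals$`3C-EP`[i, ],
                                      tc$signals$RNA[i, ])$r, 1)
  ## activated monotone increasing, repressed monotone decreasing at SD 0
  expect_true(all(apply(tc$signals$RNA[1:4, ], 1,
                        function(v) all(diff(v) > 0))))
  expect_true(all(apply(tc$signals$RNA[5:8, ], 1,
                        function(v) all(diff(v) < 0))))
  ## with noise, cohort-mean correlation recovers the planted coupling sign
  cfgN <- small_cfg()
  tcN <- simulate_timecourse(cfgN, prom)
  for (cls in list(1:4, 5:8)) {
    mu_ep <- colMeans(t(apply(tcN$signals$`3C-EP`[cls, ], 1,
                              normalize_timecourse)))
    mu_rna <- colMeans(t(apply(tcN$signals$RNA[cls, ], 1,
                               normalize_timecourse)))
    expect_gt(correlate_expression(mu_ep, mu_rna)$r, 0.5)
  }
})
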