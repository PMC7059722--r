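test_that("h_score normalizes by peak size and SE-mean PET count", {
  expect_equal(h_score(c(10, 20, 30), c(1, 1, 1)), c(0.5, 1, 1.5))
  ## scale invariance in EN
  expect_equal(h_score(7 * c(10, 20, 30), c(1, 1, 1)),
               h_score(c(10, 20, 30), c(1, 1, 1)))
  ## independent spreadsheet-style arithmetic
  EN <- c(7, 3, 5, 9); L <- c(2, 1, 1, 3)
  want <- c(7 / (2 * 6), 3 / (1 * 6), 5 / (1 * 6), 9 / (3 * 6))
  expect_equal(h_score(EN, L), want)
  expect_warning(z <- h_score(c(0, 0), c(1, 2)), "zero")
  expect_equal(z, c(0, 0))
  expect_error(h_score(1:3, 1:2), "length")
  ## identity: sum(H * L) = s for any SE
  set.seed(41)
  for (i in 1:20) {
    s <- sample(2:10, 1)
    EN <- sample(0:50, s, TRUE); EN[1] <- EN[1] + 1  # not all zero
    L <- runif(s, 0.5, 5)
    expect_equal(sum(h_score(EN, L) * L), s)
  }
})

test_that("gamma-null hub calling recovers planted upper-tail outliers", {
  set.seed(55)
  n <- 500
  h0 <- rgamma(n, shape = 2, rate = 1)
  planted <- rep(qgamma(0.999, 2, 1), 5)
  df <- data.frame(enhancer_id = sprintf("e%03d", 1:(n + 5)),
                   se_id = rep(sprintf("SE%02d", 1:101), each = 5),
                   H = c(h0, planted))
  out <- call_hubs(df, alpha = 0.05)
  planted_rows <- (n + 1):(n + 5)
  expect_gte(sum(out$enhancers$hub[planted_rows]), 4)
  ## false-hub rate among null draws approximately alpha
  fpr <- mean(out$enhancers$hub[1:n])
  expect_lt(fpr, 0.10)
  expect_gt(fpr, 0.01)
  ## hub calls sit above the fitted (1 - alpha) quantile
  q95 <- qgamma(0.95, out$fit$shape, out$fit$rate)
  expect_true(all(out$enhancers$H[out$enhancers$hub] >= q95))
})

test_that("hub calling degenerates safely and the fit is unit-invariant", {
  df <- data.frame(enhancer_id = as.character(1:30), se_id = "SE1",
                   H = rep(2, 30))
  expect_warning(out <- call_hubs(df), "equal")
  expect_false(any(out$enhancers$hub))
  expect_error(call_hubs(data.frame(enhancer_id = "a", se_id = "s", H = 1)),
               "too few")
  ## global rescaling of all L rescales H but not the hub calls
  set.seed(66)
  base <- data.frame(enhancer_id = as.character(1:200),
                     se_id = rep(sprintf("S%d", 1:40), each = 5),
                     EN = rpois(200, 20) + 1, L = runif(200, 1, 3))
  a <- call_hubs(base)
  base2 <- base; base2$L <- base2$L * 1000   # switch units kb -> bp
  b <- call_hubs(base2)
  expect_equal(a$enhancers$hub, b$enhancers$hub)
  expect_equal(a$enhancers$p_value, b$enhancers$p_value, tolerance = 1e-6)
})

test_that("hierarchical SEs are exactly those with at least one hub", {
  enh <- data.frame(se_id = c("A", "A", "A", "B", "B", "C"),
                    hub = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  out <- classify_hierarchical(enh)
  expect_equal(out$hierarchical[match(c("A", "B", "C"), out$se_id)],
               c(TRUE, FALSE, TRUE))
  expect_equal(out$n_enhancers[match("A", out$se_id)], 3L)
  ## fraction matches brute-force enumeration on a random cohort
  set.seed(8)
  enh2 <- data.frame(se_id = sample(sprintf("SE%02d", 1:30), 200, TRUE),
                     hub = runif(200) < 0.1)
  out2 <- classify_hierarchical(enh2)
  brute <- sapply(split(enh2$hub, enh2$se_id), any)
  expect_equal(mean(out2$hierarchical), mean(brute))
  ## the printed hierarchical fraction worked example
  expect_equal(capture_rate(40, 156), 25.6)
})

test_that("SE interaction partners are labeled SE-P > SE-G > SE-O", {
  genes <- data.frame(gene_id = c("g1", "g2"), gene_name = c("g1", "g2"),
                      chrom = "chr1", start = c(10000, 50000),
                      end = c(20000, 60000), strand = c("+", "-"),
                      tss = c(10000, 60000))
  calls <- data.frame(chrom = "chr1",
                      start = c(9500, 15000, 80000, 55000),
                      end = c(9600, 15100, 80100, 55100))
  lab <- categorize_se_interactions(calls, genes, promoter_window = 2000)
  expect_equal(lab, c("SE-P", "SE-G", "SE-O", "SE-G"))
  ## partner in a promoter window inside a gene body is SE-P by precedence
  lab2 <- categorize_se_interactions(
    data.frame(chrom = "chr1", start = 10500, end = 10600), genes, 2000)
  expect_equal(lab2, "SE-P")
})

test_that("SE-gene patterns label bipartite components and partition SEs", {
  links <- data.frame(
    se_id = c("SE1", "SE2", "SE2", "SE3", "SE4", "SE4", "SE5"),
    gene_id = c("gA", "gB", "gC", "gD", "gD", "gE", "gE"),
    tss = 0, mid = 0, x = 1, bf = 25)
  pat <- classify_se_gene_patterns(links, sprintf("SE%d", 1:6))
  get <- function(id) pat$pattern[pat$se_id == id]
  expect_equal(get("SE1"), "single SE to single gene")
  expect_equal(get("SE2"), "single SE to multiple genes")
  ## SE3, SE4, SE5 share genes gD/gE -> one component, multiple SEs/genes
  expect_equal(get("SE4"), "multiple SEs to multiple genes")
  expect_equal(get("SE3"), "multiple SEs to multiple genes")
  expect_equal(get("SE6"), "no significant interacting gene")
  expect_equal(nrow(pat), 6L)
  ## multiple SEs to single gene
  l2 <- data.frame(se_id = c("SEa", "SEb"), gene_id = "g1", tss = 0,
                   mid = 0, x = 1, bf = 25)
  p2 <- classify_se_gene_patterns(l2, c("SEa", "SEb"))
  expect_true(all(p2$pattern == "multiple SEs to single gene"))
})

test_that("SE-gene distance uses the strongest interacting enhancer", {
  links <- data.frame(se_id = "SE1", gene_id = "gA", tss = 50000,
                      mid = c(10000, 30000), x = c(5, 9), bf = c(30, 25))
  d <- se_gene_distance(links)
  expect_equal(d$distance, 20000)   # from the PET-9 enhancer
  ## tie on x broken by higher BF, then leftmost
  links2 <- data.frame(se_id = "SE1", gene_id = "gA", tss = 50000,
                       mid = c(10000, 30000), x = c(9, 9), bf = c(40, 25))
  expect_equal(se_gene_distance(links2)$distance, 40000)
  links3 <- data.frame(se_id = "SE1", gene_id = "gA", tss = 50000,
                       mid = c(10000, 30000), x = c(9, 9), bf = c(25, 25))
  expect_equal(se_gene_distance(links3)$distance, 40000)  # leftmost mid
  ## cohort-level hierarchical vs non-hierarchical distance comparison
  ## matches the textbook two-sample t statistic
  set.seed(99)
  dh <- rnorm(30, 60000, 10000); dn <- rnorm(40, 40000, 10000)
  tt <- t.test(dh, dn, var.equal = TRUE)
  sp <- sqrt(((30 - 1) * var(dh) + (40 - 1) * var(dn)) / (30 + 40 - 2))
  tstat <- (mean(dh) - mean(dn)) / (sp * sqrt(1 / 30 + 1 / 40))
  expect_equal(unname(tt$statistic), tstat, tolerance = 1e-12)
})
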