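test_that("Spearman rho matches the rank-difference formula", {
  s <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 1 - 6 * 4 / (5 * 24))   # 0.8
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)   # monotone -> 1
  expect_equal(spearman_cor(1:6, (1:6)^3)$p, 0)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  # constant input -> undefined, flagged
  s0 <- spearman_cor(rep(1, 5), 1:5)
  expect_false(s0$defined)
  expect_true(is.na(s0$rho))
})

test_that("Spearman p approximates the exact permutation null for small n", {
  set.seed(55)
  for (r in 1:10) {
    n <- sample(5:7, 1)
    x <- sample(100, n); y <- sample(100, n)
    s <- spearman_cor(x, y)
    p_exact <- spearman_perm_p(x, y)
    expect_true(s$approx_flagged)
    expect_lt(abs(s$p - p_exact), 0.12)
  }
})

test_that("Spearman rho is symmetric and monotone-invariant", {
  set.seed(56)
  x <- rnorm(20); y <- rnorm(20)
  expect_identical(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, y^3 + 5)$rho,
               spearman_cor(x, sign(y) * abs(y))$rho)
  # agreement with the standard implementation
  expect_equal(spearman_cor(x, y)$rho,
               unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(spearman_cor(x, y)$p, ct$p.value, tolerance = 1e-9)
})

test_that("network edges obey the strict |rho| and p thresholds", {
  # a pair with sample rho exactly 0.30 must be excluded ("above 0.3")
  x <- 1:5
  y <- c(4, 1, 3, 2, 5)   # sum d^2 = 14 -> rho = 1 - 84/120 = 0.3
  expect_equal(spearman_cor(x, y)$rho, 0.3)
  set.seed(57)
  filler <- matrix(rexp(5 * 2), 5, 2)
  tab <- abundance_table(cbind(A = x, B = y, C = filler[, 1], D = filler[, 2]),
                         sample_ids = paste0("s", 1:5))
  net <- build_network(tab, rho_min = 0.3, p_max = 1, min_mean = 0)
  ab <- net$edges[(net$edges$from == "A" & net$edges$to == "B") |
                  (net$edges$from == "B" & net$edges$to == "A"), ]
  expect_identical(nrow(ab), 0L)
})

test_that("a planted correlated pair is detected and signed", {
  # compositions are constructed directly as fractions so the planted
  # structure survives the row closure
  set.seed(58)
  hits <- 0; runs <- 20
  for (r in seq_len(runs)) {
    n <- 27
    s <- runif(n, 0.2, 0.8)                 # shared share of taxa A + B
    a <- s * runif(n, 0.40, 0.60)           # positively coupled through s
    b <- s - a
    rest <- 1 - s
    c1 <- rest * runif(n, 0.3, 0.7)
    raw <- cbind(A = a, B = b, C = c1, D = rest - c1)
    tab <- abundance_table(raw, sample_ids = paste0("s", 1:n))
    net <- build_network(tab, min_mean = 0)
    found <- any((net$edges$from == "A" & net$edges$to == "B") |
                 (net$edges$from == "B" & net$edges$to == "A"))
    if (found) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
  # dominance trade-off gives a negative edge (sign "-")
  set.seed(59)
  n <- 30
  u <- runif(n, 0.1, 0.8)
  raw <- cbind(A = u, B = (0.9 - u) * runif(n, 0.8, 1), C = 0.1 * runif(n, 0.5, 1.5))
  tab <- abundance_table(raw, sample_ids = paste0("s", 1:n))
  net <- build_network(tab, min_mean = 0)
  ab <- net$edges[(net$edges$from == "A" & net$edges$to == "B") |
                  (net$edges$from == "B" & net$edges$to == "A"), ]
  expect_identical(nrow(ab), 1L)
  expect_identical(ab$sign, "-")
})

test_that("edge sets shrink monotonically in the thresholds", {
  set.seed(60)
  tab <- abundance_table(matrix(rexp(20 * 6), 20, 6,
    dimnames = list(paste0("s", 1:20), LETTERS[1:6])))
  loose <- build_network(tab, rho_min = 0.1, p_max = 0.5, min_mean = 0)
  tight_rho <- build_network(tab, rho_min = 0.4, p_max = 0.5, min_mean = 0)
  tight_p <- build_network(tab, rho_min = 0.1, p_max = 0.05, min_mean = 0)
  key <- function(net) paste(net$edges$from, net$edges$to)
  expect_true(all(key(tight_rho) %in% key(loose)))
  expect_true(all(key(tight_p) %in% key(loose)))
})

test_that("under independence the significant-pair rate stays near p_max", {
  # calibration of the Spearman p-value itself (independent vectors; a
  # closed composition cannot have fully independent columns)
  set.seed(61)
  rejections <- 0; tests <- 600
  for (r in seq_len(tests)) {
    s <- spearman_cor(rnorm(27), rnorm(27))
    if (s$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / tests, 0.05 + 2 * sqrt(0.05 * 0.95 / tests))
})

test_that("too few surviving variables yield an empty network with a warning", {
  tab <- abundance_table(rbind(s1 = c(A = 0.99, B = 0.01),
                               s2 = c(A = 0.98, B = 0.02),
                               s3 = c(A = 0.97, B = 0.03)))
  expect_warning(net <- build_network(tab, min_mean = 0.5), "fewer than 2")
  expect_identical(nrow(net$edges), 0L)
})

test_that("graph exports round-trip (edge TSV) and emit well-formed GraphML", {
  set.seed(62)
  n <- 30
  u <- runif(n)
  raw <- cbind(A = u + rnorm(n, 0, 0.1) + 0.5, B = u + rnorm(n, 0, 0.1) + 0.5,
               C = rexp(n))
  tab <- abundance_table(raw, sample_ids = paste0("s", 1:n))
  net <- build_network(tab, min_mean = 0)
  expect_gt(nrow(net$edges), 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(net, tsv, format = "edge_tsv")
  back <- read_edge_tsv(tsv)
  expect_identical(back$from, net$edges$from)
  expect_equal(back$rho, net$edges$rho, tolerance = 1e-12)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, gml, format = "graphml")
  doc <- xml2::read_xml(gml)   # parse error would fail the test
  expect_identical(xml2::xml_name(doc), "graphml")
  # empty network still writes a valid file
  empty <- suppressWarnings(build_network(tab, rho_min = 0.999, min_mean = 0))
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, gml2, format = "graphml")
  expect_identical(xml2::xml_name(xml2::read_xml(gml2)), "graphml")
  expect_error(export_graph(net, tsv, format = "dot"), "arg")
})

test_that("taxa-environment heatmap recovers planted monotone couplings", {
  ok <- 0; runs <- 15
  for (s in seq_len(runs)) {
    coh <- generate_cohort(cohort_config(n_subjects = 6,
                                         days = c(1, 4, 9, 15, 21, 27),
                                         p_flu = 1), seed = s)
    hm <- correlation_heatmap_table(coh$table, coh$env)
    r <- hm$rho["Bifidobacteriaceae", ]
    if (r[["acetate_mM"]] > 0 && r[["pH"]] < 0 && r[["oligo_mM"]] < 0)
      ok <- ok + 1
  }
  expect_gte(ok / runs, 0.95)
})

test_that("heatmap cells are untestable for constant or sparse variables", {
  tab <- abundance_table(matrix(rexp(12), 4, 3,
    dimnames = list(paste0("s", 1:4), c("A", "B", "C"))))
  env <- environment_table(paste0("s", 1:4), constant = rep(2, 4),
                           sparse = c(1, NA, NA, NA))
  hm <- correlation_heatmap_table(tab, env)
  expect_true(all(hm$untestable[, "constant"]))
  expect_true(all(hm$untestable[, "sparse"]))
  expect_true(all(hm$n[, "sparse"] == 1))
  # permuting the (aligned) sample order leaves cells unchanged
  set.seed(63)
  env2 <- environment_table(paste0("s", 1:4), v = c(0.2, 0.9, 0.4, 0.7))
  hm1 <- correlation_heatmap_table(tab, env2)
  perm <- c(3, 1, 4, 2)
  tabp <- abundance_table(unclass(tab)[perm, ])
  envp <- env2[perm, ]
  hm2 <- correlation_heatmap_table(tabp, envp)
  expect_equal(hm2$rho, hm1$rho, tolerance = 1e-12)
})
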