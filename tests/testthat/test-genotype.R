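test_that("growth classification thresholds the smoothed saturating OD", {
  times <- seq(0, 40, by = 2)
  logistic <- function(cap) cap / (1 + (cap / 0.01 - 1) * exp(-0.4 * times))
  expect_identical(classify_growth(times, logistic(0.9))$label, "grower")
  expect_identical(classify_growth(times, logistic(0.2))$label, "non_grower")
  expect_identical(classify_growth(times, logistic(0.5))$label, "indeterminate")
  # a single-well spike does not flip a non-grower
  od <- logistic(0.2)
  od[10] <- 1.4
  expect_identical(classify_growth(times, od)$label, "non_grower")
  # replicates averaged pointwise
  m <- cbind(logistic(0.9), logistic(0.9) * 1.05)
  expect_gt(classify_growth(times, m)$saturating_od, 0.7)
  expect_error(classify_growth(times, logistic(0.9), high = 0.3, low = 0.7),
               "exceed")
  expect_error(classify_growth(c(0, 0, 1), logistic(0.9)[1:3]), "increasing")
})

test_that("noiseless synthetic curves reproduce the generating phenotype", {
  cfg <- panel_config(n_strains = 12, n_groups = 20, n_growers = 6,
                      noise_sd = 0)
  panel <- generate_strain_panel(cfg, seed = 4)
  labels <- classify_growth_table(panel$curves)
  expect_identical(unname(labels[names(panel$phenotype)]),
                   unname(panel$phenotype))
})

test_that("ortholog groups files parse into presence matrices and round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("HG_1: A|g1 A|g2 B|g3", "HG_2: C|g9"), path)
  m <- read_ortholog_groups(path, panel = c("A", "B", "C"))
  expect_identical(m["A", "HG_1"], 1L)
  expect_identical(m["B", "HG_1"], 1L)
  expect_identical(m["C", "HG_1"], 0L)
  expect_identical(m["C", "HG_2"], 1L)
  # multiplicity retained on request
  mc <- read_ortholog_groups(path, panel = c("A", "B", "C"), counts = TRUE)
  expect_identical(mc["A", "HG_1"], 2L)
  # unparseable line is rejected with its number
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("HG_1: A|g1", "no-colon-here"), bad)
  expect_error(read_ortholog_groups(bad), "line 2")
  # strain outside the declared panel warns
  expect_warning(read_ortholog_groups(path, panel = c("A", "B")), "absent")
  # empty file
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_warning(m0 <- read_ortholog_groups(empty, panel = "A"), "empty")
  expect_identical(ncol(m0), 0L)
  # write/read round trip
  out <- withr::local_tempfile(fileext = ".txt")
  write_ortholog_groups(m, out)
  back <- read_ortholog_groups(out, panel = rownames(m))
  expect_identical(unclass(back), unclass(m))
})

test_that("the packaged 29-strain panel matches its published summary counts", {
  panel <- table1_panel()
  expect_identical(nrow(panel$presence), 29L)
  expect_identical(sum(panel$phenotype == "grower"), 14L)
  expect_identical(sum(panel$phenotype == "non_grower"), 15L)
  non_growers <- names(panel$phenotype)[panel$phenotype == "non_grower"]
  fucosidase <- rowSums(panel$presence[, c("GH29", "GH95")]) > 0
  expect_identical(sum(fucosidase[non_growers]), 6L)
  # every robust grower carries at least one fucosidase gene
  growers <- names(panel$phenotype)[panel$phenotype == "grower"]
  expect_true(all(fucosidase[growers]))
})

test_that("the concordance screen singles out the transporter SBP group", {
  panel <- table1_panel()
  res <- concordance_screen(panel$presence, panel$phenotype,
                            max_exceptions = 1, orientations = "presence_positive")
  expect_identical(nrow(res$hits), 1L)
  expect_identical(res$hits$group_id, "SBP")
  expect_identical(res$hits$n_match, 28L)
  expect_identical(res$hits$n_exceptions, 1L)
  expect_match(res$hits$exceptions, "BI-14 \\(absent_but_grower\\)")
  # GH95 concordance has 5 present-but-non-grower exceptions (the
  # limited-growth B. breve strains) and is excluded at max_exceptions = 1
  pres <- unclass(panel$presence)
  y <- as.integer(panel$phenotype == "grower")
  expect_identical(sum((pres[, "GH95"] > 0) == y), 24L)
  res5 <- concordance_screen(panel$presence, panel$phenotype,
                             max_exceptions = 5, orientations = "presence_positive")
  gh95 <- res5$hits[res5$hits$group_id == "GH95", ]
  expect_identical(gh95$n_exceptions, 5L)
  expect_identical(lengths(regmatches(gh95$exceptions,
    gregexpr("present_but_non_grower", gh95$exceptions))), 5L)
})

test_that("a column equal to the phenotype matches perfectly", {
  panel <- table1_panel()
  pres <- cbind(unclass(panel$presence),
                IDENT = as.integer(panel$phenotype == "grower"))
  pres <- structure(pres, class = c("gene_presence_matrix", "matrix", "array"))
  res <- concordance_screen(pres, panel$phenotype, max_exceptions = 0,
                            orientations = "presence_positive")
  expect_identical(res$hits$group_id, "IDENT")
  expect_identical(res$hits$n_match, 29L)
  expect_identical(res$hits$exceptions, "")
})

test_that("the screen equals brute force and is order-invariant", {
  set.seed(81)
  for (r in 1:5) {
    n <- 20; g <- 100
    pres <- matrix(rbinom(n * g, 1, 0.5), n,
                   dimnames = list(sprintf("S%02d", 1:n), sprintf("G%03d", 1:g)))
    y <- setNames(sample(rep(c("grower", "non_grower"), c(8, 12))),
                  rownames(pres))
    maxe <- sample(2:6, 1)
    res <- concordance_screen(
      structure(pres, class = c("gene_presence_matrix", "matrix", "array")),
      y, max_exceptions = maxe)
    oracle <- brute_concordance(pres, as.integer(y[rownames(pres)] == "grower"), maxe)
    expect_identical(res$hits$group_id, oracle$group_id)
    expect_identical(res$hits$n_exceptions, oracle$n_exceptions)
    expect_identical(res$hits$orientation, oracle$orientation)
    # reorder strains and groups: same hits
    sp <- sample(n); gp <- sample(g)
    res2 <- concordance_screen(
      structure(pres[sp, gp], class = c("gene_presence_matrix", "matrix", "array")),
      y, max_exceptions = maxe)
    expect_identical(res2$hits, res$hits)
  }
})

test_that("indeterminate strains are excluded and tiny classes rejected", {
  pres <- structure(matrix(c(1, 1, 0, 0, 1), 5, 1,
                           dimnames = list(paste0("s", 1:5), "G1")),
                    class = c("gene_presence_matrix", "matrix", "array"))
  y <- setNames(c("grower", "grower", "non_grower", "non_grower", "indeterminate"),
                paste0("s", 1:5))
  res <- concordance_screen(pres, y, max_exceptions = 0)
  expect_identical(res$excluded, "s5")
  expect_identical(res$n_strains, 4L)
  y2 <- setNames(c("grower", rep("non_grower", 4)), paste0("s", 1:5))
  expect_error(concordance_screen(pres, y2), "at least 2")
})

test_that("planted discriminating groups are uniquely recovered across seeds", {
  hits <- 0; runs <- 25
  cfg <- panel_config(n_strains = 29, n_groups = 400, n_exceptions = 1)
  for (s in seq_len(runs)) {
    panel <- generate_strain_panel(cfg, seed = s)
    res <- concordance_screen(panel$presence, panel$phenotype, max_exceptions = 1)
    top <- res$hits[res$hits$n_exceptions == min(res$hits$n_exceptions), ]
    if (nrow(res$hits) >= 1 && nrow(top) == 1 &&
        top$group_id == panel$planted_group) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})
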