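test_that("criterion 1 reduces to the hypergeometric closed form", {
  prots <- sprintf("P%03d", 1:100)
  tissues <- c("liver", "brain")
  # 10 liver-elevated proteins
  cells <- lapply(prots[1:10], function(p) c(p, "liver"))
  expr <- toy_expression(prots, tissues, elevated_cells = cells)

  # all ten associated proteins elevated: p = 1 / C(100,10)
  r <- criterion1_overrepresentation(prots[1:10], "liver", expr, prots)
  expect_equal(r$p, 1 / choose(100, 10))
  expect_true(r$flag)

  # zero elevated associated proteins
  r0 <- criterion1_overrepresentation(prots[11:30], "liver", expr, prots)
  expect_equal(r0$p, 1)
  expect_false(r0$flag)

  # associated set = universe: overlap equals the margin, p = 1
  rall <- criterion1_overrepresentation(prots, "liver", expr, prots)
  expect_equal(rall$p, 1)

  expect_error(criterion1_overrepresentation(prots[1:5], "kidney", expr, prots),
               "kidney")
})

test_that("criterion 2 flags counts above the normal-theory upper bound", {
  counts <- c(rep(1, 9), 20)
  r <- criterion2_count_outlier(counts)
  expect_equal(r$upper_bound, mean(counts) + 1.96 * sd(counts))
  expect_equal(mean(counts), 2.9)
  expect_equal(sd(counts), 6.008, tolerance = 1e-3)
  expect_identical(which(r$flags), 10L)

  # equal counts: zero SD, strict inequality flags nothing
  req <- criterion2_count_outlier(rep(4, 12))
  expect_false(any(req$flags))
  # all-zero counts flag nothing
  expect_false(any(criterion2_count_outlier(rep(0, 8))$flags))
  expect_error(criterion2_count_outlier(3), "two tissues")
})

test_that("criterion 2 is invariant to tissue ordering", {
  set.seed(14)
  counts <- rpois(36, 2) + c(rep(0, 35), 15)
  perm <- sample(36)
  r1 <- criterion2_count_outlier(counts)
  r2 <- criterion2_count_outlier(counts[perm])
  expect_equal(r1$upper_bound, r2$upper_bound)
  expect_identical(r1$flags[perm], r2$flags)
})

test_that("criterion 3 detects uniformly elevated partner expression", {
  prots <- sprintf("P%02d", 1:20)
  tissues <- sprintf("t%02d", 1:10)
  expr <- toy_expression(prots, tissues, base = 10)
  # liver = t01 at 10x the other-tissue median for every partner
  expr$ntpm[, "t01"] <- 100
  r <- criterion3_expression_elevation(prots, "t01", expr)
  expect_lt(r$p, 0.05)
  expect_true(r$flag)

  # identical to the paired medians: all differences zero, no signal
  flat <- toy_expression(prots, tissues, base = 10)
  rf <- criterion3_expression_elevation(prots, "t01", flat)
  expect_false(rf$flag)

  # fewer than two detected partners: missing p
  low <- toy_expression(prots, tissues, base = 0.5)
  low$ntpm["P01", "t01"] <- 50
  rl <- criterion3_expression_elevation(prots, "t01", low)
  expect_true(is.na(rl$p))
  expect_false(rl$flag)
  expect_identical(rl$n_detected, 1L)

  # undetected partners (nTPM <= 1) are excluded from the test
  mixed <- toy_expression(prots, tissues, base = 10)
  mixed$ntpm[1:5, ] <- 0.05
  mixed$ntpm[, "t01"] <- mixed$ntpm[, "t01"] * 10
  rm2 <- criterion3_expression_elevation(prots, "t01", mixed)
  expect_identical(rm2$n_detected, 15L)
  expect_true(rm2$flag)
})

test_that("relevance calls combine eligibility, criteria and reliability", {
  prots <- sprintf("P%02d", 1:40)
  tissues <- sprintf("t%02d", 1:8)
  partners <- prots[1:10]
  cells <- lapply(partners, function(p) c(p, "t01"))
  expr <- toy_expression(prots, tissues, base = 10, fold = 10,
                         elevated_cells = cells)

  calls <- call_tissue_relevance("M1", partners, expr)
  liver <- calls[calls$tissue == "t01", ]
  expect_true(liver$eligible)
  expect_identical(liver$n_criteria, 3L)
  expect_identical(liver$category, "Tissue Relevant")
  expect_identical(liver$reliability, "High")
  # other tissues have no elevated partners: ineligible, Unknown
  expect_true(all(calls$category[calls$tissue != "t01"] == "Unknown"))

  # ineligibility dominates: no flags on ineligible tissues
  expect_false(any(calls$c1[!calls$eligible] | calls$c2[!calls$eligible] |
                     calls$c3[!calls$eligible]))

  # exactly 2 elevated partners in a tissue: below the >= 3 cutoff
  two <- toy_expression(prots, tissues, base = 10,
                        elevated_cells = list(c("P01", "t02"), c("P02", "t02")))
  calls2 <- call_tissue_relevance("M1", partners, two)
  expect_false(calls2$eligible[calls2$tissue == "t02"])

  # one criterion (overrepresentation only) plus curated localization: Medium.
  # Three partners elevated in every tissue: equal counts disable criterion 2,
  # flat expression disables criterion 3, overlap 3/3 elevated among 10 of 40
  # proteins keeps criterion 1 (p = C(37,7)/C(40,10) < 0.05).
  every <- unlist(lapply(tissues, function(ts)
    lapply(prots[1:3], function(p) c(p, ts))), recursive = FALSE)
  elev_only <- toy_expression(prots, tissues, base = 10, fold = 1,
                              elevated_cells = every)
  calls3 <- call_tissue_relevance("M1", partners, elev_only,
                                  hmdb_localizations = "t01")
  t01 <- calls3[calls3$tissue == "t01", ]
  expect_identical(t01$n_criteria, 1L)
  expect_true(t01$c1 && !t01$c2 && !t01$c3)
  expect_identical(t01$reliability, "Medium")
  t02 <- calls3[calls3$tissue == "t02", ]
  expect_identical(t02$reliability, "Low")  # same criterion, no support there

  # zero associations: every tissue Unknown, not an error
  none <- call_tissue_relevance("M2", character(0), expr)
  expect_true(all(none$category == "Unknown"))
})

test_that("relevance summaries and tissue sets stratify by reliability", {
  calls <- data.frame(
    metabolite = c("M1", "M1", "M2", "M3"),
    tissue = c("liver", "gut", "liver", "brain"),
    eligible = c(TRUE, TRUE, TRUE, FALSE),
    category = c("Tissue Relevant", "Tissue Relevant", "Low tissue relevance",
                 "Unknown"),
    reliability = c("High", "Low", "n/a", "n/a"),
    stringsAsFactors = FALSE)
  s <- summarize_relevance(calls)
  expect_identical(s$n_pairs_relevant, 2L)
  expect_identical(s$n_pairs_by_reliability[["High"]], 1L)
  expect_identical(s$n_metabolites_by_category[["Tissue Relevant"]], 1L)
  expect_identical(s$n_metabolites_by_category[["Low tissue relevance"]], 1L)
  expect_identical(s$n_metabolites_by_category[["Unknown"]], 1L)

  sets <- tissue_sets_from_calls(calls)
  expect_identical(sets, list(liver = "M1"))  # Low-reliability pair excluded
})

test_that("tissue enrichment ranks the matching tissue first", {
  sets <- list(liver = sprintf("M%02d", 1:10),
               brain = sprintf("M%02d", 11:18),
               gut = sprintf("M%02d", 19:25))
  res <- tsa_enrichment(sprintf("M%02d", 1:10), sets)
  expect_identical(res$term_id[1], "liver")
  expect_lt(res$p_raw[1], 0.05)

  # query disjoint from every tissue set
  res0 <- tsa_enrichment(sprintf("M%02d", 1:5), sets["brain"],
                         background = sprintf("M%02d", 1:25), adjust = "none")
  expect_true(all(res0$p_raw == 1))

  expect_error(tsa_enrichment(c("Z1", "Z2"), sets), "Z1")
})

test_that("expression tables round-trip through the long-format reader", {
  prots <- sprintf("P%02d", 1:4)
  tissues <- c("liver", "brain")
  expr <- toy_expression(prots, tissues,
                         elevated_cells = list(c("P01", "liver")))
  long <- data.frame(
    protein_id = rep(prots, times = 2),
    tissue = rep(tissues, each = 4),
    ntpm = as.vector(expr$ntpm),
    elevation_label = ifelse(as.vector(expr$elevated), "tissue enriched",
                             "none"))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression(path)
  expect_equal(back$ntpm[prots, tissues], expr$ntpm)
  expect_identical(back$elevated[prots, tissues], expr$elevated)

  long$elevation_label[1] <- "sort of elevated"
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(path), "elevation label")
})
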