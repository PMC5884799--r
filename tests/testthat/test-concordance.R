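makeConsensus <- function(id, dir, lfc, occ = 1L, group = "autoimmune",
                          n = 14L) {
  data.frame(canonical_id = id, group_label = group, direction = dir,
             occurrences = as.integer(occ), n_group = n,
             frequency = occ / n, mean_log2fc = lfc, conflict_flag = FALSE,
             opposite_count = 0L, stringsAsFactors = FALSE)
}

test_that("panel classification follows log2FC signs", {
  t1 <- loadFixturePanel("table1_non_treated")
  panel <- fixtureConsensus(t1, "group")
  aut <- fixtureConsensus(t1, "autoimmune")
  cls <- classifyPanel(panel, aut)
  status <- setNames(cls$comparator_status, cls$canonical_id)

  expect_equal(unname(status["CNTNAP2"]), "discordant")  # down vs up 2.03
  expect_equal(unname(status["SMAD4"]), "concordant")    # up vs up 1.2
  expect_equal(unname(status["ANKRD10"]), "ns")
  expect_true(is.na(cls$comparator_log2fc[cls$canonical_id == "ANKRD10"]))
  expect_equal(cls$comparator_occurrences[cls$canonical_id == "ANKRD10"], 0L)

  dup <- rbind(panel, panel[1, ])
  expect_error(classifyPanel(dup, aut), "duplicate")
})

test_that("summaries partition the panel and count correctly", {
  panel <- rbind(makeConsensus("A", "up", 2, group = "non_treated", n = 13),
                 makeConsensus("B", "down", -1.5, group = "non_treated",
                               n = 13),
                 makeConsensus("C", "up", 1.2, group = "non_treated", n = 13))
  comparator <- rbind(makeConsensus("A", "up", 1.1),
                      makeConsensus("B", "up", 2.2))
  cls <- classifyPanel(panel, comparator)
  s <- summarizeOverlap(cls)
  expect_equal(s$n_panel, 3L)
  expect_equal(s$n_overlap, 2L)
  expect_equal(s$n_concordant, 1L)
  expect_equal(s$n_discordant, 1L)
  expect_equal(s$n_overlap, s$n_concordant + s$n_discordant + s$n_ambiguous)
  expect_equal(s$n_concordant + s$n_discordant + s$n_ambiguous +
                 sum(cls$comparator_status == "ns"), s$n_panel)
  expect_equal(s$overlap_fraction, 2 / 3)

  empty <- summarizeOverlap(classifyPanel(panel[0, ], comparator))
  expect_equal(empty$n_panel, 0L)
  expect_equal(empty$n_overlap, 0L)
  expect_equal(empty$overlap_fraction, 0)
})

test_that("simultaneous sign flips leave concordance status unchanged", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    dirs <- sample(c("up", "down"), n, replace = TRUE)
    panel <- do.call(rbind, lapply(seq_len(n), function(j) {
      makeConsensus(paste0("g", j), dirs[j],
                    ifelse(dirs[j] == "up", 1, -1) * runif(1, 1, 3),
                    group = "non_treated", n = 13)
    }))
    hits <- sample(n, sample(0:n, 1))
    compDirs <- sample(c("up", "down"), length(hits), replace = TRUE)
    comparator <- if (length(hits)) {
      do.call(rbind, lapply(seq_along(hits), function(j) {
        makeConsensus(paste0("g", hits[j]), compDirs[j],
                      ifelse(compDirs[j] == "up", 1, -1) * runif(1, 1, 3))
      }))
    } else makeConsensus("dummy", "up", 1)[0, ]
    flip <- function(x) {
      x$direction <- ifelse(x$direction == "up", "down", "up")
      x$mean_log2fc <- -x$mean_log2fc
      x
    }
    a <- classifyPanel(panel, comparator)
    b <- classifyPanel(flip(panel), flip(comparator))
    expect_equal(a$comparator_status, b$comparator_status)
  }
})

test_that("tied comparator direction is surfaced as ambiguous overlap", {
  panel <- makeConsensus("G", "up", 2, group = "non_treated", n = 13)
  comparator <- makeConsensus("G", NA_character_, 0.1)
  cls <- classifyPanel(panel, comparator)
  expect_equal(cls$comparator_status, "ambiguous")
  s <- summarizeOverlap(cls)
  expect_equal(s$n_overlap, 1L)  # ambiguous still counts as overlapping
  expect_equal(s$n_concordant, 0L)
  expect_equal(s$n_discordant, 0L)
})

test_that("bundled panels reproduce every documented comparator count", {
  t1 <- loadFixturePanel("table1_non_treated")
  t2 <- loadFixturePanel("table2_treated")
  comparators <- c(virus = "virus", inflammation = "inflammation",
                   autoimmune = "autoimmune")
  sum1 <- comparatorSummary(fixtureConsensus(t1, "group"),
                            lapply(comparators, fixtureConsensus,
                                   panel = t1))
  sum2 <- comparatorSummary(fixtureConsensus(t2, "group"),
                            lapply(comparators, fixtureConsensus,
                                   panel = t2))
  get <- function(s, g, col) s[s$comparator_group == g, col]

  expect_equal(get(sum1, "virus", "n_overlap"), 3L)
  expect_equal(get(sum1, "inflammation", "n_concordant"), 2L)
  expect_equal(get(sum1, "autoimmune", "n_overlap"), 6L)
  expect_equal(get(sum1, "autoimmune", "n_discordant"), 3L)

  expect_equal(get(sum2, "virus", "n_concordant"), 4L)
  expect_equal(get(sum2, "inflammation", "n_overlap"), 3L)
  expect_equal(get(sum2, "autoimmune", "n_overlap"), 16L)
  expect_equal(get(sum2, "autoimmune", "overlap_fraction"), 1.0)
})
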