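test_that("campaign expansion matches the grid product", {
  both <- plan_campaign()
  expect_equal(nrow(both$runs), 90)
  tail_only <- plan_campaign(modes = "tail")
  expect_equal(nrow(tail_only$runs), 45)
  one <- plan_campaign(accelerations = 0.4, thresholds_d = 0.3,
                       snapshots = 1, modes = "head")
  expect_equal(nrow(one$runs), 1)
  expect_error(plan_campaign(accelerations = numeric(0)), "non-empty")

  # ordering is a-major, then d, then snapshot, then mode
  expect_true(!is.unsorted(both$runs$a))
  first_a <- both$runs[both$runs$a == 0.3, ]
  expect_true(!is.unsorted(first_a$d))
  expect_equal(both$runs$mode[1:2], c("head", "tail"))

  # per-run seeds are deterministic and distinct
  again <- plan_campaign()
  expect_identical(both$runs$seed, again$runs$seed)
  expect_equal(anyDuplicated(both$runs$seed), 0)

  set.seed(99)
  for (i in 1:200) {
    na <- sample(1:4, 1); nd <- sample(1:3, 1)
    ns <- sample(1:4, 1); nm <- sample(1:2, 1)
    pl <- plan_campaign(accelerations = seq(0.2, 0.6, length.out = na),
                        thresholds_d = seq(0.2, 0.5, length.out = nd),
                        snapshots = seq_len(ns),
                        modes = c("head", "tail")[seq_len(nm)])
    expect_equal(nrow(pl$runs), na * nd * ns * nm)
  }
})

test_that("exit points map to the pore between the flanking subunits", {
  rs <- closed_ring()
  az <- function(a, r = 20) c(r * cos(a), r * sin(a), 0)
  # midpoint between subunits 5 and 6
  mid56 <- (2 * pi * (4.5) / 16)
  expect_equal(assign_channel(az(mid56), rs), "5-6")
  expect_equal(assign_channel(az(2 * pi * 14.5 / 16), rs), "15-16")
  # wrap-around pore
  expect_equal(assign_channel(az(2 * pi * 15.5 / 16), rs), "16-1")
  # boundary tie-break: the clockwise edge of subunit 2's sector belongs to
  # the pore counterclockwise of subunit 2
  edge <- (2 * pi * 1 / 16 - rs$half_width) %% (2 * pi)
  expect_equal(assign_channel(az(edge), rs), "2-3")
  # inside the ring is not an exit
  expect_error(assign_channel(c(1, 0, 0), rs), "inside the ring")

  ro <- open_ring()
  gap_mid <- mean(2 * pi * c(14, 15) / 16)  # removed subunits 15, 16
  expect_equal(assign_channel(az(gap_mid), ro), "Gap")
})

test_that("channel assignment partitions the circle", {
  set.seed(12)
  for (sys in list(closed_ring(), open_ring(),
                   build_ring_system(5, open = TRUE, removed = c(2, 3)))) {
    azimuths <- runif(1e4, 0, 2 * pi)
    hits <- vapply(azimuths, function(a) {
      assign_channel(c(20 * cos(a), 20 * sin(a), 0), sys)
    }, "")
    expect_true(all(hits %in% sys$pores$label))
    # sector ownership widths sum to the full circle
    own <- (sys$pores$own_end - sys$pores$own_start) %% (2 * pi)
    expect_equal(sum(own), 2 * pi, tolerance = 1e-9)
    # observed frequencies match ownership widths (loose binomial check)
    freq <- table(factor(hits, levels = sys$pores$label)) / length(hits)
    expect_equal(as.numeric(freq), own / (2 * pi), tolerance = 0.05)
  }
})

test_that("channel tables reproduce the worked dissociation statistics", {
  tail_counts <- c("15-16" = 18, "16-1" = 8, "1-2" = 6, "2-3" = 5,
                   "5-6" = 2)
  tab <- channel_table(tail_counts, mode = "tail")
  expect_equal(tab$percentage[tab$channel == "15-16"], 46.2)
  expect_equal(tab$channel[1], "15-16")  # sorted by descending count
  expect_lte(abs(sum(tab$percentage) - 100), 0.2)

  # a supplied printed total is used, and a count mismatch is surfaced
  head_counts <- c("5-6" = 17, "3-4" = 8, "4-5" = 7, "2-3" = 1)
  expect_warning(tabh <- channel_table(head_counts, total = 34,
                                       mode = "head"),
                 "sum to 33")
  expect_equal(tabh$percentage[tabh$channel == "5-6"], 50.0)

  open_counts <- c("Gap" = 30, "4-5" = 3, "3-4" = 3, "1-2" = 2)
  tabo <- channel_table(open_counts, mode = "tail")
  expect_equal(tabo$percentage[tabo$channel == "Gap"], 78.9)

  expect_equal(channel_table(c("1-2" = 7))$percentage, 100.0)
  expect_error(channel_table(c("1-2" = 0)), "empty table")
  expect_error(channel_table(c("1-2" = -1)), "invalid argument")
})

test_that("event-derived tables are permutation invariant", {
  mk_ev <- function(pore, mode = "tail", occurred = TRUE) {
    if (occurred) {
      dissociation_event(TRUE, time = 1, exit_point = c(16, 0, 0),
                         pore_id = pore, mode = mode)
    } else dissociation_event(FALSE, mode = mode)
  }
  events <- c(lapply(rep("15-16", 6), mk_ev), lapply(rep("1-2", 3), mk_ev),
              lapply(rep("5-6", 1), mk_ev), list(mk_ev(NULL, occurred = FALSE)))
  tab <- channel_probabilities(events)
  expect_equal(tab$percentage[tab$channel == "15-16"], 60.0)
  expect_equal(attr(tab, "undissociated")[["tail"]], 1)

  set.seed(5)
  tab2 <- channel_probabilities(sample(events))
  expect_equal(tab[order(tab$channel), c("channel", "count", "percentage")],
               tab2[order(tab2$channel), c("channel", "count", "percentage")],
               ignore_attr = TRUE)

  only_undissociated <- list(mk_ev(NULL, occurred = FALSE))
  expect_error(channel_probabilities(only_undissociated), "empty table")
})

test_that("channel tables round-trip through TSV and CSV", {
  tab <- channel_table(c("15-16" = 18, "16-1" = 8), mode = "tail")
  tsv <- tempfile(fileext = ".tsv")
  write_channel_table(tab, tsv)
  back <- read_channel_table(tsv)
  expect_equal(back$channel, tab$channel)
  expect_equal(back$percentage, tab$percentage)
  csv <- tempfile(fileext = ".csv")
  write_channel_table(tab, csv, format = "csv")
  back2 <- read_channel_table(csv, format = "csv")
  expect_equal(back2$count, tab$count)
})
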