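test_that("filter_localizations applies inclusive thresholds and is idempotent", {
  # boundary values are retained: 20 photons, 40 nm
  one <- localization_table(1L, 0, 0, 20, 40)
  expect_identical(nrow(filter_localizations(one)), 1L)

  empty <- localization_table(integer(), numeric(), numeric(), numeric(),
                              numeric())
  expect_identical(nrow(filter_localizations(empty)), 0L)

  mixed <- localization_table(c(1L, 1L, 1L), c(0, 1, 2), c(0, 0, 0),
                              photons = c(19, 50, 50),
                              precision = c(30, 41, 39))
  kept <- filter_localizations(mixed)
  expect_equal(kept$x, 2)  # only the third row passes both thresholds

  # idempotence and order preservation on a random table
  set.seed(1)
  rnd <- localization_table(sample(1:50, 200, TRUE), runif(200), runif(200),
                            rpois(200, 30), runif(200, 10, 60))
  once <- filter_localizations(rnd)
  expect_identical(filter_localizations(once), once)
  expect_true(all(diff(match(paste(once$x, once$y),
                             paste(rnd$x, rnd$y))) > 0))
})

test_that("link_trajectories gates on distance and resolves ambiguity greedily", {
  mk <- function(frame, x, y)
    data.frame(frame = frame, x = x, y = y, photons = 100, precision = 20)

  near <- link_trajectories(mk(c(1L, 2L), c(0, 0.5), c(0, 0)))
  expect_identical(length(unique(near$trajectory)), 1L)
  expect_identical(nrow(near), 2L)

  far <- link_trajectories(mk(c(1L, 2L), c(0, 0.9), c(0, 0)))
  expect_identical(length(unique(far$trajectory)), 2L)

  # A=(0,0) in frame 1; B=(0.1,0), C=(0.3,0) in frame 2:
  # A links to its nearest neighbour B, C starts a new trajectory
  abc <- link_trajectories(mk(c(1L, 2L, 2L), c(0, 0.1, 0.3), c(0, 0, 0)))
  traj_a <- abc$trajectory[abc$frame == 1L]
  expect_identical(abc$trajectory[abc$x == 0.1], traj_a)
  expect_false(abc$trajectory[abc$x == 0.3] == traj_a)

  # a missing frame always terminates (no gap closing)
  gap <- link_trajectories(mk(c(1L, 3L), c(0, 0), c(0, 0)))
  expect_identical(length(unique(gap$trajectory)), 2L)

  expect_error(link_trajectories(mk(c(1L, 1L), c(0, 0), c(0, 0))),
               class = "sptkin_validation_error")
})

test_that("linking partitions input and respects the gate on random data", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 150L
    locs <- data.frame(frame = sample(1:25, n, TRUE),
                       x = runif(n, -1, 1), y = runif(n, -1, 1),
                       photons = 100, precision = 20)
    locs <- locs[!duplicated(locs[c("frame", "x", "y")]), ]
    tr <- link_trajectories(locs, max_jump = 0.4)
    # partition: every retained localization appears exactly once
    expect_identical(nrow(tr), nrow(locs))
    expect_identical(sort(paste(tr$frame, tr$x, tr$y)),
                     sort(paste(locs$frame, locs$x, locs$y)))
    # consecutive displacements within the gate, frames consecutive
    by_tr <- split(tr, tr$trajectory)
    for (g in by_tr) {
      if (nrow(g) > 1L) {
        expect_true(all(diff(g$frame) == 1L))
        expect_true(all(sqrt(diff(g$x)^2 + diff(g$y)^2) <= 0.4 + 1e-12))
      }
    }
  }
})

test_that("greedy linking agrees with the exhaustive min-cost oracle on sparse inputs", {
  # Greedy ascending-distance matching is not globally cost-optimal in
  # general; at realistic sparse densities it agrees with the
  # exhaustive maximal/minimal-cost assignment in the overwhelming
  # majority of cases, and always when one frame has a single point.
  set.seed(11)
  total <- 0L; agree <- 0L
  while (total < 100L) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    xy1 <- matrix(runif(2 * n1, -1, 1), ncol = 2)
    xy2 <- matrix(runif(2 * n2, -1, 1), ncol = 2)
    opt <- exhaustive_min_matching(xy1, xy2, 0.8)
    if (is.null(opt)) next  # optimum not unique
    locs <- data.frame(frame = c(rep(1L, n1), rep(2L, n2)),
                       x = c(xy1[, 1], xy2[, 1]),
                       y = c(xy1[, 2], xy2[, 2]),
                       photons = 100, precision = 20)
    tr <- link_trajectories(locs, 0.8)
    t1 <- tr$trajectory[match(paste(1L, xy1[, 1]), paste(tr$frame, tr$x))]
    t2 <- tr$trajectory[match(paste(2L, xy2[, 1]), paste(tr$frame, tr$x))]
    greedy <- vapply(seq_len(n1), function(i) {
      j <- which(t2 == t1[i])
      if (length(j) == 1L) j else 0L
    }, integer(1))
    total <- total + 1L
    if (identical(greedy, opt)) agree <- agree + 1L
    if (n1 == 1L || n2 == 1L) expect_identical(greedy, opt)
  }
  expect_gte(agree / total, 0.9)
})

test_that("Spot-On CSV round-trips and validates its format", {
  tr <- as_tracks(rbind(straight_track(3, id = 1L),
                        straight_track(2, step = 0.2, id = 2L,
                                       start_frame = 5L),
                        straight_track(4, step = 0.05, id = 3L,
                                       start_frame = 2L)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spoton_csv(tr, frame_interval = 0.02, path)
  back <- read_spoton_csv(path)
  expect_equal(back$frame, tr$frame)
  expect_equal(back$trajectory, tr$trajectory)
  expect_equal(back$x, tr$x)
  expect_equal(back$y, tr$y)
  expect_equal(attr(back, "frame_interval"), 0.02)

  # t column arithmetic: frames 1..3 at 0.02 s -> 0.00, 0.02, 0.04
  raw <- read.csv(path)
  expect_equal(raw$t[raw$trajectory == 1], c(0, 0.02, 0.04))

  # missing required column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,t,x,y", "1,0,0.1,0.2"), bad)
  expect_error(read_spoton_csv(bad), class = "sptkin_format_error")
  expect_error(read_spoton_csv(bad), "trajectory")

  # non-numeric cell names the row
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,t,trajectory,x,y", "1,0,1,0.1,0.2",
               "2,0.02,1,oops,0.2"), bad2)
  expect_error(read_spoton_csv(bad2), class = "sptkin_parse_error")
  expect_error(read_spoton_csv(bad2), "row 2")
})

test_that("localization CSV round-trips with validation", {
  locs <- loc_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations_csv(locs, path)
  back <- read_localizations_csv(path)
  expect_equal(back, locs)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,photons", "1,0,0,10"), bad)
  expect_error(read_localizations_csv(bad), class = "sptkin_format_error")
})
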