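test_that("time-delay embedding matches its definition", {
  expect_equal(time_delay_embed(0:4, 1, 2),
               rbind(c(1, 0), c(2, 1), c(3, 2), c(4, 3)))
  cst <- time_delay_embed(rep(2, 30), 10, 3)
  expect_true(all(cst == 2))
  expect_equal(nrow(cst), 30 - 20)
  expect_error(time_delay_embed(1:5, 10, 3), "too short")
})

test_that("a sine embedded at quarter-period delay lies on a circle", {
  fs <- 100; f0 <- 1
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * f0 * t)
  emb <- time_delay_embed(x, tau = fs / (4 * f0), m = 2)
  radii <- sqrt(rowSums(emb^2))
  expect_lt(max(abs(radii - 1)), 1e-6)
})

test_that("sublevel persistence matches the worked example", {
  d <- sublevel_persistence(c(0.0, 1.0, 0.2, 0.8, 0.1, 1.0))
  got <- d$pairs[order(d$pairs[, 1]), ]
  expect_equal(unname(got),
               rbind(c(0.0, 1.0), c(0.1, 1.0), c(0.2, 0.8)))
  expect_equal(sum(d$essential), 1L)
  expect_equal(unname(d$pairs[d$essential, ]), c(0.0, 1.0))
})

test_that("monotone series yield a single (min, max) pair", {
  d <- sublevel_persistence(c(1, 2, 5, 9))
  expect_equal(nrow(d$pairs), 1L)
  expect_equal(unname(d$pairs[1, ]), c(1, 9))
  expect_error(sublevel_persistence(c(1, NA, 2)), "NA")
})

test_that("sublevel persistence equals the brute-force oracle on random series", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(5:100, 1)
    x <- round(rnorm(n), 3)  # rounding provokes occasional ties/plateaus
    got <- sublevel_persistence(x)$pairs
    want <- oracle_sublevel(x)
    o1 <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    o2 <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(o1), unname(o2), tolerance = 1e-12)
  }
})

test_that("plateaus birth a single component", {
  d <- sublevel_persistence(c(3, 1, 1, 1, 3))
  expect_equal(nrow(d$pairs), 1L)
  d2 <- sublevel_persistence(c(3, 1, 1, 2, 0, 3))
  expect_equal(nrow(d2$pairs), 2L)
  expect_equal(unname(d2$pairs[!d2$essential, ]), c(1, 2))
})

test_that("number of pairs equals number of local minima on a sine", {
  t <- seq(0, 6, by = 0.01)
  x <- cos(2 * pi * t)          # 6 periods, 6 interior minima
  d <- sublevel_persistence(x)
  expect_equal(nrow(d$pairs), 6L)
  lifespans <- d$pairs[, 2] - d$pairs[, 1]
  expect_true(all(abs(lifespans - 2) < 0.01))  # peak-to-peak amplitude
})

test_that("diagrams shift with constants; lifespans are invariant", {
  set.seed(7)
  x <- rnorm(60)
  d1 <- sublevel_persistence(x)
  d2 <- sublevel_persistence(x + 5)
  expect_equal(d2$pairs[, 1], d1$pairs[, 1] + 5)
  expect_equal(d2$pairs[, 2] - d2$pairs[, 1], d1$pairs[, 2] - d1$pairs[, 1])
})

test_that("Rips persistence matches hand-computed fixtures", {
  sq <- rips_persistence(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(unname(sq$h1$pairs), matrix(c(1, sqrt(2)), 1))
  two <- rips_persistence(rbind(c(0, 0), c(3, 0)))
  expect_equal(unname(two$h0$pairs[!two$h0$essential, 2]), 3)
  expect_equal(nrow(two$h1$pairs), 0L)
  expect_error(rips_persistence(matrix(0, 0, 2)), "empty")
})

test_that("Rips H0 deaths equal MST edge lengths (random clouds <= 50 points)", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    pts <- matrix(rnorm(n * sample(2:3, 1)), nrow = n)
    got <- sort(rips_persistence(pts, 0)$h0$pairs[, 2])
    got <- got[is.finite(got)]
    expect_equal(got, oracle_mst_edges(pts), tolerance = 1e-10)
  }
})

test_that("dense circle H1 death approaches sqrt(3) R", {
  for (R in c(1, 2.5)) {
    th <- seq(0, 2 * pi, length.out = 201)[-201]
    pts <- R * cbind(cos(th), sin(th))
    h1 <- rips_persistence(pts)$h1$pairs
    death <- unname(h1[which.max(h1[, 2] - h1[, 1]), 2])
    expect_equal(death, sqrt(3) * R, tolerance = 0.05)
  }
})

test_that("birth-lifespan transform is an involution", {
  d <- persistence_diagram(rbind(c(0.2, 0.8), c(0, 1.5)), 1L)
  bl <- to_birth_lifespan(d)
  expect_equal(unname(bl$pairs), rbind(c(0.2, 0.6), c(0, 1.5)))
  expect_equal(to_birth_lifespan(bl)$pairs, d$pairs)
  empty <- persistence_diagram(matrix(0, 0, 2), 1L)
  expect_equal(nrow(to_birth_lifespan(empty)$pairs), 0L)
})

test_that("diagram spread is the single-linkage connection scale", {
  expect_equal(diagram_spread(cbind(c(0, 1, 5), c(0, 0, 0))), 4)
  expect_equal(diagram_spread(rbind(c(0, 0), c(0, 3))), 3)
  s <- 2
  tri <- s * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(diagram_spread(tri), s, tolerance = 1e-12)
  expect_true(is.na(diagram_spread(rbind(c(1, 1)))))
  # diameter reading available behind the switch
  expect_equal(diagram_spread(cbind(c(0, 1, 5), c(0, 0, 0)),
                              method = "diameter"), 5)
})

test_that("oversized clouds require subsampling", {
  pts <- matrix(rnorm(600), ncol = 3)
  expect_error(rips_persistence(pts, 1, max_points = 100), "subsample")
  sub <- subsample_cloud(pts, 50)
  expect_equal(nrow(sub), 50L)
  expect_equal(nrow(subsample_cloud(pts, 1e4)), 200L)
})

test_that("diagrams serialize to CSV in birth/death/lifespan form", {
  d0 <- sublevel_persistence(c(0, 1, 0.2, 0.8, 0.1, 1))
  d1 <- persistence_diagram(rbind(c(1, sqrt(2))), 1L)
  f <- tempfile(fileext = ".csv")
  write_diagram(list(d0, d1), f)
  back <- read.csv(f)
  expect_equal(nrow(back), 4L)
  expect_equal(back$lifespan, back$death - back$birth)
  expect_equal(sort(unique(back$dim)), c(0L, 1L))
  unlink(f)
})
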