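test_that("the 4-step enumeration reproduces the worked example exactly", {
  t4 <- isaw_table(4)
  expect_equal(sum(t4$count), 121)
  expect_equal(sum(t4$count[t4$m == 1]), 32)
  expect_equal(sum(t4$count[t4$m == 0]), 89)
  expect_equal(t4$count[t4$m == 1 & t4$r2 == 2], 24)
  expect_equal(t4$count[t4$m == 1 & t4$r2 == 4], 8)
})

test_that("tiny chains match hand enumeration", {
  t1 <- enumerate_isaw(1)
  expect_equal(as.data.frame(t1), data.frame(m = 0L, r2 = 1L, count = 1),
               ignore_attr = TRUE)

  # the five 2-step walks: one straight (r2 = 4), four bent (r2 = 2)
  b2 <- enumerate_isaw_naive(2)
  expect_equal(b2$r2, c(2L, 4L))
  expect_equal(b2$count, c(4, 1))

  # 25 three-step walks: 1 rod (r2=9), 12 one-bend (r2=5), 8 zigzag (r2=3),
  # 4 hooks with one contact (r2=1)
  t3 <- isaw_table(3)
  expect_equal(as.data.frame(t3),
               data.frame(m = c(0L, 0L, 0L, 1L), r2 = c(3L, 5L, 9L, 1L),
                          count = c(8, 12, 1, 4)),
               ignore_attr = TRUE)
})

test_that("reduced and brute-force enumerations agree entry by entry", {
  for (n in 2:8) {
    red <- isaw_table(n)
    brute <- enumerate_isaw_naive(n)
    expect_equal(as.data.frame(red)[c("m", "r2", "count")],
                 as.data.frame(brute)[c("m", "r2", "count")],
                 info = paste("n =", n))
  }
})

test_that("totals match the known self-avoiding-walk counts", {
  for (n in c(4, 6, 9, 11)) {
    expect_equal(sum(isaw_table(n)$count), SAW_COUNTS[n] / 6,
                 info = paste("n =", n))
  }
})

test_that("lattice parity, range and monotonicity invariants hold", {
  prev_total <- 0
  for (n in 2:10) {
    t <- isaw_table(n)
    expect_true(all((t$r2 - n) %% 2 == 0), info = paste("parity, n =", n))
    expect_true(all(t$r2 >= 1 & t$r2 <= n^2), info = paste("range, n =", n))
    # the straight rod is the unique walk with r2 = N^2, and it has no contact
    rod <- t[t$r2 == n^2, ]
    expect_equal(rod$count, 1)
    expect_equal(rod$m, 0L)
    total <- sum(t$count)
    expect_gt(total, prev_total)
    prev_total <- total
  }
})

test_that("prefix jobs partition the walk space with multiplicities 1/4/8", {
  jobs2 <- isaw_prefixes(2)
  expect_equal(nrow(jobs2), 2)
  expect_setequal(jobs2$multiplicity, c(1L, 4L))

  jobs4 <- isaw_prefixes(4)
  expect_equal(nrow(jobs4), 22)
  expect_true(all(jobs4$multiplicity %in% c(1L, 4L, 8L)))
  # orbit weights recover the 121 four-step walks
  expect_equal(sum(jobs4$multiplicity), 121)

  expect_error(isaw_prefixes(1), "depth")
})

test_that("merging prefix jobs reproduces single-pass enumeration exactly", {
  for (depth in 2:4) {
    jobs <- isaw_prefixes(depth)
    parts <- lapply(jobs$sites, enumerate_prefix_job, n_steps = 7)
    merged <- merge_coef_tables(parts, jobs$multiplicity)
    expect_identical(merged$count, isaw_table(7)$count,
                     info = paste("depth =", depth))
    expect_identical(merged$m, isaw_table(7)$m)
  }
  # merge of a depth-2 split also equals the independent brute-force count
  jobs <- isaw_prefixes(2)
  parts <- lapply(jobs$sites, enumerate_prefix_job, n_steps = 8)
  merged <- merge_coef_tables(parts, jobs$multiplicity)
  expect_equal(merged$count, enumerate_isaw_naive(8)$count)
})

test_that("prefix-depth splitting inside enumerate_isaw is transparent", {
  direct <- isaw_table(6)
  for (d in c(2, 4, 6)) {
    split <- enumerate_isaw(6, prefix_depth = d)
    expect_identical(split$count, direct$count, info = paste("depth", d))
  }
})

test_that("merge validates inputs", {
  expect_error(merge_coef_tables(list()), "nonempty")
  expect_error(merge_coef_tables(list(isaw_table(3), isaw_table(4))),
               "same `n_steps`")
  one <- merge_coef_tables(list(isaw_table(5)))
  expect_identical(one$count, isaw_table(5)$count)
})

test_that("invalid chain lengths are rejected", {
  expect_error(enumerate_isaw(0), "n_steps")
  expect_error(enumerate_isaw(-3), "n_steps")
  expect_error(enumerate_isaw(5.5), "n_steps")
  expect_error(enumerate_isaw_naive(11), "oracle")
  expect_error(enumerate_isaw(4, prefix_depth = 5), "exceed")
})
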