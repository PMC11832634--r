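test_that("generation is fully reproducible from the seed", {
  cfg <- generator_config(length = 60, seed = 123)
  a <- sample_protein(cfg)
  b <- sample_protein(cfg)
  expect_identical(a, b)
  c2 <- sample_protein(generator_config(length = 60, seed = 124))
  expect_false(identical(a$systems, c2$systems))
})

test_that("sampled shifts follow the configured type statistics", {
  cfg <- generator_config(sequence = rep("A", 1000),
                          noise = c(HN = 0, N = 0, C = 0, CA = 0, CB = 0),
                          seed = 99)
  sp <- sample_protein(cfg)
  st <- default_statistics()
  ca <- st[st$type == "A" & st$feature == "CA", ]
  # CLT bound: sample mean within 4 sd / sqrt(n)
  expect_lt(abs(mean(sp$systems$CA) - ca$mean), 4 * ca$sd / sqrt(1000))
  expect_equal(stats::sd(sp$systems$CA), ca$sd, tolerance = 0.15)
})

test_that("chemistry constraints hold: no proline systems, no glycine CB", {
  cfg <- generator_config(length = 150, seed = 31)
  sp <- sample_protein(cfg)
  expect_false(any(sp$systems$res_type == "P"))
  expect_equal(nrow(sp$systems), sum(sp$sequence != "P"))
  g <- sp$systems[sp$systems$res_type == "G", ]
  expect_gt(nrow(g), 0)
  expect_true(all(is.na(g$CB)))
  expect_true(all(is.na(g$TC1_CB)))
})

test_that("noise-free generation closes the TC loop exactly", {
  cfg <- generator_config(length = 80, seed = 17,
                          noise = c(HN = 0, N = 0, C = 0, CA = 0, CB = 0))
  sp <- sample_protein(cfg)
  tcs <- tc_table(sp$systems_by_temperature, cfg$temperatures)
  truth <- sp$truth[!is.na(sp$truth$id), ]
  for (iv in 1:2) {
    sub <- tcs[tcs$interval == iv & !is.na(tcs$tc), ]
    want <- truth[[paste0("tc", iv)]][
      match(paste(sub$id, sub$nucleus),
            paste(truth$id, truth$nucleus))]
    expect_equal(sub$tc, want, tolerance = 1e-9)
  }
})

test_that("benchmark splits follow the documented rounding rule", {
  set.seed(1)
  seqn <- sample(c(rep("P", 26), rep("G", 28),
                   sample(setdiff(c("A","C","D","E","F","H","I","K","L","M",
                                    "N","Q","R","S","T","V","W","Y"),
                                  NULL), 185, replace = TRUE)))
  cfg <- generator_config(sequence = seqn, seed = 5)
  n_assignable <- sum(seqn != "P")  # 213
  f <- 141 / n_assignable
  bm <- make_benchmark(cfg, n_train_fraction = f, ambiguous_fraction = 0.2)
  expect_equal(nrow(bm$train), round(f * n_assignable))
  expect_equal(nrow(bm$train), 141)
  expect_equal(nrow(bm$query), round(0.2 * n_assignable))
  expect_true(all(is.na(bm$query$res_type)))
  expect_error(make_benchmark(cfg, 0.999, 0.5), "degenerate")
  expect_error(make_benchmark(cfg, 0.5, 0), "fractions")
})

test_that("extracted chains sit between prolines, breaks or termini", {
  cfg <- generator_config(length = 239, seed = 7)
  bm <- make_benchmark(cfg, 0.6, 0.4)
  expect_gt(length(bm$chains), 0)
  id2num <- setNames(bm$systems$res_num, bm$systems$id)
  for (ch in bm$chains) {
    nums <- id2num[ch$ids]
    expect_equal(as.integer(nums), seq(nums[1], length.out = length(nums)))
    a <- unname(nums[1]); b <- unname(nums[length(nums)])
    if (ch$left_boundary == "proline")
      expect_equal(bm$sequence[a - 1], "P")
    if (ch$left_boundary == "terminus") expect_equal(a, c(1))
    if (ch$right_boundary == "proline")
      expect_equal(bm$sequence[b + 1], "P")
  }
})

test_that("the packaged statistics table has the expected structure", {
  st <- default_statistics()
  types <- unique(st$type)
  expect_length(types, 20)
  expect_true(all(st$sd > 0))
  shift_rows <- st[st$feature %in% c("HN", "N", "C", "CA", "CB"), ]
  expect_equal(nrow(shift_rows), 20 * 5 - 2)  # G lacks CB, P lacks HN
  expect_equal(nrow(st[st$type == "G" & grepl("CB", st$feature), ]), 0)
  expect_equal(nrow(st[st$type == "P" & grepl("HN", st$feature), ]), 0)
})

test_that("uninformative TCs neither help nor hurt typing", {
  set.seed(77)
  st <- benchmark_statistics(tied_pairs = NULL)
  aa18 <- unique(st$type)
  accs <- replicate(3, NA_real_, simplify = FALSE)
  for (r in 1:3) {
    seqn <- sample(rep(aa18, 20))
    cfg <- generator_config(sequence = seqn, stats = st, seed = 100 + r)
    sp <- sample_protein(cfg)
    sys <- sp$systems
    tr <- sys[seq(1, nrow(sys), 2), ]
    te <- sys[seq(2, nrow(sys), 2), ]
    acc <- vapply(c("iv", "v"), function(ss) {
      m <- tclda(tr, subset_preset(ss))
      mean(predict(m, te, type = "class") == te$res_type)
    }, numeric(1))
    accs[[r]] <- acc
  }
  diffs <- vapply(accs, function(a) a[["v"]] - a[["iv"]], numeric(1))
  expect_lt(max(abs(diffs)), 0.05)
})

test_that("shift-tied classes are separated only when TCs are informative", {
  set.seed(88)
  st <- benchmark_statistics()  # K/Q and I/V tied in shifts, 3 sd TC gap
  seqn <- sample(rep(unique(st$type), 24))
  cfg <- generator_config(sequence = seqn, stats = st, seed = 42)
  sys <- sample_protein(cfg)$systems
  tr <- sys[seq(1, nrow(sys), 2), ]
  te <- sys[seq(2, nrow(sys), 2), ]
  tied <- te$res_type %in% c("K", "Q", "I", "V")
  acc_cs <- mean(predict(tclda(tr, subset_preset("iv")),
                         te[tied, ], type = "class") == te$res_type[tied])
  acc_tc <- mean(predict(tclda(tr, subset_preset("v")),
                         te[tied, ], type = "class") == te$res_type[tied])
  expect_gt(acc_tc, acc_cs)
  expect_lt(acc_cs, 0.75)   # shift-identical pairs: near coin flip
  expect_gt(acc_tc, 0.8)
})
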